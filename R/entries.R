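#' Shift-database entries
#'
#' An entry bundles one protein: its identifier, residue sequence (codes in
#' the 23-letter alphabet), solution pH, optional per-residue Q3 secondary
#' structure labels, and a table of assigned chemical shifts.
#'
#' @param entry_id unique identifier.
#' @param sequence character vector of residue-state codes (see
#'   [residue_state()]).
#' @param records `data.frame`/`data.table` with columns `res_index`
#'   (1-based), `atom`, `shift` (ppm).
#' @param ph solution pH (default 6.4).
#' @param q3 optional character vector of per-residue labels in
#'   `{"H","E","C"}`, same length as `sequence`.
#' @return a `cs_entry` object.
#' @export
cs_entry <- function(entry_id, sequence, records, ph = 6.4, q3 = NULL) {
  stopifnot(is.character(entry_id), length(entry_id) == 1L,
            length(sequence) >= 1L)
  bad <- setdiff(unique(sequence), ALPHABET23)
  if (length(bad))
    stop("entry ", entry_id, ": unknown residue code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  records <- data.table::as.data.table(records)
  req <- c("res_index", "atom", "shift")
  if (!all(req %in% names(records)))
    stop("records must have columns res_index, atom, shift", call. = FALSE)
  records <- records[, req, with = FALSE]
  records[, res_index := as.integer(res_index)]
  records[, shift := as.numeric(shift)]
  if (nrow(records)) {
    if (any(records$res_index < 1L | records$res_index > length(sequence)))
      stop("entry ", entry_id, ": record residue_index outside sequence",
           call. = FALSE)
    if (!all(is.finite(records$shift)))
      stop("entry ", entry_id, ": non-finite shift value", call. = FALSE)
  }
  if (!is.null(q3)) {
    if (length(q3) != length(sequence))
      stop("entry ", entry_id, ": q3 length != sequence length", call. = FALSE)
    bad <- setdiff(unique(q3), c("H", "E", "C"))
    if (length(bad))
      stop("entry ", entry_id, ": q3 labels must be H/E/C", call. = FALSE)
  }
  structure(list(entry_id = entry_id, sequence = sequence, ph = ph,
                 q3 = q3, records = records),
            class = "cs_entry")
}

#' @export
print.cs_entry <- function(x, ...) {
  cat(sprintf("<cs_entry> %s: %d residues, %d shifts, pH %.1f%s\n",
              x$entry_id, length(x$sequence), nrow(x$records), x$ph,
              if (is.null(x$q3)) "" else ", Q3-labelled"))
  invisible(x)
}

# Flat records table with sequence context (neighbour residues at +/-1, +/-2)
# and the record's Q3 label when the entry carries one.
as_records_table <- function(entries) {
  lst <- lapply(entries, function(e) {
    if (!nrow(e$records)) return(NULL)
    L <- length(e$sequence)
    ctx <- data.table::data.table(
      pos = seq_len(L),
      res = e$sequence,
      nb_m2 = c(NA, NA, e$sequence)[seq_len(L)],
      nb_m1 = c(NA, e$sequence)[seq_len(L)],
      nb_p1 = c(e$sequence[-1], NA)[seq_len(L)],
      nb_p2 = c(e$sequence[-(1:2)], NA, NA)[seq_len(L)],
      q3 = if (is.null(e$q3)) NA_character_ else e$q3
    )
    dt <- data.table::copy(e$records)
    dt[, entry_id := e$entry_id]
    dt[, ph := e$ph]
    dt <- merge(dt, ctx, by.x = "res_index", by.y = "pos", sort = FALSE)
    dt
  })
  out <- data.table::rbindlist(lst)
  if (!nrow(out))
    stop("no shift records in the supplied entries", call. = FALSE)
  out
}

#' Read a shift database
#'
#' Two plain-text formats are supported.
#'
#' **tsv** -- one row per value with columns `entry_id`, `res_index`,
#' `res_letter`, `variant`, `atom`, `shift_ppm`, and optionally `ph`, `q3`.
#' Rows with `atom == "SEQ"` declare the sequence (one per position,
#' `shift_ppm` empty or NA) so that positions without assigned shifts are
#' still known; shift rows must agree with the declared sequence.
#'
#' **nmrstar_lite** -- a minimal NMR-STAR-style reader covering the
#' `_Atom_chem_shift` loop (tags `Entity_assembly_ID`/`Entry_ID` optional;
#' `Seq_ID`, `Comp_ID`, `Atom_ID`, `Val` required).  Unknown tags are
#' ignored; the sequence is reconstructed from `Comp_ID`.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"nmrstar_lite"`.
#' @return list of [cs_entry()] objects.
#' @export
read_entries <- function(path, format = c("tsv", "nmrstar_lite")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         tsv = read_entries_tsv(path),
         nmrstar_lite = read_entries_star(path))
}

read_entries_tsv <- function(path) {
  # tolerate '#'-prefixed provenance headers above the column header
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                          colClasses = list(character = "entry_id"),
                          na.strings = c("", "NA"))
  req <- c("entry_id", "res_index", "res_letter", "variant", "atom",
           "shift_ppm")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("malformed TSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"ph" %in% names(dt)) dt[, ph := 6.4]
  if (!"q3" %in% names(dt)) dt[, q3 := NA_character_]
  dt[is.na(variant), variant := "none"]
  dt[is.na(ph), ph := 6.4]
  bad <- which(!dt$res_letter %in% AA20)
  if (length(bad))
    stop("malformed row ", bad[1] + 1L, " in ", path,
         ": unknown residue letter '", dt$res_letter[bad[1]], "'",
         call. = FALSE)
  bad <- which(dt$atom != "SEQ" & !is.finite(dt$shift_ppm))
  if (length(bad))
    stop("malformed row ", bad[1] + 1L, " in ", path,
         ": missing shift value", call. = FALSE)
  dt[, res := mapply(residue_state, res_letter, variant, USE.NAMES = FALSE)]

  blocks <- rle(dt$entry_id)$values
  if (anyDuplicated(blocks))
    stop("duplicate entry_id in ", path, ": ",
         blocks[duplicated(blocks)][1], call. = FALSE)
  ids <- unique(dt$entry_id)
  entries <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- dt[entry_id == ids[k]]
    seq_rows <- sub[atom == "SEQ"]
    if (!nrow(seq_rows))
      stop("entry ", ids[k], ": no SEQ rows declaring the sequence",
           call. = FALSE)
    if (anyDuplicated(seq_rows$res_index))
      stop("entry ", ids[k], ": duplicate SEQ row", call. = FALSE)
    L <- max(seq_rows$res_index)
    if (!setequal(seq_rows$res_index, seq_len(L)))
      stop("entry ", ids[k], ": SEQ rows do not cover positions 1..", L,
           call. = FALSE)
    data.table::setorder(seq_rows, res_index)
    sequence <- seq_rows$res
    q3 <- if (all(!is.na(seq_rows$q3))) seq_rows$q3 else NULL
    shifts <- sub[atom != "SEQ"]
    if (nrow(shifts)) {
      mism <- which(sequence[shifts$res_index] != shifts$res)
      if (length(mism))
        stop("entry ", ids[k], ": residue mismatch at index ",
             shifts$res_index[mism[1]], " (sequence has ",
             sequence[shifts$res_index[mism[1]]], ", row has ",
             shifts$res[mism[1]], ")", call. = FALSE)
    }
    entries[[k]] <- cs_entry(
      ids[k], sequence,
      shifts[, .(res_index, atom, shift = shift_ppm)],
      ph = sub$ph[1], q3 = q3)
  }
  entries
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

read_entries_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  # entry id from the data block
  blk <- grep("^data_", lines, value = TRUE)
  entry_id <- if (length(blk)) sub("^data_", "", blk[1]) else
    tools::file_path_sans_ext(basename(path))
  ph <- 6.4
  ph_line <- grep("_Sample_condition.*pH|_pH\\b", lines, value = TRUE,
                  ignore.case = TRUE)
  if (length(ph_line)) {
    v <- suppressWarnings(as.numeric(sub(".*\\s", "", ph_line[1])))
    if (is.finite(v)) ph <- v
  }
  loops <- which(lines == "loop_")
  for (start in loops) {
    i <- start + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("_Atom_chem_shift", tags))) next
    want <- function(nm) {
      hit <- grep(paste0("\\.", nm, "$"), tags)
      if (!length(hit)) stop("NMR-STAR loop missing tag ", nm, call. = FALSE)
      hit[1]
    }
    i_seq <- want("Seq_ID"); i_comp <- want("Comp_ID")
    i_atom <- want("Atom_ID"); i_val <- want("Val")
    rows <- list()
    while (i <= length(lines) && !lines[i] %in% c("stop_", "loop_") &&
           nzchar(lines[i])) {
      f <- strsplit(lines[i], "\\s+")[[1]]
      if (length(f) >= max(i_seq, i_comp, i_atom, i_val))
        rows[[length(rows) + 1L]] <-
          list(seq = as.integer(f[i_seq]), comp = toupper(f[i_comp]),
               atom = f[i_atom], val = as.numeric(f[i_val]))
      i <- i + 1L
    }
    if (!length(rows)) stop("empty _Atom_chem_shift loop in ", path,
                            call. = FALSE)
    dt <- data.table::rbindlist(rows)
    letters1 <- AA3TO1[dt$comp]
    if (anyNA(letters1))
      stop("unknown residue name in ", path, ": ",
           dt$comp[which(is.na(letters1))[1]], call. = FALSE)
    L <- max(dt$seq)
    sequence <- rep(NA_character_, L)
    sequence[dt$seq] <- letters1
    if (anyNA(sequence))
      stop("entry ", entry_id, ": positions without any assigned atom; ",
           "sequence cannot be reconstructed", call. = FALSE)
    return(list(cs_entry(entry_id, sequence,
                         data.table::data.table(res_index = dt$seq,
                                                atom = dt$atom,
                                                shift = dt$val),
                         ph = ph)))
  }
  stop("no _Atom_chem_shift loop found in ", path, call. = FALSE)
}

#' Write entries in the package TSV dialect
#'
#' Emits SEQ rows for every position followed by one row per shift value;
#' [read_entries()] reads the result back.
#'
#' @param entries list of `cs_entry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_entries_tsv <- function(entries, path) {
  rows <- lapply(entries, function(e) {
    L <- length(e$sequence)
    parent <- residue_parent(e$sequence)
    vnames <- names(VARIANT_CODES)[match(e$sequence, VARIANT_CODES)]
    seq_rows <- data.table::data.table(
      entry_id = e$entry_id, res_index = seq_len(L), res_letter = parent,
      variant = ifelse(is.na(vnames), "none", vnames),
      atom = "SEQ", shift_ppm = NA_real_, ph = e$ph,
      q3 = if (is.null(e$q3)) NA_character_ else e$q3)
    if (!nrow(e$records)) return(seq_rows)
    rec <- data.table::copy(e$records)
    rec[, entry_id := e$entry_id]
    rec[, res_letter := parent[res_index]]
    rec[, variant := seq_rows$variant[res_index]]
    rec[, ph := e$ph]
    rec[, q3 := if (is.null(e$q3)) NA_character_ else e$q3[res_index]]
    rbind(seq_rows,
          rec[, .(entry_id, res_index, res_letter, variant, atom,
                  shift_ppm = shift, ph, q3)])
  })
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named list of residue-code character vectors.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("empty FASTA file: ", path, call. = FALSE)
  out <- lapply(seq_along(aa), function(k) {
    s <- strsplit(toupper(as.character(aa[[k]])), "")[[1]]
    bad <- setdiff(unique(s), AA20)
    if (length(bad))
      stop("FASTA record '", names(aa)[k], "': non-standard letter(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    s
  })
  names(out) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  out
}
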