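#' Predict chemical shifts of a disordered sequence
#'
#' Assembles the full predictor: for residue i and atom A,
#' CS = primary expectation + (1/N_W) * sum over offsets -2, -1, +1, +2 of
#' w * ddelta for the neighbours present.  Missing neighbours at the chain
#' termini contribute no term; chemically absent atoms (glycine CB, proline
#' amide H) are skipped silently; (residue, atom) categories absent from
#' the model are omitted with a flag.
#'
#' @param sequence character vector of residue-state codes, or a single
#'   string of one-letter codes.
#' @param model a trained `cs_kernel_model`.
#' @param atoms atom types to predict; default all atoms in the model.
#' @return a `cs_prediction` `data.table` with columns `res_index`, `res`,
#'   `atom`, `primary`, `correction`, `shift`, `flag_averaged`,
#'   `flag_missing_neighbor` (`shift = primary + correction` exactly).
#' @export
predict_idp <- function(sequence, model, atoms = NULL) {
  stopifnot(inherits(model, "cs_kernel_model"))
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(sequence), ALPHABET23)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(atoms)) atoms <- unique(model$primary$atom)
  L <- length(sequence)
  ctx1 <- data.table::data.table(
    res_index = seq_len(L), res = sequence,
    nb_m2 = c(NA, NA, sequence)[seq_len(L)],
    nb_m1 = c(NA, sequence)[seq_len(L)],
    nb_p1 = c(sequence[-1], NA)[seq_len(L)],
    nb_p2 = c(sequence[-(1:2)], NA, NA)[seq_len(L)])
  ctx <- data.table::rbindlist(lapply(atoms, function(a) {
    dt <- data.table::copy(ctx1); dt[, atom := a]; dt
  }))
  ctx <- ctx[atom_exists(res, atom)]
  comp <- eq4_components(model, ctx)
  dropped <- comp[flag_no_model == TRUE]
  if (nrow(dropped))
    warning(nrow(dropped), " (residue, atom) cell(s) absent from the ",
            "model were omitted", call. = FALSE)
  comp <- comp[flag_no_model == FALSE]
  nw <- model$n_w[comp$atom]
  nw[is.na(nw)] <- 1
  out <- comp[, .(res_index, res, atom, primary)]
  out[, correction := comp$corr / nw]
  out[, shift := primary + correction]
  out[, flag_averaged := comp$flag_averaged]
  out[, flag_missing_neighbor := comp$flag_missing_nb]
  data.table::setorder(out, res_index, atom)
  data.table::setattr(out, "class",
                      c("cs_prediction", class(out)))
  out[]
}

#' Predict shifts for every record of a FASTA file
#'
#' @param path FASTA file of amino-acid sequences (standard 20 letters; a
#'   variant sidecar can be applied with [apply_variant_sidecar()]).
#' @param model trained `cs_kernel_model`.
#' @param atoms atoms to predict (default: all in the model).
#' @return named list of `cs_prediction` tables, one per record.
#' @export
predict_from_fasta <- function(path, model, atoms = NULL) {
  seqs <- read_fasta_sequences(path)
  lapply(seqs, predict_idp, model = model, atoms = atoms)
}

#' Apply per-position variant overrides to a sequence
#'
#' FASTA cannot carry residue variants; a sidecar TSV with columns
#' `res_index`, `variant` upgrades individual positions (e.g. cysteines to
#' the oxidised state).
#'
#' @param sequence residue-code vector.
#' @param path sidecar TSV.
#' @return modified sequence.
#' @export
apply_variant_sidecar <- function(sequence, path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("res_index", "variant") %in% names(dt)))
  for (k in seq_len(nrow(dt))) {
    i <- dt$res_index[k]
    if (i < 1 || i > length(sequence))
      stop("variant sidecar index ", i, " outside sequence", call. = FALSE)
    sequence[i] <- residue_state(residue_parent(sequence[i]), dt$variant[k])
  }
  sequence
}

#' Write a prediction table as TSV
#'
#' @param pred a `cs_prediction`.
#' @param path output file.
#' @param header optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(pred, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  out <- data.table::copy(pred)
  out[, flags := paste0(ifelse(flag_averaged, "a", ""),
                        ifelse(flag_missing_neighbor, "t", ""))]
  data.table::setnames(out, "shift", "shift_ppm")
  writeLines(paste(c("res_index", "res", "atom", "shift_ppm", "primary",
                     "correction", "flags"), collapse = "\t"), con)
  apply(out[, .(res_index, res, atom, shift_ppm, primary, correction,
                flags)], 1L,
        function(r) writeLines(paste(r, collapse = "\t"), con))
  invisible(path)
}

#' Write a TALOS-style shift table
#'
#' Standard `DATA SEQUENCE` header plus `VARS`/`FORMAT` lines and one row
#' per (residue, atom) prediction, for interoperability with tools that
#' consume TALOS input.
#'
#' @param pred a `cs_prediction`.
#' @param sequence the predicted sequence (residue codes).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_talos <- function(pred, sequence, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seq1 <- paste(residue_parent(sequence), collapse = "")
  chunks <- substring(seq1, seq(1, nchar(seq1), 10),
                      pmin(seq(10, nchar(seq1) + 9, 10), nchar(seq1)))
  for (i in seq(1, length(chunks), 5))
    writeLines(paste("DATA SEQUENCE",
                     paste(chunks[i:min(i + 4, length(chunks))],
                           collapse = " ")), con)
  writeLines("", con)
  writeLines("VARS   RESID RESNAME ATOMNAME SHIFT", con)
  writeLines("FORMAT %4d   %1s     %4s      %8.3f", con)
  writeLines("", con)
  for (k in seq_len(nrow(pred)))
    writeLines(sprintf("%4d %1s %4s %8.3f", pred$res_index[k],
                       residue_parent(pred$res[k]), pred$atom[k],
                       pred$shift[k]), con)
  invisible(path)
}
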