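#' Database curation
#'
#' Three filters turn a raw shift collection into a training set:
#' redundancy removal by greedy identity clustering, per-entry referencing
#' quality control, and per-value outlier removal.  The reference centres
#' and spreads used by the last two are computed from the collection itself
#' per (atom, residue) category -- and per Q3 state when labels exist --
#' so no external distribution tables are required.
#'
#' @name curation
NULL

# Global (Needleman-Wunsch) identity between two residue-code sequences:
# match = 1, mismatch = 0, gap = -1 (alignment only);
# identity = matches / alignment columns (gaps count as columns).
# Variants compare by their parent residue.
seq_identity <- function(s1, s2) {
  a <- paste(residue_parent(s1), collapse = "")
  b <- paste(residue_parent(s2), collapse = "")
  mat <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  diag(mat) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Greedy identity clustering
#'
#' Entries are visited in order of decreasing record count (ties broken by
#' `entry_id`); an entry is kept iff its global pairwise identity to every
#' already-kept entry does not exceed `max_identity`.  Deterministic.
#'
#' @param entries list of [cs_entry()].
#' @param max_identity identity threshold in (0, 1); default 0.9.
#' @return list with `kept` (entries) and `report` (`data.table` of removed
#'   entries with the identity and the representative that shadowed them).
#' @export
cluster_by_identity <- function(entries, max_identity = 0.9) {
  if (!length(entries)) stop("no entries supplied", call. = FALSE)
  stopifnot(max_identity > 0, max_identity < 1)
  nrec <- vapply(entries, function(e) nrow(e$records), 0L)
  ids <- vapply(entries, function(e) e$entry_id, "")
  ord <- order(-nrec, ids)
  kept <- list()
  removed <- list()
  for (k in ord) {
    e <- entries[[k]]
    shadow <- NA_character_; ident <- NA_real_
    for (r in kept) {
      id_rk <- seq_identity(e$sequence, r$sequence)
      if (id_rk > max_identity) { shadow <- r$entry_id; ident <- id_rk; break }
    }
    if (is.na(shadow)) kept[[length(kept) + 1L]] <- e
    else removed[[length(removed) + 1L]] <-
        data.table::data.table(entry_id = e$entry_id, reason = "identity",
                               identity = ident, representative = shadow)
  }
  list(kept = kept,
       report = if (length(removed)) data.table::rbindlist(removed)
       else data.table::data.table(entry_id = character(),
                                   reason = character(),
                                   identity = numeric(),
                                   representative = character()))
}

#' Expected shift distribution centres and spreads
#'
#' Per (atom, residue) -- and per Q3 state when `use_q3` and labels exist --
#' the centre is the kernel-density expectation ([expected_shift()]) and the
#' spread the sample standard deviation.
#'
#' @param entries list of entries.
#' @param use_q3 condition on Q3 labels when present (default TRUE).
#' @param n_min_mean mode/mean threshold passed to [expected_shift()].
#' @return `data.table` with columns `atom`, `res`, `q3`, `center`, `sdev`,
#'   `n_obs`.
#' @export
expected_centers <- function(entries, use_q3 = TRUE, n_min_mean = 50) {
  rec <- as_records_table(entries)
  if (!use_q3) rec[, q3 := NA_character_]
  rec[, .(center = {
    d <- build_density(shift, floor = bw_floor_for(atom[1]))
    expected_shift(d, n_min_mean)
  }, sdev = stats::sd(shift), n_obs = .N),
  by = .(atom, res, q3)]
}

#' Referencing quality control for one entry
#'
#' Mis-referencing displaces every shift of a nucleus by a constant.  Per
#' nucleus (13C, 1H, 15N, inferred from the atom name), the offset is the
#' mean of (observed - expected centre) over the entry's records; the entry
#' fails if any |offset| exceeds its tolerance.  Default tolerances:
#' 1.5 ppm (13C), 0.5 ppm (1H), 3.5 ppm (15N).
#'
#' @param entry a [cs_entry()].
#' @param expected centres table from [expected_centers()].
#' @param tolerances named vector, names `13C`, `1H`, `15N` (ppm).
#' @return list: `pass` (logical), `offsets` (`data.table` per nucleus with
#'   offset, tolerance, n, skipped flag).
#' @export
referencing_qc <- function(entry, expected,
                           tolerances = c(`13C` = 1.5, `1H` = 0.5,
                                          `15N` = 3.5)) {
  rec <- as_records_table(list(entry))
  by_q3 <- any(!is.na(expected$q3))
  if (!by_q3) rec[, q3 := NA_character_]
  rec <- merge(rec, expected[, .(atom, res, q3, center)],
               by = c("atom", "res", "q3"), all.x = TRUE, sort = FALSE)
  rec <- rec[!is.na(center)]
  rec[, nucleus := atom_nucleus(atom)]
  res <- rec[, .(offset = mean(shift - center), n = .N), by = nucleus]
  all_nuc <- data.table::data.table(nucleus = names(tolerances),
                                    tolerance = unname(tolerances))
  res <- merge(all_nuc, res, by = "nucleus", all.x = TRUE)
  res[, skipped := is.na(offset)]
  pass <- res[!(skipped), all(abs(offset) <= tolerance)]
  list(pass = isTRUE(pass), offsets = res[])
}

#' Remove individual outlier shift values
#'
#' Drops any value more than `z_max` standard deviations from its category
#' centre.  Categories with zero or undefined spread are skipped (logged in
#' the returned report).
#'
#' @param entries list of entries.
#' @param expected centres/spreads table from [expected_centers()].
#' @param z_max threshold in standard deviations (default 3.5).
#' @return list: `entries` (filtered), `removed` (count),
#'   `removed_fraction`, `skipped_categories` (`data.table`).
#' @export
remove_outlier_values <- function(entries, expected, z_max = 3.5) {
  stopifnot(z_max > 0)
  by_q3 <- any(!is.na(expected$q3))
  skipped <- expected[is.na(sdev) | sdev == 0, .(atom, res, q3)]
  usable <- expected[!is.na(sdev) & sdev > 0]
  total <- 0L; removed <- 0L
  out <- lapply(entries, function(e) {
    if (!nrow(e$records)) return(e)
    rec <- as_records_table(list(e))
    if (!by_q3) rec[, q3 := NA_character_]
    rec <- merge(rec, usable[, .(atom, res, q3, center, sdev)],
                 by = c("atom", "res", "q3"), all.x = TRUE, sort = FALSE)
    rec[, z := abs(shift - center) / sdev]
    keep <- is.na(rec$z) | rec$z <= z_max
    total <<- total + nrow(rec)
    removed <<- removed + sum(!keep)
    cs_entry(e$entry_id, e$sequence,
             rec[keep, .(res_index, atom, shift)], ph = e$ph, q3 = e$q3)
  })
  list(entries = out, removed = removed,
       removed_fraction = if (total) removed / total else 0,
       skipped_categories = skipped)
}

#' Full curation pipeline
#'
#' Identity clustering, then referencing QC (failing entries dropped), then
#' per-value outlier removal.  Centres are recomputed after clustering so
#' that redundant entries do not dominate the reference distributions.
#' The pipeline is idempotent.
#'
#' @inheritParams cluster_by_identity
#' @inheritParams remove_outlier_values
#' @param tolerances referencing tolerances, see [referencing_qc()].
#' @return list: `entries`, `report` (a `cs_curation_report`).
#' @export
curate_entries <- function(entries, max_identity = 0.9,
                           tolerances = c(`13C` = 1.5, `1H` = 0.5,
                                          `15N` = 3.5),
                           z_max = 3.5) {
  n_in <- length(entries)
  cl <- cluster_by_identity(entries, max_identity)
  centers <- expected_centers(cl$kept)
  qc <- lapply(cl$kept, referencing_qc, expected = centers,
               tolerances = tolerances)
  pass <- vapply(qc, `[[`, TRUE, "pass")
  ref_removed <- data.table::data.table(
    entry_id = vapply(cl$kept[!pass], `[[`, "", "entry_id"),
    reason = rep("referencing", sum(!pass)),
    identity = NA_real_, representative = NA_character_)
  kept <- cl$kept[pass]
  if (!length(kept)) stop("curation removed every entry", call. = FALSE)
  # iterate outlier removal to a fixed point: recomputed spreads shrink
  # after each pass, and stopping at the first pass would make the
  # pipeline non-idempotent
  removed_total <- 0L
  n_before <- sum(vapply(kept, function(e) nrow(e$records), 0L))
  repeat {
    centers2 <- expected_centers(kept)
    ol <- remove_outlier_values(kept, centers2, z_max)
    removed_total <- removed_total + ol$removed
    kept <- ol$entries
    if (ol$removed == 0L) break
  }
  ol$removed <- removed_total
  ol$removed_fraction <- if (n_before) removed_total / n_before else 0
  removed_entries <- rbind(cl$report, ref_removed)
  report <- structure(list(
    entries_in = n_in, entries_out = length(ol$entries),
    removed_entries = removed_entries,
    removed_values = ol$removed,
    removed_values_fraction = ol$removed_fraction,
    skipped_categories = ol$skipped_categories), class = "cs_curation_report")
  stopifnot(report$entries_out + nrow(removed_entries) == n_in)
  list(entries = ol$entries, report = report)
}

#' @export
print.cs_curation_report <- function(x, ...) {
  cat(sprintf(
    "<curation> %d entries in, %d out (%d removed: %d identity, %d referencing); %d values dropped (%.2f%%)\n",
    x$entries_in, x$entries_out, nrow(x$removed_entries),
    sum(x$removed_entries$reason == "identity"),
    sum(x$removed_entries$reason == "referencing"),
    x$removed_values, 100 * x$removed_values_fraction))
  invisible(x)
}
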