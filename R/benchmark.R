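#' Benchmarking
#'
#' Accuracy is scored as the root-mean-square deviation between
#' experimental and calculated shifts, RMSD = sqrt(mean((exp - calc)^2)),
#' pooled over all residue pairs of an atom type.  The leave-one-out
#' protocol retrains the model once per entry with that entry excluded, so
#' no entry ever influences its own prediction.
#'
#' @name benchmarking
NULL

#' Root-mean-square deviation
#'
#' @param experimental,calculated paired numeric vectors.
#' @return RMSD (same units as the inputs).
#' @export
#' @examples
#' cs_rmsd(c(0, 0), c(3, -3))  # 3
cs_rmsd <- function(experimental, calculated) {
  stopifnot(length(experimental) == length(calculated))
  if (!length(experimental)) stop("no pairs", call. = FALSE)
  sqrt(mean((experimental - calculated)^2))
}

#' Leave-one-out benchmark
#'
#' For each entry: retrain on all other entries via `train_fn`, predict
#' the held-out entry via `predict_fn`, and accumulate
#' (experimental, calculated) pairs.  Per-atom RMSDs pool residuals across
#' entries (a single pooled sum, not a mean of per-entry RMSDs);
#' per-entry RMSDs are reported alongside for case-by-case comparisons.
#'
#' @param entries list of entries (length >= 2).
#' @param train_fn function(list of entries) -> model.
#' @param predict_fn function(model, entry) -> table with columns
#'   `res_index`, `atom`, `shift` (the prediction).
#' @param trim_ends discard this many residues from each terminus of every
#'   Q3 segment of the held-out entry before scoring (evaluation mask
#'   only; default 0; requires Q3-labelled entries when > 0).
#' @return a `cs_benchmark`: `per_atom` and `per_entry` `data.table`s,
#'   `pairs` (pooled residual table), `failed` (entry ids whose fold
#'   failed, with the error message), and protocol metadata.
#' @export
loo_benchmark <- function(entries, train_fn, predict_fn, trim_ends = 0) {
  if (length(entries) < 2L)
    stop("leave-one-out needs at least 2 entries", call. = FALSE)
  pairs <- list(); failed <- list()
  for (k in seq_along(entries)) {
    held <- entries[[k]]
    rest <- entries[-k]
    res <- tryCatch({
      model <- train_fn(rest)
      pred <- predict_fn(model, held)
      pred <- data.table::as.data.table(pred)[, .(res_index, atom, shift)]
      data.table::setnames(pred, "shift", "calc")
      obs <- data.table::copy(held$records)
      if (trim_ends > 0) {
        if (is.null(held$q3))
          stop("trim_ends requires Q3 labels", call. = FALSE)
        keep_pos <- interior_positions(held$q3, trim_ends)
        obs <- obs[res_index %in% keep_pos]
      }
      merge(obs, pred, by = c("res_index", "atom"))[
        , .(entry_id = held$entry_id, res_index, atom, exp = shift, calc)]
    }, error = function(e)
      structure(list(entry_id = held$entry_id,
                     message = conditionMessage(e)), class = "fold_error"))
    if (inherits(res, "fold_error")) failed[[length(failed) + 1L]] <- res
    else pairs[[length(pairs) + 1L]] <- res
  }
  if (!length(pairs)) stop("every fold failed", call. = FALSE)
  pooled <- data.table::rbindlist(pairs)
  structure(list(
    per_atom = pooled[, .(rmsd = cs_rmsd(exp, calc), n = .N), by = atom],
    per_entry = pooled[, .(rmsd = cs_rmsd(exp, calc), n = .N),
                       by = entry_id],
    pairs = pooled,
    failed = if (length(failed))
      data.table::rbindlist(lapply(failed, function(f)
        data.table::data.table(entry_id = f$entry_id,
                               message = f$message)))
    else data.table::data.table(entry_id = character(),
                                message = character()),
    protocol = list(leave_one_out = TRUE, trim_ends = trim_ends,
                    n_entries = length(entries))),
    class = "cs_benchmark")
}

# positions more than `trim` residues from both ends of their Q3 segment
interior_positions <- function(q3_labels, trim) {
  seg <- q3_segments(q3_labels)
  pos <- seq_along(q3_labels)
  si <- findInterval(pos, seg$start)
  pos[(pos - seg$start[si] + 1L > trim) & (seg$end[si] - pos + 1L > trim)]
}

#' @export
print.cs_benchmark <- function(x, ...) {
  cat(sprintf("<cs_benchmark> %d entries (LOO%s), %d failed fold(s)\n",
              x$protocol$n_entries,
              if (x$protocol$trim_ends > 0)
                paste0(", trim ", x$protocol$trim_ends) else "",
              nrow(x$failed)))
  print(x$per_atom)
  invisible(x)
}
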