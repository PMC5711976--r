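#' Secondary-structure handling and the folded-protein predictor
#'
#' Folded proteins are predicted with the same kernel machinery as
#' disordered ones, but conditioned on three-state (Q3) secondary
#' structure: separate kernel models for helix, strand and coil, an
#' empirical profile of secondary shifts around segment boundaries, and an
#' additive boundary correction within a configurable half-window of every
#' boundary.
#'
#' @name q3-prediction
NULL

Q3_STATE_NAME <- c(H = "helix", E = "strand", C = "coil")

#' Collapse 8-state secondary structure to Q3
#'
#' DSSP-style letters map as: H, G (alpha and 3-10 helix) to H; E to E;
#' everything else (I, B, T, S, `-`, space, C) to C.  Input that is already
#' 3-state passes through unchanged (the mapping is idempotent).
#'
#' @param labels a single string or character vector of per-residue labels.
#' @return a `cs_q3` object: list with `labels` (H/E/C vector) and
#'   `segments` (`data.table` of `start`, `end`, `label`, 1-based
#'   inclusive).
#' @export
#' @examples
#' merge_to_q3("HHHGGGEEBTTS--")$labels
merge_to_q3 <- function(labels) {
  if (length(labels) == 1L && nchar(labels) > 1L)
    labels <- strsplit(labels, "")[[1]]
  map <- c(H = "H", G = "H", E = "E", I = "C", B = "C", T = "C",
           S = "C", `-` = "C", ` ` = "C", C = "C")
  out <- map[labels]
  if (anyNA(out))
    stop("unknown secondary-structure letter(s): ",
         paste(unique(labels[is.na(out)]), collapse = ", "), call. = FALSE)
  out <- unname(out)
  structure(list(labels = out, segments = q3_segments(out)),
            class = "cs_q3")
}

# run-length segmentation of a 3-state label vector
q3_segments <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.table::data.table(start = c(1L, head(end, -1L) + 1L),
                         end = end, label = r$values)
}

#' @export
print.cs_q3 <- function(x, ...) {
  cat(sprintf("<cs_q3> %d residues, %d segments (%s)\n", length(x$labels),
              nrow(x$segments),
              paste(x$segments$label, collapse = "")))
  invisible(x)
}

#' Read a psipred .ss2 secondary-structure file
#'
#' Vertical format: comment/header lines, then one line per residue with
#' index, residue letter, state (C/H/E) and three state probabilities.
#'
#' @param path .ss2 file.
#' @return character vector of Q3 labels.
#' @export
read_ss2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\\s+")
  ok <- lengths(f) >= 3
  if (!any(ok)) stop("no residue lines in ", path, call. = FALSE)
  idx <- vapply(f[ok], function(x) as.integer(x[1]), 0L)
  st <- vapply(f[ok], `[`, "", 3L)
  labels <- rep(NA_character_, max(idx))
  labels[idx] <- st
  if (anyNA(labels))
    stop("missing residue indices in ", path, call. = FALSE)
  labels
}

#' Read Q3 labels from a two-column TSV
#'
#' Columns `res_index` and `q3`.
#'
#' @param path TSV file.
#' @return character vector of labels.
#' @export
read_q3_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("res_index", "q3") %in% names(dt)))
  labels <- rep(NA_character_, max(dt$res_index))
  labels[dt$res_index] <- dt$q3
  if (anyNA(labels))
    stop("missing residue indices in ", path, call. = FALSE)
  labels
}

# records table restricted to segment interiors: positions more than
# `trim` residues from both ends of their Q3 segment
interior_records <- function(rec, entries, trim) {
  if (trim <= 0) return(rec)
  keep_list <- lapply(entries, function(e) {
    if (is.null(e$q3)) return(NULL)
    seg <- q3_segments(e$q3)
    pos <- seq_along(e$q3)
    si <- findInterval(pos, seg$start)
    ok <- (pos - seg$start[si] + 1L > trim) & (seg$end[si] - pos + 1L > trim)
    data.table::data.table(entry_id = e$entry_id, res_index = pos[ok])
  })
  keep <- data.table::rbindlist(keep_list)
  rec[keep, on = c("entry_id", "res_index"), nomatch = NULL]
}

#' Train per-state Q3 kernel models
#'
#' Each record contributes only to the model of its own Q3 state.  By
#' default the first and last `interior_trim` residues of every segment are
#' excluded from the kernel statistics so that boundary regions (handled by
#' [build_boundary_profiles()]) do not contaminate the per-state
#' expectations; neighbour context is still taken from the full sequence.
#'
#' @param entries Q3-labelled entries.
#' @param atoms atom types (default: all present).
#' @param interior_trim residues discarded from each segment terminus for
#'   the statistics (default 2; 0 disables).
#' @param ... further arguments to [train_kernel_model()] (`n_min_mean`,
#'   `n_min`, `nw_grid`, `ph_bin`, `calibrate`).
#' @return a `cs_q3_models` object: list of up to three `cs_kernel_model`s
#'   named `helix`, `strand`, `coil`.  A state with no data yields no
#'   model; prediction then falls back to coil with a warning.
#' @export
train_q3_kernels <- function(entries, atoms = NULL, interior_trim = 2, ...) {
  labelled <- Filter(function(e) !is.null(e$q3), entries)
  if (!length(labelled))
    stop("no Q3-labelled entries", call. = FALSE)
  rec <- as_records_table(labelled)
  rec_int <- interior_records(rec, labelled, interior_trim)
  models <- list()
  for (st in c("H", "E", "C")) {
    sub <- rec_int[q3 == st]
    nm <- Q3_STATE_NAME[[st]]
    if (!nrow(sub)) next
    models[[nm]] <- train_kernel_model_records(
      sub, condition = nm, atoms = atoms, ...)
  }
  if (!length(models))
    stop("no state had any training data", call. = FALSE)
  structure(list(models = models, interior_trim = interior_trim),
            class = "cs_q3_models")
}

#' @export
print.cs_q3_models <- function(x, ...) {
  cat(sprintf("<cs_q3_models> states: %s (interior trim %d)\n",
              paste(names(x$models), collapse = ", "), x$interior_trim))
  invisible(x)
}

#' Empirical secondary-shift profiles around Q3 boundaries
#'
#' The secondary shift of a record is its observed shift minus the
#' coil-state primary expectation for its (residue, atom).  For every
#' ordered transition type (e.g. `"H>C"` differs from `"C>H"`) and atom,
#' the mean and SD of the secondary shifts are collected at each signed
#' distance from the boundary: -half_window .. -1 inside the first
#' segment (-1 is its last residue) and +1 .. +half_window inside the
#' second (+1 is its first residue).
#'
#' @param entries Q3-labelled entries.
#' @param coil_model the coil-state `cs_kernel_model` (random-coil
#'   reference).
#' @param half_window residues on each side of a boundary (default 6).
#' @param interior_trim trim used for the per-state mean secondary shifts
#'   stored alongside the profiles (default 2, matching
#'   [train_q3_kernels()]).
#' @return a `cs_boundary_profile`: `profile` (`data.table` keyed by
#'   transition, atom, dist with `mean_sec`, `sdev`, `n`) and `state_sec`
#'   (per-state mean secondary shift per atom).
#' @export
build_boundary_profiles <- function(entries, coil_model, half_window = 6,
                                    interior_trim = 2) {
  stopifnot(inherits(coil_model, "cs_kernel_model"))
  labelled <- Filter(function(e) !is.null(e$q3), entries)
  if (!length(labelled)) stop("no Q3-labelled entries", call. = FALSE)
  rec <- as_records_table(labelled)
  rec <- merge(rec, coil_model$primary[, .(atom, res, center = expectation)],
               by = c("atom", "res"), all.x = TRUE, sort = FALSE)
  rec <- rec[!is.na(center)]
  rec[, sec := shift - center]

  seg_info <- data.table::rbindlist(lapply(labelled, function(e) {
    seg <- q3_segments(e$q3)
    n <- nrow(seg)
    pos <- seq_along(e$q3)
    si <- findInterval(pos, seg$start)
    data.table::data.table(
      entry_id = e$entry_id, res_index = pos,
      d_prev = pos - seg$start[si] + 1L,
      d_next = seg$end[si] - pos + 1L,
      trans_prev = ifelse(si > 1L,
                          paste0(seg$label[pmax(si - 1L, 1L)], ">",
                                 seg$label[si]), NA_character_),
      trans_next = ifelse(si < n,
                          paste0(seg$label[si], ">",
                                 seg$label[pmin(si + 1L, n)]),
                          NA_character_))
  }))
  rec <- merge(rec, seg_info, by = c("entry_id", "res_index"), sort = FALSE)

  up <- rec[!is.na(trans_prev) & d_prev <= half_window,
            .(transition = trans_prev, atom, dist = d_prev, sec)]
  dn <- rec[!is.na(trans_next) & d_next <= half_window,
            .(transition = trans_next, atom, dist = -d_next, sec)]
  prof <- rbind(up, dn)[, .(mean_sec = mean(sec), sdev = stats::sd(sec),
                            n = .N), by = .(transition, atom, dist)]
  data.table::setkey(prof, transition, atom, dist)

  rec_int <- interior_records(rec, labelled, interior_trim)
  state_sec <- rec_int[!is.na(q3),
                       .(mean_sec = mean(sec), n = .N), by = .(state = q3, atom)]
  data.table::setkey(state_sec, state, atom)
  structure(list(half_window = half_window, profile = prof,
                 state_sec = state_sec),
            class = "cs_boundary_profile")
}

#' @export
print.cs_boundary_profile <- function(x, ...) {
  cat(sprintf(
    "<cs_boundary_profile> half-window %d, %d transition types, %d cells\n",
    x$half_window, length(unique(x$profile$transition)), nrow(x$profile)))
  invisible(x)
}

#' Predict chemical shifts of a folded sequence
#'
#' Per residue, the full kernel prediction from the model of its Q3 state;
#' residues within the profile half-window of a segment boundary
#' additionally receive the boundary correction, which replaces the
#' state's mean secondary-shift contribution by the profile value at their
#' signed distance (the nearest boundary wins; ties go to the preceding
#' one).  Missing profile cells leave the prediction uncorrected, flagged.
#'
#' @param sequence residue codes (vector or single string).
#' @param q3 a `cs_q3`, or a label string/vector passed to
#'   [merge_to_q3()].
#' @param models a `cs_q3_models` set.
#' @param profiles optional `cs_boundary_profile`; `NULL` disables
#'   boundary corrections.
#' @param atoms atoms to predict.
#' @return a `cs_prediction` table with additional columns
#'   `q3`, `boundary_correction`, `flag_boundary_missing`.
#' @export
predict_folded <- function(sequence, q3, models, profiles = NULL,
                           atoms = NULL) {
  stopifnot(inherits(models, "cs_q3_models"))
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (!inherits(q3, "cs_q3")) q3 <- merge_to_q3(q3)
  if (length(q3$labels) != length(sequence))
    stop("Q3 annotation length (", length(q3$labels),
         ") != sequence length (", length(sequence), ")", call. = FALSE)

  preds <- list()
  for (st in unique(q3$labels)) {
    nm <- Q3_STATE_NAME[[st]]
    m <- models$models[[nm]]
    if (is.null(m)) {
      warning("no ", nm, " model; falling back to coil", call. = FALSE)
      m <- models$models[["coil"]]
      if (is.null(m)) stop("no coil model to fall back to", call. = FALSE)
    }
    p <- suppressWarnings(predict_idp(sequence, m, atoms = atoms))
    p <- p[res_index %in% which(q3$labels == st)]
    p[, q3 := st]
    preds[[st]] <- p
  }
  out <- data.table::rbindlist(preds)
  data.table::setorder(out, res_index, atom)
  out[, boundary_correction := 0]
  out[, flag_boundary_missing := FALSE]

  if (!is.null(profiles)) {
    stopifnot(inherits(profiles, "cs_boundary_profile"))
    hw <- profiles$half_window
    seg <- q3$segments
    n <- nrow(seg)
    pos <- seq_along(sequence)
    si <- findInterval(pos, seg$start)
    d_prev <- pos - seg$start[si] + 1L
    d_next <- seg$end[si] - pos + 1L
    has_prev <- si > 1L & d_prev <= hw
    has_next <- si < n & d_next <= hw
    use_prev <- has_prev & (!has_next | d_prev <= d_next)
    use_next <- has_next & !use_prev
    trans <- rep(NA_character_, length(pos))
    dist <- rep(NA_integer_, length(pos))
    trans[use_prev] <- paste0(seg$label[si[use_prev] - 1L], ">",
                              seg$label[si[use_prev]])
    dist[use_prev] <- d_prev[use_prev]
    trans[use_next] <- paste0(seg$label[si[use_next]], ">",
                              seg$label[si[use_next] + 1L])
    dist[use_next] <- -d_next[use_next]

    bd <- data.table::data.table(res_index = pos, transition = trans,
                                 dist = dist)
    out <- merge(out, bd, by = "res_index", all.x = TRUE, sort = FALSE)
    look <- profiles$profile[out[, .(transition, atom, dist)],
                             on = c("transition", "atom", "dist")]
    base <- profiles$state_sec[out[, .(state = q3, atom)],
                               on = c("state", "atom")]
    corr <- look$mean_sec - base$mean_sec
    in_window <- !is.na(out$transition)
    missing_cell <- in_window & (is.na(look$mean_sec) | is.na(base$mean_sec))
    corr[!in_window | missing_cell] <- 0
    out[, boundary_correction := corr]
    out[, flag_boundary_missing := missing_cell]
    out[, shift := shift + boundary_correction]
    out[, transition := NULL]
    out[, dist := NULL]
    data.table::setorder(out, res_index, atom)
  }
  data.table::setattr(out, "class",
                      unique(c("cs_prediction", class(out))))
  out[]
}
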