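#' Synthetic shift databases with known ground truth
#'
#' The generator emits entries whose shifts follow exactly the statistical
#' structure the kernel predictor assumes: a per-(residue, atom) base
#' value, additive neighbour effects over a +/-2 window (independent
#' across offsets), per-Q3-state offsets with a linear boundary ramp, and
#' Gaussian observation noise -- plus optional planted pathologies
#' (referencing offsets, outliers) for exercising the curation filters.
#' Every emitted record's noiseless value is returned as ground truth, so
#' parameter recovery and noise-floor checks are exact.
#'
#' @name synthetic-data
NULL

# Approximate random-coil base shifts (ppm) for the six common backbone
# atoms.  SYNTHETIC stand-ins on a realistic scale, not literature values:
# they anchor the generator and the round-trip tests only.
build_base_table <- function() {
  ca <- c(A = 52.5, C = 58.3, D = 54.2, E = 56.6, F = 57.7, G = 45.1,
          H = 55.0, I = 61.1, K = 56.2, L = 55.1, M = 55.4, N = 53.1,
          P = 63.3, Q = 55.7, R = 56.0, S = 58.3, T = 61.8, V = 62.2,
          W = 57.5, Y = 57.9)
  cb <- c(A = 19.1, C = 28.0, D = 41.1, E = 29.9, F = 39.6, G = NA,
          H = 29.0, I = 38.8, K = 33.1, L = 42.4, M = 32.9, N = 38.9,
          P = 32.1, Q = 29.4, R = 30.9, S = 63.8, T = 69.8, V = 32.9,
          W = 29.6, Y = 38.8)
  co <- c(A = 177.8, C = 174.6, D = 176.3, E = 176.6, F = 175.8,
          G = 174.9, H = 174.1, I = 176.4, K = 176.6, L = 177.6,
          M = 176.3, N = 175.2, P = 177.3, Q = 176.0, R = 176.3,
          S = 174.6, T = 174.7, V = 176.3, W = 176.1, Y = 175.9)
  nn <- c(A = 123.8, C = 118.8, D = 120.4, E = 120.2, F = 120.3,
          G = 108.8, H = 118.2, I = 119.9, K = 120.4, L = 121.8,
          M = 119.6, N = 118.7, P = NA, Q = 119.8, R = 120.5,
          S = 115.7, T = 113.6, V = 119.2, W = 121.3, Y = 120.3)
  hn <- c(A = 8.24, C = 8.32, D = 8.34, E = 8.42, F = 8.30, G = 8.33,
          H = 8.42, I = 8.00, K = 8.29, L = 8.16, M = 8.28, N = 8.40,
          P = NA, Q = 8.32, R = 8.23, S = 8.31, T = 8.15, V = 8.03,
          W = 8.25, Y = 8.12)
  ha <- c(A = 4.32, C = 4.55, D = 4.64, E = 4.35, F = 4.62, G = 3.96,
          H = 4.73, I = 4.17, K = 4.32, L = 4.34, M = 4.48, N = 4.74,
          P = 4.42, Q = 4.34, R = 4.34, S = 4.47, T = 4.35, V = 4.12,
          W = 4.66, Y = 4.55)
  tabs <- list(CA = ca, CB = cb, C = co, N = nn, H = hn, HA = ha)
  out <- data.table::rbindlist(lapply(names(tabs), function(a)
    data.table::data.table(atom = a, res = names(tabs[[a]]),
                           base = unname(tabs[[a]]))))
  out[!is.na(base)]
}

# Sparse planted neighbour-effect table: a few strong, chemically
# plausible effects (following proline, preceding glycine, ...), scaled by
# the per-atom noise SD so every atom type carries recoverable structure.
default_neighbor_effects <- function(noise_sd) {
  plan <- data.table::data.table(
    nb = c("P", "G", "D", "W"),
    offset = c(1L, -1L, 1L, -2L),
    mult = c(-6, 4, 3, -3))
  data.table::rbindlist(lapply(names(noise_sd), function(a) {
    data.table::data.table(atom = a, nb = plan$nb, offset = plan$offset,
                           effect = plan$mult * noise_sd[[a]])
  }))
}

default_q3_offsets <- function() {
  data.table::rbindlist(list(
    data.table::data.table(atom = "CA", state = c("H", "E", "C"),
                           offset_ppm = c(3.2, -2.0, 0)),
    data.table::data.table(atom = "CB", state = c("H", "E", "C"),
                           offset_ppm = c(-0.4, 2.2, 0)),
    data.table::data.table(atom = "C", state = c("H", "E", "C"),
                           offset_ppm = c(1.8, -1.6, 0)),
    data.table::data.table(atom = "N", state = c("H", "E", "C"),
                           offset_ppm = c(-0.95, 2.2, 0)),
    data.table::data.table(atom = "H", state = c("H", "E", "C"),
                           offset_ppm = c(-0.25, 0.35, 0)),
    data.table::data.table(atom = "HA", state = c("H", "E", "C"),
                           offset_ppm = c(-0.35, 0.45, 0))))
}

#' Build a generator configuration
#'
#' @param n_entries number of entries.
#' @param length_range integer range of chain lengths.
#' @param atoms atom types to emit.
#' @param base per-(residue, atom) base shift table (`atom`, `res`,
#'   `base`); default [build_base_table()].
#' @param neighbor_effects sparse additive effect table (`atom`, `nb`,
#'   `offset`, `effect` in ppm); `NULL` for none.
#' @param with_q3 emit Q3 labels and state offsets.
#' @param q3_offsets per-(atom, state) offsets in ppm.
#' @param min_seg_len,mean_seg_extra Q3 segment lengths are
#'   `min_seg_len + Geometric(mean = mean_seg_extra)`.
#' @param ramp_len boundary ramp length: on entering a new segment the
#'   state offset interpolates linearly from the previous segment's value
#'   over this many residues (0 disables).
#' @param noise_sd named per-atom observation noise SD (ppm), all > 0.
#' @param outlier_frac fraction of records displaced as outliers.
#' @param outlier_z outlier displacement in units of the atom's noise SD.
#' @param ref_offset_entries number of (leading) entries given a constant
#'   per-nucleus referencing offset.
#' @param ref_offset_ppm named offsets (`13C`, `1H`, `15N`) in ppm.
#' @param ph solution pH recorded on every entry.
#' @param seed RNG seed; generation is fully deterministic given the
#'   config.
#' @return a validated `cs_synth_config`.
#' @export
synth_config <- function(n_entries = 50, length_range = c(60L, 120L),
                         atoms = c("CA", "CB", "C", "N", "H", "HA"),
                         base = build_base_table(),
                         neighbor_effects = NULL,
                         with_q3 = FALSE,
                         q3_offsets = default_q3_offsets(),
                         min_seg_len = 8L, mean_seg_extra = 22,
                         ramp_len = 2L,
                         noise_sd = c(CA = 0.3, CB = 0.3, C = 0.3,
                                      N = 1.0, H = 0.05, HA = 0.05),
                         outlier_frac = 0, outlier_z = 5,
                         ref_offset_entries = 0L,
                         ref_offset_ppm = c(`13C` = 0, `1H` = 0,
                                            `15N` = 0),
                         ph = 6.4, seed = 1L) {
  stopifnot(n_entries >= 1, length(length_range) == 2L,
            length_range[1] <= length_range[2])
  miss <- setdiff(atoms, names(noise_sd))
  if (length(miss))
    stop("noise_sd missing for atom(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(noise_sd[atoms] <= 0))
    stop("noise SD must be positive", call. = FALSE)
  if (outlier_frac < 0 || outlier_frac > 1)
    stop("outlier_frac must be in [0, 1]", call. = FALSE)
  if (with_q3 && ramp_len > min_seg_len)
    stop("boundary ramp (", ramp_len, ") longer than the minimum segment (",
         min_seg_len, ")", call. = FALSE)
  structure(list(
    n_entries = as.integer(n_entries),
    length_range = as.integer(length_range), atoms = atoms,
    base = data.table::as.data.table(base),
    neighbor_effects = if (is.null(neighbor_effects)) NULL
    else data.table::as.data.table(neighbor_effects),
    with_q3 = with_q3,
    q3_offsets = data.table::as.data.table(q3_offsets),
    min_seg_len = as.integer(min_seg_len),
    mean_seg_extra = mean_seg_extra, ramp_len = as.integer(ramp_len),
    noise_sd = noise_sd, outlier_frac = outlier_frac,
    outlier_z = outlier_z,
    ref_offset_entries = as.integer(ref_offset_entries),
    ref_offset_ppm = ref_offset_ppm, ph = ph, seed = as.integer(seed)),
    class = "cs_synth_config")
}

#' CI-sized preset for a disordered-protein database
#'
#' 50 entries of 60-120 residues, six backbone atoms, noise SD 0.3 ppm
#' (13C), 0.05 ppm (1H), 1.0 ppm (15N), and the sparse strong neighbour
#' effects of [default_neighbor_effects()].  No Q3 structure.
#'
#' @param seed RNG seed.
#' @return a `cs_synth_config`.
#' @export
idp_preset <- function(seed = 1L) {
  noise <- c(CA = 0.3, CB = 0.3, C = 0.3, N = 1.0, H = 0.05, HA = 0.05)
  synth_config(n_entries = 50, length_range = c(60L, 120L),
               neighbor_effects = default_neighbor_effects(noise),
               with_q3 = FALSE, noise_sd = noise, seed = seed)
}

#' CI-sized preset for a folded-protein database
#'
#' As [idp_preset()] plus Q3 segments (minimum length 8, mean ~30),
#' per-state offsets (helix - coil CA = +3.2 ppm, N = -0.95 ppm, ...) and
#' a 2-residue linear entry ramp at every boundary.
#'
#' @param seed RNG seed.
#' @return a `cs_synth_config`.
#' @export
folded_preset <- function(seed = 1L) {
  noise <- c(CA = 0.3, CB = 0.3, C = 0.3, N = 1.0, H = 0.05, HA = 0.05)
  synth_config(n_entries = 50, length_range = c(60L, 120L),
               neighbor_effects = default_neighbor_effects(noise),
               with_q3 = TRUE, min_seg_len = 8L, mean_seg_extra = 22,
               ramp_len = 2L, noise_sd = noise, seed = seed)
}

#' Generate a synthetic shift database
#'
#' @param config a [synth_config()].
#' @return list: `entries` (list of [cs_entry()]) and `truth` (list with
#'   `records` -- the exact noiseless shift of every emitted record -- and
#'   the planted parameter tables).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "cs_synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  base <- config$base[atom %in% config$atoms]
  base_key <- stats::setNames(base$base, paste(base$atom, base$res))
  eff_key <- if (!is.null(config$neighbor_effects)) {
    e <- config$neighbor_effects
    stats::setNames(e$effect, paste(e$atom, e$nb, e$offset))
  } else stats::setNames(numeric(), character())
  q3_key <- stats::setNames(config$q3_offsets$offset_ppm,
                            paste(config$q3_offsets$atom,
                                  config$q3_offsets$state))

  entries <- vector("list", config$n_entries)
  truth_rows <- vector("list", config$n_entries)
  for (k in seq_len(config$n_entries)) {
    L <- config$length_range[1] +
      sample.int(config$length_range[2] - config$length_range[1] + 1L,
                 1L) - 1L
    sq <- sample(AA20, L, replace = TRUE)
    q3 <- NULL
    if (config$with_q3) {
      q3 <- character(0)
      st <- sample(c("H", "E", "C"), 1L)
      while (length(q3) < L) {
        len <- config$min_seg_len +
          stats::rgeom(1L, 1 / (config$mean_seg_extra + 1))
        q3 <- c(q3, rep(st, len))
        st <- sample(setdiff(c("H", "E", "C"), st), 1L)
      }
      q3 <- q3[seq_len(L)]
    }

    # per-position true shifts
    ctx <- data.table::data.table(
      res_index = seq_len(L), res = sq,
      nb_m2 = c(NA, NA, sq)[seq_len(L)], nb_m1 = c(NA, sq)[seq_len(L)],
      nb_p1 = c(sq[-1], NA)[seq_len(L)],
      nb_p2 = c(sq[-(1:2)], NA, NA)[seq_len(L)])
    rows <- data.table::rbindlist(lapply(config$atoms, function(a) {
      dt <- data.table::copy(ctx); dt[, atom := a]; dt
    }))
    rows <- rows[atom_exists(res, atom)]
    rows[, truth := base_key[paste(atom, res)]]
    rows <- rows[!is.na(truth)]
    offmap <- c(nb_m2 = -2L, nb_m1 = -1L, nb_p1 = 1L, nb_p2 = 2L)
    for (nbcol in names(offmap)) {
      eff <- eff_key[paste(rows$atom, rows[[nbcol]], offmap[[nbcol]])]
      eff[is.na(eff)] <- 0
      rows[, truth := truth + eff]
    }
    if (config$with_q3) {
      seg <- q3_segments(q3)
      si <- findInterval(rows$res_index, seg$start)
      cur_off <- q3_key[paste(rows$atom, seg$label[si])]
      d <- rows$res_index - seg$start[si] + 1L
      in_ramp <- config$ramp_len > 0 & si > 1L & d <= config$ramp_len
      prev_off <- q3_key[paste(rows$atom,
                               seg$label[pmax(si - 1L, 1L)])]
      t <- d / (config$ramp_len + 1)
      q3_term <- ifelse(in_ramp, prev_off * (1 - t) + cur_off * t, cur_off)
      rows[, truth := truth + q3_term]
    }
    rows[, shift := truth +
           stats::rnorm(.N, sd = config$noise_sd[atom])]
    if (config$outlier_frac > 0) {
      hit <- stats::runif(nrow(rows)) < config$outlier_frac
      sgn <- sample(c(-1, 1), nrow(rows), replace = TRUE)
      rows[hit, shift := shift + sgn[hit] * config$outlier_z *
             config$noise_sd[atom]]
    }
    if (k <= config$ref_offset_entries) {
      off <- config$ref_offset_ppm[atom_nucleus(rows$atom)]
      off[is.na(off)] <- 0
      rows[, shift := shift + off]
    }
    eid <- sprintf("SYN%04d", k)
    entries[[k]] <- cs_entry(eid, sq,
                             rows[, .(res_index, atom, shift)],
                             ph = config$ph, q3 = q3)
    truth_rows[[k]] <- rows[, .(entry_id = eid, res_index, atom,
                                true_shift = truth)]
  }
  list(entries = entries,
       truth = list(records = data.table::rbindlist(truth_rows),
                    base = base, neighbor_effects = config$neighbor_effects,
                    q3_offsets = if (config$with_q3) config$q3_offsets
                    else NULL,
                    ramp_len = config$ramp_len))
}

#' Write the ground-truth sidecar TSV
#'
#' @param truth the `truth` element of [generate_synthetic()] output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(truth$records, path, sep = "\t", quote = FALSE)
  invisible(path)
}
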