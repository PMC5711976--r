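#' Train a kernel shift model
#'
#' For every (atom, residue) category present in the training records, a
#' Gaussian-kernel density of the observed shifts gives the primary
#' expectation.  Neighbour corrections at offsets -2, -1, +1, +2 are the
#' expectation of the pair-conditioned density minus the primary
#' expectation; pairs with fewer than `n_min` observations fall back to the
#' averaged effect of that neighbour type at that offset, pooled over all
#' centre residues (computed on residuals, observed minus the centre's
#' primary expectation).  Each correction carries an overlap weight
#' ([correction_weight()]); a per-atom normalisation factor balancing
#' primary term and corrections is calibrated by grid search
#' ([calibrate_nw()]).
#'
#' @param entries list of [cs_entry()] training entries.
#' @param condition model condition label: `"idp"`, `"helix"`, `"strand"`
#'   or `"coil"`.
#' @param atoms atom types to parameterise; default all atoms present.
#' @param ph_bin 6.4 or 2.8; entries are filtered to the matching bin
#'   (pH <= 4.5 maps to 2.8).  `NA` disables the filter.
#' @param n_min_mean sample count above which the density expectation is
#'   the weighted mean rather than the mode (default 50).
#' @param n_min minimum pair count for a specific (rather than averaged)
#'   correction; default 20.
#' @param calibrate run [calibrate_nw()] per atom (default TRUE); when
#'   FALSE every normalisation factor is 1.
#' @param nw_grid search grid for the normalisation factor.
#' @return a `cs_kernel_model`.
#' @export
train_kernel_model <- function(entries, condition = "idp", atoms = NULL,
                               ph_bin = 6.4, n_min_mean = 50, n_min = 20,
                               calibrate = TRUE,
                               nw_grid = seq(0.5, 10, by = 0.1)) {
  condition <- match.arg(condition, c("idp", "helix", "strand", "coil"))
  rec <- as_records_table(entries)
  if (!is.na(ph_bin)) {
    rec <- rec[assign_ph_bin(ph) == ph_bin]
    if (!nrow(rec))
      stop("no records in the pH ", ph_bin, " bin", call. = FALSE)
  }
  train_kernel_model_records(rec, condition = condition, atoms = atoms,
                             ph_bin = ph_bin, n_min_mean = n_min_mean,
                             n_min = n_min, calibrate = calibrate,
                             nw_grid = nw_grid)
}

# records-level trainer (shared with the Q3 per-state trainer)
train_kernel_model_records <- function(rec, condition, atoms = NULL,
                                       ph_bin = 6.4, n_min_mean = 50,
                                       n_min = 20, calibrate = TRUE,
                                       nw_grid = seq(0.5, 10, by = 0.1)) {
  if (is.null(atoms)) atoms <- sort(unique(rec$atom))
  rec <- rec[atom %in% atoms]
  if (!nrow(rec)) stop("no records for the requested atoms", call. = FALSE)

  offs <- c(-2L, -1L, 1L, 2L)
  nbcols <- c(`-2` = "nb_m2", `-1` = "nb_m1", `1` = "nb_p1", `2` = "nb_p2")

  prim_list <- list(); corr_list <- list()
  for (a in atoms) {
    ra <- rec[atom == a]
    if (!nrow(ra)) next
    floor_a <- bw_floor_for(a)

    # primary densities and expectations per residue type
    sp <- split(ra$shift, ra$res)
    dens <- lapply(sp, build_density, floor = floor_a)
    expv <- vapply(dens, expected_shift, 0, n_min_mean = n_min_mean)
    prim_list[[a]] <- data.table::data.table(
      atom = a, res = names(sp), expectation = unname(expv),
      n_obs = lengths(sp),
      bandwidth = vapply(dens, `[[`, 0, "bandwidth"))

    # residuals w.r.t. the centre's primary expectation
    ra[, resid := shift - expv[res]]
    d_pool <- build_density(ra$resid, floor = floor_a)

    # long table of (record, offset, neighbour)
    long <- data.table::rbindlist(lapply(offs, function(o) {
      dt <- ra[, .(res, shift, resid, nb = get(nbcols[[as.character(o)]]))]
      dt[, offset := o]
      dt[!is.na(nb)]
    }))
    if (!nrow(long)) next

    # averaged corrections: effect of neighbour type j at an offset,
    # pooled over all centre residues
    avg <- long[, {
      d <- build_density(resid, floor = floor_a)
      .(avg_dd = expected_shift(d, n_min_mean),
        avg_w = correction_weight(d_pool, d),
        n_all = .N)
    }, by = .(nb, offset)]

    # specific corrections where statistics allow
    cnt <- long[, .(n_pair = .N), by = .(res, nb, offset)]
    spec_keys <- cnt[n_pair >= n_min]
    spec <- if (nrow(spec_keys)) {
      long[spec_keys, on = c("res", "nb", "offset")][, {
        d_pair <- build_density(shift, floor = floor_a)
        .(ddelta_spec = expected_shift(d_pair, n_min_mean) - expv[[res[1]]],
          w_spec = correction_weight(dens[[res[1]]], d_pair),
          n_pair = .N)
      }, by = .(res, nb, offset)]
    } else {
      data.table::data.table(res = character(), nb = character(),
                             offset = integer(), ddelta_spec = numeric(),
                             w_spec = numeric(), n_pair = integer())
    }

    # assemble the full lookup: every centre residue seen for this atom x
    # every (neighbour, offset) with pooled data
    full <- data.table::CJ(res = names(sp), key_id = seq_len(nrow(avg)),
                           sorted = FALSE)
    full <- cbind(full[, .(res)], avg[full$key_id])
    full <- merge(full, cnt, by = c("res", "nb", "offset"), all.x = TRUE)
    full[is.na(n_pair), n_pair := 0L]
    full <- merge(full, spec[, .(res, nb, offset, ddelta_spec, w_spec)],
                  by = c("res", "nb", "offset"), all.x = TRUE)
    full[, averaged := n_pair < n_min]
    full[, ddelta := ifelse(averaged, avg_dd, ddelta_spec)]
    full[, w := ifelse(averaged, avg_w, w_spec)]
    full[, atom := a]
    corr_list[[a]] <- full[, .(atom, res, nb, offset, ddelta, w, n_pair,
                               averaged)]
  }

  model <- structure(list(
    condition = condition, ph_bin = ph_bin,
    n_min_mean = n_min_mean, n_min = n_min,
    primary = data.table::rbindlist(prim_list),
    corrections = data.table::rbindlist(corr_list),
    n_w = stats::setNames(rep(1, length(atoms)), atoms),
    version = as.character(utils::packageVersion("seqcs"))),
    class = "cs_kernel_model")
  data.table::setkey(model$primary, atom, res)
  data.table::setkey(model$corrections, atom, res, nb, offset)

  if (calibrate) {
    for (a in atoms) {
      model$n_w[[a]] <- calibrate_nw_records(model, rec, a, nw_grid)
    }
  }
  model
}

#' Look up one pairwise correction term
#'
#' @param model a `cs_kernel_model`.
#' @param atom,i,j atom type, centre residue code, neighbour residue code.
#' @param offset -2, -1, +1 or +2.
#' @return list with `ddelta` (ppm), `w`, `n_pair`, `averaged`; all-zero
#'   with `n_pair = 0` when the model has never seen that neighbour at that
#'   offset.
#' @export
pairwise_correction <- function(model, atom, i, j, offset) {
  stopifnot(inherits(model, "cs_kernel_model"))
  key <- list(k_atom = atom, k_res = i, k_nb = j,
              k_off = as.integer(offset))
  row <- model$corrections[key, on = c(atom = "k_atom", res = "k_res",
                                       nb = "k_nb", offset = "k_off")]
  if (nrow(row) != 1L || is.na(row$ddelta))
    return(list(ddelta = 0, w = 0, n_pair = 0L, averaged = TRUE))
  as.list(row[, .(ddelta, w, n_pair, averaged)])
}

# Per-record primary term and correction sum (sum over offsets of w * dd)
# for a context table with columns res, nb_m2, nb_m1, nb_p1, nb_p2, atom.
# Returns the table with columns primary, corr, flag_averaged,
# flag_missing_nb, flag_no_model added.
eq4_components <- function(model, ctx) {
  ctx <- data.table::copy(ctx)
  ctx[, row_id := .I]
  ctx <- merge(ctx, model$primary[, .(atom, res, primary = expectation)],
               by = c("atom", "res"), all.x = TRUE, sort = FALSE)
  ctx[, corr := 0]
  ctx[, flag_averaged := FALSE]
  ctx[, flag_missing_nb := is.na(nb_m2) | is.na(nb_m1) |
        is.na(nb_p1) | is.na(nb_p2)]
  nbcols <- c(`-2` = "nb_m2", `-1` = "nb_m1", `1` = "nb_p1", `2` = "nb_p2")
  for (o in names(nbcols)) {
    j <- ctx[[nbcols[[o]]]]
    look <- data.table::data.table(atom = ctx$atom, res = ctx$res, nb = j,
                                   offset = as.integer(o))
    hit <- model$corrections[look, on = c("atom", "res", "nb", "offset")]
    term <- hit$w * hit$ddelta
    term[is.na(term)] <- 0
    ctx[, corr := corr + term]
    ctx[, flag_averaged := flag_averaged | (!is.na(hit$averaged) &
                                              hit$averaged)]
  }
  ctx[, flag_no_model := is.na(primary)]
  data.table::setorder(ctx, row_id)
  ctx
}

calibrate_nw_records <- function(model, rec, atom_type, nw_grid) {
  ra <- rec[atom == atom_type]
  if (!nrow(ra)) return(1)
  comp <- eq4_components(model, ra)
  comp <- comp[!is.na(primary)]
  if (!nrow(comp)) return(1)
  err0 <- comp$shift - comp$primary
  rmsds <- vapply(nw_grid, function(nw)
    sqrt(mean((err0 - comp$corr / nw)^2)), 0)
  nw_grid[which.min(rmsds)]
}

#' Calibrate the correction normalisation factor
#'
#' Grid search over `nw_grid` (default 0.5 to 10 in steps of 0.1) for the
#' factor minimising the RMSD between predicted and experimental shifts of
#' one atom type on the supplied data; ties break toward the smallest
#' value.  With all corrections zero the RMSD is flat and the smallest grid
#' value is returned.
#'
#' @param model a `cs_kernel_model`.
#' @param entries training entries.
#' @param atom atom type.
#' @param nw_grid candidate values.
#' @return the calibrated factor (scalar).
#' @export
calibrate_nw <- function(model, entries, atom,
                         nw_grid = seq(0.5, 10, by = 0.1)) {
  stopifnot(inherits(model, "cs_kernel_model"))
  rec <- as_records_table(entries)
  calibrate_nw_records(model, rec, atom, nw_grid)
}

#' @export
print.cs_kernel_model <- function(x, ...) {
  cat(sprintf(
    "<cs_kernel_model> condition %s, pH %.1f: %d atoms, %d primary cells, %d corrections (%.0f%% averaged)\n",
    x$condition, x$ph_bin, length(unique(x$primary$atom)),
    nrow(x$primary), nrow(x$corrections),
    if (nrow(x$corrections)) 100 * mean(x$corrections$averaged) else 0))
  invisible(x)
}
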