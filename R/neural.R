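#' Neural refiner for predicted secondary structure
#'
#' When Q3 labels come from a secondary-structure predictor rather than
#' from an experimental structure, the per-state kernel prediction suffers
#' from label errors.  A small feedforward regressor -- 143 inputs, one
#' hidden layer of 50 tanh units, a single linear output -- absorbs part of
#' that uncertainty by looking at a wider window of labels and sequence.
#' Inputs: 28 secondary-structure nodes (4 per position over a 7-residue
#' window: three state indicators plus a terminal-region indicator) and
#' 115 sequence nodes (23 per position over a 5-residue window, BLOSUM-62
#' row scores extended to the 23-letter residue alphabet).  The target is
#' the standardised secondary shift (observed minus coil expectation,
#' z-scored per atom); training minimises mean squared error with Adam.
#'
#' @name neural-refiner
NULL

N_INPUT <- 143L
N_HIDDEN <- 50L
SS_WINDOW <- 7L
SEQ_WINDOW <- 5L

# BLOSUM-62 extended to the 23-letter alphabet: variants inherit their
# parent's row and column; the variant diagonal carries the parent
# self-score.
blosum62_23 <- function() {
  b62 <- get_blosum62()
  m <- matrix(0, 23, 23, dimnames = list(ALPHABET23, ALPHABET23))
  m[AA20, AA20] <- b62[AA20, AA20]
  for (v in names(VARIANT_PARENT)) {
    p <- VARIANT_PARENT[[v]]
    m[v, ] <- m[p, colnames(m)]
    m[, v] <- m[rownames(m), p]
    m[v, v] <- b62[p, p]
  }
  m
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Encode one residue position for the neural refiner
#'
#' Deterministic pure function of the local sequence and local secondary
#' structure: a numeric vector of exactly 143 values.  Positions outside
#' the chain contribute all-zero state/sequence nodes with the terminal
#' indicator set to 1.
#'
#' @param sequence residue-code vector.
#' @param q3_labels Q3 label vector (H/E/C), same length.
#' @param center_index 1-based position to encode.
#' @return numeric vector of length 143.
#' @export
nn_encode <- function(sequence, q3_labels, center_index) {
  L <- length(sequence)
  stopifnot(center_index >= 1L, center_index <= L,
            length(q3_labels) == L)
  b62 <- blosum62_23()
  ss <- numeric(4L * SS_WINDOW)
  half_ss <- (SS_WINDOW - 1L) %/% 2L
  for (k in seq_len(SS_WINDOW)) {
    p <- center_index + (k - 1L) - half_ss
    o <- (k - 1L) * 4L
    if (p < 1L || p > L) {
      ss[o + 4L] <- 1
    } else {
      ss[o + match(q3_labels[p], c("H", "E", "C"))] <- 1
    }
  }
  sq <- numeric(23L * SEQ_WINDOW)
  half_seq <- (SEQ_WINDOW - 1L) %/% 2L
  for (k in seq_len(SEQ_WINDOW)) {
    p <- center_index + (k - 1L) - half_seq
    o <- (k - 1L) * 23L
    if (p >= 1L && p <= L) sq[o + seq_len(23L)] <- b62[sequence[p], ]
  }
  c(ss, sq)
}

# Encode a whole entry at once (rows = positions).  Much faster than
# calling nn_encode per position; both paths are asserted equal in tests.
encode_entry_matrix <- function(sequence, q3_labels) {
  L <- length(sequence)
  b62 <- blosum62_23()
  X <- matrix(0, L, N_INPUT)
  half_ss <- (SS_WINDOW - 1L) %/% 2L
  st_idx <- match(q3_labels, c("H", "E", "C"))
  for (k in seq_len(SS_WINDOW)) {
    o <- (k - 1L) * 4L
    p <- seq_len(L) + (k - 1L) - half_ss
    inside <- p >= 1L & p <= L
    X[cbind(which(!inside), o + 4L)] <- 1
    X[cbind(which(inside), o + st_idx[p[inside]])] <- 1
  }
  half_seq <- (SEQ_WINDOW - 1L) %/% 2L
  for (k in seq_len(SEQ_WINDOW)) {
    o <- 4L * SS_WINDOW + (k - 1L) * 23L
    p <- seq_len(L) + (k - 1L) - half_seq
    inside <- p >= 1L & p <= L
    X[inside, o + seq_len(23L)] <- b62[sequence[p[inside]], , drop = FALSE]
  }
  X
}

#' Default neural-refiner training configuration
#'
#' Adam with learning rate 1e-3, beta1 0.9, beta2 0.999, epsilon 1e-8,
#' batch size 64, 200 epochs, fixed seed.
#'
#' @param lr,beta1,beta2,eps Adam hyper-parameters.
#' @param batch_size,epochs minibatch size and epoch count.
#' @param hidden hidden-layer width (default 50).
#' @param val_frac fraction of samples held out for early stopping
#'   (default 0.1; only applied when at least 50 samples are available).
#' @param patience epochs without validation improvement before stopping;
#'   the best-validation weights are kept.
#' @param seed RNG seed controlling initialisation, the validation split
#'   and shuffling.
#' @return named list.
#' @export
nn_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      batch_size = 64L, epochs = 200L, hidden = N_HIDDEN,
                      val_frac = 0.1, patience = 20L, seed = 1L) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       hidden = as.integer(hidden), val_frac = val_frac,
       patience = as.integer(patience), seed = as.integer(seed))
}

#' Forward pass of the refiner network
#'
#' out = W2 . tanh(W1' x + b1) + b2, computed on standardised inputs and
#' de-standardised with the per-atom target scaling stored in the weights.
#'
#' @param x numeric vector of length 143, or a matrix with 143 columns
#'   (raw encoding scale).
#' @param net a single network as stored in a `cs_nn_set` (`W1` 143 x H,
#'   `b1`, `W2`, `b2`, plus `x_mean`, `x_sd`, `y_mean`, `y_sd`).
#' @return predicted value(s) on the target (secondary-shift) scale.
#' @export
nn_forward <- function(x, net) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(net$W1))
    stop("encoding length ", ncol(x), " does not match network input ",
         nrow(net$W1), call. = FALSE)
  xs <- sweep(sweep(x, 2L, net$x_mean), 2L, net$x_sd, "/")
  h <- tanh(sweep(xs %*% net$W1, 2L, net$b1, "+"))
  z <- drop(h %*% net$W2) + net$b2
  z * net$y_sd + net$y_mean
}

# Adam-trained single-hidden-layer regressor on standardised data.
# Deterministic given config$seed.  A validation fraction (when the sample
# is large enough to spare one) drives early stopping: the weights of the
# epoch with the lowest validation MSE are kept, and training stops after
# `patience` epochs without improvement -- the network otherwise memorises
# observation noise on low signal-to-noise atoms.
nn_fit <- function(X, y, config) {
  stopifnot(nrow(X) == length(y), nrow(X) >= 1L)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[!is.finite(x_sd) | x_sd == 0] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) {
    warning("degenerate (constant) training targets", call. = FALSE)
    y_sd <- 1
  }
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  ys <- (y - y_mean) / y_sd

  n_in <- ncol(X); n_h <- config$hidden
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  r1 <- sqrt(6 / (n_in + n_h))
  W1 <- matrix(stats::runif(n_in * n_h, -r1, r1), n_in, n_h)
  b1 <- numeric(n_h)
  r2 <- sqrt(6 / (n_h + 1))
  W2 <- stats::runif(n_h, -r2, r2)
  b2 <- 0

  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m_t <- lapply(params, function(p) p * 0)
  v_t <- lapply(params, function(p) p * 0)
  t_step <- 0L

  n_all <- nrow(Xs)
  val_frac <- if (is.null(config$val_frac)) 0 else config$val_frac
  n_val <- if (n_all >= 50L) floor(val_frac * n_all) else 0L
  val_idx <- if (n_val > 0L) sample.int(n_all, n_val) else integer()
  train_idx <- setdiff(seq_len(n_all), val_idx)
  Xv <- Xs[val_idx, , drop = FALSE]; yv <- ys[val_idx]
  Xt <- Xs[train_idx, , drop = FALSE]; yt <- ys[train_idx]
  n <- nrow(Xt)
  bs <- min(config$batch_size, n)
  best <- list(params = params, mse = Inf, stale = 0L)
  patience <- if (is.null(config$patience)) Inf else config$patience

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      take <- idx[start:min(start + bs - 1L, n)]
      xb <- Xt[take, , drop = FALSE]
      yb <- yt[take]
      nb <- length(take)

      a1 <- sweep(xb %*% params$W1, 2L, params$b1, "+")
      h <- tanh(a1)
      z <- drop(h %*% params$W2) + params$b2
      dz <- 2 * (z - yb) / nb            # d MSE / dz
      gW2 <- drop(crossprod(h, dz))
      gb2 <- sum(dz)
      dh <- outer(dz, params$W2) * (1 - h^2)
      gW1 <- crossprod(xb, dh)
      gb1 <- colSums(dh)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)

      t_step <- t_step + 1L
      for (nm in names(params)) {
        m_t[[nm]] <- config$beta1 * m_t[[nm]] + (1 - config$beta1) * grads[[nm]]
        v_t[[nm]] <- config$beta2 * v_t[[nm]] +
          (1 - config$beta2) * grads[[nm]]^2
        mhat <- m_t[[nm]] / (1 - config$beta1^t_step)
        vhat <- v_t[[nm]] / (1 - config$beta2^t_step)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) +
                                                             config$eps)
      }
    }
    if (n_val > 0L) {
      hv <- tanh(sweep(Xv %*% params$W1, 2L, params$b1, "+"))
      zv <- drop(hv %*% params$W2) + params$b2
      mse <- mean((zv - yv)^2)
      if (mse < best$mse) best <- list(params = params, mse = mse,
                                       stale = 0L)
      else {
        best$stale <- best$stale + 1L
        if (best$stale >= patience) break
      }
    }
  }
  if (n_val > 0L) params <- best$params
  list(W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2,
       x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train one refiner network per atom type
#'
#' Builds the (encoding, secondary shift) training pairs from Q3-labelled
#' entries -- the labels used here should come from the same source that
#' will be used at prediction time (e.g. a secondary-structure predictor)
#' -- and fits a 143-50-1 tanh network per atom with Adam.
#'
#' @param entries Q3-labelled entries with shift records.
#' @param coil_model coil-state `cs_kernel_model` providing the
#'   random-coil reference for the secondary-shift targets.
#' @param atoms atoms to train (default: all present in the records).
#' @param config see [nn_config()].
#' @param q3_override optional named list (by entry_id) of label vectors
#'   replacing the entries' own labels, e.g. predictor output.
#' @return a `cs_nn_set`: list of per-atom networks plus the config.
#' @export
train_refiner <- function(entries, coil_model, atoms = NULL,
                          config = nn_config(), q3_override = NULL) {
  labelled <- Filter(function(e)
    !is.null(e$q3) || !is.null(q3_override[[e$entry_id]]), entries)
  if (!length(labelled)) stop("no Q3-labelled entries", call. = FALSE)
  enc <- lapply(labelled, function(e) {
    q3 <- q3_override[[e$entry_id]]
    if (is.null(q3)) q3 <- e$q3
    X <- encode_entry_matrix(e$sequence, q3)
    rec <- data.table::copy(e$records)
    rec[, res := e$sequence[res_index]]
    list(X = X, rec = rec)
  })
  rec_all <- data.table::rbindlist(lapply(seq_along(enc), function(k) {
    dt <- data.table::copy(enc[[k]]$rec); dt[, blk := k]; dt
  }))
  rec_all <- merge(rec_all,
                   coil_model$primary[, .(atom, res, center = expectation)],
                   by = c("atom", "res"), all.x = TRUE, sort = FALSE)
  rec_all <- rec_all[!is.na(center)]
  if (is.null(atoms)) atoms <- sort(unique(rec_all$atom))
  nets <- list()
  for (a in atoms) {
    sub <- rec_all[atom == a]
    if (!nrow(sub)) next
    sub[, row := .I]
    pieces <- lapply(split(sub, by = "blk", sorted = TRUE), function(s)
      cbind(s$row, enc[[s$blk[1]]]$X[s$res_index, , drop = FALSE]))
    Xo <- do.call(rbind, pieces)
    X <- Xo[order(Xo[, 1L]), -1L, drop = FALSE]
    y <- sub$shift - sub$center
    cfg <- config
    cfg$seed <- config$seed + match(a, atoms) - 1L
    nets[[a]] <- nn_fit(X, y, cfg)
  }
  if (!length(nets)) stop("no trainable atoms", call. = FALSE)
  structure(list(nets = nets, config = config,
                 version = as.character(utils::packageVersion("seqcs"))),
            class = "cs_nn_set")
}

#' @export
print.cs_nn_set <- function(x, ...) {
  cat(sprintf("<cs_nn_set> %d atom network(s): %s (143-%d-1, tanh)\n",
              length(x$nets), paste(names(x$nets), collapse = ", "),
              x$config$hidden))
  invisible(x)
}

#' Predict folded-protein shifts with the neural refiner
#'
#' Prediction = coil-state expectation (random-coil reference) + network
#' output for each residue/atom.  Residues whose (residue, atom) lacks a
#' coil reference are omitted.
#'
#' @param sequence residue codes (vector or single string).
#' @param q3 Q3 labels (any input accepted by [merge_to_q3()]).
#' @param nn a `cs_nn_set`.
#' @param coil_model coil-state kernel model (same reference as used in
#'   training).
#' @param atoms atoms to predict (default: all with a network).
#' @return a `data.table` with `res_index`, `res`, `atom`, `shift`.
#' @export
predict_folded_nn <- function(sequence, q3, nn, coil_model, atoms = NULL) {
  stopifnot(inherits(nn, "cs_nn_set"))
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (!inherits(q3, "cs_q3")) q3 <- merge_to_q3(q3)
  if (is.null(atoms)) atoms <- names(nn$nets)
  X <- encode_entry_matrix(sequence, q3$labels)
  out <- list()
  for (a in intersect(atoms, names(nn$nets))) {
    prim <- coil_model$primary[atom == a, .(res, center = expectation)]
    dt <- data.table::data.table(res_index = seq_along(sequence),
                                 res = sequence)
    dt <- merge(dt, prim, by = "res", sort = FALSE)
    dt <- dt[atom_exists(res, a)]
    if (!nrow(dt)) next
    dt[, atom := a]
    dt[, shift := center + nn_forward(X[res_index, , drop = FALSE],
                                      nn$nets[[a]])]
    out[[a]] <- dt[, .(res_index, res, atom, shift)]
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, res_index, atom)
  res[]
}
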