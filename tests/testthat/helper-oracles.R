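# Independent oracles and tiny fixture builders used across the suite.

# Needleman-Wunsch identity by explicit dynamic programming with traceback
# (match = 1, mismatch = 0, gap = -1; identity = matches / alignment
# columns).  Independent of the package's Biostrings-backed implementation.
nw_identity_oracle <- function(s1, s2) {
  a <- seqcs::residue_parent(s1)
  b <- seqcs::residue_parent(s2)
  n <- length(a); m <- length(b)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(S[i, j] + (a[i] == b[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (a[i] == b[j])) {
      matches <- matches + (a[i] == b[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  matches / cols
}

# closed-form overlap weight of two unit-variance Gaussians `d` apart
gaussian_overlap_w <- function(d, sigma = 1) 1 - 2 * pnorm(-d / (2 * sigma))

# analytic Gaussian as a cs_density on a fine grid
gaussian_density <- function(mu, sigma = 1, n_obs = 1000, step = 0.005,
                             span = 8) {
  grid <- seq(mu - span * sigma, mu + span * sigma, by = step * sigma)
  seqcs::cs_density(grid, dnorm(grid, mu, sigma), n_obs = n_obs,
                    bandwidth = sigma)
}

# one-entry fixture: sequence given as a string, shifts for one atom
tiny_entry <- function(id, seq_string, atom = "CA", shifts = NULL,
                       ph = 6.4, q3 = NULL) {
  sq <- strsplit(seq_string, "")[[1]]
  if (is.null(shifts)) shifts <- rep(50, length(sq))
  seqcs::cs_entry(id, sq,
                  data.frame(res_index = seq_along(sq), atom = atom,
                             shift = shifts),
                  ph = ph, q3 = q3)
}

# random sequence string of the 20 standard letters
random_seq <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               L, replace = TRUE), collapse = "")
}

# pooled RMSD of predictions for a list of entries against their records
pooled_rmsd <- function(entries, predict_one) {
  pairs <- data.table::rbindlist(lapply(entries, function(e) {
    p <- predict_one(e)
    merge(e$records, p[, c("res_index", "atom", "shift")],
          by = c("res_index", "atom"), suffixes = c("", ".pred"))
  }))
  pairs[, sqrt(mean((shift - shift.pred)^2))]
}
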