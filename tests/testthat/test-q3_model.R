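test_that("8-state labels merge to Q3 and segment correctly", {
  expect_equal(merge_to_q3("HHHGGG")$labels, rep("H", 6))
  expect_equal(merge_to_q3("EEBEE")$labels, c("E", "E", "C", "E", "E"))
  expect_equal(merge_to_q3("TTSS--")$labels, rep("C", 6))
  expect_error(merge_to_q3("HHXX"), "unknown")

  # idempotent on 3-state input; total on all 8 letters
  all8 <- "HGIEBTS-"
  once <- merge_to_q3(all8)
  expect_equal(merge_to_q3(paste(once$labels, collapse = ""))$labels,
               once$labels)

  seg <- merge_to_q3("HHHCCEEE")$segments
  expect_equal(seg$start, c(1L, 4L, 6L))
  expect_equal(seg$end, c(3L, 5L, 8L))
  expect_equal(seg$label, c("H", "C", "E"))
})

test_that("ss2 and TSV Q3 inputs parse", {
  f <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "",
               "   1 M C   0.999  0.000  0.001",
               "   2 K H   0.100  0.850  0.050",
               "   3 V E   0.050  0.050  0.900"), f)
  expect_equal(read_ss2(f), c("C", "H", "E"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("res_index\tq3", "1\tH", "2\tH", "3\tC"), f2)
  expect_equal(read_q3_tsv(f2), c("H", "H", "C"))
})

# shared folded fixture (small: 18 entries)
folded_fixture <- function(n = 18, seed = 71) {
  cfg <- folded_preset(seed)
  cfg$n_entries <- as.integer(n)
  generate_synthetic(cfg)
}

test_that("per-state training recovers planted state offsets", {
  g <- folded_fixture()
  models <- train_q3_kernels(g$entries, atoms = c("CA", "N"),
                             calibrate = FALSE)
  expect_named(models$models, c("helix", "strand", "coil"),
               ignore.order = TRUE)
  hc <- merge(models$models$helix$primary[atom == "CA",
                                          .(res, eh = expectation,
                                            n = n_obs)],
              models$models$coil$primary[atom == "CA",
                                         .(res, ec = expectation)],
              by = "res")
  expect_equal(with(hc, weighted.mean(eh - ec, n)), 3.2, tolerance = 0.15)

  # single-state database -> other models absent
  all_coil <- lapply(g$entries[1:4], function(e)
    cs_entry(e$entry_id, e$sequence, e$records, ph = e$ph,
             q3 = rep("C", length(e$sequence))))
  m1 <- train_q3_kernels(all_coil, atoms = "CA", calibrate = FALSE)
  expect_named(m1$models, "coil")
})

test_that("boundary profiles recover a planted entry ramp", {
  # dedicated config with a 4-residue ramp and long segments
  noise <- c(CA = 0.1)
  cfg <- synth_config(n_entries = 30, length_range = c(80, 100),
                      atoms = "CA", neighbor_effects = NULL,
                      with_q3 = TRUE, min_seg_len = 14,
                      mean_seg_extra = 10, ramp_len = 4,
                      noise_sd = noise, seed = 23)
  g <- generate_synthetic(cfg)
  models <- train_q3_kernels(g$entries, interior_trim = 4,
                             calibrate = FALSE)
  prof <- build_boundary_profiles(g$entries, models$models$coil,
                                  half_window = 6, interior_trim = 4)

  hc <- prof$profile[transition == "H>C" & atom == "CA"]
  expect_gt(nrow(hc), 8)
  # planted truth: entering coil from helix, offset interpolates
  # 3.2 * (1 - d/5) at d = 1..4, then 0
  for (d in 1:4) {
    expect_equal(hc[dist == d, mean_sec], 3.2 * (1 - d / 5),
                 tolerance = 3 * hc[dist == d, sdev / sqrt(n)] + 0.05)
  }
  expect_equal(hc[dist == 6, mean_sec], 0, tolerance = 0.05)
  # helix side carries no ramp (one-sided construction): stays at +3.2
  expect_equal(hc[dist == -3, mean_sec], 3.2, tolerance = 0.08)

  # flat-profile control: no ramp -> profile constant at the state offset
  cfg0 <- synth_config(n_entries = 12, length_range = c(80, 100),
                       atoms = "CA", neighbor_effects = NULL,
                       with_q3 = TRUE, min_seg_len = 14,
                       mean_seg_extra = 10, ramp_len = 0,
                       noise_sd = noise, seed = 29)
  g0 <- generate_synthetic(cfg0)
  m0 <- train_q3_kernels(g0$entries, interior_trim = 0, calibrate = FALSE)
  p0 <- build_boundary_profiles(g0$entries, m0$models$coil,
                                half_window = 4, interior_trim = 0)
  ch <- p0$profile[transition == "C>H" & atom == "CA"]
  expect_true(all(abs(ch[dist > 0, mean_sec] - 3.2) < 0.1))
  expect_true(all(abs(ch[dist < 0, mean_sec] - 0) < 0.1))
})

test_that("folded prediction: interior equality, coil equivalence, window", {
  g <- folded_fixture(12, seed = 31)
  models <- train_q3_kernels(g$entries, atoms = "CA")
  profiles <- build_boundary_profiles(g$entries, models$models$coil)

  e <- g$entries[[1]]
  q3 <- merge_to_q3(e$q3)
  with_bd <- predict_folded(e$sequence, q3, models, profiles)
  without <- predict_folded(e$sequence, q3, models, NULL)

  # interior residues (beyond the half-window) are untouched
  seg <- q3$segments
  pos <- seq_along(e$sequence)
  si <- findInterval(pos, seg$start)
  interior <- (pos - seg$start[si] + 1 > profiles$half_window |
                 si == 1) &
              (seg$end[si] - pos + 1 > profiles$half_window |
                 si == nrow(seg))
  expect_identical(with_bd[res_index %in% pos[interior], shift],
                   without[res_index %in% pos[interior], shift])
  expect_true(all(with_bd[res_index %in% pos[interior],
                          boundary_correction] == 0))

  # all-coil input equals the plain coil-model prediction
  sq <- e$sequence[1:30]
  pc <- predict_folded(sq, rep("C", 30), models, profiles, atoms = "CA")
  pi <- suppressWarnings(predict_idp(sq, models$models$coil,
                                     atoms = "CA"))
  expect_equal(pc$shift, pi$shift)
})

test_that("boundary corrections reduce held-out RMSD on ramped data", {
  g <- folded_fixture(24, seed = 37)
  tr <- g$entries[1:18]; te <- g$entries[19:24]
  models <- train_q3_kernels(tr, atoms = c("CA", "C"))
  profiles <- build_boundary_profiles(tr, models$models$coil)
  r_with <- pooled_rmsd(te, function(e)
    predict_folded(e$sequence, merge_to_q3(e$q3), models, profiles))
  r_without <- pooled_rmsd(te, function(e)
    predict_folded(e$sequence, merge_to_q3(e$q3), models, NULL))
  expect_lt(r_with, r_without)
})

test_that("missing state model falls back to coil with a warning", {
  g <- folded_fixture(6, seed = 41)
  all_coil <- lapply(g$entries, function(e)
    cs_entry(e$entry_id, e$sequence, e$records, ph = e$ph,
             q3 = rep("C", length(e$sequence))))
  m <- train_q3_kernels(all_coil, atoms = "CA", calibrate = FALSE)
  w <- testthat::capture_warnings(
    p <- predict_folded(g$entries[[1]]$sequence,
                        merge_to_q3(g$entries[[1]]$q3), m, NULL))
  expect_true(any(grepl("falling back to coil", w)))
  expect_gt(nrow(p), 0)
})
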