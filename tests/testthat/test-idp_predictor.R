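# hand-built two-residue-type model for exact reduction checks
toy_model <- function(dd = 0, w = 1, nw = 1) {
  primary <- data.table::data.table(
    atom = "CA", res = c("A", "G"), expectation = c(52.0, 45.0),
    n_obs = c(100L, 100L), bandwidth = 0.1)
  corr <- data.table::CJ(atom = "CA", res = c("A", "G"),
                         nb = c("A", "G"), offset = c(-2L, -1L, 1L, 2L))
  corr[, `:=`(ddelta = dd, w = w, n_pair = 100L, averaged = FALSE)]
  m <- structure(list(condition = "idp", ph_bin = 6.4, n_min_mean = 50,
                      n_min = 20, primary = primary, corrections = corr,
                      n_w = c(CA = nw), version = "0"),
                 class = "cs_kernel_model")
  data.table::setkey(m$primary, atom, res)
  data.table::setkey(m$corrections, atom, res, nb, offset)
  m
}

test_that("prediction reduces to the primary term when corrections vanish", {
  m <- toy_model(dd = 0)
  p <- predict_idp("AGGAAG", m)
  expect_identical(p$shift, p$primary)          # exact, all positions
  expect_identical(p$correction, rep(0, nrow(p)))
  expect_equal(p[res == "A", primary], rep(52, sum(p$res == "A")))

  # length-1 sequence: no neighbours at all
  p1 <- predict_idp("A", m)
  expect_equal(nrow(p1), 1L)
  expect_identical(p1$shift, 52.0)
  expect_true(p1$flag_missing_neighbor)
})

test_that("shift = primary + correction exactly, with the 1/N_W scaling", {
  m1 <- toy_model(dd = 0.4, w = 0.5, nw = 1)
  m2 <- toy_model(dd = 0.4, w = 0.5, nw = 2)
  p1 <- predict_idp("AGGAAGAG", m1)
  p2 <- predict_idp("AGGAAGAG", m2)
  expect_identical(p1$shift, p1$primary + p1$correction)
  # doubling the normalisation factor halves every correction
  expect_equal(p2$correction, p1$correction / 2)
  # interior residue has 4 neighbour terms: 4 * w * dd / nw
  interior <- p1[res_index == 4]
  expect_equal(interior$correction, 4 * 0.5 * 0.4)
})

test_that("predictions depend only on the +/-2 window", {
  set.seed(10)
  g <- generate_synthetic(idp_preset(55))
  m <- train_kernel_model(g$entries[1:10], atoms = "CA")
  sq <- strsplit("AAAAAAAAAAAA", "")[[1]]
  p0 <- suppressWarnings(predict_idp(sq, m))
  sq2 <- sq; sq2[7] <- "W"   # mutate i + 3 relative to residue 4
  p1 <- suppressWarnings(predict_idp(sq2, m))
  expect_identical(p0[res_index == 4, shift], p1[res_index == 4, shift])
  # but residues within the window do change
  expect_false(isTRUE(all.equal(p0[res_index == 6, shift],
                                p1[res_index == 6, shift])))
})

test_that("FASTA prediction handles records and contract errors", {
  m <- toy_model()
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">one", "AGGAG", ">two desc", "GGA"), f)
  out <- suppressWarnings(predict_from_fasta(f, m))
  expect_named(out, c("one", "two"))
  expect_equal(nrow(out$one), 5L)
  expect_equal(nrow(out$two), 3L)

  fx <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">bad", "AGXAG"), fx)
  expect_error(predict_from_fasta(fx, m), "bad")

  fe <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), fe)
  expect_error(predict_from_fasta(fe, m), "empty|read")
})

test_that("chemically absent atoms are skipped; variants map through", {
  primary <- data.table::data.table(
    atom = c("CB", "H", "CB"), res = c("A", "A", "C_ox"),
    expectation = c(19, 8.2, 42.8), n_obs = 100L, bandwidth = 0.1)
  corr <- primary[0, .(atom, res)][, `:=`(nb = character(),
    offset = integer(), ddelta = numeric(), w = numeric(),
    n_pair = integer(), averaged = logical())]
  m <- structure(list(condition = "idp", ph_bin = 6.4, n_min_mean = 50,
                      n_min = 20, primary = primary, corrections = corr,
                      n_w = c(CB = 1, H = 1), version = "0"),
                 class = "cs_kernel_model")
  data.table::setkey(m$primary, atom, res)
  data.table::setkey(m$corrections, atom, res, nb, offset)

  p <- suppressWarnings(predict_idp(c("A", "G", "P", "A"), m))
  expect_false(any(p$res == "G" & p$atom == "CB"))  # no glycine CB
  expect_false(any(p$res == "P" & p$atom == "H"))   # no proline amide H

  sidecar <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("res_index\tvariant", "2\tcys_oxidized"), sidecar)
  sq <- apply_variant_sidecar(c("A", "C", "A"), sidecar)
  expect_equal(sq, c("A", "C_ox", "A"))
  p2 <- suppressWarnings(predict_idp(sq, m))
  expect_equal(p2[res == "C_ox" & atom == "CB", shift], 42.8)
})

test_that("prediction writers emit parseable tables", {
  m <- toy_model()
  sq <- strsplit("AGGAG", "")[[1]]
  p <- predict_idp(sq, m)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_tsv(p, f1, header = "# test")
  back <- data.table::fread(f1, skip = 1)
  expect_equal(nrow(back), nrow(p))
  expect_equal(back$shift_ppm, p$shift)

  f2 <- withr::local_tempfile(fileext = ".tab")
  write_talos(p, sq, f2)
  lines <- readLines(f2)
  expect_true(any(grepl("^DATA SEQUENCE AGGAG", lines)))
  expect_true(any(grepl("^VARS", lines)))
  expect_equal(sum(grepl("^\\s*\\d+\\s+[A-Z]\\s+CA", lines)), nrow(p))
})
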