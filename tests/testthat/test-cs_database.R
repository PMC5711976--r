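make_db_tsv <- function(path, extra_rows = NULL) {
  lines <- c(
    "entry_id\tres_index\tres_letter\tvariant\tatom\tshift_ppm\tph\tq3",
    "E1\t1\tA\tnone\tSEQ\t\t6.4\t",
    "E1\t2\tC\tnone\tSEQ\t\t6.4\t",
    "E1\t3\tD\tnone\tSEQ\t\t6.4\t",
    "E1\t1\tA\tnone\tCA\t52.4\t6.4\t",
    "E1\t2\tC\tnone\tCA\t58.1\t6.4\t",
    "E1\t3\tD\tnone\tCA\t54.0\t6.4\t",
    extra_rows)
  writeLines(lines, path)
  path
}

test_that("TSV entries parse, with contract errors on bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  make_db_tsv(f)
  e <- read_entries(f)
  expect_length(e, 1L)
  expect_equal(e[[1]]$sequence, c("A", "C", "D"))
  expect_equal(nrow(e[[1]]$records), 3L)
  expect_equal(e[[1]]$records$shift, c(52.4, 58.1, 54.0))

  # residue letter disagreeing with the declared sequence
  f2 <- withr::local_tempfile(fileext = ".tsv")
  make_db_tsv(f2, "E1\t2\tG\tnone\tCB\t45.0\t6.4\t")
  expect_error(read_entries(f2), "mismatch")

  # duplicate entry id (second block reusing E1)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  make_db_tsv(f3, c("E2\t1\tG\tnone\tSEQ\t\t6.4\t",
                    "E1\t1\tA\tnone\tSEQ\t\t6.4\t"))
  expect_error(read_entries(f3), "duplicate entry_id")

  # missing shift on a non-SEQ row names the line
  f4 <- withr::local_tempfile(fileext = ".tsv")
  make_db_tsv(f4, "E1\t1\tA\tnone\tCB\t\t6.4\t")
  expect_error(read_entries(f4), "row 8")

  expect_error(read_entries(withr::local_tempfile()), "not found")
})

test_that("TSV round-trips through write_entries_tsv", {
  set.seed(1)
  g <- generate_synthetic(synth_config(n_entries = 3,
                                       length_range = c(10, 15),
                                       with_q3 = TRUE, min_seg_len = 4,
                                       ramp_len = 2, seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_entries_tsv(g$entries, f)
  back <- read_entries(f)
  expect_length(back, 3L)
  for (k in 1:3) {
    expect_equal(back[[k]]$sequence, g$entries[[k]]$sequence)
    expect_equal(back[[k]]$q3, g$entries[[k]]$q3)
    o1 <- data.table::setorder(data.table::copy(g$entries[[k]]$records),
                               res_index, atom)
    o2 <- data.table::setorder(data.table::copy(back[[k]]$records),
                               res_index, atom)
    expect_equal(o1$shift, o2$shift, tolerance = 1e-10)
  }
})

test_that("NMR-STAR-lite loop parses", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_demo",
    "loop_",
    "  _Atom_chem_shift.ID",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 1 ALA CA 52.4",
    "  2 1 ALA CB 19.0",
    "  3 2 GLY CA 45.2",
    "stop_"), f)
  e <- read_entries(f, format = "nmrstar_lite")
  expect_length(e, 1L)
  expect_equal(e[[1]]$entry_id, "demo")
  expect_equal(e[[1]]$sequence, c("A", "G"))
  expect_equal(e[[1]]$records$shift, c(52.4, 19.0, 45.2))
})

test_that("identity clustering matches the DP oracle and is greedy", {
  s1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s2 <- s1; s2[3] <- "A"                      # 19/20 identical
  s3 <- rev(s1)                               # dissimilar
  expect_equal(seqcs:::seq_identity(s1, s1), 1.0)
  expect_equal(seqcs:::seq_identity(s1, s2), nw_identity_oracle(s1, s2))
  expect_equal(seqcs:::seq_identity(s1, s3), nw_identity_oracle(s1, s3),
               tolerance = 0.051)  # degenerate optima may differ slightly

  # two identical sequences -> one kept
  e1 <- tiny_entry("A1", "ACDEFGHIKL")
  e2 <- tiny_entry("A2", "ACDEFGHIKL")
  cl <- cluster_by_identity(list(e1, e2), 0.9)
  expect_length(cl$kept, 1L)
  expect_equal(cl$report$reason, "identity")

  # 50% identity -> both kept
  e3 <- tiny_entry("A3", "ACDEFACDEF")
  e4 <- tiny_entry("A4", "ACDEFYWYWY")
  expect_length(cluster_by_identity(list(e3, e4), 0.9)$kept, 2L)

  expect_error(cluster_by_identity(list(), 0.9), "no entries")
})

test_that("clustering collapses a planted >90%-identity family (oracle)", {
  set.seed(21)
  base <- random_seq(100)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- vapply(v[i], function(a) sample(setdiff(c("A","C","D","E","F",
      "G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"), a), 1),
      "")
    paste(v, collapse = "")
  }
  fam <- c(base, mutate(base, 3), mutate(base, 5))       # >90% mutual id
  others <- replicate(7, random_seq(100))
  seqs <- c(fam, others)
  entries <- lapply(seq_along(seqs), function(k)
    tiny_entry(sprintf("S%02d", k), seqs[k]))

  # brute-force all-pairs oracle: expected number kept under the same
  # greedy order (equal record counts -> entry_id order)
  idm <- outer(seq_along(seqs), seq_along(seqs), Vectorize(function(i, j)
    nw_identity_oracle(strsplit(seqs[i], "")[[1]],
                       strsplit(seqs[j], "")[[1]])))
  kept_oracle <- c()
  for (i in seq_along(seqs)) {
    if (all(idm[i, kept_oracle] <= 0.9)) kept_oracle <- c(kept_oracle, i)
  }
  expect_equal(length(kept_oracle), 8L)

  cl <- cluster_by_identity(entries, 0.9)
  expect_length(cl$kept, length(kept_oracle))
  expect_setequal(vapply(cl$kept, `[[`, "", "entry_id"),
                  sprintf("S%02d", kept_oracle))
})

test_that("clustering is order-stable under input permutation", {
  set.seed(77)
  entries <- lapply(1:8, function(k)
    tiny_entry(sprintf("P%d", k), random_seq(60)))
  kept1 <- vapply(cluster_by_identity(entries, 0.9)$kept, `[[`, "",
                  "entry_id")
  kept2 <- vapply(cluster_by_identity(rev(entries), 0.9)$kept, `[[`, "",
                  "entry_id")
  expect_identical(kept1, kept2)  # equal record counts: entry_id order
})

test_that("referencing QC applies the per-nucleus tolerances", {
  set.seed(5)
  cfg <- synth_config(n_entries = 6, length_range = c(40, 60), seed = 9)
  g <- generate_synthetic(cfg)
  centers <- expected_centers(g$entries)

  # entry drawn at the centres: passes with ~zero offsets
  qc0 <- referencing_qc(g$entries[[2]], centers)
  expect_true(qc0$pass)
  expect_true(all(abs(qc0$offsets[!(skipped)]$offset) < 0.2))

  # +2.0 ppm 13C displacement fails (tolerance 1.5)
  shifted <- g$entries[[1]]
  rec <- data.table::copy(shifted$records)
  is_c <- substr(rec$atom, 1, 1) == "C"
  rec[is_c, shift := shift + 2.0]
  bad <- cs_entry("BAD", shifted$sequence, rec, ph = shifted$ph)
  qc <- referencing_qc(bad, centers)
  expect_false(qc$pass)
  expect_equal(qc$offsets[nucleus == "13C", offset], 2.0, tolerance = 0.2)

  # +0.4 ppm 1H displacement passes (tolerance 0.5)
  rec2 <- data.table::copy(shifted$records)
  is_h <- substr(rec2$atom, 1, 1) == "H"
  rec2[is_h, shift := shift + 0.4]
  okish <- cs_entry("OK", shifted$sequence, rec2, ph = shifted$ph)
  expect_true(referencing_qc(okish, centers)$pass)
})

test_that("outlier removal drops exactly the >z_max values", {
  set.seed(6)
  g <- generate_synthetic(synth_config(n_entries = 8,
                                       length_range = c(50, 70),
                                       neighbor_effects = NULL, seed = 13))
  centers <- expected_centers(g$entries)

  # plant one 4-SD and one 3-SD displacement in entry 1
  e <- g$entries[[1]]
  rec <- data.table::copy(e$records)
  i4 <- which(rec$atom == "CA")[1]
  i3 <- which(rec$atom == "CA")[2]
  cat1 <- centers[atom == "CA" & res == e$sequence[rec$res_index[i4]]]
  rec[i4, shift := cat1$center + 4.0 * cat1$sdev]
  cat2 <- centers[atom == "CA" &
                    res == e$sequence[rec$res_index[i3]]]
  rec[i3, shift := cat2$center + 3.0 * cat2$sdev]
  g$entries[[1]] <- cs_entry(e$entry_id, e$sequence, rec, ph = e$ph)

  out <- remove_outlier_values(g$entries, centers, z_max = 3.5)
  kept1 <- out$entries[[1]]$records
  expect_false(any(abs(kept1$shift - (cat1$center + 4 * cat1$sdev)) < 1e-9))
  expect_true(any(abs(kept1$shift - (cat2$center + 3 * cat2$sdev)) < 1e-9))

  # never removes a value within z_max (verified by construction)
  rec_all <- seqcs:::as_records_table(out$entries)
  merged <- merge(rec_all, centers[, .(atom, res, center, sdev)],
                  by = c("atom", "res"))
  expect_true(merged[!is.na(sdev) & sdev > 0,
                     all(abs(shift - center) / sdev <= 3.5 + 1e-9)])
})

test_that("curation pipeline is idempotent and keeps its books", {
  set.seed(30)
  cfg <- synth_config(n_entries = 6, length_range = c(40, 60),
                      outlier_frac = 0.01, seed = 17)
  g <- generate_synthetic(cfg)
  # add a near-duplicate of entry 1
  dup <- cs_entry("DUP1", g$entries[[1]]$sequence,
                  g$entries[[1]]$records[1:10], ph = 6.4)
  entries <- c(g$entries, list(dup))

  cur <- curate_entries(entries)
  rep <- cur$report
  expect_equal(rep$entries_in, 7L)
  expect_equal(rep$entries_out + nrow(rep$removed_entries), 7L)
  expect_true("DUP1" %in% rep$removed_entries$entry_id)
  expect_gte(rep$removed_values_fraction, 0)
  expect_lte(rep$removed_values_fraction, 1)

  cur2 <- curate_entries(cur$entries)
  expect_equal(length(cur2$entries), length(cur$entries))
  r1 <- data.table::rbindlist(lapply(cur$entries, `[[`, "records"))
  r2 <- data.table::rbindlist(lapply(cur2$entries, `[[`, "records"))
  expect_equal(nrow(r1), nrow(r2))
  expect_equal(sort(r1$shift), sort(r2$shift))
})
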