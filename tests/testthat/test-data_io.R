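test_that("NMR-STAR reader extracts the assigned-chemical-shift loop", {
  tab <- read_shift_table(star_fixture("WT"), "nmrstar", "WT")
  expect_s3_class(tab, "shift_table")
  expect_true(all(c("C", "CA", "N", "H") %in% tab$atom))
  # key filter entries present: V76 carbonyl and Y78 alpha carbon
  expect_false(is.na(filterdyn:::shift_at(tab, 76, "C")))
  expect_false(is.na(filterdyn:::shift_at(tab, 78, "CA")))
  # W67 indole side-chain pair kept as its own rows
  expect_false(is.na(filterdyn:::shift_at(tab, 67, "NE1")))
  expect_identical(attr(tab, "variant_id"), "WT")
})

test_that("NMR-STAR rows with missing values are skipped and counted", {
  lines <- c("data_x", "loop_",
             "  _Atom_chem_shift.Seq_ID", "  _Atom_chem_shift.Comp_ID",
             "  _Atom_chem_shift.Atom_ID", "  _Atom_chem_shift.Val",
             "  76 VAL C 178.1",
             "  77 GLY C .",      # unparseable value -> skipped
             "  78 TYR CA 60.2",
             "stop_")
  p <- withr::local_tempfile(fileext = ".str")
  writeLines(lines, p)
  tab <- read_shift_table(p, "nmrstar")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "skipped"), 1L)
})

test_that("all-unparseable NMR-STAR file errors naming the offending line", {
  lines <- c("data_x", "loop_",
             "  _Atom_chem_shift.Seq_ID", "  _Atom_chem_shift.Comp_ID",
             "  _Atom_chem_shift.Atom_ID", "  _Atom_chem_shift.Val",
             "  . VAL C .", "stop_")
  p <- withr::local_tempfile(fileext = ".str")
  writeLines(lines, p)
  expect_error(read_shift_table(p, "nmrstar"), "\\. VAL C \\.")
})

test_that("TSV shift tables parse and reject duplicate (residue, atom) keys", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("resno\tresname\tatom\tshift", "76\tVAL\tC\t178.1"), p)
  tab <- read_shift_table(p, "tsv")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$shift, 178.1)
  writeLines(c("resno\tresname\tatom\tshift",
               "76\tVAL\tC\t178.1", "76\tVAL\tC\t178.3"), p)
  expect_error(read_shift_table(p, "tsv"), "duplicate.*76 C")
})

test_that("decay-series reader aligns delays and flags missing intensities", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\t0\t5\t10\t20\t40\t80",
               "V76\t1\t0.9\t0.8\t0.65\t0.4\t0.2",
               "Y78\t1\t0.8\t0.7\t0.5\t0.3\t0.1",
               "G79\t1\t0.7\tNA\t0.4\t0.2\t0.05"), p)
  set <- read_decay_series(p, "R1rho", delay_unit = "ms")
  expect_equal(set$delays, c(0, 5, 10, 20, 40, 80))
  expect_equal(nrow(set$intensities), 3L)
  expect_identical(set$flagged, "G79")  # kept, flagged, not dropped
  # minimal valid set: one residue, two delays
  writeLines(c("residue\t0\t10", "V76\t1\t0.5"), p)
  expect_equal(length(read_decay_series(p)$delays), 2L)
  # non-monotonic delays rejected
  writeLines(c("residue\t0\t10\t5", "V76\t1\t0.5\t0.7"), p)
  expect_error(read_decay_series(p), "strictly increasing")
})

test_that("PDB structures and multi-model trajectories read back verbatim", {
  s <- gen_filter_structure()
  xyz <- round(s$xyz, 3)       # PDB carries 3 decimals
  p <- withr::local_tempfile(fileext = ".pdb")
  write_minipdb(s$atoms, xyz, p)
  rs <- read_structure(p)
  expect_equal(rs$atoms$chain, s$atoms$chain)
  expect_equal(rs$atoms$resno, s$atoms$resno)
  expect_equal(rs$atoms$elety, s$atoms$elety)
  expect_equal(unname(rs$xyz), unname(xyz), tolerance = 1e-9)
  # 2-model file -> 2-frame ensemble
  m2 <- xyz + 1
  write_minipdb(s$atoms, list(xyz, m2), p)
  tr <- read_trajectory(p)
  expect_equal(length(tr$frames), 2L)
  expect_equal(unname(tr$frames[[2]]), unname(m2), tolerance = 1e-9)
})

test_that("frames with the wrong atom count are a consistency error", {
  s <- gen_filter_structure()
  expect_error(sf_trajectory(s$atoms, list(s$xyz, s$xyz[-1, ])),
               "wrong atom count")
})

test_that("monomer snapshot extraction matches the closed-form count", {
  tr <- gen_filter_trajectory(duration_ns = 100, spacing_ns = 10)
  expect_length(extract_monomer_snapshots(tr, 10), 40L)  # 10 frames x 4
  # stride below frame spacing is an error
  expect_error(extract_monomer_snapshots(tr, 5), "smaller than the frame")
  # single frame, stride = spacing, one subunit
  one <- sf_trajectory(data.frame(chain = "A", resno = 1L, resid = "GLY",
                                  elety = "CA"),
                       list(matrix(0, 1, 3)), times = 10)
  expect_length(extract_monomer_snapshots(one, 10), 1L)
  # property: retained_frames x n_subunits over random durations/strides
  set.seed(42)
  for (i in 1:8) {
    dt <- sample(c(2, 5, 10), 1)
    nfr <- sample(5:40, 1)
    mult <- sample(1:4, 1)
    D <- dt * nfr
    stride <- dt * mult
    tr <- gen_filter_trajectory(duration_ns = D, spacing_ns = dt,
                                jitter_sd = 0, seed = i)
    expect_length(extract_monomer_snapshots(tr, stride),
                  floor(D / stride) * 4L)
  }
})

test_that("profiles round-trip through write_profile to 6 decimals", {
  df <- data.frame(residue = c("V76", "Y78"),
                   rate = c(0.0123456789, 15.987654321),
                   se = c(1.234e-4, 0.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile(df, p, comments = "round-trip check")
  back <- read_profile(p)
  expect_equal(back$residue, df$residue)
  expect_equal(back$rate, df$rate, tolerance = 1e-6)
  expect_equal(back$se, df$se, tolerance = 1e-6)
})
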