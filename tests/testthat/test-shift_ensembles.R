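mk_assign <- function(labels, resno = 76L, chain = "A") {
  d <- data.frame(chain = chain, resno = resno, frame = seq_along(labels),
                  label = factor(labels,
                                 levels = c("inwards", "outwards", "other")))
  class(d) <- c("state_assignment", "data.frame")
  d
}

test_that("frame-shift tables load, reject duplicates and report frame gaps", {
  df <- data.frame(frame = c(1, 1, 2, 2), chain = "A", resno = 76L,
                   atom = c("C", "CA", "C", "CA"),
                   shift = c(178, 58, 176, 58.5))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_profile(df, p)
  ens <- load_frame_shifts(p)
  expect_s3_class(ens, "shift_ensemble")
  expect_equal(length(unique(ens$frame)), 2L)
  # loss-free round trip
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_frame_shifts(ens, p2)
  back <- load_frame_shifts(p2)
  expect_equal(back$shift, ens$shift, tolerance = 1e-9)
  # duplicate key
  write_profile(rbind(df, df[1, ]), p)
  expect_error(load_frame_shifts(p), "duplicate")
  # frame gap named by number
  write_profile(data.frame(frame = c(1, 3), chain = "A", resno = 76L,
                           atom = "C", shift = c(178, 177)), p)
  expect_error(load_frame_shifts(p), "missing frame\\(s\\): 2")
})

test_that("offsets apply once per atom class and commute with averaging", {
  a <- mk_assign(rep(c("inwards", "outwards"), 50))
  ens <- surrogate_predict(a, surrogate_params(resno = 76), seed = 4)
  m0 <- ensemble_mean_shift(ens, 76, "C")
  ens0 <- apply_offset(ens, "C", 0)            # zero offset is the identity
  expect_equal(ens0$shift, ens$shift)
  ens1 <- apply_offset(ens, "C", 2.5)
  expect_equal(ens1$shift[ens1$atom == "C"],
               ens$shift[ens$atom == "C"] + 2.5)
  expect_equal(ens1$shift[ens1$atom == "CA"], ens$shift[ens$atom == "CA"])
  expect_equal(ensemble_mean_shift(ens1, 76, "C"), m0 + 2.5,
               tolerance = 1e-12)
  expect_error(apply_offset(ens1, "C", 2.5), "already applied")
})

test_that("surrogate predictions are seeded, reproducible and calibrated", {
  a <- mk_assign(sample(c("inwards", "outwards"), 400, TRUE))
  p <- surrogate_params(resno = 76)
  e1 <- surrogate_predict(a, p, seed = 9)
  e2 <- surrogate_predict(a, p, seed = 9)
  expect_identical(e1$shift, e2$shift)
  # sd -> 0 limit: every frame sits exactly on its state mean
  p0 <- p; p0$sd <- 1e-12
  e0 <- surrogate_predict(a, p0, seed = 9)
  mu <- ifelse(a$label == "inwards",
               p$mean[p$atom == "C" & p$state == "inwards"],
               p$mean[p$atom == "C" & p$state == "outwards"])
  expect_equal(e0$shift[e0$atom == "C"], mu, tolerance = 1e-6)
  # law of large numbers: empirical state means near planted means
  big <- mk_assign(rep(c("inwards", "outwards"), c(6000, 4000)))
  eb <- surrogate_predict(big, p, seed = 2)
  for (st in c("inwards", "outwards")) {
    got <- mean(eb$shift[eb$atom == "C"][big$label == st])
    want <- p$mean[p$atom == "C" & p$state == st]
    n_st <- sum(big$label == st)
    expect_lt(abs(got - want), 3 * p$sd[1] / sqrt(n_st))
  }
  expect_error(surrogate_predict(mk_assign("inwards", resno = 99L), p),
               "cover none")
})

test_that("per-state histograms recover the planted state separation", {
  g <- gen_two_state_dihedrals(n_frames = 10000, seed = 6)
  a <- classify_states(g$dihedrals, g$windows)
  ens <- surrogate_predict(a, surrogate_params(resno = 76), seed = 3)
  h <- state_shift_histogram(ens, a, 76, "C")
  sep <- h$stats$mean[h$stats$state == "inwards"] -
    h$stats$mean[h$stats$state == "outwards"]
  expect_lt(abs(sep - 2.5), 0.1)
  expect_equal(sum(h$stats$n), 10000L)
  expect_equal(sum(vapply(h$histograms, function(x) sum(x$counts), 0)),
               10000)
  # single-state assignment gives a single nonempty histogram
  a1 <- mk_assign(rep("inwards", 50))
  e1 <- surrogate_predict(a1, surrogate_params(resno = 76), seed = 1)
  h1 <- state_shift_histogram(e1, a1, 76, "C")
  expect_identical(names(h1$histograms), "inwards")
})

test_that("ensemble mean equals the population-weighted state means", {
  # 0.6 x 178.0 + 0.4 x 175.5 = 177.0
  lab <- rep(c("inwards", "outwards"), c(60, 40))
  p <- surrogate_params(resno = 76, delta_co = 2.5, base_co = 175.5,
                        sd = 1e-9)
  a <- mk_assign(lab)
  ens <- surrogate_predict(a, p, seed = 1)
  expect_equal(ensemble_mean_shift(ens, 76, "C"), 177.0, tolerance = 1e-6)
  # single frame: the mean is that frame's value
  a1 <- mk_assign("inwards")
  e1 <- surrogate_predict(a1, surrogate_params(resno = 76), seed = 5)
  expect_equal(ensemble_mean_shift(e1, 76, "C"),
               e1$shift[e1$atom == "C"][1])
  # decomposition identity on a noisy ensemble: pooled mean equals the
  # population-weighted per-state empirical means
  set.seed(44)
  lab2 <- mk_assign(sample(c("inwards", "outwards"), 500, TRUE, c(0.7, 0.3)))
  ens2 <- surrogate_predict(lab2, surrogate_params(resno = 76), seed = 7)
  e_c <- ens2$shift[ens2$atom == "C"]
  p_hat <- mean(lab2$label == "inwards")
  decomposed <- p_hat * mean(e_c[lab2$label == "inwards"]) +
    (1 - p_hat) * mean(e_c[lab2$label == "outwards"])
  expect_equal(decomposed, ensemble_mean_shift(ens2, 76, "C"),
               tolerance = 1e-9)
})

test_that("predicted CSP equals the two-state closed form and is antisymmetric", {
  p <- surrogate_params(resno = 76, sd = 1e-9)   # noise-free limit
  lab_ref <- mk_assign(rep(c("inwards", "outwards"), c(600, 400)))
  lab_qry <- mk_assign(rep(c("inwards", "outwards"), c(900, 100)))
  er <- surrogate_predict(lab_ref, p, seed = 1)
  eq <- surrogate_predict(lab_qry, p, seed = 2)
  prof <- predicted_csp(eq, er, atom = "C")
  expect_equal(prof$value, 0.3 * 2.5, tolerance = 1e-6)  # dp * dmu
  # ensemble against itself is zero; swapping flips the sign
  expect_equal(predicted_csp(er, er, atom = "C")$value, 0)
  expect_equal(predicted_csp(er, eq, atom = "C")$value, -prof$value,
               tolerance = 1e-12)
  # CA channel uses its own separation
  prof_ca <- predicted_csp(eq, er, atom = "CA")
  expect_equal(prof_ca$value, 0.3 * 2.0, tolerance = 1e-6)
})
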