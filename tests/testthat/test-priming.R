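test_that("feature extraction returns zeros for flat trajectories", {
  tt <- seq(0, 100, by = 1)
  flat <- time_course(tt, matrix(0.3, length(tt), 3,
                                 dimnames = list(NULL, c("x1", "x2", "x3"))))
  tcs <- time_course_set(list(untreated = flat, LD = flat, HD = flat, LD_HD = flat))
  f <- extract_features(tcs, "x3", c(0, 50), c(50, 100))
  expect_equal(unname(f$dss_ld), c(0, 0, 0))
  expect_equal(unname(f$dmax_hd), c(0, 0, 0))
  expect_equal(unname(f$dmax_ldhd), c(0, 0, 0))
  expect_equal(f$readout_max_ld, 0)
})

test_that("dss_ld is the LD end-of-period level minus the untreated baseline", {
  tt <- seq(0, 100, by = 1)
  mk <- function(x1) time_course(tt, cbind(x1 = x1, x2 = 0.2, x3 = 0.05))
  untreated <- mk(rep(0.4, length(tt)))
  ld <- mk(seq(0.4, 0.1, length.out = 51)[pmin(tt + 1, 51)])  # ends at 0.1 by t = 50
  tcs <- time_course_set(list(untreated = untreated, LD = ld, HD = untreated,
                              LD_HD = untreated))
  f <- extract_features(tcs, "x3", c(0, 50), c(50, 100))
  expect_equal(unname(f$dss_ld[["x1"]]), -0.3, tolerance = 1e-12)
})

test_that("feature extraction names the missing arm and rejects bad windows", {
  tt <- seq(0, 100, by = 1)
  flat <- time_course(tt, matrix(0.3, length(tt), 3,
                                 dimnames = list(NULL, c("x1", "x2", "x3"))))
  tcs <- time_course_set(list(untreated = flat, LD = flat, HD = flat))
  expect_error(extract_features(tcs, "x3", c(0, 50), c(50, 100)), "LD_HD")
  tcs2 <- time_course_set(list(untreated = flat, LD = flat, HD = flat, LD_HD = flat))
  expect_error(extract_features(tcs2, "x3", c(0, 50), c(50, 200)), "outside")
})

test_that("features scale linearly with the trajectories", {
  set.seed(7)
  tt <- seq(0, 100, by = 0.5)
  mk <- function() {
    vals <- sapply(1:3, function(i) {
      a <- runif(1, 0.1, 0.6)
      a / (1 + exp(-(tt - runif(1, 20, 80)) / runif(1, 2, 10)))
    })
    colnames(vals) <- c("x1", "x2", "x3")
    time_course(tt, vals)
  }
  tcs <- time_course_set(list(untreated = mk(), LD = mk(), HD = mk(), LD_HD = mk()))
  f1 <- extract_features(tcs, "x3", c(0, 50), c(50, 100))
  cc <- 2.5
  scaled <- lapply(tcs, function(tc) time_course(tc$times, tc$values * cc))
  f2 <- extract_features(time_course_set(scaled), "x3", c(0, 50), c(50, 100))
  expect_equal(f2$dss_ld, f1$dss_ld * cc, tolerance = 1e-12)
  expect_equal(f2$dmax_hd, f1$dmax_hd * cc, tolerance = 1e-12)
  expect_equal(f2$dmax_ldhd, f1$dmax_ldhd * cc, tolerance = 1e-12)
  expect_equal(f2$readout_max_hd, f1$readout_max_hd * cc, tolerance = 1e-12)
})

test_that("the three priming clauses decide the verdict as stated", {
  th <- priming_thresholds()
  v1 <- evaluate_priming(fab_features(ld = 0.05, hd = 0.40, ldhd = 0.65), th)
  expect_true(v1$primed)
  v2 <- evaluate_priming(fab_features(ld = 0.05, hd = 0.40, ldhd = 0.55), th)
  expect_false(v2$primed)
  expect_match(v2$reason, "ratio")
  v3 <- evaluate_priming(fab_features(ld = 0.20, hd = 0.40, ldhd = 0.90), th)
  expect_false(v3$primed)
  expect_match(v3$reason, "LD")
})

test_that("the verdict is monotone in the LD+HD readout maximum", {
  th <- priming_thresholds()
  set.seed(42)
  for (i in 1:50) {
    ld <- runif(1, 0, 0.2); hd <- runif(1, 0, 0.8); ldhd <- runif(1, 0, 1)
    v <- evaluate_priming(fab_features(ld = ld, hd = hd, ldhd = ldhd), th)
    if (v$primed) {
      v2 <- evaluate_priming(fab_features(ld = ld, hd = hd, ldhd = ldhd + 0.1), th)
      expect_true(v2$primed)
    }
  }
})

test_that("mechanism rules classify the canonical feature patterns", {
  th <- priming_thresholds()
  expect_equal(classify_mechanism(fab_features(dss_x1 = -0.3, dss_x2 = 0), th)$label, "SD")
  expect_equal(classify_mechanism(fab_features(dss_x2 = 0.25, dmax_diff_x2 = 0.30), th)$label, "PS")
  expect_equal(classify_mechanism(fab_features(dss_x2 = 0.25, dmax_diff_x2 = 0.02), th)$label, "AI")
  none <- classify_mechanism(fab_features(), th)
  expect_equal(none$label, "none")
})

test_that("non-primed systems always classify to none", {
  th <- priming_thresholds()
  lab <- classify_mechanism(fab_features(dss_x1 = -0.5, ldhd = 0.45), th)
  expect_equal(lab$label, "none")
  expect_length(lab$evidence, 0)
})

test_that("exactly one mechanism fires when one regulator is beyond the cutoff", {
  th <- priming_thresholds()
  set.seed(11)
  for (i in 1:60) {
    big <- runif(1, 0.15, 0.6) * sample(c(-1, 1), 1)
    diff <- if (runif(1) < 0.5) runif(1, 0.15, 0.4) else runif(1, 0, 0.08)
    f <- if (big < 0) fab_features(dss_x1 = big, dss_x2 = runif(1, -0.05, 0.05))
         else fab_features(dss_x1 = runif(1, -0.05, 0.05), dss_x2 = big,
                           dmax_diff_x2 = diff)
    lab <- classify_mechanism(f, th)
    expect_length(lab$evidence, 1)
    expect_true(lab$label %in% c("PS", "AI", "SD"))
  }
})

test_that("simultaneous rules keep all evidence and apply SD precedence", {
  th <- priming_thresholds()
  f <- fab_features(dss_x1 = -0.3, dss_x2 = 0.25, dmax_diff_x2 = 0.30)
  lab <- classify_mechanism(f, th)
  expect_equal(lab$label, "SD")
  expect_length(lab$evidence, 2)
})

test_that("a signed graph gates rules by regulator sign and flags missing readouts", {
  th <- priming_thresholds()
  g_act <- signed_graph(data.frame(from = c("x1", "x2"), sign = c(1, 1),
                                   to = c("x3", "x3")))
  # x1 drops but activates the readout: the suppressor rule must not fire
  f <- fab_features(dss_x1 = -0.3, dss_x2 = 0)
  expect_equal(classify_mechanism(f, th, graph = g_act)$label, "none")
  g_inh <- signed_graph(data.frame(from = c("x1", "x2"), sign = c(-1, 1),
                                   to = c("x3", "x3")))
  expect_equal(classify_mechanism(f, th, graph = g_inh)$label, "SD")
  # AI needs an inhibiting partner somewhere in the graph
  f_ai <- fab_features(dss_x2 = 0.25, dmax_diff_x2 = 0.02)
  expect_equal(classify_mechanism(f_ai, th, graph = g_inh)$label, "AI")
  expect_equal(classify_mechanism(f_ai, th, graph = g_act)$label, "none")
  g_no <- signed_graph(data.frame(from = "a", sign = 1, to = "b"))
  expect_error(classify_mechanism(f, th, graph = g_no), "readout")
})
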