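test_that("the Hill function has its closed-form anchor points", {
  for (K in c(0.05, 0.5, 2)) {
    for (n in c(1, 2, 3)) {
      expect_equal(hill(K, K, n), 0.5)
      expect_equal(hill(0, K, n), 0)
    }
  }
  expect_true(hill(10, 0.5, 3) > 0.99)
})

test_that("topology invariants are enforced", {
  expect_error(trinode_topology(data.frame(from = "S", to = "x1", sign = 1)),
               "S -> x1 and S -> x2")
  expect_error(trinode_topology(data.frame(from = c("S", "S", "x3"),
                                           to = c("x1", "x2", "S"),
                                           sign = c(1, 1, 1))),
               "no incoming")
  expect_error(trinode_topology(data.frame(from = c("S", "S"),
                                           to = c("x1", "x2"), sign = c(1, 1))),
               "x1 -> x3")
})

test_that("a system at its zero-stimulus steady state stays flat", {
  p <- generate_trinode_exemplars()$PS
  x0 <- trinode_steady_state(p, S = 0)
  prot <- stimulus_protocol(data.frame(duration = 100, dose = 0), "untreated")
  tc <- simulate_trinode(p, prot, x0 = x0)
  drift <- max(abs(sweep(tc$values, 2, x0)))
  expect_lt(drift, 1e-6)
})

test_that("adaptive and fixed-step integrations agree on the exemplars", {
  prot <- priming_protocols()
  for (p in generate_trinode_exemplars()) {
    x0 <- trinode_steady_state(p, S = 0)
    a <- simulate_trinode(p, prot$LD_HD, x0 = x0, method = "lsoda")
    b <- simulate_trinode(p, prot$LD_HD, x0 = x0, method = "rk4")
    expect_equal(a$times, b$times)
    expect_lt(max(abs(a$values - b$values)), 1e-4)
  }
})

test_that("trajectories started in the unit box stay in the unit box", {
  set.seed(301)
  prot <- priming_protocols()
  topos <- list(trinode_default_topology("activating"),
                trinode_default_topology("inhibitory"))
  for (i in 1:12) {
    p <- random_trinode_params(topos[[(i %% 2) + 1]])
    tc <- simulate_trinode(p, prot$LD_HD, x0 = runif(3), method = "rk4")
    expect_true(all(tc$values >= -1e-9 & tc$values <= 1 + 1e-9))
  }
})

test_that("the pathway-synergy exemplar shows the stated maximum excess", {
  p <- generate_trinode_exemplars()$PS
  prot <- priming_protocols()
  hdw <- attr(prot, "hd_period")
  x0 <- trinode_steady_state(p, S = 0)
  # dense-grid brute-force maxima as the reference
  hd_d <- simulate_trinode(p, prot$HD, dt = 0.05, x0 = x0, method = "rk4")
  ldhd_d <- simulate_trinode(p, prot$LD_HD, dt = 0.05, x0 = x0, method = "rk4")
  dense_diff <- max(ldhd_d$values[ldhd_d$times >= hdw[1], "x2"]) -
    max(hd_d$values[hd_d$times >= hdw[1], "x2"])
  f <- trinode_features(p, prot)
  pkg_diff <- f$dmax_ldhd[["x2"]] - f$dmax_hd[["x2"]]
  expect_gt(pkg_diff, 0.1)
  expect_equal(pkg_diff, dense_diff, tolerance = 1e-3)
})

test_that("each exemplar passes the priming criteria and classifies to its label", {
  prot <- priming_protocols()
  ex <- generate_trinode_exemplars()
  for (nm in names(ex)) {
    f <- trinode_features(ex[[nm]], prot)
    expect_true(evaluate_priming(f)$primed, label = paste(nm, "primed"))
    lab <- classify_mechanism(f, graph = trinode_signed_graph(ex[[nm]]$topology))
    expect_equal(lab$label, nm)
  }
})

test_that("the exported signed graph mirrors the topology signs", {
  topo <- trinode_default_topology("inhibitory")
  g <- trinode_signed_graph(topo)
  expect_equal(signed_path_sign(g, "x1", "x3", 1), -1L)
  expect_equal(signed_path_sign(g, "x2", "x3", 1), 1L)
  expect_equal(signed_path_sign(g, "S", "x1", 1), 1L)
})
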