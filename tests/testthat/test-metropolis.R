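test_that("the free-parameter mask has the documented size", {
  expect_length(primingscreen:::trinode_param_mask(trinode_default_topology("inhibitory")), 14)
  # without an internal edge there is no optional edge pair to sample
  expect_length(primingscreen:::trinode_param_mask(trinode_default_topology("activating")), 12)
})

test_that("the search is deterministic given seed and configuration", {
  cfg <- metropolis_config(n_chains = 2, stage1_iters = 40, stage2_iters = 40,
                           seed = 5)
  r1 <- suppressMessages(metropolis_search(cfg))
  r2 <- suppressMessages(metropolis_search(cfg))
  expect_equal(length(r1), length(r2))
  if (length(r1)) {
    for (i in seq_along(r1)) {
      expect_equal(r1[[i]]$features$dss_ld, r2[[i]]$features$dss_ld)
      expect_equal(r1[[i]]$params$k, r2[[i]]$params$k)
    }
  }
})

test_that("region summaries tabulate one row per record with label splits", {
  mk_rec <- function(dss1, dss2, diff2, label) {
    structure(list(topology = trinode_default_topology("activating"),
                   params = NULL,
                   features = fab_features(dss_x1 = dss1, dss_x2 = dss2,
                                           dmax_diff_x2 = diff2),
                   label = structure(list(label = label, evidence = "x"),
                                     class = "mechanism_label"),
                   chain = 1L),
              class = "primed_network_record")
  }
  recs <- list(mk_rec(-0.3, 0.0, 0.0, "SD"),
               mk_rec(0.0, 0.3, 0.3, "PS"),
               mk_rec(0.0, 0.3, 0.02, "AI"))
  s <- summarize_regions(recs)
  expect_equal(nrow(s$table), 3)
  expect_setequal(names(s$histograms), c("SD", "PS", "AI"))
  expect_equal(s$table$dmax_diff_x2[s$table$label == "PS"], 0.3)
  expect_true(all(s$table$dss_x1[s$table$label == "SD"] < -0.1))
})
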