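small_spec <- synthetic_spec(n_probes = 800, noise_sd = 0.2)
quiet_spec <- synthetic_spec(n_probes = 800, noise_sd = 0.02)

test_that("Welch p-values match the reference implementation", {
  set.seed(99)
  for (i in 1:25) {
    a <- rnorm(sample(3:6, 1), mean = runif(1, 5, 12), sd = runif(1, 0.1, 1))
    b <- rnorm(sample(3:6, 1), mean = runif(1, 5, 12), sd = runif(1, 0.1, 1))
    expect_equal(welch_test(a, b), t.test(a, b)$p.value, tolerance = 1e-12)
    expect_equal(welch_test(a, b), welch_test(b, a))
  }
  a <- c(10.1, 10.2, 9.9); b <- c(12.0, 12.3, 11.8)
  expect_equal(welch_test(a, b), t.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("Welch degenerate conventions hold", {
  expect_equal(welch_test(c(5, 5, 5), c(5, 5)), 1)
  expect_warning(p <- welch_test(c(5, 5, 5), c(6, 6)), "zero variance")
  expect_equal(p, 0)
  x <- rnorm(4)
  expect_equal(welch_test(x, x), 1)   # identical groups, nonzero variance: t = 0
})

test_that("the vectorised row-wise Welch test agrees with the scalar one", {
  set.seed(5)
  mat <- matrix(2^rnorm(60, 8), nrow = 10)
  p_vec <- primingscreen:::row_welch(mat, 1:3, 4:6)
  for (i in 1:10)
    expect_equal(p_vec[i], welch_test(log2(mat[i, 1:3]), log2(mat[i, 4:6])),
                 tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(13)
  p <- runif(200)
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_true(all(bh_fdr(p) >= p))
})

test_that("fold changes are ratios of linear means with reciprocal symmetry", {
  exprs <- rbind(P1 = c(250, 250, 250, 100, 100, 100),
                 P2 = c(80, 80, 80, 80, 80, 80))
  colnames(exprs) <- paste0("s", 1:6)
  samples <- data.frame(condition = rep(c("LD", "Control"), each = 3),
                        pool = rep(1:3, 2))
  es <- expression_set(exprs, samples)
  fc <- fold_change(es, comparison_spec("LD", "Control"))
  expect_equal(fc$fc[fc$probe_id == "P1"], 2.5)
  expect_equal(fc$fc[fc$probe_id == "P2"], 1.0)
  rev <- fold_change(es, comparison_spec("Control", "LD"))
  expect_equal(fc$fc * rev$fc, c(1, 1), ignore_attr = TRUE)
  expect_error(fold_change(es, comparison_spec("HD3", "Control")), "HD3")
})

test_that("the detection-call filter keeps any probe with a Present call", {
  g <- generate_expression(small_spec, seed = 1)
  filtered <- present_call_filter(g$es)
  expect_equal(nrow(filtered$exprs), sum(!g$truth$absent))
  expect_setequal(rownames(filtered$exprs), g$truth$probe_id[!g$truth$absent])
  # a single Present call among 18 samples is enough to survive
  es2 <- g$es
  pid <- g$truth$probe_id[g$truth$absent][1]
  es2$calls[pid, 5] <- "P"
  expect_true(pid %in% rownames(present_call_filter(es2)$exprs))
  es3 <- g$es; es3$calls <- NULL
  expect_warning(out <- present_call_filter(es3), "no-op")
  expect_equal(dim(out$exprs), dim(es3$exprs))
})

test_that("non-trivial selection excludes nulls, includes responders, and is monotone", {
  g <- generate_expression(quiet_spec, seed = 2)
  es <- present_call_filter(g$es)
  de <- de_table(es)
  sel <- select_nontrivial(es, de)
  truth <- g$truth[match(rownames(es$exprs), g$truth$probe_id), ]
  nulls <- truth$probe_id[truth$class == "null"]
  responders <- truth$probe_id[truth$ld_class != "LD-silent"]
  expect_length(intersect(sel, nulls), 0)
  expect_true(all(responders %in% sel))
  relaxed <- select_nontrivial(es, de, alpha = 1)
  expect_true(all(sel %in% relaxed))
  expect_gt(length(relaxed), length(sel) - 1)
})

test_that("low-dose response and dynamics classes recover the planted truth at low noise", {
  g <- generate_expression(quiet_spec, seed = 3)
  es <- present_call_filter(g$es)
  de <- de_table(es)
  truth <- g$truth[match(rownames(es$exprs), g$truth$probe_id), ]
  expect_equal(as.character(classify_ld_response(es, de)), truth$ld_class,
               ignore_attr = TRUE)
  expect_equal(as.character(classify_dynamics(es, "HD", de)), truth$dyn_hd,
               ignore_attr = TRUE)
  expect_equal(as.character(classify_dynamics(es, "LDHD", de)), truth$dyn_ldhd,
               ignore_attr = TRUE)
})

test_that("readout tiers recover the planted candidates and strict implies relaxed", {
  g <- generate_expression(quiet_spec, seed = 4)
  es <- present_call_filter(g$es)
  de <- de_table(es)
  ro <- identify_readouts(es, de)
  truth <- g$truth[match(ro$probe_id, g$truth$probe_id), ]
  expect_true(all(ro$strict <= ro$relaxed))
  expect_setequal(ro$probe_id[ro$relaxed], truth$probe_id[truth$readout_relaxed])
  expect_setequal(ro$probe_id[ro$strict], truth$probe_id[truth$readout_strict])
})

test_that("reshuffling recovers planted transitions with conserved row sums", {
  g <- generate_expression(quiet_spec, seed = 5)
  scr <- screen_expression(g$es)
  truth <- g$truth[match(scr$classification$probe_id, g$truth$probe_id), ]
  keep <- scr$classification$nontrivial
  tr <- scr$reshuffle$transitions
  hd_sizes <- table(factor(truth$dyn_hd[keep],
                           c("early", "late", "persistent", "silent")))
  expect_equal(as.vector(rowSums(tr)), as.vector(hd_sizes))
  moved <- scr$reshuffle$moved
  expect_equal(sum(moved$from == "early" & moved$to == "late"), 3)
  expect_equal(sum(moved$from == "late" & moved$to == "early"), 12)
  expect_equal(length(scr$reshuffle$switched_off), 45)  # 30 early + 15 late
  # identical classifications give a diagonal matrix
  dyn <- classify_dynamics(scr$es, "HD", scr$de)
  tr_id <- reshuffle_analysis(dyn, dyn)$transitions
  expect_equal(sum(tr_id) - sum(diag(tr_id)), 0)
})

test_that("mechanism roles map the planted classes per the screening recipes", {
  g <- generate_expression(quiet_spec, seed = 6)
  scr <- screen_expression(g$es)
  truth <- g$truth[match(scr$classification$probe_id, g$truth$probe_id), ]
  got <- as.character(scr$classification$role)
  for (r in c("PS-regulator", "AI-regulator", "SD-suppressor"))
    expect_setequal(scr$classification$probe_id[got == r],
                    truth$probe_id[truth$role == r])
  expect_true(all(truth$probe_id[truth$role == "HD-partner"] %in%
                    scr$classification$probe_id[got == "HD-partner"]))
})

test_that("screening is deterministic and filter order does not matter", {
  g <- generate_expression(small_spec, seed = 7)
  s1 <- screen_expression(g$es)
  s2 <- screen_expression(g$es)
  expect_identical(s1$classification, s2$classification)
  # the detection-call filter commutes with fold-change filtering (fold
  # changes are per-probe, so filtering order cannot change them)
  es_f <- present_call_filter(g$es)
  fc_hit <- function(es) {
    de <- de_table(es)
    hit <- Reduce(`|`, lapply(de[c("LD", "HD3", "HD24", "LDHD3", "LDHD24")],
                              function(d) d$fc >= 2 | d$fc <= 0.5))
    rownames(es$exprs)[hit]
  }
  expect_setequal(fc_hit(es_f), intersect(fc_hit(g$es), rownames(es_f$exprs)))
})
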