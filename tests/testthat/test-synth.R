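test_that("the generator is deterministic given spec and seed", {
  spec <- synthetic_spec(n_probes = 500)
  g1 <- generate_expression(spec, seed = 10)
  g2 <- generate_expression(spec, seed = 10)
  expect_identical(g1$es$exprs, g2$es$exprs)
  expect_identical(g1$es$calls, g2$es$calls)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_expression(spec, seed = 11)
  expect_false(identical(g1$es$exprs, g3$es$exprs))
})

test_that("an infeasible spec is rejected", {
  expect_error(synthetic_spec(n_probes = 100), "exceed")
  expect_error(generate_expression(synthetic_spec(n_probes = 500)), "seed")
})

test_that("the noiseless limit reproduces the ground truth exactly", {
  spec <- synthetic_spec(n_probes = 600, noise_sd = 1e-4)
  g <- generate_expression(spec, seed = 12)
  scr <- screen_expression(g$es)
  truth <- g$truth[match(scr$classification$probe_id, g$truth$probe_id), ]
  expect_equal(as.character(scr$classification$ld_class), truth$ld_class,
               ignore_attr = TRUE)
  expect_equal(as.character(scr$classification$dynamics_hd), truth$dyn_hd,
               ignore_attr = TRUE)
  expect_equal(as.character(scr$classification$dynamics_ldhd), truth$dyn_ldhd,
               ignore_attr = TRUE)
  expect_equal(scr$classification$readout_relaxed, truth$readout_relaxed)
  expect_equal(scr$classification$readout_strict, truth$readout_strict)
})

test_that("null-gene Welch p-values are uniform", {
  spec <- synthetic_spec(n_probes = 2400)
  g <- generate_expression(spec, seed = 13)
  es <- g$es
  nulls <- g$truth$probe_id[g$truth$class == "null" & !g$truth$absent]
  nulls <- nulls[seq_len(2000)]
  p <- primingscreen:::row_welch(es$exprs[nulls, ],
                                 primingscreen:::cond_cols(es, "LD"),
                                 primingscreen:::cond_cols(es, "Control"))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted network motifs are recovered and decoys stay silent", {
  net <- generate_network(n_ps = 3, n_ai = 2, n_sd = 2, seed = 20)
  found <- find_motifs(net$graph, net$roles, readouts = "R1")
  key <- function(d) paste(d$x1, d$x2, d$x3, d$mechanism)
  expect_true(all(key(net$motifs) %in% key(found)))
  # every emitted motif re-verifies against the path-sign oracle
  need <- list(PS = c(1, 1), AI = c(1, -1), SD = c(-1, 1))
  for (i in seq_len(nrow(found))) {
    s <- need[[found$mechanism[i]]]
    expect_true(s[1] %in% signed_path_sign(net$graph, found$x1[i], found$x3[i], 3))
    expect_true(s[2] %in% signed_path_sign(net$graph, found$x2[i], found$x3[i], 3))
  }
  # decoy genes carry no role, so they can never appear in a motif
  expect_false(any(grepl("^D", c(found$x1, found$x2))))
})

test_that("zero planted motifs yield an empty result", {
  net <- generate_network(n_ps = 0, n_ai = 0, n_sd = 0, seed = 21)
  found <- find_motifs(net$graph, data.frame(gene = character(0),
                                             role = character(0)),
                       readouts = "R1")
  expect_equal(nrow(found), 0)
})

test_that("adding a decoy inhibitor edge never deletes a planted motif", {
  net <- generate_network(n_ps = 2, n_ai = 1, n_sd = 1, seed = 22)
  found1 <- find_motifs(net$graph, net$roles, readouts = "R1")
  edges <- graph_edges(net$graph)
  edges <- rbind(edges, data.frame(from = "DXX", sign = -1, to = "R1",
                                   provenance = "direct"))
  found2 <- find_motifs(signed_graph(edges), net$roles, readouts = "R1")
  key <- function(d) paste(d$x1, d$x2, d$x3, d$mechanism)
  expect_true(all(key(found1) %in% key(found2)))
})
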