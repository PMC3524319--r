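test_that("SIF edge lists parse, merge duplicates and accept cycles", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("TNF\t+\tSTAT1p", "TNF\t+\tSTAT1p", "A\t-\tB\tindirect",
               "B\t+\tA", "# comment", ""), f)
  g <- read_sif(f)
  ed <- graph_edges(g)
  expect_equal(nrow(ed), 3)  # duplicate TNF edge merged
  expect_equal(ed$sign[ed$from == "A"], -1L)
  expect_equal(ed$provenance[ed$from == "A"], "indirect")
  # round trip
  f2 <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, f2)
  expect_equal(graph_edges(read_sif(f2)), ed, ignore_attr = TRUE)
})

test_that("malformed sign tokens are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\t+\tB", "A\t?\tC"), f)
  expect_error(read_sif(f), "line 2")
  writeLines(c("A\t+"), f)
  expect_error(read_sif(f), "3 tab-separated")
})

test_that("duplicate edges keep the strongest provenance", {
  g <- signed_graph(data.frame(from = c("A", "A"), sign = c(1, 1),
                               to = c("B", "B"),
                               provenance = c("indirect", "direct")))
  expect_equal(graph_edges(g)$provenance, "direct")
  expect_error(signed_graph(data.frame(from = "A", sign = 0, to = "B")), "zero")
  expect_error(signed_graph(data.frame(from = c("A", "a"), sign = c(1, 1),
                                       to = c("B", "B"))), "case folding")
})

test_that("path signs multiply along simple paths", {
  g <- signed_graph(data.frame(from = c("A", "B"), sign = c(1, -1),
                               to = c("B", "C")))
  expect_equal(signed_path_sign(g, "A", "C", 3), -1L)
  expect_equal(signed_path_sign(g, "C", "A", 3), integer(0))
  expect_equal(signed_path_sign(g, "A", "Z", 3), integer(0))
  # both signs when parallel routes disagree
  g2 <- signed_graph(data.frame(from = c("A", "A", "M"), sign = c(1, -1, 1),
                                to = c("C", "M", "C")))
  expect_equal(signed_path_sign(g2, "A", "C", 3), c(-1L, 1L))
})

test_that("path-sign enumeration matches a brute-force oracle on random graphs", {
  set.seed(77)
  nodes <- paste0("n", 1:6)
  for (rep in 1:15) {
    ne <- sample(6:12, 1)
    edges <- unique(data.frame(from = sample(nodes, ne, TRUE),
                               sign = sample(c(-1, 1), ne, TRUE),
                               to = sample(nodes, ne, TRUE)))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (!nrow(edges)) next
    g <- signed_graph(edges)
    for (len in 2:4) {
      got <- signed_path_sign(g, "n1", "n6", len)
      want <- brute_force_path_signs(edges, "n1", "n6", len)
      expect_equal(got, want, label = paste("rep", rep, "len", len))
    }
  }
})

fig6_graph <- function() {
  signed_graph(data.frame(
    from = c("TNF", "S100A9", "P38", "IL15", "SOCS1"),
    sign = c(1, 1, 1, 1, -1),
    to = c("STAT1p", "P38", "STAT1p", "STAT1p", "STAT1p"),
    provenance = c("direct", "direct", "direct", "direct", "direct")))
}

test_that("the TNF/S100A9 pathway-synergy fixture yields exactly one motif", {
  roles <- data.frame(gene = c("TNF", "S100A9"),
                      role = c("HD-partner", "PS-regulator"))
  found <- find_motifs(fig6_graph(), roles, readouts = "STAT1p")
  expect_equal(nrow(found), 1)
  expect_equal(found$mechanism, "PS")
  expect_equal(found$x1, "S100A9")   # indirect route via P38, net +1
  expect_equal(found$x2, "TNF")
})

test_that("the IL-15/SOCS1 activator-induction fixture yields exactly one motif", {
  roles <- data.frame(gene = c("IL15", "SOCS1"),
                      role = c("AI-regulator", "HD-partner"))
  found <- find_motifs(fig6_graph(), roles, readouts = "STAT1p")
  expect_equal(nrow(found), 1)
  expect_equal(found$mechanism, "AI")
  expect_equal(found$x1, "IL15")
  expect_equal(found$x2, "SOCS1")
})

test_that("motif search warns on absent readouts and errors on empty readout lists", {
  roles <- data.frame(gene = "TNF", role = "HD-partner")
  expect_warning(out <- find_motifs(fig6_graph(), roles, readouts = "NOPE"),
                 "not in graph")
  expect_equal(nrow(out), 0)
  expect_error(find_motifs(fig6_graph(), roles, readouts = character(0)), "empty")
})

test_that("adding edges never removes motifs and ambiguity is flagged", {
  g <- fig6_graph()
  roles <- data.frame(gene = c("TNF", "S100A9", "IL15", "SOCS1"),
                      role = c("HD-partner", "PS-regulator", "AI-regulator",
                               "HD-partner"))
  base <- find_motifs(g, roles, readouts = "STAT1p")
  ed <- graph_edges(g)
  ed2 <- rbind(ed, data.frame(from = "S100A9", sign = -1, to = "STAT1p",
                              provenance = "indirect"))
  grown <- find_motifs(signed_graph(ed2), roles, readouts = "STAT1p")
  key <- function(d) paste(d$x1, d$x2, d$x3, d$mechanism)
  expect_true(all(key(base) %in% key(grown)))
  # S100A9 now reaches the readout with both signs: its motif is flagged
  expect_true(all(grown$sign_ambiguous[grown$x1 == "S100A9"]))
})

test_that("motifs on small planted graphs match a template brute force", {
  set.seed(123)
  for (rep in 1:6) {
    net <- generate_network(n_ps = sample(0:1, 1), n_ai = sample(0:1, 1),
                            n_sd = sample(0:1, 1), seed = 500 + rep,
                            n_decoys = 2)
    ed <- graph_edges(net$graph)
    found <- find_motifs(net$graph, net$roles, readouts = "R1")
    # brute force: all ordered gene pairs against the sign templates
    need <- list(PS = c(1, 1), AI = c(1, -1), SD = c(-1, 1))
    role_of <- function(gene) net$roles$role[match(gene, net$roles$gene)]
    want <- list()
    for (mech in names(need)) {
      r1 <- switch(mech, PS = "PS-regulator", AI = "AI-regulator",
                   SD = "SD-suppressor")
      r2 <- switch(mech, PS = "HD-partner", AI = "HD-partner",
                   SD = c("HD-partner", "AI-regulator"))
      for (a in net$roles$gene[net$roles$role == r1])
        for (b in net$roles$gene[net$roles$role %in% r2])
          if (a != b &&
              need[[mech]][1] %in% brute_force_path_signs(ed, a, "R1", 3) &&
              need[[mech]][2] %in% brute_force_path_signs(ed, b, "R1", 3))
            want[[length(want) + 1]] <- paste(a, b, "R1", mech)
    }
    key <- paste(found$x1, found$x2, found$x3, found$mechanism)
    expect_setequal(key, if (length(want)) unlist(want) else character(0))
  }
})
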