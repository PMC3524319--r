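#' Specification of the synthetic six-condition expression design
#'
#' Describes a synthetic probes x samples experiment emulating a
#' three-pool macrophage priming time course: six condition groups
#' (Control, LD, HD 3 h, HD 24 h, LD+HD 3 h, LD+HD 24 h), log-normal
#' baseline intensities, multiplicative log-normal replicate noise, and
#' planted gene classes with known fold changes:
#' * LD-induced regulators (split into pathway-synergy-type, whose primed
#'   expression exceeds HD, and activator-induction-type, equal under both
#'   arms), and LD-reduced suppressors;
#' * LD-silent HD-responders with early / late / persistent dynamics,
#'   identical in both arms;
#' * reshufflers whose dynamics class differs between the HD and primed
#'   arms (early-to-late, late-to-early, ...), switched-off and
#'   switched-on genes;
#' * readout candidates: LD-silent, HD-responsive, with primed expression
#'   exceeding HD by a planted excess (above 2-fold for the strict tier,
#'   between 1.5- and 2-fold for relaxed-only candidates);
#' * a planted all-Absent subset exercising the detection-call filter.
#'
#' @param n_probes total probes (default 12000).
#' @param n_pools replicate pools per condition (default 3).
#' @param n_ld_induced,n_ld_reduced planted LD-responsive class sizes
#'   (defaults 27 and 20).
#' @param ps_fraction fraction of LD-induced probes of pathway-synergy
#'   type (default 0.5).
#' @param n_early,n_late,n_persistent LD-silent HD-responder class sizes
#'   (defaults 78, 40, 55).
#' @param n_early_to_late,n_early_to_persistent,n_late_to_early,n_late_to_persistent
#'   planted dynamics reshufflers, drawn from the early/late classes
#'   (defaults 3, 2, 12, 5).
#' @param n_off_early,n_off_late genes responsive under HD but switched
#'   off in the primed arm (defaults 30, 15).
#' @param n_on_early genes silent under HD but early-responsive in the
#'   primed arm (default 27).
#' @param n_readouts,n_readouts_strict readout candidates and how many of
#'   them carry a strict (above 2-fold) primed excess (defaults 5, 2).
#' @param effect_fc planted fold change of responder classes (default 4).
#' @param readout_hd_fc HD response of readouts (default 2.5).
#' @param readout_excess_strict,readout_excess_relaxed primed-over-HD
#'   excess of strict and relaxed-only readouts (defaults 2.2, 1.7).
#' @param noise_sd replicate noise standard deviation on the log2 scale
#'   (default 0.2).
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution
#'   (defaults 8, 1.5).
#' @param absent_frac fraction of probes planted as all-Absent
#'   (default 0.05).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_probes = 12000, n_pools = 3,
                           n_ld_induced = 27, n_ld_reduced = 20, ps_fraction = 0.5,
                           n_early = 78, n_late = 40, n_persistent = 55,
                           n_early_to_late = 3, n_early_to_persistent = 2,
                           n_late_to_early = 12, n_late_to_persistent = 5,
                           n_off_early = 30, n_off_late = 15, n_on_early = 27,
                           n_readouts = 5, n_readouts_strict = 2,
                           effect_fc = 4, readout_hd_fc = 2.5,
                           readout_excess_strict = 2.2, readout_excess_relaxed = 1.7,
                           noise_sd = 0.2, baseline_mean = 8, baseline_sd = 1.5,
                           absent_frac = 0.05) {
  spec <- as.list(environment())
  stopifnot(spec$noise_sd > 0, spec$n_pools >= 2, spec$ps_fraction >= 0,
            spec$ps_fraction <= 1,
            n_early_to_late + n_early_to_persistent + n_off_early <= n_early,
            n_late_to_early + n_late_to_persistent + n_off_late <= n_late,
            n_readouts_strict <= n_readouts)
  planted <- n_ld_induced + n_ld_reduced + n_early + n_late + n_persistent +
    n_on_early + n_readouts
  if (planted > n_probes)
    stop("planted classes (", planted, ") exceed n_probes (", n_probes, ")")
  structure(spec, class = "synthetic_spec")
}

# condition shift matrix rows for one probe class, log2 units
.shift_row <- function(ld = 0, hd3 = 0, hd24 = 0, ldhd3 = 0, ldhd24 = 0) {
  c(Control = 0, LD = ld, HD3 = hd3, HD24 = hd24, LDHD3 = ldhd3, LDHD24 = ldhd24)
}

#' Generate a synthetic expression experiment with ground truth
#'
#' Draws baseline intensities, applies the planted class fold changes on
#' the log2 scale, adds i.i.d. log-normal replicate noise and assembles
#' detection calls. The generated matrix is byte-identical for a given
#' spec and seed.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer seed (mandatory).
#' @return list with `es` (an [expression_set]) and `truth`, a data.frame
#'   with per-probe `class`, expected `ld_class`, `dyn_hd`, `dyn_ldhd`,
#'   `role`, `readout_relaxed`, `readout_strict` and `absent` columns.
#' @export
generate_expression <- function(spec = synthetic_spec(), seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- spec$n_probes
  probe_id <- sprintf("P%05d", seq_len(n))
  gene_symbol <- sprintf("G%05d", seq_len(n))
  lfc <- log2(spec$effect_fc)
  rfc <- log2(spec$readout_hd_fc)

  # assign planted classes to the first probes (order carries no signal:
  # baselines and noise are i.i.d. across probes)
  cls <- rep("null", n)
  idx <- 0L
  take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
  n_ps <- round(spec$n_ld_induced * spec$ps_fraction)
  i_ld_ps <- take(n_ps)
  i_ld_ai <- take(spec$n_ld_induced - n_ps)
  i_ld_red <- take(spec$n_ld_reduced)
  i_early <- take(spec$n_early)
  i_late <- take(spec$n_late)
  i_pers <- take(spec$n_persistent)
  i_on <- take(spec$n_on_early)
  i_read_s <- take(spec$n_readouts_strict)
  i_read_r <- take(spec$n_readouts - spec$n_readouts_strict)
  # reshufflers and switched-off genes are members of the early/late classes
  i_e2l <- i_early[seq_len(spec$n_early_to_late)]
  i_e2p <- i_early[spec$n_early_to_late + seq_len(spec$n_early_to_persistent)]
  i_off_e <- i_early[spec$n_early_to_late + spec$n_early_to_persistent +
                       seq_len(spec$n_off_early)]
  i_l2e <- i_late[seq_len(spec$n_late_to_early)]
  i_l2p <- i_late[spec$n_late_to_early + seq_len(spec$n_late_to_persistent)]
  i_off_l <- i_late[spec$n_late_to_early + spec$n_late_to_persistent +
                      seq_len(spec$n_off_late)]

  cls[i_ld_ps] <- "ld_induced_ps"; cls[i_ld_ai] <- "ld_induced_ai"
  cls[i_ld_red] <- "ld_reduced"
  cls[i_early] <- "early"; cls[i_late] <- "late"; cls[i_pers] <- "persistent"
  cls[i_e2l] <- "early_to_late"; cls[i_e2p] <- "early_to_persistent"
  cls[i_off_e] <- "early_off"
  cls[i_l2e] <- "late_to_early"; cls[i_l2p] <- "late_to_persistent"
  cls[i_off_l] <- "late_off"
  cls[i_on] <- "on_early"
  cls[i_read_s] <- "readout_strict"; cls[i_read_r] <- "readout_relaxed"

  shift_for <- function(class) {
    x_s <- log2(spec$readout_excess_strict)
    x_r <- log2(spec$readout_excess_relaxed)
    switch(class,
      null = .shift_row(),
      ld_induced_ps = .shift_row(ld = lfc, ldhd3 = lfc, ldhd24 = lfc),
      ld_induced_ai = .shift_row(ld = lfc, hd3 = lfc, hd24 = lfc,
                                 ldhd3 = lfc, ldhd24 = lfc),
      ld_reduced = .shift_row(ld = -lfc, ldhd3 = -lfc, ldhd24 = -lfc),
      early = .shift_row(hd3 = lfc, ldhd3 = lfc),
      late = .shift_row(hd24 = lfc, ldhd24 = lfc),
      persistent = .shift_row(hd3 = lfc, hd24 = lfc, ldhd3 = lfc, ldhd24 = lfc),
      early_to_late = .shift_row(hd3 = lfc, ldhd24 = lfc),
      early_to_persistent = .shift_row(hd3 = lfc, ldhd3 = lfc, ldhd24 = lfc),
      early_off = .shift_row(hd3 = lfc),
      late_to_early = .shift_row(hd24 = lfc, ldhd3 = lfc),
      late_to_persistent = .shift_row(hd24 = lfc, ldhd3 = lfc, ldhd24 = lfc),
      late_off = .shift_row(hd24 = lfc),
      on_early = .shift_row(ldhd3 = lfc),
      readout_strict = .shift_row(hd3 = rfc, hd24 = rfc,
                                  ldhd3 = rfc + x_s, ldhd24 = rfc + x_s),
      readout_relaxed = .shift_row(hd3 = rfc, hd24 = rfc,
                                   ldhd3 = rfc + x_r, ldhd24 = rfc + x_r),
      stop("unknown class ", class))
  }

  conds <- rep(priming_conditions(), each = spec$n_pools)
  pools <- rep(seq_len(spec$n_pools), times = length(priming_conditions()))
  sample_id <- paste0(conds, "_", pools)
  base <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  shifts <- t(vapply(cls, shift_for, numeric(6)))
  mu <- base + shifts[, conds]                 # n x samples, log2 scale
  log2mat <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
  exprs <- 2^log2mat
  dimnames(exprs) <- list(probe_id, sample_id)

  # detection calls: planted all-Absent subset among null probes
  n_absent <- round(spec$absent_frac * n)
  i_absent <- which(cls == "null")[seq_len(min(n_absent, sum(cls == "null")))]
  calls <- matrix("P", n, length(conds), dimnames = dimnames(exprs))
  calls[i_absent, ] <- "A"

  dyn_from <- function(h3, h24)
    ifelse(h3 & h24, "persistent", ifelse(h3, "early", ifelse(h24, "late", "silent")))
  truth <- data.frame(
    probe_id = probe_id, gene_symbol = gene_symbol, class = cls,
    ld_class = ifelse(cls %in% c("ld_induced_ps", "ld_induced_ai"), "LD-induced",
               ifelse(cls == "ld_reduced", "LD-reduced", "LD-silent")),
    dyn_hd = dyn_from(shifts[, "HD3"] != 0, shifts[, "HD24"] != 0),
    dyn_ldhd = dyn_from(shifts[, "LDHD3"] != 0, shifts[, "LDHD24"] != 0),
    role = ifelse(cls == "ld_induced_ps", "PS-regulator",
           ifelse(cls == "ld_induced_ai", "AI-regulator",
           ifelse(cls == "ld_reduced", "SD-suppressor",
           ifelse(cls %in% c("early", "late", "persistent", "early_to_late",
                             "early_to_persistent", "late_to_early",
                             "late_to_persistent", "early_off", "late_off"),
                  "HD-partner", "none")))),
    # readout flags follow the definition applied to the planted means:
    # LD-silent with a primed excess over HD at a matching time (some
    # reshufflers and switched-on genes qualify at one time point)
    readout_relaxed = shifts[, "LD"] == 0 &
      (shifts[, "LDHD3"] - shifts[, "HD3"] >= log2(1.5) |
       shifts[, "LDHD24"] - shifts[, "HD24"] >= log2(1.5)),
    readout_strict = shifts[, "LD"] == 0 &
      (shifts[, "LDHD3"] - shifts[, "HD3"] >= 1 |
       shifts[, "LDHD24"] - shifts[, "HD24"] >= 1),
    absent = seq_len(n) %in% i_absent,
    stringsAsFactors = FALSE)

  samples <- data.frame(sample_id = sample_id, condition = conds, pool = pools,
                        stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       stringsAsFactors = FALSE)
  list(es = expression_set(exprs, samples, probes, calls), truth = truth)
}

#' Generate a signed network with planted priming motifs
#'
#' Builds a regulatory graph around one or more readout nodes in which
#' each requested motif follows its mechanism template (PS: two
#' activating paths; AI: activating regulator plus inhibiting partner;
#' SD: inhibiting suppressor plus activating partner). A fraction of
#' connections is routed through intermediate nodes (provenance
#' `indirect`), and decoy edges violating the sign templates are added.
#'
#' @param n_ps,n_ai,n_sd planted motif counts (defaults 3, 2, 2).
#' @param seed integer seed.
#' @param readout readout node name (default `"R1"`).
#' @param indirect_frac fraction of regulator-readout connections routed
#'   via an intermediate node (default 0.3).
#' @param n_decoys number of template-violating decoy edges (default 6).
#' @return list with `graph` (a [signed_graph]), `motifs` (data.frame of
#'   planted `x1`, `x2`, `x3`, `mechanism`) and `roles` (data.frame with
#'   `gene`, `role`, `ldhd_similar`) suitable for [find_motifs()].
#' @export
generate_network <- function(n_ps = 3, n_ai = 2, n_sd = 2, seed = 1,
                             readout = "R1", indirect_frac = 0.3, n_decoys = 6) {
  set.seed(seed)
  edges <- list()
  roles <- list()
  motifs <- list()
  inter_count <- 0L
  add_edge <- function(from, sign, to, via_intermediate) {
    if (via_intermediate) {
      inter_count <<- inter_count + 1L
      mid <- sprintf("I%02d", inter_count)
      # net sign preserved: put the sign on the first hop
      edges[[length(edges) + 1L]] <<- data.frame(from = from, sign = sign, to = mid,
                                                 provenance = "indirect")
      edges[[length(edges) + 1L]] <<- data.frame(from = mid, sign = 1, to = to,
                                                 provenance = "indirect")
    } else {
      edges[[length(edges) + 1L]] <<- data.frame(from = from, sign = sign, to = to,
                                                 provenance = "direct")
    }
  }
  plant <- function(kind, i) {
    a <- sprintf("%sA%02d", kind, i)   # LD-responsive regulator / suppressor
    b <- sprintf("%sB%02d", kind, i)   # partner
    via_a <- stats::runif(1) < indirect_frac
    via_b <- stats::runif(1) < indirect_frac
    if (kind == "PS") {
      add_edge(a, 1, readout, via_a); add_edge(b, 1, readout, via_b)
      roles[[length(roles) + 1L]] <<- data.frame(
        gene = c(a, b), role = c("PS-regulator", "HD-partner"),
        ldhd_similar = c(FALSE, TRUE))
    } else if (kind == "AI") {
      add_edge(a, 1, readout, via_a); add_edge(b, -1, readout, via_b)
      roles[[length(roles) + 1L]] <<- data.frame(
        gene = c(a, b), role = c("AI-regulator", "HD-partner"),
        ldhd_similar = c(TRUE, TRUE))
    } else {
      add_edge(a, -1, readout, via_a); add_edge(b, 1, readout, via_b)
      roles[[length(roles) + 1L]] <<- data.frame(
        gene = c(a, b), role = c("SD-suppressor", "HD-partner"),
        ldhd_similar = c(FALSE, TRUE))
    }
    motifs[[length(motifs) + 1L]] <<- data.frame(x1 = a, x2 = b, x3 = readout,
                                                 mechanism = kind)
  }
  for (i in seq_len(n_ps)) plant("PS", i)
  for (i in seq_len(n_ai)) plant("AI", i)
  for (i in seq_len(n_sd)) plant("SD", i)
  # decoys: unlabeled genes touching the readout, and wrong-sign edges
  # between labeled genes that do not create new role-consistent paths
  for (d in seq_len(n_decoys)) {
    dn <- sprintf("D%02d", d)
    add_edge(dn, sample(c(-1, 1), 1), readout, FALSE)
  }
  graph <- signed_graph(do.call(rbind, edges))
  empty_motifs <- data.frame(x1 = character(0), x2 = character(0),
                             x3 = character(0), mechanism = character(0))
  empty_roles <- data.frame(gene = character(0), role = character(0),
                            ldhd_similar = logical(0))
  list(graph = graph,
       motifs = if (length(motifs)) do.call(rbind, motifs) else empty_motifs,
       roles = if (length(roles)) do.call(rbind, roles) else empty_roles)
}

#' Hand-constructed exemplar parameter sets for the three priming mechanisms
#'
#' Three fixed three-node parameter sets, one per mechanism, that satisfy
#' the full priming criterion and classify to their intended label:
#' * `PS` (pathway synergy, activating topology): the x1 pathway is fast
#'   with a high stimulus threshold, the x2 pathway slow with a low
#'   threshold, both activate the readout; low-dose pretreatment
#'   pre-builds x2 so the two pathways transiently synergize.
#' * `AI` (activator induction, inhibitory topology with a negligible
#'   internal edge): x2 is a slow low-threshold activator pre-induced by
#'   the low dose, x1 a high-dose-induced inhibitor; pretreatment lets the
#'   activator outrun the inhibitor while the x2 maxima under LD+HD and
#'   HD remain indistinguishable.
#' * `SD` (suppressor deactivation, inhibitory topology): x1 is a
#'   basally active suppressor of the readout, repressed by the
#'   LD-responsive x2; pretreatment lowers the suppressor so the
#'   high-dose response is disinhibited (the slow x2 build-up also fires
#'   the synergy rule; the suppressor rule takes precedence).
#'
#' @return named list of `trinode_params` (`PS`, `AI`, `SD`).
#' @export
generate_trinode_exemplars <- function() {
  nodes <- c("S", "x1", "x2", "x3")
  mk <- function(kind, k, g, KS1, KS2, w13, K13, w23, K23,
                 w21 = NA, K21 = NA, b1 = 0.01) {
    topo <- trinode_default_topology(kind)
    w <- matrix(1, 4, 4, dimnames = list(nodes, nodes))
    K <- matrix(0.5, 4, 4, dimnames = list(nodes, nodes))
    K["S", "x1"] <- KS1; K["S", "x2"] <- KS2
    w["x1", "x3"] <- w13; K["x1", "x3"] <- K13
    w["x2", "x3"] <- w23; K["x2", "x3"] <- K23
    if (!is.na(w21)) { w["x2", "x1"] <- w21; K["x2", "x1"] <- K21 }
    trinode_params(topo, k = c(x1 = k[1], x2 = k[2], x3 = k[3]),
                   gamma = c(x1 = g[1], x2 = g[2], x3 = g[3]),
                   w = w, K = K, b = c(b1, 0.01, 0.01))
  }
  list(
    PS = mk("activating", k = c(2.9889, 0.0093, 1.3301),
            g = c(1.6556, 0.0060, 2.9428), KS1 = 0.7115, KS2 = 0.0505,
            w13 = 0.2316, K13 = 0.5343, w23 = 3.6518, K23 = 0.8453),
    AI = mk("inhibitory", k = c(0.1084, 0.4028, 2.9924),
            g = c(0.1286, 0.0929, 2.5543), KS1 = 0.6276, KS2 = 0.1920,
            w13 = 6.3030, K13 = 0.2689, w23 = 0.7095, K23 = 0.7007,
            w21 = 0.0616, K21 = 1.7477, b1 = 0.0109),
    SD = mk("inhibitory", k = c(0.3110, 0.0070, 2.5854),
            g = c(0.0261, 0.0046, 1.9732), KS1 = 1.2247, KS2 = 0.0953,
            w13 = 0.5907, K13 = 0.5843, w23 = 5.0190, K23 = 0.8265,
            w21 = 9.4921, K21 = 0.1465, b1 = 0.2158))
}
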