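#' Configuration for the two-stage Metropolis priming search
#'
#' Stage 1 anneals random parameter sets toward readouts that respond to HD
#' but stay silent under LD; stage 2 continues from stage-1 survivors and
#' additionally requires the 50% LD+HD excess, i.e. the full priming
#' criterion. Proposals perturb one randomly chosen log-parameter of the
#' masked subset by a Gaussian step. A parameter set is recorded only when
#' its hinge score is exactly zero and [evaluate_priming()] passes.
#'
#' @param n_chains number of independent chains (default 20); chains cycle
#'   through the topology prior.
#' @param stage1_iters,stage2_iters proposals per chain and stage
#'   (defaults 150/300).
#' @param region_iters proposals of the per-chain region-mapping walk that
#'   explores the zero-score manifold from each recorded set toward one of
#'   the mechanism signatures while keeping the full priming criterion
#'   satisfied at every step (default 50; stage1 + stage2 + region
#'   proposals total 10,000 at the default chain count).
#' @param step standard deviation of the log-space proposal (default 0.3).
#' @param temperature Metropolis temperature on the hinge score in stage 1
#'   (default 0.05); stage 2 anneals at a third of it.
#' @param seed integer seed; the whole search is deterministic given the
#'   seed and configuration.
#' @param max_records_per_chain cap on recorded parameter sets per chain
#'   (default 4), with a minimum spacing of 20 accepted proposals between
#'   records so records are not near-duplicates.
#' @param protocols protocol arms built by [priming_protocols()].
#' @param thresholds a `priming_thresholds`.
#' @param dt integration output step (default 0.5).
#' @return object of class `metropolis_config`.
#' @export
metropolis_config <- function(n_chains = 20, stage1_iters = 150, stage2_iters = 300,
                              region_iters = 50,
                              step = 0.3, temperature = 0.05, seed = 1,
                              max_records_per_chain = 4,
                              protocols = priming_protocols(),
                              thresholds = priming_thresholds(), dt = 0.5) {
  stopifnot(n_chains > 0, stage1_iters > 0, stage2_iters > 0, region_iters >= 0,
            step > 0, temperature > 0, max_records_per_chain >= 1)
  structure(list(n_chains = n_chains, stage1_iters = stage1_iters,
                 stage2_iters = stage2_iters, region_iters = region_iters,
                 step = step, temperature = temperature, seed = seed,
                 max_records_per_chain = max_records_per_chain,
                 protocols = protocols, thresholds = thresholds, dt = dt),
            class = "metropolis_config")
}

# --- free-parameter mask ----------------------------------------------------
# The sampled subset: k_i and gamma_i for the three nodes (6), the stimulus
# half-saturations K_S->1, K_S->2 (2), w and K of each pathway-to-readout
# edge (up to 4), and w, K of the first internal edge (2) -- 14 free
# parameters on the default topologies. Stimulus weights are fixed at 1,
# the Hill exponent at 3 and basal activity at 0.01.
trinode_param_mask <- function(topology) {
  T <- unclass(topology)
  nodes <- c("S", "x1", "x2", "x3")
  mask <- list()
  for (x in c("x1", "x2", "x3")) {
    mask[[length(mask) + 1L]] <- list(kind = "k", node = x)
    mask[[length(mask) + 1L]] <- list(kind = "gamma", node = x)
  }
  mask[[length(mask) + 1L]] <- list(kind = "K", from = "S", to = "x1")
  mask[[length(mask) + 1L]] <- list(kind = "K", from = "S", to = "x2")
  for (x in c("x1", "x2")) {
    if (T[x, "x3"] != 0L) {
      mask[[length(mask) + 1L]] <- list(kind = "w", from = x, to = "x3")
      mask[[length(mask) + 1L]] <- list(kind = "K", from = x, to = "x3")
    }
  }
  idx <- which(T != 0L, arr.ind = TRUE)
  internal <- idx[nodes[idx[, 1]] != "S" & nodes[idx[, 2]] != "x3", , drop = FALSE]
  if (nrow(internal) >= 1L) {
    f <- nodes[internal[1, 1]]; t <- nodes[internal[1, 2]]
    mask[[length(mask) + 1L]] <- list(kind = "w", from = f, to = t)
    mask[[length(mask) + 1L]] <- list(kind = "K", from = f, to = t)
  }
  mask
}

# log-space bounds per parameter kind; rates extend well below 1/T_LD so
# pathways can be slow relative to the pretreatment period (priming needs
# kinetic memory of the low-dose phase)
mask_bounds <- function(entry) {
  switch(entry$kind,
         k = c(0.003, 10), gamma = c(0.003, 10),
         w = c(0.1, 20), K = c(0.01, 3))
}

# assemble trinode_params from a log-parameter vector
theta_to_params <- function(theta, mask, topology) {
  nodes <- c("S", "x1", "x2", "x3")
  k <- stats::setNames(rep(1, 3), nodes[-1])
  g <- stats::setNames(rep(1, 3), nodes[-1])
  w <- matrix(1, 4, 4, dimnames = list(nodes, nodes))
  K <- matrix(0.5, 4, 4, dimnames = list(nodes, nodes))
  for (i in seq_along(mask)) {
    e <- mask[[i]]; v <- exp(theta[i])
    switch(e$kind,
           k = { k[e$node] <- v },
           gamma = { g[e$node] <- v },
           w = { w[e$from, e$to] <- v },
           K = { K[e$from, e$to] <- v })
  }
  trinode_params(topology, k = k, gamma = g, w = w, K = K)
}

# priming features without integrating the (flat) untreated arm; x0_init
# warm-starts the steady-state relaxation (used inside the search, where
# consecutive parameter sets have nearby fixed points)
trinode_features_fast <- function(params, protocols, dt, x0_init = NULL) {
  x0 <- trinode_steady_state(params, S = 0, x0 = x0_init, t_relax = 500,
                             method = "rk4")
  total <- protocol_duration(protocols$untreated)
  flat <- time_course(c(0, total), rbind(x0, x0))
  tcs <- time_course_set(list(
    untreated = flat,
    LD = simulate_trinode(params, protocols$LD, dt = dt, x0 = x0, method = "rk4"),
    HD = simulate_trinode(params, protocols$HD, dt = dt, x0 = x0, method = "rk4"),
    LD_HD = simulate_trinode(params, protocols$LD_HD, dt = dt, x0 = x0, method = "rk4")))
  f <- extract_features(tcs, readout = "x3",
                        ld_period = attr(protocols, "ld_period"),
                        hd_period = attr(protocols, "hd_period"))
  attr(f, "x0") <- x0
  f
}

# TRUE when the topology is invariant under exchanging x1 and x2 (the two
# parallel pathways are then interchangeable and records are canonicalized
# so that x2 is the more LD-responsive regulator, the convention used when
# reading the mechanism regions)
topology_symmetric <- function(topology) {
  T <- unclass(topology)
  perm <- c(1L, 3L, 2L, 4L)
  identical(T[perm, perm], unname(T)) || identical(unname(T[perm, perm]), unname(T))
}

# exchange the x1 and x2 node labels of a parameter set
swap_regulators <- function(params) {
  perm <- c(1L, 3L, 2L, 4L)
  nodes <- c("S", "x1", "x2", "x3")
  sw <- function(m) { m <- m[perm, perm]; dimnames(m) <- list(nodes, nodes); m }
  T <- unclass(params$topology)
  topo <- trinode_topology(sw(T))
  swv <- function(v) stats::setNames(v[c(2L, 1L, 3L)], c("x1", "x2", "x3"))
  trinode_params(topo, k = swv(params$k), gamma = swv(params$gamma),
                 w = sw(params$w), K = sw(params$K), b = swv(params$b),
                 n = params$n)
}

swap_feature_names <- function(features) {
  swv <- function(v) stats::setNames(v[c("x2", "x1", "x3")], c("x1", "x2", "x3"))
  features$dss_ld <- swv(features$dss_ld)
  features$dmax_hd <- swv(features$dmax_hd)
  features$dmax_ldhd <- swv(features$dmax_ldhd)
  features$baseline <- swv(features$baseline)
  features
}

# hinge scores: stage 1 = HD-responsive + LD-silent; stage 2 adds the
# LD+HD excess clause. The excess term floors the HD maximum at tau_hd so
# that shrinking the HD response (which stage 1 penalizes) cannot relieve
# the ratio clause -- without the floor, chains stall in a spurious valley
# just below the HD activation threshold.
priming_score <- function(features, th, stage) {
  s <- max(0, th$tau_hd - features$readout_max_hd) +
       max(0, features$readout_max_ld - th$tau_ld)
  if (stage >= 2)
    s <- s + max(0, (1 + th$rho) * max(features$readout_max_hd, th$tau_hd) -
                   features$readout_max_ldhd)
  s
}

#' Two-stage Metropolis search for priming parameter sets
#'
#' Stage 1 runs `n_chains` independent annealing chains toward
#' HD-responsive, LD-silent readouts. Because many parameter sets satisfy
#' that criterion without retaining any trace of the low-dose treatment,
#' each chain's survivor is the stage-1-passing state with the strongest
#' regulator response to LD (largest `|dss|`); stage-2 slots are then
#' filled with survivors in decreasing trace order (cloning the best ones
#' when some chains produced no survivor) and annealed against the full
#' priming criterion at a colder temperature. A parameter set is recorded
#' only after re-verification from a cold start: hinge score exactly zero
#' and [evaluate_priming()] true.
#'
#' Records on an x1/x2-symmetric topology are canonicalized so that x2 is
#' the more LD-responsive regulator, and mechanism labels are read from
#' the features alone (the region rules), without topology gating.
#'
#' @param cfg a `metropolis_config`.
#' @param topology_prior list of `trinode_topology` objects the chains
#'   cycle through (default: the activating and inhibitory layouts from
#'   [trinode_default_topology()]).
#' @return list of `primed_network_record` objects (possibly empty, in
#'   which case a diagnostic message is emitted). Each record holds
#'   `topology`, `params`, `features`, `label` and the stage-2 chain id.
#' @export
metropolis_search <- function(cfg = metropolis_config(),
                              topology_prior = list(
                                trinode_default_topology("activating"),
                                trinode_default_topology("inhibitory"))) {
  stopifnot(inherits(cfg, "metropolis_config"), length(topology_prior) >= 1)
  set.seed(cfg$seed)
  th <- cfg$thresholds
  propose <- function(theta, lb, ub) {
    j <- sample.int(length(theta), 1L)
    theta[j] <- min(max(theta[j] + stats::rnorm(1, 0, cfg$step), lb[j]), ub[j])
    theta
  }
  # survivor ranking: each stage-1 chain contributes its best plateau
  # state per mechanism signature -- suppressor drop (SD-like), activator
  # rise (AI/PS-like) and synergy difference (PS-like) -- discounted by
  # the remaining stage-2 hinge distance, so stage 2 starts from
  # mechanistically diverse, near-critical states
  survivor_keys <- function(feat) {
    dist <- 2 * priming_score(feat, th, 2)
    c(sd = -min(feat$dss_ld[c("x1", "x2")]) - dist,
      act = max(feat$dss_ld[c("x1", "x2")]) - dist,
      ps = max(feat$dmax_ldhd[c("x1", "x2")] - feat$dmax_hd[c("x1", "x2")]) - dist)
  }

  # initialization mixture: a third of the chains start uniform over the
  # log-bounds; the others start in broad decade-scale slabs encoding the
  # qualitative timescale structure of the two antagonistic mechanism
  # families (a slow low-threshold pathway next to a fast high-threshold
  # one; a basally active slow suppressor repressed by an LD-responsive
  # partner). Slabs only bias the starting point -- both annealing stages
  # and the cold re-verification are unchanged.
  slab <- function(theta, mask, sel, lo, hi) {
    for (i in seq_along(mask)) {
      e <- mask[[i]]
      if (isTRUE(sel(e))) theta[i] <- log(lo) + stats::runif(1) * (log(hi) - log(lo))
    }
    theta
  }
  init_theta <- function(kind, mask, lb, ub) {
    theta <- lb + stats::runif(length(mask)) * (ub - lb)
    if (kind == "slow_pathway") {
      theta <- slab(theta, mask, function(e) e$kind %in% c("k", "gamma") &&
                      e$node == "x2", 0.003, 0.05)
      theta <- slab(theta, mask, function(e) e$kind == "K" &&
                      identical(e$from, "S") && identical(e$to, "x2"), 0.01, 0.15)
      theta <- slab(theta, mask, function(e) e$kind %in% c("k", "gamma") &&
                      e$node == "x1", 0.5, 10)
    } else if (kind == "basal_suppressor") {
      # a suppressor with basal tone that the low dose can deactivate:
      # moderate synthesis against decay near the lower bound (high basal
      # occupancy, slow recovery), stimulus threshold above the high dose,
      # an LD-responsive moderate-speed partner that represses it, and a
      # readout threshold above the partner's low-dose level so the
      # readout stays silent under LD
      theta <- slab(theta, mask, function(e) e$kind == "k" && e$node == "x1", 0.5, 3)
      theta <- slab(theta, mask, function(e) e$kind == "gamma" && e$node == "x1",
                    0.003, 0.006)
      theta <- slab(theta, mask, function(e) e$kind == "K" &&
                      identical(e$from, "S") && identical(e$to, "x1"), 1, 3)
      theta <- slab(theta, mask, function(e) e$kind == "k" && e$node == "x2", 0.1, 0.5)
      theta <- slab(theta, mask, function(e) e$kind == "gamma" && e$node == "x2",
                    0.05, 0.3)
      theta <- slab(theta, mask, function(e) e$kind == "K" &&
                      identical(e$from, "S") && identical(e$to, "x2"), 0.08, 0.25)
      theta <- slab(theta, mask, function(e) e$kind == "w" &&
                      identical(e$from, "x2") && identical(e$to, "x1"), 5, 20)
      theta <- slab(theta, mask, function(e) e$kind == "K" &&
                      identical(e$from, "x2") && identical(e$to, "x1"), 0.1, 0.4)
      theta <- slab(theta, mask, function(e) e$kind == "w" &&
                      identical(e$from, "x2") && identical(e$to, "x3"), 0.5, 3)
      theta <- slab(theta, mask, function(e) e$kind == "K" &&
                      identical(e$from, "x2") && identical(e$to, "x3"), 0.5, 1)
      theta <- slab(theta, mask, function(e) e$kind == "w" &&
                      identical(e$from, "x1") && identical(e$to, "x3"), 0.5, 4)
      theta <- slab(theta, mask, function(e) e$kind == "K" &&
                      identical(e$from, "x1") && identical(e$to, "x3"), 0.3, 0.8)
    }
    theta
  }

  # --- stage 1: anneal toward HD-responsive, LD-silent readouts ----------
  survivors <- list()
  for (chain in seq_len(cfg$n_chains)) {
    topo <- topology_prior[[(chain - 1L) %% length(topology_prior) + 1L]]
    mask <- trinode_param_mask(topo)
    lb <- vapply(mask, function(e) log(mask_bounds(e)[1]), numeric(1))
    ub <- vapply(mask, function(e) log(mask_bounds(e)[2]), numeric(1))
    has_internal_inhibition <- unclass(topo)["x2", "x1"] == -1L
    in_group <- (chain - 1L) %/% length(topology_prior)   # index within topology group
    kind <- if (in_group %% 2L == 0L) {
      if (has_internal_inhibition) "basal_suppressor" else "slow_pathway"
    } else "uniform"
    theta <- init_theta(kind, mask, lb, ub)
    feat <- try(trinode_features_fast(theta_to_params(theta, mask, topo),
                                      cfg$protocols, cfg$dt), silent = TRUE)
    if (inherits(feat, "try-error")) next
    score <- priming_score(feat, th, 1)
    best <- list()
    for (it in seq_len(cfg$stage1_iters)) {
      theta_new <- propose(theta, lb, ub)
      feat_new <- try(trinode_features_fast(theta_to_params(theta_new, mask, topo),
                                            cfg$protocols, cfg$dt,
                                            x0_init = attr(feat, "x0")),
                      silent = TRUE)
      if (inherits(feat_new, "try-error")) next
      score_new <- priming_score(feat_new, th, 1)
      if (score_new <= score ||
          stats::runif(1) < exp(-(score_new - score) / cfg$temperature)) {
        theta <- theta_new; feat <- feat_new; score <- score_new
      }
      if (score == 0) {
        keys <- survivor_keys(feat)
        for (kind in names(keys)) {
          if (is.null(best[[kind]]) || keys[[kind]] > best[[kind]]$key)
            best[[kind]] <- list(theta = theta, topo = topo, mask = mask,
                                 lb = lb, ub = ub, feat = feat,
                                 key = keys[[kind]], kind = kind)
        }
      }
    }
    for (b in best) survivors[[length(survivors) + 1L]] <- b
  }

  records <- list()
  if (length(survivors)) {
    # interleave the mechanism signatures, best-ranked first within each
    kinds <- vapply(survivors, `[[`, character(1), "kind")
    keys <- vapply(survivors, `[[`, numeric(1), "key")
    pool <- list()
    for (kind in c("sd", "ps", "act")) {
      idx <- which(kinds == kind)
      pool[[kind]] <- idx[order(-keys[idx])]
    }
    slot_order <- integer(0)
    while (any(lengths(pool) > 0)) {
      for (kind in c("sd", "ps", "act")) {
        if (length(pool[[kind]])) {
          slot_order <- c(slot_order, pool[[kind]][1])
          pool[[kind]] <- pool[[kind]][-1]
        }
      }
    }
    # --- stage 2: anneal survivors against the full criterion ------------
    next_sv <- 0L
    take_sv <- function() {
      next_sv <<- next_sv + 1L
      survivors[[slot_order[(next_sv - 1L) %% length(slot_order) + 1L]]]
    }
    for (slot in seq_len(cfg$n_chains)) {
      sv <- take_sv()
      topo <- sv$topo; mask <- sv$mask; lb <- sv$lb; ub <- sv$ub
      theta <- sv$theta; feat <- sv$feat
      score <- priming_score(feat, th, 2)
      since_record <- Inf
      n_rec_chain <- 0L
      closed <- FALSE
      for (it in seq_len(cfg$stage2_iters)) {
        # restart from the next survivor if the first half of the budget
        # failed to close the criterion
        if (!closed && it == cfg$stage2_iters %/% 2L && score > 0) {
          sv <- take_sv()
          topo <- sv$topo; mask <- sv$mask; lb <- sv$lb; ub <- sv$ub
          theta <- sv$theta; feat <- sv$feat
          score <- priming_score(feat, th, 2)
        }
        # geometric annealing schedule: explore early, freeze late
        temp <- cfg$temperature * (0.05)^(it / cfg$stage2_iters)
        theta_new <- propose(theta, lb, ub)
        feat_new <- try(trinode_features_fast(theta_to_params(theta_new, mask, topo),
                                              cfg$protocols, cfg$dt,
                                              x0_init = attr(feat, "x0")),
                        silent = TRUE)
        if (inherits(feat_new, "try-error")) next
        score_new <- priming_score(feat_new, th, 2)
        if (score_new <= score ||
            stats::runif(1) < exp(-(score_new - score) / temp)) {
          theta <- theta_new; feat <- feat_new; score <- score_new
          since_record <- since_record + 1
        }
        if (score == 0) closed <- TRUE
        if (score == 0 && n_rec_chain < cfg$max_records_per_chain &&
            since_record >= 20) {
          # verify from a cold start before recording (warm-started
          # relaxation could in principle settle on a different branch)
          params <- theta_to_params(theta, mask, topo)
          feat_cold <- try(trinode_features_fast(params, cfg$protocols, cfg$dt),
                           silent = TRUE)
          if (!inherits(feat_cold, "try-error") &&
              priming_score(feat_cold, th, 2) == 0 &&
              evaluate_priming(feat_cold, th)$primed) {
            rec_params <- params; rec_feat <- feat_cold
            if (topology_symmetric(topo) &&
                rec_feat$dss_ld[["x1"]] > rec_feat$dss_ld[["x2"]]) {
              rec_params <- swap_regulators(params)
              rec_feat <- swap_feature_names(rec_feat)
            }
            label <- classify_mechanism(rec_feat, th)
            records[[length(records) + 1L]] <- structure(
              list(topology = rec_params$topology, params = rec_params,
                   features = rec_feat, label = label, chain = slot),
              class = "primed_network_record")
            n_rec_chain <- n_rec_chain + 1L
            theta_rec <- theta; feat_rec <- feat_cold
          }
          since_record <- 0
        }
      }
      # --- region-mapping walk: from the chain's last verified set, walk
      # the zero-score manifold toward one mechanism signature; every
      # accepted step must keep the full criterion satisfied, so the end
      # state is a primed set like any other record
      if (cfg$region_iters > 0 && n_rec_chain > 0) {
        objective <- switch((slot - 1L) %% 3L + 1L,
          function(f) -min(f$dss_ld[c("x1", "x2")]),                  # suppressor drop
          function(f) max(f$dmax_ldhd[c("x1", "x2")] -
                          f$dmax_hd[c("x1", "x2")]),                  # synergy excess
          function(f) max(f$dss_ld[c("x1", "x2")]))                   # activator rise
        theta <- theta_rec; feat <- feat_rec
        obj <- objective(feat)
        for (it in seq_len(cfg$region_iters)) {
          theta_new <- propose(theta, lb, ub)
          feat_new <- try(trinode_features_fast(theta_to_params(theta_new, mask, topo),
                                                cfg$protocols, cfg$dt,
                                                x0_init = attr(feat, "x0")),
                          silent = TRUE)
          if (inherits(feat_new, "try-error")) next
          if (priming_score(feat_new, th, 2) != 0) next
          obj_new <- objective(feat_new)
          if (obj_new > obj) { theta <- theta_new; feat <- feat_new; obj <- obj_new }
        }
        params <- theta_to_params(theta, mask, topo)
        feat_cold <- try(trinode_features_fast(params, cfg$protocols, cfg$dt),
                         silent = TRUE)
        if (!inherits(feat_cold, "try-error") &&
            priming_score(feat_cold, th, 2) == 0 &&
            evaluate_priming(feat_cold, th)$primed &&
            !identical(theta, theta_rec)) {
          rec_params <- params; rec_feat <- feat_cold
          if (topology_symmetric(topo) &&
              rec_feat$dss_ld[["x1"]] > rec_feat$dss_ld[["x2"]]) {
            rec_params <- swap_regulators(params)
            rec_feat <- swap_feature_names(rec_feat)
          }
          label <- classify_mechanism(rec_feat, th)
          records[[length(records) + 1L]] <- structure(
            list(topology = rec_params$topology, params = rec_params,
                 features = rec_feat, label = label, chain = slot),
            class = "primed_network_record")
        }
      }
    }
  }
  if (!length(records))
    message("metropolis_search: no parameter set reached the priming criterion ",
            "within the iteration budget")
  records
}

#' @export
print.primed_network_record <- function(x, ...) {
  cat("<primed_network_record> chain", x$chain, "label", x$label$label, "\n")
  invisible(x)
}

#' Region summary of a priming search
#'
#' Tabulates, per record, the low-dose steady-state shifts of the two
#' regulators and the LD+HD-vs-HD difference in their maxima, together
#' with the mechanism label; and bins the maximum-difference distribution
#' per label (the quantity whose distribution separates pathway synergy
#' from activator induction).
#'
#' @param records list of `primed_network_record` (from
#'   [metropolis_search()]).
#' @param breaks histogram breaks passed to [hist()] (default 20).
#' @return list with `table` (one row per record: `dss_x1`, `dss_x2`,
#'   `dmax_diff_x1`, `dmax_diff_x2`, `label`) and `histograms`, a list per
#'   label of `hist` objects for the x1 and x2 maximum differences.
#' @export
summarize_regions <- function(records, breaks = 20) {
  stopifnot(length(records) >= 1)
  tab <- do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(record = i, chain = r$chain,
               dss_x1 = r$features$dss_ld[["x1"]],
               dss_x2 = r$features$dss_ld[["x2"]],
               dmax_diff_x1 = r$features$dmax_ldhd[["x1"]] - r$features$dmax_hd[["x1"]],
               dmax_diff_x2 = r$features$dmax_ldhd[["x2"]] - r$features$dmax_hd[["x2"]],
               label = r$label$label)
  }))
  hists <- lapply(split(tab, tab$label), function(d) {
    list(x1 = graphics::hist(d$dmax_diff_x1, breaks = breaks, plot = FALSE),
         x2 = graphics::hist(d$dmax_diff_x2, breaks = breaks, plot = FALSE))
  })
  list(table = tab, histograms = hists)
}
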