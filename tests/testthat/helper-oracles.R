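# Independent oracles used across the suite.

# Brute-force enumeration of all simple directed paths (<= max_len edges)
# and their net signs, independent of igraph. Edges: data.frame(from,
# sign, to). Parallel edges of opposite sign are enumerated separately.
brute_force_path_signs <- function(edges, src, dst, max_len) {
  signs <- integer(0)
  recurse <- function(node, visited, sign, depth) {
    if (depth > max_len) return()
    out <- edges[edges$from == node, , drop = FALSE]
    for (r in seq_len(nrow(out))) {
      nxt <- out$to[r]
      s <- sign * out$sign[r]
      if (nxt == dst) {
        signs <<- union(signs, s)
      } else if (!(nxt %in% visited)) {
        recurse(nxt, c(visited, nxt), s, depth + 1L)
      }
    }
  }
  recurse(src, c(src), 1L, 1L)
  sort(as.integer(signs))
}

# Benjamini-Hochberg step-up computed from the definition: sort, p*(m/i),
# cumulative minimum from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# fabricate a priming_features object that passes the default criteria,
# with chosen regulator features
fab_features <- function(dss_x1 = 0, dss_x2 = 0, dmax_hd_x2 = 0.4,
                         dmax_diff_x2 = 0, ld = 0.05, hd = 0.4, ldhd = 0.65) {
  priming_features(
    dss_ld = c(x1 = dss_x1, x2 = dss_x2),
    dmax_hd = c(x1 = 0.4, x2 = dmax_hd_x2),
    dmax_ldhd = c(x1 = 0.4, x2 = dmax_hd_x2 + dmax_diff_x2),
    readout_max_ld = ld, readout_max_hd = hd, readout_max_ldhd = ldhd,
    readout = "x3")
}

# small random trinode parameter set within the search bounds
random_trinode_params <- function(topology) {
  mask <- primingscreen:::trinode_param_mask(topology)
  lb <- vapply(mask, function(e) log(primingscreen:::mask_bounds(e)[1]), numeric(1))
  ub <- vapply(mask, function(e) log(primingscreen:::mask_bounds(e)[2]), numeric(1))
  theta <- lb + stats::runif(length(mask)) * (ub - lb)
  primingscreen:::theta_to_params(theta, mask, topology)
}

# scaled-down synthetic design for cheap i/o and plumbing tests
tiny_spec <- function(n_probes = 60, noise_sd = 0.2) {
  synthetic_spec(n_probes = n_probes, noise_sd = noise_sd,
                 n_ld_induced = 4, n_ld_reduced = 3,
                 n_early = 6, n_late = 5, n_persistent = 4,
                 n_early_to_late = 1, n_early_to_persistent = 1,
                 n_late_to_early = 1, n_late_to_persistent = 1,
                 n_off_early = 2, n_off_late = 1, n_on_early = 2,
                 n_readouts = 2, n_readouts_strict = 1)
}
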