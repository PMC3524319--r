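#' Three-node motif topology
#'
#' The generic priming motif: a stimulus S activates two parallel pathways
#' (x1 and x2) that converge on a monitored readout x3. Edge signs are
#' given as a 4 x 4 matrix `T[j, i]` over nodes `S, x1, x2, x3`, where
#' `T[j, i] = +1/-1/0` means j activates / inhibits / does not regulate i.
#' `S -> x1` and `S -> x2` must be present with sign +1, S has no incoming
#' edges, and at least one of `x1 -> x3`, `x2 -> x3` must be nonzero.
#' Internal edges (x1 <-> x2, feedback from x3, self-loops) are allowed.
#'
#' @param edges either a signed 4x4 matrix with dimnames
#'   `c("S","x1","x2","x3")`, or a data.frame with columns `from`, `to`,
#'   `sign`.
#' @return object of class `trinode_topology` (the sign matrix).
#' @export
trinode_topology <- function(edges) {
  nodes <- c("S", "x1", "x2", "x3")
  if (is.data.frame(edges)) {
    T <- matrix(0L, 4, 4, dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(edges))) {
      T[edges$from[r], edges$to[r]] <- as.integer(edges$sign[r])
    }
  } else {
    T <- edges
    stopifnot(is.matrix(T), all(dim(T) == c(4, 4)))
    if (is.null(dimnames(T))) dimnames(T) <- list(nodes, nodes)
  }
  storage.mode(T) <- "integer"
  if (!all(T %in% c(-1L, 0L, 1L))) stop("edge signs must be -1, 0 or +1")
  if (T["S", "x1"] != 1L || T["S", "x2"] != 1L)
    stop("S -> x1 and S -> x2 must be present with sign +1")
  if (any(T[, "S"] != 0L)) stop("S must have no incoming edges")
  if (T["x1", "x3"] == 0L && T["x2", "x3"] == 0L)
    stop("at least one of x1 -> x3, x2 -> x3 must be nonzero")
  structure(T, class = "trinode_topology")
}

#' Default topologies for the priming search
#'
#' Two canonical convergence patterns: `"activating"` (both pathways
#' activate the readout, the pathway-synergy / activator-induction layout)
#' and `"inhibitory"` (x1 inhibits the readout and is itself repressed by
#' x2, the suppressor-deactivation layout).
#'
#' @param kind `"activating"` or `"inhibitory"`.
#' @return a `trinode_topology`.
#' @export
trinode_default_topology <- function(kind = c("activating", "inhibitory")) {
  kind <- match.arg(kind)
  df <- switch(kind,
    activating = data.frame(
      from = c("S", "S", "x1", "x2"),
      to   = c("x1", "x2", "x3", "x3"),
      sign = c(1, 1, 1, 1)),
    inhibitory = data.frame(
      from = c("S", "S", "x1", "x2", "x2"),
      to   = c("x1", "x2", "x3", "x3", "x1"),
      sign = c(1, 1, -1, 1, -1))
  )
  trinode_topology(df)
}

#' Three-node model parameters
#'
#' Each node i has a maximal production rate `k[i]`, a decay rate
#' `gamma[i]` and a basal activity `b[i]`; each active edge j -> i has a
#' weight `w[j, i]` and a half-saturation constant `K[j, i]`; the Hill
#' exponent `n` is shared. The dynamics are
#' `dx_i/dt = k_i A_i (1 - x_i) - gamma_i (1 + I_i) x_i` with
#' `A_i = b_i + sum_act w H(u)`, `I_i = sum_inh w H(u)` and
#' `H(u; K, n) = u^n / (K^n + u^n)`, which keeps all activities in [0, 1]
#' (reduced units, 1 = maximum induction).
#'
#' @param topology a `trinode_topology`.
#' @param k,gamma named numeric length-3 vectors (`x1`, `x2`, `x3`), > 0.
#' @param w,K 4x4 matrices (same dimnames as the topology) with positive
#'   entries on the active edges.
#' @param b basal activity, length 1 or 3 (default 0.01).
#' @param n shared Hill exponent (default 3).
#' @return object of class `trinode_params`.
#' @export
trinode_params <- function(topology, k, gamma, w, K, b = 0.01, n = 3) {
  nodes <- c("S", "x1", "x2", "x3")
  xn <- nodes[-1]
  k <- k[xn]; gamma <- gamma[xn]
  stopifnot(all(k > 0), all(gamma > 0), n >= 1, all(b >= 0))
  if (length(b) == 1L) b <- rep(b, 3)
  if (is.null(names(b))) names(b) <- xn
  act <- which(unclass(topology) != 0L, arr.ind = TRUE)
  for (r in seq_len(nrow(act))) {
    j <- act[r, 1]; i <- act[r, 2]
    if (!is.finite(w[j, i]) || w[j, i] <= 0 || !is.finite(K[j, i]) || K[j, i] <= 0)
      stop("edge ", nodes[j], " -> ", nodes[i], " needs positive w and K")
  }
  structure(list(topology = topology, k = k, gamma = gamma, w = w, K = K,
                 b = b[xn], n = n),
            class = "trinode_params")
}

#' Hill activation function
#'
#' `H(u; K, n) = u^n / (K^n + u^n)`; `H(K, K, n) = 0.5`, `H(0, K, n) = 0`.
#'
#' @param u input level (>= 0).
#' @param K half-saturation constant (> 0).
#' @param n Hill exponent (>= 1).
#' @return activation in [0, 1].
#' @export
hill <- function(u, K, n) {
  un <- u^n
  un / (K^n + un)
}

# unpack trinode_params into the flat edge arrays used by the compiled core
trinode_cpp_args <- function(params) {
  T <- unclass(params$topology)
  edges <- which(T != 0L, arr.ind = TRUE)
  list(efrom = as.integer(edges[, 1] - 1L),   # 0 = S, 1..3 = x1..x3
       eto = as.integer(edges[, 2] - 2L),     # 0..2 = x1..x3
       esign = as.integer(T[edges]),
       ew = as.numeric(params$w[edges]), eK = as.numeric(params$K[edges]),
       k = as.numeric(params$k), g = as.numeric(params$gamma),
       b = as.numeric(params$b), n = params$n)
}

# RHS closure for the three-node model; S is passed via parms$S
trinode_rhs <- function(params) {
  T <- unclass(params$topology)
  nodes <- c("S", "x1", "x2", "x3")
  edges <- which(T != 0L, arr.ind = TRUE)
  ew <- params$w[edges]; eK <- params$K[edges]
  es <- T[edges]
  efrom <- edges[, 1]; eto <- edges[, 2] - 1L  # target index into x (1..3)
  k <- params$k; g <- params$gamma; b <- params$b; n <- params$n
  function(t, x, parms) {
    u <- c(parms$S, x)                 # levels indexed as S, x1, x2, x3
    h <- ew * hill(u[efrom], eK, n)
    A <- b
    I <- numeric(3)
    for (e in seq_along(h)) {
      if (es[e] > 0L) A[eto[e]] <- A[eto[e]] + h[e]
      else            I[eto[e]] <- I[eto[e]] + h[e]
    }
    list(k * A * (1 - x) - g * (1 + I) * x)
  }
}

#' Steady state of the three-node model at fixed stimulus
#'
#' Relaxes the system by long integration and checks the RHS norm.
#'
#' @param params a `trinode_params`.
#' @param S stimulus level (default 0).
#' @param x0 initial state (default basal levels).
#' @param t_relax relaxation horizon (default 2000 time units).
#' @param tol tolerance on the RHS sup-norm (default 1e-9).
#' @param method `"lsoda"` (adaptive, default) or `"rk4"` (compiled
#'   fixed-step core, used by the Metropolis search).
#' @return named steady-state vector `c(x1, x2, x3)`.
#' @export
trinode_steady_state <- function(params, S = 0, x0 = NULL,
                                 t_relax = 2000, tol = 1e-9,
                                 method = c("lsoda", "rk4")) {
  method <- match.arg(method)
  if (is.null(x0)) x0 <- stats::setNames(rep(0.01, 3), c("x1", "x2", "x3"))
  if (method == "rk4") {
    a <- trinode_cpp_args(params)
    x <- trinode_relax_cpp(as.numeric(x0), a$efrom, a$eto, a$esign, a$ew, a$eK,
                           a$k, a$g, a$b, a$n, S, tol, 16 * t_relax)
    return(stats::setNames(x, c("x1", "x2", "x3")))
  }
  rhs <- trinode_rhs(params)
  for (round in 1:4) {
    sol <- deSolve::ode(y = x0, times = c(0, t_relax), func = rhs,
                        parms = list(S = S), method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    x0 <- sol[nrow(sol), -1]
    if (max(abs(unlist(rhs(0, x0, list(S = S))))) < tol) break
    t_relax <- t_relax * 4
  }
  resid <- max(abs(unlist(rhs(0, x0, list(S = S)))))
  if (resid >= tol)
    warning("steady state residual ", signif(resid, 3), " above tolerance")
  x0
}

#' Simulate the three-node model under a stimulus protocol
#'
#' The system is first relaxed to its zero-stimulus steady state, then the
#' protocol's piecewise-constant dose segments are integrated with state
#' continuity at dose changes.
#'
#' @param params a `trinode_params` (carries its topology).
#' @param protocol a `stimulus_protocol`.
#' @param dt output grid spacing (default 0.5 time units).
#' @param x0 optional initial state; default: relaxed zero-stimulus steady
#'   state.
#' @param method `"lsoda"` (adaptive-step, default) or `"rk4"` (compiled
#'   fixed-step 4th-order core; much faster, used by the search). The two
#'   agree to better than 1e-4 sup-norm on well-posed parameter sets.
#' @return a `time_course` over variables `x1, x2, x3`.
#' @export
simulate_trinode <- function(params, protocol, dt = 0.5, x0 = NULL,
                             method = c("lsoda", "rk4")) {
  stopifnot(inherits(params, "trinode_params"), inherits(protocol, "stimulus_protocol"))
  method <- match.arg(method)
  if (is.null(x0)) x0 <- trinode_steady_state(params, S = 0, method = method)
  if (method == "rk4") {
    a <- trinode_cpp_args(params)
    segs <- protocol$segments
    sol <- trinode_rk4_cpp(as.numeric(x0), a$efrom, a$eto, a$esign, a$ew, a$eK,
                           a$k, a$g, a$b, a$n,
                           as.numeric(segs$duration), as.numeric(segs$dose),
                           dt, 0.05)
    states <- sol$states
    colnames(states) <- c("x1", "x2", "x3")
    return(time_course(sol$times, states))
  }
  rhs <- trinode_rhs(params)
  segs <- protocol$segments
  ends <- cumsum(segs$duration); starts <- c(0, ends[-length(ends)])
  times_all <- NULL; values_all <- NULL
  x <- x0
  for (i in seq_len(nrow(segs))) {
    tt <- unique(c(seq(starts[i], ends[i], by = dt), ends[i]))
    sol <- tryCatch(
      deSolve::ode(y = x, times = tt, func = rhs, parms = list(S = segs$dose[i]),
                   method = "lsoda", rtol = 1e-8, atol = 1e-10),
      warning = function(w) stop("integrator problem in segment ", i, ": ",
                                 conditionMessage(w), call. = FALSE))
    if (nrow(sol) < length(tt))
      stop("integration failed in segment ", i, " of protocol ", protocol$label)
    x <- sol[nrow(sol), -1]
    keep <- if (is.null(times_all)) seq_len(nrow(sol)) else -1L
    times_all <- c(times_all, sol[keep, 1])
    values_all <- rbind(values_all, sol[keep, -1, drop = FALSE])
  }
  colnames(values_all) <- c("x1", "x2", "x3")
  time_course(times_all, values_all)
}

#' Simulate all four arms of a priming experiment
#'
#' @param params a `trinode_params`.
#' @param protocols output of [priming_protocols()].
#' @param dt output grid spacing.
#' @return a `time_course_set` with the protocol windows attached as
#'   attributes `ld_period` and `hd_period`.
#' @export
simulate_trinode_arms <- function(params, protocols = priming_protocols(), dt = 0.5) {
  x0 <- trinode_steady_state(params, S = 0)
  tcs <- lapply(protocols, function(p)
    simulate_trinode(params, p, dt = dt, x0 = x0))
  out <- time_course_set(tcs)
  attr(out, "ld_period") <- attr(protocols, "ld_period")
  attr(out, "hd_period") <- attr(protocols, "hd_period")
  out
}

#' Priming features of a three-node parameter set
#'
#' Convenience wrapper: simulate the four arms and extract features with
#' x3 as the readout.
#'
#' @inheritParams simulate_trinode_arms
#' @return a `priming_features` object.
#' @export
trinode_features <- function(params, protocols = priming_protocols(), dt = 0.5) {
  tcs <- simulate_trinode_arms(params, protocols, dt)
  extract_features(tcs, readout = "x3",
                   ld_period = attr(tcs, "ld_period"),
                   hd_period = attr(tcs, "hd_period"))
}

#' Signed graph of a three-node topology
#'
#' Exports the regulator-to-readout structure as a `signed_graph` so that
#' [classify_mechanism()] can check sign consistency.
#'
#' @param topology a `trinode_topology`.
#' @return a `signed_graph`.
#' @export
trinode_signed_graph <- function(topology) {
  T <- unclass(topology)
  idx <- which(T != 0L, arr.ind = TRUE)
  nodes <- rownames(T)
  signed_graph(data.frame(
    from = nodes[idx[, 1]],
    sign = T[idx],
    to = nodes[idx[, 2]],
    provenance = "direct"))
}
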