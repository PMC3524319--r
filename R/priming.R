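#' Priming thresholds
#'
#' The operational definition of priming uses three clauses on the readout:
#' (1) low dose alone must not activate it (maximum below `tau_ld`, in
#' reduced units where 1 is the maximum induction); (2) high dose alone must
#' activate it (at least `tau_hd`); (3) the sequential low-then-high
#' treatment must exceed the high-dose response by at least a fraction
#' `rho` (default 50%). `delta` is the resolution cutoff used when
#' classifying mechanisms: changes smaller than `delta` in absolute value
#' are treated as "no change".
#'
#' @param tau_ld bound on the readout maximum under LD (default 0.1).
#' @param tau_hd minimum readout maximum under HD (default 0.1).
#' @param rho required fractional excess of LD+HD over HD (default 0.5).
#' @param delta classification resolution cutoff (default 0.1).
#' @return object of class `priming_thresholds`.
#' @export
priming_thresholds <- function(tau_ld = 0.1, tau_hd = 0.1, rho = 0.5, delta = 0.1) {
  stopifnot(tau_ld >= 0, tau_hd >= 0, rho > 0, delta >= 0)
  structure(list(tau_ld = tau_ld, tau_hd = tau_hd, rho = rho, delta = delta),
            class = "priming_thresholds")
}

#' Extract priming summary features from a set of time courses
#'
#' Computes, for every variable, the steady-state change at the end of the
#' LD period (`dss_ld`, LD arm level minus untreated baseline) and the
#' maximal excursion above baseline during the HD treatment window under HD
#' alone (`dmax_hd`) and under LD+HD (`dmax_ldhd`), plus the maxima of the
#' designated readout under each arm (baseline-subtracted).
#'
#' The untreated arm defines the baseline: its level at the start of the
#' protocol, which for a pre-relaxed system is its steady state.
#'
#' @param tcs a `time_course_set` containing `untreated`, `LD`, `HD` and
#'   `LD_HD` arms on grids covering both analysis windows.
#' @param readout name of the readout variable.
#' @param ld_period,hd_period numeric length-2 windows (time units) for the
#'   LD treatment and the HD treatment.
#' @return object of class `priming_features`: named vectors `dss_ld`,
#'   `dmax_hd`, `dmax_ldhd`, scalars `readout_max_ld`, `readout_max_hd`,
#'   `readout_max_ldhd`, the `readout` name and the `baseline` vector.
#' @export
extract_features <- function(tcs, readout, ld_period, hd_period) {
  need <- c("untreated", "LD", "HD", "LD_HD")
  miss <- setdiff(need, names(tcs))
  if (length(miss))
    stop("time_course_set is missing protocol arm(s): ", paste(miss, collapse = ", "))
  vars <- tcs$untreated$variables
  if (!readout %in% vars) stop("readout '", readout, "' not among variables")
  for (arm in need) {
    rng <- range(tcs[[arm]]$times)
    if (ld_period[1] < rng[1] || hd_period[2] > rng[2])
      stop("analysis period outside the time grid of arm '", arm, "'")
  }
  baseline <- vapply(vars, function(v) tc_at(tcs$untreated, v, tcs$untreated$times[1]),
                     numeric(1))
  dss_ld <- vapply(vars, function(v) tc_at(tcs$LD, v, ld_period[2]), numeric(1)) - baseline
  dmax_hd <- vapply(vars, function(v) tc_max_in(tcs$HD, v, hd_period), numeric(1)) - baseline
  dmax_ldhd <- vapply(vars, function(v) tc_max_in(tcs$LD_HD, v, hd_period), numeric(1)) - baseline
  rmax <- function(arm) {
    win <- range(tcs[[arm]]$times)
    tc_max_in(tcs[[arm]], readout, win) - baseline[[readout]]
  }
  out <- list(dss_ld = dss_ld, dmax_hd = dmax_hd, dmax_ldhd = dmax_ldhd,
              readout_max_ld = rmax("LD"), readout_max_hd = rmax("HD"),
              readout_max_ldhd = rmax("LD_HD"),
              readout = readout, baseline = baseline)
  if (!all(is.finite(unlist(out[1:6])))) stop("non-finite priming features")
  structure(out, class = "priming_features")
}

#' Construct priming features directly
#'
#' Convenience constructor for the feature container, used when the summary
#' statistics are already available (e.g. from expression data).
#'
#' @param dss_ld,dmax_hd,dmax_ldhd named per-variable feature vectors.
#' @param readout_max_ld,readout_max_hd,readout_max_ldhd readout maxima.
#' @param readout readout name.
#' @param baseline optional named baseline vector (default all zero).
#' @return object of class `priming_features`.
#' @export
priming_features <- function(dss_ld, dmax_hd, dmax_ldhd,
                             readout_max_ld, readout_max_hd, readout_max_ldhd,
                             readout = "x3", baseline = NULL) {
  if (is.null(baseline)) baseline <- stats::setNames(numeric(length(dss_ld)), names(dss_ld))
  structure(list(dss_ld = dss_ld, dmax_hd = dmax_hd, dmax_ldhd = dmax_ldhd,
                 readout_max_ld = readout_max_ld, readout_max_hd = readout_max_hd,
                 readout_max_ldhd = readout_max_ldhd,
                 readout = readout, baseline = baseline),
            class = "priming_features")
}

#' @export
print.priming_features <- function(x, ...) {
  cat("<priming_features> readout =", x$readout, "\n")
  m <- rbind(dss_ld = x$dss_ld, dmax_hd = x$dmax_hd, dmax_ldhd = x$dmax_ldhd)
  print(round(m, 4))
  cat(sprintf("readout max: LD %.4f | HD %.4f | LD+HD %.4f\n",
              x$readout_max_ld, x$readout_max_hd, x$readout_max_ldhd))
  invisible(x)
}

#' Decide whether a system is primed
#'
#' Applies the three dose-response clauses: LD must not activate the readout
#' (`readout_max_ld < tau_ld`), HD must activate it
#' (`readout_max_hd >= tau_hd`), and LD+HD must exceed HD by at least the
#' fraction `rho` (`readout_max_ldhd >= (1 + rho) * readout_max_hd`).
#'
#' @param features a `priming_features` object.
#' @param th a `priming_thresholds` object.
#' @return object of class `priming_verdict`: list with logical `primed`
#'   and `reason` (`"ok"` or the first failed clause).
#' @examples
#' f <- priming_features(c(x1 = 0, x2 = 0), c(x1 = 0, x2 = 0), c(x1 = 0, x2 = 0),
#'                       readout_max_ld = 0.05, readout_max_hd = 0.4,
#'                       readout_max_ldhd = 0.65)
#' evaluate_priming(f, priming_thresholds())
#' @export
evaluate_priming <- function(features, th = priming_thresholds()) {
  stopifnot(inherits(features, "priming_features"), inherits(th, "priming_thresholds"))
  reason <- "ok"
  primed <- TRUE
  if (!(features$readout_max_ld < th$tau_ld)) {
    primed <- FALSE; reason <- "LD activates the readout (clause 1)"
  } else if (!(features$readout_max_hd >= th$tau_hd)) {
    primed <- FALSE; reason <- "HD fails to activate the readout (clause 2)"
  } else if (!(features$readout_max_ldhd >= (1 + th$rho) * features$readout_max_hd)) {
    primed <- FALSE; reason <- "LD+HD excess below the required ratio (clause 3)"
  }
  structure(list(primed = primed, reason = reason), class = "priming_verdict")
}

#' @export
print.priming_verdict <- function(x, ...) {
  cat("<priming_verdict>", if (x$primed) "PRIMED" else "not primed",
      "-", x$reason, "\n")
  invisible(x)
}

#' Classify the priming mechanism from summary features
#'
#' Primed systems divide into mechanism regions by the behaviour of the
#' upstream regulators (all variables except the readout):
#' * Suppressor Deactivation (SD): some regulator drops under LD
#'   (`dss_ld < -delta`); with a signed graph supplied, that regulator must
#'   inhibit the readout.
#' * Pathway Synergy (PS): some regulator rises under LD
#'   (`dss_ld > delta`) and its maximum under LD+HD exceeds that under HD by
#'   more than `delta`; with a graph, the regulator must activate the
#'   readout.
#' * Activator Induction (AI): a regulator rises under LD but its LD+HD
#'   maximum is indistinguishable from the HD maximum
#'   (`|dmax_ldhd - dmax_hd| <= delta`); with a graph, the regulator must
#'   activate the readout and some other (HD-responsive) regulator must
#'   inhibit it.
#'
#' When distinct regulators fire different rules simultaneously the label
#' follows the precedence SD > PS > AI, and all firing rules are kept in the
#' evidence.
#'
#' @param features a `priming_features` object for a primed system.
#' @param th a `priming_thresholds` object (only `delta` is used).
#' @param graph optional `signed_graph` used for sign-consistency checks;
#'   the readout must be one of its nodes.
#' @param regulators optional character vector naming the regulator
#'   variables (default: all variables except the readout).
#' @return object of class `mechanism_label`: list with `label` in
#'   `c("PS", "AI", "SD", "none")` and a character vector `evidence`.
#' @export
classify_mechanism <- function(features, th = priming_thresholds(), graph = NULL,
                               regulators = NULL) {
  stopifnot(inherits(features, "priming_features"))
  if (!evaluate_priming(features, th)$primed)
    return(structure(list(label = "none", evidence = character(0)),
                     class = "mechanism_label"))
  delta <- th$delta
  if (is.null(regulators))
    regulators <- setdiff(names(features$dss_ld), features$readout)
  if (!is.null(graph)) {
    if (!graph_has_node(graph, features$readout))
      stop("readout '", features$readout, "' absent from the signed graph")
  }
  reg_sign <- function(reg) {
    # net direct-edge sign regulator -> readout, NA when absent from graph
    if (is.null(graph)) return(NA_integer_)
    if (!graph_has_node(graph, reg)) return(NA_integer_)
    s <- signed_path_sign(graph, reg, features$readout, max_len = 1L)
    if (length(s) == 1L) s else NA_integer_
  }
  evidence <- character(0)
  fired <- character(0)
  for (reg in regulators) {
    d <- features$dss_ld[[reg]]
    if (d < -delta) {
      if (!is.null(graph)) {
        s <- reg_sign(reg)
        if (!identical(s, -1L)) next
      }
      fired <- c(fired, "SD")
      evidence <- c(evidence, sprintf("%s: dss_ld = %.3f < -delta (suppressor deactivated)", reg, d))
    } else if (d > delta) {
      if (!is.null(graph)) {
        s <- reg_sign(reg)
        if (!identical(s, 1L)) next
      }
      diff <- features$dmax_ldhd[[reg]] - features$dmax_hd[[reg]]
      if (diff > delta) {
        fired <- c(fired, "PS")
        evidence <- c(evidence, sprintf(
          "%s: dss_ld = %.3f > delta and dmax(LD+HD) - dmax(HD) = %.3f > delta (synergy)", reg, d, diff))
      } else if (abs(diff) <= delta) {
        ok_ai <- TRUE
        if (!is.null(graph)) {
          others <- setdiff(regulators, reg)
          ok_ai <- any(vapply(others, function(o) identical(reg_sign(o), -1L), logical(1)))
        }
        if (ok_ai) {
          fired <- c(fired, "AI")
          evidence <- c(evidence, sprintf(
            "%s: dss_ld = %.3f > delta with dmax(LD+HD) ~ dmax(HD) (diff %.3f, activator pre-induced)",
            reg, d, diff))
        }
      }
    }
  }
  label <- if ("SD" %in% fired) "SD" else if ("PS" %in% fired) "PS" else
    if ("AI" %in% fired) "AI" else "none"
  structure(list(label = label, evidence = evidence), class = "mechanism_label")
}

#' @export
print.mechanism_label <- function(x, ...) {
  cat("<mechanism_label>", x$label, "\n")
  if (length(x$evidence)) cat(paste0("  - ", x$evidence, collapse = "\n"), "\n")
  invisible(x)
}
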