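#' Stimulus protocols
#'
#' A stimulus protocol is an ordered sequence of piecewise-constant dose
#' segments. Priming experiments use four arms: untreated, low dose only
#' (LD), high dose only (HD), and low dose followed by high dose (LD_HD),
#' optionally separated by a zero-dose wash.
#'
#' @param segments data.frame with columns `duration` (> 0, time units) and
#'   `dose` (>= 0, concentration in reduced units or ug/L).
#' @param label one of `"untreated"`, `"LD"`, `"HD"`, `"LD_HD"`.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(data.frame(duration = c(50, 50), dose = c(0.1, 1)), "LD_HD")
#' @export
stimulus_protocol <- function(segments, label = c("untreated", "LD", "HD", "LD_HD")) {
  label <- match.arg(label)
  stopifnot(is.data.frame(segments), all(c("duration", "dose") %in% names(segments)))
  if (any(segments$duration <= 0)) stop("all segment durations must be > 0")
  if (any(segments$dose < 0)) stop("doses must be >= 0")
  if (label == "LD_HD") {
    pos <- which(segments$dose > 0)
    if (length(pos) < 2L)
      stop("an LD_HD protocol needs an LD segment strictly before the HD segment")
    if (segments$dose[pos[1L]] >= segments$dose[pos[length(pos)]])
      stop("in an LD_HD protocol the LD dose must precede and be lower than the HD dose")
  }
  structure(list(segments = segments, label = label), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", x$label, "\n", sep = "")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Total duration of a protocol
#' @param protocol a `stimulus_protocol`.
#' @return total duration (scalar).
#' @export
protocol_duration <- function(protocol) sum(protocol$segments$duration)

#' Dose as a function of time
#'
#' @param protocol a `stimulus_protocol`.
#' @param t vector of times (protocol starts at 0).
#' @return dose at each time (0 beyond the last segment).
#' @export
protocol_dose <- function(protocol, t) {
  ends <- cumsum(protocol$segments$duration)
  starts <- c(0, ends[-length(ends)])
  out <- numeric(length(t))
  for (i in seq_along(ends)) {
    sel <- t >= starts[i] & t < ends[i]
    out[sel] <- protocol$segments$dose[i]
  }
  out[t >= ends[length(ends)]] <- 0
  out
}

#' Build the four aligned arms of a priming experiment
#'
#' All four protocols span the same total time `ld_duration + wash +
#' hd_duration`, so that the HD treatment window is identical in the HD and
#' LD_HD arms and the LD window identical in the LD and LD_HD arms.
#'
#' @param ld_dose,hd_dose doses for the low and high treatment.
#' @param ld_duration,hd_duration segment lengths (time units).
#' @param wash optional zero-dose wash between LD and HD (0 for none).
#' @return named list of `stimulus_protocol`s (`untreated`, `LD`, `HD`,
#'   `LD_HD`) with attributes `ld_period` and `hd_period` giving the two
#'   analysis windows.
#' @export
priming_protocols <- function(ld_dose = 0.1, hd_dose = 1,
                              ld_duration = 50, hd_duration = 50, wash = 0) {
  stopifnot(ld_dose < hd_dose, ld_duration > 0, hd_duration > 0, wash >= 0)
  pre <- ld_duration + wash
  total <- pre + hd_duration
  seg <- function(durs, doses) data.frame(duration = durs, dose = doses)
  mk <- function(durs, doses, label) {
    keep <- durs > 0
    stimulus_protocol(seg(durs[keep], doses[keep]), label)
  }
  arms <- list(
    untreated = mk(total, 0, "untreated"),
    LD        = mk(c(ld_duration, wash + hd_duration), c(ld_dose, 0), "LD"),
    HD        = mk(c(pre, hd_duration), c(0, hd_dose), "HD"),
    LD_HD     = mk(c(ld_duration, wash, hd_duration), c(ld_dose, 0, hd_dose), "LD_HD")
  )
  attr(arms, "ld_period") <- c(0, ld_duration)
  attr(arms, "hd_period") <- c(pre, total)
  arms
}

#' Time-course container
#'
#' @param times strictly increasing time grid.
#' @param values numeric matrix, `length(times)` rows, one column per variable.
#' @return object of class `time_course`.
#' @export
time_course <- function(times, values) {
  values <- as.matrix(values)
  stopifnot(length(times) == nrow(values), !is.unsorted(times, strictly = TRUE))
  if (anyNA(values)) stop("time course contains missing values")
  structure(list(times = as.numeric(times), values = values,
                 variables = colnames(values)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course> ", length(x$times), " points x ",
      ncol(x$values), " variables (", paste(x$variables, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

# linear interpolation of one variable at time t
tc_at <- function(tc, var, t) {
  stats::approx(tc$times, tc$values[, var], xout = t, rule = 2)$y
}

# maximum of one variable over a closed window [a, b]
tc_max_in <- function(tc, var, window) {
  inside <- tc$times >= window[1] & tc$times <= window[2]
  if (!any(inside))
    stop("window [", window[1], ", ", window[2], "] outside the time grid")
  ends <- stats::approx(tc$times, tc$values[, var], xout = window, rule = 2)$y
  max(c(tc$values[inside, var], ends))
}

#' Bundle time courses for the four protocol arms
#'
#' @param ... named `time_course` objects; names must include `untreated`,
#'   `LD`, `HD` and `LD_HD` (any subset is allowed, but feature extraction
#'   needs all four).
#' @return object of class `time_course_set`.
#' @export
time_course_set <- function(...) {
  tcs <- list(...)
  if (length(tcs) == 1L && is.list(tcs[[1L]]) && !inherits(tcs[[1L]], "time_course"))
    tcs <- tcs[[1L]]
  stopifnot(length(tcs) > 0, !is.null(names(tcs)))
  ok <- vapply(tcs, inherits, logical(1), "time_course")
  if (!all(ok)) stop("all elements must be time_course objects")
  structure(tcs, class = "time_course_set")
}

#' First time a variable reaches a level
#'
#' Linear-interpolated first crossing time of `level` from below within a
#' window; used for timing signatures (e.g. whether pretreatment advances
#' an activator or delays a suppressor).
#'
#' @param tc a `time_course`.
#' @param var variable name.
#' @param level threshold level.
#' @param window numeric length-2 time window (default: whole course).
#' @return first crossing time, or `NA` if the level is never reached.
#' @export
crossing_time <- function(tc, var, level, window = range(tc$times)) {
  sel <- tc$times >= window[1] & tc$times <= window[2]
  t <- tc$times[sel]; v <- tc$values[sel, var]
  above <- which(v >= level)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(t[1])
  t[i - 1L] + (level - v[i - 1L]) / (v[i] - v[i - 1L]) * (t[i] - t[i - 1L])
}

#' Time of the maximum of a variable
#'
#' @param tc a `time_course`.
#' @param var variable name.
#' @param window numeric length-2 time window (default: whole course).
#' @return time at which the grid maximum occurs.
#' @export
peak_time <- function(tc, var, window = range(tc$times)) {
  sel <- tc$times >= window[1] & tc$times <= window[2]
  tc$times[sel][which.max(tc$values[sel, var])]
}
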