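#' OD600 growth curve
#'
#' @param times Sampling times in minutes, strictly increasing, length >= 2.
#' @param od OD600 readings, same length as `times`, non-negative.
#' @param label Free-text label.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, label = "") {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) < 2L || length(times) != length(od)) {
    stop("need >= 2 paired (time, od) samples", call. = FALSE)
  }
  if (anyNA(times) || any(diff(times) <= 0)) {
    stop("time vector must be strictly increasing", call. = FALSE)
  }
  if (anyNA(od) || any(od < 0)) stop("od must be non-negative", call. = FALSE)
  structure(list(times = times, od = od, label = as.character(label)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s: %d samples, %.0f-%.0f min, max OD %.3f\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times), min(x$times), max(x$times), max(x$od)))
  invisible(x)
}

#' Optional moving-median spike filter for plate-reader curves
#'
#' @param curve A `growth_curve`.
#' @param window Odd window width (default 3).
#' @return The smoothed `growth_curve`.
#' @export
smooth_curve <- function(curve, window = 3L) {
  stopifnot(inherits(curve, "growth_curve"))
  growth_curve(curve$times, stats::runmed(curve$od, window), curve$label)
}

#' Time for a culture to reach an OD600 threshold
#'
#' Returns the first time at which the curve crosses `threshold`, linearly
#' interpolated between the bracketing samples. If the first sample is
#' already at or above threshold, its time is returned. If the threshold is
#' never reached, the result is censored at the last sampling time.
#'
#' @param curve A `growth_curve`.
#' @param threshold OD600 threshold (default 0.4).
#' @return A list with `time` (minutes) and `censored` (logical).
#' @examples
#' time_to_threshold(growth_curve(c(100, 110), c(0.3, 0.5)))  # 105 min
#' @export
time_to_threshold <- function(curve, threshold = 0.4) {
  stopifnot(inherits(curve, "growth_curve"))
  od <- curve$od; tt <- curve$times
  idx <- which(od >= threshold)
  if (length(idx) == 0L) {
    return(list(time = tt[length(tt)], censored = TRUE))
  }
  i <- idx[1L]
  if (i == 1L) return(list(time = tt[1L], censored = FALSE))
  # linear interpolation between the bracketing samples
  frac <- (threshold - od[i - 1L]) / (od[i] - od[i - 1L])
  list(time = tt[i - 1L] + frac * (tt[i] - tt[i - 1L]), censored = FALSE)
}

#' Selection quartet of threshold-crossing times
#'
#' The four culture times feeding the Normalized Selective Advantage:
#' recombinant (`R`) and negative-control (`C`) cultures inoculated into
#' selective (`S`) and nonselective (`NS`) media. Censored cultures (never
#' reached threshold within the kinetic horizon) carry the horizon as their
#' time with a censoring flag.
#'
#' @param t_rs,t_cs,t_rns,t_cns Times (minutes) to reach the OD threshold.
#' @param censored Logical length-4 vector flagging censoring of
#'   `(t_rs, t_cs, t_rns, t_cns)`, in that order.
#' @param horizon Kinetic horizon in minutes (informational).
#' @return An object of class `selection_quartet`.
#' @export
selection_quartet <- function(t_rs, t_cs, t_rns, t_cns,
                              censored = c(FALSE, FALSE, FALSE, FALSE),
                              horizon = NULL) {
  tt <- c(t_rs = t_rs, t_cs = t_cs, t_rns = t_rns, t_cns = t_cns)
  if (anyNA(tt) || any(tt <= 0)) {
    stop("all quartet times must be positive", call. = FALSE)
  }
  censored <- rep_len(as.logical(censored), 4L)
  structure(list(t_rs = t_rs, t_cs = t_cs, t_rns = t_rns, t_cns = t_cns,
                 censored = stats::setNames(censored,
                                            c("t_rs", "t_cs", "t_rns", "t_cns")),
                 horizon = horizon),
            class = "selection_quartet")
}

#' Build a selection quartet from four growth curves
#'
#' @param rs,cs,rns,cns `growth_curve` objects for the four conditions.
#' @param threshold OD600 threshold (default 0.4).
#' @return A `selection_quartet`.
#' @export
quartet_from_curves <- function(rs, cs, rns, cns, threshold = 0.4) {
  th <- lapply(list(rs, cs, rns, cns), time_to_threshold,
               threshold = threshold)
  selection_quartet(th[[1]]$time, th[[2]]$time, th[[3]]$time, th[[4]]$time,
                    censored = vapply(th, `[[`, logical(1), "censored"),
                    horizon = max(vapply(list(rs, cs, rns, cns),
                                         function(cv) max(cv$times),
                                         numeric(1))))
}

#' Normalized Selective Advantage (NSA)
#'
#' \deqn{NSA = 1 - \frac{t^{RS} \, (t^{CNS}/t^{RNS})}{t^{CS}}}
#' where each `t` is the time for that culture to reach OD600 >= 0.4. The
#' nonselective ratio normalises for disparate inoculums. NSA = 1 means
#' perfect selection (no control escape); NSA = 0 means complete escape
#' (recombinant and control grow alike in selection). If the control
#' selective time is censored, the returned value is a conservative lower
#' bound and is flagged.
#'
#' @param q A `selection_quartet`.
#' @return A list with `nsa` (<= 1), `censored` (any quartet time censored)
#'   and `lower_bound` (`TRUE` when `t_cs` was censored, so the true NSA is
#'   at least the reported value).
#' @examples
#' nsa(selection_quartet(300, 600, 200, 200))  # 0.5
#' @export
nsa <- function(q) {
  stopifnot(inherits(q, "selection_quartet"))
  if (q$t_rns <= 0 || q$t_cs <= 0) {
    stop("nonselective and control-selective times must be positive",
         call. = FALSE)
  }
  val <- 1 - (q$t_rs * (q$t_cns / q$t_rns)) / q$t_cs
  list(nsa = val,
       censored = any(q$censored),
       lower_bound = isTRUE(q$censored[["t_cs"]]))
}

#' Normalized Culture Time causality score
#'
#' Affine normalization of a candidate oligo's counter-selection culture
#' time between the positive control (marker-knockout recombination, score
#' 0) and the mock recombination (score 1):
#' \deqn{NCT = \frac{t_{oligo} - t_{positive}}{t_{mock} - t_{positive}}.}
#' Scores near 0 indicate the oligo encodes an escape mutation, scores near
#' 1 an unrelated mutation; values slightly outside `[0, 1]` can occur.
#' By convention scores below `causal_threshold` are called causal and
#' scores in `[causal_threshold, 1)` borderline.
#'
#' @param t_oligo,t_mock,t_positive Times (minutes) to reach the OD
#'   threshold for the candidate-oligo, mock and positive-control cultures.
#' @param causal_threshold Causal call threshold (default 0.6).
#' @return A list with `nct`, `call` (one of `"causal"`, `"borderline"`,
#'   `"unrelated"`) and the three input times.
#' @examples
#' normalized_culture_time(700, 900, 500)  # 0.5, causal
#' @export
normalized_culture_time <- function(t_oligo, t_mock, t_positive,
                                    causal_threshold = 0.6) {
  if (t_mock == t_positive) {
    stop("degenerate controls: t_mock must differ from t_positive",
         call. = FALSE)
  }
  nct <- (t_oligo - t_positive) / (t_mock - t_positive)
  call <- if (nct < causal_threshold) "causal"
          else if (nct < 1) "borderline" else "unrelated"
  list(nct = nct, call = call,
       t_oligo = t_oligo, t_mock = t_mock, t_positive = t_positive)
}

#' Growth delay of a culture in selective versus nonselective media
#'
#' Difference in OD600 threshold-crossing times between paired selective
#' and nonselective cultures of the same clone. If the selective culture
#' never reaches threshold within its kinetic window, growth is flagged as
#' absent ("No Growth"). A censored nonselective culture is
#' uninterpretable and raises an error.
#'
#' @param selective,nonselective `growth_curve` objects.
#' @param threshold OD600 threshold (default 0.4).
#' @param doubling_time Optional doubling time (minutes) to also express
#'   the delay in doublings.
#' @return A list with `delay_min`, `no_growth` (logical) and, when
#'   `doubling_time` is given, `doublings`.
#' @export
growth_delay <- function(selective, nonselective, threshold = 0.4,
                         doubling_time = NULL) {
  ts <- time_to_threshold(selective, threshold)
  tn <- time_to_threshold(nonselective, threshold)
  if (tn$censored) {
    stop("nonselective culture never reached threshold; delay uninterpretable",
         call. = FALSE)
  }
  if (ts$censored) {
    return(list(delay_min = NA_real_, no_growth = TRUE,
                doublings = if (is.null(doubling_time)) NULL else NA_real_))
  }
  delay <- ts$time - tn$time
  out <- list(delay_min = delay, no_growth = FALSE)
  if (!is.null(doubling_time)) out$doublings <- delay / doubling_time
  out
}

#' Read growth curves from CSV
#'
#' Expects columns `time_min`, `od600` and a grouping column (default
#' `condition`, e.g. RS/CS/RNS/CNS for a selection quartet).
#'
#' @param path CSV file path.
#' @param group Name of the grouping column.
#' @return A named list of `growth_curve` objects, one per group level.
#' @export
read_growth_curves <- function(path, group = "condition") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "od600", group)
  if (!all(need %in% names(df))) {
    stop("growth-curve CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df[[group]]), function(d) {
    d <- d[order(d$time_min), ]
    growth_curve(d$time_min, d$od600, label = d[[group]][1L])
  })
}

#' Write a set of growth curves to CSV
#'
#' @param curves Named list of `growth_curve` objects.
#' @param path Output CSV path.
#' @param group Name of the grouping column.
#' @return `path`, invisibly.
#' @export
write_growth_curves <- function(curves, path, group = "condition") {
  rows <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(time_min = cv$times, od600 = cv$od,
               label = cv$label, check.names = FALSE,
               stringsAsFactors = FALSE,
               tmpgroup = nm)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "tmpgroup"] <- group
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
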