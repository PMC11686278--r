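# Slice-electrophysiology pharmacology: PSC stream metrics, baseline-
# relative wash-on time courses, responder classification, access-
# resistance QC, and cohort summaries.

#' Construct a PSC event stream
#'
#' @param event_times sorted event times, seconds.
#' @param amplitudes event amplitude magnitudes, pA (> 0).
#' @param windows named list of \code{c(start, end)} pairs:
#'   \code{baseline}, \code{wash}, \code{washout}, ordered and disjoint.
#' @param polarity \code{"excitatory"} or \code{"inhibitory"}.
#' @return Object of class \code{psc_stream}.
#' @export
psc_stream <- function(event_times, amplitudes,
                       windows, polarity = "excitatory") {
  if (length(event_times) != length(amplitudes))
    stop_param("times and amplitudes must have equal length")
  if (is.unsorted(event_times)) stop_data("event times must be sorted")
  if (any(amplitudes <= 0)) stop_data("amplitudes must be positive magnitudes")
  structure(list(event_times = event_times, amplitudes = amplitudes,
                 windows = windows, polarity = polarity),
            class = "psc_stream")
}

#' @export
print.psc_stream <- function(x, ...) {
  cat(sprintf("%s PSC stream: %d events over [%g, %g] s\n", x$polarity,
              length(x$event_times), x$windows$baseline[1],
              x$windows$washout[2]))
  invisible(x)
}

#' PSC metrics in a window
#'
#' Frequency is event count over window duration; synaptic drive is the
#' composite frequency x mean amplitude. An empty window yields frequency 0
#' with amplitude (and drive) flagged undefined (NA).
#'
#' @param stream a \code{psc_stream}.
#' @param window length-2 numeric or a window name in the stream
#'   (\code{"baseline"}, \code{"wash"}, \code{"washout"}).
#' @return List: \code{frequency} (Hz), \code{mean_amplitude} (pA),
#'   \code{synaptic_drive} (Hz x pA), \code{n_events}.
#' @examples
#' # 30 events in 60 s at 20 pA: frequency 0.5 Hz, drive 10 Hz*pA
#' @export
event_metrics <- function(stream, window = "baseline") {
  if (is.character(window)) window <- stream$windows[[window]]
  dur <- window[2] - window[1]
  if (dur <= 0) stop_param("window duration must be > 0")
  sel <- in_interval(stream$event_times, window[1], window[2])
  n <- sum(sel)
  freq <- n / dur
  amp <- if (n > 0) mean(stream$amplitudes[sel]) else NA_real_
  list(frequency = freq, mean_amplitude = amp,
       synaptic_drive = freq * amp, n_events = n)
}

#' Baseline-relative time course of a PSC metric
#'
#' Bins the recording into \code{bin}-second bins and expresses each bin's
#' metric as percent of the baseline-window mean.
#'
#' @param stream a \code{psc_stream}.
#' @param metric \code{"frequency"} or \code{"amplitude"}.
#' @param bin bin width, seconds (default 60: 1-min bins).
#' @return data.frame: \code{bin_start}, \code{bin_end}, \code{value},
#'   \code{pct_baseline}, \code{phase} (baseline/wash/washout); attribute
#'   \code{baseline_mean}.
#' @export
percent_baseline_timecourse <- function(stream, metric = c("frequency",
                                                           "amplitude"),
                                        bin = 60) {
  metric <- match.arg(metric)
  w <- stream$windows
  if (w$baseline[2] - w$baseline[1] < 2 * bin)
    stop_param("baseline window must cover >= 2 bins")
  edges <- seq(w$baseline[1], w$washout[2], by = bin)
  if (edges[length(edges)] < w$washout[2])
    edges <- c(edges, w$washout[2])
  nb <- length(edges) - 1
  value <- vapply(seq_len(nb), function(k) {
    sel <- in_interval(stream$event_times, edges[k], edges[k + 1])
    if (metric == "frequency") sum(sel) / (edges[k + 1] - edges[k])
    else if (any(sel)) mean(stream$amplitudes[sel]) else NA_real_
  }, numeric(1))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  phase <- ifelse(centers < w$baseline[2], "baseline",
                  ifelse(centers < w$wash[1], "gap",
                  ifelse(centers < w$wash[2], "wash",
                  ifelse(centers < w$washout[1], "gap", "washout"))))
  base_mean <- mean(value[phase == "baseline"], na.rm = TRUE)
  if (!is.finite(base_mean) || base_mean <= 0)
    stop_data("baseline metric is zero or undefined; cannot normalize")
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
                    value = value, pct_baseline = value / base_mean * 100,
                    phase = phase)
  attr(out, "baseline_mean") <- base_mean
  out
}

#' Classify a cell's drug response
#'
#' A cell is a responder if the mean wash-on percent-of-baseline deviates
#' from 100 by at least 15 points (rule \code{mean15}) OR any single
#' wash-on bin deviates by at least 50 points (rule \code{minute50}); both
#' thresholds inclusive. The response direction follows the firing
#' criterion of larger absolute deviation.
#'
#' @param tc output of \code{\link{percent_baseline_timecourse}}.
#' @param mean_threshold,minute_threshold rule thresholds in percent
#'   deviation from 100 (defaults 15 and 50).
#' @return List: \code{category} (increase/decrease/no_change),
#'   \code{max_delta_pct} (signed wash-on deviation of largest magnitude),
#'   \code{mean_delta_pct}, \code{triggering_rule}.
#' @export
classify_responder <- function(tc, mean_threshold = 15,
                               minute_threshold = 50) {
  wash <- tc$pct_baseline[tc$phase == "wash"]
  wash <- wash[is.finite(wash)]
  if (length(wash) == 0) stop_data("no wash-on bins")
  mean_delta <- mean(wash) - 100
  dev <- wash - 100
  max_delta <- dev[which.max(abs(dev))]
  mean_fires <- abs(mean_delta) >= mean_threshold
  minute_fires <- abs(max_delta) >= minute_threshold
  rule <- if (!mean_fires && !minute_fires) "none"
          else if (mean_fires && (!minute_fires ||
                                  abs(mean_delta) >= abs(max_delta))) "mean15"
          else "minute50"
  category <- if (rule == "none") "no_change"
              else if ((if (rule == "mean15") mean_delta else max_delta) > 0)
                "increase" else "decrease"
  list(category = category, max_delta_pct = max_delta,
       mean_delta_pct = mean_delta, triggering_rule = rule)
}

#' Access-resistance quality control
#'
#' A recording is excluded when the access resistance changes by more than
#' \code{threshold} (default 20%) relative to the first measurement.
#'
#' @param series access-resistance measurements over time, MOhm (> 0).
#' @param threshold maximum tolerated relative change (0.20 = 20%).
#' @return List: \code{included} (logical), \code{max_change_pct}.
#' @export
qc_access <- function(series, threshold = 0.20) {
  if (length(series) == 0) stop_data("empty access-resistance series")
  if (any(series <= 0)) stop_data("access resistance must be positive")
  rel <- abs(series - series[1]) / series[1]
  list(included = max(rel) <= threshold, max_change_pct = max(rel) * 100)
}

#' Cohort responder proportions
#'
#' @param calls list of \code{\link{classify_responder}} results (or a
#'   character vector of categories).
#' @return Named numeric vector of fractions (increase, decrease,
#'   no_change), summing to 1.
#' @export
cohort_response_summary <- function(calls) {
  if (length(calls) == 0) stop_data("empty cohort")
  cats <- if (is.character(calls)) calls
          else vapply(calls, `[[`, character(1), "category")
  lv <- c("increase", "decrease", "no_change")
  tab <- table(factor(cats, levels = lv))
  stats::setNames(as.numeric(tab) / length(cats), lv)
}
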