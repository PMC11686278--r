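# internal argument checking helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(structure(class = c("estrocal_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("estrocal_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a finite numeric scalar")
  if (strict && x <= min) stop_param(name, " must be > ", min)
  if (!strict && x < min) stop_param(name, " must be >= ", min)
  invisible(x)
}

#' Construct an epoch schedule table
#'
#' An epoch schedule is an ordered set of labelled, half-open time
#' intervals \code{[start_s, end_s)}, in seconds from acquisition start.
#'
#' @param label character vector of interval labels.
#' @param start_s,end_s numeric vectors of interval bounds (seconds).
#' @return A \code{data.frame} with columns \code{label}, \code{start_s},
#'   \code{end_s}.
#' @examples
#' epoch_schedule(c("W1", "EtOH", "W2"), c(0, 3600, 10800),
#'                c(3600, 10800, 12600))
#' @export
epoch_schedule <- function(label, start_s, end_s) {
  if (length(label) != length(start_s) || length(label) != length(end_s))
    stop_param("label, start_s, end_s must have equal length")
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (any(!is.finite(start_s)) || any(!is.finite(end_s)))
    stop_param("interval bounds must be finite")
  if (any(end_s <= start_s)) stop_param("intervals must have positive length")
  if (is.unsorted(start_s, strictly = TRUE) ||
      any(start_s[-1] < end_s[-length(end_s)]))
    stop_param("intervals must be disjoint and ordered")
  data.frame(label = as.character(label), start_s = start_s, end_s = end_s,
             stringsAsFactors = FALSE)
}

# membership of times in a half-open interval [start, end)
in_interval <- function(t, start, end) t >= start & t < end
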