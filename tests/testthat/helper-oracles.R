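# Independent oracles used across the suite. Each one re-derives the rule
# it checks by a different route than the implementation.

# Bout rule by exhaustive enumeration of contiguous lick subsets: a bout is
# a maximal run with all inter-lick intervals <= max_ili that has at least
# min_licks licks and spans at least min_duration.
oracle_bouts <- function(licks, max_ili = 1.0, min_licks = 2,
                         min_duration = 0.5) {
  n <- length(licks)
  out <- NULL
  if (n == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_licks = integer(0), duration = numeric(0)))
  for (i in seq_len(n)) for (j in i:n) {
    run <- licks[i:j]
    if (j > i && any(diff(run) > max_ili)) next
    maximal <- (i == 1 || licks[i] - licks[i - 1] > max_ili) &&
      (j == n || licks[j + 1] - licks[j] > max_ili)
    if (!maximal) next
    k <- j - i + 1
    dur <- licks[j] - licks[i]
    if (k >= min_licks && dur >= min_duration)
      out <- rbind(out, data.frame(onset = licks[i], offset = licks[j],
                                   n_licks = k, duration = dur))
  }
  if (is.null(out))
    data.frame(onset = numeric(0), offset = numeric(0),
               n_licks = integer(0), duration = numeric(0))
  else out[order(out$onset), , drop = FALSE]
}

# Weighted least squares by the closed-form normal equations.
oracle_wls <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  slope <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  intercept <- (sy - slope * sx) / sw
  c(intercept = intercept, slope = slope)
}

# Holm-Sidak step-down by a rank-wise max formulation (no sort/restore):
# adjusted p_i = max over all j with rank_j <= rank_i of
# 1 - (1 - p_(j))^(m - rank_j + 1), capped at 1.
oracle_holm_sidak <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(r <= r[i])
    min(1, max(1 - (1 - p[js])^(m - r[js] + 1)))
  }, numeric(1))
}

# Responder rule with the two criteria evaluated independently.
oracle_responder <- function(wash_pct, mean_thr = 15, minute_thr = 50) {
  mean_delta <- mean(wash_pct) - 100
  dev <- wash_pct - 100
  max_delta <- dev[which.max(abs(dev))]
  fired <- list()
  if (abs(mean_delta) >= mean_thr)
    fired$mean15 <- mean_delta
  if (abs(max_delta) >= minute_thr)
    fired$minute50 <- max_delta
  if (length(fired) == 0) return("no_change")
  winner <- fired[[which.max(vapply(fired, abs, numeric(1)))]]
  if (winner > 0) "increase" else "decrease"
}

# Minimal trace constructor for detector tests.
make_trace <- function(z, fs_eff = 10) {
  structure(list(time_s = (seq_along(z) - 1) / fs_eff, z = z,
                 fs_eff = fs_eff),
            class = "processed_trace")
}

# Exponential-decay transient train sampled at fs.
transient_train <- function(times, amps, duration, fs, tau = 1.5) {
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (j in seq_along(times)) {
    idx <- which(t >= times[j])
    x[idx] <- x[idx] + amps[j] * exp(-(t[idx] - times[j]) / tau)
  }
  x
}
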