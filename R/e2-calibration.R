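# LC-MS/MS quantification arithmetic: 1/C-weighted linear calibration,
# back-calculation, per-level accuracy/CV, and LLOQ determination.

#' Two-fold serial dilution design
#'
#' Concentrations of a serial two-fold dilution of the high standard plus a
#' blank: \code{high, high/2, ..., high/2^(n-2), 0}. The default (4 ng/ml
#' high standard, 14 standards including the blank) has its lowest nonzero
#' level at 4/2^12 ng/ml, about 0.98 pg/ml.
#'
#' @param high_conc high calibration standard concentration (default 4,
#'   ng/ml).
#' @param n_standards total standards including the blank (default 14).
#' @return Numeric vector of nominal concentrations, descending, ending in
#'   0.
#' @export
serial_dilution_design <- function(high_conc = 4, n_standards = 14) {
  if (n_standards < 2) stop_param("n_standards must be >= 2")
  check_scalar(high_conc, "high_conc", 0, strict = TRUE)
  c(high_conc / 2^(0:(n_standards - 2)), 0)
}

#' Fit a 1/C-weighted linear calibration curve
#'
#' Weighted least squares of the analyte/internal-standard peak-area ratio
#' on nominal concentration, each replicate point weighted 1/C. The blank
#' (C = 0) is excluded from the fit (its weight is undefined).
#'
#' @param standards data.frame with \code{nominal_conc} and \code{ratio}
#'   (one row per replicate injection); a \code{replicate_id} column is
#'   allowed and ignored by the fit.
#' @param weighted use 1/C weights (default). \code{FALSE} gives the
#'   ordinary unweighted fit.
#' @param per_level_mean fit on level means instead of individual
#'   replicates.
#' @return Object of class \code{calibration_fit}: \code{slope},
#'   \code{intercept}, \code{n_points}, \code{weighted}, and the underlying
#'   \code{lm} fit.
#' @export
fit_calibration <- function(standards, weighted = TRUE,
                            per_level_mean = FALSE) {
  d <- standards[standards$nominal_conc > 0, , drop = FALSE]
  if (length(unique(d$nominal_conc)) < 2)
    stop_data("need >= 2 distinct nonzero concentrations")
  if (per_level_mean)
    d <- stats::aggregate(ratio ~ nominal_conc, d, mean)
  w <- if (weighted) 1 / d$nominal_conc else rep(1, nrow(d))
  fit <- stats::lm(ratio ~ nominal_conc, data = d, weights = w)
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf["nominal_conc"]),
                 intercept = unname(cf["(Intercept)"]),
                 n_points = nrow(d), weighted = weighted, lm = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration fit (%s): ratio = %.6g * C + %.6g  (%d points)\n",
              if (x$weighted) "1/C weighted" else "unweighted",
              x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, conc, ...) {
  object$slope * conc + object$intercept
}

#' Back-calculate concentration from a peak-area ratio
#'
#' Inverts the calibration line: \code{C = (ratio - intercept) / slope}.
#' Negative results (ratios below the fitted blank response) are returned
#' as-is with a \code{below_blank} attribute.
#'
#' @param ratio observed peak-area ratio(s).
#' @param fit a \code{calibration_fit}.
#' @return Concentration(s) in the units of the standards.
#' @export
back_calculate <- function(ratio, fit) {
  if (fit$slope == 0) stop_data("degenerate fit: zero slope")
  conc <- (ratio - fit$intercept) / fit$slope
  attr(conc, "below_blank") <- conc < 0
  conc
}

#' Per-level accuracy/CV and the lower limit of quantification
#'
#' For each nonzero level, back-calculates the replicate ratios and
#' computes the mean accuracy (back-calculated / nominal x 100) and CV
#' (sd / mean x 100). The LLOQ is the smallest nominal concentration with
#' mean accuracy in [80, 120] (inclusive) and CV strictly below 20%.
#' Levels with a single replicate are skipped with a warning (CV
#' undefined).
#'
#' @param standards replicate table as in \code{\link{fit_calibration}}.
#' @param fit a \code{calibration_fit}.
#' @param accuracy_bounds inclusive accuracy window, percent.
#' @param cv_max strict CV bound, percent.
#' @return List: \code{lloq} (NA with \code{defined = FALSE} if no level
#'   passes), \code{defined}, and \code{per_level} (nominal_conc, n,
#'   accuracy_pct, cv_pct, passes).
#' @export
determine_lloq <- function(standards, fit, accuracy_bounds = c(80, 120),
                           cv_max = 20) {
  d <- standards[standards$nominal_conc > 0, , drop = FALSE]
  levels <- sort(unique(d$nominal_conc))
  rows <- lapply(levels, function(cc) {
    r <- d$ratio[d$nominal_conc == cc]
    if (length(r) < 2) {
      warning(sprintf("level %g has a single replicate; skipped (CV undefined)", cc))
      return(data.frame(nominal_conc = cc, n = length(r),
                        accuracy_pct = NA_real_, cv_pct = NA_real_,
                        passes = FALSE))
    }
    bc <- back_calculate(r, fit)
    acc <- mean(bc) / cc * 100
    cv <- stats::sd(bc) / mean(bc) * 100
    data.frame(nominal_conc = cc, n = length(r), accuracy_pct = acc,
               cv_pct = cv,
               passes = acc >= accuracy_bounds[1] & acc <= accuracy_bounds[2] &
                 cv < cv_max)
  })
  per_level <- do.call(rbind, rows)
  pass <- per_level$nominal_conc[per_level$passes]
  list(lloq = if (length(pass)) min(pass) else NA_real_,
       defined = length(pass) > 0, per_level = per_level)
}
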