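#' Half-maximal analgesic dose (AD50) from a dose-response table
#'
#' Converts per-animal mean grimace scores to percent of maximal possible
#' effect, anchored at the vehicle group (0% effect) and floored at the
#' uninjured baseline level (100% effect):
#' \deqn{\%MPE = 100 \, (\bar y_{vehicle} - y) / (\bar y_{vehicle} - baseline)}
#' then fits an ordinary least-squares line of %MPE on log10(dose) over the
#' non-vehicle animals and reads off the dose at which the fitted line
#' crosses 50%. The confidence interval comes from the regression variance of
#' the estimated log10-AD50 (delta method, t quantile on the residual
#' degrees of freedom), back-transformed to the dose scale; Fieller's
#' theorem is available as an alternative.
#'
#' If the fitted slope is not positive, or the crossing dose falls more than
#' 10-fold outside the tested dose range, the estimate is flagged with an
#' extrapolation warning (kept on the result, not thrown).
#'
#' @param data data frame with columns `dose` (mg/kg; vehicle rows carry the
#'   vehicle dose, default 0) and `response` (per-animal mean grimace score).
#'   An `animal_id` column is allowed and ignored.
#' @param baseline_level mean grimace score of uninjured animals (the 100%
#'   effect floor).
#' @param vehicle_dose dose value identifying the vehicle group.
#' @param conf_level confidence level for the interval.
#' @param ci_method `"delta"` (default) or `"fieller"`.
#' @return An `ad50_result`: `estimate`, `ci_low`, `ci_high` (dose units),
#'   `slope`, `intercept` (of %MPE on log10 dose), `se_log_ad50`,
#'   `n_per_dose`, `vehicle_mean`, `baseline_level`, `warnings`, `fit`.
#' @export
ad50 <- function(data, baseline_level, vehicle_dose = 0,
                 conf_level = 0.95, ci_method = c("delta", "fieller")) {
  ci_method <- match.arg(ci_method)
  stopifnot(all(c("dose", "response") %in% names(data)))
  veh <- data$response[data$dose == vehicle_dose]
  if (length(veh) == 0) stop("no vehicle-group rows (dose == ", vehicle_dose, ")")
  active <- data[data$dose != vehicle_dose, , drop = FALSE]
  if (any(active$dose <= 0)) stop("non-vehicle doses must be positive")
  if (length(unique(active$dose)) < 2) {
    stop("need at least 2 distinct non-vehicle doses")
  }
  vehicle_mean <- mean(veh)
  if (vehicle_mean <= baseline_level) {
    stop("degenerate effect: vehicle mean (", signif(vehicle_mean, 4),
         ") does not exceed the baseline level (", signif(baseline_level, 4), ")")
  }
  mpe <- 100 * (vehicle_mean - active$response) / (vehicle_mean - baseline_level)
  ld <- log10(active$dose)
  fit <- stats::lm(mpe ~ ld)
  b <- stats::coef(fit)
  # vcov warns on an exactly collinear (zero-residual) fit; that is a
  # designed input here, and its zero variance is the right answer
  V <- suppressWarnings(stats::vcov(fit))
  warnings <- character(0)

  slope <- unname(b[2]); intercept <- unname(b[1])
  tq <- stats::qt(1 - (1 - conf_level) / 2, stats::df.residual(fit))
  if (!is.finite(slope) || slope <= 0) {
    warnings <- c(warnings,
                  "non-positive slope: fitted line never crosses 50% upward")
    x50 <- NA_real_; se <- NA_real_; ci_log <- c(NA_real_, NA_real_)
  } else {
    x50 <- (50 - intercept) / slope
    g <- c(-1 / slope, -x50 / slope)
    se <- sqrt(drop(t(g) %*% V %*% g))
    if (ci_method == "delta") {
      ci_log <- x50 + c(-1, 1) * tq * se
    } else {
      # Fieller: solve (b0 + b1 x - 50)^2 = t^2 Var(b0 + b1 x) for x
      A <- slope^2 - tq^2 * V[2, 2]
      B <- 2 * (slope * (intercept - 50) - tq^2 * V[1, 2])
      C <- (intercept - 50)^2 - tq^2 * V[1, 1]
      disc <- B^2 - 4 * A * C
      if (A > 0 && disc >= 0) {
        ci_log <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
      } else {
        warnings <- c(warnings, "Fieller interval is unbounded")
        ci_log <- c(-Inf, Inf)
      }
    }
    rng <- range(active$dose)
    if (10^x50 < rng[1] / 10 || 10^x50 > rng[2] * 10) {
      warnings <- c(warnings, paste0(
        "extrapolation: AD50 estimate lies >10-fold outside the tested ",
        "dose range [", rng[1], ", ", rng[2], "]"))
    }
  }
  n_per_dose <- as.data.frame(table(dose = active$dose),
                              responseName = "n")
  n_per_dose$dose <- as.numeric(as.character(n_per_dose$dose))
  structure(
    list(estimate = 10^x50, ci_low = 10^ci_log[1], ci_high = 10^ci_log[2],
         slope = slope, intercept = intercept, se_log_ad50 = se,
         conf_level = conf_level, ci_method = ci_method,
         n_per_dose = n_per_dose, vehicle_mean = vehicle_mean,
         baseline_level = baseline_level, warnings = warnings, fit = fit),
    class = "ad50_result"
  )
}

#' @export
print.ad50_result <- function(x, digits = 3, ...) {
  if (is.finite(x$estimate)) {
    cat(sprintf("AD50 = %s (%.0f%% CI %s-%s) dose units\n",
                format(x$estimate, digits = digits), 100 * x$conf_level,
                format(x$ci_low, digits = digits),
                format(x$ci_high, digits = digits)))
  } else {
    cat("AD50: no finite estimate\n")
  }
  cat(sprintf("  %%MPE = %s + %s * log10(dose); n = %s per dose\n",
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits),
              paste(x$n_per_dose$n, collapse = "/")))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
coef.ad50_result <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    ad50 = object$estimate)
}

#' @export
confint.ad50_result <- function(object, parm = "ad50", level = NULL, ...) {
  out <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
                dimnames = list("ad50", c("lower", "upper")))
  out
}
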