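#' Intraclass correlation coefficients for a ratings matrix
#'
#' Quantifies inter-rater reliability from the two-way (subjects x raters)
#' layout in which every scorer rates every image. Mean squares come from the
#' two-way ANOVA decomposition (subjects, raters, residual), and the four
#' usual variants are reported: single- or average-measure, under consistency
#' (rater main effects ignored) or absolute agreement (rater effects counted
#' as disagreement). Because the workflow averages action-unit scores across
#' the coder panel, the default reported variant is the two-way random
#' effects, average-measure, absolute-agreement coefficient.
#'
#' Rows (subjects) with any missing cell are dropped (complete-case), with a
#' message.
#'
#' @param x a `ratings_matrix` from [assemble_matrix()], or a plain numeric
#'   subjects x raters matrix.
#' @param variant which variant to report as `estimate` (all four are always
#'   computed and returned).
#' @return An `icc_result`: `estimate`, `variant`, `estimates` (all four),
#'   `n_subjects`, `n_raters`, `ms` (subject, rater, residual mean squares),
#'   `n_dropped`.
#' @export
rgs_icc <- function(x, variant = c("average_absolute", "single_absolute",
                                   "average_consistency",
                                   "single_consistency")) {
  variant <- match.arg(variant)
  m <- if (inherits(x, "ratings_matrix")) x$scores else as.matrix(x)
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " subject(s) with missing ratings")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("ICC needs at least 2 raters")
  if (n < 2) stop("ICC needs at least 2 complete subjects")
  if (stats::var(as.vector(m)) < .Machine$double.eps) {
    stop("degenerate ratings: zero total variance")
  }
  dat <- data.frame(score = as.vector(m),
                    subject = factor(rep(seq_len(n), times = k)),
                    rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(score ~ subject + rater, data = dat)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  est <- c(
    single_absolute =
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    average_absolute = (msr - mse) / (msr + (msc - mse) / n),
    single_consistency = (msr - mse) / (msr + (k - 1) * mse),
    average_consistency = (msr - mse) / msr
  )
  structure(
    list(estimate = unname(est[variant]), variant = variant, estimates = est,
         n_subjects = n, n_raters = k,
         ms = c(subject = msr, rater = msc, residual = mse),
         n_dropped = n_dropped),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf("Intraclass correlation (%d subjects x %d raters)\n",
              x$n_subjects, x$n_raters))
  for (v in names(x$estimates)) {
    mark <- if (v == x$variant) " <- reported" else ""
    cat(sprintf("  %-20s %s%s\n", v, format(x$estimates[[v]], digits = digits),
                mark))
  }
  invisible(x)
}

#' @export
coef.icc_result <- function(object, ...) object$estimates
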