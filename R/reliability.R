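#' Validate a repeated-measures table
#'
#' Agreement statistics operate on long-format repeated measurements: one
#' row per (subject, session) with a numeric value. The design must be
#' balanced (every subject measured in every session) with at least two
#' subjects and two sessions.
#'
#' @param data A `data.frame` with columns `subject`, `session`, `value`.
#' @return A numeric matrix (subjects x sessions), invisibly used by the
#'   statistics below.
#' @keywords internal
repeated_matrix <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("subject", "session", "value") %in% names(data)))
  if (anyNA(data$value) || any(!is.finite(data$value)))
    stop("values must be finite and non-missing")
  tab <- table(data$subject, data$session)
  if (nrow(tab) < 2L || ncol(tab) < 2L || any(tab != 1L)) {
    stop(errorCondition(
      "unbalanced design: every subject needs exactly one value per session (>= 2 subjects, >= 2 sessions)",
      class = c("octa_unbalanced", "error", "condition")))
  }
  m <- matrix(NA_real_, nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  for (i in seq_len(nrow(data)))
    m[as.character(data$subject[i]), as.character(data$session[i])] <-
      data$value[i]
  m
}

#' Two-way intraclass correlation coefficient
#'
#' Single-measurement ICC from the two-way ANOVA mean squares. The default
#' `type = "agreement"` is ICC(A,1) (two-way model, absolute agreement,
#' single rater/session), the standard choice for test-retest of one
#' device:
#' `ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' with `MS_R`, `MS_C`, `MS_E` the subject, session and error mean squares,
#' `n` subjects and `k` sessions. `type = "consistency"` gives ICC(C,1),
#' which ignores systematic session shifts. 95 percent confidence bounds
#' follow the standard F-distribution construction (McGraw and Wong).
#'
#' @param data Long-format `data.frame` (`subject`, `session`, `value`).
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `reliability_result`: `icc`, `icc_ci_low`,
#'   `icc_ci_high`, the mean squares, `n_subjects`, `k_sessions`, `type`.
#' @section Errors: `octa_unbalanced` for unbalanced input,
#'   `octa_degenerate` when the data have zero total variance.
#' @export
icc_two_way <- function(data, type = c("agreement", "consistency"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  m <- repeated_matrix(data)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  if (sum((m - grand)^2) <= 0) {
    stop(errorCondition("zero total variance: ICC undefined",
                        class = c("octa_degenerate", "error", "condition")))
  }
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse <= 0) {
      ci <- c(1, 1)
      icc <- 1
    } else {
      # McGraw & Wong (1996) CI for ICC(A,1)
      fj <- msc / mse
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * fj + b)^2 /
        ((a^2 * fj^2) / (k - 1) + b^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(lower, upper)
    }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) {
      ci <- c(1, 1)
      icc <- 1
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  }
  ci <- pmin(pmax(ci, -1), 1)
  structure(list(icc = icc, icc_ci_low = ci[1], icc_ci_high = ci[2],
                 msr = msr, msc = msc, mse = mse,
                 n_subjects = n, k_sessions = k, type = type,
                 conf_level = conf_level),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.3f (%.0f%% CI %.3f to %.3f), n = %d, k = %d\n",
              if (x$type == "agreement") "A" else "C",
              x$icc, 100 * x$conf_level, x$icc_ci_low, x$icc_ci_high,
              x$n_subjects, x$k_sessions))
  invisible(x)
}

#' Coefficient of repeatability
#'
#' For a paired (two-session) design, `CR = 1.96 * SD(d)` where `d` are the
#' within-subject session differences: 95 percent of repeat differences are
#' expected to fall below the CR in magnitude. The confidence interval
#' follows from the chi-square distribution of the difference variance. The
#' alternative convention `method = "within_sd"` uses
#' `2.77 * within-subject SD` (equivalent in expectation for two sessions,
#' since `SD(d) = sqrt(2) * s_w`).
#'
#' @param data Long-format `data.frame` with exactly two sessions per
#'   subject and at least 3 subjects.
#' @param method `"bland_altman"` (1.96 x SD of differences, default) or
#'   `"within_sd"` (2.77 x within-subject SD).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `cr_result`: `cr`, `cr_ci_low`, `cr_ci_high`,
#'   `sd_diff`, `n_subjects`.
#' @export
coefficient_of_repeatability <- function(data,
                                         method = c("bland_altman",
                                                    "within_sd"),
                                         conf_level = 0.95) {
  method <- match.arg(method)
  m <- repeated_matrix(data)
  if (ncol(m) != 2L)
    stop("coefficient of repeatability requires exactly two sessions")
  n <- nrow(m)
  if (n < 3L)
    stop(errorCondition("need at least 3 subjects",
                        class = c("octa_too_few", "error", "condition")))
  d <- m[, 1] - m[, 2]
  sd_d <- stats::sd(d)
  cr <- if (method == "bland_altman") 1.96 * sd_d else
    2.77 * sd_d / sqrt(2)
  alpha <- 1 - conf_level
  # chi-square bounds on the difference variance
  lo <- sd_d * sqrt((n - 1) / stats::qchisq(1 - alpha / 2, n - 1))
  hi <- sd_d * sqrt((n - 1) / stats::qchisq(alpha / 2, n - 1))
  scale <- if (method == "bland_altman") 1.96 else 2.77 / sqrt(2)
  structure(list(cr = cr, cr_ci_low = scale * lo, cr_ci_high = scale * hi,
                 sd_diff = sd_d, n_subjects = n, method = method,
                 conf_level = conf_level),
            class = "cr_result")
}

#' @export
print.cr_result <- function(x, ...) {
  cat(sprintf("CR = %.4f (%.0f%% CI %.4f to %.4f), n = %d\n",
              x$cr, 100 * x$conf_level, x$cr_ci_low, x$cr_ci_high,
              x$n_subjects))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`, their mean (the bias) and the 95 percent limits
#' of agreement `mean(d) +/- 1.96 * SD(d)`.
#'
#' @param a,b Paired measurements (equal length >= 3).
#' @return A list of class `bland_altman`: `mean_difference`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n_pairs`, plus the pair means and differences
#'   for plotting.
#' @export
bland_altman <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  if (length(a) < 3L)
    stop(errorCondition("need at least 3 pairs",
                        class = c("octa_too_few", "error", "condition")))
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_difference = md,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 sd_diff = s, n_pairs = length(a),
                 means = (a + b) / 2, differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4f, 95%% LoA %.4f to %.4f (n = %d)\n",
              x$mean_difference, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of pair",
                              ylab = "Difference", ...) {
  graphics::plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$mean_difference, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Expected 95 percent CI width for an ICC, and its inversion
#'
#' Precision planning for reliability studies: the large-sample variance
#' approximation of Bonett (2002) for a two-way single-measurement ICC,
#' `Var(ICC) ~= 2 (1 - rho)^2 (1 + (k - 1) rho)^2 / (k (k - 1) (n - 1))`,
#' gives an expected confidence-interval width `2 z sqrt(Var)`.
#' `icc_for_width()` inverts the relation: the ICC detectable with a given
#' CI width at a given design. For `k > 2` the width is not monotone in the
#' ICC; the inversion returns the upper (detectable) root.
#'
#' @param n Number of subjects (>= 5).
#' @param k Number of raters/sessions (>= 2).
#' @param icc Assumed ICC, strictly inside (0, 1).
#' @param width Target 95 percent CI width, in (0, 2).
#' @param conf_level Confidence level (default 0.95).
#' @return `icc_ci_width()`: the approximate CI width. `icc_for_width()`:
#'   the ICC whose expected CI width equals `width`.
#' @examples
#' icc_for_width(30, 2, 0.2)  # the design rule: ~0.85
#' @export
icc_ci_width <- function(n, k, icc, conf_level = 0.95) {
  stopifnot(n >= 5, k >= 2, all(icc > 0), all(icc < 1))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(2 * (1 - icc)^2 * (1 + (k - 1) * icc)^2 / (k * (k - 1) * (n - 1)))
  2 * z * se
}

#' @rdname icc_ci_width
#' @export
icc_for_width <- function(n, k, width, conf_level = 0.95) {
  stopifnot(n >= 5, k >= 2, width > 0, width < 2)
  # restrict to the decreasing branch (rho above the interior maximum)
  lo <- if (k > 2) (k - 2) / (2 * (k - 1)) + 1e-9 else 1e-9
  f <- function(rho) icc_ci_width(n, k, rho, conf_level) - width
  if (f(lo) < 0)
    stop(sprintf("every ICC above %.3f already has CI width below %.3f", lo,
                 width))
  stats::uniroot(f, c(lo, 1 - 1e-12), tol = 1e-12)$root
}
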