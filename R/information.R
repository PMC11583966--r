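#' Physician private diagnostic information
#'
#' The per-consultation private-information statistic is the difference
#' between the machine prediction error and the physician decision error,
#' \code{abs(y - m) - abs(y - d)}.  It is positive exactly when the
#' physician's decision is strictly closer to the laboratory outcome than
#' the risk prediction is, and always lies in [-1, 1].  The equivalent
#' algebraic form \code{(d - m) * y + (m - d) * (1 - y)} is asserted against
#' the definition.
#'
#' @param m Risk predictions in [0, 1].
#' @param d Binary physician decisions.
#' @param y Binary laboratory outcomes.
#' @return Numeric vector of private-information values.
#' @examples
#' private_info(m = 0.3, d = 1, y = 1)  #  0.7
#' private_info(m = 0.3, d = 0, y = 1)  # -0.3
#' @export
private_info <- function(m, d, y) {
  if (!is.numeric(m) || anyNA(m) || any(m < 0 | m > 1)) {
    stop_with("abx_domain_error", "m must lie in [0, 1]")
  }
  if (!is_binary(d) || !is_binary(y)) {
    stop_with("abx_domain_error", "d and y must be binary (0/1)")
  }
  definition <- abs(y - m) - abs(y - d)
  algebraic <- (d - m) * y + (m - d) * (1 - y)
  stopifnot(isTRUE(all.equal(definition, algebraic, tolerance = 1e-12)))
  definition
}

bin_frame <- function(df, bin_size) {
  n_bins <- nrow(df) %/% bin_size
  if (n_bins == 0L) {
    stop_with("abx_bin_error",
              "bin size %d exceeds the %d available consultations",
              bin_size, nrow(df))
  }
  keep <- df[seq_len(n_bins * bin_size), , drop = FALSE]  # drop partial bin
  bin <- rep(seq_len(n_bins), each = bin_size)
  agg <- function(v) as.numeric(tapply(v, bin, mean))
  out <- data.frame(
    bin = seq_len(n_bins),
    n = bin_size,
    mean_m = agg(keep$m),
    mean_y = agg(keep$y),
    mean_iota = agg(private_info(keep$m, keep$d, keep$y))
  )
  if (!anyNA(keep$dipstick_used)) {
    out$dipstick_rate <- agg(keep$dipstick_used)
  }
  if (!anyNA(keep$microscopy_used)) {
    out$microscopy_rate <- agg(keep$microscopy_used)
  }
  out
}

#' Risk-binned cohort profiles
#'
#' Sorts consultations by predicted risk (ties broken by consultation
#' identifier for determinism), forms consecutive bins of \code{bin_size}
#' and computes per-bin means of the risk score, the laboratory outcome and
#' the private-information statistic; a trailing partial bin is dropped.
#' Conditional-on-treatment profiles are computed by sorting and binning
#' within each physician-decision stratum separately, so the treated and
#' untreated curves can be compared at matched risk levels.
#'
#' @param cohort Cohort.
#' @param bin_size Number of consultations per bin (100 by default).
#' @return An object of class \code{abx_risk_bins}: list with data frames
#'   \code{overall}, \code{treated} and \code{untreated} (the latter two
#'   \code{NULL} when a stratum is smaller than one bin).
#' @export
risk_bins <- function(cohort, bin_size = 100) {
  df <- cohort_data(cohort)
  if (!(is.numeric(bin_size) && length(bin_size) == 1L && bin_size >= 1)) {
    stop_with("abx_parameter_error", "bin_size must be a positive integer")
  }
  ord <- order(df$m, df$consultation_id)
  sorted <- df[ord, , drop = FALSE]
  stratum <- function(rows) {
    if (sum(rows) < bin_size) return(NULL)
    bin_frame(sorted[rows, , drop = FALSE], bin_size)
  }
  structure(
    list(
      overall = bin_frame(sorted, bin_size),
      treated = stratum(sorted$d == 1),
      untreated = stratum(sorted$d == 0),
      bin_size = bin_size
    ),
    class = "abx_risk_bins"
  )
}

#' @export
print.abx_risk_bins <- function(x, ...) {
  cat(sprintf("<abx_risk_bins> bins of %d: %d overall, %s treated, %s untreated\n",
              x$bin_size, nrow(x$overall),
              if (is.null(x$treated)) "no" else nrow(x$treated),
              if (is.null(x$untreated)) "no" else nrow(x$untreated)))
  invisible(x)
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' Computes the area under the ROC curve as the probability that a randomly
#' chosen positive consultation has a higher risk prediction than a randomly
#' chosen negative one, counting ties as one half, via midranks.
#'
#' @param m Risk predictions.
#' @param y Binary outcomes; both classes must be present.
#' @return The AUC, a number in [0, 1].
#' @examples
#' auc_mann_whitney(c(0.2, 0.8), c(0, 1))  # 1
#' @export
auc_mann_whitney <- function(m, y) {
  if (!is_binary(y)) {
    stop_with("abx_domain_error", "y must be binary (0/1)")
  }
  n1 <- as.numeric(sum(y == 1))
  n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) {
    stop_with("abx_undefined_auc_error",
              "AUC is undefined when only one outcome class is present")
  }
  r <- rank(m)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve of the risk predictions
#'
#' Sweeps the prescribe-above threshold over the unique prediction values
#' and records the false- and true-positive rates; the curve starts at
#' (0, 0) and ends at (1, 1), and its trapezoidal area is asserted to equal
#' the rank-based AUC to within 1e-12.
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class \code{abx_roc}: list with nondecreasing
#'   \code{fpr} and \code{tpr} vectors and the \code{auc}.
#' @export
roc_curve <- function(m, y) {
  auc <- auc_mann_whitney(m, y)  # validates inputs
  ord <- order(m, decreasing = TRUE)
  ys <- y[ord]
  ms <- m[ord]
  n1 <- sum(ys == 1)
  n0 <- sum(ys == 0)
  # cumulative counts at each distinct threshold (ties grouped)
  last_of_group <- which(!duplicated(ms, fromLast = TRUE))
  tpr <- c(0, cumsum(ys)[last_of_group] / n1)
  fpr <- c(0, cumsum(1 - ys)[last_of_group] / n0)
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  stopifnot(abs(area - auc) < 1e-12)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "abx_roc")
}

#' @export
print.abx_roc <- function(x, ...) {
  cat(sprintf("<abx_roc> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Point-of-care diagnostic use across the risk range
#'
#' Per-bin dipstick, microscopy and any-diagnostic use rates for
#' consecutive bins of consultations sorted by predicted risk, together
#' with the cohort-level rates.
#'
#' @inheritParams risk_bins
#' @return A list with \code{bins} (data frame of per-bin rates) and
#'   \code{overall} (named vector of cohort-level dipstick, microscopy and
#'   any-diagnostic rates).
#' @export
diagnostic_rate_by_risk <- function(cohort, bin_size = 100) {
  df <- cohort_data(cohort)
  if (anyNA(df$dipstick_used) || anyNA(df$microscopy_used)) {
    stop_with("abx_parameter_error",
              "diagnostic-use indicators are required for this profile")
  }
  profile <- risk_bins(cohort, bin_size)
  bins <- profile$overall
  ord <- order(df$m, df$consultation_id)
  sorted <- df[ord, , drop = FALSE]
  n_keep <- nrow(bins) * bin_size
  keep <- sorted[seq_len(n_keep), , drop = FALSE]
  bin <- rep(seq_len(nrow(bins)), each = bin_size)
  any_diag <- pmax(keep$dipstick_used, keep$microscopy_used)
  bins$any_diagnostic_rate <- as.numeric(tapply(any_diag, bin, mean))
  list(
    bins = bins[, c("bin", "n", "mean_m", "dipstick_rate", "microscopy_rate",
                    "any_diagnostic_rate")],
    overall = c(
      dipstick = mean(df$dipstick_used),
      microscopy = mean(df$microscopy_used),
      any_diagnostic = mean(pmax(df$dipstick_used, df$microscopy_used))
    )
  )
}
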