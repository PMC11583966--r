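#' Payoff weights for the prescribing trade-off
#'
#' @param alpha Relative sickness cost of delaying treatment for a true
#'   infection until laboratory results arrive; strictly positive.
#' @param beta Relative resistance-promoting cost of any antibiotic
#'   prescription; strictly positive.
#' @return An object of class \code{abx_payoff_weights}.
#' @export
payoff_weights <- function(alpha, beta) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) &&
        alpha > 0)) {
    stop_with("abx_parameter_error", "alpha must be a positive number")
  }
  if (!(is.numeric(beta) && length(beta) == 1L && is.finite(beta) &&
        beta > 0)) {
    stop_with("abx_parameter_error", "beta must be a positive number")
  }
  structure(list(alpha = alpha, beta = beta), class = "abx_payoff_weights")
}

#' Realized payoff of a prescription decision
#'
#' The payoff of deciding \code{d} for a patient with laboratory outcome
#' \code{y} is \code{-alpha * y * (1 - d) - beta * d}: an untreated
#' infection costs \code{alpha} (sickness while awaiting the result), and
#' every prescription costs \code{beta} (promotion of resistance) whether or
#' not the infection is real.
#'
#' @param d,y Binary vectors (recycled to a common length).
#' @param weights An \code{abx_payoff_weights}.
#' @return Numeric vector of payoffs (nonpositive).
#' @examples
#' w <- payoff_weights(alpha = 1, beta = 0.5)
#' payoff(d = c(0, 1, 0), y = c(0, 0, 1), w)
#' @export
payoff <- function(d, y, weights) {
  stopifnot(inherits(weights, "abx_payoff_weights"))
  if (!is_binary(d) || !is_binary(y)) {
    stop_with("abx_domain_error", "d and y must be binary (0/1) vectors")
  }
  -weights$alpha * y * (1 - d) - weights$beta * d
}

#' Aggregate payoff difference of a counterfactual policy
#'
#' Computes the total payoff gain of a counterfactual assignment over the
#' observed decisions,
#' \code{alpha * sum(y * (delta - d)) - beta * sum(delta - d)}.
#' The first term is the change in treated infections, the second the change
#' in overall antibiotic use; whenever a policy holds treated infections
#' fixed and lowers use, the gain is positive for every choice of weights.
#' The closed form is asserted against the consultation-wise sum of payoff
#' differences.
#'
#' @param cohort Cohort.
#' @param assignment An \code{abx_assignment} aligned with the cohort.
#' @param weights An \code{abx_payoff_weights}.
#' @return The aggregate payoff difference (a single number).
#' @export
aggregate_payoff_diff <- function(cohort, assignment, weights) {
  df <- cohort_data(cohort)
  stopifnot(inherits(assignment, "abx_assignment"))
  if (length(assignment$delta) != nrow(df)) {
    stop_with("abx_alignment_error",
              "assignment has %d rows but cohort has %d",
              length(assignment$delta), nrow(df))
  }
  delta <- assignment$delta
  closed <- weights$alpha * sum(df$y * (delta - df$d)) -
    weights$beta * sum(delta - df$d)
  recordwise <- sum(payoff(delta, df$y, weights) - payoff(df$d, df$y, weights))
  stopifnot(isTRUE(all.equal(closed, recordwise, tolerance = 1e-9)))
  closed
}

outcome_counts <- function(presc, y) {
  c(
    consultations = length(y),
    uti = sum(y),
    treated_uti = sum(presc * y),
    prescriptions = sum(presc),
    overprescribing = sum(presc * (1 - y))
  )
}

#' Counterfactual outcome accounting for a policy assignment
#'
#' Tabulates, for the observed decisions and for the counterfactual
#' assignment: consultations, laboratory-confirmed infections, treated
#' infections (prescriptions to \code{y = 1}), antibiotic prescriptions, and
#' overprescribing (prescriptions to \code{y = 0}).  Reports the percent
#' change of treated infections, antibiotic use and overprescribing relative
#' to baseline, plus the shares of physician decisions overruled and of
#' consultations delegated.
#'
#' @param cohort Cohort.
#' @param assignment An \code{abx_assignment} aligned with the cohort.
#' @param on_zero What to do when a baseline denominator is zero:
#'   \code{"error"} (default) raises an error naming the quantity,
#'   \code{"na"} flags the percentage as \code{NA} (used for batch stratum
#'   reports).
#' @return An \code{abx_outcome_report}: list with \code{counts} (baseline
#'   and counterfactual), \code{pct} (the five percentages) and the policy.
#' @examples
#' co <- data.frame(m = c(0.2, 0.4, 0.6, 0.8), d = c(1, 1, 0, 0),
#'                  y = c(1, 0, 1, 0))
#' asg <- apply_policy(co, delegation_policy(0.3, 0.7))
#' evaluate_policy(co, asg)
#' @export
evaluate_policy <- function(cohort, assignment, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  df <- cohort_data(cohort)
  stopifnot(inherits(assignment, "abx_assignment"))
  if (length(assignment$delta) != nrow(df)) {
    stop_with("abx_alignment_error",
              "assignment has %d rows but cohort has %d",
              length(assignment$delta), nrow(df))
  }
  base <- outcome_counts(df$d, df$y)
  cf <- outcome_counts(assignment$delta, df$y)
  # accounting identities
  stopifnot(
    base[["overprescribing"]] ==
      base[["prescriptions"]] - base[["treated_uti"]],
    cf[["overprescribing"]] == cf[["prescriptions"]] - cf[["treated_uti"]],
    base[["treated_uti"]] <= min(base[["uti"]], base[["prescriptions"]]),
    all(base <= base[["consultations"]]), all(cf <= cf[["consultations"]])
  )
  pct_change <- function(quantity) {
    b <- base[[quantity]]
    if (b == 0) {
      if (on_zero == "error") {
        stop_with("abx_undefined_percentage_error",
                  "baseline count of '%s' is zero; percent change undefined",
                  quantity)
      }
      return(NA_real_)
    }
    100 * (cf[[quantity]] - b) / b
  }
  pct <- c(
    treated_uti = pct_change("treated_uti"),
    antibiotic_use = pct_change("prescriptions"),
    overprescribing = pct_change("overprescribing"),
    overruled = 100 * mean(assignment$overruled),
    delegated = 100 * mean(assignment$delegated)
  )
  structure(
    list(counts = data.frame(quantity = names(base),
                             baseline = unname(base),
                             counterfactual = unname(cf)),
         pct = pct,
         ci = NULL,
         policy = assignment$policy),
    class = "abx_outcome_report"
  )
}

#' @export
print.abx_outcome_report <- function(x, digits = 1, ...) {
  cat("Counterfactual policy outcomes\n")
  if (inherits(x$policy, "abx_automation_policy")) {
    cat(sprintf("  k    %.3f\n", x$policy$k))
  } else if (inherits(x$policy, "abx_delegation_policy")) {
    cat(sprintf("  k_L  %.3f\n  k_H  %.3f\n", x$policy$k_L, x$policy$k_H))
  }
  labels <- c(
    treated_uti = "Change in treated UTI, in %",
    antibiotic_use = "Change in antibiotic use, in %",
    overprescribing = "Change in overprescribing, in %",
    overruled = "Physician decisions overruled, in %",
    delegated = "Patients delegated to physicians, in %"
  )
  for (nm in names(labels)) {
    line <- sprintf("  %-40s %6.*f", labels[[nm]], digits, x$pct[[nm]])
    if (!is.null(x$ci)) {
      line <- paste0(line, sprintf("  [%.*f, %.*f]", digits, x$ci["low", nm],
                                   digits, x$ci["high", nm]))
    }
    cat(line, "\n")
  }
  cnt <- x$counts
  for (i in seq_len(nrow(cnt))) {
    cat(sprintf("  %-24s %8d -> %8d\n", cnt$quantity[i],
                cnt$baseline[i], cnt$counterfactual[i]))
  }
  invisible(x)
}

#' Bootstrap specification
#'
#' @param n_samples Number of bootstrap resamples (1000 by default).
#' @param ci_level Confidence level of the percentile interval.
#' @param seed Integer seed for the resampling stream.
#' @param cluster If \code{TRUE}, resample whole clinics instead of
#'   individual consultations.
#' @return An object of class \code{abx_bootstrap_spec}.
#' @export
bootstrap_spec <- function(n_samples = 1000, ci_level = 0.95, seed = 1L,
                           cluster = FALSE) {
  if (!(is.numeric(n_samples) && length(n_samples) == 1L && n_samples >= 1)) {
    stop_with("abx_parameter_error", "n_samples must be a positive integer")
  }
  if (!(is.numeric(ci_level) && ci_level > 0 && ci_level < 1)) {
    stop_with("abx_parameter_error", "ci_level must lie in (0, 1)")
  }
  structure(list(n_samples = as.integer(n_samples), ci_level = ci_level,
                 seed = as.integer(seed), cluster = isTRUE(cluster)),
            class = "abx_bootstrap_spec")
}

#' Bootstrap confidence intervals for policy outcomes
#'
#' Resamples consultations with replacement (n out of n), holding the risk
#' predictions and the already-fitted policy thresholds fixed, re-applies
#' the policy and recomputes the five outcome percentages on each resample.
#' Confidence intervals are percentile intervals at \code{ci_level}; point
#' estimates come from the full cohort.  Deterministic given the spec seed.
#'
#' @param cohort Cohort.
#' @param policy A fitted \code{abx_policy} (thresholds fixed).
#' @param spec An \code{abx_bootstrap_spec}.
#' @return An \code{abx_outcome_report} whose \code{ci} element is a
#'   2 x 5 matrix of interval bounds, with the resample draws attached as
#'   attribute \code{"resamples"}.
#' @export
bootstrap_policy_ci <- function(cohort, policy, spec = bootstrap_spec()) {
  stopifnot(inherits(spec, "abx_bootstrap_spec"))
  df <- cohort_data(cohort)
  report <- evaluate_policy(df, apply_policy(df, policy), on_zero = "na")
  draws <- with_local_seed(spec$seed, {
    vapply(seq_len(spec$n_samples), function(b) {
      idx <- if (spec$cluster) {
        clinics <- unique(df$clinic_id)
        take <- sample(clinics, length(clinics), replace = TRUE)
        unlist(lapply(take, function(cl) which(df$clinic_id == cl)),
               use.names = FALSE)
      } else {
        sample.int(nrow(df), nrow(df), replace = TRUE)
      }
      res <- df[idx, , drop = FALSE]
      res$consultation_id <- sprintf("b%07d", seq_along(idx))
      evaluate_policy(res, apply_policy(res, policy), on_zero = "na")$pct
    }, numeric(5))
  })
  probs <- c((1 - spec$ci_level) / 2, 1 - (1 - spec$ci_level) / 2)
  ci <- apply(draws, 1, function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    stats::quantile(v, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
  })
  dimnames(ci) <- list(c("low", "high"), rownames(draws))
  report$ci <- ci
  attr(report, "resamples") <- t(draws)
  report
}

#' Policy outcomes stratified by clinic laboratory-test intensity
#'
#' Measures each clinic's test intensity as the share of its consultations
#' with a laboratory sample submitted, then evaluates the (already fitted)
#' policy separately on the tested consultations of clinics at or above
#' versus below each intensity threshold.  Empty strata produce reports with
#' \code{NA} percentages rather than errors.
#'
#' @param cohort Cohort with \code{clinic_id} and \code{tested} columns.
#' @param policy A fitted \code{abx_policy}.
#' @param thresholds Numeric vector of intensity cut points.
#' @return A list with one element per threshold, each containing
#'   \code{threshold}, \code{above} and \code{below} outcome reports (or
#'   \code{NULL} for an empty stratum) and the stratum sizes.
#' @export
test_intensity_strata <- function(cohort, policy, thresholds) {
  df <- cohort_data(cohort)
  if (anyNA(df$clinic_id) || anyNA(df$tested)) {
    stop_with("abx_parameter_error",
              "test-intensity stratification requires clinic_id and tested")
  }
  intensity_by_clinic <- tapply(df$tested, df$clinic_id, mean)
  intensity <- intensity_by_clinic[df$clinic_id]
  tested <- df$tested == 1
  lapply(thresholds, function(th) {
    eval_stratum <- function(rows) {
      if (!any(rows)) return(list(report = NULL, n = 0L))
      sub <- df[rows, , drop = FALSE]
      list(report = evaluate_policy(sub, apply_policy(sub, policy),
                                    on_zero = "na"),
           n = sum(rows))
    }
    above <- eval_stratum(tested & intensity >= th)
    below <- eval_stratum(tested & intensity < th)
    list(threshold = th,
         above = above$report, n_above = above$n,
         below = below$report, n_below = below$n)
  })
}
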