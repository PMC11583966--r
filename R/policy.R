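#' Prescription policy objects
#'
#' \code{automation_policy(k)} is the full-automation rule: prescribe
#' (\code{delta = 1}) exactly when the predicted risk strictly exceeds the
#' threshold \code{k}, so \code{delta = 0} whenever \code{m <= k}.
#' \code{delegation_policy(k_L, k_H)} is the two-threshold delegation rule:
#' delay (\code{delta = 0}) when \code{m <= k_L}, prescribe when
#' \code{m >= k_H}, and defer to the physician's observed decision
#' (\code{delta = d}) on the open interval in between.
#'
#' Thresholds outside [0, 1] (including infinities) are permitted as
#' sentinels: \code{automation_policy(-1)} prescribes to everyone and
#' \code{delegation_policy(-Inf, Inf)} is the status-quo rule that delegates
#' every decision.
#'
#' @param k,k_L,k_H Numeric thresholds, \code{k_L <= k_H}.
#' @return A policy object of class \code{abx_automation_policy} or
#'   \code{abx_delegation_policy} (both inherit \code{abx_policy}).
#' @export
automation_policy <- function(k) {
  if (!(is.numeric(k) && length(k) == 1L && !is.na(k))) {
    stop_with("abx_parameter_error", "k must be a single number")
  }
  structure(list(k = k), class = c("abx_automation_policy", "abx_policy"))
}

#' @rdname automation_policy
#' @export
delegation_policy <- function(k_L, k_H) {
  if (!(is.numeric(k_L) && is.numeric(k_H) && length(k_L) == 1L &&
        length(k_H) == 1L && !is.na(k_L) && !is.na(k_H))) {
    stop_with("abx_parameter_error", "k_L and k_H must be single numbers")
  }
  if (k_L > k_H) {
    stop_with("abx_parameter_error",
              "k_L (%g) must not exceed k_H (%g)", k_L, k_H)
  }
  structure(list(k_L = k_L, k_H = k_H),
            class = c("abx_delegation_policy", "abx_policy"))
}

#' @export
print.abx_automation_policy <- function(x, ...) {
  cat(sprintf("<automation policy> k = %g", x$k))
  if (!is.null(x$objective)) {
    cat(sprintf("  [objective %g, constraint %g]", x$objective, x$constraint))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.abx_delegation_policy <- function(x, ...) {
  cat(sprintf("<delegation policy> k_L = %g, k_H = %g", x$k_L, x$k_H))
  if (!is.null(x$objective)) {
    cat(sprintf("  [objective %g, constraint %g]", x$objective, x$constraint))
  }
  cat("\n")
  invisible(x)
}

new_assignment <- function(cohort_df, delta, delegated, policy) {
  stopifnot(length(delta) == nrow(cohort_df))
  structure(
    list(
      delta = as.integer(delta),
      delegated = as.logical(delegated),
      overruled = as.integer(delta) != as.integer(cohort_df$d),
      policy = policy
    ),
    class = "abx_assignment"
  )
}

#' @export
print.abx_assignment <- function(x, ...) {
  cat(sprintf(
    "<abx_assignment> %d consultations: %.1f%% prescribed, %.1f%% delegated, %.1f%% overruled\n",
    length(x$delta), 100 * mean(x$delta), 100 * mean(x$delegated),
    100 * mean(x$overruled)))
  invisible(x)
}

#' Apply a prescription policy to a cohort
#'
#' Computes the counterfactual prescription \code{delta} for every
#' consultation, together with per-consultation \code{delegated} and
#' \code{overruled} flags.  Boundary conventions: full automation prescribes
#' iff \code{m > k} (strict); delegation delays iff \code{m <= k_L},
#' prescribes iff \code{m >= k_H}, and uses the physician's decision on the
#' open interval \code{(k_L, k_H)}.
#'
#' @param cohort Cohort (or data frame with columns \code{m}, \code{d},
#'   \code{y}).
#' @param policy An \code{abx_policy}.
#' @return An \code{abx_assignment}: list with \code{delta},
#'   \code{delegated}, \code{overruled} and the policy applied.
#' @examples
#' co <- data.frame(m = c(0.1, 0.5, 0.9), d = c(1, 1, 0), y = c(0, 1, 1))
#' apply_policy(co, automation_policy(0.5))$delta
#' apply_policy(co, delegation_policy(0.32, 0.601))$delta
#' @export
apply_policy <- function(cohort, policy) UseMethod("apply_policy", policy)

#' @export
apply_policy.abx_automation_policy <- function(cohort, policy) {
  apply_automation(cohort, policy)
}

#' @export
apply_policy.abx_delegation_policy <- function(cohort, policy) {
  apply_delegation(cohort, policy)
}

#' @rdname apply_policy
#' @export
apply_automation <- function(cohort, policy) {
  df <- cohort_data(cohort)
  if (nrow(df) == 0L) {
    stop_with("abx_parameter_error", "cohort must be nonempty")
  }
  stopifnot(inherits(policy, "abx_automation_policy"))
  delta <- as.integer(df$m > policy$k)
  new_assignment(df, delta, delegated = rep(FALSE, nrow(df)), policy = policy)
}

#' @rdname apply_policy
#' @export
apply_delegation <- function(cohort, policy) {
  df <- cohort_data(cohort)
  if (nrow(df) == 0L) {
    stop_with("abx_parameter_error", "cohort must be nonempty")
  }
  stopifnot(inherits(policy, "abx_delegation_policy"))
  delayed <- df$m <= policy$k_L
  forced <- !delayed & df$m >= policy$k_H
  delta <- ifelse(delayed, 0L, ifelse(forced, 1L, as.integer(df$d)))
  new_assignment(df, delta, delegated = !delayed & !forced, policy = policy)
}

# Sorted prefix/suffix accounting shared by both optimizers.  Everything is
# expressed per unique risk value:
#   A  / Ay : physician prescriptions / treated infections among m <= value
#   B  / By : unprescribed consultations / untreated infections among
#             m >= value
policy_prefix_sums <- function(df) {
  ord <- order(df$m)
  ms <- df$m[ord]
  ys <- as.numeric(df$y[ord])
  ds <- as.numeric(df$d[ord])
  last <- which(!duplicated(ms, fromLast = TRUE))
  first <- which(!duplicated(ms))
  cum_y <- cumsum(ys)
  cum_d <- cumsum(ds)
  cum_yd <- cumsum(ys * ds)
  suf_nd <- rev(cumsum(rev(1 - ds)))
  suf_ynd <- rev(cumsum(rev(ys * (1 - ds))))
  list(
    values = ms[last],
    n = length(ms),
    sum_y = sum(ys), sum_d = sum(ds), sum_yd = sum(ys * ds),
    count_le = last,
    y_le = cum_y[last], d_le = cum_d[last], yd_le = cum_yd[last],
    nd_ge = suf_nd[first], ynd_ge = suf_ynd[first]
  )
}

#' Fit the optimal full-automation threshold
#'
#' Finds the threshold \code{k} minimising the change in antibiotic use,
#' \code{sum(delta - d)}, subject to not reducing the number of treated
#' infections, \code{sum(y * (delta - d)) >= 0}.  Candidate thresholds are
#' the observed unique risk values plus sentinels below the minimum
#' (prescribe to all) and above the maximum (prescribe to none); the
#' objective is piecewise constant between observed values.  Ties are broken
#' towards the smallest constraint slack, then the largest threshold.
#'
#' @param cohort Cohort with at least one \code{y = 1} consultation.
#' @return An \code{abx_automation_policy} whose \code{objective} and
#'   \code{constraint} fields hold the attained change in prescriptions and
#'   in treated infections.
#' @examples
#' co <- data.frame(m = c(0.1, 0.5, 0.9), d = c(0, 1, 1), y = c(0, 0, 1))
#' optimize_automation(co)
#' @export
optimize_automation <- function(cohort) {
  df <- cohort_data(cohort)
  if (nrow(df) == 0L) stop_with("abx_parameter_error", "cohort must be nonempty")
  if (sum(df$y) == 0) {
    stop_with("abx_parameter_error",
              "cohort must contain at least one positive laboratory outcome")
  }
  ps <- policy_prefix_sums(df)
  # k candidates: sentinel below min (prescribe all), then each unique value
  # (delta = 1 iff m > value).
  k_cand <- c(min(ps$values) - 1, ps$values)
  n_presc <- c(ps$n, ps$n - ps$count_le)
  y_presc <- c(ps$sum_y, ps$sum_y - ps$y_le)
  objective <- n_presc - ps$sum_d
  constraint <- y_presc - ps$sum_yd
  feasible <- constraint >= 0
  stopifnot(any(feasible))  # prescribe-to-all sentinel is always feasible
  idx <- which(feasible)
  pick <- idx[order(objective[idx], constraint[idx], -k_cand[idx])[1]]
  pol <- automation_policy(k_cand[pick])
  pol$objective <- objective[pick]
  pol$constraint <- constraint[pick]
  pol
}

#' Fit the optimal delegation thresholds
#'
#' Finds \code{(k_L, k_H)} minimising the change in antibiotic use,
#' \code{sum(delta - d)}, subject to \code{sum(y * (delta - d)) >= 0}, over
#' all ordered pairs of candidate thresholds (observed unique risk values
#' plus sentinels).  Because the rule only changes decisions outside the
#' delegation interval, the objective separates into a delay part (prefix
#' sums below \code{k_L}) and a prescribe part (suffix sums at or above
#' \code{k_H}); for each \code{k_L} the optimal \code{k_H} is the largest
#' feasible one, found by binary search, so fitting is
#' \code{O(U log U)} in the number of unique risk values.  The status-quo
#' pair (delegate everyone) is always a candidate, hence the attained
#' objective is never positive.  Ties are broken towards the smallest
#' constraint slack, then the widest delegation interval, then the smallest
#' \code{k_L}.
#'
#' @inheritParams optimize_automation
#' @return An \code{abx_delegation_policy} with \code{objective} and
#'   \code{constraint} fields.
#' @examples
#' co <- data.frame(m = c(0.1, 0.5, 0.9), d = c(1, 1, 0), y = c(0, 1, 1))
#' optimize_delegation(co)
#' @export
optimize_delegation <- function(cohort) {
  df <- cohort_data(cohort)
  if (nrow(df) == 0L) stop_with("abx_parameter_error", "cohort must be nonempty")
  if (sum(df$y) == 0) {
    stop_with("abx_parameter_error",
              "cohort must contain at least one positive laboratory outcome")
  }
  ps <- policy_prefix_sums(df)
  u <- length(ps$values)
  # k_L candidates indexed 0..u (0 = sentinel: delay nobody); k_H candidates
  # indexed 1..u+1 over the same value grid (u+1 = sentinel: force nobody).
  k_l_values <- c(min(ps$values) - 1, ps$values)
  k_h_values <- c(ps$values, max(ps$values) + 1)
  delay_d <- c(0, ps$d_le)        # A(k_L)
  delay_yd <- c(0, ps$yd_le)      # Ay(k_L)
  force_nd <- c(ps$nd_ge, 0)      # B(k_H)
  force_ynd <- c(ps$ynd_ge, 0)    # By(k_H)
  # For each k_L, the best k_H is the largest with By >= Ay (B and By are
  # non-increasing in k_H, so larger k_H means fewer forced prescriptions).
  by_sorted <- rev(force_ynd)                      # non-decreasing
  j_star <- (u + 1L) - findInterval(delay_yd - 0.5, by_sorted)
  i_all <- 0:u
  valid <- j_star > i_all                          # enforce k_L < k_H
  if (!any(valid)) {
    stop_with("abx_internal_error", "no feasible delegation pair found")
  }
  i <- i_all[valid]
  j <- j_star[valid]
  objective <- -delay_d[i + 1L] + force_nd[j]
  constraint <- -delay_yd[i + 1L] + force_ynd[j]
  width <- k_h_values[j] - k_l_values[i + 1L]
  pick <- order(objective, constraint, -width, k_l_values[i + 1L])[1]
  pol <- delegation_policy(k_l_values[i[pick] + 1L], k_h_values[j[pick]])
  pol$objective <- objective[pick]
  pol$constraint <- constraint[pick]
  stopifnot(pol$objective <= 0)  # status quo is always feasible
  pol
}

#' Exhaustive constrained optimum over all assignments
#'
#' Enumerates every binary assignment \code{delta} on a small cohort and
#' returns the constrained optimum: minimal \code{sum(delta - d)} subject to
#' \code{sum(y * (delta - d)) >= 0}.  This optimises over a superset of the
#' threshold rules and is used to verify that, when the outcome rate is
#' monotone in predicted risk (and monotone within each physician-decision
#' stratum for delegation), the fitted threshold rules attain the
#' unrestricted optimum.
#'
#' @param cohort Cohort of at most 20 consultations.
#' @return A list with \code{delta} (one optimal assignment),
#'   \code{objective} and \code{constraint}.
#' @export
oracle_best_assignment <- function(cohort) {
  df <- cohort_data(cohort)
  n <- nrow(df)
  if (n > 20L) {
    stop_with("abx_size_error",
              "exhaustive search supports at most 20 consultations, got %d", n)
  }
  if (n == 0L) stop_with("abx_parameter_error", "cohort must be nonempty")
  codes <- 0:(2^n - 1)
  delta_mat <- vapply(seq_len(n),
                      function(b) bitwAnd(codes, bitwShiftL(1L, b - 1L)) > 0L,
                      logical(length(codes)))
  if (is.null(dim(delta_mat))) delta_mat <- matrix(delta_mat, nrow = 1L)
  sum_delta <- rowSums(delta_mat)
  sum_ydelta <- as.numeric(delta_mat %*% as.numeric(df$y))
  objective <- sum_delta - sum(df$d)
  constraint <- sum_ydelta - sum(df$y * df$d)
  feasible <- constraint >= 0
  idx <- which(feasible)
  pick <- idx[order(objective[idx], constraint[idx])[1]]
  list(
    delta = as.integer(delta_mat[pick, ]),
    objective = objective[pick],
    constraint = constraint[pick]
  )
}

#' Deployment-style sequential re-optimisation of delegation thresholds
#'
#' Splits a dated cohort into consecutive periods of \code{frequency_days},
#' refits the delegation thresholds for each period on the consultations in
#' a rolling window of \code{window_days} strictly before the period start,
#' and applies each period's policy to that period's consultations.  The
#' first period, having no history, uses the status-quo rule (all decisions
#' delegated).  This mirrors how thresholds would be fixed ahead of time in
#' an actual implementation, in contrast to the in-sample fits of
#' \code{\link{optimize_delegation}}.
#'
#' @param cohort Dated cohort.
#' @param window_days Length of the rolling training window, in days.
#' @param frequency_days Re-fitting frequency, in days.
#' @return A list with \code{periods} (a data frame of period bounds,
#'   thresholds and sample sizes), \code{assignment} (the pooled
#'   \code{abx_assignment} over the whole cohort) and \code{report} (the
#'   pooled \code{\link{evaluate_policy}} outcome report).
#' @export
sequential_reoptimize <- function(cohort, window_days = 365,
                                  frequency_days = 30) {
  df <- cohort_data(cohort)
  if (anyNA(df$date)) {
    stop_with("abx_parameter_error",
              "sequential re-optimisation requires consultation dates")
  }
  if (!(window_days > 0 && frequency_days > 0)) {
    stop_with("abx_parameter_error",
              "window_days and frequency_days must be positive")
  }
  dates <- as.Date(df$date)
  starts <- seq(min(dates), max(dates), by = frequency_days)
  delta <- integer(nrow(df))
  delegated <- logical(nrow(df))
  periods <- data.frame(
    start = as.Date(character()), end = as.Date(character()),
    k_L = numeric(), k_H = numeric(),
    n_train = integer(), n_applied = integer()
  )
  for (p in seq_along(starts)) {
    p_start <- starts[p]
    p_end <- p_start + frequency_days - 1
    in_period <- dates >= p_start & dates <= p_end
    train <- dates < p_start & dates >= p_start - window_days
    if (sum(train) == 0 || sum(df$y[train]) == 0) {
      pol <- delegation_policy(-Inf, Inf)  # status quo: delegate everyone
    } else {
      pol <- optimize_delegation(df[train, , drop = FALSE])
    }
    if (any(in_period)) {
      asg <- apply_delegation(df[in_period, , drop = FALSE], pol)
      delta[in_period] <- asg$delta
      delegated[in_period] <- asg$delegated
    }
    periods <- rbind(periods, data.frame(
      start = p_start, end = p_end, k_L = pol$k_L, k_H = pol$k_H,
      n_train = sum(train), n_applied = sum(in_period)
    ))
  }
  assignment <- new_assignment(df, delta, delegated,
                               policy = list(kind = "sequential_delegation",
                                             periods = periods))
  list(
    periods = periods,
    assignment = assignment,
    report = evaluate_policy(df, assignment)
  )
}
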