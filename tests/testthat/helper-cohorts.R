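# Shared fixtures: tiny cohort builders and independent brute-force oracles
# for the constrained threshold optimisations.  The oracles re-derive every
# assignment from the rule definitions with plain loops; they share no code
# with the package's prefix-sum implementations.

tiny_cohort <- function(m, d, y, ...) {
  as_cohort(data.frame(m = m, d = d, y = y, ...))
}

# Random small cohorts with deliberate ties in m to stress the boundary
# conventions (delta = 0 at m == k; delay at m == k_L; prescribe at m == k_H).
rand_cohort <- function(n, seed, tie_grid = 10) {
  set.seed(seed)
  m <- round(runif(n), sample(c(1, 2, 16), 1))
  if (runif(1) < 0.5) m <- round(m * tie_grid) / tie_grid
  d <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, pmin(1, m + 0.1))
  if (sum(y) == 0) y[sample.int(n, 1)] <- 1
  tiny_cohort(m, d, y)
}

automation_delta <- function(m, k) as.integer(m > k)

delegation_delta <- function(m, d, k_l, k_h) {
  ifelse(m <= k_l, 0L, ifelse(m >= k_h, 1L, as.integer(d)))
}

brute_automation <- function(cohort) {
  df <- cohort_data(cohort)
  cands <- c(min(df$m) - 1, sort(unique(df$m)), max(df$m) + 1)
  rows <- lapply(cands, function(k) {
    delta <- automation_delta(df$m, k)
    data.frame(k = k, objective = sum(delta - df$d),
               constraint = sum(df$y * (delta - df$d)))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$constraint >= 0, , drop = FALSE]
  tab[order(tab$objective, tab$constraint, -tab$k)[1], , drop = FALSE]
}

brute_delegation <- function(cohort) {
  df <- cohort_data(cohort)
  uv <- sort(unique(df$m))
  grid <- expand.grid(k_L = c(min(uv) - 1, uv), k_H = c(uv, max(uv) + 1))
  grid <- grid[grid$k_H > grid$k_L, , drop = FALSE]
  res <- t(mapply(function(kl, kh) {
    delta <- delegation_delta(df$m, df$d, kl, kh)
    c(sum(delta - df$d), sum(df$y * (delta - df$d)))
  }, grid$k_L, grid$k_H))
  grid$objective <- res[, 1]
  grid$constraint <- res[, 2]
  grid$width <- grid$k_H - grid$k_L
  grid <- grid[grid$constraint >= 0, , drop = FALSE]
  grid[order(grid$objective, grid$constraint, -grid$width, grid$k_L)[1], ,
       drop = FALSE]
}

# A cohort whose outcome is a deterministic increasing function of m, so the
# outcome rate is monotone and threshold rules attain the exhaustive optimum.
# Risk values must be distinct: with ties an unrestricted assignment can
# split a tie group, which no function of m can do.
monotone_cohort <- function(n, seed) {
  set.seed(seed)
  m <- sort(runif(n))
  y <- as.integer(m > quantile(m, 0.6))
  if (sum(y) == 0) y[n] <- 1L
  d <- rbinom(n, 1, 0.5)
  tiny_cohort(m, d, y)
}

default_test_cohort <- local({
  cache <- NULL
  function(n = 60000, seed = 421) {
    if (is.null(cache)) {
      cfg <- generator_config(n = n)
      cache <<- generate_cohort(cfg, seed = seed)
    }
    cache
  }
})
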