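# Independent brute-force oracles: naive loop re-evaluations of the pooling
# formulas and a full permutation enumeration for the Mann-Whitney test. Kept
# deliberately separate from the package code paths they check.

oracle_pool <- function(yi, vi, tau2 = 0) {
  num <- 0
  den <- 0
  for (i in seq_along(yi)) {
    w <- 1 / (vi[i] + tau2)
    num <- num + w * yi[i]
    den <- den + w
  }
  list(point = num / den, se = sqrt(1 / den))
}

oracle_dl_tau2 <- function(yi, vi) {
  k <- length(yi)
  w <- numeric(k)
  for (i in seq_len(k)) w[i] <- 1 / vi[i]
  xbar <- oracle_pool(yi, vi)$point
  q <- 0
  for (i in seq_len(k)) q <- q + w[i] * (yi[i] - xbar)^2
  cc <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / cc)
}

oracle_random_pool <- function(yi, vi) {
  oracle_pool(yi, vi, tau2 = oracle_dl_tau2(yi, vi))
}

# Exact two-sided Mann-Whitney by enumerating every assignment of the pooled
# ranks to group a; two-sided p counts assignments at least as far from the
# null mean as observed (equivalent to tail doubling by symmetry).
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * (n - na) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Tiny handcrafted two-comparison corpus used across tests.
toy_corpus <- function() {
  row <- function(study_id, design, cid, mt, st, nt, mc, sc, nc,
                  direction = "higher_is_better", center = NA_integer_) {
    data.frame(study_id = study_id, design = design, comparison_id = cid,
               center = center, direction = direction,
               mean_treat = mt, disp_treat = st, n_treat = nt,
               mean_control = mc, disp_control = sc, n_control = nc,
               dispersion_kind = "SD", stringsAsFactors = FALSE)
  }
  rbind(
    row("A_ML", "multilab", "A", 0.3, 1, 60, 0.0, 1, 60),
    row("A_S1", "single", "A", 1.2, 1, 10, 0.0, 1, 10),
    row("A_S2", "single", "A", 0.9, 1, 12, 0.0, 1, 12),
    row("A_S3", "single", "A", 1.5, 1, 8, 0.0, 1, 8),
    # lower-is-better outcome: beneficial treatment lowers the mean
    row("B_ML", "multilab", "B", -0.4, 1, 50, 0.0, 1, 50,
        direction = "lower_is_better"),
    row("B_S1", "single", "B", -1.0, 1, 9, 0.0, 1, 9,
        direction = "lower_is_better"),
    row("B_S2", "single", "B", -0.8, 1, 11, 0.0, 1, 11,
        direction = "lower_is_better")
  )
}

random_effect_instances <- function(n_instances, seed, k_max = 10) {
  withr::with_seed(seed, lapply(seq_len(n_instances), function(i) {
    k <- sample(2:k_max, 1)
    list(yi = stats::rnorm(k, 0, 1.5), vi = stats::runif(k, 0.01, 0.5))
  }))
}
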