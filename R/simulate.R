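# Synthetic matched multilab/single-lab corpora with known ground truth. All
# simulation is on the standardized (unit within-group SD) scale: the
# downstream analysis consumes SMDs, so native units carry no information.
# One master seed yields per-comparison substream seeds, so a corpus is
# bit-identical across reruns and individual comparisons can be regenerated.

#' Simulation configuration
#'
#' Defaults emulate the published corpus structure: a handful of centers per
#' multilab study with totals around a median of 111 animals, up to ten small
#' single-lab studies per comparison with totals around a median of 19, and
#' quality-practice probabilities at the observed per-design rates.
#'
#' @param n_comparisons Number of matched comparisons (default 14).
#' @param mu_delta,tau_comparison Mean and SD of the true per-comparison
#'   effect delta_i on the SMD scale (defaults 0.5, 0.3).
#' @param n_centers Integer range (min, max) of experimental centers per
#'   multilab study (default 2-5).
#' @param n_per_arm_multi Range of per-arm, per-center sample sizes for the
#'   multilab study (default 8-24, giving a median total near 111).
#' @param n_singles Range of single-lab studies per comparison (default 4-10,
#'   capped at 10).
#' @param n_per_arm_single Range of per-arm sizes in single-lab studies
#'   (default 5-14, giving a median total near 19).
#' @param bias_single Additive SMD inflation applied to every single-lab
#'   study's true effect (default 0: the no-design-bias baseline).
#' @param tau_single SD of between-study heterogeneity among single-lab
#'   studies within a comparison (default 0.3).
#' @param tau_center SD of between-center shifts within a multilab study
#'   (default 0.2).
#' @param selection If `TRUE`, each single-lab study is redrawn until its
#'   two-sided Welch t-test has p < 0.05 (significance-gated publication), up
#'   to `max_redraws`.
#' @param max_redraws Redraw cap per study under selection (default 20).
#' @param aggregate_multilab If `TRUE`, the multilab study is written as one
#'   aggregate pair of arms; default `FALSE` writes per-center strata.
#' @param quality_probs List with numeric vectors `multilab` and `single` of
#'   length 5: Bernoulli probabilities of the five quality flags.
#' @param seed Master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_comparisons = 14,
                       mu_delta = 0.5, tau_comparison = 0.3,
                       n_centers = c(2, 5),
                       n_per_arm_multi = c(8, 24),
                       n_singles = c(4, 10),
                       n_per_arm_single = c(5, 14),
                       bias_single = 0,
                       tau_single = 0.3,
                       tau_center = 0.2,
                       selection = FALSE,
                       max_redraws = 20,
                       aggregate_multilab = FALSE,
                       quality_probs = list(
                         multilab = c(0.94, 0.19, 0.69, 0.75, 0.38),
                         single = c(0.57, 0.07, 0.24, 0.53, 0.38)
                       ),
                       seed = 1L) {
  ranges <- list(n_centers = n_centers, n_per_arm_multi = n_per_arm_multi,
                 n_singles = n_singles, n_per_arm_single = n_per_arm_single)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1) stop("invalid range for ", nm)
  }
  if (n_singles[2] > 10) stop("at most 10 single-lab studies per comparison")
  if (any(c(tau_comparison, tau_single, tau_center) < 0)) {
    stop("heterogeneity SDs must be nonnegative")
  }
  probs <- c(quality_probs$multilab, quality_probs$single)
  if (length(probs) != 10 || any(probs < 0 | probs > 1)) {
    stop("quality_probs needs two length-5 probability vectors")
  }
  structure(
    list(n_comparisons = as.integer(n_comparisons), mu_delta = mu_delta,
         tau_comparison = tau_comparison, n_centers = as.integer(n_centers),
         n_per_arm_multi = as.integer(n_per_arm_multi),
         n_singles = as.integer(n_singles),
         n_per_arm_single = as.integer(n_per_arm_single),
         bias_single = bias_single, tau_single = tau_single,
         tau_center = tau_center, selection = isTRUE(selection),
         max_redraws = as.integer(max_redraws),
         aggregate_multilab = isTRUE(aggregate_multilab),
         quality_probs = quality_probs, seed = as.integer(seed)),
    class = "sim_config"
  )
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

draw_flags <- function(probs) {
  stats::setNames(as.list(stats::rbinom(5, 1, probs)), quality_flag_cols)
}

study_row <- function(study_id, design, comparison_id, center, arms, flags,
                      species, year, total_animals) {
  data.frame(
    study_id = study_id, design = design, comparison_id = comparison_id,
    center = center, outcome_label = "primary_outcome",
    direction = "higher_is_better", species = species, sex = "M", year = year,
    mean_treat = arms$mean_t, disp_treat = arms$sd_t, n_treat = arms$n_t,
    mean_control = arms$mean_c, disp_control = arms$sd_c, n_control = arms$n_c,
    dispersion_kind = "SD", total_animals = total_animals,
    randomized = flags$randomized, rand_method_lowrob = flags$rand_method_lowrob,
    blind_personnel = flags$blind_personnel, blind_assessor = flags$blind_assessor,
    complete_data = flags$complete_data, stringsAsFactors = FALSE
  )
}

draw_arms <- function(theta, n_t, n_c) {
  x_t <- stats::rnorm(n_t, theta, 1)
  x_c <- stats::rnorm(n_c, 0, 1)
  list(mean_t = mean(x_t), sd_t = stats::sd(x_t), n_t = n_t,
       mean_c = mean(x_c), sd_c = stats::sd(x_c), n_c = n_c,
       p = tryCatch(stats::t.test(x_t, x_c)$p.value, error = function(e) 1))
}

#' Simulate one matched comparison
#'
#' Draws the comparison's true effect delta_i ~ N(mu_delta, tau_comparison^2);
#' the multilab study observes delta_i plus a per-center shift at each of its
#' centers; each single-lab study observes delta_i + bias_single + u_j with
#' u_j ~ N(0, tau_single^2) at small n. Under significance-gated selection a
#' single-lab study is redrawn until p < 0.05 or the redraw cap is hit (the
#' last draw is kept with a warning when the cap binds).
#'
#' @param cfg A [sim_config()].
#' @param index Comparison number (used in identifiers).
#' @param seed Substream seed for this comparison.
#' @return List with `studies` (rows in the standard schema) and `truth`
#'   (delta, per-study latent effects, redraw counts).
#' @export
simulate_comparison <- function(cfg, index, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(seed)
  cid <- sprintf("C%02d", index)
  delta <- stats::rnorm(1, cfg$mu_delta, cfg$tau_comparison)

  n_centers <- sample_range(cfg$n_centers)
  center_rows <- vector("list", n_centers)
  multi_flags <- draw_flags(cfg$quality_probs$multilab)
  multi_total <- 0L
  for (ctr in seq_len(n_centers)) {
    shift <- stats::rnorm(1, 0, cfg$tau_center)
    n_arm <- sample_range(cfg$n_per_arm_multi)
    arms <- draw_arms(delta + shift, n_arm, n_arm)
    multi_total <- multi_total + arms$n_t + arms$n_c
    center_rows[[ctr]] <- c(arms, shift = shift)
  }
  multi_id <- paste0(cid, "_ML")
  if (cfg$aggregate_multilab || n_centers == 1L) {
    agg <- aggregate_center_arms(center_rows)
    multi <- study_row(multi_id, "multilab", cid, NA_integer_, agg, multi_flags,
                       species = "rat", year = 2018L, total_animals = multi_total)
  } else {
    multi <- do.call(rbind, lapply(seq_len(n_centers), function(ctr) {
      study_row(multi_id, "multilab", cid, ctr, center_rows[[ctr]], multi_flags,
                species = "rat", year = 2018L, total_animals = multi_total)
    }))
  }

  n_singles <- sample_range(cfg$n_singles)
  singles <- vector("list", n_singles)
  theta_singles <- numeric(n_singles)
  redraws <- integer(n_singles)
  for (j in seq_len(n_singles)) {
    theta_j <- delta + cfg$bias_single + stats::rnorm(1, 0, cfg$tau_single)
    n_arm <- sample_range(cfg$n_per_arm_single)
    arms <- draw_arms(theta_j, n_arm, n_arm)
    if (cfg$selection) {
      while (arms$p >= 0.05 && redraws[j] < cfg$max_redraws) {
        redraws[j] <- redraws[j] + 1L
        arms <- draw_arms(theta_j, n_arm, n_arm)
      }
      if (arms$p >= 0.05) {
        warning(cid, " study ", j, ": selection gate unmet after ",
                cfg$max_redraws, " redraws; keeping last draw")
      }
    }
    theta_singles[j] <- theta_j
    singles[[j]] <- study_row(
      sprintf("%s_SL%02d", cid, j), "single", cid, NA_integer_, arms,
      draw_flags(cfg$quality_probs$single),
      species = "rat", year = sample(2000:2019, 1),
      total_animals = arms$n_t + arms$n_c
    )
  }
  list(studies = rbind(multi, do.call(rbind, singles)),
       truth = list(comparison_id = cid, delta = delta,
                    theta_singles = theta_singles, redraws = redraws,
                    n_centers = n_centers))
}

# Combine per-center arms into one aggregate pair using exact pooled moments.
aggregate_center_arms <- function(center_rows) {
  pool_arm <- function(means, sds, ns) {
    n <- sum(ns)
    m <- sum(ns * means) / n
    ss <- sum((ns - 1) * sds^2) + sum(ns * (means - m)^2)
    list(mean = m, sd = sqrt(ss / (n - 1)), n = n)
  }
  t_arm <- pool_arm(vapply(center_rows, `[[`, numeric(1), "mean_t"),
                    vapply(center_rows, `[[`, numeric(1), "sd_t"),
                    vapply(center_rows, `[[`, numeric(1), "n_t"))
  c_arm <- pool_arm(vapply(center_rows, `[[`, numeric(1), "mean_c"),
                    vapply(center_rows, `[[`, numeric(1), "sd_c"),
                    vapply(center_rows, `[[`, numeric(1), "n_c"))
  list(mean_t = t_arm$mean, sd_t = t_arm$sd, n_t = t_arm$n,
       mean_c = c_arm$mean, sd_c = c_arm$sd, n_c = c_arm$n, p = NA_real_)
}

#' Simulate a full matched corpus
#'
#' @param cfg A [sim_config()]; `cfg$seed` drives per-comparison substreams.
#' @return List with `studies` (stacked data frame in the standard schema)
#'   and `truth` (one entry per comparison, plus the config).
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  sub_seeds <- withr::with_seed(cfg$seed,
                                sample.int(.Machine$integer.max, cfg$n_comparisons))
  sims <- lapply(seq_len(cfg$n_comparisons), function(i) {
    simulate_comparison(cfg, i, sub_seeds[i])
  })
  list(studies = do.call(rbind, lapply(sims, `[[`, "studies")),
       truth = lapply(sims, `[[`, "truth"),
       config = cfg)
}

#' Parameter-recovery experiment for the pooled DSMD
#'
#' Runs the full pipeline on `n_replicates` independent corpora and reports
#' bias, RMSE, and empirical 95% CI coverage of the pooled DSMD against the
#' injected target. Without selection the target is `bias_single`; with
#' selection it is `bias_single` plus the selection-induced inflation, which
#' is measured by rerunning each replicate with the gate switched off (a
#' matched no-selection control arm) and taking the mean difference.
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Number of independent corpora.
#' @param seed Seed for the replicate substreams (default `cfg$seed`).
#' @return List with the per-replicate estimates and the summary (target,
#'   bias, rmse, coverage, mean_se).
#' @export
recovery_experiment <- function(cfg = sim_config(), n_replicates = 50,
                                seed = cfg$seed) {
  stopifnot(n_replicates >= 1)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_replicates))
  one <- function(r, selection) {
    cfg_r <- cfg
    cfg_r$selection <- selection
    cfg_r$seed <- rep_seeds[r]
    rep <- design_contrast(simulate_corpus(cfg_r)$studies)
    p <- rep$pooled_dsmd
    c(dsmd = p$point, se = p$se, ci_low = p$ci_low, ci_high = p$ci_high)
  }
  est <- t(vapply(seq_len(n_replicates), one, numeric(4), selection = cfg$selection))
  inflation <- 0
  if (cfg$selection) {
    ctrl <- t(vapply(seq_len(n_replicates), one, numeric(4), selection = FALSE))
    inflation <- mean(est[, "dsmd"]) - mean(ctrl[, "dsmd"])
  }
  target <- cfg$bias_single + inflation
  covered <- est[, "ci_low"] <= target & target <= est[, "ci_high"]
  list(
    estimates = as.data.frame(est),
    target = target, selection_inflation = inflation,
    bias = mean(est[, "dsmd"]) - target,
    rmse = sqrt(mean((est[, "dsmd"] - target)^2)),
    coverage = mean(covered),
    mean_se = mean(est[, "se"]),
    n_replicates = n_replicates
  )
}
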