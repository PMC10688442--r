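#' Factorial experiment design
#'
#' The 2 x 2 x 2 design crossing density dependence (`alpha` 0 vs 0.0035),
#' founding size (`N0` 100 vs 20) and initial genetic diversity (high vs
#' low), with a fixed number of replicate trials per treatment. Per-trial
#' seeds are derived deterministically from `base_seed` and the trial index,
#' so results depend only on the design, never on execution order.
#'
#' @param reps Replicate trials per treatment.
#' @param horizon Generations per trial (15 for trajectory analyses, 50 for
#'   outcome probabilities).
#' @param base_seed Integer base seed.
#' @param alpha,N0,diversity Factor levels (vectors) for the three
#'   treatments.
#' @param census_cap Trial truncation size.
#' @param ... Further scalar arguments passed to [sim_params()] (e.g.
#'   `theta`, `w2`).
#' @return An object of class `rescue_design`: the treatment table plus
#'   design constants.
#' @examples
#' d <- rescue_design(reps = 2, horizon = 3, base_seed = 1)
#' d$treatments
#' @export
rescue_design <- function(reps, horizon = 15, base_seed = 1,
                          alpha = c(0, 0.0035), N0 = c(100, 20),
                          diversity = c("high", "low"),
                          census_cap = 10000, ...) {
  stopifnot(reps >= 1)
  tr <- expand.grid(alpha = alpha, N0 = N0, diversity = diversity,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr$density <- ifelse(tr$alpha > 0, "NDD", "DI")
  tr$size <- ifelse(tr$N0 >= 100, "large", "small")
  structure(list(treatments = tr, reps = as.integer(reps),
                 horizon = as.integer(horizon),
                 base_seed = as.integer(base_seed),
                 census_cap = census_cap, extra = list(...)),
            class = "rescue_design")
}

#' @export
print.rescue_design <- function(x, ...) {
  cat(sprintf("rescue_design: %d treatments x %d reps, horizon %d, base seed %d\n",
              nrow(x$treatments), x$reps, x$horizon, x$base_seed))
  print(x$treatments)
  invisible(x)
}

trial_seed <- function(base_seed, index) {
  # distinct, order-independent per-trial seeds within 32-bit range
  as.integer((as.double(base_seed) + 1000003 * index) %% .Machine$integer.max)
}

#' Run a factorial simulation experiment
#'
#' Executes `reps` independent trials in every treatment cell, each with its
#' own deterministic seed, and classifies every trial's outcome.
#'
#' @param design A [rescue_design()].
#' @param keep_trajectories Keep the full per-generation trajectories (needed
#'   for ensemble means, `k0` estimation and vortex analysis). Set `FALSE`
#'   to retain outcomes only.
#' @return An object of class `rescue_experiment`: list with `design`,
#'   `trials` (list of `rescue_trajectory`, or `NULL`), and `outcomes`
#'   (data.frame with one row per trial, including `trial_id`, `treatment`
#'   and `seed`).
#' @export
run_design <- function(design, keep_trajectories = TRUE) {
  stopifnot(inherits(design, "rescue_design"))
  tr <- design$treatments
  n_tr <- nrow(tr)
  total <- n_tr * design$reps
  trials <- if (keep_trajectories) vector("list", total) else NULL
  outs <- vector("list", total)
  idx <- 0L
  for (i in seq_len(n_tr)) {
    for (r in seq_len(design$reps)) {
      idx <- idx + 1L
      seed <- trial_seed(design$base_seed, idx)
      params <- do.call(sim_params, c(
        list(alpha = tr$alpha[i], N0 = tr$N0[i], diversity = tr$diversity[i],
             horizon = design$horizon, census_cap = design$census_cap,
             seed = seed),
        design$extra))
      traj <- run_trial(params)
      if (keep_trajectories) trials[[idx]] <- traj
      o <- trial_outcome(traj)
      o$trial_id <- idx
      o$treatment <- i
      o$seed <- seed
      outs[[idx]] <- o
    }
  }
  structure(list(design = design, trials = trials,
                 outcomes = do.call(rbind, outs)),
            class = "rescue_experiment")
}

#' @export
print.rescue_experiment <- function(x, ...) {
  o <- x$outcomes
  cat(sprintf("rescue_experiment: %d trials (%d treatments x %d reps), horizon %d\n",
              nrow(o), nrow(x$design$treatments), x$design$reps,
              x$design$horizon))
  cat(sprintf("  extinct %.1f%%, censored %.1f%%, fitness-rescued %.1f%%\n",
              100 * mean(o$extinct), 100 * mean(o$status == "censored"),
              100 * mean(o$rescue_fitness)))
  invisible(x)
}

treatment_key <- function(o) paste(o$density, o$size, o$diversity, sep = "/")

#' Ensemble mean population size over time
#'
#' Unconditional mean census size per treatment and generation, counting
#' extinct populations as size 0 from the generation after their last census
#' onward (so the possibility of extinction is folded into expected size).
#' Cap-censored trials contribute only their observed generations by default
#' (with `n` adjusted), or carry their last census forward if
#' `carry_censored` is `TRUE`.
#'
#' @param experiment A `rescue_experiment` run with trajectories kept.
#' @param carry_censored Carry a censored trial's last census forward.
#' @return Data.frame with `treatment`, `t`, `mean`, `se`, `n`.
#' @export
ensemble_size_mean <- function(experiment, carry_censored = FALSE) {
  stopifnot(inherits(experiment, "rescue_experiment"),
            !is.null(experiment$trials))
  o <- experiment$outcomes
  horizon <- experiment$design$horizon
  out <- list()
  for (key in unique(treatment_key(o))) {
    sel <- which(treatment_key(o) == key)
    mat <- matrix(NA_real_, length(sel), horizon + 1L)
    for (j in seq_along(sel)) {
      traj <- experiment$trials[[sel[j]]]
      r <- traj$records
      mat[j, r$t + 1L] <- r$N
      last <- r$t[nrow(r)]
      if (last < horizon) {
        fill <- if (traj$status == "extinct") 0
        else if (carry_censored) r$N[nrow(r)] else NA_real_
        mat[j, (last + 2L):(horizon + 1L)] <- fill
      }
    }
    n <- colSums(!is.na(mat))
    mu <- colMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
    out[[key]] <- data.frame(treatment = key, t = 0:horizon, mean = mu,
                             se = sdv / sqrt(pmax(n, 1)), n = n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ensemble means of state variables conditioned on final status
#'
#' Mean genotype, fitness, additive variance or fixation counts are undefined
#' for extinct populations, so unconditional ensemble means do not exist.
#' This computes, per treatment and generation, the mean of a recorded state
#' variable over trials sharing a final status (surviving or extinct), using
#' only generations at which each trial was alive (`N >= 1`).
#'
#' @param experiment A `rescue_experiment` with trajectories kept.
#' @param variable One of `"gbar"`, `"zbar"`, `"Wbar"`, `"Rbar"`,
#'   `"sigma_a2"`, `"fixed_pos"`, `"fixed_neg"`, `"N"`.
#' @param status `"surviving"` or `"extinct"` (censored trials count as
#'   surviving for this stratification).
#' @return Data.frame with `treatment`, `t`, `mean`, `se`, `n`; empty (zero
#'   rows) for an empty stratum.
#' @export
conditioned_ensemble_means <- function(experiment,
                                       variable = c("gbar", "zbar", "Wbar",
                                                    "Rbar", "sigma_a2",
                                                    "fixed_pos", "fixed_neg",
                                                    "N"),
                                       status = c("surviving", "extinct")) {
  variable <- match.arg(variable)
  status <- match.arg(status)
  stopifnot(inherits(experiment, "rescue_experiment"),
            !is.null(experiment$trials))
  o <- experiment$outcomes
  in_stratum <- if (status == "extinct") o$extinct else !o$extinct
  horizon <- experiment$design$horizon
  out <- list()
  for (key in unique(treatment_key(o))) {
    sel <- which(treatment_key(o) == key & in_stratum)
    if (length(sel) == 0) next
    mat <- matrix(NA_real_, length(sel), horizon + 1L)
    for (j in seq_along(sel)) {
      r <- experiment$trials[[sel[j]]]$records
      alive <- r$N >= 1
      mat[j, r$t[alive] + 1L] <- r[[variable]][alive]
    }
    n <- colSums(!is.na(mat))
    keep <- n > 0
    mu <- colMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
    out[[key]] <- data.frame(treatment = key, t = (0:horizon)[keep],
                             mean = mu[keep],
                             se = (sdv / sqrt(pmax(n, 1)))[keep],
                             n = n[keep])
  }
  if (length(out) == 0)
    return(data.frame(treatment = character(), t = integer(),
                      mean = numeric(), se = numeric(), n = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First-step adaptation rate per diversity treatment
#'
#' Convenience wrapper over [estimate_k0()] that groups an experiment's
#' trials by the genetic diversity treatment.
#'
#' @param experiment A `rescue_experiment` with trajectories kept.
#' @return Data.frame with one row per diversity level: `diversity`, `k0`,
#'   `se`, `n`.
#' @export
k0_by_diversity <- function(experiment) {
  stopifnot(inherits(experiment, "rescue_experiment"),
            !is.null(experiment$trials))
  o <- experiment$outcomes
  theta <- experiment$trials[[1]]$params$theta
  out <- lapply(unique(o$diversity), function(d) {
    est <- estimate_k0(experiment$trials[o$diversity == d], theta)
    data.frame(diversity = d, k0 = est$k0, se = est$se, n = est$n)
  })
  do.call(rbind, out)
}
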