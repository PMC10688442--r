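test_that("the factorial design enumerates eight seeded treatments", {
  d <- rescue_design(reps = 2, horizon = 3, base_seed = 1)
  expect_equal(nrow(d$treatments), 8)
  e <- run_design(d, keep_trajectories = FALSE)
  expect_equal(nrow(e$outcomes), 16)
  expect_equal(length(unique(e$outcomes$seed)), 16)
  # identical base seed reproduces the experiment exactly
  e2 <- run_design(rescue_design(reps = 2, horizon = 3, base_seed = 1),
                   keep_trajectories = FALSE)
  expect_identical(e$outcomes, e2$outcomes)
  # a different base seed changes the draw
  e3 <- run_design(rescue_design(reps = 2, horizon = 3, base_seed = 2),
                   keep_trajectories = FALSE)
  expect_false(identical(e$outcomes$maladaptation0, e3$outcomes$maladaptation0))
})

test_that("ensemble size means count extinct populations as zeros", {
  ext <- fake_traj(c(100, 40, 0), status = "extinct")
  alive <- fake_traj(c(100, 90, 100, 120, 150))
  outs <- do.call(rbind, lapply(list(ext, alive), trial_outcome))
  outs$trial_id <- 1:2
  fake_exp <- structure(list(
    design = rescue_design(reps = 2, horizon = 4, base_seed = 1),
    trials = list(ext, alive), outcomes = outs),
    class = "rescue_experiment")
  es <- ensemble_size_mean(fake_exp)
  expect_equal(es$mean, c(100, 65, 50, 60, 75))
  expect_equal(es$n, rep(2L, 5))
  # all trials extinct: mean is zero thereafter
  both_ext <- structure(list(
    design = fake_exp$design, trials = list(ext, ext),
    outcomes = {o <- rbind(trial_outcome(ext), trial_outcome(ext))
      o$trial_id <- 1:2; o}),
    class = "rescue_experiment")
  es2 <- ensemble_size_mean(both_ext)
  expect_equal(es2$mean[es2$t >= 3], c(0, 0))
})

test_that("censored trials leave the ensemble unless carried forward", {
  cen <- fake_traj(c(100, 8000, 12000), status = "censored")
  alive <- fake_traj(c(100, 90, 100, 120, 150))
  outs <- do.call(rbind, lapply(list(cen, alive), trial_outcome))
  outs$trial_id <- 1:2
  fake_exp <- structure(list(
    design = rescue_design(reps = 2, horizon = 4, base_seed = 1),
    trials = list(cen, alive), outcomes = outs),
    class = "rescue_experiment")
  es <- ensemble_size_mean(fake_exp)
  expect_equal(es$n, c(2L, 2L, 2L, 1L, 1L))
  expect_equal(es$mean[es$t == 3], 120)
  carried <- ensemble_size_mean(fake_exp, carry_censored = TRUE)
  expect_equal(carried$mean[carried$t == 3], (12000 + 120) / 2)
})

test_that("conditioned means stratify by fate and use live generations only", {
  set.seed(91)
  d <- rescue_design(reps = 120, horizon = 15, base_seed = 17,
                     N0 = 20, alpha = 0.0035, diversity = "high")
  e <- run_design(d)
  surv <- conditioned_ensemble_means(e, "sigma_a2", "surviving")
  ext <- conditioned_ensemble_means(e, "sigma_a2", "extinct")
  # founding additive variance near 0.5 (finite founding samples and
  # survival conditioning shift it by no more than ~0.02)
  expect_lt(abs(surv$mean[surv$t == 0] - 0.5), 0.02)
  # genetic variance declines through time among survivors
  expect_lt(surv$mean[surv$t == 15], surv$mean[surv$t == 0])
  # doomed populations carry less variance than survivors at matched times
  shared <- intersect(surv$t, ext$t)
  mid <- shared[shared >= 3 & shared <= 8]
  expect_true(mean(ext$mean[match(mid, ext$t)] <
                     surv$mean[match(mid, surv$t)]) > 0.5)
  # an experiment with no extinctions has an empty extinct stratum
  quiet <- structure(list(
    design = rescue_design(reps = 1, horizon = 2, base_seed = 1),
    trials = list(fake_traj(c(100, 120, 130))),
    outcomes = local({o <- trial_outcome(fake_traj(c(100, 120, 130)))
      o$trial_id <- 1; o})),
    class = "rescue_experiment")
  expect_equal(nrow(conditioned_ensemble_means(quiet, "gbar", "extinct")), 0)
})

test_that("treatment orderings at reduced replication match expectations", {
  set.seed(92)
  d <- rescue_design(reps = 150, horizon = 15, base_seed = 23)
  e <- run_design(d)
  o <- e$outcomes
  cellkey <- paste(o$size, o$diversity)
  for (cell in unique(cellkey)) {
    di <- o$extinct[cellkey == cell & o$density == "DI"]
    ndd <- o$extinct[cellkey == cell & o$density == "NDD"]
    se_diff <- sqrt(var(di) / length(di) + var(ndd) / length(ndd))
    # density dependence raises extinction (one-sided, noise-aware)
    expect_gt(mean(ndd) - mean(di), -3 * se_diff)
  }
  divkey <- paste(o$size, o$density)
  for (cell in unique(divkey)) {
    hi <- o$rescue_fitness[divkey == cell & o$diversity == "high"]
    lo <- o$rescue_fitness[divkey == cell & o$diversity == "low"]
    se_diff <- sqrt(var(hi) / length(hi) + var(lo) / length(lo))
    # low diversity lowers rescue probability
    expect_gt(mean(hi) - mean(lo), -3 * se_diff)
  }
  # mean additive variance declines over the simulation in every treatment
  surv <- conditioned_ensemble_means(e, "sigma_a2", "surviving")
  for (key in unique(surv$treatment)) {
    s <- surv[surv$treatment == key, ]
    expect_lt(s$mean[s$t == max(s$t)], s$mean[s$t == 0])
  }
  # density-dependent size trajectories bottom out lower than paired DI cells
  es <- ensemble_size_mean(e)
  for (cell in unique(paste(o$size, o$diversity))) {
    parts <- strsplit(cell, " ")[[1]]
    di_min <- min(es$mean[es$treatment == paste("DI", parts[1], parts[2],
                                                sep = "/")])
    ndd_min <- min(es$mean[es$treatment == paste("NDD", parts[1], parts[2],
                                                 sep = "/")])
    expect_lt(ndd_min, di_min)
  }
  # k0 per diversity level: adaptation is slower with less variance
  k0s <- k0_by_diversity(e)
  expect_gt(k0s$k0[k0s$diversity == "low"], k0s$k0[k0s$diversity == "high"])
})
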