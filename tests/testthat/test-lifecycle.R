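test_that("phenotypes are genotype plus Normal(0, sigma_e2) noise drawn at birth", {
  set.seed(21)
  pop <- init_population(sim_params(N0 = 50))
  expect_equal(draw_phenotypes(pop, 0), genotype_values(pop))
  big <- init_population(sim_params(N0 = 1e5, census_cap = 2e5))
  dev <- draw_phenotypes(big, 0.5) - genotype_values(big)
  expect_lt(abs(var(dev) / 0.5 - 1), 0.02)
  expect_lt(abs(mean(dev)), 3 * sqrt(0.5 / 1e5))
})

test_that("intrinsic fitness is Gaussian in distance from the optimum", {
  expect_equal(intrinsic_fitness(2.8, 2.8, 3.5, 2), 2)
  # pre-change mean phenotype immediately after the shift
  expect_equal(intrinsic_fitness(0, 2.8, 3.5, 2), 0.6525595892, tolerance = 1e-9)
  expect_equal(intrinsic_fitness(-3:3, 0, 1e12, 2), rep(2, 7), tolerance = 1e-6)
  expect_error(intrinsic_fitness(0, 2.8, 0, 2))
})

test_that("Ricker factor discounts fitness by density", {
  expect_equal(expected_offspring(1.7, 0, 5000), 1.7)
  expect_equal(expected_offspring(2, 0.0035, 100), 1.409376179, tolerance = 1e-9)
  # replacement density: R = 1 at N = log(W)/alpha
  expect_equal(expected_offspring(2, 0.0035, log(2) / 0.0035), 1)
})

test_that("single-sex populations produce no offspring", {
  set.seed(31)
  pop <- init_population(sim_params(N0 = 10))
  pop$female <- rep(TRUE, 10)
  off <- produce_offspring(pop, rep(2, 10))
  expect_equal(census_size(off), 0)
  expect_equal(off$t, 1L)
  pop$female <- rep(FALSE, 10)
  expect_equal(census_size(produce_offspring(pop, rep(2, 10))), 0)
})

test_that("every offspring allele copy comes from the matching parent", {
  set.seed(32)
  for (rep in 1:5) {
    pop <- init_population(sim_params(N0 = 40))
    off <- produce_offspring(pop, rep(1.5, 40), keep_parents = TRUE)
    if (census_size(off) == 0) next
    mom <- attr(off, "mother")
    dad <- attr(off, "father")
    ok_m <- off$a1 == pop$a1[mom, , drop = FALSE] |
      off$a1 == pop$a2[mom, , drop = FALSE]
    ok_d <- off$a2 == pop$a1[dad, , drop = FALSE] |
      off$a2 == pop$a2[dad, , drop = FALSE]
    expect_true(all(ok_m))
    expect_true(all(ok_d))
    expect_true(all(pop$female[mom]))
    expect_true(all(!pop$female[dad]))
  }
})

test_that("offspring numbers are Poisson with mean 2R per female", {
  set.seed(33)
  pop <- init_population(sim_params(N0 = 40))
  nf <- sum(pop$female)
  R <- 1.3
  counts <- replicate(2000, census_size(produce_offspring(pop, rep(R, 40))))
  expect_lt(abs(mean(counts) - 2 * R * nf), 3 * sd(counts) / sqrt(2000))
})

test_that("one generation records parent statistics before reproduction", {
  set.seed(34)
  params <- sim_params(N0 = 60, alpha = 0.0035)
  pop <- init_population(params)
  res <- step_generation(pop, params)
  rec <- res$record
  expect_equal(rec[["N"]], 60)
  expect_equal(rec[["Rbar"]], rec[["Wbar"]] * exp(-0.0035 * 60))
  expect_equal(rec[["gbar"]], mean(genotype_values(pop)))
  expect_equal(res$state$t, 1L)
})

test_that("the demographic skeleton follows the Ricker expectation", {
  # clonal all-positive genomes at a matching optimum: W = Wmax exactly
  set.seed(35)
  m <- 25
  N <- 30
  params <- sim_params(m = m, theta = sqrt(m), w2 = 3.5, Wmax = 2,
                       sigma_e2 = 0, alpha = 0.0035, N0 = N)
  n1 <- replicate(1500, {
    pop <- make_pop(matrix(1L, N, m), matrix(1L, N, m),
                    female = rep(c(TRUE, FALSE), N / 2))
    census_size(step_generation(pop, params)$state)
  })
  expected <- N * 2 * exp(-0.0035 * N)
  expect_lt(abs(mean(n1) - expected), 3 * sd(n1) / sqrt(1500))
})

test_that("density-independent growth at the optimum compounds at Wmax", {
  set.seed(36)
  m <- 25
  params <- sim_params(m = m, theta = sqrt(m), sigma_e2 = 0, alpha = 0,
                       N0 = 50)
  n3 <- replicate(300, {
    pop <- make_pop(matrix(1L, 50, m), matrix(1L, 50, m),
                    female = rep(c(TRUE, FALSE), 25))
    for (i in 1:3) pop <- step_generation(pop, params)$state
    census_size(pop)
  })
  expect_lt(abs(mean(n3) - 50 * 2^3), 3 * sd(n3) / sqrt(300))
})

test_that("neutral allele frequencies are conserved in expectation", {
  # selection switched off by a flat landscape; drift only
  set.seed(37)
  params <- sim_params(theta = 0, w2 = 1e12, Wmax = 1.4, alpha = 0, N0 = 50,
                       sigma_e2 = 0.5)
  pbar <- replicate(300, {
    pop <- init_population(params)
    for (i in 1:4) {
      nxt <- step_generation(pop, params)$state
      if (census_size(nxt) < 2) return(NA_real_)
      pop <- nxt
    }
    mean(allele_frequencies(pop))
  })
  pbar <- pbar[!is.na(pbar)]
  expect_lt(abs(mean(pbar) - 0.5), 3 * sd(pbar) / sqrt(length(pbar)))
})

test_that("trials terminate with a single well-defined status", {
  set.seed(38)
  # doomed: optimum far beyond the reachable genotype range
  doomed <- run_trial(sim_params(theta = 25, N0 = 20, horizon = 15, seed = 5))
  expect_equal(doomed$status, "extinct")
  expect_lte(doomed$records$t[nrow(doomed$records)], 15)
  tr <- run_trial(sim_params(N0 = 100, horizon = 10, seed = 6))
  expect_true(tr$status %in% c("extinct", "surviving", "censored"))
  # extinction is absorbing: records stop at the first census <= 1
  if (doomed$status == "extinct") {
    n <- doomed$records$N
    expect_true(all(n[-length(n)] > 1))
    expect_lte(n[length(n)], 1)
  }
})

test_that("a fixed seed makes trials bit-reproducible", {
  p <- sim_params(N0 = 30, horizon = 8, alpha = 0.0035, seed = 1234)
  a <- run_trial(p)
  b <- run_trial(p)
  expect_identical(a$records, b$records)
  expect_identical(a$status, b$status)
})

test_that("midparent brood rule preserves the total expected offspring", {
  set.seed(39)
  pop <- init_population(sim_params(N0 = 40))
  R <- runif(40, 0.5, 1.5)
  counts <- replicate(2000, census_size(
    produce_offspring(pop, R, brood = "midparent")))
  # each female's brood mean is R_f + E[R_male]; expectation over mates
  expected <- sum(R[pop$female]) + sum(pop$female) * mean(R[!pop$female])
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(2000))
})
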