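#' Draw phenotypes at birth
#'
#' A phenotype is the genotypic value plus an environmental deviation drawn
#' once, at birth, from Normal(0, `sigma_e2`). Deviations are never redrawn:
#' every individual keeps the phenotype it was born with for its single
#' generation of life.
#'
#' @param pop A non-empty [population_state()].
#' @param sigma_e2 Environmental phenotypic variance.
#' @return Numeric vector of phenotypes `z_i = g_i + e_i`.
#' @export
draw_phenotypes <- function(pop, sigma_e2) {
  g <- genotype_values(pop)
  if (sigma_e2 == 0) return(g)
  g + stats::rnorm(length(g), mean = 0, sd = sqrt(sigma_e2))
}

#' Intrinsic fitness under Gaussian stabilizing selection
#'
#' Expected offspring number of an individual in the absence of density
#' effects: `W = Wmax * exp(-(z - theta)^2 / (2 * w2))`.
#'
#' @param z Phenotype(s).
#' @param theta Phenotypic optimum.
#' @param w2 Variance of the fitness landscape (must be positive).
#' @param Wmax Maximum intrinsic fitness.
#' @return Intrinsic fitness, in `(0, Wmax]`.
#' @examples
#' intrinsic_fitness(0, theta = 2.8, w2 = 3.5, Wmax = 2) # about 0.65
#' @export
intrinsic_fitness <- function(z, theta, w2, Wmax) {
  stopifnot(w2 > 0)
  Wmax * exp(-(z - theta)^2 / (2 * w2))
}

#' Density-regulated expected offspring number
#'
#' Ricker regulation of intrinsic fitness: `R = W * exp(-alpha * N)`, where
#' `N` is the current census size. With `alpha = 0` growth is density
#' independent and `R = W`.
#'
#' @param W Intrinsic fitness value(s).
#' @param alpha Strength of negative density dependence (>= 0).
#' @param N Current census size.
#' @return Expected offspring number(s) `R`.
#' @export
expected_offspring <- function(W, alpha, N) {
  stopifnot(alpha >= 0, N >= 0)
  W * exp(-alpha * N)
}

#' One round of mating and reproduction
#'
#' Each female mates with one male drawn uniformly at random from the males
#' (males may sire several broods). Brood size is Poisson with mean `2 * R`
#' of the mother (or, optionally, the parents' summed `R` under the
#' midparent rule). Each offspring receives, independently at every locus,
#' one uniformly chosen allele copy from each parent (free recombination, no
#' linkage, no mutation), is assigned a sex by a fair coin, and draws its
#' phenotype at birth. If either sex is absent the returned generation is
#' empty: extinction is then certain at the next census.
#'
#' @param pop Parent [population_state()].
#' @param R Per-individual expected offspring numbers (length `N`).
#' @param sigma_e2 Environmental variance for the offspring phenotypes.
#' @param brood `"female"` or `"midparent"` brood-size rule.
#' @param keep_parents If `TRUE`, attach integer attributes `mother` and
#'   `father` (row indices into the parent state) to the result.
#' @return Offspring [population_state()] at generation `t + 1` (possibly
#'   empty).
#' @export
produce_offspring <- function(pop, R, sigma_e2 = 0,
                              brood = c("female", "midparent"),
                              keep_parents = FALSE) {
  brood <- match.arg(brood)
  N <- census_size(pop)
  if (N == 0) stop("cannot breed an empty population")
  stopifnot(length(R) == N)
  m <- ncol(pop$a1)
  fem <- which(pop$female)
  mal <- which(!pop$female)
  empty <- function() {
    population_state(pop$t + 1L, matrix(integer(), 0, m),
                     matrix(integer(), 0, m), logical(0), numeric(0))
  }
  if (length(fem) == 0 || length(mal) == 0) return(empty())

  mate <- mal[sample.int(length(mal), length(fem), replace = TRUE)]
  lambda <- switch(brood,
                   female = 2 * R[fem],
                   midparent = R[fem] + R[mate])
  broods <- stats::rpois(length(fem), lambda)
  K <- sum(broods)
  if (K == 0) return(empty())

  mom <- rep(fem, broods)
  dad <- rep(mate, broods)
  # one uniformly chosen copy per parent per locus
  inherit <- function(idx) {
    pick <- matrix(stats::runif(K * m) < 0.5, K, m)
    child <- pop$a2[idx, , drop = FALSE]
    first <- pop$a1[idx, , drop = FALSE]
    child[pick] <- first[pick]
    child
  }
  c1 <- inherit(mom)
  c2 <- inherit(dad)
  off <- population_state(pop$t + 1L, c1, c2,
                          female = stats::runif(K) < 0.5,
                          z = numeric(K))
  off$z <- draw_phenotypes(off, sigma_e2)
  if (keep_parents) {
    attr(off, "mother") <- mom
    attr(off, "father") <- dad
  }
  off
}

record_fields <- c("t", "N", "gbar", "zbar", "Wbar", "Rbar",
                   "sigma_a2", "fixed_pos", "fixed_neg")

# Census statistics of the current (parent) generation. Genetic fields are NA
# for an empty population.
census_record <- function(pop, params) {
  N <- census_size(pop)
  rec <- stats::setNames(rep(NA_real_, length(record_fields)), record_fields)
  rec["t"] <- pop$t
  rec["N"] <- N
  if (N == 0) return(rec)
  g <- genotype_values(pop)
  p <- allele_frequencies(pop)
  W <- intrinsic_fitness(pop$z, params$theta, params$w2, params$Wmax)
  fx <- fixation_counts(p)
  rec["gbar"] <- mean(g)
  rec["zbar"] <- mean(pop$z)
  rec["Wbar"] <- mean(W)
  rec["Rbar"] <- mean(expected_offspring(W, params$alpha, N))
  rec["sigma_a2"] <- switch(params$sa2_method,
                            frequency = additive_genetic_variance(p, params$m),
                            genotypic = genic_variance_genotypic(g))
  rec["fixed_pos"] <- fx["pos"]
  rec["fixed_neg"] <- fx["neg"]
  rec
}

#' Advance one generation
#'
#' Order of operations within a time step: census the parents and record
#' their statistics (size, mean genotype/phenotype, mean intrinsic fitness,
#' mean expected offspring with the Ricker term evaluated at the parents'
#' census size, additive genetic variance, fixation counts), then reproduce
#' and replace the generation (non-overlapping generations).
#'
#' @param state Parent [population_state()] (non-empty).
#' @param params A [sim_params()] object.
#' @return A list with elements `state` (the offspring generation, possibly
#'   empty) and `record` (named numeric vector of parent-census statistics).
#' @export
step_generation <- function(state, params) {
  rec <- census_record(state, params)
  W <- intrinsic_fitness(state$z, params$theta, params$w2, params$Wmax)
  R <- expected_offspring(W, params$alpha, census_size(state))
  off <- produce_offspring(state, R, sigma_e2 = params$sigma_e2,
                           brood = params$brood)
  list(state = off, record = rec)
}

#' Run one simulation trial
#'
#' Founds a population, iterates the life cycle and stops at the first of:
#' extinction (census `N <= 1`; a singleton cannot mate, so size 0 or 1 is
#' treated as extinct throughout), the generation horizon, or censoring when
#' the census exceeds `census_cap`. Every censused generation, including the
#' terminal one, is recorded. If `params$seed` is set the trial has its own
#' seeded random stream and is bit-reproducible.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `rescue_trajectory`: a list with `records`
#'   (data.frame, one row per censused generation), `status` (`"extinct"`,
#'   `"surviving"` or `"censored"`), `extinction_gen` (first generation with
#'   `N <= 1`, or `NA`), `maladaptation0` (`theta` minus the founding mean
#'   genotype) and `params`.
#' @examples
#' tr <- run_trial(sim_params(N0 = 20, horizon = 5, seed = 42))
#' tr$records$N
#' @export
run_trial <- function(params) {
  params <- validate_sim_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- init_population(params)
  recs <- matrix(NA_real_, params$horizon + 1L, length(record_fields),
                 dimnames = list(NULL, record_fields))
  status <- "surviving"
  ext_gen <- NA_integer_
  n_rec <- 0L
  repeat {
    t <- state$t
    N <- census_size(state)
    n_rec <- n_rec + 1L
    recs[n_rec, ] <- census_record(state, params)
    if (N <= 1) { status <- "extinct"; ext_gen <- t; break }
    if (N > params$census_cap) { status <- "censored"; break }
    if (t >= params$horizon) break
    state <- produce_offspring(
      state,
      expected_offspring(
        intrinsic_fitness(state$z, params$theta, params$w2, params$Wmax),
        params$alpha, N),
      sigma_e2 = params$sigma_e2, brood = params$brood)
  }
  records <- as.data.frame(recs[seq_len(n_rec), , drop = FALSE])
  records$t <- as.integer(records$t)
  structure(list(records = records, status = status,
                 extinction_gen = ext_gen,
                 maladaptation0 = params$theta - records$gbar[1],
                 params = params),
            class = "rescue_trajectory")
}

#' @export
print.rescue_trajectory <- function(x, ...) {
  r <- x$records
  cat(sprintf("rescue_trajectory: %d censuses (t = 0..%d), status = %s\n",
              nrow(r), r$t[nrow(r)], x$status))
  cat(sprintf("  N0 = %g, final N = %g, initial maladaptation = %.3f\n",
              r$N[1], r$N[nrow(r)], x$maladaptation0))
  invisible(x)
}
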