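#' Simulation parameters
#'
#' Construct and validate the full parameter set for one simulation trial.
#' Defaults encode the study conditions: a 25-locus diploid quantitative
#' trait, an environmental shift that moves the phenotypic optimum from 0 to
#' `theta = 2.8`, Gaussian stabilizing selection with landscape variance
#' `w2 = 3.5`, maximum intrinsic fitness `Wmax = 2`, environmental phenotypic
#' variance `sigma_e2 = 0.5`, and Ricker density regulation `exp(-alpha * N)`.
#'
#' @param m Number of biallelic loci. Each allele copy contributes
#'   `+1/(2*sqrt(m))` or `-1/(2*sqrt(m))` to the genotype.
#' @param theta Phenotypic optimum after the environmental change (the
#'   pre-change optimum is 0, so `theta` is also the initial expected
#'   maladaptation).
#' @param w2 Variance (squared width) of the Gaussian fitness landscape;
#'   inversely proportional to the strength of selection.
#' @param Wmax Maximum intrinsic fitness, attained at the optimum phenotype.
#' @param sigma_e2 Environmental (non-genetic) phenotypic variance.
#' @param alpha Strength of negative density dependence in the Ricker factor
#'   `exp(-alpha * N)`; `0` gives density-independent growth.
#' @param N0 Founding population size.
#' @param diversity `"high"` (all loci segregating at expected frequency 1/2)
#'   or `"low"` (six loci fixed for the positive allele and six for the
#'   negative allele at founding).
#' @param horizon Number of generation transitions to simulate; the founding
#'   census is generation 0.
#' @param census_cap Census size above which a trial is stopped and flagged
#'   censored (sustained super-replacement growth).
#' @param seed Integer seed for the trial's random number stream, or `NULL`
#'   to use the current stream.
#' @param brood `"female"` (brood size is Poisson with mean twice the
#'   mother's expected offspring number) or `"midparent"` (mean is the sum of
#'   the two parents' expected offspring numbers); `"female"` is the model
#'   default.
#' @param sa2_method How per-generation additive genetic variance is
#'   recorded: `"frequency"` (the allele-frequency form, the default) or
#'   `"genotypic"` (sample variance of genotypic values).
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(N0 = 20, diversity = "low", alpha = 0.0035, seed = 1)
#' p$theta
#' @export
sim_params <- function(m = 25, theta = 2.8, w2 = 3.5, Wmax = 2,
                       sigma_e2 = 0.5, alpha = 0, N0 = 100,
                       diversity = c("high", "low"), horizon = 15,
                       census_cap = 10000, seed = NULL,
                       brood = c("female", "midparent"),
                       sa2_method = c("frequency", "genotypic")) {
  diversity <- match.arg(diversity)
  brood <- match.arg(brood)
  sa2_method <- match.arg(sa2_method)
  p <- list(m = as.integer(m), theta = theta, w2 = w2, Wmax = Wmax,
            sigma_e2 = sigma_e2, alpha = alpha, N0 = as.integer(N0),
            diversity = diversity, horizon = as.integer(horizon),
            census_cap = census_cap, seed = seed, brood = brood,
            sa2_method = sa2_method)
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(
    "m must be >= 1" = p$m >= 1,
    "w2 must be > 0" = p$w2 > 0,
    "Wmax must be > 0" = p$Wmax > 0,
    "sigma_e2 must be >= 0" = p$sigma_e2 >= 0,
    "alpha must be >= 0" = p$alpha >= 0,
    "N0 must be >= 2 (mating requires both sexes)" = p$N0 >= 2,
    "horizon must be >= 1" = p$horizon >= 1,
    "census_cap must exceed N0" = p$census_cap > p$N0
  )
  if (p$diversity == "low" && p$m < 13)
    stop("low-diversity founding needs at least 13 loci (12 are fixed)")
  if (!is.null(p$seed)) {
    stopifnot("seed must be a finite number" = is.finite(p$seed))
    p$seed <- as.integer(p$seed %% .Machine$integer.max)
  }
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  loci m = %d, optimum theta = %g, w2 = %g, Wmax = %g, sigma_e2 = %g\n",
              x$m, x$theta, x$w2, x$Wmax, x$sigma_e2))
  cat(sprintf("  alpha = %g (%s), N0 = %d, diversity = %s\n",
              x$alpha, if (x$alpha > 0) "density-dependent" else "density-independent",
              x$N0, x$diversity))
  cat(sprintf("  horizon = %d generations, census cap = %g, seed = %s\n",
              x$horizon, x$census_cap,
              if (is.null(x$seed)) "<none>" else format(x$seed)))
  invisible(x)
}
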