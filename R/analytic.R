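#' Constant-variance analytic projection with a Ricker term
#'
#' Deterministic reference model in which phenotypic variance and the rate of
#' adaptation are held constant: the classic geometric-lag model of
#' adaptation after a sudden optimum shift, multiplied by a Ricker density
#' factor. The recursion is
#' \deqn{N_{t+1} = N_t \, W_{max} \sqrt{\frac{w^2}{w^2+\sigma^2_{a,0}+\sigma^2_e}}
#'   \exp\!\left(-\frac{(k_0^t \theta)^2}{2 (w^2+\sigma^2_{a,0}+\sigma^2_e)}\right)
#'   e^{-\alpha N_t},}
#' where `k0` is the per-generation multiplier of the phenotypic lag
#' (adaptation shrinks the lag geometrically) and `sigma_a0_2` the constant
#' additive variance. Sizes are real-valued: there is no demographic
#' stochasticity or drift.
#'
#' @param N0 Initial size.
#' @param T Number of generations to project (returns `T + 1` values).
#' @param k0 Lag multiplier, normally in `(0, 1]`; `k0 = 1` means no
#'   adaptation.
#' @param theta,w2,Wmax,sigma_e2,alpha As in [sim_params()].
#' @param sigma_a0_2 Constant additive genetic variance.
#' @return Numeric vector `N_0 .. N_T`.
#' @examples
#' project_gh_ricker(100, 15, k0 = 0.944, alpha = 0.0035)
#' @export
project_gh_ricker <- function(N0, T, k0, theta = 2.8, w2 = 3.5, Wmax = 2,
                              sigma_e2 = 0.5, alpha = 0, sigma_a0_2 = 0.5) {
  stopifnot(T >= 1, w2 > 0, Wmax > 0, sigma_a0_2 >= 0, sigma_e2 >= 0,
            alpha >= 0, N0 >= 0)
  V <- w2 + sigma_a0_2 + sigma_e2
  base <- Wmax * sqrt(w2 / V)
  N <- numeric(T + 1)
  N[1] <- N0
  for (t in 0:(T - 1)) {
    lag <- k0^t * theta
    N[t + 2] <- N[t + 1] * base * exp(-lag^2 / (2 * V)) * exp(-alpha * N[t + 1])
  }
  N
}

#' Estimate the first-step rate of phenotypic change
#'
#' For each trial that survives its first generation, the lag ratio
#' `k = (theta - gbar_1) / (theta - gbar_0)` measures how much of the
#' phenotypic gap to the optimum remains after one generation; `k0` is the
#' arithmetic mean of `k` over trials. Trials whose founding gap
#' `|theta - gbar_0|` is below `tol` are excluded (division guard). Because
#' fitness acts through fecundity and each brood's size follows a single
#' parent's expected offspring number, the per-brood relative selection
#' gradient is carried by one parent: the constant-variance expectation is
#' `1 - sigma_a2 / (2 (w2 + sigma_a2 + sigma_e2))` (17/18, about 0.944, at
#' the high-diversity defaults). Estimate `k0` separately within each
#' genetic diversity treatment.
#'
#' @param trials A list of `rescue_trajectory` objects (e.g. one diversity
#'   treatment of an experiment).
#' @param theta Phenotypic optimum.
#' @param tol Absolute tolerance for the founding-gap division guard.
#' @return A list with `k0` (mean), `se`, `n` (trials used) and `n_dropped`.
#' @export
estimate_k0 <- function(trials, theta, tol = 1e-9) {
  k <- vapply(trials, function(tr) {
    r <- tr$records
    if (nrow(r) < 2 || r$N[2] < 1) return(NA_real_)
    d0 <- theta - r$gbar[1]
    if (abs(d0) < tol) return(NA_real_)
    (theta - r$gbar[2]) / d0
  }, numeric(1))
  used <- k[!is.na(k)]
  if (length(used) == 0) stop("no trial survived to generation 1")
  list(k0 = mean(used),
       se = stats::sd(used) / sqrt(length(used)),
       n = length(used),
       n_dropped = sum(is.na(k)))
}

#' Equilibrium size of the density-dependent analytic model
#'
#' Fixed point of the analytic recursion at zero phenotypic lag (a fully
#' adapted population): `N* = log(Wmax * sqrt(w2 / (w2 + sigma_a0_2 +
#' sigma_e2))) / alpha`. This is the model's carrying capacity; the constant
#' variance load `sqrt(w2 / V)` keeps it below `log(Wmax) / alpha`.
#'
#' @inheritParams project_gh_ricker
#' @return The positive equilibrium `N*`.
#' @examples
#' equilibrium_size(alpha = 0.0035) # about 162
#' @export
equilibrium_size <- function(alpha, Wmax = 2, w2 = 3.5, sigma_e2 = 0.5,
                             sigma_a0_2 = 0.5) {
  stopifnot(w2 > 0, Wmax > 0, sigma_a0_2 >= 0, sigma_e2 >= 0)
  if (alpha <= 0) stop("no finite equilibrium without density dependence")
  growth <- Wmax * sqrt(w2 / (w2 + sigma_a0_2 + sigma_e2))
  if (growth < 1) stop("zero-lag growth factor below 1: no positive equilibrium")
  log(growth) / alpha
}
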