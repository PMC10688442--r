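#' Reverse time for an extinct trajectory
#'
#' Re-centres an extinct trial on its extinction so that all extinct
#' populations share a common origin: `tau = 0` is the first generation at
#' which the population is extinct (census 0 or 1), `tau = 1` the last
#' generation with census above 1, and so on back to founding.
#'
#' @param traj An extinct `rescue_trajectory`.
#' @return The trajectory's records with an added `tau` column, ordered by
#'   increasing `tau`.
#' @export
reverse_time <- function(traj) {
  ext <- classify_extinction(traj)
  if (is.na(ext)) stop("vortex analysis is defined only for extinct trajectories")
  r <- traj$records[traj$records$t <= ext, , drop = FALSE]
  r$tau <- ext - r$t
  r[order(r$tau), , drop = FALSE]
}

#' Per-generation vortex rates in reversed time
#'
#' For each `tau >= 1` (note `tau + 1` is the *earlier* generation):
#' the population growth rate `r_tau = log(N_tau / N_tau+1)` (negative while
#' declining toward extinction), the proportional loss of additive genetic
#' variance `nu_tau = 1 - (sigma_a2)_tau / (sigma_a2)_tau+1` (positive when
#' diversity is being lost, never above 1), and the rate of adaptation
#' `1 - k_tau` with `k_tau = (theta - gbar_tau) / (theta - gbar_tau+1)`
#' (near 0 when adaptation has stalled). Rates at `tau = 0` are not
#' estimated (growth is `-Inf` at size 0 and genetic state is undefined).
#' Denominator guards: a rate is `NA` when `(sigma_a2)_tau+1` is 0 or
#' `|theta - gbar_tau+1|` is below `tol`.
#'
#' @param tau_records Output of [reverse_time()].
#' @param theta Phenotypic optimum.
#' @param tol Absolute division-guard tolerance.
#' @return Data.frame with `tau`, `r`, `nu`, `one_minus_k`.
#' @export
vortex_rates <- function(tau_records, theta, tol = 1e-9) {
  r <- tau_records[tau_records$tau >= 1, , drop = FALSE]
  r <- r[order(r$tau), , drop = FALSE]
  if (nrow(r) < 2)
    return(data.frame(tau = integer(), r = numeric(), nu = numeric(),
                      one_minus_k = numeric()))
  now <- r[-nrow(r), , drop = FALSE]   # tau
  before <- r[-1, , drop = FALSE]      # tau + 1 (earlier generation)
  growth <- log(now$N / before$N)
  nu <- ifelse(abs(before$sigma_a2) < tol, NA_real_,
               1 - now$sigma_a2 / before$sigma_a2)
  k <- ifelse(abs(theta - before$gbar) < tol, NA_real_,
              (theta - now$gbar) / (theta - before$gbar))
  data.frame(tau = now$tau, r = growth, nu = nu, one_minus_k = 1 - k)
}

#' Ensemble extinction-vortex statistics
#'
#' Aligns every extinct trial of an experiment on its time to extinction and
#' averages the three vortex rates at each `tau`, per treatment and pooled
#' across all treatments. Evidence of an extinction vortex is a decreasing
#' mean growth rate and an increasing mean loss of genetic diversity as
#' `tau` approaches 0.
#'
#' @param experiment A `rescue_experiment` with trajectories kept (use the
#'   15-generation design, where state variables are tracked throughout).
#' @param pooled Also emit rows pooled over all treatments (labelled
#'   `"pooled"`).
#' @return Data.frame with `treatment`, `tau`, `metric` (`"r"`, `"nu"`,
#'   `"one_minus_k"`), `mean`, `se`, `n` (contributing trials; division-guard
#'   drops are excluded and counted in `n_dropped`).
#' @export
ensemble_vortex <- function(experiment, pooled = TRUE) {
  stopifnot(inherits(experiment, "rescue_experiment"),
            !is.null(experiment$trials))
  o <- experiment$outcomes
  theta <- experiment$trials[[1]]$params$theta
  ext_idx <- which(o$extinct)
  if (length(ext_idx) == 0) {
    return(structure(data.frame(treatment = character(), tau = integer(),
                                metric = character(), mean = numeric(),
                                se = numeric(), n = integer(),
                                n_dropped = integer()),
                     empty = TRUE))
  }
  rates <- lapply(ext_idx, function(i) {
    vr <- vortex_rates(reverse_time(experiment$trials[[i]]), theta)
    if (nrow(vr) > 0) vr$treatment <- treatment_key(o[i, , drop = FALSE])
    vr
  })
  rates <- do.call(rbind, rates[vapply(rates, nrow, 0L) > 0])
  groups <- if (pooled) c(unique(rates$treatment), "pooled")
  else unique(rates$treatment)
  out <- list()
  for (grp in groups) {
    sub <- if (grp == "pooled") rates else rates[rates$treatment == grp, ]
    for (metric in c("r", "nu", "one_minus_k")) {
      for (tau in sort(unique(sub$tau))) {
        x <- sub[[metric]][sub$tau == tau]
        dropped <- sum(is.na(x))
        x <- x[!is.na(x)]
        if (length(x) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          treatment = grp, tau = tau, metric = metric,
          mean = mean(x),
          se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
          n = length(x), n_dropped = dropped,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
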