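#' Build the regression table for outcome models
#'
#' One row per trial of a (50-generation) experiment: the Bernoulli outcome,
#' 0/1 indicators for density dependence (`densdep`), large founding size
#' (`large`) and high diversity (`highdiv`), and the trial's own observed
#' initial maladaptation `theta - gbar_0` in genotype units (with 25 loci,
#' one genotype unit corresponds to switching five allele copies per
#' individual, since `5 / sqrt(25) = 1`).
#'
#' @param outcomes Data.frame of [trial_outcome()] rows.
#' @param outcome `"extinct"`, `"rescue_fitness"` or `"rescue_size"`.
#' @return Data.frame with columns `outcome`, `densdep`, `large`, `highdiv`,
#'   `maladaptation0`.
#' @export
build_regression_table <- function(outcomes,
                                   outcome = c("extinct", "rescue_fitness",
                                               "rescue_size")) {
  outcome <- match.arg(outcome)
  y <- as.integer(outcomes[[outcome]])
  tab <- data.frame(outcome = y,
                    densdep = as.integer(outcomes$density == "NDD"),
                    large = as.integer(outcomes$size == "large"),
                    highdiv = as.integer(outcomes$diversity == "high"),
                    maladaptation0 = outcomes$maladaptation0)
  stopifnot(!anyNA(tab))
  if (length(unique(y)) < 2)
    attr(tab, "degenerate") <- TRUE
  tab
}

#' Fit the saturated logistic outcome model
#'
#' Maximum-likelihood logistic regression of the Bernoulli outcome on the
#' full four-way interaction of density dependence, founding size, genetic
#' diversity and initial maladaptation. Perfect or quasi-perfect separation
#' (non-convergence, or fitted probabilities collapsing to 0/1) is detected
#' and reported; a ridge-penalized refit (iterated weighted least squares
#' with a small quadratic penalty on the slopes) is then used so that finite
#' coefficients are always returned.
#'
#' @param table Output of [build_regression_table()].
#' @param penalty Ridge penalty used only in the separation fallback.
#' @return Object of class `rescue_logit`: list with `coef`, `vcov`, `fit`
#'   (the `glm` object or `NULL` after fallback), `separation` flag and the
#'   model `terms`.
#' @export
fit_logistic <- function(table, penalty = 1e-4) {
  if (isTRUE(attr(table, "degenerate")))
    stop("outcome is constant: logistic model is degenerate")
  form <- outcome ~ densdep * large * highdiv * maladaptation0
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = table),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  separated <- warned && (!fit$converged ||
                            any(mu > 1 - 1e-8) || any(mu < 1e-8)) &&
    max(abs(stats::coef(fit))) > 15
  if (!separated) {
    return(structure(list(coef = stats::coef(fit), vcov = stats::vcov(fit),
                          fit = fit, separation = FALSE, terms = form),
                     class = "rescue_logit"))
  }
  # ridge-penalized IWLS fallback (penalty on all but the intercept)
  X <- stats::model.matrix(form, table)
  y <- table$outcome
  pen <- diag(c(0, rep(penalty, ncol(X) - 1)))
  beta <- rep(0, ncol(X))
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    score <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  V <- solve(H)
  names(beta) <- colnames(X)
  structure(list(coef = beta, vcov = V, fit = NULL, separation = TRUE,
                 terms = form),
            class = "rescue_logit")
}

#' @export
print.rescue_logit <- function(x, ...) {
  cat("Logistic outcome model:", deparse(x$terms), "\n")
  if (x$separation)
    cat("  (separation detected; ridge-penalized fit)\n")
  print(round(x$coef, 4))
  invisible(x)
}

logit_row <- function(fit, densdep, large, highdiv, maladaptation0) {
  nd <- data.frame(densdep = densdep, large = large, highdiv = highdiv,
                   maladaptation0 = maladaptation0)
  stats::model.matrix(stats::delete.response(stats::terms(fit$terms)), nd)
}

#' Density-dependence effect sizes per size x diversity cell
#'
#' The log-odds contrast of turning density dependence on, evaluated within
#' each founding-size x diversity cell at that cell's mean observed initial
#' maladaptation, exponentiated to an odds ratio. Wald 95% intervals come
#' from the delta method on the linear contrast.
#'
#' @param fit A `rescue_logit`.
#' @param table The regression table the model was fitted to (supplies the
#'   cell-mean maladaptation values).
#' @return Data.frame with `size`, `diversity`, `maladaptation_at`,
#'   `log_or`, `se`, `odds_ratio`, `lo`, `hi`.
#' @export
density_effect_sizes <- function(fit, table) {
  cells <- expand.grid(large = c(1L, 0L), highdiv = c(1L, 0L))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- table$large == cells$large[i] & table$highdiv == cells$highdiv[i]
    x0 <- mean(table$maladaptation0[sel])
    ctr <- logit_row(fit, 1L, cells$large[i], cells$highdiv[i], x0) -
      logit_row(fit, 0L, cells$large[i], cells$highdiv[i], x0)
    est <- drop(ctr %*% fit$coef)
    se <- sqrt(drop(ctr %*% fit$vcov %*% t(ctr)))
    out[[i]] <- data.frame(
      size = if (cells$large[i] == 1) "large" else "small",
      diversity = if (cells$highdiv[i] == 1) "high" else "low",
      maladaptation_at = x0, log_or = est, se = se,
      odds_ratio = exp(est),
      lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Maladaptation slope within each treatment cell
#'
#' The change in log odds per unit of initial maladaptation (one genotype
#' unit = five allele copies switched per individual at 25 loci), evaluated
#' within each of the eight density x size x diversity cells.
#'
#' @param fit A `rescue_logit`.
#' @return Data.frame with `density`, `size`, `diversity`, `slope`, `se`,
#'   `lo`, `hi` (Wald 95%).
#' @export
maladaptation_slopes <- function(fit) {
  cells <- expand.grid(densdep = c(0L, 1L), large = c(1L, 0L),
                       highdiv = c(1L, 0L))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    ctr <- logit_row(fit, cells$densdep[i], cells$large[i], cells$highdiv[i], 1) -
      logit_row(fit, cells$densdep[i], cells$large[i], cells$highdiv[i], 0)
    est <- drop(ctr %*% fit$coef)
    se <- sqrt(drop(ctr %*% fit$vcov %*% t(ctr)))
    out[[i]] <- data.frame(
      density = if (cells$densdep[i] == 1) "NDD" else "DI",
      size = if (cells$large[i] == 1) "large" else "small",
      diversity = if (cells$highdiv[i] == 1) "high" else "low",
      slope = est, se = se, lo = est - 1.96 * se, hi = est + 1.96 * se,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
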