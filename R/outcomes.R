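#' Extinction generation of a trajectory
#'
#' The first censused generation with `N <= 1` (a census of 0 or 1 counts as
#' extinct: a singleton cannot mate). Surviving and censored trajectories
#' return `NA`.
#'
#' @param traj A `rescue_trajectory`.
#' @return Integer generation of extinction, or `NA`.
#' @export
classify_extinction <- function(traj) {
  w <- which(traj$records$N <= 1)
  if (length(w) == 0) NA_integer_ else traj$records$t[w[1]]
}

# first index starting a run of >= len consecutive TRUEs; NA if none
first_run_start <- function(ok, len = 3L) {
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0) NA_integer_ else starts[hit[1]]
}

#' Time of evolutionary rescue under a given criterion
#'
#' Fitness-based rescue: mean expected offspring number `Rbar_t` strictly
#' greater than 1 for three consecutive censused generations. Size-based
#' rescue: census size strictly exceeding the founding size for three
#' consecutive generations. The rescue time is the first of the three
#' generations. Ties do not count (strict inequalities), and a rescue flag is
#' never revoked by later decline or extinction. For censored trajectories
#' the observed prefix is scanned; if no three-generation run completed
#' before censoring and `censored_rescue` is `TRUE` (default), the trial is
#' classified rescued at the start of the trailing qualifying run (exceeding
#' the census cap implies sustained super-replacement).
#'
#' @param traj A `rescue_trajectory`.
#' @param criterion `"fitness"` or `"size"`.
#' @param censored_rescue Classify cap-censored trials without a completed
#'   run as rescued at censoring.
#' @return Integer rescue time (generation), or `NA` if never rescued.
#' @export
classify_rescue <- function(traj, criterion = c("fitness", "size"),
                            censored_rescue = TRUE) {
  criterion <- match.arg(criterion)
  r <- traj$records
  ok <- switch(criterion,
               fitness = r$Rbar > 1,
               size = r$N > r$N[1])
  i <- first_run_start(ok, 3L)
  if (!is.na(i)) return(r$t[i])
  if (traj$status == "censored" && censored_rescue) {
    ok[is.na(ok)] <- FALSE
    trailing <- 0L
    while (trailing < length(ok) && ok[length(ok) - trailing]) trailing <- trailing + 1L
    return(r$t[length(ok) - max(trailing - 1L, 0L)])
  }
  NA_integer_
}

#' Classify one trial's outcome
#'
#' Collapses a trajectory into the per-trial record used by the experiment
#' summaries and regressions: extinction flag/time, rescue flags/times under
#' both criteria, instantaneous-rescue flags (rescue time 0 or 1),
#' extinct-after-rescue flags, and the initial maladaptation
#' `theta - gbar_0`.
#'
#' @param traj A `rescue_trajectory`.
#' @param censored_rescue Passed to [classify_rescue()].
#' @return One-row data.frame.
#' @export
trial_outcome <- function(traj, censored_rescue = TRUE) {
  ext <- classify_extinction(traj)
  tf <- classify_rescue(traj, "fitness", censored_rescue)
  ts <- classify_rescue(traj, "size", censored_rescue)
  p <- traj$params
  data.frame(
    alpha = p$alpha, N0 = p$N0, diversity = p$diversity,
    density = if (p$alpha > 0) "NDD" else "DI",
    size = if (p$N0 >= 100) "large" else "small",
    status = traj$status,
    end_gen = traj$records$t[nrow(traj$records)],
    extinct = !is.na(ext), extinction_gen = ext,
    rescue_fitness = !is.na(tf), t_rescue_fitness = tf,
    rescue_size = !is.na(ts), t_rescue_size = ts,
    instant_fitness = !is.na(tf) && tf <= 1,
    instant_size = !is.na(ts) && ts <= 1,
    extinct_after_rescue_fitness = !is.na(tf) && !is.na(ext),
    extinct_after_rescue_size = !is.na(ts) && !is.na(ext),
    maladaptation0 = traj$maladaptation0,
    stringsAsFactors = FALSE)
}

#' Per-generation extinction probability series
#'
#' Instantaneous mode: probability of going extinct in generation `t`
#' conditioned on having survived to `t` (censored trials leave the risk set
#' after their last observed generation). Cumulative mode: probability of
#' extinction in or before `t` out of all trials; this series is
#' non-decreasing. Standard errors are binomial.
#'
#' @param outcomes Data.frame of [trial_outcome()] rows (one treatment or any
#'   grouping the caller has already applied).
#' @param mode `"instantaneous"` or `"cumulative"`.
#' @param t_max Last generation to report; defaults to the largest observed
#'   end generation.
#' @return Data.frame with columns `t`, `prob`, `se`, `n` (denominator);
#'   instantaneous rows with an empty risk set are dropped.
#' @export
extinction_prob_series <- function(outcomes,
                                   mode = c("instantaneous", "cumulative"),
                                   t_max = max(outcomes$end_gen)) {
  mode <- match.arg(mode)
  stopifnot(nrow(outcomes) >= 1)
  ts <- 0:t_max
  if (mode == "cumulative") {
    n <- nrow(outcomes)
    prob <- vapply(ts, function(t)
      sum(outcomes$extinct & outcomes$extinction_gen <= t) / n, numeric(1))
    return(data.frame(t = ts, prob = prob,
                      se = sqrt(prob * (1 - prob) / n), n = n))
  }
  out <- lapply(ts, function(t) {
    at_risk <- (!outcomes$extinct | outcomes$extinction_gen >= t) &
      outcomes$end_gen >= t
    n <- sum(at_risk)
    if (n == 0) return(NULL)
    p <- sum(outcomes$extinct & outcomes$extinction_gen == t & at_risk) / n
    data.frame(t = t, prob = p, se = sqrt(p * (1 - p) / n), n = n)
  })
  do.call(rbind, out)
}

#' Treatment-level rescue summary
#'
#' For each treatment cell and each rescue criterion: the probability of
#' rescue, the proportion (and count) of rescued trials whose rescue was
#' instantaneous (time 0 or 1), the mean time to rescue among rescued trials,
#' and the probability of extinction after rescue. The layout mirrors a
#' rescue-probability summary table with one row per
#' criterion x size x diversity x density cell.
#'
#' @param outcomes Data.frame of [trial_outcome()] rows.
#' @return Data.frame with columns `criterion`, `size`, `diversity`,
#'   `density`, `n`, `prob_rescue`, `propn_instant`, `n_instant`,
#'   `mean_time`, `prob_extinct_after`.
#' @export
rescue_summary <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  cells <- unique(outcomes[, c("size", "diversity", "density")])
  rows <- list()
  for (crit in c("fitness", "size")) {
    resc <- outcomes[[paste0("rescue_", crit)]]
    tt <- outcomes[[paste0("t_rescue_", crit)]]
    inst <- outcomes[[paste0("instant_", crit)]]
    extafter <- outcomes[[paste0("extinct_after_rescue_", crit)]]
    for (i in seq_len(nrow(cells))) {
      sel <- outcomes$size == cells$size[i] &
        outcomes$diversity == cells$diversity[i] &
        outcomes$density == cells$density[i]
      n <- sum(sel)
      nr <- sum(resc[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        criterion = crit, size = cells$size[i],
        diversity = cells$diversity[i], density = cells$density[i],
        n = n, prob_rescue = nr / n,
        propn_instant = if (nr > 0) sum(inst[sel]) / nr else NA_real_,
        n_instant = sum(inst[sel]),
        mean_time = if (nr > 0) mean(tt[sel][resc[sel]]) else NA_real_,
        prob_extinct_after = if (nr > 0) sum(extafter[sel]) / nr else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
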