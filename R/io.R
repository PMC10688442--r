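#' Flatten trajectories to a long table
#'
#' One row per (trial, censused generation) with the trial's treatment
#' labels and terminal status; genetic fields of an empty census are `NA`
#' (written as empty CSV fields).
#'
#' @param experiment A `rescue_experiment` with trajectories kept.
#' @return Data.frame with columns `trial_id`, `density`, `size`,
#'   `diversity`, `status`, then the per-generation record fields.
#' @export
trajectories_table <- function(experiment) {
  stopifnot(inherits(experiment, "rescue_experiment"),
            !is.null(experiment$trials))
  o <- experiment$outcomes
  rows <- lapply(seq_along(experiment$trials), function(i) {
    r <- experiment$trials[[i]]$records
    cbind(data.frame(trial_id = o$trial_id[i], density = o$density[i],
                     size = o$size[i], diversity = o$diversity[i],
                     status = o$status[i], stringsAsFactors = FALSE),
          r)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write experiment outputs as CSV
#'
#' Writes `trajectories.csv` (when trajectories were kept), `outcomes.csv`
#' and `manifest.json` (design, seeds and package version: enough to
#' byte-reproduce every trial) into a directory.
#'
#' @param experiment A `rescue_experiment`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(experiment$trials)) {
    p <- file.path(dir, "trajectories.csv")
    utils::write.csv(trajectories_table(experiment), p, row.names = FALSE,
                     na = "")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "outcomes.csv")
  utils::write.csv(experiment$outcomes, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  d <- experiment$design
  manifest <- list(
    package = "evorescue",
    version = as.character(utils::packageVersion("evorescue")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    base_seed = d$base_seed, reps = d$reps, horizon = d$horizon,
    census_cap = d$census_cap, treatments = d$treatments,
    trial_seeds = experiment$outcomes$seed)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(paths, p))
}

#' Read a flat key-value configuration file
#'
#' YAML with flat keys; unknown keys fail fast with the offending key named.
#' Missing keys take the default study configuration (see
#' [default_config()]).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, user)
}

#' Default study configuration
#'
#' The full default parameter and design set: 25 loci, optimum shift to 2.8,
#' `Wmax = 2`, `w2 = 3.5`, `sigma_e2 = 0.5`, the 2 x 2 x 2 treatment design
#' (`alpha` 0/0.0035, `N0` 100/20, diversity high/low), census cap 10000,
#' and desk-scale replicate counts (1000 per treatment over 15 generations
#' for trajectory analyses; 500 per treatment over 50 generations for
#' outcome probabilities).
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(m = 25, theta = 2.8, w2 = 3.5, Wmax = 2, sigma_e2 = 0.5,
       alpha_levels = c(0, 0.0035), N0_levels = c(100, 20),
       diversity_levels = c("high", "low"),
       census_cap = 10000,
       reps_short = 1000, horizon_short = 15,
       reps_long = 500, horizon_long = 50,
       base_seed = 1)
}
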