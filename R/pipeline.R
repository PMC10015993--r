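#' Load a run configuration
#'
#' A run configuration ties the pipeline stages together: synthetic specs
#' (or input file paths), measure settings, comparison options, a run seed
#' and an output directory. Stage seeds are derived deterministically from
#' the run seed, so a full simulate / score / compare run is bit-
#' reproducible. Configurations round-trip through YAML.
#'
#' @param path YAML file, or a list with the same structure.
#' @return List of class `run_config` with elements `seed`, `out_dir`,
#'   `forecast` (n_sims, sigma_nat, sigma_unit), `ratings` (n_participants,
#'   generating_measure, noise settings), `measures`, `measure_config`
#'   fields, `n_perm`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    seed = NULL,
    out_dir = ".",
    forecast = list(n_sims = 20000L, sigma_nat = 1, sigma_unit = 1),
    ratings = list(
      n_participants = 207L, generating_measure = "cesm",
      slope = 2, intercept = 4.6, participant_sd = 1, residual_sd = 3
    ),
    measures = c("cesm", "nsm", "pivotality", "delta_p_obs", "pns",
                 "power_pc"),
    min_sims = 10L,
    nsm_w_nec = 1,
    n_perm = 2000L
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seed)) {
    stop("run config must name a `seed`", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

write_manifest <- function(out_dir, stage, seeds, extra = list()) {
  manifest <- c(
    list(
      stage = stage, seeds = seeds,
      package_version = as.character(utils::packageVersion("causalworlds")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
}

#' Simulate stage: write a synthetic ensemble and ratings to disk
#'
#' Generates a 2020-style forecast ensemble and a ratings table whose
#' generating model is the configured measure, and writes both (plus a
#' manifest of derived seeds) under the output directory. Rerunning with
#' the same config reproduces the files bit for bit.
#'
#' @param config A [run_config()] (or path / list accepted by it).
#' @return Invisibly, list with `ensemble`, `ratings`, `scores` and the
#'   file paths written.
#' @export
run_simulate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(
    forecast = derive_seed(cfg$seed, 1L),
    ratings = derive_seed(cfg$seed, 2L)
  )
  fspec <- forecast_spec_2020(seeds$forecast,
    sigma_nat = cfg$forecast$sigma_nat, sigma_unit = cfg$forecast$sigma_unit
  )
  ens <- simulate_forecast(fspec, cfg$forecast$n_sims)
  actual <- actual_world_2020(ens$map)
  scores <- score_all(ens, actual, measures = cfg$ratings$generating_measure)
  gen <- stats::setNames(
    scores[[cfg$ratings$generating_measure]], scores$unit
  )
  gen <- gen[!is.na(gen)]
  rspec <- rating_spec(gen,
    n_participants = cfg$ratings$n_participants, seed = seeds$ratings,
    intercept = cfg$ratings$intercept, slope = cfg$ratings$slope,
    participant_sd = cfg$ratings$participant_sd,
    residual_sd = cfg$ratings$residual_sd
  )
  ratings <- simulate_ratings(rspec)

  ens_path <- file.path(cfg$out_dir, "ensemble.csv")
  rat_path <- file.path(cfg$out_dir, "ratings.csv")
  utils::write.csv(as.data.frame(ens$outcomes), ens_path, row.names = FALSE)
  write_table(ratings, rat_path)
  write_manifest(cfg$out_dir, "simulate", seeds,
    list(n_sims = nrow(ens$outcomes))
  )
  invisible(list(
    ensemble = ens, ratings = ratings, scores = scores,
    paths = c(ensemble = ens_path, ratings = rat_path)
  ))
}

#' Score stage: causal score table for an ensemble
#'
#' Computes the configured causal measures for every unit the focal
#' candidate won in the actual world and writes the unit-by-measure table.
#'
#' @param config A [run_config()].
#' @param ensemble Optional in-memory [world_ensemble]; otherwise
#'   `ensemble.csv` under the config's output directory is read.
#' @return Invisibly, the score data frame (also written to `scores.csv`).
#' @export
run_score <- function(config, ensemble = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(ensemble)) {
    ensemble <- read_simulations(
      file.path(cfg$out_dir, "ensemble.csv"),
      dialect = "binary_csv"
    )
  }
  actual <- actual_world_2020(ensemble$map)
  mc <- measure_config(
    cesm_method = "exhaustive",
    min_sims = cfg$min_sims, nsm_w_nec = cfg$nsm_w_nec
  )
  scores <- score_all(ensemble, actual, measures = cfg$measures, config = mc)
  write_table(scores, file.path(cfg$out_dir, "scores.csv"))
  write_manifest(cfg$out_dir, "score", list(run = cfg$seed),
    list(measures = cfg$measures, min_sims = cfg$min_sims)
  )
  invisible(scores)
}

#' Compare stage: model-vs-human statistics
#'
#' Computes, for each measure column of a score table: the unit-mean
#' correlation fit, the paired permutation p-value against every other
#' measure, the regression of scores and of human means on prior
#' probability and electoral votes, and the subgroup-invariance summary.
#' Tables are written under the output directory.
#'
#' @param config A [run_config()].
#' @param scores,ratings,ensemble Optional in-memory objects; otherwise read
#'   from the config's output directory.
#' @return Invisibly, list with `fits`, `perm_p` (matrix), `regressions`,
#'   `subgroup`.
#' @export
run_compare <- function(config, scores = NULL, ratings = NULL,
                        ensemble = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(scores)) {
    scores <- read_score_table(file.path(cfg$out_dir, "scores.csv"))
  }
  if (is.null(ratings)) {
    ratings <- read_ratings(file.path(cfg$out_dir, "ratings.csv"))
  }
  if (is.null(ensemble)) {
    ensemble <- read_simulations(
      file.path(cfg$out_dir, "ensemble.csv"),
      dialect = "binary_csv"
    )
  }
  means <- state_means(ratings)
  measure_cols <- setdiff(names(scores), "unit")

  fits <- do.call(rbind, lapply(measure_cols, function(m) {
    sv <- stats::setNames(scores[[m]], scores$unit)
    cbind(measure = m, model_human_correlation(sv, means))
  }))

  perm_p <- matrix(NA_real_, length(measure_cols), length(measure_cols),
    dimnames = list(measure_cols, measure_cols)
  )
  for (i in seq_along(measure_cols)) {
    for (jj in seq_along(measure_cols)) {
      if (i == jj) next
      a <- stats::setNames(scores[[measure_cols[i]]], scores$unit)
      b <- stats::setNames(scores[[measure_cols[jj]]], scores$unit)
      perm_p[i, jj] <- paired_permutation_test(
        a, b, means,
        n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 100L + 10L * i + jj)
      )$p
    }
  }

  targets <- c(
    list(humans = stats::setNames(means$mean, means$unit)),
    stats::setNames(
      lapply(measure_cols, function(m) {
        stats::setNames(scores[[m]], scores$unit)
      }),
      measure_cols
    )
  )
  regressions <- do.call(rbind, lapply(names(targets), function(nm) {
    rg <- prior_votes_regression(targets[[nm]], ensemble)
    cbind(target = nm, rg)
  }))

  subgroup <- tryCatch(
    subgroup_invariance(ratings),
    error = function(e) NULL
  )

  write_table(fits, file.path(cfg$out_dir, "fits.csv"))
  write_table(
    cbind(measure = rownames(perm_p), as.data.frame(perm_p)),
    file.path(cfg$out_dir, "permutation_p.csv")
  )
  write_table(regressions, file.path(cfg$out_dir, "regressions.csv"))
  write_manifest(cfg$out_dir, "compare", list(run = cfg$seed),
    list(n_perm = cfg$n_perm)
  )
  invisible(list(
    fits = fits, perm_p = perm_p, regressions = regressions,
    subgroup = subgroup
  ))
}

#' Model-recovery experiment
#'
#' End-to-end check that the comparison pipeline identifies the generating
#' model: score one synthetic ensemble under all measures, then repeatedly
#' generate ratings from one measure's scores (at the default noise
#' calibration) and record how often that measure achieves the highest
#' unit-mean correlation with the synthetic human data.
#'
#' @param config A [run_config()]; `ratings$generating_measure` names the
#'   generator.
#' @param n_replicates Number of seeded ratings replicates.
#' @return List with `recovery_rate`, `winners` (character vector per
#'   replicate), `scores`.
#' @export
run_recover <- function(config, n_replicates = 100L) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  fspec <- forecast_spec_2020(derive_seed(cfg$seed, 1L),
    sigma_nat = cfg$forecast$sigma_nat, sigma_unit = cfg$forecast$sigma_unit
  )
  ens <- simulate_forecast(fspec, cfg$forecast$n_sims)
  actual <- actual_world_2020(ens$map)
  mc <- measure_config(min_sims = cfg$min_sims, nsm_w_nec = cfg$nsm_w_nec)
  scores <- score_all(ens, actual, measures = cfg$measures, config = mc)
  gen_name <- cfg$ratings$generating_measure
  gen <- stats::setNames(scores[[gen_name]], scores$unit)
  gen <- gen[!is.na(gen)]

  measure_cols <- setdiff(names(scores), "unit")
  winners <- vapply(seq_len(n_replicates), function(rep) {
    rspec <- rating_spec(gen,
      n_participants = cfg$ratings$n_participants,
      seed = derive_seed(cfg$seed, 1000L + rep),
      intercept = cfg$ratings$intercept, slope = cfg$ratings$slope,
      participant_sd = cfg$ratings$participant_sd,
      residual_sd = cfg$ratings$residual_sd
    )
    means <- state_means(simulate_ratings(rspec))
    rs <- vapply(measure_cols, function(m) {
      sv <- stats::setNames(scores[[m]], scores$unit)
      model_human_correlation(sv, means)$r
    }, numeric(1))
    names(which.max(rs))
  }, character(1))

  list(
    recovery_rate = mean(winners == gen_name),
    winners = winners,
    scores = scores
  )
}
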