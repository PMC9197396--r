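#' Pipeline configuration
#'
#' Collects everything one analysis run needs: the task and cohort
#' configurations, the output directory, the seed, and per-stage switches.
#' Can be serialised to/read from YAML or JSON via [read_pipeline_config()].
#'
#' @param task A [task_config()] object.
#' @param cohort A [cohort_config()] object.
#' @param output_dir Directory for the CSV/JSON artifacts.
#' @param seed Integer seed recorded in all outputs.
#' @param stages Named logical switches: `passive`, `efficiency`,
#'   `optimality`, `metrics`, `report`.
#' @param trajectories `"simulator"` reuses the observer replay computed
#'   while simulating (point-capped; the default), `"exact"` recomputes
#'   every trajectory with the full grid observer.
#' @return An object of class `cq_pipeline_config`.
#' @export
pipeline_config <- function(task = task_config(), cohort = cohort_config(),
                            output_dir = tempfile("cq_run_"), seed = 1,
                            stages = c(passive = TRUE, efficiency = TRUE,
                                       optimality = TRUE, metrics = TRUE,
                                       report = TRUE),
                            trajectories = c("simulator", "exact")) {
  stopifnot(inherits(task, "cq_task"), inherits(cohort, "cq_cohort_config"))
  defaults <- c(passive = TRUE, efficiency = TRUE, optimality = TRUE,
                metrics = TRUE, report = TRUE)
  defaults[names(stages)] <- stages
  structure(
    list(task = task, cohort = cohort, output_dir = output_dir,
         seed = as.integer(seed), stages = defaults,
         trajectories = match.arg(trajectories)),
    class = "cq_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys `task`, `cohort`, `seed`, `output_dir`, `stages`,
#' `trajectories`; `task` and `cohort` entries override the corresponding
#' [task_config()] / [cohort_config()] defaults.
#'
#' @param path File path (`.yml`/`.yaml`/`.json`).
#' @return A `cq_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  task <- do.call(task_config, as.list(raw$task))
  cohort <- do.call(cohort_config, as.list(raw$cohort))
  args <- list(task = task, cohort = cohort)
  for (k in c("output_dir", "seed", "trajectories")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$stages)) args$stages <- unlist(raw$stages)
  do.call(pipeline_config, args)
}

# all numeric columns serialised at 6 significant digits for diff-stable runs
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a dataset's tables as CSV files
#'
#' @param dataset A `cq_dataset` (see [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(dataset$trials, file.path(dir, "trials.csv"))
  write_table(dataset$samples, file.path(dir, "samples.csv"))
  write_table(dataset$questionnaires, file.path(dir, "questionnaires.csv"))
  if (!is.null(dataset$passive)) {
    write_table(dataset$passive, file.path(dir, "passive.csv"))
    write_table(dataset$offer_dots, file.path(dir, "offer_dots.csv"))
  }
  invisible(dir)
}

required_columns <- list(
  trials = c("participant_id", "trial_id", "R0", "eta_s", "hidden_x",
             "hidden_y", "placement_x", "placement_y", "n_paid_samples",
             "error_px", "score"),
  samples = c("participant_id", "trial_id", "sample_index", "t_s", "x", "y",
              "colour", "paid"),
  questionnaires = c("participant_id", "group", "bdi", "hads_anx",
                     "hads_dep", "ace_iii")
)

#' Load and validate a dataset from CSV files
#'
#' Reads `trials.csv`, `samples.csv`, `questionnaires.csv` (and
#' `passive.csv` when present) from a directory, checking the schema and
#' cross-file integrity: required columns, every sample row joining a trial
#' row, every trial joining a questionnaire participant, timestamps
#' non-decreasing within each trial, and the first dot of each trial being
#' the free (unpaid) one. Each violation is a distinct error.
#'
#' @param dir Directory containing the CSV files.
#' @return A `cq_dataset` list of validated data.frames.
#' @export
load_dataset <- function(dir) {
  read1 <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(required_columns[[name]], names(df))
    if (length(miss)) {
      stop(sprintf("missing column(s) in %s.csv: %s", name,
                   paste(miss, collapse = ", ")))
    }
    df
  }
  trials <- read1("trials")
  samples <- read1("samples")
  questionnaires <- read1("questionnaires")

  tkey <- paste(trials$participant_id, trials$trial_id)
  skey <- paste(samples$participant_id, samples$trial_id)
  if (!all(skey %in% tkey)) {
    stop("orphan sample rows: sample(s) referencing no trial, e.g. ",
         skey[!skey %in% tkey][1])
  }
  if (!all(trials$participant_id %in% questionnaires$participant_id)) {
    stop("integrity error: trial(s) referencing unknown participant(s): ",
         paste(setdiff(trials$participant_id,
                       questionnaires$participant_id)[1], collapse = ", "))
  }
  for (k in split(seq_len(nrow(samples)), skey)) {
    o <- k[order(samples$sample_index[k])]
    if (is.unsorted(samples$t_s[o])) {
      stop("timestamp-order error: decreasing timestamps in trial ",
           skey[k[1]])
    }
    if (samples$paid[o[1]] != 0) {
      stop("first sample of trial ", skey[k[1]], " must be the free dot")
    }
  }
  out <- list(trials = trials, samples = samples,
              questionnaires = questionnaires)
  ppath <- file.path(dir, "passive.csv")
  if (file.exists(ppath)) {
    out$passive <- utils::read.csv(ppath, stringsAsFactors = FALSE)
  }
  class(out) <- "cq_dataset"
  out
}

# tiny FNV-1a hash of the serialised configuration, for provenance
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[c("seed", "trajectories")]),
                           deparse(unclass(config$task)),
                           deparse(unclass(config$cohort)), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# per-participant EE trajectories: reuse the simulator's observer replay or
# recompute each trial exactly on the full grid
trajectory_stage <- function(dataset, task, mode) {
  if (mode == "simulator" && !is.null(dataset$trajectories)) {
    return(dataset$trajectories)
  }
  ids <- unique(dataset$trials$participant_id)
  out <- lapply(ids, function(id) {
    sm <- dataset$samples[dataset$samples$participant_id == id, ]
    byt <- split(sm, factor(sm$trial_id, levels = sort(unique(sm$trial_id))))
    lapply(byt, function(s) ee_trajectory(s[order(s$sample_index), ], task))
  })
  names(out) <- ids
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> observe -> fit -> optimality -> metrics ->
#' report. Writes `trials.csv`, `samples.csv`, `questionnaires.csv`,
#' `passive.csv`, `ee_trajectories.csv`, `efficiency.csv`,
#' `optimality.csv`, `metrics.csv` and `stats_report.json` into the
#' configured output directory. Idempotent under a fixed seed: two runs
#' with the same configuration produce byte-identical files.
#'
#' @param config A [pipeline_config()] object, or the path of a YAML/JSON
#'   configuration file.
#' @return An object of class `cq_run_report`: per-stage row counts, the
#'   group contrasts and correlation table, and provenance (seed, config
#'   hash, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cq_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- "simulate"
  counts <- list()
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 package_version = as.character(utils::packageVersion("circlequest")))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- config$cohort
  cohort$seed <- NULL  # seeding handled here, once, for the whole run
  dataset <- run_stage("simulate",
    simulate_cohort(cohort, config$task,
                    include_passive = config$stages[["passive"]]))
  write_dataset(dataset, config$output_dir)
  counts$trials <- nrow(dataset$trials)
  counts$samples <- nrow(dataset$samples)
  counts$participants <- nrow(dataset$questionnaires)
  if (!is.null(dataset$passive)) counts$passive <- nrow(dataset$passive)

  traj <- run_stage("observe",
    trajectory_stage(dataset, config$task, config$trajectories))
  traj_df <- do.call(rbind, lapply(names(traj), function(id) {
    do.call(rbind, lapply(seq_along(traj[[id]]), function(t) {
      v <- traj[[id]][[t]]
      data.frame(participant_id = id, trial_id = t,
                 dot_index = seq_along(v), ee_px = v,
                 stringsAsFactors = FALSE)
    }))
  }))
  write_table(traj_df, file.path(config$output_dir, "ee_trajectories.csv"))
  counts$ee_trajectories <- nrow(traj_df)

  fits <- NULL
  if (config$stages[["efficiency"]]) {
    fits <- run_stage("efficiency",
      lapply(traj, fit_extraction_rate))
    eff <- data.frame(
      participant_id = names(fits),
      alpha = vapply(fits, `[[`, numeric(1), "alpha"),
      ee_inf = vapply(fits, `[[`, numeric(1), "ee_inf"),
      baseline = vapply(fits, `[[`, numeric(1), "baseline"),
      sse = vapply(fits, `[[`, numeric(1), "sse"),
      row.names = NULL, stringsAsFactors = FALSE)
    write_table(eff, file.path(config$output_dir, "efficiency.csv"))
    counts$efficiency <- nrow(eff)
  }

  deviations <- NULL
  if (config$stages[["optimality"]] && !is.null(fits)) {
    deviations <- run_stage("optimality",
      deviation_from_optimal(dataset$trials, fits, config$task))
    write_table(deviations, file.path(config$output_dir, "optimality.csv"))
    counts$optimality <- nrow(deviations)
  }

  metrics <- NULL
  if (config$stages[["metrics"]]) {
    metrics <- run_stage("metrics",
      behavioural_summary(dataset$trials, dataset$samples, fits = fits,
                          trajectories = traj, deviations = deviations,
                          groups = dataset$questionnaires))
    write_table(metrics, file.path(config$output_dir, "metrics.csv"))
    counts$metrics <- nrow(metrics)
  }

  if (config$stages[["report"]] && !is.null(metrics)) {
    stats <- run_stage("report", {
      qn <- dataset$questionnaires
      ab <- affective_burden(qn$bdi, qn$hads_anx)
      m <- merge(metrics, data.frame(participant_id = qn$participant_id,
                                     burden = ab$scores, age = qn$age,
                                     ace_iii = qn$ace_iii),
                 by = "participant_id")
      contrasts <- lapply(c("mean_samples", "mean_ISI", "alpha", "deviation"),
                          function(v) {
        ct <- permutation_group_contrast(m[[v]], m$group)
        list(measure = v, mean_difference = ct$mean_difference,
             p_value = ct$p_value)
      })
      sci <- m[m$group == "SCI", ]
      cors <- lapply(c("mean_ISI", "deviation"), function(v) {
        if (nrow(sci) < 5) {  # need n >= covariates + 3
          return(list(measure = v, rho = NA, p_value = NA, n = nrow(sci)))
        }
        ps <- partial_spearman(sci$burden, sci[[v]],
                               cbind(sci$age, sci$ace_iii))
        list(measure = v, rho = ps$rho, p_value = ps$p_value, n = ps$n)
      })
      list(pc1_variance_pct = ab$variance_explained,
           group_contrasts = contrasts,
           burden_correlations_sci = cors,
           bonferroni_threshold = bonferroni_threshold(length(cors)))
    })
    report$stats <- stats
    jsonlite::write_json(
      c(report["seed"], report["config_hash"], stats),
      file.path(config$output_dir, "stats_report.json"),
      auto_unbox = TRUE, digits = 6, pretty = TRUE)
  }

  report$counts <- counts
  report$output_dir <- config$output_dir
  class(report) <- "cq_run_report"
  report
}

#' @export
print.cq_run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  seed %d, config %s, version %s\n",
              x$seed, x$config_hash, x$package_version))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %d rows\n", nm, x$counts[[nm]]))
  }
  cat("  outputs in", x$output_dir, "\n")
  invisible(x)
}
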