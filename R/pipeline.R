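## Orchestration: one call (or CLI invocation) runs
## generate -> extract -> fit -> evaluate -> interpret and writes a
## reproducible, timestamp-free report bundle.

#' Assemble a pipeline run configuration
#'
#' @param cohort named list of [cohort_config()] arguments (without `seed`).
#' @param windows feature window lengths in days.
#' @param min_coverage,max_missing feature-extraction thresholds.
#' @param alpha regularization for LASSO/l2,1 fits (scalar, or a grid tuned
#'   by inner validation).
#' @param msvr_C,msvr_lambda m-SVR hyperparameters.
#' @param algorithms algorithms to evaluate (see [run_protocol()]).
#' @param extra_schemes additional evaluation schemes to run besides each
#'   algorithm's prescribed one (only `"chronological"` is valid for all).
#' @param symptoms symptom subset (default all ten).
#' @param bootstrap_n bootstrap resamples for report CIs.
#' @param seed single global seed; every stage derives its own stream from
#'   it.
#' @return a `run_config` (serializable with [save_config()]).
#' @export
run_config <- function(cohort = list(),
                       windows = c(2, 4, 6, 8, 10, 12, 14),
                       min_coverage = 0.7, max_missing = 0.5,
                       alpha = 0.05, msvr_C = 10, msvr_lambda = 4,
                       algorithms = c("stl", "mtl_patients"),
                       extra_schemes = character(0),
                       symptoms = NULL,
                       bootstrap_n = 500,
                       seed = 1) {
  structure(list(
    cohort = cohort,
    features = list(windows = as.numeric(windows),
                    min_coverage = as.numeric(min_coverage),
                    max_missing = as.numeric(max_missing)),
    models = list(alpha = as.numeric(alpha), msvr_C = as.numeric(msvr_C),
                  msvr_lambda = as.numeric(msvr_lambda)),
    evaluation = list(algorithms = as.character(algorithms),
                      extra_schemes = as.character(extra_schemes),
                      bootstrap_n = as.numeric(bootstrap_n)),
    symptoms = symptoms,
    seed = as.numeric(seed)
  ), class = "run_config")
}

#' Save / load a run configuration (JSON round-trip)
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `save_config` returns `path` invisibly; `load_config` the
#'   restored `run_config` (identical to the saved one).
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  ## JSON has no integer/double or empty-vector distinctions; restore the
  ## canonical types run_config() produces
  num <- function(x) if (is.numeric(x)) as.numeric(x) else x
  chr <- function(x) if (length(x)) as.character(unlist(x)) else character(0)
  obj$cohort <- lapply(obj$cohort, num)
  obj$features <- lapply(obj$features, num)
  obj$models <- lapply(obj$models, num)
  obj$evaluation$algorithms <- chr(obj$evaluation$algorithms)
  obj$evaluation$extra_schemes <- chr(obj$evaluation$extra_schemes)
  obj$evaluation$bootstrap_n <- as.numeric(obj$evaluation$bootstrap_n)
  if (!is.null(obj$symptoms)) obj$symptoms <- chr(obj$symptoms)
  obj$seed <- as.numeric(obj$seed)
  structure(obj, class = "run_config")
}

#' Read a cohort from a manifest
#'
#' Validates schemas while loading: unparseable timestamps and EMA scores
#' outside 0-3 are itemized rejections; unsorted timestamps are accepted,
#' sorted, and noted in the returned `log`.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_cohort()] (or any same-schema manifest).
#' @return a `rhythm_cohort` (without generator ground truth) with a `log`
#'   of non-fatal notes.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  dir <- dirname(manifest_path)
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  problems <- character(0)
  notes <- character(0)
  items <- unlist(man$ema_items)
  patients <- lapply(man$patients, function(entry) {
    streams <- lapply(names(entry$streams), function(m) {
      f <- file.path(dir, entry$streams[[m]])
      if (!file.exists(f)) {
        problems <<- c(problems, paste("missing file:", f))
        return(NULL)
      }
      df <- utils::read.csv(f, stringsAsFactors = FALSE)
      ts <- as.POSIXct(df$timestamp, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                      "%Y-%m-%d %H:%M:%OS"))
      if (anyNA(ts) && nrow(df) > 0L) {
        problems <<- c(problems,
                       sprintf("%s: unparseable timestamp at row %d", f,
                               which(is.na(ts))[1L]))
        return(NULL)
      }
      df$timestamp <- ts
      if (is.unsorted(ts)) {
        notes <<- c(notes, sprintf("%s: timestamps unsorted; sorted", f))
        df <- df[order(ts), , drop = FALSE]
      }
      df
    })
    names(streams) <- names(entry$streams)
    ef <- file.path(dir, entry$ema)
    ema <- utils::read.csv(ef, stringsAsFactors = FALSE)
    score_cols <- setdiff(names(ema), "date")
    for (cl in score_cols) {
      bad <- which(!(ema[[cl]] %in% 0:3))
      if (length(bad)) {
        problems <<- c(problems,
                       sprintf("%s: EMA item '%s' out of 0-3 range at row %d",
                               ef, cl, bad[1L]))
      }
    }
    ema$date <- as.Date(ema$date)
    list(id = entry$id, streams = streams, ema = ema)
  })
  if (length(problems)) {
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(list(config = NULL, patients = unname(patients),
                 ground_truth = NULL, log = notes),
            class = "rhythm_cohort")
}

#' Bin a patient's raw streams to hourly series
#'
#' @param patient one element of a cohort's `patients` list.
#' @param modalities modality subset (default all).
#' @param span optional `c(start, end)` `POSIXct`; defaults to the union of
#'   the patient's stream extents, widened to whole days.
#' @return named list of [hourly_series].
#' @export
patient_series <- function(patient, modalities = names(patient$streams),
                           span = NULL) {
  if (is.null(span)) {
    ts <- do.call(c, lapply(patient$streams[modalities], function(s) {
      range(as.POSIXct(s$timestamp, tz = "UTC"))
    }))
    t0 <- trunc(min(ts), units = "days")
    t1 <- trunc(max(ts) + 86400, units = "days")
    span <- c(t0, t1)
  }
  out <- lapply(modalities, function(m) {
    kind <- if (m %in% EVENT_MODALITIES) "event" else "continuous"
    bin_hourly(patient$streams[[m]], kind = kind,
               start = span[1L], end = span[2L])
  })
  stats::setNames(out, modalities)
}

#' Extract feature matrices for a whole cohort
#'
#' @param cohort a `rhythm_cohort`.
#' @param windows window lengths in days.
#' @param modalities modality subset (default all in the cohort).
#' @param min_coverage,max_missing see [build_feature_matrix()].
#' @return named list per patient of [build_feature_matrix()] results.
#' @export
cohort_features <- function(cohort, windows = c(2, 4, 6, 8, 10, 12, 14),
                            modalities = NULL, min_coverage = 0.7,
                            max_missing = 0.5) {
  stopifnot(inherits(cohort, "rhythm_cohort"))
  out <- lapply(cohort$patients, function(p) {
    mods <- modalities %||% names(p$streams)
    series <- patient_series(p, mods)
    build_feature_matrix(series, p$ema, windows = windows,
                         min_coverage = min_coverage,
                         max_missing = max_missing)
  })
  stats::setNames(out, vapply(cohort$patients, `[[`, character(1), "id"))
}

#' Run the full pipeline
#'
#' generate -> write/read cohort -> extract features -> fit & evaluate ->
#' interpret, writing a deterministic report bundle: cohort CSVs, feature
#' matrices, an evaluation CSV + JSON summary, factor contributions,
#' subtype report, fitted-weight JSONs, and a manifest.  Identical
#' config + seed give a bit-identical evaluation CSV.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results and file
#'   paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, secs = proc.time()[["elapsed"]] - t0)
  }
  times <- list()

  ## 1. generate + write + read back (validating I/O round trip)
  st <- t_stage({
    cc <- do.call(cohort_config,
                  c(config$cohort, list(seed = child_seed(config$seed, 1))))
    cohort <- generate_cohort(cc)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    cohort
  })
  cohort <- st$value; times$generate <- st$secs
  loaded <- read_cohort(file.path(out_dir, "cohort", "manifest.json"))

  ## 2. features
  st <- t_stage({
    fs <- cohort_features(loaded, windows = config$features$windows,
                          min_coverage = config$features$min_coverage,
                          max_missing = config$features$max_missing)
    fdir <- file.path(out_dir, "features")
    dir.create(fdir, showWarnings = FALSE)
    for (pt in names(fs)) {
      df <- data.frame(date = as.character(fs[[pt]]$dates),
                       fs[[pt]]$X, check.names = FALSE)
      utils::write.csv(df, file.path(fdir, paste0(pt, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(fs[[1L]]$catalog,
                         file.path(fdir, "feature_tags.json"),
                         dataframe = "rows", pretty = TRUE)
    fs
  })
  feats <- st$value; times$features <- st$secs

  data <- lapply(feats, function(f) list(X = f$X, Y = f$Y))
  if (!is.null(config$symptoms)) {
    data <- lapply(data, function(d) {
      d$Y <- d$Y[, config$symptoms, drop = FALSE]; d
    })
  }
  ema_table <- do.call(rbind, lapply(names(feats), function(pt) {
    data.frame(patient = pt, date = as.character(feats[[pt]]$dates),
               stringsAsFactors = FALSE)
  }))

  ## 3. evaluate
  st <- t_stage({
    preds <- list()
    for (algorithm in config$evaluation$algorithms) {
      schemes <- c(algo_scheme(algorithm), config$evaluation$extra_schemes)
      for (scheme in schemes) {
        plan <- make_cv_plan(ema_table, scheme,
                             seed = child_seed(config$seed, 2))
        pr <- run_protocol(algorithm, data, plan,
                           alpha = config$models$alpha,
                           msvr_C = config$models$msvr_C,
                           msvr_lambda = config$models$msvr_lambda)
        pr$scheme <- scheme
        preds[[paste(algorithm, scheme)]] <- pr
      }
    }
    do.call(rbind, preds)
  })
  pred_df <- st$value; times$evaluate <- st$secs
  rownames(pred_df) <- NULL
  utils::write.csv(pred_df, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  report <- evaluation_report(pred_df,
                              bootstrap_n = config$evaluation$bootstrap_n,
                              seed = child_seed(config$seed, 3))
  jsonlite::write_json(list(cells = report$cells,
                            algorithms = report$algorithms),
                       file.path(out_dir, "evaluation_summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)

  ## 4. interpret: full-data patient-coupled fits per symptom
  st <- t_stage({
    idir <- file.path(out_dir, "interpretation")
    dir.create(idir, showWarnings = FALSE)
    symptoms <- config$symptoms %||% colnames(data[[1L]]$Y)
    alpha0 <- config$models$alpha[1L]
    contribs <- list()
    subtypes <- list()
    for (sym in symptoms) {
      Xb <- lapply(data, `[[`, "X")
      yb <- lapply(data, function(d) d$Y[, sym])
      fit <- fit_mtl_l21(Xb, yb, alpha0, layout = "patients")
      write_fit_json(fit, file.path(idir, paste0("fit_", sym, ".json")))
      for (dim in c("modality", "periodicity", "window")) {
        fc <- factor_contribution(fit, dim)
        fc$symptom <- sym
        contribs[[paste(sym, dim)]] <- fc
      }
      Wp <- t(fit$W)   # patients x features
      n_pat <- nrow(Wp)
      k_max <- min(10L, n_pat - 1L)
      if (k_max >= 2L) {
        res <- find_subtypes(Wp, k_range = 2:k_max,
                             seed = child_seed(config$seed, 4))
        subtypes[[sym]] <- list(
          symptom = sym, k = res$k,
          silhouette = as.list(res$silhouette),
          labels = as.list(res$labels), flags = res$flags)
      }
    }
    contrib_df <- do.call(rbind, contribs)
    rownames(contrib_df) <- NULL
    utils::write.csv(contrib_df,
                     file.path(idir, "factor_contributions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(subtypes, file.path(idir, "subtypes.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(contributions = contrib_df, subtypes = subtypes)
  })
  interp <- st$value; times$interpret <- st$secs

  ## 5. manifest (deterministic) + wall times (informational, separate)
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, c("manifest.json", "stage_times.csv"))
  save_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("rhythmMTL")),
         seed = config$seed, files = sort(files)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(
    data.frame(stage = names(times), secs = round(unlist(times), 2)),
    file.path(out_dir, "stage_times.csv"), row.names = FALSE)

  invisible(list(cohort = cohort, features = feats, predictions = pred_df,
                 report = report, interpretation = interp,
                 out_dir = out_dir))
}

#' A small demonstration configuration
#'
#' Six patients, 60 days, a reduced window set and algorithm list, sized to
#' run the full pipeline in well under ten minutes on one CPU.
#'
#' @param seed global seed.
#' @return a `run_config`.
#' @export
demo_config <- function(seed = 1) {
  run_config(
    cohort = list(n_patients = 6, n_days = 60,
                  modalities = c("light", "sound", "screen_on_time",
                                 "sms_sent"),
                  windows = c(2, 4), infradian_pool = c(64, 72)),
    windows = c(2, 4),
    alpha = 0.1,
    algorithms = c("stl", "mtl_patients"),
    symptoms = c("depressed", "stressed", "social"),
    bootstrap_n = 200,
    seed = seed
  )
}
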