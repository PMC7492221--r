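## Synthetic CrossCheck-like cohorts with known ground truth: planted
## ultradian/circadian/infradian rhythm structure in every modality, EMA
## labels generated from a sparse linear map of true rhythm features, and
## planted patient subtypes expressed as distinct weight templates
## (environmental-light-dominant vs phone-usage-dominant).

#' EMA item names
#'
#' The ten momentary self-report items, each scored 0 (not at all) to
#' 3 (extremely).
#' @export
ema_items <- function() {
  c("depressed", "seeing_things", "harm", "hearing_voices", "sleep",
    "stressed", "think", "hopeful", "social", "calm")
}

## Modality base levels (continuous: signal units; event: rate per hour).
modality_base_level <- function(mod) {
  base <- c(acceleration = 1.5, light = 3.0, sound = 2.5,
            screen_on_time = 1.2, conversation_length = 1.0,
            location = 1.0, sms_sent = 2.0, sms_read = 2.0,
            calls = 1.5, app_usage = 2.5)
  unname(ifelse(mod %in% names(base), base[mod], 1.5))
}

## Modalities realized as inhomogeneous Poisson event streams (the rest are
## continuous hourly samples).
EVENT_MODALITIES <- c("sms_sent", "sms_read", "calls", "app_usage")

## Subtype weight templates: which pair of modalities carries the planted
## support.  "light" mirrors an environmental-light-dominant phenotype,
## "phone" a phone-usage-dominant one.
template_modalities <- function(template) {
  switch(template,
    light = c("light", "sound"),
    phone = c("screen_on_time", "sms_sent"),
    stop(sprintf("unknown subtype template '%s'", template), call. = FALSE)
  )
}

#' Cohort generator configuration
#'
#' Describes a synthetic cohort: size, sensing modalities, EMA cadence
#' (a report every 2-3 days by default), the planted sparse weight support,
#' label noise, and the subtype mixture.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_days days of sensing per patient (>= 16, so a 14-day feature
#'   window fits at least one EMA).
#' @param ema_cadence_days pool of gaps (days) between successive EMA
#'   prompts; default `c(2, 3)`.
#' @param modalities sensing modalities to emulate.
#' @param n_true_features number of nonzero-weight features per subtype
#'   template (1-8).
#' @param noise_sd Gaussian noise added to EMA scores before discretization.
#' @param subtype_spec list of `list(fraction =, template =)` entries;
#'   fractions must sum to 1; templates are `"light"` or `"phone"`.
#' @param missing_fraction fraction of hours masked in random blocks
#'   (continuous modalities only; default 0.05).
#' @param obs_noise_sd observation noise of continuous samples, as a
#'   fraction of the modality base level.
#' @param windows analysis window lengths (days) the cohort is meant to be
#'   analyzed with; the planted support lives in the two smallest.
#' @param ultradian_pool,infradian_pool candidate planted periods (hours)
#'   for the ultradian (< 20 h) and infradian (> 30 h) components; the
#'   circadian component is always 24 h.  All must be resolvable within the
#'   longest analysis window.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L,
                          n_days = 60L,
                          ema_cadence_days = c(2L, 3L),
                          modalities = c("acceleration", "light", "sound",
                                         "screen_on_time", "sms_sent",
                                         "calls"),
                          n_true_features = 6L,
                          noise_sd = 0.3,
                          subtype_spec = list(
                            list(fraction = 0.3, template = "phone"),
                            list(fraction = 0.7, template = "light")
                          ),
                          missing_fraction = 0.05,
                          obs_noise_sd = 0.2,
                          windows = c(2, 4, 6, 8, 10, 12, 14),
                          ultradian_pool = c(4, 8, 16),
                          infradian_pool = c(64, 72, 128),
                          seed = 1L) {
  if (n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  if (n_days < 16L) stop("n_days must be >= 16", call. = FALSE)
  if (length(windows) < 2L) stop("need at least two analysis windows", call. = FALSE)
  fr <- vapply(subtype_spec, function(s) s$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) {
    stop("subtype fractions must sum to 1", call. = FALSE)
  }
  templates <- vapply(subtype_spec, function(s) s$template, character(1))
  for (tp in templates) {
    mods <- template_modalities(tp)
    if (!all(mods %in% modalities)) {
      stop(sprintf("template '%s' needs modalities %s in `modalities`",
                   tp, paste(mods, collapse = ", ")), call. = FALSE)
    }
  }
  if (n_true_features < 1L || n_true_features > 8L) {
    stop("n_true_features must be in 1..8", call. = FALSE)
  }
  longest_h <- max(windows) * 24
  planted <- c(ultradian_pool, 24, infradian_pool)
  if (any(planted > longest_h)) {
    stop("planted periods exceed the longest analysis window", call. = FALSE)
  }
  if (any(ultradian_pool >= 20) || any(infradian_pool <= 30)) {
    stop("period pools must respect the ultradian (<20 h) / infradian (>30 h) bands",
         call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), n_days = as.integer(n_days),
    ema_cadence_days = as.integer(ema_cadence_days),
    modalities = modalities, n_true_features = as.integer(n_true_features),
    noise_sd = noise_sd, subtype_spec = subtype_spec,
    missing_fraction = missing_fraction, obs_noise_sd = obs_noise_sd,
    windows = sort(as.numeric(windows)),
    ultradian_pool = ultradian_pool, infradian_pool = infradian_pool,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

## Ordered support candidates for a subtype template; truncated to
## n_true_features.  Columns: feature name and base |weight|.
template_support <- function(template, config, planted_periods) {
  mods <- template_modalities(template)
  A <- mods[1L]; B <- mods[2L]
  w1 <- config$windows[1L]; w2 <- config$windows[2L]
  pu <- function(m) paste0(planted_periods[[m]]["ultradian"], "-hour_PSD")
  cand <- data.frame(
    name = c(feature_name(A, "amplitude", w1),
             feature_name(A, pu(A), w1),
             feature_name(B, "amplitude", w1),
             feature_name(B, pu(B), w1),
             feature_name(A, "M10", w2),
             feature_name(B, "M10", w2),
             feature_name(A, "L5", w2),
             feature_name(B, "L5", w2)),
    weight = c(0.45, 0.35, 0.30, 0.25, 0.30, 0.20, 0.20, 0.15),
    stringsAsFactors = FALSE
  )
  cand[seq_len(config$n_true_features), , drop = FALSE]
}

#' Generate a synthetic cohort
#'
#' Continuous modalities are clipped sums of a baseline plus circadian,
#' ultradian and infradian sinusoids whose baseline and amplitudes drift
#' from day to day (log-AR(1) multipliers), plus Gaussian observation noise;
#' event modalities are inhomogeneous Poisson streams whose hourly rate is
#' the same kind of mixture.  EMA item scores are a sparse linear map of the
#' *noise-free* planted rhythm features (per-patient z-scored across that
#' patient's EMA dates), plus Gaussian noise, discretized to 0-3 by
#' round-half-to-even and clipping.
#'
#' @param config a [cohort_config()].
#' @return an object of class `rhythm_cohort`: a list with `config`,
#'   `patients` (each with `id`, `streams` — a named list of
#'   `timestamp`/`value` data frames — and `ema`), and `ground_truth`
#'   (per-patient true weight matrices over the canonical feature space,
#'   subtype labels, planted periods, per-patient rhythm parameters, and the
#'   noise-free planted feature values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  mods <- config$modalities
  n_days <- config$n_days
  n_hours <- n_days * 24L
  start_date <- as.Date("2020-01-01")
  start_time <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  items <- ema_items()

  ## planted periods, common across patients (needed for a common support)
  planted_periods <- lapply(mods, function(m) {
    c(ultradian = sample_one(config$ultradian_pool),
      circadian = 24,
      infradian = sample_one(config$infradian_pool))
  })
  names(planted_periods) <- mods

  ## subtype assignment: contiguous blocks by configured fractions
  fr <- vapply(config$subtype_spec, function(s) s$fraction, numeric(1))
  counts <- diff(c(0L, round(cumsum(fr) * config$n_patients)))
  if (any(counts < 1L)) {
    stop("every subtype must receive at least one patient", call. = FALSE)
  }
  subtype_labels <- rep(seq_along(counts), counts)

  supports <- lapply(config$subtype_spec, function(s) {
    template_support(s$template, config, planted_periods)
  })

  catalog <- feature_catalog(mods, config$windows)
  for (s in supports) {
    missing <- setdiff(s$name, catalog$name)
    if (length(missing)) {
      stop("planted support feature not in catalog: ", missing[1L],
           call. = FALSE)
    }
  }

  ## per-(subtype, symptom, feature) signs, fixed across patients
  sign_mats <- lapply(supports, function(s) {
    matrix(sample(c(-1, 1), nrow(s) * length(items), replace = TRUE),
           nrow = nrow(s), dimnames = list(s$name, items))
  })

  patients <- vector("list", config$n_patients)
  true_weights <- vector("list", config$n_patients)
  true_features <- vector("list", config$n_patients)
  rhythm_params <- vector("list", config$n_patients)

  label_windows <- config$windows[1:2]

  ## ---- pass 1: rhythm parameters, clean signals, EMA dates, and the
  ## noise-free planted feature values ---------------------------------------
  clean_list <- vector("list", config$n_patients)
  dates_list <- vector("list", config$n_patients)
  feats_list <- vector("list", config$n_patients)

  for (p in seq_len(config$n_patients)) {
    st <- subtype_labels[p]
    sup <- supports[[st]]
    sup_mods <- unique(parse_feature_name(sup$name)$modality)

    params <- lapply(mods, function(m) {
      B0 <- modality_base_level(m) * exp(stats::rnorm(1, 0, 0.15))
      list(
        B0 = B0,
        A_c0 = 0.55 * B0 * exp(stats::rnorm(1, 0, 0.15)),
        A_u0 = 0.30 * B0 * exp(stats::rnorm(1, 0, 0.15)),
        A_i0 = 0.15 * B0 * exp(stats::rnorm(1, 0, 0.15)),
        phase_c = stats::runif(1, 0, 24),
        phase_u = stats::runif(1, 0, 2 * pi),
        phase_i = stats::runif(1, 0, 2 * pi),
        periods = planted_periods[[m]],
        drift_B = ar1_series(n_days, rho = 0.6),
        drift_Ac = ar1_series(n_days, rho = 0.6),
        drift_Au = ar1_series(n_days, rho = 0.6)
      )
    })
    names(params) <- mods

    clean <- lapply(mods, function(m) {
      hourly_series(clean_profile(params[[m]], n_hours), start = start_time)
    })
    names(clean) <- mods

    ## EMA dates: first report once the longest window fits, then every
    ## 2-3 days (the configured cadence)
    wmax <- max(config$windows)
    offs <- integer(0)
    o <- as.integer(wmax)
    while (o <= n_days) {
      offs <- c(offs, o)
      o <- o + sample_one(config$ema_cadence_days)
    }
    dates <- start_date + offs

    clean_list[[p]] <- clean
    dates_list[[p]] <- dates
    feats_list[[p]] <- clean_support_features(clean[sup_mods], dates,
                                              sup$name, label_windows)
    rhythm_params[[p]] <- params
  }

  ## ---- label standardization: per support column, across all EMA rows of
  ## the patients sharing that subtype (keeps the pooled regression of EMA
  ## on features well-specified) ---------------------------------------------
  z_stats <- lapply(seq_along(supports), function(st) {
    rows <- do.call(rbind, feats_list[subtype_labels == st])
    list(mu = colMeans(rows),
         sd = pmax(apply(rows, 2L, stats::sd), 1e-12))
  })

  ## ---- pass 2: labels and realized sensor streams -------------------------
  for (p in seq_len(config$n_patients)) {
    st <- subtype_labels[p]
    sup <- supports[[st]]
    clean <- clean_list[[p]]
    dates <- dates_list[[p]]
    feats <- feats_list[[p]]

    z <- sweep(sweep(feats, 2L, z_stats[[st]]$mu), 2L, z_stats[[st]]$sd, "/")
    W <- matrix(0, nrow = nrow(catalog), ncol = length(items),
                dimnames = list(catalog$name, items))
    jitter <- exp(stats::rnorm(nrow(sup), 0, 0.1))
    W[sup$name, ] <- (sup$weight * jitter) * sign_mats[[st]]
    lin <- z %*% W[sup$name, , drop = FALSE]
    noise <- matrix(stats::rnorm(length(lin), 0, config$noise_sd),
                    nrow = nrow(lin))
    scores <- pmin(pmax(round(1.5 + lin + noise), 0), 3)
    ema <- data.frame(date = dates, check.names = FALSE)
    ema[items] <- as.data.frame(scores)

    streams <- lapply(mods, function(m) {
      cp <- clean[[m]]$values
      if (m %in% EVENT_MODALITIES) {
        realize_event_stream(cp, start_time)
      } else {
        realize_continuous_stream(cp, start_time,
                                  sd = config$obs_noise_sd *
                                    modality_base_level(m),
                                  missing_fraction = config$missing_fraction)
      }
    })
    names(streams) <- mods

    patients[[p]] <- list(id = sprintf("P%03d", p), streams = streams,
                          ema = ema)
    true_weights[[p]] <- W
    true_features[[p]] <- list(raw = feats, z = z)
  }

  structure(list(
    config = config,
    patients = patients,
    ground_truth = list(
      true_weights = true_weights,
      subtype_labels = subtype_labels,
      supports = lapply(supports, `[[`, "name"),
      planted_periods = planted_periods,
      rhythm_params = rhythm_params,
      true_features = true_features,
      ema_items = items
    )
  ), class = "rhythm_cohort")
}

## deterministic single draw from a pool (sample() would treat a scalar pool
## as 1:n)
sample_one <- function(pool) {
  if (length(pool) == 1L) return(pool)
  pool[sample.int(length(pool), 1L)]
}

## stationary AR(1) with unit marginal variance
ar1_series <- function(n, rho) {
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1L] <- e[1L]
  s <- sqrt(1 - rho^2)
  for (i in seq_len(n - 1L)) x[i + 1L] <- rho * x[i] + s * e[i + 1L]
  x
}

## deterministic hourly signal: drifting baseline + circadian + ultradian +
## infradian components, clipped at zero
clean_profile <- function(par, n_hours) {
  t <- seq_len(n_hours) - 1L
  day <- pmin(t %/% 24L + 1L, length(par$drift_B))
  hod <- t %% 24L
  B <- par$B0 * exp(0.25 * par$drift_B[day])
  Ac <- par$A_c0 * exp(0.35 * par$drift_Ac[day])
  Au <- par$A_u0 * exp(0.35 * par$drift_Au[day])
  x <- B +
    Ac * cos(2 * pi * (hod - par$phase_c) / 24) +
    Au * cos(2 * pi * t / par$periods["ultradian"] - par$phase_u) +
    par$A_i0 * cos(2 * pi * t / par$periods["infradian"] - par$phase_i)
  pmax(x, 0)
}

## Noise-free feature values for the planted support only (fast path: only
## the metrics the support needs are evaluated).
clean_support_features <- function(clean_series, dates, support_names,
                                   windows) {
  info <- parse_feature_name(support_names)
  out <- matrix(NA_real_, nrow = length(dates), ncol = length(support_names),
                dimnames = list(as.character(dates), support_names))
  for (i in seq_along(dates)) {
    to <- as.POSIXct(paste(as.Date(dates[i]), "00:00:00"), tz = "UTC")
    for (k in seq_along(support_names)) {
      w <- info$window_days[k]
      win <- slice_hours(clean_series[[info$modality[k]]],
                         to - w * 86400, to)
      met <- info$metric[k]
      out[i, k] <- if (met == "amplitude") {
        ml <- m10_l5(win)
        relative_amplitude(ml["M10"], ml["L5"])
      } else if (met %in% c("M10", "L5")) {
        m10_l5(win)[[met]]
      } else if (grepl("-hour_PSD$", met)) {
        p <- as.numeric(sub("-hour_PSD$", "", met))
        psd_band_power(win)[[met]]
      } else {
        extract_features(stats::setNames(list(win), info$modality[k]),
                         dates[i], w)[[support_names[k]]]
      }
    }
  }
  out
}

## column z-scores robust to zero spread
scale_safe <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  sweep(sweep(m, 2L, mu), 2L, sd, "/")
}

realize_continuous_stream <- function(clean, start_time, sd,
                                      missing_fraction) {
  n <- length(clean)
  vals <- pmax(clean + stats::rnorm(n, 0, sd), 0)
  masked <- mask_blocks(n, missing_fraction)
  keep <- which(!masked)
  data.frame(
    timestamp = start_time + (keep - 1L) * 3600,
    value = vals[keep]
  )
}

realize_event_stream <- function(rate, start_time) {
  counts <- stats::rpois(length(rate), rate)
  total <- sum(counts)
  if (total == 0L) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      value = numeric(0)))
  }
  hour_idx <- rep(seq_along(rate) - 1L, counts)
  offs <- stats::runif(total)
  o <- order(hour_idx + offs)
  data.frame(
    timestamp = start_time + (hour_idx + offs)[o] * 3600,
    value = rep(1, total)
  )
}

## mask a target fraction of hours in geometric-length blocks (~4 h mean)
mask_blocks <- function(n, fraction) {
  masked <- rep(FALSE, n)
  if (fraction <= 0) return(masked)
  target <- round(fraction * n)
  guard <- 0L
  while (sum(masked) < target && guard < 10L * n) {
    guard <- guard + 1L
    start <- sample.int(n, 1L)
    len <- min(1L + stats::rgeom(1L, 1 / 4), 6L)
    masked[start:min(start + len - 1L, n)] <- TRUE
  }
  masked
}

#' Generate an inhomogeneous Poisson event stream
#'
#' Draws Poisson counts per hour with the given rate profile and expands
#' them to timestamps uniform within each hour.
#'
#' @param rate_profile an [hourly_series] or non-negative numeric vector of
#'   hourly rates.
#' @param seed integer seed; identical seeds give identical streams.
#' @return data frame with sorted `timestamp` and `value` (= 1) columns.
#' @export
generate_event_stream <- function(rate_profile, seed = 1L) {
  rate <- as_hourly_values(rate_profile)
  if (anyNA(rate) || any(rate < 0)) {
    stop("rate profile must be non-negative everywhere", call. = FALSE)
  }
  start <- if (inherits(rate_profile, "hourly_series")) {
    rate_profile$start
  } else {
    as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  }
  with_seed(seed, realize_event_stream(rate, start))
}

#' Write a cohort to disk
#'
#' One `timestamp,value` CSV per (patient, modality) with ISO-8601 UTC
#' timestamps, one EMA CSV per patient, a `ground_truth.json`, and a
#' `manifest.json` listing all files.
#'
#' @param cohort a `rhythm_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rhythm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(patients = list(), modalities = cohort$config$modalities,
                   ema_items = ema_items())
  for (p in cohort$patients) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    entry <- list(id = p$id, streams = list(), ema = NULL)
    for (m in names(p$streams)) {
      f <- file.path(pdir, paste0(m, ".csv"))
      df <- p$streams[[m]]
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
      entry$streams[[m]] <- file.path(p$id, paste0(m, ".csv"))
    }
    f <- file.path(pdir, "ema.csv")
    utils::write.csv(p$ema, f, row.names = FALSE, quote = FALSE)
    entry$ema <- file.path(p$id, "ema.csv")
    manifest$patients[[p$id]] <- entry
  }
  gt <- cohort$ground_truth
  gt_json <- list(
    subtype_labels = gt$subtype_labels,
    supports = gt$supports,
    planted_periods = gt$planted_periods,
    ema_items = gt$ema_items,
    true_weights = lapply(gt$true_weights, function(W) {
      nz <- which(rowSums(abs(W)) > 0)
      list(features = rownames(W)[nz],
           weights = unname(as.data.frame(W[nz, , drop = FALSE])))
    })
  )
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
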