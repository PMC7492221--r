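## Training/evaluation protocols and paired statistical comparisons.
##
## Protocols (algorithm -> prescribed cross-validation):
##   A msvr_linear        personalized, fivefold
##   B msvr_rbf           personalized, fivefold
##   C mtl_patients       semi leave-one-subject-out
##   D mtl_symptoms       personalized, fivefold
##   E mtl_symptoms_gen   generalized, leave-one-subject-out
##   F stl                personalized, fivefold
##   G stl_gen            generalized, leave-one-subject-out
## Every algorithm additionally supports the chronological 80/20 split
## (applied per patient).

ALGORITHMS <- c(A = "msvr_linear", B = "msvr_rbf", C = "mtl_patients",
                D = "mtl_symptoms", E = "mtl_symptoms_gen", F = "stl",
                G = "stl_gen")

algo_scheme <- function(algorithm) {
  switch(algorithm,
    msvr_linear = , msvr_rbf = , mtl_symptoms = , stl = "fivefold",
    mtl_patients = "semi_loso",
    mtl_symptoms_gen = , stl_gen = "loso",
    stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
}

#' Build a cross-validation plan
#'
#' @param ema_table data frame with `patient` and `date` columns, one row
#'   per EMA record.
#' @param scheme `"fivefold"` (per-patient random partition),
#'   `"semi_loso"` (per-patient folds, to be combined with the other
#'   patients' full data at training time), `"loso"` (fold = patient), or
#'   `"chronological"` (per patient: first 80% train, latest 20% test).
#' @param seed fold-assignment seed.
#' @param n_folds folds for the fivefold/semi-LOSO schemes (default 5).
#' @param train_frac training fraction for the chronological scheme.
#' @return a `cv_plan`: the input table with a `fold` column plus scheme
#'   metadata.
#' @export
make_cv_plan <- function(ema_table, scheme = c("fivefold", "semi_loso",
                                               "loso", "chronological"),
                         seed = 1L, n_folds = 5L, train_frac = 0.8) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("patient", "date") %in% names(ema_table)))
  tab <- ema_table[order(ema_table$patient, as.Date(ema_table$date)), ,
                   drop = FALSE]
  tab$row <- stats::ave(seq_len(nrow(tab)), tab$patient,
                        FUN = seq_along)
  patients <- unique(tab$patient)
  counts <- table(tab$patient)

  if (scheme %in% c("fivefold", "semi_loso")) {
    too_few <- names(counts)[counts < n_folds]
    if (length(too_few)) {
      stop("patients with fewer than ", n_folds, " EMA rows: ",
           paste(too_few, collapse = ", "), call. = FALSE)
    }
    tab$fold <- NA_integer_
    for (i in seq_along(patients)) {
      idx <- which(tab$patient == patients[i])
      tab$fold[idx] <- with_seed(child_seed(seed, i),
                                 sample(rep_len(seq_len(n_folds),
                                                length(idx))))
    }
  } else if (scheme == "loso") {
    tab$fold <- match(tab$patient, patients)
  } else {
    tab$fold <- NA_character_
    for (pt in patients) {
      idx <- which(tab$patient == pt)
      n_train <- floor(train_frac * length(idx))
      tab$fold[idx] <- c(rep("train", n_train),
                         rep("test", length(idx) - n_train))
    }
  }
  structure(list(table = tab, scheme = scheme, seed = seed,
                 n_folds = n_folds, train_frac = train_frac),
            class = "cv_plan")
}

#' Run one training/evaluation protocol
#'
#' Fits the requested algorithm under the plan and returns exactly one
#' out-of-fold prediction per (EMA row, symptom).
#'
#' @param algorithm one of `"msvr_linear"`, `"msvr_rbf"`, `"mtl_patients"`,
#'   `"mtl_symptoms"`, `"mtl_symptoms_gen"`, `"stl"`, `"stl_gen"` (or the
#'   protocol letters A-G).
#' @param data named list, one entry per patient, each `list(X = feature
#'   matrix, Y = label matrix)` with shared column spaces.
#' @param plan a [make_cv_plan()] plan; its scheme must match the
#'   algorithm's prescription (the chronological scheme is accepted for
#'   all).
#' @param alpha regularization for the LASSO/l2,1 fits: a scalar, or a grid
#'   to be tuned by inner validation.
#' @param symptoms symptom (label column) subset; default all.
#' @param msvr_C,msvr_lambda,msvr_sigma m-SVR hyperparameters.
#' @param clip clip predictions to the 0-3 scale (default `FALSE`).
#' @return long data frame: `algorithm`, `patient`, `symptom`, `row`,
#'   `date`, `fold`, `y_true`, `y_pred`.
#' @export
run_protocol <- function(algorithm, data, plan, alpha = 0.05,
                         symptoms = NULL, msvr_C = 10, msvr_lambda = 4,
                         msvr_sigma = NULL, clip = FALSE) {
  if (algorithm %in% names(ALGORITHMS)) algorithm <- ALGORITHMS[[algorithm]]
  stopifnot(inherits(plan, "cv_plan"))
  required <- algo_scheme(algorithm)
  if (!plan$scheme %in% c(required, "chronological")) {
    stop(sprintf("algorithm '%s' requires scheme '%s' (or chronological), got '%s'",
                 algorithm, required, plan$scheme), call. = FALSE)
  }
  patients <- names(data)
  if (is.null(symptoms)) symptoms <- colnames(data[[1L]]$Y)
  tab <- plan$table

  rows_of <- function(pt) tab[tab$patient == pt, , drop = FALSE]
  preds <- list()
  emit <- function(pt, sym, rows, dates, fold, y_true, y_pred) {
    if (clip) y_pred <- pmin(pmax(y_pred, 0), 3)
    preds[[length(preds) + 1L]] <<- data.frame(
      algorithm = algorithm, patient = pt, symptom = sym, row = rows,
      date = as.character(dates), fold = as.character(fold),
      y_true = y_true, y_pred = y_pred, stringsAsFactors = FALSE)
  }

  fit_personalized <- function(pt, tr_idx, te_idx, fold_id) {
    X <- data[[pt]]$X; Y <- data[[pt]]$Y[, symptoms, drop = FALSE]
    ptab <- rows_of(pt)
    Xtr <- X[tr_idx, , drop = FALSE]; Xte <- X[te_idx, , drop = FALSE]
    if (algorithm == "stl") {
      for (sym in symptoms) {
        a <- tune_or_fixed(alpha, Xtr, Y[tr_idx, sym, drop = FALSE],
                           function(Xt, Yt, al) {
                             fit_lasso_stl(Xt, as.numeric(Yt), al)
                           })
        fit <- fit_lasso_stl(Xtr, Y[tr_idx, sym], a)
        emit(pt, sym, ptab$row[te_idx], ptab$date[te_idx], fold_id,
             Y[te_idx, sym], predict(fit, Xte))
      }
    } else if (algorithm == "mtl_symptoms") {
      a <- tune_or_fixed(alpha, Xtr, Y[tr_idx, , drop = FALSE],
                         function(Xt, Yt, al) {
                           fit_mtl_l21(Xt, Yt, al, layout = "symptoms")
                         })
      fit <- fit_mtl_l21(Xtr, Y[tr_idx, , drop = FALSE], a,
                         layout = "symptoms")
      P <- predict(fit, Xte)
      for (sym in symptoms) {
        emit(pt, sym, ptab$row[te_idx], ptab$date[te_idx], fold_id,
             Y[te_idx, sym], P[, sym])
      }
    } else {  # msvr
      kern <- if (algorithm == "msvr_rbf") "rbf" else "linear"
      fit <- fit_msvr(Xtr, Y[tr_idx, , drop = FALSE], kernel = kern,
                      C = msvr_C, lambda = msvr_lambda, sigma = msvr_sigma)
      P <- predict(fit, Xte)
      for (sym in symptoms) {
        emit(pt, sym, ptab$row[te_idx], ptab$date[te_idx], fold_id,
             Y[te_idx, sym], P[, sym])
      }
    }
  }

  if (algorithm %in% c("stl", "mtl_symptoms", "msvr_linear", "msvr_rbf")) {
    for (pt in patients) {
      ptab <- rows_of(pt)
      fold_ids <- if (plan$scheme == "chronological") "test"
                  else sort(unique(ptab$fold))
      for (f in fold_ids) {
        te_idx <- which(ptab$fold == f)
        tr_idx <- which(ptab$fold != f)
        if (length(tr_idx) < 2L) next
        fit_personalized(pt, tr_idx, te_idx, f)
      }
    }
  } else if (algorithm %in% c("stl_gen", "mtl_symptoms_gen")) {
    for (pt in patients) {
      ptab <- rows_of(pt)
      if (plan$scheme == "chronological") {
        tr <- lapply(patients, function(q) {
          qt <- rows_of(q); which(qt$fold == "train")
        })
        names(tr) <- patients
        te_idx <- which(ptab$fold == "test")
      } else {
        tr <- lapply(setdiff(patients, pt), function(q) {
          seq_len(nrow(data[[q]]$X))
        })
        names(tr) <- setdiff(patients, pt)
        te_idx <- seq_len(nrow(ptab))
      }
      Xtr <- do.call(rbind, lapply(names(tr), function(q) {
        data[[q]]$X[tr[[q]], , drop = FALSE]
      }))
      Ytr <- do.call(rbind, lapply(names(tr), function(q) {
        data[[q]]$Y[tr[[q]], symptoms, drop = FALSE]
      }))
      if (length(te_idx) == 0L) next
      Xte <- data[[pt]]$X[te_idx, , drop = FALSE]
      if (algorithm == "stl_gen") {
        for (sym in symptoms) {
          a <- tune_or_fixed(alpha, Xtr, Ytr[, sym, drop = FALSE],
                             function(Xt, Yt, al) {
                               fit_lasso_stl(Xt, as.numeric(Yt), al)
                             })
          fit <- fit_lasso_stl(Xtr, Ytr[, sym], a)
          emit(pt, sym, rows_of(pt)$row[te_idx], rows_of(pt)$date[te_idx],
               pt, data[[pt]]$Y[te_idx, sym], predict(fit, Xte))
        }
      } else {
        a <- tune_or_fixed(alpha, Xtr, Ytr,
                           function(Xt, Yt, al) {
                             fit_mtl_l21(Xt, Yt, al, layout = "symptoms")
                           })
        fit <- fit_mtl_l21(Xtr, Ytr, a, layout = "symptoms")
        P <- predict(fit, Xte)
        for (sym in symptoms) {
          emit(pt, sym, rows_of(pt)$row[te_idx], rows_of(pt)$date[te_idx],
               pt, data[[pt]]$Y[te_idx, sym], P[, sym])
        }
      }
    }
  } else {  # mtl_patients
    for (sym in symptoms) {
      if (plan$scheme == "chronological") {
        Xb <- lapply(patients, function(q) {
          qt <- rows_of(q)
          data[[q]]$X[which(qt$fold == "train"), , drop = FALSE]
        })
        yb <- lapply(patients, function(q) {
          qt <- rows_of(q)
          data[[q]]$Y[which(qt$fold == "train"), sym]
        })
        names(Xb) <- names(yb) <- patients
        a <- tune_alpha_mtl_patients(alpha, Xb, yb)
        fit <- fit_mtl_l21(Xb, yb, a, layout = "patients")
        for (pt in patients) {
          ptab <- rows_of(pt)
          te_idx <- which(ptab$fold == "test")
          if (!length(te_idx)) next
          Xte <- data[[pt]]$X[te_idx, , drop = FALSE]
          emit(pt, sym, ptab$row[te_idx], ptab$date[te_idx], "test",
               data[[pt]]$Y[te_idx, sym], predict(fit, Xte, task = pt))
        }
      } else {
        for (pt in patients) {
          ptab <- rows_of(pt)
          for (f in sort(unique(ptab$fold))) {
            te_idx <- which(ptab$fold == f)
            Xb <- lapply(patients, function(q) {
              if (q == pt) {
                data[[q]]$X[which(ptab$fold != f), , drop = FALSE]
              } else {
                data[[q]]$X
              }
            })
            yb <- lapply(patients, function(q) {
              if (q == pt) {
                data[[q]]$Y[which(ptab$fold != f), sym]
              } else {
                data[[q]]$Y[, sym]
              }
            })
            names(Xb) <- names(yb) <- patients
            a <- tune_alpha_mtl_patients(alpha, Xb, yb)
            fit <- fit_mtl_l21(Xb, yb, a, layout = "patients")
            Xte <- data[[pt]]$X[te_idx, , drop = FALSE]
            emit(pt, sym, ptab$row[te_idx], ptab$date[te_idx], f,
                 data[[pt]]$Y[te_idx, sym], predict(fit, Xte, task = pt))
          }
        }
      }
    }
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  out
}

## scalar alpha -> use as is; grid -> inner 3-fold CV via select_alpha
tune_or_fixed <- function(alpha, X, Y, trainer) {
  if (length(alpha) == 1L) return(alpha)
  select_alpha(trainer, X, Y, grid = alpha)$alpha
}

## grid tuning for the patients layout: chronological 80/20 validation split
## within every task's training rows (cheap: one fit per grid value)
tune_alpha_mtl_patients <- function(alpha, Xb, yb) {
  if (length(alpha) == 1L) return(alpha)
  tr <- lapply(Xb, function(x) seq_len(floor(0.8 * nrow(x))))
  va <- Map(function(x, t) setdiff(seq_len(nrow(x)), t), Xb, tr)
  Xtr <- Map(function(x, t) x[t, , drop = FALSE], Xb, tr)
  ytr <- Map(function(y, t) y[t], yb, tr)
  err <- vapply(alpha, function(al) {
    fit <- fit_mtl_l21(Xtr, ytr, al, layout = "patients")
    pr <- unlist(Map(function(q) {
      if (!length(va[[q]])) return(numeric(0))
      predict(fit, Xb[[q]][va[[q]], , drop = FALSE], task = q)
    }, names(Xb)))
    tru <- unlist(Map(function(q) yb[[q]][va[[q]]], names(Xb)))
    rmse(pr, tru)
  }, numeric(1))
  ord <- order(alpha, decreasing = TRUE)
  alpha[ord][which.min(err[ord])]
}

#' Root-mean-square error
#'
#' @param pred,truth equal-length numeric vectors (length >= 1).
#' @return non-negative scalar.
#' @seealso [rmse_pct()] for the value as a percent of the 0-3 EMA scale.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1L) {
    stop("pred and truth must be equal-length, non-empty", call. = FALSE)
  }
  sqrt(mean((pred - truth)^2))
}

#' RMSE as a percent of the 0-3 EMA scale
#' @param x an RMSE value.
#' @return `x / 3 * 100`.
#' @export
rmse_pct <- function(x) x / 3 * 100

#' Summarize protocol predictions into an evaluation report
#'
#' Per-(algorithm, patient, symptom) RMSE plus per-algorithm mean/median
#' RMSE with nonparametric bootstrap percentile confidence intervals over
#' the (patient, symptom) cells.
#'
#' @param pred_df prediction data frame(s) from [run_protocol()] (row-bind
#'   several algorithms to compare them).
#' @param bootstrap_n bootstrap resamples for the CIs (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return an `evaluation_report`: list with `cells` (long RMSE table) and
#'   `algorithms` (summary with CIs).
#' @export
evaluation_report <- function(pred_df, bootstrap_n = 2000L, conf = 0.95,
                              seed = 1L) {
  key <- interaction(pred_df$algorithm, pred_df$patient, pred_df$symptom,
                     drop = TRUE)
  cells <- do.call(rbind, lapply(split(pred_df, key), function(g) {
    data.frame(algorithm = g$algorithm[1L], patient = g$patient[1L],
               symptom = g$symptom[1L], n = nrow(g),
               rmse = rmse(g$y_pred, g$y_true), stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  cells$rmse_pct <- rmse_pct(cells$rmse)

  alg <- do.call(rbind, lapply(split(cells, cells$algorithm), function(g) {
    boot <- with_seed(seed, {
      vapply(seq_len(bootstrap_n), function(i) {
        mean(g$rmse[sample.int(nrow(g), replace = TRUE)])
      }, numeric(1))
    })
    qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2))
    data.frame(algorithm = g$algorithm[1L], n_cells = nrow(g),
               mean_rmse = mean(g$rmse), median_rmse = stats::median(g$rmse),
               ci_lo = qs[1L], ci_hi = qs[2L], stringsAsFactors = FALSE)
  }))
  rownames(alg) <- NULL
  structure(list(cells = cells, algorithms = alg, conf = conf),
            class = "evaluation_report")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values.  Zero differences are
#' dropped (Wilcoxon's original rule).  The exact null distribution is used
#' for n <= 25 untied pairs; otherwise a normal approximation with
#' continuity and tie corrections.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return list with `statistic` (`V - n(n+1)/4`, antisymmetric under
#'   swapping `a` and `b`), `V`, `p.value`, `n` (non-zero pairs), `method`,
#'   and `undefined` (`TRUE` when all pairs are tied).
#' @export
paired_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired", call. = FALSE)
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, V = NA_real_, p.value = NA_real_,
                n = 0L, method = "undefined", undefined = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- if (V > mu) {
      2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else if (V < mu) {
      2 * stats::psignrank(V, n)
    } else {
      1
    }
    method <- "exact"
  } else {
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24
    if (ties) {
      tt <- table(abs(d))
      sigma2 <- sigma2 - sum(tt^3 - tt) / 48
    }
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = V - mu, V = V, p.value = min(p, 1), n = n,
       method = method, undefined = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (same order), monotone and capped at 1.
#' @export
holm_bonferroni <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(cummax((m - seq_len(m) + 1) * pvals[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
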