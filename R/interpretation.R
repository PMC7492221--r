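## Heterogeneity and subtype layer: ranking features by weight, aggregating
## weights along the modality / periodicity / window dimensions, and
## clustering patients into subtypes from the weight vectors of their
## patient-coupled multi-task models.

## Coerce a fit or raw weights into a features x tasks matrix of weights.
weight_matrix <- function(fit) {
  if (inherits(fit, "stl_fit")) {
    matrix(fit$weights, ncol = 1L,
           dimnames = list(names(fit$weights), "task1"))
  } else if (inherits(fit, "mtl_fit")) {
    fit$W
  } else if (is.matrix(fit)) {
    fit
  } else if (is.numeric(fit) && !is.null(names(fit))) {
    matrix(fit, ncol = 1L, dimnames = list(names(fit), "task1"))
  } else {
    stop("cannot extract named weights from this object", call. = FALSE)
  }
}

#' Rank features by absolute weight
#'
#' The higher the absolute weight, the more predictive the feature.  For
#' multi-task fits a feature's score is the mean absolute weight across
#' tasks.  Ties break lexicographically by name.
#'
#' @param fit a fitted model (`stl_fit`, `mtl_fit`) or named weight
#'   vector/matrix.
#' @param n number of features to return (default all nonzero).
#' @return data frame `name`, `weight` (signed mean across tasks),
#'   `abs_weight`, ordered by decreasing `abs_weight`; zero rows (with
#'   attribute `all_zero = TRUE`) when every weight is zero.
#' @export
rank_features <- function(fit, n = Inf) {
  W <- weight_matrix(fit)
  score <- rowMeans(abs(W))
  signed <- rowMeans(W)
  keep <- score > 0
  if (!any(keep)) {
    out <- data.frame(name = character(0), weight = numeric(0),
                      abs_weight = numeric(0))
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  df <- data.frame(name = rownames(W)[keep], weight = signed[keep],
                   abs_weight = score[keep], stringsAsFactors = FALSE)
  df <- df[order(-df$abs_weight, df$name), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, n)
}

#' Mean aggregated weight (contribution) per factor
#'
#' For each factor of a dimension (modality, periodicity, or window length),
#' the contribution is the mean absolute weight over all features carrying
#' that factor, c_p = (1/n) sum |w_i| — aggregated across tasks for matrix
#' fits.  The means of the positive weights and of the absolute negative
#' weights are also reported separately.
#'
#' @param fit fitted model or named weight vector/matrix over canonical
#'   feature names.
#' @param dimension `"modality"`, `"periodicity"` or `"window"`.
#' @return data frame: `dimension`, `factor`, `c_p`, `mean_positive`,
#'   `mean_negative`, `n_weights`, ordered by decreasing `c_p`.
#' @export
factor_contribution <- function(fit, dimension = c("modality", "periodicity",
                                                   "window")) {
  dimension <- match.arg(dimension)
  W <- weight_matrix(fit)
  info <- parse_feature_name(rownames(W))
  fac <- switch(dimension,
                modality = info$modality,
                periodicity = info$periodicity,
                window = paste0(info$window_days, "-day_window"))
  out <- do.call(rbind, lapply(split(seq_len(nrow(W)), fac), function(idx) {
    w <- as.numeric(W[idx, , drop = FALSE])
    pos <- w[w > 0]
    neg <- w[w < 0]
    data.frame(
      dimension = dimension, factor = fac[idx[1L]],
      c_p = mean(abs(w)),
      mean_positive = if (length(pos)) mean(pos) else 0,
      mean_negative = if (length(neg)) mean(abs(neg)) else 0,
      n_weights = length(w), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$c_p, out$factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean silhouette width of a clustering
#'
#' Euclidean silhouette: for each point, `(b - a) / max(a, b)` where `a` is
#' the mean distance to its own cluster and `b` the smallest mean distance
#' to another cluster; singletons score 0.
#'
#' @param X numeric matrix (points x coordinates).
#' @param labels integer cluster labels, length `nrow(X)`, at least 2
#'   distinct values.
#' @return mean silhouette width, in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  ks <- unique(labels)
  if (length(ks) < 2L) stop("need at least 2 clusters", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1L)
    b <- min(vapply(setdiff(ks, labels[i]), function(k) {
      mean(D[i, labels == k])
    }, numeric(1)))
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

## k-means++ seeding followed by Lloyd iterations; best of `restarts` by
## total within-cluster sum of squares
kmeanspp <- function(X, k, restarts = 10L, seed = 1L, iter_max = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- matrix(NA_real_, k, ncol(X))
      centers[1L, ] <- X[sample.int(n, 1L), ]
      d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
      j <- 2L
      while (j <= k) {
        prob <- d2 / sum(d2)
        if (!all(is.finite(prob)) || sum(d2) <= 0) {
          centers[j, ] <- X[sample.int(n, 1L), ]
        } else {
          centers[j, ] <- X[sample.int(n, 1L, prob = prob), ]
        }
        d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
        j <- j + 1L
      }
      km <- tryCatch(
        stats::kmeans(X, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd"),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  best
}

#' Cluster patients into subtypes from model weight vectors
#'
#' K-Means (k-means++ seeding, 10 restarts, fixed seed) on per-patient
#' absolute weight vectors for every K in `k_range`; the K maximizing the
#' mean Euclidean silhouette is selected (smaller K on ties).  Weight
#' vectors are L2-normalized by default so patients cluster by weight
#' *pattern* rather than magnitude.
#'
#' @param weights patients x features matrix of (signed) model weights, one
#'   row per patient; absolute values are taken internally.
#' @param k_range candidate numbers of clusters (default `2:10`); requires
#'   at least `max(k_range) + 1` patients.
#' @param seed clustering seed.
#' @param normalize L2-normalize the absolute weight vectors (default TRUE).
#' @return a `subtype_result`: `labels` (1..K per patient), `k` (chosen K),
#'   `silhouette` (named vector over scanned K, NA where skipped),
#'   `centroids`, and `flags` for skipped K.  When every K is degenerate
#'   (e.g. all patients identical) `k` is `NA` and no labels are returned.
#' @export
find_subtypes <- function(weights, k_range = 2:10, seed = 1L,
                          normalize = TRUE) {
  V <- abs(as.matrix(weights))
  n <- nrow(V)
  if (n < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 patients", call. = FALSE)
  }
  if (normalize) {
    nr <- sqrt(rowSums(V * V))
    nr[nr < 1e-300] <- 1
    V <- V / nr
  }
  sil <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  flags <- character(0)
  n_distinct <- nrow(unique(V))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (n_distinct < k + 1L) {
      flags <- c(flags, sprintf("K=%d skipped: fewer than %d distinct weight vectors",
                                k, k + 1L))
      next
    }
    km <- kmeanspp(V, k, seed = child_seed(seed, k))
    if (is.null(km) || length(unique(km$cluster)) < 2L) {
      flags <- c(flags, sprintf("K=%d skipped: degenerate clustering", k))
      next
    }
    fits[[i]] <- km
    sil[i] <- silhouette_score(V, km$cluster)
  }
  if (all(is.na(sil))) {
    return(structure(list(labels = NULL, k = NA_integer_, silhouette = sil,
                          centroids = NULL, flags = flags),
                     class = "subtype_result"))
  }
  best <- which.max(replace(sil, is.na(sil), -Inf))
  km <- fits[[best]]
  structure(list(
    labels = stats::setNames(km$cluster, rownames(V)),
    k = k_range[best], silhouette = sil, centroids = km$centers,
    flags = flags
  ), class = "subtype_result")
}

#' Summarize discovered subtypes
#'
#' For each subtype: the top predictive features (mean signed weight within
#' the cluster, ranked by absolute value), the factor contributions along
#' each dimension, and the mean EMA scores.
#'
#' @param result a [find_subtypes()] result with labels.
#' @param weights the patients x features signed weight matrix used for
#'   clustering.
#' @param ema_means optional patients x items matrix of mean EMA scores.
#' @param top_n features per subtype table (default 10).
#' @return list of per-subtype summaries (`n_patients`, `top_features`,
#'   `contributions`, `mean_ema`, `small_cluster` flag for singletons).
#' @export
compare_subtypes <- function(result, weights, ema_means = NULL, top_n = 10L) {
  stopifnot(inherits(result, "subtype_result"))
  if (is.null(result$labels)) stop("no clustering available", call. = FALSE)
  W <- as.matrix(weights)
  lapply(sort(unique(result$labels)), function(k) {
    idx <- which(result$labels == k)
    mw <- colMeans(W[idx, , drop = FALSE])
    list(
      subtype = k,
      n_patients = length(idx),
      small_cluster = length(idx) < 2L,
      top_features = rank_features(stats::setNames(mw, colnames(W)),
                                   n = top_n),
      contributions = lapply(
        stats::setNames(nm = c("modality", "periodicity", "window")),
        function(dim) factor_contribution(t(W[idx, , drop = FALSE]), dim)),
      mean_ema = if (!is.null(ema_means)) {
        colMeans(ema_means[idx, , drop = FALSE])
      }
    )
  })
}
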