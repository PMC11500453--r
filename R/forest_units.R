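#' Bray-Curtis dissimilarity between samples
#'
#' `BC(a, b) = 1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b))`, computed with
#' \pkg{vegan}. A pair of all-zero samples is undefined under the formula and
#' is reported as 0 with a warning.
#'
#' @param X non-negative samples x features matrix.
#' @return symmetric dissimilarity matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(X) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("bray_curtis requires non-negative values")
  D <- as.matrix(suppressWarnings(vegan::vegdist(X, method = "bray")))
  zero <- rowSums(X) == 0
  if (sum(zero) >= 2L) {
    warning("all-zero sample pair(s): dissimilarity defined as 0")
    D[zero, zero] <- 0
  }
  diag(D) <- 0
  D
}

# Affinity propagation (Frey & Dueck message passing) on a similarity matrix
# whose diagonal holds the preference. Returns NULL unless the exemplar set
# is stable for `convits` consecutive iterations.
ap_cluster <- function(S, damping = 0.9, max_iter = 200L, convits = 20L) {
  n <- nrow(S)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; last <- NULL
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last)) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= convits && length(ex) > 0L) {
      assign_to <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
      assign_to[ex] <- ex
      return(list(exemplars = ex, assignment = assign_to, iterations = it))
    }
  }
  NULL
}

#' Cluster the majority-class samples
#'
#' Runs affinity propagation on the negative Bray-Curtis dissimilarity,
#' sweeping damping (0.5, 0.7, 0.9) and preference (median, minimum of the
#' similarities); the first convergent run whose cluster count falls in
#' `[2, ap_clusters]` wins. If no run qualifies, falls back to K-means on the
#' raw features with `k = min(ap_clusters, n)`. Fewer than two samples yield
#' a single cluster without clustering.
#'
#' @param X majority-class samples x features matrix.
#' @param cfg a [microhdf_config()].
#' @param D optional precomputed dissimilarity matrix for `X`.
#' @return list with `assignment` (integer cluster id per row of `X`),
#'   `n_clusters`, and `method` (one of `"affinity_propagation"`,
#'   `"kmeans_fallback"`, `"single"`).
#' @export
cluster_majority <- function(X, cfg = microhdf_config(), D = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L)
    return(list(assignment = rep(1L, n), n_clusters = 1L, method = "single"))
  if (is.null(D)) D <- bray_curtis(X)
  S <- -as.matrix(D)
  off <- S[upper.tri(S) | lower.tri(S)]
  for (damping in c(0.5, 0.7, 0.9)) {
    for (pref in c(stats::median(off), min(off))) {
      Sp <- S; diag(Sp) <- pref
      fit <- ap_cluster(Sp, damping = damping, max_iter = cfg$ap_max_iter)
      if (!is.null(fit)) {
        k <- length(fit$exemplars)
        if (k >= 2L && k <= cfg$ap_clusters) {
          lab <- match(fit$assignment, fit$exemplars)
          return(list(assignment = lab, n_clusters = k,
                      method = "affinity_propagation"))
        }
      }
    }
  }
  k <- min(cfg$ap_clusters, n, nrow(unique(X)))
  km <- stats::kmeans(X, centers = k, nstart = 3L, iter.max = 50L)
  list(assignment = as.integer(km$cluster), n_clusters = k,
       method = "kmeans_fallback")
}

# Largest-remainder apportionment of m draws across cluster sizes, with the
# guarantee that every non-empty cluster contributes at least one sample when
# m >= number of clusters. Never allocates more than a cluster's size.
allocate_quota <- function(sizes, m) {
  k <- length(sizes)
  quota <- m * sizes / sum(sizes)
  alloc <- floor(quota)
  rem <- m - sum(alloc)
  if (rem > 0L) {
    ord <- order(quota - alloc, -sizes, decreasing = TRUE)
    ord <- ord[alloc[ord] < sizes[ord]]
    take <- utils::head(ord, rem)
    alloc[take] <- alloc[take] + 1L
    rem <- m - sum(alloc)
    while (rem > 0L) {  # ties exhausted against capacity; fill greedily
      i <- which.max(sizes - alloc)
      alloc[i] <- alloc[i] + 1L; rem <- rem - 1L
    }
  }
  if (m >= k) {
    for (i in which(alloc == 0L & sizes > 0L)) {
      j <- which.max(alloc)
      if (alloc[j] > 1L) { alloc[j] <- alloc[j] - 1L; alloc[i] <- 1L }
    }
  }
  as.integer(alloc)
}

#' Build class-balanced training subsets
#'
#' Per subset, `m = round(undersample * n_majority)` majority samples are
#' drawn without replacement, allocated across the majority clusters
#' proportionally to cluster size (largest-remainder rounding), and paired
#' with `m` minority samples drawn with replacement (bootstrap). The N
#' subsets differ by seed stream.
#'
#' @param X samples x features matrix.
#' @param y integer 0/1 labels (one per row of `X`).
#' @param clusters result of [cluster_majority()] on the majority rows.
#' @param cfg a [microhdf_config()].
#' @param seed seed for the sampling streams (default from `cfg`).
#' @return list of `n_subsets` sets, each with `idx` (row indices into `X`),
#'   `majority_idx`, `minority_idx`.
#' @export
build_balanced_sets <- function(X, y, clusters, cfg = microhdf_config(),
                                seed = cfg$seed) {
  stopifnot(length(y) == nrow(X))
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  maj_class <- if (counts[["1"]] > counts[["0"]]) 1L else 0L
  maj <- which(y == maj_class); min_ <- which(y != maj_class)
  m <- round_half_up(cfg$undersample * length(maj))
  if (m < 1L) stop("undersampling ratio too small: empty majority subset")
  stopifnot(length(clusters$assignment) == length(maj))
  cl <- clusters$assignment
  cl_ids <- sort(unique(cl))
  sizes <- as.integer(table(factor(cl, levels = cl_ids)))
  alloc <- allocate_quota(sizes, m)
  lapply(seq_len(cfg$n_subsets), function(s) {
    set.seed(child_seed(seed, paste0("subset", s)))
    maj_pick <- unlist(lapply(seq_along(cl_ids), function(ci) {
      pool <- maj[cl == cl_ids[ci]]
      if (alloc[ci] == 0L) return(integer(0))
      pool[sample.int(length(pool), alloc[ci])]
    }), use.names = FALSE)
    min_pick <- min_[sample.int(length(min_), m, replace = TRUE)]
    list(idx = c(maj_pick, min_pick),
         majority_idx = maj_pick, minority_idx = min_pick)
  })
}

# probability forest wrapper; X is a matrix, y integer 0/1
fit_prob_forest <- function(X, y, num_trees, seed, extratrees = FALSE,
                            mtry = NULL) {
  yf <- factor(y, levels = c(0L, 1L))
  if (any(table(yf) == 0L)) stop("single-class training set")
  args <- list(x = as.data.frame(X, check.names = FALSE), y = yf,
               num.trees = num_trees, probability = TRUE,
               importance = "impurity", seed = seed, num.threads = 1L,
               verbose = FALSE)
  if (!is.null(mtry)) args$mtry <- mtry
  if (extratrees) {
    args$splitrule <- "extratrees"; args$num.random.splits <- 1L
    args$replace <- FALSE; args$sample.fraction <- 1
  }
  do.call(ranger::ranger, args)
}

forest_proba <- function(fit, X) {
  p <- stats::predict(fit, data = as.data.frame(X, check.names = FALSE),
                      num.threads = 1L, verbose = FALSE)$predictions
  p <- p[, c("0", "1"), drop = FALSE]
  p <- p / pmax(rowSums(p), .Machine$double.eps)
  colnames(p) <- c("control", "case")
  rownames(p) <- rownames(X)
  p
}

#' Fit a class-rebalancing random forest unit (RF-CUS)
#'
#' Clusters the majority class (affinity propagation on Bray-Curtis, with
#' K-means fallback), builds `n_subsets` class-balanced subsets by stratified
#' undersampling plus minority bootstrap, fits one random forest of
#' `cfg$trees` trees per subset, and aggregates predictions by unweighted
#' averaging of the forests' class-probability votes.
#'
#' @param X samples x features matrix.
#' @param y integer 0/1 labels.
#' @param cfg a [microhdf_config()].
#' @param seed seed for this unit's streams.
#' @return an object of class `rf_cus_unit`.
#' @export
fit_rf_cus <- function(X, y, cfg = microhdf_config(), seed = cfg$seed) {
  X <- as.matrix(X)
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  maj_class <- if (counts[["1"]] > counts[["0"]]) 1L else 0L
  set.seed(child_seed(seed, "cluster"))
  clusters <- cluster_majority(X[y == maj_class, , drop = FALSE], cfg)
  sets <- build_balanced_sets(X, y, clusters, cfg, seed = seed)
  forests <- lapply(seq_along(sets), function(s)
    fit_prob_forest(X[sets[[s]]$idx, , drop = FALSE], y[sets[[s]]$idx],
                    cfg$trees, child_seed(seed, paste0("forest", s))))
  structure(list(forests = forests, clusters = clusters, sets = sets,
                 features = colnames(X), n_forests = length(forests)),
            class = "rf_cus_unit")
}

#' Class-distribution predictions of an RF-CUS unit
#' @param unit a fitted `rf_cus_unit`.
#' @param X new samples x features matrix (same columns as training).
#' @return matrix with columns `control`, `case`; rows sum to 1.
#' @export
rf_cus_proba <- function(unit, X) {
  X <- as.matrix(X)[, unit$features, drop = FALSE]
  p <- Reduce(`+`, lapply(unit$forests, function(f) forest_proba(f, X)))
  p / length(unit$forests)
}

#' LDA effect-size scores for feature ranking
#'
#' LEfSe-style ranking statistic: abundances are scaled to a per-million
#' basis, features are screened with a Kruskal-Wallis test at `alpha`, and
#' surviving features receive `log10` of the averaged linear-discriminant and
#' raw between-class mean differences (floored at 1, so scores are >= 0).
#' Non-surviving and constant features score 0.
#'
#' @param X non-negative samples x features matrix (relative abundances).
#' @param y integer 0/1 labels.
#' @param alpha Kruskal-Wallis screening level (default 0.05).
#' @return named numeric vector of scores, one per column of `X`.
#' @export
lda_effect_scores <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  yf <- factor(y, levels = c(0L, 1L))
  vapply(seq_len(ncol(X)), function(d) {
    xs <- X[, d] * 1e6
    if (stats::sd(xs) == 0) return(0)
    pv <- suppressWarnings(stats::kruskal.test(xs, yf)$p.value)
    if (is.na(pv) || pv > alpha) return(0)
    d_raw <- abs(mean(xs[y == 1L]) - mean(xs[y == 0L]))
    d_lda <- tryCatch({
      fit <- MASS::lda(matrix(xs, ncol = 1L), grouping = yf)
      sc <- as.numeric(matrix(xs, ncol = 1L) %*% fit$scaling)
      abs(mean(sc[y == 1L]) - mean(sc[y == 0L]))
    }, error = function(e) d_raw)
    log10(max((d_raw + d_lda) / 2, 1))
  }, numeric(1)) -> scores
  names(scores) <- colnames(X)
  scores
}

# rank feature names by decreasing score, ties broken by name (C collation)
rank_by_score <- function(scores) {
  nm <- names(scores)
  old <- Sys.getlocale("LC_COLLATE"); on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  nm[order(-scores, nm)]
}

# out-of-fold balanced accuracy of a small ERT on the candidate feature set
sfs_score <- function(X, y, cols, cfg, seed) {
  fold <- stratified_folds(y, cfg$sfs_cv_folds, seed)
  pred <- numeric(length(y))
  for (f in seq_len(cfg$sfs_cv_folds)) {
    tr <- fold != f
    fit <- fit_prob_forest(X[tr, cols, drop = FALSE], y[tr], cfg$sfs_trees,
                           child_seed(seed, paste0("sfs_fold", f)),
                           extratrees = TRUE)
    pred[!tr] <- forest_proba(fit, X[!tr, cols, drop = FALSE])[, "case"]
  }
  yhat <- as.integer(pred > 0.5)
  r1 <- mean(yhat[y == 1L] == 1L)
  r0 <- mean(yhat[y == 0L] == 0L)
  (r1 + r0) / 2
}

#' Sequential forward selection over ranked features
#'
#' Greedy wrapper: starting from the top-ranked feature, candidates are added
#' in rank order and kept iff they improve the internal cross-validated
#' balanced accuracy of an ERT classifier by more than `sfs_tol`. Scanning
#' stops after `sfs_patience` consecutive non-improvements, after
#' `sfs_max_scan` candidates, or when the ranking is exhausted. The result is
#' never empty (it is seeded with the top-ranked feature).
#'
#' @param ranking character vector of feature names, best first.
#' @param X samples x features matrix.
#' @param y integer 0/1 labels.
#' @param cfg a [microhdf_config()].
#' @param seed seed for the internal CV streams.
#' @return integer column indices into `X` of the selected subset.
#' @export
sequential_forward_select <- function(ranking, X, y, cfg = microhdf_config(),
                                      seed = cfg$seed) {
  X <- as.matrix(X)
  stopifnot(length(ranking) >= 1L, all(ranking %in% colnames(X)))
  selected <- ranking[1L]
  if (length(ranking) > 1L) {
    best <- sfs_score(X, y, selected, cfg, seed)
    misses <- 0L
    scan <- ranking[2L:min(length(ranking), cfg$sfs_max_scan)]
    for (feat in scan) {
      sc <- sfs_score(X, y, c(selected, feat), cfg, seed)
      if (sc > best + cfg$sfs_tol) {
        selected <- c(selected, feat); best <- sc; misses <- 0L
      } else {
        misses <- misses + 1L
        if (misses >= cfg$sfs_patience) break
      }
    }
  }
  match(selected, colnames(X))
}

#' Fit a dimensionality-reducing ERT unit
#'
#' Ranks features by [lda_effect_scores()], picks a local-optimal subset with
#' [sequential_forward_select()], and fits an extremely randomized trees
#' ensemble whose split candidates are restricted to that subset.
#'
#' @param X samples x features matrix.
#' @param y integer 0/1 labels.
#' @param cfg a [microhdf_config()].
#' @param seed unit seed.
#' @param selected optional precomputed column indices (skips ranking + SFS).
#' @return an object of class `ert_unit`.
#' @export
fit_erts <- function(X, y, cfg = microhdf_config(), seed = cfg$seed,
                     selected = NULL) {
  X <- as.matrix(X)
  if (is.null(selected)) {
    scores <- lda_effect_scores(X, y)
    ranking <- rank_by_score(scores)
    selected <- sequential_forward_select(ranking, X, y, cfg,
                                          child_seed(seed, "sfs"))
  }
  if (length(selected) == 0L) stop("selected feature set is empty")
  if (any(selected < 1L | selected > ncol(X)))
    stop("selected references out-of-range columns")
  fit <- fit_prob_forest(X[, selected, drop = FALSE], y, cfg$trees,
                         child_seed(seed, "ert"), extratrees = TRUE)
  structure(list(forest = fit, selected = as.integer(selected),
                 features = colnames(X),
                 selected_names = colnames(X)[selected]),
            class = "ert_unit")
}

#' Class-distribution predictions of an ERT unit
#' @param unit a fitted `ert_unit`.
#' @param X new samples x features matrix (same columns as training).
#' @return matrix with columns `control`, `case`; rows sum to 1.
#' @export
erts_proba <- function(unit, X) {
  X <- as.matrix(X)[, unit$features, drop = FALSE]
  forest_proba(unit$forest, X[, unit$selected, drop = FALSE])
}
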