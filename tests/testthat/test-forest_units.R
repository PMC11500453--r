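test_that("Bray-Curtis matches the hand formula and handles degeneracies", {
  X <- rbind(a = c(0.2, 0.8), b = c(0.8, 0.2), c = c(0.2, 0.8))
  D <- bray_curtis(X)
  expect_equal(D["a", "b"], 0.6)
  expect_equal(D["a", "c"], 0)          # identical rows
  disj <- rbind(c(1, 0), c(0, 1))
  expect_equal(bray_curtis(disj)[1, 2], 1)  # disjoint supports
  # oracle: direct formula on random non-negative matrices
  set.seed(3)
  for (i in 1:5) {
    M <- matrix(stats::rexp(5 * 8), 5, 8) * rbinom(40, 1, 0.7)
    M[1, ] <- pmax(M[1, ], 0.01)  # avoid all-zero pair here
    Dm <- bray_curtis(M)
    for (p in 1:4) for (q in (p + 1):5) {
      ref <- 1 - 2 * sum(pmin(M[p, ], M[q, ])) / (sum(M[p, ]) + sum(M[q, ]))
      expect_equal(Dm[p, q], ref, tolerance = 1e-12)
    }
    expect_equal(Dm, t(Dm))
    expect_equal(unname(diag(Dm)), rep(0, 5))
  }
  zz <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_warning(Dz <- bray_curtis(zz), "all-zero")
  expect_equal(Dz[1, 2], 0)
  expect_error(bray_curtis(rbind(c(-1, 2))), "non-negative")
})

test_that("majority clustering recovers blobs and falls back when forced", {
  bl <- blob_data(per_blob = 10L, seed = 2L)
  cl <- cluster_majority(bl$X, microhdf_config())
  expect_equal(cl$method, "affinity_propagation")
  expect_equal(cl$n_clusters, 3L)
  # perfect agreement with the generating blob structure up to relabelling
  tab <- table(cl$assignment, bl$blob)
  expect_equal(sum(apply(tab, 2, max)), 30L)
  # forced non-convergence triggers the K-means fallback
  cl2 <- cluster_majority(bl$X, microhdf_config(ap_max_iter = 1L))
  expect_equal(cl2$method, "kmeans_fallback")
  # single sample: no clustering run
  cl3 <- cluster_majority(bl$X[1, , drop = FALSE], microhdf_config())
  expect_equal(cl3$method, "single")
  expect_equal(cl3$n_clusters, 1L)
})

test_that("balanced subsets have the prescribed size and class balance", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 30L, n_case = 25L,
                                            n_control = 85L, seed = 2L))
  X <- unclass(dat$profile)
  y <- unname(dat$labels[rownames(dat$profile)])
  cl <- cluster_majority(X[y == 0L, , drop = FALSE], microhdf_config())
  sets <- build_balanced_sets(X, y, cl, microhdf_config(), seed = 7L)
  expect_length(sets, 10L)
  for (s in sets) {
    expect_length(s$majority_idx, 34L)       # round(0.4 * 85)
    expect_length(s$minority_idx, 34L)
    expect_true(all(y[s$majority_idx] == 0L))
    expect_true(all(y[s$minority_idx] == 1L))
    expect_false(anyDuplicated(s$majority_idx) > 0L)  # without replacement
    # every non-empty cluster contributes when m >= n_clusters
    expect_setequal(unique(cl$assignment[match(s$majority_idx, which(y == 0L))]),
                    seq_len(cl$n_clusters))
  }
  # u = 1 with one cluster: a permutation of the whole majority class
  one <- list(assignment = rep(1L, 85L), n_clusters = 1L, method = "single")
  full <- build_balanced_sets(X, y, one,
                              microhdf_config(undersample = 1, n_subsets = 2L))
  expect_setequal(full[[1]]$majority_idx, which(y == 0L))
  few <- c(1:4, 106L)  # 4 majority controls, 1 case; m = round(0.1 * 4) = 0
  expect_error(build_balanced_sets(X[few, ], y[few],
    list(assignment = rep(1L, 4L), n_clusters = 1L, method = "single"),
    microhdf_config(undersample = 0.1)), "too small")
})

test_that("RF-CUS separates separable data and emits valid distributions", {
  sep <- separable_data(seed = 5L)
  unit <- fit_rf_cus(sep$X, sep$y, fast_cfg())
  p <- rf_cus_proba(unit, sep$X)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_equal(unname(microhdf:::auc_score(sep$y, p[, "case"])), 1)
  expect_error(fit_rf_cus(sep$X, rep(0L, nrow(sep$X)), fast_cfg()),
               "both classes")
})

test_that("LDA effect scores rank shifted features first, invariant to row order", {
  set.seed(6)
  n <- 50L
  y <- rep(c(0L, 1L), each = n)
  X <- matrix(stats::rexp(2 * n * 10), 2 * n, 10)
  X[y == 1L, 3] <- X[y == 1L, 3] * 10      # planted 10x shift
  X <- X / rowSums(X)
  X <- cbind(X, const = 0.5)               # constant after closure
  colnames(X) <- c(paste0("f", 1:10), "const")
  sc <- lda_effect_scores(X, y)
  expect_equal(names(which.max(sc)), "f3")
  expect_equal(unname(sc["const"]), 0)
  perm <- sample(nrow(X))
  expect_equal(lda_effect_scores(X[perm, ], y[perm]), sc)
  # a feature identical in both classes scores 0
  same <- cbind(flat = rep(c(1, 2), n))
  expect_equal(unname(lda_effect_scores(cbind(same, X[, 3, drop = FALSE]),
                                        y)["flat"]), 0)
})

test_that("sequential forward selection recovers informative features", {
  cfg <- fast_cfg()
  # single feature: returned as-is
  one <- separable_data(n_noise = 0L, seed = 2L)
  expect_equal(sequential_forward_select("sig", one$X, one$y, cfg), 1L)
  # pure-noise features: the accepted set stays near the seeded top-ranked
  # feature (chance improvements ratchet the bar, so growth self-limits)
  set.seed(9)
  Xn <- matrix(stats::runif(60 * 20), 60, 20,
               dimnames = list(NULL, paste0("n", 1:20)))
  yn <- rep(c(0L, 1L), each = 30L)
  lens <- vapply(1:3, function(s)
    length(sequential_forward_select(paste0("n", 1:20), Xn, yn, cfg,
                                     seed = s)), integer(1))
  expect_lte(median(lens), 5L)
  expect_lte(max(lens), 8L)
  # informative recovery: 5 informative + 45 noise
  hits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    y <- rep(c(0L, 1L), each = 40L)
    X <- matrix(stats::rexp(80 * 50), 80, 50,
                dimnames = list(NULL, sprintf("f%02d", 1:50)))
    X[y == 1L, 1:5] <- X[y == 1L, 1:5] * 6
    X <- X / rowSums(X)
    ranking <- microhdf:::rank_by_score(lda_effect_scores(X, y))
    sel <- sequential_forward_select(ranking, X, y, cfg, seed = 200 + s)
    sum(colnames(X)[sel] %in% sprintf("f%02d", 1:5))
  }, numeric(1))
  expect_gte(median(hits), 4)
})

test_that("ERT units train on the selected subset and emit distributions", {
  sep <- separable_data(seed = 7L)
  unit <- fit_erts(sep$X, sep$y, fast_cfg())
  expect_true("sig" %in% unit$selected_names)
  p <- erts_proba(unit, sep$X)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  expect_equal(unname(microhdf:::auc_score(sep$y, p[, "case"])), 1)
  # selected = all features behaves like a plain ERT ensemble
  all_sel <- fit_erts(sep$X, sep$y, fast_cfg(), selected = seq_len(ncol(sep$X)))
  expect_equal(length(all_sel$selected), ncol(sep$X))
  expect_error(fit_erts(sep$X, sep$y, fast_cfg(), selected = 99L),
               "out-of-range")
})

test_that("rebalancing lifts minority recall over a plain forest", {
  # imbalanced (IR = 4) moderate-signal data; directional, multi-seed
  wins <- 0L
  for (s in 1:3) {
    dat <- simulate_microbiome(synthetic_spec(
      n_taxa = 60L, n_case = 15L, n_control = 60L, n_differential = 8L,
      effect_size = 3, seed = 40L + s))
    X <- unclass(dat$profile)
    y <- unname(dat$labels[rownames(dat$profile)])
    set.seed(s)
    tr <- sort(c(sample(which(y == 0L), 40L), sample(which(y == 1L), 10L)))
    te <- setdiff(seq_along(y), tr)
    unit <- fit_rf_cus(X[tr, ], y[tr], fast_cfg(seed = 70L + s))
    rec_cus <- mean(rf_cus_proba(unit, X[te, ])[y[te] == 1L, "case"] > 0.5)
    rf <- ranger::ranger(x = as.data.frame(X[tr, ]), y = factor(y[tr]),
                         num.trees = 100L, probability = TRUE,
                         seed = 70L + s, num.threads = 1L)
    rec_rf <- mean(stats::predict(rf, data = as.data.frame(X[te, ]),
      num.threads = 1L)$predictions[y[te] == 1L, "1"] > 0.5)
    wins <- wins + (rec_cus >= rec_rf)
  }
  expect_gte(wins, 2L)
})
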