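# shared fixtures: everything is generated in code at test time

toy_tree <- function() read_newick(text = "((A,B)C,(D)E)R;")

toy_profile <- function() {
  abundance_profile(matrix(c(0.5, 0.3, 0.2,
                             0.2, 0.3, 0.5), 2, 3, byrow = TRUE,
                           dimnames = list(c("s1", "s2"), c("A", "B", "D"))))
}

# reduced-size configuration used throughout the suite; the architecture is
# unchanged, only ensemble sizes and wrapper budgets are scaled down
fast_cfg <- function(seed = 11L, ...) {
  defaults <- list(trees = 25L, n_subsets = 3L, max_layers = 1L,
                   sfs_trees = 10L, sfs_cv_folds = 2L, sfs_max_scan = 10L,
                   seed = seed)
  do.call(microhdf_config, utils::modifyList(defaults, list(...)))
}

# linearly separable two-class toy matrix
separable_data <- function(n_per_class = 20L, n_noise = 5L, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n_per_class)
  signal <- ifelse(y == 1L, 1, 0) + stats::runif(2L * n_per_class, 0, 0.2)
  X <- cbind(signal, matrix(stats::runif(2L * n_per_class * n_noise),
                            nrow = 2L * n_per_class, ncol = n_noise))
  colnames(X) <- c("sig", if (n_noise > 0L) paste0("noise", seq_len(n_noise)))
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  list(X = X, y = y)
}

# three well-separated compositional blobs
blob_data <- function(per_blob = 10L, seed = 1L) {
  set.seed(seed)
  centers <- rbind(c(8, 1, 1, 0.5), c(1, 8, 0.5, 1), c(0.5, 1, 8, 1))
  X <- do.call(rbind, lapply(1:3, function(b) {
    m <- matrix(stats::rexp(per_blob * 4), per_blob, 4) * 0.2 +
      matrix(centers[b, ], per_blob, 4, byrow = TRUE)
    m / rowSums(m)
  }))
  list(X = X, blob = rep(1:3, each = per_blob))
}

# brute-force AUC oracle: all case-control pairs, ties credited 0.5
pairwise_auc <- function(y, s) {
  pos <- s[y == 1L]; neg <- s[y == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# a baseline plain random forest exposed through the repeated_cv plug-in
# interface, for like-for-like fold comparisons
plain_rf_fit <- function(profile, labels, tree, cfg) {
  y <- factor(as.integer(labels[rownames(profile)]), levels = c(0L, 1L))
  list(fit = ranger::ranger(
         x = as.data.frame(unclass(profile), check.names = FALSE), y = y,
         num.trees = 100L, probability = TRUE, seed = cfg$seed,
         num.threads = 1L),
       taxa = colnames(profile))
}

plain_rf_predict <- function(model, profile) {
  X <- matrix(0, nrow(profile), length(model$taxa),
              dimnames = list(rownames(profile), model$taxa))
  common <- intersect(colnames(profile), model$taxa)
  X[, common] <- unclass(profile)[, common]
  stats::predict(model$fit, data = as.data.frame(X, check.names = FALSE),
                 num.threads = 1L)$predictions[, "1"]
}
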