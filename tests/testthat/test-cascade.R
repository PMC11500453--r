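test_that("a layer augments features with out-of-fold class vectors", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 40L, n_case = 20L,
    n_control = 20L, n_differential = 5L, effect_size = 5, seed = 12L))
  H <- assemble_views(dat$profile, mode = "O")
  y <- unname(dat$labels[rownames(dat$profile)])
  layer <- fit_layer(H, y, fast_cfg(), seed = 3L)
  expect_equal(ncol(layer$oof), 8L)  # 4 units x 2 classes
  expect_true(all(layer$oof >= 0 & layer$oof <= 1))
  expect_false(anyNA(layer$oof))
  # unit probability pairs are valid distributions
  for (u in 1:4)
    expect_equal(unname(rowSums(layer$oof[, (2 * u - 1):(2 * u)])),
                 rep(1, nrow(H)), tolerance = 1e-9)
  # the two RF-CUS units differ only by their seed stream
  expect_equal(length(layer$units$rfcus1$forests),
               length(layer$units$rfcus2$forests))
  mix <- c(1L, 2L, 21L, 22L)  # two samples per class, fewer than 3 folds
  expect_error(fit_layer(H[mix, ], y[mix], fast_cfg()), "fewer samples")
})

test_that("augmentation re-appends the original features at every depth", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 100L, n_case = 30L,
    n_control = 30L, n_differential = 5L, effect_size = 5, seed = 9L))
  cfg <- fast_cfg(seed = 5L, channels = "abundance", max_layers = 2L,
                  early_stop = FALSE)
  m <- fit_microhdf(dat$profile, dat$labels, NULL, cfg)
  expect_length(m$channels$A$layers, 2L)
  X0 <- assemble_views(to_relative(dat$profile), mode = "O")
  attr(X0, "feature_map") <- NULL
  for (l in 1:2) {
    h <- augmented_features(m, "A", l)
    expect_equal(ncol(h), 108L)  # 100 raw + 4 units x 2 classes
    expect_identical(unname(h[, 9:108]), unname(unclass(X0)))
  }
})

test_that("channel growth respects bounds and records the trace", {
  sep <- separable_data(n_per_class = 15L, seed = 3L)
  ch <- fit_channel(sep$X, sep$y, fast_cfg(), seed = 2L)
  expect_length(ch$layers, 1L)               # max_layers = 1 bound
  expect_equal(ch$val_auc, max(ch$trace[seq_len(ch$best_depth)]))
  expect_gte(ch$val_auc, 0.95)               # separable data
  expect_error(fit_channel(sep$X[1, , drop = FALSE], 1L, fast_cfg()),
               "single-sample")
})

test_that("the fitted cascade predicts valid, alignment-robust distributions", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 50L, n_case = 25L,
    n_control = 25L, n_differential = 5L, effect_size = 6, seed = 14L))
  # string labels exercise the label-map round trip
  labs <- stats::setNames(ifelse(dat$labels == 1L, "disease", "healthy"),
                          names(dat$labels))
  y <- make_labels(labs, positive_class = "disease")
  m <- fit_microhdf(dat$profile, y, dat$tree, fast_cfg(seed = 21L))
  p <- predict_proba(m, dat$profile)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  pred <- predict(m, dat$profile)
  expect_setequal(unique(pred), c("disease", "healthy"))
  expect_equal(names(pred), rownames(dat$profile))
  # taxa permuted in the test profile: identical predictions
  perm <- abundance_profile(unclass(dat$profile)[, sample(ncol(dat$profile))])
  expect_equal(predict_proba(m, perm), p)
  # an all-zero test sample yields a valid distribution
  z <- abundance_profile(matrix(0, 1, ncol(dat$profile),
    dimnames = list("zzz", colnames(dat$profile))))
  pz <- predict_proba(m, z)
  expect_equal(unname(rowSums(pz)), 1, tolerance = 1e-9)
  # resubstitution keeps the training signal on separable-grade data
  expect_gte(microhdf:::auc_score(unname(dat$labels[rownames(p)]),
                                  p[, "case"]),
             max(vapply(m$channels, `[[`, numeric(1), "val_auc")) - 0.05)
})

test_that("single-channel and merged architectures run on the same data", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 40L, n_case = 15L,
    n_control = 15L, n_differential = 5L, effect_size = 6, seed = 17L))
  for (arch in c("abundance", "phylo", "merged")) {
    m <- fit_microhdf(dat$profile, dat$labels, dat$tree,
                      fast_cfg(seed = 30L, channels = arch))
    expect_length(m$channels, 1L)
    p <- predict_proba(m, dat$profile)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  }
})

test_that("prediction requires overlapping taxa", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 30L, n_case = 10L,
    n_control = 10L, seed = 19L))
  m <- fit_microhdf(dat$profile, dat$labels, NULL,
                    fast_cfg(seed = 40L, channels = "abundance"))
  alien <- abundance_profile(matrix(1, 2, 2,
    dimnames = list(c("a", "b"), c("k__Z|s__Z1", "k__Z|s__Z2"))))
  expect_error(predict_proba(m, alien), "empty overlap")
})
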