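# names of the four per-layer units, in the fixed concatenation order
.layer_units <- c("rfcus1", "rfcus2", "ert1", "ert2")

aug_colnames <- function(units = .layer_units) {
  as.vector(t(outer(units, c("control", "case"),
                    function(u, cl) paste("aug", u, cl, sep = ":"))))
}

#' Fit one cascade layer (2 RF-CUS + 2 ERT units)
#'
#' Fits the four forest units on the full layer input and, separately,
#' produces out-of-fold class-probability vectors through an internal
#' stratified split, so no sample's augmented output comes from a unit
#' trained on that sample. The ERT units' feature subsets are selected once
#' per unit on the full layer input and reused in the fold refits.
#'
#' @param H samples x features layer input.
#' @param y integer 0/1 labels.
#' @param cfg a [microhdf_config()].
#' @param seed layer seed.
#' @return a `cascade_layer`: fitted units, out-of-fold class vectors
#'   (`oof`, width 8), fold assignment and internal-validation AUC.
#' @export
fit_layer <- function(H, y, cfg = microhdf_config(), seed = cfg$seed) {
  H <- as.matrix(H)
  stopifnot(nrow(H) == length(y))
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  if (min(counts) < cfg$oof_folds)
    stop("fewer samples in a class than internal folds")
  # per-unit feature selection for the ERT units, shared across fold refits
  scores <- lda_effect_scores(H, y)
  ranking <- rank_by_score(scores)
  sel <- list(
    ert1 = sequential_forward_select(ranking, H, y, cfg,
                                     child_seed(seed, "sfs1")),
    ert2 = sequential_forward_select(ranking, H, y, cfg,
                                     child_seed(seed, "sfs2")))
  fit_unit <- function(unit, X, yy, sd) {
    if (startsWith(unit, "rfcus")) fit_rf_cus(X, yy, cfg, sd)
    else fit_erts(X, yy, cfg, sd, selected = sel[[unit]])
  }
  unit_proba <- function(unit, fit, X) {
    if (startsWith(unit, "rfcus")) rf_cus_proba(fit, X) else erts_proba(fit, X)
  }
  units <- lapply(.layer_units, function(u)
    fit_unit(u, H, y, child_seed(seed, u)))
  names(units) <- .layer_units
  fold <- stratified_folds(y, cfg$oof_folds, child_seed(seed, "oof"))
  oof <- matrix(NA_real_, nrow(H), 2L * length(.layer_units),
                dimnames = list(rownames(H), aug_colnames()))
  for (f in seq_len(cfg$oof_folds)) {
    tr <- fold != f
    for (u in seq_along(.layer_units)) {
      un <- .layer_units[u]
      fit <- fit_unit(un, H[tr, , drop = FALSE], y[tr],
                      child_seed(seed, paste0(un, "_fold", f)))
      p <- unit_proba(un, fit, H[!tr, , drop = FALSE])
      oof[!tr, (2L * u - 1L):(2L * u)] <- p
    }
  }
  case_cols <- seq(2L, ncol(oof), by = 2L)
  val_auc <- auc_score(y, rowMeans(oof[, case_cols, drop = FALSE]))
  structure(list(units = units, oof = oof, fold = fold, val_auc = val_auc,
                 selected = sel, input_width = ncol(H),
                 input_names = colnames(H)),
            class = "cascade_layer")
}

# class vectors of a fitted layer's units on new data (width 8)
layer_proba <- function(layer, H) {
  out <- lapply(seq_along(.layer_units), function(u) {
    un <- .layer_units[u]
    if (startsWith(un, "rfcus")) rf_cus_proba(layer$units[[un]], H)
    else erts_proba(layer$units[[un]], H)
  })
  m <- do.call(cbind, out)
  colnames(m) <- aug_colnames()
  m
}

#' Grow one cascade channel
#'
#' Stacks layers; layer `l + 1` consumes the previous layer's out-of-fold
#' class vectors concatenated with the ORIGINAL input features (the
#' augmentation always re-appends `x`). Growth stops when the
#' internal-validation AUC fails to improve for `layer_patience` consecutive
#' layers or at `max_layers`; the best-scoring depth is kept.
#'
#' @param X0 samples x features channel input.
#' @param y integer 0/1 labels.
#' @param cfg a [microhdf_config()].
#' @param seed channel seed.
#' @return a `cascade_channel`: the kept layers, per-layer augmented training
#'   matrices, validation trace and best depth.
#' @export
fit_channel <- function(X0, y, cfg = microhdf_config(), seed = cfg$seed) {
  X0 <- as.matrix(X0)
  if (nrow(X0) < 2L) stop("degenerate single-sample input")
  layers <- list(); aug <- list(); trace <- numeric(0)
  best_auc <- -Inf; best_depth <- 1L; misses <- 0L
  h <- X0
  for (l in seq_len(cfg$max_layers)) {
    layer <- fit_layer(h, y, cfg, child_seed(seed, paste0("layer", l)))
    layers[[l]] <- layer
    aug[[l]] <- cbind(layer$oof, X0)
    trace[l] <- layer$val_auc
    if (layer$val_auc > best_auc + 1e-9) {
      best_auc <- layer$val_auc; best_depth <- l; misses <- 0L
    } else {
      misses <- misses + 1L
      if (cfg$early_stop && misses >= cfg$layer_patience) break
    }
    h <- aug[[l]]
  }
  if (!cfg$early_stop) best_depth <- length(layers)
  layers <- layers[seq_len(best_depth)]
  structure(list(layers = layers, aug = aug[seq_len(best_depth)],
                 trace = trace, best_depth = best_depth,
                 val_auc = max(trace[seq_len(best_depth)]),
                 X0_names = colnames(X0)),
            class = "cascade_channel")
}

# forward pass of a fitted channel on new features; returns the last layer's
# class vectors (width 8)
channel_proba <- function(channel, X0) {
  h <- X0
  p <- NULL
  for (layer in channel$layers) {
    p <- layer_proba(layer, h)
    h <- cbind(p, X0)
  }
  p
}

# Build per-channel feature matrices from a profile. Returns named list of
# matrices plus the feature maps used by the FIV report.
channel_inputs <- function(profile, tree, cfg) {
  phylo_mode <- switch(cfg$mode,
                       "O" = "", "O+L" = "L", "O+P" = "P",
                       "O+L+P" = "L+P", "L+P" = "L+P")
  need_phylo <- cfg$channels %in% c("both", "phylo") ||
    (cfg$channels == "merged" && cfg$mode != "O")
  mats <- list()
  if (need_phylo) {
    if (is.null(tree)) tree <- build_taxonomy_tree(profile)
    mL <- if (grepl("L", cfg$mode) || cfg$channels %in% c("both", "phylo"))
      populate_template(profile, tree,
                        level_template(tree, cfg$level_include_internal))
    mP <- if (grepl("P", cfg$mode) || cfg$channels %in% c("both", "phylo"))
      populate_template(profile, tree,
                        postorder_template(tree, cfg$postorder_include_internal))
  } else {
    mL <- NULL; mP <- NULL
  }
  switch(cfg$channels,
    both = {
      if (phylo_mode == "") stop("channels='both' needs phylogeny views; ",
                                 "use mode 'O+L+P', 'O+L' or 'O+P'")
      mats$A <- assemble_views(profile, mode = "O")
      mats$B <- assemble_views(profile, mL, mP, mode = phylo_mode)
    },
    abundance = mats$A <- assemble_views(profile, mode = "O"),
    phylo = {
      pm <- if (phylo_mode == "") "L+P" else phylo_mode
      mats$B <- assemble_views(profile, mL, mP, mode = pm)
    },
    merged = mats$M <- assemble_views(profile, mL, mP, mode = cfg$mode))
  list(mats = mats, tree = tree)
}

#' Fit the full two-channel deep forest cascade
#'
#' Channel A learns from the raw abundance matrix, channel B from the
#' phylogeny-derived traversal views (level and/or post-order); each channel
#' is an independently stopped cascade of layers of 2 RF-CUS + 2 ERT units.
#' The final layer (one plain random forest plus one ERT ensemble) consumes
#' the concatenation of the channels' last-layer class vectors and its two
#' distributions are averaged for prediction. Single-channel and merged
#' architectures are available through `cfg$channels`.
#'
#' @param profile an [abundance_profile()]; renormalized to relative
#'   abundances internally.
#' @param labels named 0/1 labels (see [make_labels()]) covering every sample.
#' @param tree optional `taxonomy_tree`; built from the lineage strings when
#'   absent and reconciled with the profile when supplied.
#' @param cfg a [microhdf_config()].
#' @return a fitted `microhdf_model`.
#' @export
fit_microhdf <- function(profile, labels, tree = NULL,
                         cfg = microhdf_config()) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (!is.null(attr(labels, "label_map"))) lm <- attr(labels, "label_map")
  else lm <- c("0", "1")
  labels <- labels[rownames(profile)]
  if (anyNA(labels)) stop("unlabelled samples in training profile")
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  profile <- to_relative(profile)
  if (!is.null(tree)) tree <- reconcile_tree(tree, profile)
  ci <- channel_inputs(profile, tree, cfg)
  channels <- lapply(names(ci$mats), function(ch)
    fit_channel(ci$mats[[ch]], y, cfg, child_seed(cfg$seed, paste0("chan", ch))))
  names(channels) <- names(ci$mats)
  Z <- do.call(cbind, lapply(names(channels), function(ch) {
    m <- channels[[ch]]$layers[[channels[[ch]]$best_depth]]$oof
    colnames(m) <- paste0(ch, ":", colnames(m))
    m
  }))
  if (cfg$final_raw_features)
    Z <- cbind(Z, assemble_views(profile, mode = "O"))
  final <- list(
    rf = fit_prob_forest(Z, y, cfg$trees, child_seed(cfg$seed, "final_rf")),
    ert = fit_prob_forest(Z, y, cfg$trees, child_seed(cfg$seed, "final_ert"),
                          extratrees = TRUE))
  feature_maps <- lapply(ci$mats, attr, "feature_map")
  structure(list(channels = channels, final = final, cfg = cfg,
                 label_map = lm, taxa = colnames(profile),
                 tree = ci$tree, feature_maps = feature_maps,
                 final_names = colnames(Z),
                 trace = lapply(channels, `[[`, "trace")),
            class = "microhdf_model")
}

#' @export
print.microhdf_model <- function(x, ...) {
  cat(sprintf("<microhdf_model> channels: %s; depths: %s; %d taxa\n",
              paste(names(x$channels), collapse = "+"),
              paste(vapply(x$channels, `[[`, 1L, "best_depth"),
                    collapse = "/"),
              length(x$taxa)))
  invisible(x)
}

# align a new profile onto the training taxa: drop extras, zero-fill missing
align_profile <- function(model, profile) {
  extra <- setdiff(colnames(profile), model$taxa)
  missing <- setdiff(model$taxa, colnames(profile))
  if (length(intersect(colnames(profile), model$taxa)) == 0L)
    stop("empty overlap between training and test taxa")
  if (length(extra) || length(missing))
    warning(sprintf("taxon alignment: %d extra dropped, %d missing zero-filled",
                    length(extra), length(missing)))
  m <- matrix(0, nrow(profile), length(model$taxa),
              dimnames = list(rownames(profile), model$taxa))
  common <- intersect(colnames(profile), model$taxa)
  m[, common] <- unclass(profile)[, common]
  rs <- rowSums(m)
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  abundance_profile(m)
}

#' Predict class distributions from a fitted cascade
#'
#' @param model a fitted `microhdf_model`.
#' @param profile an [abundance_profile()]; taxa are aligned to the training
#'   taxa by id (missing taxa zero-filled, extras dropped, with a warning).
#' @return matrix with columns `control` and `case`, rows summing to 1.
#' @export
predict_proba <- function(model, profile) {
  profile <- align_profile(model, profile)
  ci <- channel_inputs(profile, model$tree, model$cfg)
  Z <- do.call(cbind, lapply(names(model$channels), function(ch) {
    m <- channel_proba(model$channels[[ch]], ci$mats[[ch]])
    colnames(m) <- paste0(ch, ":", colnames(m))
    m
  }))
  if (model$cfg$final_raw_features)
    Z <- cbind(Z, assemble_views(profile, mode = "O"))
  p <- (forest_proba(model$final$rf, Z) + forest_proba(model$final$ert, Z)) / 2
  rownames(p) <- rownames(profile)
  p
}

#' Predict class labels from a fitted cascade
#'
#' Threshold on the case probability (`cfg$threshold`, default 0.5); ties go
#' to control. Labels are reported in the original label vocabulary.
#'
#' @param object a fitted `microhdf_model`.
#' @param profile an [abundance_profile()].
#' @param ... unused.
#' @return named character vector of predicted labels.
#' @export
predict.microhdf_model <- function(object, profile, ...) {
  p <- predict_proba(object, profile)
  cls <- as.integer(p[, "case"] > object$cfg$threshold)
  stats::setNames(object$label_map[cls + 1L], rownames(p))
}

#' Per-layer augmented training features of a channel
#'
#' The augmented representation `h` of a layer is the layer's out-of-fold
#' class vectors concatenated with the channel's original input features, so
#' its trailing block always equals `x` exactly.
#'
#' @param model a fitted `microhdf_model`.
#' @param channel channel name (`"A"`, `"B"` or `"M"`).
#' @param layer layer index.
#' @return the augmented samples x (8 + input width) matrix.
#' @export
augmented_features <- function(model, channel, layer) {
  ch <- model$channels[[channel]]
  if (is.null(ch)) stop("no such channel: ", channel)
  if (layer < 1L || layer > length(ch$aug)) stop("layer index out of range")
  ch$aug[[layer]]
}
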