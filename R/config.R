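#' Configuration for forest units and the cascade
#'
#' Defaults follow the published setting of the method: `trees = 100`
#' decision trees per forest, undersampling ratio `undersample = 0.4`
#' (the per-subset fraction of the majority class retained), an
#' affinity-propagation target of about `ap_clusters = 15` clusters, and two
#' RF-CUS plus two ERT units per cascade layer. The number of balanced
#' subsets `n_subsets` and all wrapper/stopping parameters are stated
#' defaults of this implementation.
#'
#' @param trees trees per forest (T).
#' @param n_subsets balanced majority/minority subset pairs per RF-CUS unit (N).
#' @param undersample undersampling ratio u in (0, 1]: each balanced subset
#'   keeps `round(u * n_majority)` majority samples.
#' @param ap_clusters target cluster count k for affinity propagation; also
#'   the K of the K-means fallback (capped at the majority size).
#' @param ap_max_iter iteration cap per affinity-propagation run.
#' @param max_layers maximum cascade depth per channel.
#' @param layer_patience stop growing a channel after this many consecutive
#'   layers without internal-validation AUC improvement.
#' @param early_stop disable to always grow to `max_layers`.
#' @param oof_folds internal folds used to produce out-of-fold class vectors
#'   for feature augmentation.
#' @param sfs_cv_folds,sfs_trees,sfs_tol,sfs_patience,sfs_max_scan sequential
#'   forward selection: internal CV folds, trees of the wrapper ERT,
#'   minimum balanced-accuracy improvement to keep a feature, consecutive
#'   non-improvements tolerated, and the cap on candidates scanned.
#' @param mode feature views for the phylogeny channel / merged runs:
#'   `"O"`, `"O+L"`, `"O+P"`, `"O+L+P"` or `"L+P"`.
#' @param channels `"both"` (abundance + phylogeny, the default two-channel
#'   architecture), `"abundance"`, `"phylo"`, or `"merged"` (a single channel
#'   on the concatenated views in `mode`).
#' @param level_include_internal,postorder_include_internal which nodes enter
#'   the level-order and post-order templates.
#' @param final_raw_features also append raw features to the final-layer
#'   input (default `FALSE`: the final layer sees class vectors only).
#' @param reselect_per_layer re-run ERT feature selection at every cascade
#'   layer (default) instead of once on the first layer's features.
#' @param threshold decision threshold on the case probability; ties go to
#'   control.
#' @param seed master seed; all randomness derives from it via named streams.
#' @return a validated list of class `microhdf_config`.
#' @export
microhdf_config <- function(trees = 100L,
                            n_subsets = 10L,
                            undersample = 0.4,
                            ap_clusters = 15L,
                            ap_max_iter = 200L,
                            max_layers = 5L,
                            layer_patience = 1L,
                            early_stop = TRUE,
                            oof_folds = 3L,
                            sfs_cv_folds = 3L,
                            sfs_trees = 25L,
                            sfs_tol = 1e-4,
                            sfs_patience = 10L,
                            sfs_max_scan = 50L,
                            mode = "O+L+P",
                            channels = c("both", "abundance", "phylo", "merged"),
                            level_include_internal = TRUE,
                            postorder_include_internal = FALSE,
                            final_raw_features = FALSE,
                            reselect_per_layer = TRUE,
                            threshold = 0.5,
                            seed = 42L) {
  cfg <- list(trees = as.integer(trees), n_subsets = as.integer(n_subsets),
              undersample = undersample, ap_clusters = as.integer(ap_clusters),
              ap_max_iter = as.integer(ap_max_iter),
              max_layers = as.integer(max_layers),
              layer_patience = as.integer(layer_patience),
              early_stop = isTRUE(early_stop),
              oof_folds = as.integer(oof_folds),
              sfs_cv_folds = as.integer(sfs_cv_folds),
              sfs_trees = as.integer(sfs_trees), sfs_tol = sfs_tol,
              sfs_patience = as.integer(sfs_patience),
              sfs_max_scan = as.integer(sfs_max_scan),
              mode = match.arg(mode, c("O+L+P", "O", "O+L", "O+P", "L+P")),
              channels = match.arg(channels),
              level_include_internal = isTRUE(level_include_internal),
              postorder_include_internal = isTRUE(postorder_include_internal),
              final_raw_features = isTRUE(final_raw_features),
              reselect_per_layer = isTRUE(reselect_per_layer),
              threshold = threshold, seed = as.integer(seed))
  stopifnot(cfg$trees >= 1L, cfg$n_subsets >= 1L,
            cfg$undersample > 0, cfg$undersample <= 1,
            cfg$ap_clusters >= 1L, cfg$max_layers >= 1L,
            cfg$oof_folds >= 2L, cfg$sfs_cv_folds >= 2L,
            cfg$threshold > 0, cfg$threshold < 1)
  class(cfg) <- "microhdf_config"
  cfg
}

#' @export
print.microhdf_config <- function(x, ...) {
  cat("<microhdf_config>\n")
  cat(sprintf("  trees=%d  subsets=%d  undersample=%.2f  ap_clusters=%d\n",
              x$trees, x$n_subsets, x$undersample, x$ap_clusters))
  cat(sprintf("  channels=%s  mode=%s  max_layers=%d  seed=%d\n",
              x$channels, x$mode, x$max_layers, x$seed))
  invisible(x)
}
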