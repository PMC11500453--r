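# Gini impurity-decrease importance of every forest in a layer, summed over
# the layer's input features. RF-CUS sub-forests each count as one forest.
collect_layer_importance <- function(layer) {
  acc <- stats::setNames(numeric(layer$input_width), layer$input_names)
  add <- function(imp) {
    imp <- imp[!is.na(imp)]
    acc[names(imp)] <<- acc[names(imp)] + imp
  }
  for (un in names(layer$units)) {
    unit <- layer$units[[un]]
    if (inherits(unit, "rf_cus_unit")) {
      for (f in unit$forests) add(f$variable.importance)
    } else {
      add(unit$forest$variable.importance)
    }
  }
  acc
}

# map layer-input column names to original feature ids; augmented
# class-vector dimensions fall into the reserved "__augmented__" bucket
map_to_original <- function(nm, feature_map) {
  out <- ifelse(startsWith(nm, "aug:"), "__augmented__",
                unname(feature_map[nm]))
  out[is.na(out)] <- nm[is.na(out)]
  out
}

#' Raw per-feature gain of one cascade layer
#'
#' Sums the Gini impurity decrease attributed to each feature over all trees
#' of all forests of the layer (each RF-CUS sub-forest counts as one forest).
#' Gains on augmented class-vector dimensions accumulate under the reserved
#' `__augmented__` bucket.
#'
#' @param model a fitted `microhdf_model`.
#' @param channel channel name.
#' @param layer layer index.
#' @param feature optional original feature id to extract a single gain.
#' @return named numeric vector of raw gains by original feature id (plus
#'   `__augmented__`), or a single value when `feature` is given.
#' @export
layer_feature_gain <- function(model, channel, layer, feature = NULL) {
  ch <- model$channels[[channel]]
  if (is.null(ch)) stop("no such channel: ", channel)
  if (layer < 1L || layer > length(ch$layers))
    stop("layer index out of range")
  acc <- collect_layer_importance(ch$layers[[layer]])
  orig <- map_to_original(names(acc), model$feature_maps[[channel]])
  gains <- tapply(acc, orig, sum)
  gains <- stats::setNames(as.numeric(gains), names(gains))
  if (!is.null(feature)) {
    if (!feature %in% names(gains)) return(0)
    return(gains[[feature]])
  }
  gains
}

#' Normalized feature importance values (FIV)
#'
#' Accumulates the raw per-layer gains of every cascade layer of every
#' channel (and the final layer), maps each column back to its original
#' feature id — a taxon appearing in several views (raw, level, post-order)
#' is summed under its single taxon id, internal template positions report
#' under the internal node's lineage path — excludes the augmented
#' class-vector dimensions, and normalizes so the values sum to 1.
#'
#' @param model a fitted `microhdf_model`.
#' @return a `fiv_report`: named numeric `fiv` (sums to 1), the excluded
#'   `augmented_gain`, per-layer raw gains, and metadata.
#' @export
compute_fiv <- function(model) {
  per_layer <- list()
  total <- numeric(0)
  bump <- function(gains) {
    for (nm in names(gains))
      total[nm] <<- (if (nm %in% names(total)) total[[nm]] else 0) + gains[[nm]]
  }
  for (ch in names(model$channels)) {
    for (l in seq_along(model$channels[[ch]]$layers)) {
      g <- layer_feature_gain(model, ch, l)
      per_layer[[paste0(ch, ".layer", l)]] <- g
      bump(g)
    }
  }
  # final layer: its inputs are channel class vectors (all augmented) unless
  # raw features were appended
  fin <- stats::setNames(numeric(length(model$final_names)), model$final_names)
  for (f in list(model$final$rf, model$final$ert)) {
    imp <- f$variable.importance
    fin[names(imp)] <- fin[names(imp)] + imp
  }
  fm_all <- do.call(c, unname(model$feature_maps)) %||% character(0)
  orig <- ifelse(grepl("(^|:)aug:", names(fin)), "__augmented__",
                 ifelse(names(fin) %in% names(fm_all),
                        fm_all[names(fin)], names(fin)))
  fing <- tapply(fin, orig, sum)
  bump(stats::setNames(as.numeric(fing), names(fing)))
  per_layer[["final"]] <- stats::setNames(as.numeric(fing), names(fing))
  aug <- if ("__augmented__" %in% names(total)) total[["__augmented__"]] else 0
  fiv <- total[names(total) != "__augmented__"]
  if (length(fiv) == 0L || sum(fiv) <= 0) {
    warning("all-zero total gain: returning uniform importance")
    ids <- model$taxa
    fiv <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  } else {
    fiv <- fiv / sum(fiv)
  }
  structure(list(fiv = fiv, augmented_gain = aug, per_layer = per_layer,
                 meta = list(L = sum(vapply(model$channels, function(ch)
                               length(ch$layers), integer(1))),
                             N = model$cfg$n_subsets, T = model$cfg$trees,
                             D = length(fiv))),
            class = "fiv_report")
}

#' @export
print.fiv_report <- function(x, ...) {
  cat(sprintf("<fiv_report> %d features, sum = %.6f\n",
              length(x$fiv), sum(x$fiv)))
  print(utils::head(top_k(x, 5L)))
  invisible(x)
}

#' Top-k features by importance
#'
#' @param report a `fiv_report`.
#' @param k number of features (capped at the feature count).
#' @return data.frame with `feature`, `fiv`, `rank`, in descending
#'   importance; ties broken by feature name.
#' @export
top_k <- function(report, k = 20L) {
  stopifnot(k >= 1L)
  old <- Sys.getlocale("LC_COLLATE"); on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  ord <- order(-report$fiv, names(report$fiv))
  k <- min(k, length(report$fiv))
  data.frame(feature = names(report$fiv)[ord][seq_len(k)],
             fiv = unname(report$fiv[ord])[seq_len(k)],
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Write a feature-importance report as TSV
#'
#' @param report a `fiv_report`.
#' @param path output TSV path (`feature<TAB>FIV<TAB>rank`).
#' @export
write_fiv_report <- function(report, path) {
  df <- top_k(report, length(report$fiv))
  names(df) <- c("feature", "FIV", "rank")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
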