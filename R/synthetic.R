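#' Specification for the synthetic microbiome generator
#'
#' The generator emulates zero-inflated, compositional relative-abundance
#' profiles: per-taxon log-normal base abundances, abundance-dependent
#' (detection-limit) dropout, a
#' multiplicative fold-change planted on differential taxa in case samples,
#' and a regular rank hierarchy (kingdom through species) with the given
#' branching factor supplying MetaPhlAn-style lineage strings and a matching
#' taxonomy tree.
#'
#' @param n_taxa number of species-level taxa D.
#' @param n_case,n_control class sizes (their ratio sets the imbalance
#'   ratio).
#' @param n_differential number of planted differential taxa.
#' @param effect_size multiplicative fold-change applied to differential
#'   taxa in cases before renormalization (1 = null generator).
#' @param zero_inflation dropout probability at the median log-abundance, in
#'   `[0, 1)`; entries far above the detection limit drop out less often.
#' @param dispersion sd of the per-entry log-normal abundances.
#' @param tree_branching children per internal node of the rank hierarchy.
#' @param clustered plant the differential taxa as sibling leaves (default),
#'   so phylogeny-derived features carry signal; `FALSE` scatters them.
#' @param seed generator seed.
#' @return a validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa = 200L, n_case = 50L, n_control = 50L,
                           n_differential = 10L, effect_size = 3,
                           zero_inflation = 0.3, dispersion = 1,
                           tree_branching = 3L, clustered = TRUE,
                           seed = 1L) {
  spec <- list(n_taxa = as.integer(n_taxa), n_case = as.integer(n_case),
               n_control = as.integer(n_control),
               n_differential = as.integer(n_differential),
               effect_size = effect_size, zero_inflation = zero_inflation,
               dispersion = dispersion,
               tree_branching = as.integer(tree_branching),
               clustered = isTRUE(clustered), seed = as.integer(seed))
  stopifnot(spec$n_taxa >= 1L, spec$n_case >= 1L, spec$n_control >= 1L,
            spec$n_differential >= 0L, spec$n_differential <= spec$n_taxa,
            spec$effect_size > 0,
            spec$zero_inflation >= 0, spec$zero_inflation < 1,
            spec$dispersion > 0, spec$tree_branching >= 2L)
  class(spec) <- "synthetic_spec"
  spec
}

# lineage strings over a regular rank hierarchy: species i belongs to genus
# ceiling(i / b), genera to families the same way, and so on up to a single
# kingdom; consecutive species indices are siblings.
synthetic_lineages <- function(n_taxa, branching) {
  prefixes <- c("k", "p", "c", "o", "f", "g", "s")
  idx <- seq_len(n_taxa)
  groups <- list(s = idx)
  g <- idx
  for (p in rev(prefixes[-7L])) {
    g <- ceiling(g / branching)
    groups[[p]] <- g
  }
  groups$k <- rep(1L, n_taxa)  # single kingdom
  vapply(idx, function(i)
    paste(vapply(prefixes, function(p)
      sprintf("%s__%s%d", p, toupper(p), groups[[p]][i]), character(1)),
      collapse = "|"), character(1))
}

#' Generate a synthetic cohort
#'
#' Fully deterministic given the spec's seed. Case samples carry the planted
#' multiplicative fold-change on the differential taxa; every row is
#' renormalized to sum to 1 (at least one entry per sample survives
#' dropout).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `profile` (an [abundance_profile()]), `labels` (named
#'   0/1), `tree` (the matching `taxonomy_tree`), `differential` (the planted
#'   taxon ids) and `spec`.
#' @export
simulate_microbiome <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  D <- spec$n_taxa
  n <- spec$n_case + spec$n_control
  taxa <- synthetic_lineages(D, spec$tree_branching)
  set.seed(child_seed(spec$seed, "base"))
  mu <- stats::rnorm(D, 0, 1)
  set.seed(child_seed(spec$seed, "differential"))
  diff_idx <- if (spec$n_differential == 0L) integer(0)
    else if (spec$clustered) {
      start <- sample.int(D - spec$n_differential + 1L, 1L)
      seq(start, length.out = spec$n_differential)
    } else sample.int(D, spec$n_differential)
  y <- c(rep(0L, spec$n_control), rep(1L, spec$n_case))
  set.seed(child_seed(spec$seed, "abundance"))
  A <- matrix(exp(stats::rnorm(n * D, mean = rep(mu, each = n),
                               sd = spec$dispersion)), n, D)
  if (length(diff_idx))
    A[y == 1L, diff_idx] <- A[y == 1L, diff_idx] * spec$effect_size
  # detection-limit dropout: the probability of observing a zero decreases
  # with the entry's abundance (zero_inflation is the dropout probability at
  # the median log-abundance), so zeros behave like real below-detection
  # events rather than label-independent noise
  if (spec$zero_inflation > 0) {
    la <- log(A)
    p_drop <- stats::plogis(stats::qlogis(spec$zero_inflation) -
                              (la - stats::median(la)))
    keep <- matrix(stats::runif(n * D) >= p_drop, n, D)
    # at least one entry per sample survives dropout
    champion <- max.col(A)
    keep[cbind(seq_len(n), champion)] <- TRUE
    A <- A * keep
  }
  A <- A / rowSums(A)
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(A) <- list(ids, taxa)
  labels <- stats::setNames(y, ids)
  attr(labels, "label_map") <- c("0", "1")
  list(profile = abundance_profile(A), labels = labels,
       tree = build_taxonomy_tree(taxa),
       differential = taxa[diff_idx], spec = spec)
}

#' Sweep imbalance ratio against undersampling ratio
#'
#' For every (IR, undersampling ratio) cell, generates a cohort with
#' `n_control = round(IR * n_case)` (case count taken from `base_spec`),
#' runs repeated cross-validation, and records the mean AUC.
#'
#' @param ir_values imbalance ratios to simulate.
#' @param u_values undersampling ratios to configure.
#' @param base_spec a [synthetic_spec()] supplying everything but the class
#'   sizes.
#' @param cfg a [microhdf_config()] (the undersampling ratio is overridden
#'   per cell).
#' @param k,repeats cross-validation settings per cell.
#' @param path optional TSV output path for the matrix.
#' @return data.frame with columns `IR`, `undersample`, `mean_auc`.
#' @export
sweep_imbalance <- function(ir_values, u_values,
                            base_spec = synthetic_spec(),
                            cfg = microhdf_config(), k = 3L, repeats = 1L,
                            path = NULL) {
  grid <- expand.grid(IR = ir_values, undersample = u_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    spec_i <- base_spec
    spec_i$n_control <- as.integer(round_half_up(grid$IR[i] * base_spec$n_case))
    spec_i$seed <- child_seed(base_spec$seed, sprintf("cell%d", i))
    dat <- simulate_microbiome(spec_i)
    cfg_i <- cfg
    cfg_i$undersample <- grid$undersample[i]
    rep_i <- repeated_cv(dat$profile, dat$labels, dat$tree, cfg_i,
                         k = k, repeats = repeats)
    grid$mean_auc[i] <- rep_i$aggregate$mean[rep_i$aggregate$metric == "auc"]
  }
  if (!is.null(path))
    utils::write.table(grid, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  grid
}
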