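#' Class imbalance ratio
#'
#' Majority-class count divided by minority-class count, rounded half-up to
#' two decimals.
#'
#' @param labels 0/1 integer labels (or anything coercible via table over two
#'   classes).
#' @return the imbalance ratio IR (>= 1).
#' @export
imbalance_ratio <- function(labels) {
  counts <- table(labels)
  if (length(counts) < 2L) stop("single-class input: IR undefined")
  if (length(counts) > 2L) stop("more than two classes")
  round_half_up(max(counts) / min(counts), 2L)
}

#' Cohort summary
#'
#' @param labels 0/1 labels (1 = case).
#' @param n_features number of taxa/features in the cohort's profile.
#' @return data.frame with n_case, n_control, total samples TN, n_features
#'   and the imbalance ratio.
#' @export
cohort_summary <- function(labels, n_features = NA_integer_) {
  n_case <- sum(labels == 1L); n_control <- sum(labels == 0L)
  data.frame(n_case = n_case, n_control = n_control,
             TN = n_case + n_control, n_features = n_features,
             IR = imbalance_ratio(labels))
}

# rank-statistic AUC with midrank tie correction
auc_score <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: single-class y_true")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# precision-recall step integral (average precision); ties grouped by score
aupr_score <- function(y, scores) {
  y <- as.integer(y)
  if (sum(y == 1L) == 0L) stop("AUPR undefined: no positive samples")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- rev(!duplicated(rev(ss)))  # last index within each score group
  prec <- (tp / (tp + fp))[last]
  rec <- (tp / sum(y))[last]
  sum(diff(c(0, rec)) * prec)
}

#' Binary classification metrics
#'
#' AUC (rank statistic with tie correction), AUPR (precision-recall step
#' integral), and threshold metrics computed for the case class.
#'
#' @param y_true 0/1 labels.
#' @param scores case-class scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5; ties go to control).
#' @return named numeric vector: `auc`, `aupr`, `accuracy`, `recall`, `f1`.
#' @export
binary_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  acc <- mean(pred == y_true)
  rec <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (is.na(rec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(auc = auc_score(y_true, scores), aupr = aupr_score(y_true, scores),
    accuracy = acc, recall = rec, f1 = f1)
}

subset_profile <- function(profile, idx) {
  abundance_profile(unclass(profile)[idx, , drop = FALSE])
}

#' Repeated stratified cross-validation
#'
#' Stratified k-fold cross-validation repeated `repeats` times; the model is
#' refit per training fold, so feature selection and clustering happen inside
#' the training fold only. Metrics are computed per repeat on the pooled
#' out-of-fold predictions, then aggregated as mean and sd over repeats.
#'
#' @param profile an [abundance_profile()].
#' @param labels named 0/1 labels covering the profile.
#' @param tree optional `taxonomy_tree`.
#' @param cfg a [microhdf_config()].
#' @param k folds (default 5).
#' @param repeats repetitions (default 10).
#' @param seed seed for fold assignment (default from `cfg`).
#' @param fit_fun model-fitting function `(profile, labels, tree, cfg)`;
#'   defaults to [fit_microhdf()]. Swapping it in lets baselines run on
#'   identical folds.
#' @param predict_fun matching `(model, profile)` case-probability function.
#' @return an `eval_report`: per-repeat metrics, aggregate mean +/- sd, fold
#'   assignments and the seed.
#' @export
repeated_cv <- function(profile, labels, tree = NULL,
                        cfg = microhdf_config(), k = 5L, repeats = 10L,
                        seed = cfg$seed,
                        fit_fun = fit_microhdf,
                        predict_fun = function(m, p) predict_proba(m, p)[, "case"]) {
  labels <- labels[rownames(profile)]
  if (anyNA(labels)) stop("unlabelled samples in profile")
  y <- as.integer(labels)
  if (min(table(y)) < k) stop("a class has fewer samples than folds")
  per_repeat <- vector("list", repeats)
  fold_list <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k, child_seed(seed, paste0("rep", r)))
    fold_list[[r]] <- fold
    scores <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      cfg_f <- cfg
      cfg_f$seed <- child_seed(seed, sprintf("rep%d_fold%d", r, f))
      model <- fit_fun(subset_profile(profile, tr), labels[tr], tree, cfg_f)
      scores[!tr] <- predict_fun(model, subset_profile(profile, !tr))
    }
    per_repeat[[r]] <- c(repeat_idx = r,
                         binary_metrics(y, scores, cfg$threshold))
  }
  per_repeat <- as.data.frame(do.call(rbind, per_repeat))
  agg <- data.frame(
    metric = c("auc", "aupr", "accuracy", "recall", "f1"),
    mean = vapply(c("auc", "aupr", "accuracy", "recall", "f1"),
                  function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(c("auc", "aupr", "accuracy", "recall", "f1"),
                function(m) stats::sd(per_repeat[[m]]), numeric(1)),
    row.names = NULL)
  agg$sd[is.na(agg$sd)] <- 0
  structure(list(per_repeat = per_repeat, aggregate = agg,
                 folds = fold_list, seed = seed, k = k, repeats = repeats),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV x %d repeats\n", x$k, x$repeats))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Cross-study validation
#'
#' A single fit on the training cohort and a single evaluation on the test
#' cohort, with taxa aligned by id (zero-fill for missing taxa).
#'
#' @param train_profile,train_labels training cohort.
#' @param test_profile,test_labels test cohort.
#' @param tree optional `taxonomy_tree`.
#' @param cfg a [microhdf_config()].
#' @return an `eval_report` with a single row of metrics.
#' @export
cross_study <- function(train_profile, train_labels,
                        test_profile, test_labels,
                        tree = NULL, cfg = microhdf_config()) {
  if (length(intersect(colnames(train_profile), colnames(test_profile))) == 0L)
    stop("empty taxon intersection between cohorts")
  model <- fit_microhdf(train_profile, train_labels, tree, cfg)
  y <- as.integer(test_labels[rownames(test_profile)])
  scores <- predict_proba(model, test_profile)[, "case"]
  met <- binary_metrics(y, scores, cfg$threshold)
  per_repeat <- as.data.frame(t(c(repeat_idx = 1, met)))
  agg <- data.frame(metric = names(met), mean = unname(met), sd = 0)
  structure(list(per_repeat = per_repeat, aggregate = agg,
                 folds = NULL, seed = cfg$seed, k = NA_integer_,
                 repeats = 1L, model = model),
            class = "eval_report")
}
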