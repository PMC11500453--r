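#' Construct an abundance profile
#'
#' An `abundance_profile` is a samples x taxa matrix of non-negative
#' abundances with unique sample and taxon identifiers. Taxon identifiers are
#' MetaPhlAn-style rank-prefixed lineage strings
#' (`k__...|p__...|...|s__...`), although any unique strings are accepted;
#' lineage strings are required only when the taxonomy tree is to be built
#' from them.
#'
#' @param values numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids character vectors; default to the dimnames of
#'   `values`.
#' @return an object of class `abundance_profile` (a matrix with validated
#'   dimnames).
#' @export
abundance_profile <- function(values, sample_ids = rownames(values),
                              taxon_ids = colnames(values)) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty abundance table")
  if (!is.numeric(values)) stop("non-numeric abundance values")
  if (anyNA(values)) stop("missing abundance cells")
  if (any(values < 0)) stop("negative abundance")
  if (is.null(sample_ids) || is.null(taxon_ids))
    stop("sample and taxon ids are required")
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(taxon_ids)) stop("duplicate taxon ids")
  stopifnot(length(sample_ids) == nrow(values),
            length(taxon_ids) == ncol(values))
  dimnames(values) <- list(sample_ids, taxon_ids)
  class(values) <- c("abundance_profile", "matrix", "array")
  values
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> %d samples x %d taxa\n", nrow(x), ncol(x)))
  cat(sprintf("  row sums: [%.4g, %.4g]\n",
              min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

#' Read a tab-separated abundance table
#'
#' The table carries one header row and one id column. Orientation is
#' explicit: `taxa_rows` (the MetaPhlAn convention, default) means rows are
#' taxa and columns are samples; `samples_rows` the transpose. No
#' auto-detection is attempted.
#'
#' @param path file path of a TSV table.
#' @param orientation `"taxa_rows"` or `"samples_rows"`.
#' @return an [abundance_profile()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty table")
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing cells in abundance table")
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  abundance_profile(m)
}

#' Write an abundance table as TSV
#'
#' @param profile an [abundance_profile()].
#' @param path output path.
#' @param orientation see [read_abundance_table()].
#' @export
write_abundance_table <- function(profile, path,
                                  orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  m <- unclass(profile)
  if (orientation == "taxa_rows") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (orientation == "taxa_rows") "taxon_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalize a profile to per-sample relative abundances
#'
#' Divides every row by its sum so row sums are exactly 1. Idempotent, and
#' agnostic to whether the input arrived as proportions or percentages.
#'
#' @param profile an [abundance_profile()].
#' @return the renormalized profile.
#' @export
to_relative <- function(profile) {
  rs <- rowSums(profile)
  if (any(rs <= 0)) {
    bad <- rownames(profile)[rs <= 0]
    stop("all-zero sample row(s): ", paste(bad, collapse = ", "))
  }
  abundance_profile(unclass(profile) / rs)
}

# canonical rank order and single-letter prefixes of lineage strings
.ranks <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
            f = "family", g = "genus", s = "species")

#' Parse a rank-prefixed lineage string
#'
#' @param taxon_id a `|`-separated lineage such as
#'   `"k__Bacteria|p__Firmicutes|...|s__Roseburia_hominis"`.
#' @return a data.frame with columns `rank` (long rank name) and `name`,
#'   ordered from kingdom downwards; class `"lineage"`.
#' @export
parse_lineage <- function(taxon_id) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L)
  tokens <- strsplit(taxon_id, "|", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L) stop("empty lineage string")
  ok <- grepl("^[A-Za-z]__", tokens)
  if (!all(ok)) stop("malformed lineage token: ", tokens[!ok][1L])
  prefix <- substr(tokens, 1L, 1L)
  unknown <- !prefix %in% names(.ranks)
  if (any(unknown)) stop("unknown rank prefix: ", tokens[unknown][1L])
  pos <- match(prefix, names(.ranks))
  if (any(diff(pos) <= 0)) stop("out-of-order ranks in lineage: ", taxon_id)
  name <- substring(tokens, 4L)
  if (any(!nzchar(name))) stop("empty rank name in lineage: ", taxon_id)
  out <- data.frame(rank = unname(.ranks[prefix]), name = name,
                    token = tokens, stringsAsFactors = FALSE)
  class(out) <- c("lineage", "data.frame")
  out
}

#' Read a sample-label table
#'
#' Two tab-separated columns, `sample_id` then label, no header. Labels may be
#' `0`/`1` (0 = control, 1 = case) or two arbitrary strings, mapped to 0/1 in
#' first-seen order unless `positive_class` names the case label explicitly.
#'
#' @param path TSV path.
#' @param positive_class optional label string to map to class 1 (case).
#' @return named integer vector of 0/1 with attribute `label_map` giving the
#'   original label for each class.
#' @export
read_labels <- function(path, positive_class = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("label table needs sample_id<TAB>label")
  make_labels(stats::setNames(df[[2L]], df[[1L]]), positive_class)
}

#' Coerce a labelled vector to 0/1 sample labels
#'
#' @param labels named vector (names are sample ids) of two classes.
#' @param positive_class optional value to treat as class 1.
#' @return named integer 0/1 vector with a `label_map` attribute.
#' @export
make_labels <- function(labels, positive_class = NULL) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be uniquely named by sample id")
  vals <- as.character(labels)
  uniq <- unique(vals)
  if (length(uniq) > 2L) stop("more than two classes in labels")
  if (all(uniq %in% c("0", "1"))) {
    map <- c("0", "1")
  } else {
    map <- uniq
    if (length(map) == 1L) map <- c(map, NA_character_)
  }
  if (!is.null(positive_class)) {
    if (!positive_class %in% vals) stop("positive_class not found in labels")
    map <- c(setdiff(uniq, positive_class), positive_class)
  }
  y <- as.integer(match(vals, map) - 1L)
  names(y) <- names(labels)
  attr(y, "label_map") <- map
  y
}

# check labels against a profile; training requires both classes
check_labels <- function(profile, labels, training = TRUE) {
  missing <- setdiff(names(labels), rownames(profile))
  if (length(missing))
    stop("labelled samples absent from profile: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  if (training) {
    y <- labels[rownames(profile)]
    if (anyNA(y)) stop("unlabelled samples in training profile")
    if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  }
  invisible(TRUE)
}
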