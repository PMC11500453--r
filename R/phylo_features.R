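#' Build the least-pruned taxonomy tree from lineage strings
#'
#' Every taxon id of the profile is parsed as a rank-prefixed lineage and
#' inserted as a root-to-leaf path; shared prefixes share nodes. Single-child
#' internal nodes are retained so rank levels stay aligned. Children are
#' sorted lexicographically by token at every node, which makes the traversal
#' templates reproducible regardless of input taxon order.
#'
#' @param profile an [abundance_profile()] whose taxon ids parse as lineages,
#'   or a character vector of lineage strings.
#' @return a `taxonomy_tree` whose leaves carry the profile taxon ids.
#' @export
build_taxonomy_tree <- function(profile) {
  taxa <- if (inherits(profile, "abundance_profile")) colnames(profile)
          else as.character(profile)
  if (length(taxa) == 0L) stop("empty profile: no taxa to build a tree from")
  name <- "root"; rank <- NA_character_
  parent <- NA_integer_; children <- list(integer(0))
  taxon_id <- NA_character_
  # child lookup by (parent index, token)
  find_child <- function(p, token) {
    for (ch in children[[p]]) if (name[ch] == token) return(ch)
    0L
  }
  add_node <- function(p, token, rk) {
    name <<- c(name, token); rank <<- c(rank, rk)
    parent <<- c(parent, p); children[[length(name)]] <<- integer(0)
    children[[p]] <<- c(children[[p]], length(name))
    taxon_id <<- c(taxon_id, NA_character_)
    length(name)
  }
  leaf_path <- function(i) {
    toks <- character(0)
    while (!is.na(parent[i])) { toks <- c(name[i], toks); i <- parent[i] }
    paste(toks, collapse = "|")
  }
  leaf_of_token <- new.env(parent = emptyenv())
  for (tx in taxa) {
    lin <- parse_lineage(tx)
    node <- 1L
    for (r in seq_len(nrow(lin))) {
      token <- lin$token[r]
      nxt <- find_child(node, token)
      if (nxt == 0L) nxt <- add_node(node, token, lin$rank[r])
      node <- nxt
    }
    if (!is.na(taxon_id[node])) stop("duplicate leaf lineage: ", tx)
    term <- lin$token[nrow(lin)]
    prev <- get0(term, envir = leaf_of_token)
    if (!is.null(prev) && prev != node)
      stop(sprintf("conflicting lineages: leaf '%s' appears under '%s' and '%s'",
                   term, leaf_path(prev), leaf_path(node)))
    assign(term, node, envir = leaf_of_token)
    taxon_id[node] <- tx
  }
  lf <- lengths(children) == 0L
  if (any(lf & is.na(taxon_id)))
    stop("internal error: leaf without taxon id")
  tree <- new_taxonomy_tree(name, rank, parent, children, taxon_id)
  sort_children(tree)
}

# sort children lexicographically by node name at every node (C collation,
# so ordering does not depend on the session locale)
sort_children <- function(tree) {
  old <- Sys.getlocale("LC_COLLATE"); on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  tree$children <- lapply(tree$children, function(ch)
    ch[order(tree$name[ch])])
  tree
}

#' Reconcile a supplied tree with a profile
#'
#' Leaves are matched to profile taxa by the terminal rank token (or the full
#' taxon id). Tree leaves matching no profile taxon are pruned (least-pruned
#' semantics); profile taxa absent from the tree are appended as direct
#' children of the root, with a warning in both cases.
#'
#' @param tree a `taxonomy_tree` (for instance from [read_newick()]).
#' @param profile an [abundance_profile()].
#' @return a `taxonomy_tree` whose leaf set maps 1:1 onto the profile taxa.
#' @export
reconcile_tree <- function(tree, profile) {
  taxa <- colnames(profile)
  term <- vapply(taxa, function(tx) {
    toks <- strsplit(tx, "|", fixed = TRUE)[[1L]]
    toks[length(toks)]
  }, character(1))
  # also match leaf names against terminal tokens stripped of rank prefixes
  bare <- sub("^[a-z]__", "", term)
  leaves <- which(is_leaf(tree))
  match_taxon <- function(leaf_name) {
    hit <- which(taxa == leaf_name | term == leaf_name | bare == leaf_name)
    if (length(hit) == 1L) hit else 0L
  }
  hit <- vapply(tree$name[leaves], match_taxon, integer(1))
  tree$taxon_id[leaves] <- ifelse(hit > 0L, taxa[hit], NA_character_)
  drop <- leaves[hit == 0L]
  if (length(drop))
    warning(length(drop), " tree leaves absent from the profile were pruned")
  tree <- prune_leaves(tree, drop)
  missing <- setdiff(taxa, tree$taxon_id)
  if (length(missing)) {
    warning(length(missing),
            " profile taxa absent from the tree; appended under the root")
    for (tx in missing) {
      tree$name <- c(tree$name, term[match(tx, taxa)])
      tree$rank <- c(tree$rank, NA_character_)
      tree$parent <- c(tree$parent, tree$root)
      tree$children[[length(tree$name)]] <- integer(0)
      tree$children[[tree$root]] <- c(tree$children[[tree$root]],
                                      length(tree$name))
      tree$taxon_id <- c(tree$taxon_id, tx)
      tree$edge_length <- c(tree$edge_length, NA_real_)
    }
  }
  if (length(tree_leaves(tree)) == 0L)
    stop("no profile taxa could be matched to the tree")
  tree
}

# drop the given leaves, then any internal node left without leaf descendants
prune_leaves <- function(tree, drop) {
  lf <- is_leaf(tree)
  keep <- logical(n_nodes(tree))
  for (i in postorder_indices(tree)) {
    keep[i] <- if (lf[i]) !(i %in% drop)
               else any(keep[tree$children[[i]]])
  }
  keep[tree$root] <- TRUE
  idx <- which(keep)
  remap <- match(seq_len(n_nodes(tree)), idx)
  new_taxonomy_tree(
    name = tree$name[idx], rank = tree$rank[idx],
    parent = remap[tree$parent[idx]],
    children = lapply(tree$children[idx], function(ch)
      remap[ch[keep[ch]]]),
    taxon_id = tree$taxon_id[idx],
    edge_length = tree$edge_length[idx])
}

#' Level-order traversal template
#'
#' Visits every node breadth-first, top to bottom and left to right (root
#' first). By default all nodes are included, associating positions with tree
#' levels (evolutionary stages).
#'
#' @param tree a `taxonomy_tree`.
#' @param include_internal include internal nodes (default `TRUE`).
#' @return a `traversal_template`.
#' @export
level_template <- function(tree, include_internal = TRUE) {
  idx <- levelorder_indices(tree)
  if (!include_internal) idx <- idx[is_leaf(tree)[idx]]
  new_template("level", tree, idx, include_internal)
}

#' Post-order traversal template
#'
#' Depth-first order in which a node follows its children; restricted to
#' leaves by default, giving the left-to-right leaf sequence in which taxa
#' sharing ancestry are adjacent.
#'
#' @param tree a `taxonomy_tree`.
#' @param include_internal include internal nodes (default `FALSE`).
#' @return a `traversal_template`.
#' @export
postorder_template <- function(tree, include_internal = FALSE) {
  idx <- postorder_indices(tree)
  if (!include_internal) idx <- idx[is_leaf(tree)[idx]]
  new_template("postorder", tree, idx, include_internal)
}

new_template <- function(strategy, tree, idx, include_internal) {
  lab <- node_labels(tree)
  out <- list(strategy = strategy, index = idx, ids = lab[idx],
              include_internal = include_internal)
  if (anyDuplicated(out$ids)) stop("non-unique node labels in template")
  class(out) <- "traversal_template"
  out
}

#' @export
print.traversal_template <- function(x, ...) {
  cat(sprintf("<traversal_template> %s, %d positions (internal nodes: %s)\n",
              x$strategy, length(x$ids), x$include_internal))
  invisible(x)
}

#' Populate a traversal template with sample abundances
#'
#' Leaf positions carry the taxon's abundance; internal-node positions carry
#' the sum of their descendant leaves' abundances, so the value at every node
#' equals the sum over its children (hierarchical consistency) and the root
#' carries the sample's total abundance.
#'
#' @param profile an [abundance_profile()].
#' @param tree the `taxonomy_tree` the template was derived from.
#' @param template a `traversal_template`.
#' @return samples x positions matrix (class `phylo_feature_matrix`) with
#'   template ids as column names.
#' @export
populate_template <- function(profile, tree, template) {
  desc <- descendant_leaves(tree)
  leaf_tx <- tree$taxon_id
  cols <- lapply(template$index, function(i) {
    tx <- leaf_tx[desc[[i]]]
    miss <- setdiff(tx, colnames(profile))
    if (length(miss))
      stop("template/tree mismatch: taxa not in profile: ",
           paste(utils::head(miss, 3L), collapse = ", "))
    if (length(tx) == 1L) profile[, tx]
    else rowSums(profile[, tx, drop = FALSE])
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(profile), template$ids)
  attr(m, "strategy") <- template$strategy
  # map each column back to its original feature id: the taxon id for a leaf
  # position, the node's full lineage path for an internal position
  paths <- node_paths(tree)
  lf <- is_leaf(tree)
  attr(m, "taxon_map") <- stats::setNames(
    ifelse(lf[template$index], leaf_tx[template$index], paths[template$index]),
    template$ids)
  class(m) <- c("phylo_feature_matrix", "matrix", "array")
  m
}

#' Assemble feature views into one matrix
#'
#' Column-wise concatenation of the raw abundance view (`O`) and the
#' level-order (`L`) and post-order (`P`) phylogeny views, with provenance
#' encoded in column-name prefixes `raw:`, `lvl:` and `post:`.
#'
#' @param profile an [abundance_profile()] (the `O` view).
#' @param matrixL,matrixP populated templates (may be `NULL` when unused).
#' @param mode one of `"O"`, `"O+L"`, `"O+P"`, `"O+L+P"`, `"L+P"`.
#' @return a numeric matrix with provenance-prefixed column names.
#' @export
assemble_views <- function(profile, matrixL = NULL, matrixP = NULL,
                           mode = c("O+L+P", "O", "O+L", "O+P", "L+P")) {
  mode <- match.arg(mode)
  parts <- list()
  maps <- list()
  tag <- function(m, prefix) {
    colnames(m) <- paste0(prefix, colnames(m))
    m
  }
  want <- strsplit(mode, "+", fixed = TRUE)[[1L]]
  if ("O" %in% want) {
    parts$O <- tag(unclass(profile), "raw:")
    maps$O <- stats::setNames(colnames(profile), colnames(parts$O))
  }
  if ("L" %in% want) {
    if (is.null(matrixL)) stop("mode ", mode, " needs the level view")
    map <- attr(matrixL, "taxon_map") %||%
      stats::setNames(colnames(matrixL), colnames(matrixL))
    parts$L <- tag(unclass(matrixL), "lvl:")
    maps$L <- stats::setNames(unname(map), colnames(parts$L))
  }
  if ("P" %in% want) {
    if (is.null(matrixP)) stop("mode ", mode, " needs the post-order view")
    map <- attr(matrixP, "taxon_map") %||%
      stats::setNames(colnames(matrixP), colnames(matrixP))
    parts$P <- tag(unclass(matrixP), "post:")
    maps$P <- stats::setNames(unname(map), colnames(parts$P))
  }
  rn <- lapply(parts, rownames)
  if (!all(vapply(rn, identical, logical(1), rn[[1L]])))
    stop("sample-id mismatch between views")
  out <- do.call(cbind, unname(parts))
  attr(out, "feature_map") <- do.call(c, unname(maps))
  out
}
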