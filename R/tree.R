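# Taxonomy tree container: parallel vectors over nodes plus an ordered
# children list. Child order is part of the object (templates depend on it).
new_taxonomy_tree <- function(name, rank, parent, children, taxon_id,
                              edge_length = rep(NA_real_, length(name))) {
  stopifnot(length(name) == length(parent),
            length(children) == length(name))
  tree <- list(name = name, rank = rank, parent = parent,
               children = children, taxon_id = taxon_id,
               edge_length = edge_length,
               root = which(is.na(parent))[1L])
  if (sum(is.na(parent)) != 1L) stop("tree must have exactly one root")
  class(tree) <- "taxonomy_tree"
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d nodes, %d leaves\n",
              n_nodes(x), length(tree_leaves(x))))
  invisible(x)
}

n_nodes <- function(tree) length(tree$name)

is_leaf <- function(tree) lengths(tree$children) == 0L

#' Leaf indices of a taxonomy tree, in tree (left-to-right) order
#' @param tree a taxonomy tree.
#' @return integer node indices.
#' @export
tree_leaves <- function(tree) {
  ord <- postorder_indices(tree)
  ord[is_leaf(tree)[ord]]
}

# Full path label: tokens from root (exclusive) joined by "|"; unique by
# construction. For a leaf built from a lineage it equals the taxon id.
node_paths <- function(tree) {
  lab <- character(n_nodes(tree))
  walk <- function(i, prefix) {
    lab[i] <<- if (is.na(tree$parent[i])) tree$name[i]
               else if (nzchar(prefix)) paste(prefix, tree$name[i], sep = "|")
               else tree$name[i]
    pref <- if (is.na(tree$parent[i])) "" else lab[i]
    for (ch in tree$children[[i]]) walk(ch, pref)
  }
  walk(tree$root, "")
  lab
}

# Display label: the node's own name where unique in the tree, the full path
# where the name is ambiguous.
node_labels <- function(tree) {
  nm <- tree$name
  dup <- unique(nm[duplicated(nm)])
  paths <- node_paths(tree)
  ifelse(nm %in% dup, paths, nm)
}

# depth-first post-order node index sequence (children before parent)
postorder_indices <- function(tree) {
  out <- integer(0)
  rec <- function(i) {
    for (ch in tree$children[[i]]) rec(ch)
    out[[length(out) + 1L]] <<- i
  }
  rec(tree$root)
  out
}

# breadth-first (level) node index sequence, root first, left-to-right
levelorder_indices <- function(tree) {
  queue <- tree$root
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    queue <- c(queue, tree$children[[i]])
  }
  out
}

# indices of descendant leaves for every node (list of integer vectors)
descendant_leaves <- function(tree) {
  leaf <- is_leaf(tree)
  desc <- vector("list", n_nodes(tree))
  for (i in postorder_indices(tree)) {
    desc[[i]] <- if (leaf[i]) i
                 else unlist(desc[tree$children[[i]]], use.names = FALSE)
  }
  desc
}

#' Read a rooted tree from a Newick file or string
#'
#' A purpose-built recursive-descent parser: unlike general phylogenetics
#' readers, it preserves single-child internal nodes exactly (taxonomy trees
#' use them to keep rank levels aligned) together with their labels, child
#' order and optional branch lengths.
#'
#' @param path path to a Newick file, or `NULL` when `text` is given.
#' @param text optional Newick string.
#' @return a `taxonomy_tree`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- gsub("[[:space:]]", "", text)
  chars <- strsplit(text, "")[[1L]]
  if (sum(chars == "(") != sum(chars == ")"))
    stop("unbalanced parentheses in Newick input")
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$name <- character(0); env$parent <- integer(0)
  env$children <- list(); env$edge_length <- numeric(0)
  peek <- function() if (env$pos <= length(chars)) chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L
  read_label <- function() {
    out <- character(0)
    while (!peek() %in% c("", "(", ")", ",", ":", ";")) {
      out <- c(out, peek()); advance()
    }
    paste(out, collapse = "")
  }
  add_node <- function(name, parent) {
    env$name <- c(env$name, name)
    env$parent <- c(env$parent, parent)
    env$children[[length(env$name)]] <- integer(0)
    env$edge_length <- c(env$edge_length, NA_real_)
    if (!is.na(parent))
      env$children[[parent]] <- c(env$children[[parent]], length(env$name))
    length(env$name)
  }
  parse_subtree <- function(parent) {
    if (peek() == "(") {
      node <- add_node(NA_character_, parent)
      advance()
      repeat {
        parse_subtree(node)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("could not parse Newick input: expected ',' or ')'")
      }
      lab <- read_label()
      if (nzchar(lab)) env$name[node] <- lab
    } else {
      lab <- read_label()
      if (!nzchar(lab)) stop("could not parse Newick input: empty leaf label")
      node <- add_node(lab, parent)
    }
    if (peek() == ":") {
      advance()
      bl <- read_label()
      env$edge_length[node] <- suppressWarnings(as.numeric(bl))
      if (is.na(env$edge_length[node]))
        stop("could not parse Newick branch length: ", bl)
    }
    node
  }
  parse_subtree(NA_integer_)
  if (peek() != ";") stop("could not parse Newick input: missing ';'")
  leaf <- lengths(env$children) == 0L
  if (anyDuplicated(env$name[leaf]))
    stop("duplicate leaf names: ",
         paste(unique(env$name[leaf][duplicated(env$name[leaf])]),
               collapse = ", "))
  name <- env$name
  unnamed <- which(is.na(name))
  if (length(unnamed)) name[unnamed] <- paste0("node", unnamed)
  taxon_id <- rep(NA_character_, length(name))
  taxon_id[leaf] <- name[leaf]
  new_taxonomy_tree(name, rep(NA_character_, length(name)), env$parent,
                    env$children, taxon_id, env$edge_length)
}

#' Write a taxonomy tree as Newick
#'
#' @param tree a `taxonomy_tree`.
#' @param path output file path; when `NULL` the Newick string is returned.
#' @return the path (invisibly) or the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  fmt <- function(i) {
    lab <- tree$name[i]
    bl <- if (!is.na(tree$edge_length[i]))
            sprintf(":%g", tree$edge_length[i]) else ""
    if (is_leaf(tree)[i]) return(paste0(lab, bl))
    inner <- paste(vapply(tree$children[[i]], fmt, character(1)),
                   collapse = ",")
    paste0("(", inner, ")", lab, bl)
  }
  s <- paste0(fmt(tree$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}
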