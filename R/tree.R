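# Parse trees and unlabeled syntactic trees (USTs).  A tree is a nested list
# with fields `label` (character) and `children` (list; NULL for a terminal
# leaf).  Terminals are leaves; every terminal sits under its lexical
# non-terminal, so the minimum leaf-to-leaf path in any CFC/CNF tree is 4.

#' Construct a tree node
#' @param label Node label (non-terminal name, or terminal symbol for a leaf).
#' @param children List of child nodes; `NULL` marks a terminal leaf.
#' @return A `parse_tree` node.
#' @export
tree_node <- function(label, children = NULL) {
  structure(list(label = label, children = children), class = "parse_tree")
}

is_leaf <- function(node) is.null(node$children)

#' Terminal yield of a tree
#' @param tree A `parse_tree` (or UST).
#' @return Character vector of leaf labels in left-to-right order.
#' @export
tree_yield <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_yield), use.names = FALSE)
}

#' Skeleton (unlabeled syntactic tree) of a parse tree
#'
#' Drops all non-leaf labels, keeping the tree shape and the terminal
#' leaves. Leaf distances, and hence consistency with a contact map, depend
#' only on the skeleton.
#'
#' @param tree A `parse_tree`.
#' @return The UST, in the same nested-list representation.
#' @export
skeleton <- function(tree) {
  if (is_leaf(tree)) return(tree)
  tree_node("", lapply(tree$children, skeleton))
}

#' Serialize a tree as a bracketed string
#'
#' Example output: `(s (h V) (t (l N) (l G)) (h I))`.
#'
#' @param tree A `parse_tree`.
#' @return A single character string.
#' @export
format_tree <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  inner <- paste(vapply(tree$children, format_tree, ""), collapse = " ")
  paste0("(", tree$label, " ", inner, ")")
}

#' @export
print.parse_tree <- function(x, ...) {
  cat(format_tree(x), "\n")
  invisible(x)
}

#' Parse a bracketed tree string
#' @param s A string as produced by [format_tree()].
#' @return A `parse_tree`.
#' @export
parse_tree_string <- function(s) {
  tokens <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  parse_node <- function() {
    tok <- tokens[pos]
    if (tok == "(") {
      pos <<- pos + 1L
      label <- tokens[pos]
      pos <<- pos + 1L
      children <- list()
      while (tokens[pos] != ")") children[[length(children) + 1L]] <- parse_node()
      pos <<- pos + 1L
      tree_node(label, children)
    } else {
      pos <<- pos + 1L
      tree_node(tok)
    }
  }
  out <- parse_node()
  if (pos != length(tokens) + 1L) stop("trailing tokens in tree string")
  out
}

#' Leaf-to-leaf distance matrix of a tree
#'
#' Shortest-path length, counted in edges, between every pair of leaves
#' (terminals) of the tree. For CFC parse trees the two terminals generated
#' by a contact rule are at distance exactly 4 (terminal - lexical
#' non-terminal - contact node - lexical non-terminal - terminal), the
#' minimum attainable between distinct leaves.
#'
#' @param tree A `parse_tree` or UST.
#' @return Symmetric integer matrix `n x n` with zero diagonal, where `n`
#'   is the number of leaves.
#' @export
leaf_distance_matrix <- function(tree) {
  n <- length(tree_yield(tree))
  D <- matrix(0L, n, n)
  counter <- 0L
  # rec() returns a matrix with columns (idx, depth) for the leaves under a
  # node, depths measured from that node; cross-child leaf pairs meet at the
  # node, so their path length is the sum of their depths.
  rec <- function(node) {
    if (is_leaf(node)) {
      counter <<- counter + 1L
      return(cbind(idx = counter, depth = 0L))
    }
    parts <- lapply(node$children, function(ch) {
      p <- rec(ch)
      p[, "depth"] <- p[, "depth"] + 1L
      p
    })
    k <- length(parts)
    if (k > 1L) {
      for (a in 1L:(k - 1L)) for (b in (a + 1L):k) {
        pa <- parts[[a]]; pb <- parts[[b]]
        sub <- outer(pa[, "depth"], pb[, "depth"], `+`)
        D[pa[, "idx"], pb[, "idx"]] <<- sub
        D[pb[, "idx"], pa[, "idx"]] <<- t(sub)
      }
    }
    do.call(rbind, parts)
  }
  rec(tree)
  D
}
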