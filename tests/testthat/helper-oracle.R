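# Independent oracles for the chart parser, built on exhaustive enumeration
# of CFC tree shapes.  A shape is an ordered tree whose nodes are leaf-parent
# ("L", one terminal under its lexical non-terminal), binary ("B") or
# contact ("C", two leaf-parent flanks around an inner subtree).  Summing
# rule probabilities over all label assignments of one shape is a direct
# product-sum over the shape; summing over shapes is exhaustive over parse
# trees.  Leaf distances for the consistency filter come from igraph
# shortest paths, independent of the package's own tree code.

# all shapes with m leaves (memoised; S(6) = 58)
oracle_shapes <- local({
  cache <- list()
  function(m) {
    key <- as.character(m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- list()
    if (m == 1L) {
      out <- list(list(type = "L"))
    } else {
      for (k in seq_len(m - 1L)) {
        for (s1 in oracle_shapes(k)) for (s2 in oracle_shapes(m - k))
          out[[length(out) + 1L]] <- list(type = "B", left = s1, right = s2)
      }
      if (m >= 4L) {
        for (inner in oracle_shapes(m - 2L))
          out[[length(out) + 1L]] <- list(type = "C", inner = inner)
      }
    }
    cache[[key]] <<- out
    out
  }
})

# leaf-to-leaf distances of a shape via igraph shortest paths
oracle_shape_leaf_dist <- function(shape) {
  edges <- integer(0)
  leaves <- integer(0)
  nid <- 0L
  walk <- function(s) {
    nid <<- nid + 1L
    me <- nid
    if (s$type == "L") {
      nid <<- nid + 1L            # terminal node under the lexical parent
      edges <<- c(edges, me, nid)
      leaves <<- c(leaves, nid)
    } else if (s$type == "B") {
      for (ch in list(s$left, s$right)) {
        cid <- walk(ch)
        edges <<- c(edges, me, cid)
      }
    } else {
      lf <- walk(list(type = "L")); edges <<- c(edges, me, lf)
      cid <- walk(s$inner); edges <<- c(edges, me, cid)
      rf <- walk(list(type = "L")); edges <<- c(edges, me, rf)
    }
    me
  }
  walk(shape)
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::distances(g)[leaves, leaves, drop = FALSE]
}

shape_has_contact <- function(shape) {
  if (shape$type == "C") return(TRUE)
  if (shape$type == "B")
    return(shape_has_contact(shape$left) || shape_has_contact(shape$right))
  FALSE
}

# leaf distances of an actual tree object via igraph (DFS leaf order =
# yield order)
oracle_tree_leaf_dist <- function(tree) {
  edges <- integer(0); leaves <- integer(0); nid <- 0L
  walk <- function(node) {
    nid <<- nid + 1L; me <- nid
    if (is.null(node$children)) { leaves <<- c(leaves, me); return(me) }
    for (ch in node$children) { cid <- walk(ch); edges <<- c(edges, me, cid) }
    me
  }
  walk(tree)
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::distances(g)[leaves, leaves, drop = FALSE]
}

oracle_shape_consistent <- function(shape, map, delta = 4L) {
  if (nrow(map$pairs) == 0L) return(TRUE)
  D <- oracle_shape_leaf_dist(shape)
  all(D[map$pairs] <= delta)
}

# product-sum (or max-product) of rule probabilities over all labelings of
# one shape; returns a named vector over non-terminals at the shape root.
# chars: terminal characters; lex_ones replaces lexical probabilities by
# their total mass (1 for a proper grammar).
oracle_shape_mass <- function(shape, chars, g, op = c("sum", "max"),
                              lex_ones = FALSE) {
  op <- match.arg(op)
  comb <- if (op == "sum") `+` else pmax
  r <- g$rules
  lexv <- function(ch) {
    v <- setNames(numeric(length(g$nts$lexical)), g$nts$lexical)
    if (lex_ones) { v[] <- 1; return(v) }
    rows <- which(r$kind == "lexical" & r$rhs1 == ch)
    for (rw in rows) v[r$lhs[rw]] <- comb(v[r$lhs[rw]], r$prob[rw])
    v
  }
  pos <- 0L
  look <- function(v, sym) if (sym %in% names(v)) v[[sym]] else 0
  rec <- function(s) {
    if (s$type == "L") {
      pos <<- pos + 1L
      return(lexv(chars[pos]))
    }
    out <- setNames(numeric(length(g$nts$structural)), g$nts$structural)
    if (s$type == "B") {
      L <- rec(s$left); R <- rec(s$right)
      rows <- which(r$kind == "branching")
      for (rw in rows) {
        t <- look(L, r$rhs1[rw]) * look(R, r$rhs2[rw])
        if (t != 0) out[r$lhs[rw]] <- comb(out[r$lhs[rw]], r$prob[rw] * t)
      }
    } else {
      lf <- rec(list(type = "L"))
      inn <- rec(s$inner)
      rf <- rec(list(type = "L"))
      rows <- which(r$kind == "contact")
      for (rw in rows) {
        t <- lf[r$rhs1[rw]] * inn[r$rhs2[rw]] * rf[r$rhs3[rw]]
        out[r$lhs[rw]] <- comb(out[r$lhs[rw]], r$prob[rw] * t)
      }
    }
    out
  }
  rec(shape)
}

oracle_inside <- function(g, x, map = NULL, op = "sum", lex_ones = FALSE) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  if (is.null(map)) map <- contact_map(n)
  total <- 0
  comb <- if (op == "sum") `+` else max
  for (shape in oracle_shapes(n)) {
    if (!oracle_shape_consistent(shape, map)) next
    v <- oracle_shape_mass(shape, chars, g, op = op, lex_ones = lex_ones)
    total <- comb(total, v[[g$nts$start]])
  }
  total
}

oracle_skeleton_mass <- function(g, n, map = NULL) {
  # summation identity: total mass over all sequences of length n
  sigma <- g$alphabet
  seqs <- do.call(expand.grid, rep(list(sigma), n))
  total <- 0
  for (k in seq_len(nrow(seqs))) {
    x <- paste(unlist(seqs[k, ]), collapse = "")
    total <- total + oracle_inside(g, x, map)
  }
  total
}

# explicit tree walk: probability of one parse tree as the product of its
# rule probabilities (used to validate Viterbi output trees)
tree_derivation_prob <- function(tree, g) {
  r <- g$rules
  prob_of <- function(lhs, rhs) {
    rows <- which(r$lhs == lhs &
                  r$rhs1 == rhs[1] &
                  (if (length(rhs) >= 2) !is.na(r$rhs2) & r$rhs2 == rhs[2]
                   else is.na(r$rhs2)) &
                  (if (length(rhs) >= 3) !is.na(r$rhs3) & r$rhs3 == rhs[3]
                   else is.na(r$rhs3)))
    if (length(rows) != 1L) stop("rule not found: ", lhs, " -> ",
                                 paste(rhs, collapse = " "))
    r$prob[rows]
  }
  walk <- function(node) {
    if (is.null(node$children)) return(1)
    rhs <- vapply(node$children, `[[`, "", "label")
    p <- prob_of(node$label, rhs)
    for (ch in node$children) p <- p * walk(ch)
    p
  }
  walk(tree)
}
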