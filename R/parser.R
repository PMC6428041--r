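# R-side surface of the CKY chart parser: inside probabilities (optionally
# contact-constrained), the skeleton-mass denominator used by contrastive
# estimation, and most-likely (Viterbi) parse trees.

# Integer encoding of a grammar for the C++ kernels.  Symbols are indexed
# 0-based: lexical non-terminals first, then structural.
compile_grammar <- function(g) {
  stopifnot(inherits(g, "cfc_grammar"))
  lex_names <- g$nts$lexical
  st_names <- g$nts$structural
  allv <- c(lex_names, st_names)
  r <- g$rules
  lex <- which(r$kind == "lexical")
  br <- which(r$kind == "branching")
  ct <- which(r$kind == "contact")
  list(
    n_lex = length(lex_names), n_nt = length(st_names),
    alphabet = g$alphabet,
    lex_names = lex_names, st_names = st_names,
    lex_lhs = match(r$lhs[lex], lex_names) - 1L,
    lex_term = match(r$rhs1[lex], g$alphabet) - 1L,
    br_lhs = match(r$lhs[br], st_names) - 1L,
    br_b = match(r$rhs1[br], allv) - 1L,
    br_c = match(r$rhs2[br], allv) - 1L,
    ct_lhs = match(r$lhs[ct], st_names) - 1L,
    ct_t = match(r$rhs1[ct], lex_names) - 1L,
    ct_w = match(r$rhs2[ct], st_names) - 1L,
    ct_u = match(r$rhs3[ct], lex_names) - 1L,
    lex_rows = lex, br_rows = br, ct_rows = ct,
    start = match(g$nts$start, st_names) - 1L)
}

encode_sequence <- function(x, alphabet) {
  if (length(x) == 1L && is.character(x)) x <- strsplit(x, "")[[1]]
  idx <- match(x, alphabet)
  if (anyNA(idx))
    stop("sequence contains symbol(s) outside the grammar alphabet: ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  idx - 1L
}

check_map_arg <- function(map, n) {
  if (is.null(map)) return(matrix(integer(0), ncol = 2L))
  stopifnot(inherits(map, "contact_map"))
  if (map$length != n)
    stop("contact map length (", map$length,
         ") does not match sequence length (", n, ")")
  cf <- suppressWarnings(is_cf_compatible(map))
  if (nrow(cf$crossing) > 0L)
    stop("contact map is not CF-compatible (crossing or overlapping pairs)")
  map$pairs
}

# low-level entry used by the trainer: precompiled grammar + theta vector
inside_enc <- function(enc, theta, seq_int, contacts, lex_ones = FALSE) {
  cpp_inside(seq_int, enc$n_lex, enc$n_nt,
             enc$lex_lhs, enc$lex_term, theta[enc$lex_rows],
             enc$br_lhs, enc$br_b, enc$br_c, theta[enc$br_rows],
             enc$ct_lhs, enc$ct_t, enc$ct_w, enc$ct_u, theta[enc$ct_rows],
             contacts, lex_ones, enc$start)
}

#' Inside (total parse) log-probability of a sequence
#'
#' Sums the probabilities of all parse trees yielding `x` under grammar
#' `g`; with a contact map, only trees consistent with the map (every
#' contact pair generated by a contact rule) contribute.
#'
#' @param g A `cfc_grammar`.
#' @param x Sequence: single string or character vector of residues.
#' @param map Optional `contact_map` of matching length; must be
#'   CF-compatible.
#' @return Natural-log probability; `-Inf` when no (consistent) parse
#'   exists.
#' @export
#' @examples
#' g <- toy_hairpin_grammar()
#' inside(g, "IGNVDLIA")
inside <- function(g, x, map = NULL) {
  enc <- compile_grammar(g)
  seq_int <- encode_sequence(x, g$alphabet)
  contacts <- check_map_arg(map, length(seq_int))
  inside_enc(enc, g$rules$prob, seq_int, contacts)
}

#' Skeleton mass: total probability of consistent tree shapes
#'
#' The probability, over all sequences of length `n`, of the set of
#' syntactic trees consistent with the contact map - the denominator of the
#' map-relative contrastive objective. Computed by the same constrained
#' chart with every lexical-rule probability replaced by its total emission
#' mass (1 for a proper grammar), so the value does not depend on the
#' lexical probabilities.
#'
#' @param g A `cfc_grammar`.
#' @param n Sequence length.
#' @param map Optional `contact_map` of length `n`.
#' @return Natural-log probability.
#' @export
skeleton_mass <- function(g, n, map = NULL) {
  enc <- compile_grammar(g)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  contacts <- check_map_arg(map, n)
  inside_enc(enc, g$rules$prob, rep(0L, n), contacts, lex_ones = TRUE)
}

#' Most likely parse tree (Viterbi)
#'
#' Returns an argmax-probability parse tree of `x`, restricted to
#' map-consistent trees when a contact map is supplied. Deterministic
#' tie-break: branching rules before contact rules, then rule-table order,
#' then leftmost split point.
#'
#' @inheritParams inside
#' @return A list with `tree` (a `parse_tree`, or `NULL` when no parse
#'   exists) and `logprob` (natural log; `-Inf` for no parse).
#' @export
viterbi <- function(g, x, map = NULL) {
  enc <- compile_grammar(g)
  seq_int <- encode_sequence(x, g$alphabet)
  n <- length(seq_int)
  contacts <- check_map_arg(map, n)
  theta <- g$rules$prob
  res <- cpp_viterbi(seq_int, enc$n_lex, enc$n_nt,
                     enc$lex_lhs, enc$lex_term, theta[enc$lex_rows],
                     enc$br_lhs, enc$br_b, enc$br_c, theta[enc$br_rows],
                     enc$ct_lhs, enc$ct_t, enc$ct_w, enc$ct_u,
                     theta[enc$ct_rows],
                     contacts, enc$start)
  if (!is.finite(res$logprob))
    return(list(tree = NULL, logprob = -Inf))
  syms <- g$alphabet[seq_int + 1L]
  bidx <- function(j, i, nt) ((j - 1L) * n + (i - 1L)) * enc$n_nt + nt + 1L
  build <- function(j, i, v) {
    # v: 0-based index over all non-terminals (lexical then structural)
    if (v < enc$n_lex) {
      stopifnot(j == 1L)
      return(tree_node(enc$lex_names[v + 1L], list(tree_node(syms[i]))))
    }
    nt <- v - enc$n_lex
    type <- res$btype[bidx(j, i, nt)]
    r <- res$brule[bidx(j, i, nt)] + 1L
    if (type == 1L) {
      k <- res$bsplit[bidx(j, i, nt)]
      tree_node(enc$st_names[nt + 1L], list(
        build(k, i, enc$br_b[r]),
        build(j - k, i + k, enc$br_c[r])))
    } else if (type == 2L) {
      e <- i + j - 1L
      tree_node(enc$st_names[nt + 1L], list(
        tree_node(enc$lex_names[enc$ct_t[r] + 1L], list(tree_node(syms[i]))),
        build(j - 2L, i + 1L, enc$n_lex + enc$ct_w[r]),
        tree_node(enc$lex_names[enc$ct_u[r] + 1L], list(tree_node(syms[e])))))
    } else {
      stop("internal error: missing backpointer")  # nocov
    }
  }
  tree <- build(n, 1L, enc$n_lex + enc$start)
  list(tree = tree, logprob = res$logprob)
}
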