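# Shared fixtures: tiny deterministic grammars and random proper covering
# grammars over a 2-letter alphabet.

# {s -> t t (1), t -> A (1)}: parses exactly "AA"
tiny_grammar <- function() {
  nts <- nt_inventory("t", "s")
  rules <- data.frame(lhs = c("t", "s"), rhs1 = c("A", "t"),
                      rhs2 = c(NA, "t"), rhs3 = NA_character_, prob = 1)
  suppressWarnings(cfc_grammar(aa_alphabet(), nts, rules))
}

# covering grammar over alphabet {A, B} with random proper theta
random_ab_grammar <- function(seed, n_lex = 2L, n_nt = 2L, contacts = TRUE) {
  set.seed(seed)
  nts <- nt_inventory(paste0("t", seq_len(n_lex)),
                      paste0("n", seq_len(n_nt)),
                      contact_capable = if (contacts)
                        paste0("n", seq_len(n_nt)) else character(0))
  g <- build_covering_grammar(aa_alphabet(c("A", "B")), nts)
  normalize_theta(g, runif(nrow(g$rules)))
}

# a fixed hand-built CFC tree: contact rule at the root around a 2-leaf core
# yield: A B B A; contact pair (1, 4) at leaf distance 4
contact_demo_tree <- function() {
  tree_node("s", list(
    tree_node("t1", list(tree_node("A"))),
    tree_node("n2", list(
      tree_node("t1", list(tree_node("B"))),
      tree_node("t2", list(tree_node("B"))))),
    tree_node("t2", list(tree_node("A")))))
}

random_nested_map <- function(n, max_pairs = 2L) {
  # a nested (CF-compatible) map with pairs of separation >= 3
  pairs <- matrix(integer(0), ncol = 2L)
  lo <- 1L; hi <- n
  while (nrow(pairs) < max_pairs && hi - lo >= 3L) {
    pairs <- rbind(pairs, c(lo, hi))
    lo <- lo + 1L; hi <- hi - 1L
  }
  suppressWarnings(contact_map(n, pairs))
}
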