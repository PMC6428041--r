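# Generative sampling from CFC grammars and synthetic benchmark
# construction: sequence/contact-map samples from a known grammar plus
# unigram background negatives, so the whole training/evaluation pipeline
# can be exercised without external data.

#' Sample a derivation from a grammar
#'
#' Expands the start symbol top-down, choosing at each step a rule for the
#' left-most non-terminal according to the rule probabilities. The
#' resulting parse tree is drawn with its derivation probability,
#' conditioned on the derivation depth staying within `max_depth`.
#'
#' @param g A proper `cfc_grammar`.
#' @param max_depth Maximum expansion depth before the draw is abandoned
#'   (guards against divergent grammars).
#' @return List with `sequence` (string), `tree` (a `parse_tree`) and
#'   `logprob` (natural log of the derivation probability), or `NULL` with
#'   a `"depth_overflow"` condition message when the depth cap is hit.
#' @export
sample_derivation <- function(g, max_depth = 50L) {
  stopifnot(inherits(g, "cfc_grammar"))
  r <- g$rules
  by_lhs <- split(seq_len(nrow(r)), r$lhs)
  logp <- 0
  overflow <- FALSE
  expand <- function(sym, depth) {
    if (overflow) return(NULL)
    if (sym %in% g$alphabet) return(tree_node(sym))
    if (depth > max_depth) {
      overflow <<- TRUE
      return(NULL)
    }
    idx <- by_lhs[[sym]]
    if (is.null(idx)) stop("non-terminal without rules: ", sym)
    pick <- idx[sample.int(length(idx), 1L, prob = r$prob[idx])]
    logp <<- logp + log(r$prob[pick])
    rhs <- c(r$rhs1[pick], r$rhs2[pick], r$rhs3[pick])
    rhs <- rhs[!is.na(rhs)]
    children <- lapply(rhs, expand, depth = depth + 1L)
    if (overflow) return(NULL)
    tree_node(sym, children)
  }
  tree <- expand(g$nts$start, 1L)
  if (overflow) {
    message("depth_overflow: derivation exceeded max_depth = ", max_depth)
    return(NULL)
  }
  list(sequence = paste(tree_yield(tree), collapse = ""), tree = tree,
       logprob = logp)
}

#' Contact map generated by a parse tree
#'
#' Every contact rule in the derivation generates one pair: the positions
#' of the two terminals emitted through its flanking lexical
#' non-terminals. The result is CF-compatible by construction and every
#' pair sits at leaf distance exactly 4 in the source tree.
#'
#' @param tree A `parse_tree` from a CFC grammar.
#' @return A `contact_map`.
#' @export
map_from_tree <- function(tree) {
  n <- length(tree_yield(tree))
  pairs <- matrix(integer(0), ncol = 2L)
  counter <- 0L
  walk <- function(node) {
    if (is_leaf(node)) {
      counter <<- counter + 1L
      return(counter)
    }
    first <- counter + 1L
    for (ch in node$children) walk(ch)
    last <- counter
    if (length(node$children) == 3L)  # contact rule: V_N -> V_T V_N V_T
      pairs <<- rbind(pairs, c(first, last))
    first
  }
  walk(tree)
  suppressWarnings(contact_map(n, pairs))
}

#' Hairpin-motif fixture grammar
#'
#' A small CFC grammar modeling a beta-hairpin-like protein motif: nested
#' contact rules generate the ladder of the stem between hydrophobic
#' residues (`h`), a two-residue loop of loop-friendly residues (`l`), and
#' optional bulges of arbitrary residues (`x`). With the defaults the most
#' common product is an 8-residue hairpin (three stem rungs plus the
#' loop); raising `stem_extend` lengthens the stem.
#'
#' @param stem_extend Probability of extending the stem by one more rung.
#' @param bulge Probability of inserting a bulge residue in the loop
#'   region.
#' @return A proper `cfc_grammar` with lexical non-terminals `h`, `l`,
#'   `x`, structural non-terminals `s` (start), `t`, `u`, `b`, and contact
#'   rules including `s -> h t h`.
#' @export
#' @examples
#' g <- toy_hairpin_grammar()
#' set.seed(7); sample_derivation(g)$sequence
toy_hairpin_grammar <- function(stem_extend = 0.15, bulge = 0.15) {
  stopifnot(stem_extend >= 0, stem_extend < 1, bulge >= 0, bulge < 1)
  hydro <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
  loopy <- c("D", "G", "N", "P", "S", "T")
  alphabet <- aa_alphabet()
  lex_probs <- function(favoured, w = 9) {
    p <- setNames(rep(1, length(alphabet)), alphabet)
    p[favoured] <- w
    p / sum(p)
  }
  h <- lex_probs(hydro)
  l <- lex_probs(loopy)
  x <- setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  lex <- rbind(
    data.frame(lhs = "h", rhs1 = alphabet, prob = as.numeric(h)),
    data.frame(lhs = "l", rhs1 = alphabet, prob = as.numeric(l)),
    data.frame(lhs = "x", rhs1 = alphabet, prob = as.numeric(x)))
  lex$rhs2 <- NA_character_; lex$rhs3 <- NA_character_
  struct <- data.frame(
    lhs  = c("s", "t", "t", "u", "b", "b"),
    rhs1 = c("h", "h", "h", "b", "l", "x"),
    rhs2 = c("t", "t", "u", "b", "l", "b"),
    rhs3 = c("h", "h", "h", NA, NA, NA),
    prob = c(1, stem_extend, 1 - stem_extend, 1, 1 - bulge, bulge))
  rules <- rbind(lex[, c("lhs", "rhs1", "rhs2", "rhs3", "prob")],
                 struct[, c("lhs", "rhs1", "rhs2", "rhs3", "prob")])
  nts <- nt_inventory(lexical = c("h", "l", "x"),
                      structural = c("s", "t", "u", "b"),
                      start = "s",
                      branch_capable = c("u", "b"),
                      contact_capable = c("s", "t"))
  cfc_grammar(alphabet, nts, rules)
}

#' Build a synthetic sequence/contact-map benchmark
#'
#' Positives are rejection-sampled derivations from the generator grammar
#' (optionally filtered to a target length), each paired with the contact
#' map its own parse tree generates. Negatives are i.i.d. draws from a
#' unigram background of the same lengths, so that discrimination measures
#' grammatical structure rather than composition alone.
#'
#' @param g Generator `cfc_grammar` (proper).
#' @param n_pos,n_neg Numbers of positive and negative sequences.
#' @param target_length Optional exact length filter for positives.
#' @param seed Integer seed; the benchmark is bit-reproducible from it.
#' @param background Named frequency vector for negatives. By default the
#'   empirical residue composition of the sampled positives (with one
#'   pseudocount per alphabet symbol) is used, so that positives and
#'   negatives are composition-matched and discrimination measures
#'   grammatical structure rather than composition; with no positives the
#'   package's amino-acid background is used.
#' @param max_attempts Rejection-sampling cap per accepted positive.
#' @return Object of class `synthetic_benchmark`: `positives` (a
#'   [training_sample()]), `negatives` (character vector), `generator`
#'   and `meta`.
#' @export
make_benchmark <- function(g, n_pos, n_neg, target_length = NULL, seed = 1L,
                           background = NULL, max_attempts = 1e4L) {
  stopifnot(inherits(g, "cfc_grammar"))
  set.seed(seed)
  positives <- vector("list", n_pos)
  if (n_pos > 0L) for (k in seq_len(n_pos)) {
    accepted <- FALSE
    for (attempt in seq_len(max_attempts)) {
      d <- withCallingHandlers(sample_derivation(g),
                               message = function(m) invokeRestart("muffleMessage"))
      if (is.null(d)) next
      if (!is.null(target_length) && nchar(d$sequence) != target_length) next
      positives[[k]] <- list(x = d$sequence, map = map_from_tree(d$tree),
                             tree = d$tree)
      accepted <- TRUE
      break
    }
    if (!accepted)
      stop("rejection sampling exceeded ", max_attempts, " attempts per item; ",
           "is target_length reachable under the generator grammar?")
  }
  lens <- if (n_pos > 0L) vapply(positives, function(p) nchar(p$x), 1L)
          else rep(if (is.null(target_length)) 10L else target_length, n_neg)
  if (is.null(background)) {
    if (n_pos > 0L) {
      res <- unlist(strsplit(vapply(positives, `[[`, "", "x"), ""))
      counts <- table(factor(res, levels = g$alphabet)) + 1  # pseudocounts
      background <- setNames(as.numeric(counts) / sum(counts), g$alphabet)
    } else {
      background <- default_null_model()$frequencies
    }
  }
  negatives <- character(n_neg)
  if (n_neg > 0L) for (k in seq_len(n_neg)) {
    len <- lens[((k - 1L) %% length(lens)) + 1L]
    negatives[k] <- paste(sample(names(background), len, replace = TRUE,
                                 prob = background), collapse = "")
  }
  structure(list(
    positives = if (n_pos > 0L) training_sample(positives) else NULL,
    negatives = negatives,
    generator = g,
    meta = list(seed = seed, n_pos = n_pos, n_neg = n_neg,
                target_length = target_length)),
    class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic benchmark: %d positives, %d negatives (seed %d)\n",
              x$meta$n_pos, x$meta$n_neg, x$meta$seed))
  invisible(x)
}

#' Write a benchmark to a directory
#'
#' Layout: `positives.fasta`, `negatives.fasta`, `maps/pos<k>.txt`
#' (pair-list contact maps) and `meta.json`.
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  pos <- if (is.null(bench$positives)) list() else bench$positives$items
  write_fasta(setNames(vapply(pos, `[[`, "", "x"),
                       sprintf("pos%03d", seq_along(pos))),
              file.path(dir, "positives.fasta"))
  write_fasta(setNames(bench$negatives,
                       sprintf("neg%03d", seq_along(bench$negatives))),
              file.path(dir, "negatives.fasta"))
  for (k in seq_along(pos))
    write_contact_map(pos[[k]]$map, file.path(dir, "maps",
                                              sprintf("pos%03d.txt", k)))
  jsonlite::write_json(bench$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a benchmark directory written by [write_benchmark()]
#' @param dir Benchmark directory.
#' @return List with `positives` (a [training_sample()] or `NULL`),
#'   `negatives` and `meta`.
#' @export
read_benchmark <- function(dir) {
  posf <- read_fasta(file.path(dir, "positives.fasta"))
  items <- lapply(seq_along(posf), function(k) list(
    x = unname(posf[k]),
    map = read_contact_map(file.path(dir, "maps",
                                     sprintf("pos%03d.txt", k)))))
  list(positives = if (length(items)) training_sample(items) else NULL,
       negatives = unname(read_fasta(file.path(dir, "negatives.fasta"))),
       meta = jsonlite::read_json(file.path(dir, "meta.json")))
}
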