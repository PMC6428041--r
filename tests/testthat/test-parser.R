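test_that("inside handles deterministic and impossible inputs", {
  g <- tiny_grammar()
  expect_equal(exp(inside(g, "AA")), 1.0)
  expect_identical(inside(g, "AAA"), -Inf)
  expect_identical(inside(g, "A"), -Inf)
  expect_error(inside(g, "AZ1"), "outside the grammar alphabet")
  expect_error(inside(g, ""), "empty")
})

test_that("inside agrees with exhaustive enumeration over shapes", {
  for (seed in 1:4) {
    g <- random_ab_grammar(seed)
    set.seed(seed + 50)
    for (n in c(3, 5, 6)) {
      x <- paste(sample(c("A", "B"), n, replace = TRUE), collapse = "")
      expect_equal(exp(inside(g, x)), oracle_inside(g, x), tolerance = 1e-12)
    }
  }
})

test_that("constrained inside sums exactly the map-consistent trees", {
  g <- random_ab_grammar(7)
  # empty map: identical to the unconstrained inside
  expect_identical(inside(g, "ABBA", contact_map(4)), inside(g, "ABBA"))
  # one pair but no contact rules: no consistent tree
  gcnf <- random_ab_grammar(7, contacts = FALSE)
  m <- suppressWarnings(contact_map(5, rbind(c(1, 5))))
  expect_identical(inside(gcnf, "ABBBA", m), -Inf)
  # enumeration oracle with the consistency filter
  set.seed(70)
  for (seed in 1:4) {
    g <- random_ab_grammar(seed + 20)
    for (n in 4:6) {
      x <- paste(sample(c("A", "B"), n, replace = TRUE), collapse = "")
      m <- random_nested_map(n, max_pairs = 2L)
      expect_equal(exp(inside(g, x, m)), oracle_inside(g, x, m),
                   tolerance = 1e-12)
    }
  }
})

test_that("crossing maps and length mismatches are rejected", {
  g <- random_ab_grammar(1)
  bad <- contact_map(8, rbind(c(1, 5), c(3, 8)))
  expect_error(inside(g, "ABABABAB", bad), "not CF-compatible")
  expect_error(inside(g, "ABA", contact_map(5)), "does not match")
})

test_that("skeleton mass is lexical-theta-invariant and satisfies the summation identity", {
  g <- random_ab_grammar(13)
  m <- random_nested_map(5, max_pairs = 1L)
  base <- skeleton_mass(g, 5, m)
  # perturbing only lexical probabilities leaves the value unchanged
  g2 <- g
  lex <- g2$rules$kind == "lexical"
  set.seed(2)
  w <- g2$rules$prob
  w[lex] <- runif(sum(lex))
  g2 <- normalize_theta(g2, w)
  expect_identical(skeleton_mass(g2, 5, m), base)
  # identity: mass equals the sum of constrained insides over all sequences
  for (n in c(3, 5)) {
    mm <- random_nested_map(n, max_pairs = 1L)
    seqs <- apply(do.call(expand.grid, rep(list(c("A", "B")), n)), 1,
                  paste, collapse = "")
    total <- sum(vapply(seqs, function(x) exp(inside(g, x, mm)), 0))
    expect_equal(exp(skeleton_mass(g, n, mm)), total, tolerance = 1e-9)
  }
  # single-skeleton case
  g1 <- tiny_grammar()
  expect_equal(exp(skeleton_mass(g1, 2)), 1.0)
})

test_that("viterbi returns the argmax tree with its exact derivation probability", {
  # deterministic grammar: tree probability equals inside probability
  g <- tiny_grammar()
  v <- viterbi(g, "AA")
  expect_equal(v$logprob, inside(g, "AA"))
  expect_identical(format_tree(v$tree), "(s (t A) (t A))")

  for (seed in 1:4) {
    g <- random_ab_grammar(seed + 40)
    set.seed(seed)
    x <- paste(sample(c("A", "B"), 5, replace = TRUE), collapse = "")
    v <- viterbi(g, x)
    expect_equal(exp(v$logprob), oracle_inside(g, x, op = "max"),
                 tolerance = 1e-12)
    # the returned tree's own derivation product matches the reported value
    expect_equal(tree_derivation_prob(v$tree, g), exp(v$logprob),
                 tolerance = 1e-12)
    expect_identical(paste(tree_yield(v$tree), collapse = ""), x)
    # constrained viterbi yields a consistent skeleton
    m <- random_nested_map(5, max_pairs = 1L)
    vc <- viterbi(g, x, m)
    if (!is.null(vc$tree)) {
      expect_true(is_consistent(skeleton(vc$tree), m, 4))
      expect_lte(vc$logprob, v$logprob + 1e-12)
    }
  }
})

test_that("no-parse inputs give an explicit no-parse result", {
  gcnf <- random_ab_grammar(3, contacts = FALSE)
  m <- suppressWarnings(contact_map(5, rbind(c(1, 5))))
  v <- viterbi(gcnf, "ABABA", m)
  expect_null(v$tree)
  expect_identical(v$logprob, -Inf)
})

test_that("probability ordering invariants hold across random instances", {
  set.seed(99)
  for (seed in 1:6) {
    g <- random_ab_grammar(seed + 60)
    n <- sample(4:7, 1)
    x <- paste(sample(c("A", "B"), n, replace = TRUE), collapse = "")
    m1 <- random_nested_map(n, max_pairs = 1L)
    m2 <- random_nested_map(n, max_pairs = 2L)
    li <- inside(g, x)
    lc1 <- inside(g, x, m1)
    lc2 <- inside(g, x, m2)
    expect_lte(li, 0)
    expect_lte(lc1, li)
    # monotonicity: adding a pair never increases the constrained inside
    if (nrow(m2$pairs) > nrow(m1$pairs)) expect_lte(lc2, lc1)
    # skeleton mass dominates any single sequence's constrained inside
    expect_gte(skeleton_mass(g, n, m1) + 1e-12, lc1)
    vv <- viterbi(g, x)
    expect_lte(vv$logprob, li + 1e-12)
  }
})

test_that("total sequence probability stays within 1 for proper grammars", {
  g <- random_ab_grammar(8)
  total <- 0
  for (n in 1:6) {
    seqs <- apply(do.call(expand.grid, rep(list(c("A", "B")), n)), 1,
                  paste, collapse = "")
    total <- total + sum(vapply(seqs, function(x) {
      v <- inside(g, x)
      if (is.finite(v)) exp(v) else 0
    }, 0))
  }
  expect_lte(total, 1 + 1e-9)
})

test_that("runtime grows polynomially, about cubically, with sequence length", {
  nts <- nt_inventory(paste0("l", 1:3), paste0("v", 0:3),
                      contact_capable = paste0("v", 0:3))
  g <- build_covering_grammar(aa_alphabet(), nts)
  enc <- compile_grammar(g)
  theta <- g$rules$prob
  no_map <- matrix(integer(0), ncol = 2L)
  set.seed(6)
  times <- vapply(c(16L, 32L, 64L), function(n) {
    s <- sample(0L:19L, n, replace = TRUE)
    inside_enc(enc, theta, s, no_map)  # warm up
    reps <- max(5L, 640L %/% n)
    t0 <- proc.time()[["elapsed"]]
    for (r in seq_len(reps)) inside_enc(enc, theta, s, no_map)
    (proc.time()[["elapsed"]] - t0) / reps
  }, 0)
  slope <- coef(lm(log(times) ~ log(c(16, 32, 64))))[2]
  # cubic predicts 3; wide bounds tolerate timer noise and constant overheads
  expect_gt(slope, 1.2)
  expect_lt(slope, 4.8)
})

test_that("long sequences stay numerically stable", {
  nts <- nt_inventory(paste0("l", 1:3), paste0("v", 0:3),
                      contact_capable = paste0("v", 0:3))
  g <- build_covering_grammar(aa_alphabet(), nts)
  set.seed(4)
  x <- paste(sample(aa_alphabet(), 120, replace = TRUE), collapse = "")
  lp <- inside(g, x)
  expect_true(is.finite(lp))
  expect_lt(lp, -100)  # far below linear-space underflow territory
  v <- viterbi(g, x)
  expect_true(is.finite(v$logprob))
  expect_lte(v$logprob, lp)
})
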