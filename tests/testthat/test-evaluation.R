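test_that("null-model scores follow the decimal-log convention", {
  uni <- null_model(setNames(rep(1 / 20, 20), aa_alphabet()))
  x <- "ACDEFGHIKL"
  expect_equal(null_logprob(x, uni), -10 * log10(20), tolerance = 1e-12)
  # a probability ratio of 1000 corresponds to a score of exactly 3
  lp_grammar <- null_logprob(x, uni) + log10(1000)
  expect_equal(lp_grammar - null_logprob(x, uni), 3, tolerance = 1e-12)
  # non-uniform 3-residue case against the direct product
  f <- null_model(c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(null_logprob("ABC", f), log10(0.5 * 0.3 * 0.2),
               tolerance = 1e-12)
  expect_error(null_logprob("AXZ", f), "not covered")
  expect_error(null_model(c(A = 0.5, B = 0.3)), "sum to 1")
  nm <- default_null_model()
  expect_equal(sum(nm$frequencies), 1, tolerance = 1e-12)
  expect_setequal(names(nm$frequencies), aa_alphabet())
})

test_that("a grammar that factorizes like the null model scores zero", {
  # fixed-length chain emitting i.i.d. residues with the null frequencies
  nm <- null_model(c(A = 0.5, B = 0.3, C = 0.2))
  nts <- nt_inventory("l", c("s", "d"))
  rules <- rbind(
    data.frame(lhs = "l", rhs1 = c("A", "B", "C"), rhs2 = NA, rhs3 = NA,
               prob = c(0.5, 0.3, 0.2)),
    data.frame(lhs = "s", rhs1 = "l", rhs2 = "d", rhs3 = NA, prob = 1),
    data.frame(lhs = "d", rhs1 = "l", rhs2 = "l", rhs3 = NA, prob = 1))
  g <- cfc_grammar(aa_alphabet(c("A", "B", "C")), nts, rules)
  for (x in c("ABC", "CCA", "BBB"))
    expect_equal(score_sequence(g, x, nm), 0, tolerance = 1e-9)
  expect_identical(score_sequence(g, "AB", nm), -Inf)
})

test_that("ensemble scores are arithmetic means of member scores", {
  nm <- default_null_model()
  g1 <- toy_hairpin_grammar()
  g2 <- toy_hairpin_grammar(stem_extend = 0.4)
  x <- "LIGNSDVA"
  s1 <- score_sequence(g1, x, nm)
  s2 <- score_sequence(g2, x, nm)
  expect_equal(ensemble_score(list(g1), x, nm), s1)
  expect_equal(ensemble_score(list(g1, g1, g1), x, nm), s1)
  expect_equal(ensemble_score(list(g1, g2), x, nm), (s1 + s2) / 2,
               tolerance = 1e-12)
})

test_that("average precision matches hand-computed step sums", {
  # perfect separation
  expect_equal(recall_precision_ap(c(5, 4), c(1, 0))$ap, 1.0)
  # all positives ranked last
  expect_equal(recall_precision_ap(rep(0, 3), rep(1, 97))$ap, 3 / 100,
               tolerance = 1e-12)
  # 6-item worked example: pos {5,3,1}, neg {4,2,0}
  # steps: R=1/3 P=1; R=2/3 P=2/3; R=1 P=3/5 -> AP = 1/3 + 2/9 + 1/5
  res <- recall_precision_ap(c(5, 3, 1), c(4, 2, 0))
  expect_equal(res$ap, 1 / 3 + 2 / 9 + 1 / 5, tolerance = 1e-12)
  expect_identical(nrow(res$curve), 6L)
})

test_that("AP is invariant under strictly monotone score transforms", {
  set.seed(12)
  for (rep in 1:5) {
    pos <- rnorm(6); neg <- rnorm(20, -1)
    ap0 <- recall_precision_ap(pos, neg)$ap
    expect_equal(recall_precision_ap(exp(pos), exp(neg))$ap, ap0)
    expect_equal(recall_precision_ap(3 * pos + 7, 3 * neg + 7)$ap, ap0)
  }
  # ties share one threshold step
  tied <- recall_precision_ap(c(1, 1), c(1, 0))
  expect_equal(tied$ap, 2 / 3, tolerance = 1e-12)
})

test_that("descriptive metrics score tree-derived contact predictions", {
  # tree whose contact pairs exactly equal the reference map
  tr <- tree_node("s", list(
    tree_node("h", list(tree_node("L"))),
    tree_node("t", list(
      tree_node("h", list(tree_node("I"))),
      tree_node("u", list(
        tree_node("b", list(tree_node("l", list(tree_node("G"))),
                            tree_node("l", list(tree_node("N"))))),
        tree_node("b", list(tree_node("l", list(tree_node("S"))),
                            tree_node("l", list(tree_node("D"))))))),
      tree_node("h", list(tree_node("V"))))),
    tree_node("h", list(tree_node("A")))))
  n <- length(tree_yield(tr))
  expect_identical(n, 8L)
  full <- contact_map(8, rbind(c(1, 8), c(2, 7)))
  rep1 <- descriptive_metrics(tr, training_map = full, full_map = full)
  expect_equal(rep1$recall_at_delta, 1.0)
  expect_equal(rep1$precision_at_delta, 1.0)
  expect_equal(rep1$ap_over_deltas, 1.0)

  # CNF tree: no leaf pair with separation >= 3 is within delta = 4
  cnf <- tree_node("s", list(
    tree_node("d", list(
      tree_node("l", list(tree_node("A"))),
      tree_node("l", list(tree_node("B"))))),
    tree_node("d", list(
      tree_node("l", list(tree_node("C"))),
      tree_node("l", list(tree_node("D")))))))
  repc <- descriptive_metrics(cnf, training_map = contact_map(4, rbind(c(1, 4))),
                              full_map = contact_map(4, rbind(c(1, 4))))
  expect_equal(repc$recall_at_delta, 0)
  expect_identical(repc$n_predicted, 0L)

  # 8-leaf tree, 3-pair reference map, hand-counted metrics:
  # predictions at delta=4 are (1,8) and (2,7); reference {(1,8),(2,7),(3,6)}
  full3 <- contact_map(8, rbind(c(1, 8), c(2, 7), c(3, 6)))
  rep3 <- descriptive_metrics(tr, training_map = full3, full_map = full3)
  expect_equal(rep3$recall_at_delta, 2 / 3, tolerance = 1e-12)
  expect_equal(rep3$precision_at_delta, 1.0)
  expect_identical(rep3$n_predicted, 2L)
  expect_true(all(rep3$local$local_ap[c(1, 2, 7, 8)] == 1))

  # empty reference map: undefined, not zero
  expect_message(
    rep0 <- descriptive_metrics(tr, training_map = NULL,
                                full_map = contact_map(8)),
    "undefined")
  expect_true(is.na(rep0$precision_at_delta))
  expect_true(is.na(rep0$ap_over_deltas))
})

test_that("recall at delta is non-decreasing in delta", {
  g <- toy_hairpin_grammar()
  set.seed(14)
  d <- sample_derivation(g)
  m <- map_from_tree(d$tree)
  if (nrow(m$pairs) > 0) {
    vals <- vapply(4:8, function(dd)
      descriptive_metrics(d$tree, training_map = m, delta = dd)$recall_at_delta, 0)
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("sliding-window scan locates a planted motif", {
  nm <- default_null_model()
  g <- toy_hairpin_grammar(stem_extend = 0.65)
  set.seed(41)
  motif <- NULL
  repeat {
    d <- sample_derivation(g)
    if (nchar(d$sequence) == 16) { motif <- d$sequence; break }
  }
  bg <- function(n) paste(sample(names(nm$frequencies), n, replace = TRUE,
                                 prob = nm$frequencies), collapse = "")
  long <- paste0(bg(20), motif, bg(20))
  res <- scan_sequence(long, g, nm, window_min = 14, window_max = 18,
                       threshold = 2)
  expect_gt(nrow(res$hits), 0)
  top <- res$windows[which.max(res$windows$score), ]
  # the best window overlaps the plant site (positions 21..36)
  expect_lt(top$start, 37)
  expect_gt(top$start + top$width - 1, 20)

  # scan of a window-sized sequence reduces to score_sequence
  one <- scan_sequence(motif, g, nm, window_min = 16, window_max = 16,
                       threshold = -Inf)
  expect_identical(nrow(one$windows), 1L)
  expect_equal(one$windows$score, score_sequence(g, motif, nm))

  # sequence shorter than the window: empty result
  short <- scan_sequence("ACDEF", g, nm, window_min = 16, window_max = 18)
  expect_identical(nrow(short$windows), 0L)
})

test_that("cross-validation enumerates all validation/test combinations", {
  sp <- cv_split(8, folds = 8, seed = 2)
  expect_length(sp, 56L)
  for (s in sp) {
    expect_length(s$train, 6L)
    expect_length(s$validation, 1L)
    expect_length(s$test, 1L)
    expect_setequal(c(s$train, s$validation, s$test), 1:8)
  }
  combos <- unique(t(vapply(sp, function(s)
    c(s$fold_validation, s$fold_test), c(0, 0))))
  expect_identical(nrow(combos), 56L)
  expect_identical(cv_split(24, seed = 9)[[1]]$train,
                   cv_split(24, seed = 9)[[1]]$train)
  expect_error(cv_split(5, folds = 8), "at least")
})
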