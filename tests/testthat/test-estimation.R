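make_sample <- function(g, n_items, seed, with_maps = TRUE) {
  set.seed(seed)
  items <- lapply(seq_len(n_items), function(k) {
    d <- sample_derivation(g)
    list(x = d$sequence,
         map = if (with_maps) map_from_tree(d$tree) else NULL)
  })
  training_sample(items)
}

test_that("the ML objective matches direct inside computations", {
  g <- tiny_grammar()
  s <- training_sample(list(list(x = "AA")))
  expect_equal(objective_ml(g, s), 0)  # generates exactly the sample
  s2 <- training_sample(list(list(x = "AA"), list(x = "AAA")))
  expect_identical(objective_ml(g, s2), -Inf)

  # random grammars against the enumeration oracle
  for (seed in 1:3) {
    gr <- random_ab_grammar(seed + 80)
    set.seed(seed)
    items <- lapply(1:3, function(k) {
      n <- sample(4:6, 1)
      x <- paste(sample(c("A", "B"), n, replace = TRUE), collapse = "")
      list(x = x, map = random_nested_map(n, max_pairs = 1L))
    })
    s3 <- training_sample(items)
    expected <- mean(vapply(items, function(it)
      log(oracle_inside(gr, it$x, it$map)), 0))
    expect_equal(objective_ml(gr, s3), expected, tolerance = 1e-9)
  }
})

test_that("with empty maps the ML objective is the plain log-likelihood", {
  gr <- random_ab_grammar(5)
  set.seed(5)
  items <- lapply(1:4, function(k)
    list(x = paste(sample(c("A", "B"), 5, replace = TRUE), collapse = "")))
  s <- training_sample(items)
  plain <- mean(vapply(items, function(it) inside(gr, it$x), 0))
  expect_equal(objective_ml(gr, s), plain, tolerance = 1e-12)
})

test_that("the map-relative contrastive objective is a normalized log-ratio", {
  # single-terminal alphabet: every sequence is the whole neighborhood
  nts <- nt_inventory("t", c("s", "v"), contact_capable = c("s", "v"))
  g1 <- build_covering_grammar(aa_alphabet("A"), nts)
  m <- suppressWarnings(contact_map(5, rbind(c(1, 5))))
  s1 <- training_sample(list(list(x = "AAAAA")), shared_map = m)
  expect_equal(objective_ce_m(g1, s1), 0, tolerance = 1e-12)

  # general case: value <= 0, equal to the brute-force ratio over Sigma^n
  gr <- random_ab_grammar(17)
  set.seed(17)
  xs <- replicate(3, paste(sample(c("A", "B"), 5, replace = TRUE), collapse = ""))
  m5 <- random_nested_map(5, max_pairs = 1L)
  s <- training_sample(lapply(xs, function(x) list(x = x)), shared_map = m5)
  val <- objective_ce_m(gr, s)
  expect_lte(val, 1e-12)
  allx <- apply(do.call(expand.grid, rep(list(c("A", "B")), 5)), 1,
                paste, collapse = "")
  denom <- sum(vapply(allx, function(x) oracle_inside(gr, x, m5), 0))
  expected <- mean(vapply(xs, function(x)
    log(oracle_inside(gr, x, m5)), 0)) - log(denom)
  expect_equal(val, expected, tolerance = 1e-9)

  expect_error(objective_ce_m(gr, training_sample(lapply(xs, function(x)
    list(x = x)))), "shared_map")
})

test_that("the sequence-relative contrastive objective is zero iff maps are empty", {
  gr <- random_ab_grammar(23)
  set.seed(23)
  xs <- replicate(3, paste(sample(c("A", "B"), 5, replace = TRUE), collapse = ""))
  s_empty <- training_sample(lapply(xs, function(x) list(x = x)))
  expect_identical(objective_ce_x(gr, s_empty), 0)

  items <- lapply(xs, function(x)
    list(x = x, map = random_nested_map(5, max_pairs = 1L)))
  s <- training_sample(items)
  val <- objective_ce_x(gr, s)
  expect_lte(val, 0)
  expected <- mean(vapply(items, function(it)
    log(oracle_inside(gr, it$x, it$map)) - log(oracle_inside(gr, it$x)), 0))
  expect_equal(val, expected, tolerance = 1e-9)

  # unparsable sequence: -Inf with a diagnostic
  g0 <- tiny_grammar()
  s_bad <- training_sample(list(list(x = "AC")))
  expect_message(res <- objective_ce_x(g0, s_bad), "zero unconstrained")
  expect_identical(res, -Inf)
})

test_that("zero-generation GA returns the best of the initial population", {
  g <- toy_hairpin_grammar()
  s <- make_sample(g, 4, seed = 31)
  cfg <- ga_config(population_size = 10L, generations = 0L, seed = 7L)
  fit <- train_ga(g, s, cfg)
  expect_true(validate_properness(fit$grammar)$proper)
  # the starting grammar is seeded into the population
  expect_gte(fit$objective, objective_ml(g, s) - 1e-9)
  expect_identical(nrow(fit$trace), 1L)
})

test_that("GA training is reproducible and monotone in best-so-far", {
  g <- toy_hairpin_grammar()
  s <- make_sample(g, 4, seed = 37)
  g0 <- normalize_theta(g, rep(1, nrow(g$rules)))  # uniform start
  cfg <- ga_config(population_size = 14L, generations = 12L, seed = 11L)
  fit1 <- train_ga(g0, s, cfg)
  fit2 <- train_ga(g0, s, cfg)
  expect_identical(fit1$grammar$rules$prob, fit2$grammar$rules$prob)
  expect_true(all(diff(fit1$trace$best) >= 0))
  expect_true(validate_properness(fit1$grammar)$proper)
  expect_gte(fit1$objective, objective_ml(g0, s) - 1e-9)
})

test_that("GA reaches the analytic optimum of a one-parameter grammar", {
  # t -> A (p) | B (1-p); sample {AA, AB} has ML optimum p = 3/4
  nts <- nt_inventory("t", "s")
  rules <- data.frame(lhs = c("t", "t", "s"), rhs1 = c("A", "B", "t"),
                      rhs2 = c(NA, NA, "t"), rhs3 = NA_character_,
                      prob = c(0.5, 0.5, 1))
  g <- cfc_grammar(aa_alphabet(c("A", "B")), nts, rules)
  s <- training_sample(list(list(x = "AA"), list(x = "AB")))
  # dense grid over the single free parameter as the oracle
  grid <- seq(0.001, 0.999, by = 0.001)
  obj <- vapply(grid, function(p) (2 * log(p) + log(p) + log(1 - p)) / 2, 0)
  p_star <- grid[which.max(obj)]
  expect_equal(p_star, 0.75, tolerance = 1e-6)
  cfg <- ga_config(population_size = 30L, generations = 60L, seed = 3L)
  fit <- train_ga(g, s, cfg)
  p_hat <- fit$grammar$rules$prob[1]
  expect_equal(p_hat, 0.75, tolerance = 0.03)
  expect_gte(fit$objective, max(obj) - 5e-3)
})

test_that("unparsable populations abort with guidance", {
  g <- tiny_grammar()
  s <- training_sample(list(list(x = "ACCA")))
  expect_error(train_ga(g, s, ga_config(population_size = 4L,
                                        generations = 1L)),
               "entire initial population")
})
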