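# Training objectives and the Pittsburgh-style genetic algorithm.  Each GA
# individual is a full vector of non-negative rule weights, decoded into a
# proper grammar by per-lhs normalization, so every individual in every
# generation is a valid probabilistic grammar.

#' Assemble a training sample
#'
#' @param items List of items, each a list with elements `x` (sequence
#'   string) and `map` (a [contact_map()], or `NULL` for no constraints).
#' @param shared_map Optional single `contact_map` shared by all items, as
#'   required by the map-relative contrastive objective; implies equal
#'   sequence lengths.
#' @return An object of class `training_sample`.
#' @export
training_sample <- function(items, shared_map = NULL) {
  stopifnot(is.list(items), length(items) > 0L)
  items <- lapply(items, function(it) {
    stopifnot(!is.null(it$x))
    if (is.null(it$map)) it$map <- contact_map(nchar(it$x))
    stopifnot(inherits(it$map, "contact_map"))
    if (nchar(it$x) != it$map$length)
      stop("sequence/map length mismatch in training item")
    cf <- suppressWarnings(is_cf_compatible(it$map))
    if (nrow(cf$crossing) > 0L)
      stop("training map is not CF-compatible")
    it
  })
  if (!is.null(shared_map)) {
    stopifnot(inherits(shared_map, "contact_map"))
    lens <- vapply(items, function(it) nchar(it$x), 1L)
    if (any(lens != shared_map$length))
      stop("shared_map requires all sequences to have its length")
  }
  structure(list(items = items, shared_map = shared_map),
            class = "training_sample")
}

#' @export
print.training_sample <- function(x, ...) {
  lens <- vapply(x$items, function(it) nchar(it$x), 1L)
  npairs <- vapply(x$items, function(it) nrow(it$map$pairs), 1L)
  cat(sprintf("Training sample: %d item(s), lengths %d-%d, %d contact pair(s) total%s\n",
              length(x$items), min(lens), max(lens), sum(npairs),
              if (!is.null(x$shared_map)) sprintf(", shared map with %d pair(s)",
                                                  nrow(x$shared_map$pairs)) else ""))
  invisible(x)
}

# shared machinery: per-item constrained / unconstrained log-probabilities
sample_logprobs <- function(enc, theta, sample, constrained = TRUE) {
  vapply(sample$items, function(it) {
    seq_int <- encode_sequence(it$x, enc$alphabet)
    contacts <- if (constrained) it$map$pairs else matrix(integer(0), ncol = 2L)
    inside_enc(enc, theta, seq_int, contacts)
  }, 0)
}

#' Maximum-likelihood objective
#'
#' Mean, over training items, of the log-probability of the set of parse
#' trees of the sequence consistent with its contact map. With all-empty
#' maps this is the plain mean sequence log-likelihood.
#'
#' @param g A `cfc_grammar`.
#' @param sample A [training_sample()].
#' @return Mean natural-log probability (`-Inf` when any item is
#'   unparsable under its constraints).
#' @export
objective_ml <- function(g, sample) {
  stopifnot(inherits(sample, "training_sample"))
  enc <- compile_grammar(g)
  mean(sample_logprobs(enc, g$rules$prob, sample, constrained = TRUE))
}

#' Map-relative contrastive objective
#'
#' Mean log-probability of each item's consistent trees, minus the
#' log skeleton mass of the shared contact map (the probability of all
#' consistent tree shapes over any sequence of the common length). Always
#' `<= 0`; maximised when the grammar concentrates the mass it spends on
#' map-consistent shapes onto the sample sequences.
#'
#' @inheritParams objective_ml
#' @return Mean natural-log probability ratio.
#' @export
objective_ce_m <- function(g, sample) {
  stopifnot(inherits(sample, "training_sample"))
  if (is.null(sample$shared_map))
    stop("the map-relative contrastive objective requires a shared_map")
  enc <- compile_grammar(g)
  n <- sample$shared_map$length
  smap <- sample$shared_map$pairs
  num <- vapply(sample$items, function(it) {
    inside_enc(enc, g$rules$prob, encode_sequence(it$x, enc$alphabet), smap)
  }, 0)
  denom <- inside_enc(enc, g$rules$prob, rep(0L, n), smap, lex_ones = TRUE)
  mean(num) - denom
}

#' Sequence-relative contrastive objective
#'
#' Mean, over items, of the log-ratio between the probability of the
#' sequence's map-consistent trees and the probability of all its trees.
#' Always `<= 0`; exactly 0 when every map is empty. Maximised when parse
#' trees of sample sequences are consistent with their contact maps.
#'
#' @inheritParams objective_ml
#' @return Mean natural-log probability ratio; `-Inf` (with a diagnostic
#'   message) when a sequence has probability 0.
#' @export
objective_ce_x <- function(g, sample) {
  stopifnot(inherits(sample, "training_sample"))
  enc <- compile_grammar(g)
  num <- sample_logprobs(enc, g$rules$prob, sample, constrained = TRUE)
  den <- sample_logprobs(enc, g$rules$prob, sample, constrained = FALSE)
  if (any(!is.finite(den))) {
    message("sequence(s) with zero unconstrained probability at item(s): ",
            paste(which(!is.finite(den)), collapse = ", "))
    return(-Inf)
  }
  mean(num - den)
}

objective_fun <- function(objective = c("ML", "CE_m", "CE_X")) {
  objective <- match.arg(objective)
  switch(objective,
         ML = objective_ml, CE_m = objective_ce_m, CE_X = objective_ce_x)
}

#' Genetic-algorithm configuration
#'
#' Defaults: population 100, 500 generations, tournament selection of size
#' 3, uniform crossover applied to 80% of offspring pairs, per-gene
#' multiplicative log-normal mutation (`w <- w * exp(N(0, sigma))`) with
#' probability 0.1 and log-scale standard deviation 1, elitism 2.
#' Multiplicative mutation matches the scale of rule weights, which span
#' orders of magnitude once normalized into probabilities.
#'
#' @param population_size Number of individuals (>= 2).
#' @param generations Number of generations (0 returns the best random
#'   initial individual).
#' @param crossover_rate Probability that an offspring pair undergoes
#'   uniform crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sigma Log-scale standard deviation of the multiplicative
#'   weight perturbation.
#' @param elitism Number of best individuals copied unchanged.
#' @param tournament_size Tournament size for parent selection.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param objective One of `"ML"`, `"CE_m"`, `"CE_X"`.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, generations = 500L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      mutation_sigma = 1, elitism = 2L,
                      tournament_size = 3L, seed = 1L,
                      objective = c("ML", "CE_m", "CE_X")) {
  objective <- match.arg(objective)
  stopifnot(population_size >= 2L, generations >= 0L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_sigma > 0, elitism >= 0L,
            elitism < population_size, tournament_size >= 1L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sigma = mutation_sigma,
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed), objective = objective),
            class = "ga_config")
}

# decode a weight chromosome into proper probabilities; an all-zero lhs
# group (possible after mutation clamping) falls back to uniform
decode_chromosome <- function(w, lhs_index, lhs_sizes) {
  tot <- vapply(lhs_index, function(idx) sum(w[idx]), 0)
  for (k in seq_along(lhs_index)) {
    idx <- lhs_index[[k]]
    if (tot[k] > 0) w[idx] <- w[idx] / tot[k]
    else w[idx] <- 1 / length(idx)
  }
  w
}

# objective evaluated on a theta vector with precompiled grammar
eval_theta <- function(theta, enc, sample, objective) {
  if (objective == "ML") {
    mean(sample_logprobs(enc, theta, sample, constrained = TRUE))
  } else if (objective == "CE_m") {
    smap <- sample$shared_map$pairs
    n <- sample$shared_map$length
    num <- vapply(sample$items, function(it)
      inside_enc(enc, theta, encode_sequence(it$x, enc$alphabet), smap), 0)
    mean(num) - inside_enc(enc, theta, rep(0L, n), smap, lex_ones = TRUE)
  } else {
    num <- sample_logprobs(enc, theta, sample, constrained = TRUE)
    den <- sample_logprobs(enc, theta, sample, constrained = FALSE)
    if (any(!is.finite(den))) return(-Inf)
    mean(num - den)
  }
}

#' Train rule probabilities with a genetic algorithm
#'
#' Pittsburgh-style evolution: each individual is a complete vector of rule
#' weights over the fixed rule set of `g0`, decoded into a proper grammar
#' by per-lhs normalization. The initial population contains `g0` itself
#' plus random individuals; elitism makes the best objective value
#' non-decreasing across generations.
#'
#' @param g0 Starting `cfc_grammar` (fixes the rule set; its theta seeds
#'   one individual).
#' @param sample A [training_sample()].
#' @param cfg A [ga_config()].
#' @return A list with `grammar` (trained, proper), `objective` (its
#'   objective value), `trace` (data frame of best/mean objective per
#'   generation) and `config`.
#' @export
train_ga <- function(g0, sample, cfg = ga_config()) {
  stopifnot(inherits(g0, "cfc_grammar"), inherits(sample, "training_sample"),
            inherits(cfg, "ga_config"))
  if (cfg$objective == "CE_m" && is.null(sample$shared_map))
    stop("objective CE_m requires a training sample with a shared_map")
  enc <- compile_grammar(g0)
  nrules <- nrow(g0$rules)
  lhs_fac <- factor(g0$rules$lhs)
  lhs_index <- split(seq_len(nrules), lhs_fac)
  lhs_sizes <- lengths(lhs_index)

  set.seed(cfg$seed)
  pop <- matrix(runif(cfg$population_size * nrules), nrow = cfg$population_size)
  pop[1L, ] <- g0$rules$prob  # seed individual: the starting grammar

  # precompute per-item encodings once; the GA performs ~1e5 evaluations
  no_contacts <- matrix(integer(0), ncol = 2L)
  seqs <- lapply(sample$items, function(it) encode_sequence(it$x, enc$alphabet))
  cons <- lapply(sample$items, function(it) it$map$pairs)
  nit <- length(seqs)
  smap <- if (!is.null(sample$shared_map)) sample$shared_map$pairs else NULL
  shared_n <- if (!is.null(sample$shared_map)) sample$shared_map$length else NA_integer_
  eval_fast <- function(theta) {
    if (cfg$objective == "ML") {
      s <- 0
      for (k in seq_len(nit)) {
        v <- inside_enc(enc, theta, seqs[[k]], cons[[k]])
        if (!is.finite(v)) return(-Inf)
        s <- s + v
      }
      s / nit
    } else if (cfg$objective == "CE_m") {
      s <- 0
      for (k in seq_len(nit)) {
        v <- inside_enc(enc, theta, seqs[[k]], smap)
        if (!is.finite(v)) return(-Inf)
        s <- s + v
      }
      s / nit - inside_enc(enc, theta, rep(0L, shared_n), smap, lex_ones = TRUE)
    } else {
      s <- 0
      for (k in seq_len(nit)) {
        num <- inside_enc(enc, theta, seqs[[k]], cons[[k]])
        den <- inside_enc(enc, theta, seqs[[k]], no_contacts)
        if (!is.finite(num) || !is.finite(den)) return(-Inf)
        s <- s + (num - den)
      }
      s / nit
    }
  }
  evaluate <- function(w)
    eval_fast(decode_chromosome(w, lhs_index, lhs_sizes))
  fitness <- apply(pop, 1L, evaluate)
  if (all(!is.finite(fitness)))
    stop("objective is -Inf for the entire initial population; ",
         "the sample is unparsable under the grammar's rule set ",
         "(check contact separations and alphabet coverage)")

  trace <- data.frame(generation = 0L, best = max(fitness),
                      mean = mean(fitness[is.finite(fitness)]))
  if (cfg$generations > 0L) for (gen in seq_len(cfg$generations)) {
    ord <- order(fitness, decreasing = TRUE)
    newpop <- matrix(0, cfg$population_size, nrules)
    nelite <- cfg$elitism
    if (nelite > 0L) newpop[seq_len(nelite), ] <- pop[ord[seq_len(nelite)], ]
    tournament <- function() {
      cand <- sample.int(cfg$population_size, cfg$tournament_size, replace = TRUE)
      cand[which.max(fitness[cand])]
    }
    i <- nelite + 1L
    while (i <= cfg$population_size) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      if (runif(1) < cfg$crossover_rate) {
        swap <- runif(nrules) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      for (child in list(p1, p2)) {
        if (i > cfg$population_size) break
        mut <- runif(nrules) < cfg$mutation_rate
        if (any(mut))
          child[mut] <- child[mut] * exp(rnorm(sum(mut), 0, cfg$mutation_sigma))
        newpop[i, ] <- child
        i <- i + 1L
      }
    }
    pop <- newpop
    fitness <- apply(pop, 1L, evaluate)
    trace <- rbind(trace, data.frame(generation = gen,
                                     best = max(trace$best[nrow(trace)], max(fitness)),
                                     mean = mean(fitness[is.finite(fitness)])))
  }
  best <- which.max(fitness)
  theta <- decode_chromosome(pop[best, ], lhs_index, lhs_sizes)
  g <- g0
  g$rules$prob <- theta
  list(grammar = g, objective = fitness[best], trace = trace, config = cfg)
}

#' Multi-restart GA training
#'
#' Runs [train_ga()] with several seeds derived from `cfg$seed` and
#' returns all runs plus the best-objective grammar; the per-run grammars
#' can be combined with [ensemble_score()].
#'
#' @inheritParams train_ga
#' @param replicates Number of independent runs.
#' @return List with `runs` (list of [train_ga()] results), `best` (index
#'   of the best run) and `grammar` (best grammar).
#' @export
train_ga_multi <- function(g0, sample, cfg = ga_config(), replicates = 3L) {
  runs <- lapply(seq_len(replicates), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + (k - 1L) * 1000L
    train_ga(g0, sample, cfg_k)
  })
  objs <- vapply(runs, `[[`, 0, "objective")
  best <- which.max(objs)
  list(runs = runs, best = best, grammar = runs[[best]]$grammar)
}
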