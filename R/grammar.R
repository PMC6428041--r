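# Grammars in Chomsky Form with Contacts (CFC): Chomsky Normal Form plus
# contact rules V_N -> V_T V_N V_T whose flanking lexical non-terminals
# generate a residue pair in spatial contact.  A CFC grammar with no contact
# rules is an ordinary CNF grammar.

#' Amino-acid alphabet
#'
#' The default terminal alphabet: the 20 standard amino-acid one-letter codes.
#'
#' @param symbols Character vector of single-character terminal symbols.
#' @return Character vector of terminal symbols (class-free; validated).
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function(symbols = c("A", "C", "D", "E", "F", "G", "H", "I",
                                    "K", "L", "M", "N", "Q", "P", "R", "S",
                                    "T", "V", "W", "Y")) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) stop("alphabet must be non-empty")
  if (anyDuplicated(symbols)) stop("alphabet contains duplicated symbols")
  if (any(nchar(symbols) != 1L)) stop("alphabet symbols must be single characters")
  symbols
}

#' Non-terminal inventory of a CFC grammar
#'
#' Declares the lexical non-terminals (rewritten only into terminals), the
#' structural non-terminals, the start symbol, and which structural
#' non-terminals may head branching rules (`v -> y z`) and contact rules
#' (`v -> t w u` with `t`, `u` lexical).
#'
#' @param lexical Character vector of lexical non-terminal names.
#' @param structural Character vector of structural non-terminal names.
#' @param start Start symbol; must be one of `structural`.
#' @param branch_capable Structural non-terminals allowed on the left-hand
#'   side of branching rules. Default: all.
#' @param contact_capable Structural non-terminals allowed on the left-hand
#'   side of contact rules. Default: none (plain CNF inventory).
#' @return An object of class `nt_inventory`.
#' @export
#' @examples
#' nt_inventory(c("l1", "l2", "l3"), c("v0", "v1", "v2", "v3"))
nt_inventory <- function(lexical, structural, start = structural[1],
                         branch_capable = structural,
                         contact_capable = character(0)) {
  lexical <- as.character(lexical)
  structural <- as.character(structural)
  if (length(lexical) == 0L) stop("at least one lexical non-terminal is required")
  if (length(structural) == 0L) stop("at least one structural non-terminal is required")
  if (anyDuplicated(c(lexical, structural)))
    stop("lexical and structural non-terminal names must be disjoint and unique")
  if (!start %in% structural) stop("start symbol must be a structural non-terminal")
  if (!all(branch_capable %in% structural))
    stop("branch_capable must be a subset of the structural non-terminals")
  if (!all(contact_capable %in% structural))
    stop("contact_capable must be a subset of the structural non-terminals")
  uncovered <- setdiff(structural, union(branch_capable, contact_capable))
  if (length(uncovered) > 0L)
    warning("structural non-terminal(s) with no rule capability: ",
            paste(uncovered, collapse = ", "), " (cannot be rewritten)")
  if (!start %in% c(branch_capable, contact_capable))
    warning("start symbol is neither branch- nor contact-capable: it cannot derive any string")
  structure(list(lexical = lexical, structural = structural, start = start,
                 branch_capable = branch_capable,
                 contact_capable = contact_capable),
            class = "nt_inventory")
}

#' @export
print.nt_inventory <- function(x, ...) {
  cat("Non-terminal inventory\n")
  cat("  lexical:   ", paste(x$lexical, collapse = " "), "\n")
  cat("  structural:", paste(x$structural, collapse = " "),
      sprintf("(start: %s)\n", x$start))
  cat("  branch-capable: ", paste(x$branch_capable, collapse = " "), "\n")
  cat("  contact-capable:", if (length(x$contact_capable))
    paste(x$contact_capable, collapse = " ") else "(none; CNF)", "\n")
  invisible(x)
}

new_cfc_grammar <- function(alphabet, nts, rules) {
  stopifnot(is.data.frame(rules))
  g <- structure(list(alphabet = alphabet, nts = nts, rules = rules),
                 class = "cfc_grammar")
  g
}

#' Construct a CFC grammar from an explicit rule table
#'
#' @param alphabet Terminal alphabet, see [aa_alphabet()].
#' @param nts Non-terminal inventory, see [nt_inventory()].
#' @param rules Data frame with columns `lhs`, `rhs1`, `rhs2`, `rhs3`
#'   (`NA` where unused) and `prob`. Rule kind is inferred from the
#'   right-hand-side arity and checked against the CFC pattern.
#' @return An object of class `cfc_grammar`.
#' @export
cfc_grammar <- function(alphabet, nts, rules) {
  stopifnot(inherits(nts, "nt_inventory"))
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  need <- c("lhs", "rhs1", "rhs2", "rhs3", "prob")
  if (!all(c("lhs", "rhs1", "prob") %in% names(rules)))
    stop("rules must have at least columns lhs, rhs1, prob")
  if (is.null(rules$rhs2)) rules$rhs2 <- NA_character_
  if (is.null(rules$rhs3)) rules$rhs3 <- NA_character_
  rules <- rules[, need]
  rules$kind <- ifelse(!is.na(rules$rhs3), "contact",
                       ifelse(!is.na(rules$rhs2), "branching", "lexical"))
  validate_rules(alphabet, nts, rules)
  g <- new_cfc_grammar(alphabet, nts, rules)
  rep <- validate_properness(g)
  if (!rep$proper)
    stop("grammar is not proper; offending non-terminal(s): ",
         paste(rep$report$lhs[rep$report$violation], collapse = ", "),
         ". Renormalize with normalize_theta().")
  g
}

validate_rules <- function(alphabet, nts, rules) {
  all_v <- c(nts$lexical, nts$structural)
  if (any(all_v %in% alphabet))
    stop("non-terminal names must be disjoint from the alphabet")
  lex <- rules$kind == "lexical"
  br <- rules$kind == "branching"
  ct <- rules$kind == "contact"
  if (any(lex & !rules$lhs %in% nts$lexical))
    stop("lexical rules must have a lexical non-terminal on the left-hand side")
  if (any(lex & !rules$rhs1 %in% alphabet))
    stop("lexical rules must rewrite into a terminal symbol")
  if (any(br & !rules$lhs %in% nts$branch_capable))
    stop("branching rules must have a branch-capable structural lhs")
  if (any(br & (!rules$rhs1 %in% all_v | !rules$rhs2 %in% all_v)))
    stop("branching rule right-hand sides must be non-terminals")
  if (any(ct & !rules$lhs %in% nts$contact_capable))
    stop("contact rules must have a contact-capable structural lhs")
  bad_ct <- ct & (!rules$rhs1 %in% nts$lexical |
                  !rules$rhs2 %in% nts$structural |
                  !rules$rhs3 %in% nts$lexical)
  if (any(bad_ct))
    stop("contact rule right-hand side must follow the pattern ",
         "(lexical, structural, lexical); offending rule(s): ",
         paste(which(bad_ct), collapse = ", "))
  key <- paste(rules$lhs, rules$rhs1, rules$rhs2, rules$rhs3)
  if (anyDuplicated(key)) stop("duplicated rules in the rule table")
  if (any(rules$prob < 0 | rules$prob > 1 | !is.finite(rules$prob)))
    stop("rule probabilities must lie in [0, 1]")
  invisible(TRUE)
}

#' Build the covering grammar over an inventory
#'
#' The covering grammar contains every rule allowed by the CFC pattern:
#' all lexical rules (each lexical non-terminal into each terminal), all
#' branching rules headed by branch-capable non-terminals with any pair of
#' non-terminals on the right, and all contact rules headed by
#' contact-capable non-terminals with any (lexical, structural, lexical)
#' triple on the right. Probabilities are initialised uniformly per
#' left-hand side. Closed forms for the rule-set sizes:
#' `|R_a| = |V_T| * |alphabet|`, `|R_b| = |branch| * (|V_T|+|V_N|)^2`,
#' `|R_c| = |contact| * |V_T|^2 * |V_N|`.
#'
#' @inheritParams cfc_grammar
#' @return A proper `cfc_grammar` with uniform rule probabilities.
#' @export
#' @examples
#' g <- build_covering_grammar(aa_alphabet(),
#'   nt_inventory(paste0("l", 1:3), paste0("v", 0:3)))
#' table(g$rules$kind)  # 60 lexical, 196 branching
build_covering_grammar <- function(alphabet, nts) {
  stopifnot(inherits(nts, "nt_inventory"))
  alphabet <- aa_alphabet(alphabet)
  all_v <- c(nts$lexical, nts$structural)
  lex <- expand.grid(lhs = nts$lexical, rhs1 = alphabet,
                     stringsAsFactors = FALSE)
  lex$rhs2 <- NA_character_; lex$rhs3 <- NA_character_; lex$kind <- "lexical"
  parts <- list(lex)
  if (length(nts$branch_capable) > 0L) {
    br <- expand.grid(lhs = nts$branch_capable, rhs1 = all_v, rhs2 = all_v,
                      stringsAsFactors = FALSE)
    br$rhs3 <- NA_character_; br$kind <- "branching"
    parts <- c(parts, list(br))
  }
  if (length(nts$contact_capable) > 0L) {
    ct <- expand.grid(lhs = nts$contact_capable, rhs1 = nts$lexical,
                      rhs2 = nts$structural, rhs3 = nts$lexical,
                      stringsAsFactors = FALSE)
    ct$kind <- "contact"
    parts <- c(parts, list(ct))
  }
  rules <- do.call(rbind, lapply(parts, function(p)
    p[, c("lhs", "rhs1", "rhs2", "rhs3", "kind")]))
  rownames(rules) <- NULL
  rules$prob <- 0
  for (v in unique(rules$lhs)) {
    idx <- rules$lhs == v
    rules$prob[idx] <- 1 / sum(idx)
  }
  cfc_grammar(alphabet, nts, rules)
}

#' Check that a grammar is proper
#'
#' A probabilistic grammar is proper when, for every non-terminal, the
#' probabilities of all rules rewriting it sum to one.
#'
#' @param g A `cfc_grammar`.
#' @param tol Absolute tolerance on each per-non-terminal sum.
#' @return A list with elements `proper` (logical) and `report`
#'   (data frame of per-lhs sums with a `violation` flag).
#' @export
validate_properness <- function(g, tol = 1e-9) {
  stopifnot(inherits(g, "cfc_grammar"))
  sums <- tapply(g$rules$prob, g$rules$lhs, sum)
  report <- data.frame(lhs = names(sums), sum = as.numeric(sums),
                       stringsAsFactors = FALSE)
  report$violation <- abs(report$sum - 1) > tol
  rownames(report) <- NULL
  list(proper = !any(report$violation), report = report)
}

#' Normalize rule weights into proper probabilities
#'
#' Divides each rule weight by the total weight of its left-hand side,
#' yielding a proper probability assignment. This is the decoding step used
#' for genetic-algorithm chromosomes, and the repair step for non-proper
#' grammar files.
#'
#' @param g A `cfc_grammar` (its current `prob` column is used when
#'   `weights` is missing).
#' @param weights Optional non-negative weight per rule, in rule-table order.
#' @return The grammar with a proper `prob` column.
#' @export
normalize_theta <- function(g, weights = NULL) {
  stopifnot(inherits(g, "cfc_grammar"))
  w <- if (is.null(weights)) g$rules$prob else as.numeric(weights)
  if (length(w) != nrow(g$rules))
    stop("weights must have one entry per rule (", nrow(g$rules), ")")
  if (any(!is.finite(w) | w < 0)) stop("weights must be finite and non-negative")
  tot <- tapply(w, g$rules$lhs, sum)
  zero <- names(tot)[tot == 0]
  if (length(zero) > 0L)
    stop("all-zero weight group for non-terminal(s): ",
         paste(zero, collapse = ", "))
  g$rules$prob <- w / as.numeric(tot[g$rules$lhs])
  g
}

#' Number of rules by kind
#' @param g A `cfc_grammar`.
#' @return Named integer vector with counts `lexical`, `branching`,
#'   `contact`, `total`.
#' @export
rule_counts <- function(g) {
  stopifnot(inherits(g, "cfc_grammar"))
  k <- g$rules$kind
  c(lexical = sum(k == "lexical"), branching = sum(k == "branching"),
    contact = sum(k == "contact"), total = length(k))
}

#' @export
print.cfc_grammar <- function(x, ...) {
  n <- rule_counts(x)
  cat(sprintf("CFC grammar: |alphabet| = %d, %d lexical + %d structural non-terminals\n",
              length(x$alphabet), length(x$nts$lexical), length(x$nts$structural)))
  cat(sprintf("  rules: %d lexical, %d branching, %d contact (%d total)\n",
              n["lexical"], n["branching"], n["contact"], n["total"]))
  cat(sprintf("  start symbol: %s%s\n", x$nts$start,
              if (n["contact"] == 0L) "  [Chomsky Normal Form]" else ""))
  invisible(x)
}

# ---- grammar file format -----------------------------------------------
# Header lines declare the inventories; one rule per line afterwards:
#   LHS -> RHS1 [RHS2 [RHS3]] <tab> probability
# '#' starts a comment.  A file without any probability column receives a
# uniform theta.

#' Write a grammar to a text file
#'
#' @param g A `cfc_grammar`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(g, path) {
  stopifnot(inherits(g, "cfc_grammar"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("alphabet: ", paste(g$alphabet, collapse = "")),
    paste0("lexical: ", paste(g$nts$lexical, collapse = " ")),
    paste0("structural: ", paste(g$nts$structural, collapse = " ")),
    paste0("start: ", g$nts$start),
    paste0("branch: ", paste(g$nts$branch_capable, collapse = " ")),
    paste0("contact: ", paste(g$nts$contact_capable, collapse = " "))
  ), con)
  r <- g$rules
  rhs <- apply(r[, c("rhs1", "rhs2", "rhs3")], 1L, function(z)
    paste(z[!is.na(z)], collapse = " "))
  writeLines(sprintf("%s -> %s\t%.15g", r$lhs, rhs, r$prob), con)
  invisible(path)
}

#' Read a grammar from a text file
#'
#' @param path Grammar file as written by [write_grammar()].
#' @param renormalize If `TRUE`, a non-proper probability assignment is
#'   repaired by [normalize_theta()]; if `FALSE` (default) it is an error.
#' @return A `cfc_grammar`.
#' @export
read_grammar <- function(path, renormalize = FALSE) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^(alphabet|lexical|structural|start|branch|contact):", lines)
  header <- lines[hdr]
  get_field <- function(name, required = TRUE) {
    m <- grep(paste0("^", name, ":"), header, value = TRUE)
    if (length(m) == 0L) {
      if (required) stop("grammar file missing header line '", name, ":'")
      return(character(0))
    }
    strsplit(trimws(sub("^[a-z]+:", "", m[1])), "\\s+")[[1]]
  }
  alphabet <- strsplit(paste(get_field("alphabet"), collapse = ""), "")[[1]]
  nts <- nt_inventory(lexical = get_field("lexical"),
                      structural = get_field("structural"),
                      start = get_field("start"),
                      branch_capable = get_field("branch", required = FALSE),
                      contact_capable = get_field("contact", required = FALSE))
  rl <- lines[!hdr]
  if (length(rl) == 0L) stop("grammar file contains no rules")
  # probability, when present, is tab-separated from the rule
  tab_parts <- strsplit(rl, "\t", fixed = TRUE)
  rule_str <- trimws(vapply(tab_parts, `[`, "", 1L))
  prob_str <- trimws(vapply(tab_parts, function(z)
    if (length(z) >= 2L) z[length(z)] else NA_character_, ""))
  if (!all(grepl("->", rule_str, fixed = TRUE)))
    stop("malformed rule line(s): ",
         paste(rl[!grepl("->", rule_str, fixed = TRUE)], collapse = "; "))
  arrow <- regexpr("->", rule_str, fixed = TRUE)
  lhs <- trimws(substr(rule_str, 1L, arrow - 1L))
  rhs_str <- trimws(substr(rule_str, arrow + 2L, nchar(rule_str)))
  if (any(!nzchar(lhs)) || any(!nzchar(rhs_str)))
    stop("malformed rule line(s): empty left- or right-hand side")
  rhs <- strsplit(rhs_str, "\\s+")
  n_rhs <- vapply(rhs, length, 1L)
  if (any(n_rhs < 1L | n_rhs > 3L))
    stop("rules must have 1 (lexical), 2 (branching) or 3 (contact) right-hand-side symbols")
  rules <- data.frame(
    lhs = lhs,
    rhs1 = vapply(rhs, `[`, "", 1L),
    rhs2 = vapply(rhs, function(z) if (length(z) >= 2L) z[2L] else NA_character_, ""),
    rhs3 = vapply(rhs, function(z) if (length(z) >= 3L) z[3L] else NA_character_, ""),
    stringsAsFactors = FALSE)
  has_prob <- !is.na(prob_str) & nzchar(prob_str)
  if (all(!has_prob)) {
    rules$prob <- 1  # uniform theta assigned below via normalize
  } else if (all(has_prob)) {
    rules$prob <- as.numeric(prob_str)
    if (anyNA(rules$prob)) stop("unparseable probability value in grammar file")
  } else {
    stop("grammar file mixes rules with and without probabilities")
  }
  rules$kind <- ifelse(!is.na(rules$rhs3), "contact",
                       ifelse(!is.na(rules$rhs2), "branching", "lexical"))
  validate_rules(alphabet, nts, rules)
  g <- new_cfc_grammar(alphabet, nts, rules)
  if (all(!has_prob)) return(normalize_theta(g))
  rep <- validate_properness(g)
  if (!rep$proper) {
    if (renormalize) g <- normalize_theta(g)
    else stop("grammar file probabilities are not proper (per-lhs sums differ from 1); ",
              "use renormalize = TRUE to repair")
  }
  g
}
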