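# Partial contact maps: sets of 1-based residue pairs (i, j), i < j, for a
# sequence of length n.  A map is context-free compatible when no two pairs
# cross or overlap (nesting is allowed), so that a single context-free parse
# tree can realise all pairs.

#' Construct a contact map
#'
#' @param length Sequence length `n` (number of residues).
#' @param pairs Two-column matrix (or data frame) of 1-based position pairs;
#'   rows with `i > j` are flipped, duplicates dropped.
#' @return An object of class `contact_map` with fields `length` and
#'   `pairs` (integer matrix, ordered by left endpoint).
#' @export
#' @examples
#' contact_map(8, rbind(c(1, 8), c(2, 7)))
contact_map <- function(length, pairs = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, 2:1]
    if (any(pairs[, 1L] < 1L | pairs[, 2L] > length))
      stop("contact pairs out of range 1..", length)
    if (any(pairs[, 1L] == pairs[, 2L]))
      stop("a position cannot be in contact with itself")
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    sep2 <- pairs[, 2L] - pairs[, 1L] == 2L
    if (any(sep2))
      warning("pair(s) with sequence separation exactly 2 cannot be realised ",
              "by any CFC derivation (the inner non-terminal yields at least ",
              "2 terminals); their constrained probability is 0")
  }
  colnames(pairs) <- c("i", "j")
  structure(list(length = length, pairs = pairs), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: length %d, %d pair(s)\n", x$length, nrow(x$pairs)))
  if (nrow(x$pairs) > 0L)
    cat(paste(sprintf("  %d-%d", x$pairs[, 1L], x$pairs[, 2L]), collapse = "\n"), "\n")
  invisible(x)
}

#' Number of pairs in a contact map
#' @param map A `contact_map`.
#' @return Integer.
#' @export
n_contacts <- function(map) nrow(map$pairs)

#' Test context-free compatibility of a contact map
#'
#' A map is CF-compatible when no two pairs cross or share an endpoint
#' (nesting allowed) and every pair respects the minimum sequence
#' separation. Crossing test for pairs `(i,j)`, `(k,l)`: a violation occurs
#' when exactly one endpoint of one pair falls inside the span of the other.
#'
#' @param map A `contact_map`.
#' @param min_separation Minimum `j - i` per pair (default 2; pairs closer
#'   than this cannot be nested around any residue).
#' @return A list: `compatible` (logical), `crossing` (matrix of violating
#'   pair-index pairs), `too_close` (indices of pairs violating the
#'   separation).
#' @export
#' @examples
#' is_cf_compatible(contact_map(21, rbind(c(17, 21), c(5, 18))))$compatible  # FALSE
is_cf_compatible <- function(map, min_separation = 2L) {
  stopifnot(inherits(map, "contact_map"))
  p <- map$pairs
  np <- nrow(p)
  crossing <- matrix(integer(0), ncol = 2L,
                     dimnames = list(NULL, c("pair_a", "pair_b")))
  if (np >= 2L) {
    for (a in 1L:(np - 1L)) for (b in (a + 1L):np) {
      i <- p[a, 1L]; j <- p[a, 2L]; k <- p[b, 1L]; l <- p[b, 2L]
      inside_k <- i <= k & k <= j
      inside_l <- i <= l & l <= j
      shared <- length(intersect(c(i, j), c(k, l))) > 0L
      if (xor(inside_k, inside_l) || shared)
        crossing <- rbind(crossing, c(a, b))
    }
  }
  too_close <- which(p[, 2L] - p[, 1L] < min_separation)
  list(compatible = nrow(crossing) == 0L && length(too_close) == 0L,
       crossing = crossing, too_close = too_close)
}

#' Derive a contact map from residue coordinates
#'
#' Marks positions `(i, j)` as in contact when the Euclidean distance
#' between their representative coordinates is below `tau` and the sequence
#' separation `j - i` is at least `min_sequence_separation`.
#'
#' @param coords Numeric matrix or data frame with columns `x`, `y`, `z`
#'   (rows indexed 1..n) of representative atom coordinates in Angstroms.
#' @param tau Distance threshold in Angstroms (default 8).
#' @param min_sequence_separation Minimum `j - i` (default 3, non-local
#'   contacts only); use 0 to disable.
#' @return A `contact_map` (typically not CF-compatible; see
#'   [extract_cf_compatible_subset()]).
#' @export
contacts_from_coordinates <- function(coords, tau = 8,
                                      min_sequence_separation = 3L) {
  coords <- as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  n <- nrow(coords)
  if (n < 2L) stop("at least two residues are required")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  D <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(D) & D < tau, arr.ind = TRUE)
  keep <- idx[, 2L] - idx[, 1L] >= min_sequence_separation
  contact_map(n, idx[keep, , drop = FALSE])
}

#' Read a coordinate table from CSV
#'
#' Expected columns: `pos, x, y, z` with 1-based positions.
#'
#' @param path CSV file path.
#' @return Data frame ordered by position.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pos", "x", "y", "z") %in% names(df)))
    stop("coordinate file must have columns pos, x, y, z")
  df <- df[order(df$pos), ]
  if (!identical(as.integer(df$pos), seq_len(nrow(df))))
    stop("positions must be exactly 1..n")
  df
}

#' Maximal CF-compatible subset of a contact map
#'
#' Selects a maximum-cardinality non-crossing, non-overlapping subset of the
#' pairs by interval dynamic programming (as used for non-crossing base
#' pairing in RNA folding). The result is always CF-compatible; an already
#' compatible map is returned unchanged.
#'
#' @param full A `contact_map`.
#' @param min_separation Pairs with `j - i` below this are dropped first
#'   (default 3, the smallest separation a CFC derivation can realise).
#' @return A `contact_map` with a subset of the input pairs.
#' @export
extract_cf_compatible_subset <- function(full, min_separation = 3L) {
  stopifnot(inherits(full, "contact_map"))
  n <- full$length
  p <- full$pairs
  p <- p[p[, 2L] - p[, 1L] >= min_separation, , drop = FALSE]
  if (nrow(p) == 0L) return(contact_map(n))
  # pair lookup: has_pair[i, j] for candidate pairs
  has <- matrix(FALSE, n, n)
  has[p] <- TRUE
  # M[i, j]: max number of compatible pairs with both endpoints in i..j
  M <- matrix(0L, n, n)
  choice <- matrix(0L, n, n)  # 0 = skip i; k > 0 = pair (i, k)
  for (span in 2L:n) {
    for (i in 1L:(n - span + 1L)) {
      j <- i + span - 1L
      best <- M[i + 1L, j]; bk <- 0L
      ks <- which(has[i, (i + 1L):j]) + i
      for (k in ks) {
        inner <- if (k - i >= 2L) M[i + 1L, k - 1L] else 0L
        outer_ <- if (j - k >= 1L) M[k + 1L, j] else 0L
        cand <- 1L + inner + outer_
        if (cand > best) { best <- cand; bk <- k }
      }
      M[i, j] <- best
      choice[i, j] <- bk
    }
  }
  kept <- matrix(integer(0), ncol = 2L)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j) next
    k <- choice[i, j]
    if (k == 0L) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else {
      kept <- rbind(kept, c(i, k))
      if (k - i >= 2L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
      if (j - k >= 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j)
    }
  }
  contact_map(n, kept)
}

#' Consistency of a tree with a contact map
#'
#' A syntactic tree is consistent with a contact map when, for every pair
#' `(i, j)` in the map, the leaf-to-leaf path length in the tree satisfies
#' `d_u(i, j) <= delta`. At the default `delta = 4`, consistency for a CFC
#' parse tree means every contact pair is generated by a contact rule.
#'
#' @param tree A `parse_tree` or UST whose yield length matches the map.
#' @param map A `contact_map`.
#' @param delta Path-length threshold in edges (default 4).
#' @return Logical.
#' @export
is_consistent <- function(tree, map, delta = 4L) {
  stopifnot(inherits(map, "contact_map"))
  n <- length(tree_yield(tree))
  if (n != map$length)
    stop("tree yield length (", n, ") does not match map length (", map$length, ")")
  if (nrow(map$pairs) == 0L) return(TRUE)
  D <- leaf_distance_matrix(tree)
  all(D[map$pairs] <= delta)
}

# ---- contact-map file format -------------------------------------------
# `length n` header, then one whitespace-separated `i j` pair per line,
# 1-based.  '#' starts a comment.

#' Write a contact map to a pair-list file
#' @param map A `contact_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  lines <- c(paste("length", map$length),
             sprintf("%d %d", map$pairs[, 1L], map$pairs[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a contact map from a pair-list file
#' @param path File as written by [write_contact_map()].
#' @return A `contact_map`.
#' @export
read_contact_map <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !grepl("^length\\s+\\d+$", lines[1]))
    stop("contact-map file must start with a 'length n' header")
  n <- as.integer(sub("^length\\s+", "", lines[1]))
  body <- lines[-1]
  if (length(body) == 0L) return(contact_map(n))
  toks <- strsplit(body, "\\s+")
  if (any(vapply(toks, length, 1L) != 2L))
    stop("contact pairs must be 'i j' lines")
  pairs <- matrix(as.integer(unlist(toks)), ncol = 2L, byrow = TRUE)
  contact_map(n, pairs)
}
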