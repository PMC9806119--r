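# Cross-sample overlap statistics: shared-set proportions and hypergeometric
# significance for unannotated-junction sets and altered-event sets.

#' Construct a junction set for overlap testing
#'
#' @param sample_id Label.
#' @param keys Character junction/event keys (members).
#' @param universe Character keys eligible for membership; must contain
#'   `keys`.
#' @return A `JunctionSet`.
#' @export
junction_set <- function(sample_id, keys, universe) {
  keys <- unique(keys); universe <- unique(universe)
  if (!all(keys %in% universe)) stop("set is not a subset of its universe")
  structure(list(sample_id = sample_id, keys = keys, universe = universe),
            class = "JunctionSet")
}

#' Proportion of shared junctions between two sets
#'
#' The number of common junctions divided by the total number of distinct
#' junctions in the two sets being compared. The default denominator is the
#' union |A or B| (so identical sets score 1); `denominator = "sum"` uses
#' |A| + |B|.
#'
#' @param a,b `JunctionSet`s.
#' @param denominator "union" (default) or "sum".
#' @return Symmetric proportion in \[0, 1\].
#' @export
shared_proportion <- function(a, b, denominator = c("union", "sum")) {
  denominator <- match.arg(denominator)
  if (!length(a$keys) && !length(b$keys)) {
    stop("shared proportion undefined for two empty sets")
  }
  k <- length(intersect(a$keys, b$keys))
  d <- switch(denominator,
              union = length(union(a$keys, b$keys)),
              sum = length(a$keys) + length(b$keys))
  k / d
}

#' Upper-tail hypergeometric probability of an overlap
#'
#' P(X >= k) for X ~ Hypergeometric(N, |A|, |B|): the probability of drawing
#' at least k members of A when |B| items are drawn from a universe of size N
#' without replacement. Computed with the log-space-stable distribution
#' function, exact for N up to at least 1e6.
#'
#' @param k Observed overlap.
#' @param size_a,size_b Set sizes.
#' @param n_universe Universe size N.
#' @return Upper-tail p-value in (0, 1\].
#' @export
hypergeometric_tail <- function(k, size_a, size_b, n_universe) {
  stopifnot(k >= 0, size_a <= n_universe, size_b <= n_universe,
            k <= min(size_a, size_b))
  if (k == 0) return(1)
  stats::phyper(k - 1, size_a, n_universe - size_a, size_b,
                lower.tail = FALSE)
}

#' Hypergeometric overlap test between two junction sets
#'
#' @param a,b `JunctionSet`s on the same universe.
#' @param denominator Passed to [shared_proportion()].
#' @return An `OverlapResult`: list with sample_a, sample_b, k, size_a,
#'   size_b, n_universe, shared_proportion, p_value, neg_log10_p.
#' @export
hypergeometric_overlap_test <- function(a, b, denominator = "union") {
  if (!setequal(a$universe, b$universe)) {
    stop("junction sets have mismatched universes")
  }
  k <- length(intersect(a$keys, b$keys))
  p <- hypergeometric_tail(k, length(a$keys), length(b$keys),
                           length(a$universe))
  structure(list(
    sample_a = a$sample_id, sample_b = b$sample_id,
    k = k, size_a = length(a$keys), size_b = length(b$keys),
    n_universe = length(a$universe),
    shared_proportion = shared_proportion(a, b, denominator),
    p_value = p, neg_log10_p = -log10(p)
  ), class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult %s vs %s: k=%d of |A|=%d,|B|=%d (N=%d), shared %.3f, p=%.3g\n",
              x$sample_a, x$sample_b, x$k, x$size_a, x$size_b, x$n_universe,
              x$shared_proportion, x$p_value))
  invisible(x)
}

#' Pairwise overlap matrix across samples
#'
#' @param sets List of `JunctionSet`s on a common universe (>= 2).
#' @param denominator Passed to [shared_proportion()].
#' @return List with `long` (data.frame: sample_i, sample_j, k, size_i,
#'   size_j, n_universe, proportion, p_value, neg_log10_p; all ordered
#'   pairs including the diagonal), `proportion` and `neg_log10_p`
#'   (symmetric matrices; diagonal proportion 1, diagonal p-value from the
#'   self-overlap test).
#' @export
pairwise_matrix <- function(sets, denominator = "union") {
  if (length(sets) < 2L) stop("need at least 2 sets")
  ids <- vapply(sets, function(s) s$sample_id, character(1))
  n <- length(sets)
  prop <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nlp <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  long <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- hypergeometric_overlap_test(sets[[i]], sets[[j]], denominator)
    prop[i, j] <- r$shared_proportion
    nlp[i, j] <- r$neg_log10_p
    long[[length(long) + 1L]] <- data.frame(
      sample_i = ids[i], sample_j = ids[j], k = r$k,
      size_i = r$size_a, size_j = r$size_b, n_universe = r$n_universe,
      proportion = r$shared_proportion, p_value = r$p_value,
      neg_log10_p = r$neg_log10_p, stringsAsFactors = FALSE
    )
  }
  list(long = do.call(rbind, long), proportion = prop, neg_log10_p = nlp)
}
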