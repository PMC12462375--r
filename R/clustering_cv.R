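# Sequence-alignment distance between heterodimers, single-linkage
# clustering with recorded merge heights, and cluster-respecting
# cross-validation folds.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# encode amino-acid strings as 0-based indices into the scoring matrix
.encode_seqs <- function(seqs, alphabet) {
  lapply(strsplit(seqs, ""), function(ch) {
    idx <- match(ch, alphabet)
    idx[is.na(idx)] <- match("X", alphabet)
    idx - 1L
  })
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under BLOSUM62 with affine gaps (Gotoh
#' recursion): a gap of length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param seq_i,seq_j Amino-acid strings (standard alphabet; any letter
#'   outside the scoring matrix is scored via the matrix's X row).
#'   `seq_j` may be a character vector, in which case all of its elements
#'   are aligned against `seq_i` in one call.
#' @param gap_open,gap_extend Gap penalties (defaults 11 and 1, the usual
#'   BLOSUM62 pairing).
#' @return Numeric score(s), non-negative.
#' @export
sw_score <- function(seq_i, seq_j, gap_open = 11, gap_extend = 1) {
  if (!nzchar(seq_i) || any(!nzchar(seq_j))) stop("empty sequence")
  mat <- .blosum62()
  alpha <- rownames(mat)
  .sw_score_codes(.encode_seqs(seq_i, alpha)[[1]],
                  .encode_seqs(seq_j, alpha),
                  mat, gap_open, gap_extend)
}

#' Normalized sequence distance between two proteins
#'
#' `d = 1 - SW(i, j) / sqrt(SW(i, i) * SW(j, j))`, where SW is the
#' Smith-Waterman score. Zero for identical sequences; clamped into
#' \[0, 1\].
#'
#' @inheritParams sw_score
#' @return Distance in \[0, 1\].
#' @export
protein_distance <- function(seq_i, seq_j, gap_open = 11, gap_extend = 1) {
  sii <- sw_score(seq_i, seq_i, gap_open, gap_extend)
  sjj <- sw_score(seq_j, seq_j, gap_open, gap_extend)
  if (sii <= 0 || sjj <= 0)
    stop("non-positive self-alignment score; pathological sequence")
  sij <- sw_score(seq_i, seq_j, gap_open, gap_extend)
  min(max(1 - sij / sqrt(sii * sjj), 0), 1)
}

#' Distance between two heterodimers
#'
#' Half the smaller of the two chain-matching sums of protein distances:
#' the result does not depend on the order of the two heterodimers nor on
#' the order of the chains within each.
#'
#' @param pair_1,pair_2 Character vectors of length two holding the two
#'   chain sequences of each heterodimer.
#' @inheritParams sw_score
#' @return Distance in \[0, 1\].
#' @export
heterodimer_distance <- function(pair_1, pair_2, gap_open = 11, gap_extend = 1) {
  stopifnot(length(pair_1) == 2L, length(pair_2) == 2L)
  d <- function(i, j) protein_distance(pair_1[i], pair_2[j], gap_open, gap_extend)
  0.5 * min(d(1, 1) + d(2, 2), d(1, 2) + d(2, 1))
}

#' Heterodimer distance matrix for a dataset
#'
#' Computes all pairwise heterodimer distances. Alignments are done once
#' per unique sequence pair (family members sharing sequences are not
#' realigned), vectorized over the Biostrings aligner.
#'
#' @param pairs Tibble with columns `accession`, `seq_a`, `seq_b`.
#' @inheritParams sw_score
#' @return Symmetric numeric matrix with zero diagonal, dimnames set to
#'   the accessions.
#' @export
heterodimer_dist_matrix <- function(pairs, gap_open = 11, gap_extend = 1) {
  stopifnot(all(c("accession", "seq_a", "seq_b") %in% names(pairs)))
  seqs <- unique(c(pairs$seq_a, pairs$seq_b))
  u <- length(seqs)
  mat <- .blosum62()
  codes <- .encode_seqs(seqs, rownames(mat))
  self <- vapply(seq_len(u), function(i)
    .sw_score_codes(codes[[i]], codes[i], mat, gap_open, gap_extend),
    numeric(1))
  S <- matrix(0, u, u)
  diag(S) <- self
  for (i in seq_len(u - 1L)) {
    js <- seq.int(i + 1L, u)
    S[i, js] <- S[js, i] <- .sw_score_codes(codes[[i]], codes[js], mat,
                                            gap_open, gap_extend)
  }
  D <- 1 - S / sqrt(outer(self, self))
  D[D < 0] <- 0; D[D > 1] <- 1
  ia <- match(pairs$seq_a, seqs); ib <- match(pairs$seq_b, seqs)
  n <- nrow(pairs)
  out <- matrix(0, n, n, dimnames = list(pairs$accession, pairs$accession))
  for (k in seq_len(n - 1L)) {
    ls <- seq.int(k + 1L, n)
    straight <- D[ia[k], ia[ls]] + D[ib[k], ib[ls]]
    crossed <- D[ia[k], ib[ls]] + D[ib[k], ia[ls]]
    out[k, ls] <- out[ls, k] <- 0.5 * pmin(straight, crossed)
  }
  out
}

#' Single-linkage clustering with recorded merge heights
#'
#' Agglomerative single-linkage clustering over a precomputed distance
#' matrix. Merge heights are recorded so memberships can be read off at
#' any minimum-separation threshold: the clusters at threshold `t` are
#' exactly the connected components of the graph joining items at
#' distance strictly below `t`.
#'
#' @param dmat Symmetric numeric matrix with zero diagonal (dimnames used
#'   as item identifiers).
#' @param thresholds Optional numeric vector of separation thresholds at
#'   which memberships are materialized eagerly.
#' @return Object of class `cluster_model`: merge list, heights, labels
#'   and (optionally) threshold memberships.
#' @export
single_linkage <- function(dmat, thresholds = NULL) {
  if (!is.matrix(dmat) || nrow(dmat) != ncol(dmat) ||
      !isTRUE(all.equal(dmat, t(dmat), tolerance = 1e-12)) ||
      any(abs(diag(dmat)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(dmat)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dmat)))
  hc <- stats::hclust(stats::as.dist(dmat), method = "single")
  model <- structure(list(merge = hc$merge, height = hc$height,
                          labels = labels, n = nrow(dmat),
                          thresholds = thresholds, membership = NULL),
                     class = "cluster_model")
  if (!is.null(thresholds)) {
    model$membership <- lapply(stats::setNames(thresholds, thresholds),
                               function(t) cluster_membership(model, t))
  }
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d items, %d merges, heights in [%.3g, %.3g]\n",
              x$n, length(x$height),
              if (length(x$height)) min(x$height) else NA,
              if (length(x$height)) max(x$height) else NA))
  invisible(x)
}

#' Cluster membership at a minimum-separation threshold
#'
#' Applies all merges with height strictly below `threshold`, so that any
#' two items left in different clusters are at single-link distance at
#' least `threshold`.
#'
#' @param model A `cluster_model`.
#' @param threshold Minimum cluster separation.
#' @return Named integer vector: cluster id per item.
#' @export
cluster_membership <- function(model, threshold) {
  n <- model$n
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # hclust merge rows: negative = singleton item, positive = earlier merge
  rep_of_merge <- integer(length(model$height))
  for (m in seq_along(model$height)) {
    if (model$height[m] >= threshold) next
    left <- model$merge[m, 1]; right <- model$merge[m, 2]
    li <- if (left < 0) -left else rep_of_merge[left]
    ri <- if (right < 0) -right else rep_of_merge[right]
    rl <- find(li); rr <- find(ri)
    parent[rl] <- rr
    rep_of_merge[m] <- rr
  }
  # merges at or above threshold still need representatives for later rows
  for (m in seq_along(model$height)) {
    if (rep_of_merge[m] == 0L) {
      left <- model$merge[m, 1]
      rep_of_merge[m] <- if (left < 0) -left else rep_of_merge[left]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), model$labels)
}

#' Assign cluster-respecting cross-validation folds
#'
#' Clusters at the given separation threshold are shuffled (seeded) and
#' greedily assigned, one whole cluster at a time, to the currently
#' smallest fold, so no cluster ever spans two folds.
#'
#' @param model A `cluster_model`, or a named membership vector from
#'   [cluster_membership()].
#' @param threshold Separation threshold (ignored when a membership
#'   vector is given).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed making the assignment deterministic.
#' @return Tibble with columns `accession`, `cluster`, `fold`; attributes
#'   `n_folds` and `seed`.
#' @export
assign_folds <- function(model, threshold = NULL, n_folds = 5, seed = 1) {
  memb <- if (inherits(model, "cluster_model")) {
    stopifnot(!is.null(threshold))
    cluster_membership(model, threshold)
  } else model
  clusters <- split(names(memb), memb)
  if (length(clusters) < n_folds)
    stop("only ", length(clusters), " clusters at threshold ", threshold,
         " for ", n_folds, " folds")
  ord <- withr::with_seed(seed, sample.int(length(clusters)))
  sizes <- integer(n_folds)
  fold_of_cluster <- integer(length(clusters))
  for (ci in ord) {
    f <- which.min(sizes)
    fold_of_cluster[ci] <- f
    sizes[f] <- sizes[f] + length(clusters[[ci]])
  }
  out <- tibble::tibble(
    accession = names(memb),
    cluster = unname(memb),
    fold = fold_of_cluster[match(memb, as.integer(names(clusters)))])
  attr(out, "n_folds") <- n_folds
  attr(out, "seed") <- seed
  out
}
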