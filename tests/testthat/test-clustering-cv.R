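# Sequence distances, single-linkage clustering and fold assignment.

test_that("self-alignment of an identity string sums the matrix diagonal", {
  s <- "HEAGAWGHEE"
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  diag_sum <- sum(diag(e$BLOSUM62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]]))
  expect_equal(sw_score(s, s), diag_sum)
})

test_that("an all-mismatch pair floors at the local-alignment zero", {
  expect_equal(sw_score("AAAA", "CCCC"), 0)
})

test_that("alignment scores equal the textbook DP oracle", {
  set.seed(42)
  for (k in 1:100) {
    s1 <- random_aa_seq(sample(8:40, 1))
    s2 <- random_aa_seq(sample(8:40, 1))
    expect_equal(sw_score(s1, s2), sw_dp_oracle(s1, s2),
                 label = sprintf("pair %d", k))
  }
})

test_that("alignment scores agree with the Biostrings aligner", {
  set.seed(7)
  for (k in 1:20) {
    s1 <- random_aa_seq(30); s2 <- random_aa_seq(30)
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s2), Biostrings::AAString(s1), type = "local",
      substitutionMatrix = e$BLOSUM62, gapOpening = 10, gapExtension = 1,
      scoreOnly = TRUE)
    expect_equal(sw_score(s1, s2), max(ref, 0))
  }
})

test_that("normalized protein distance behaves as a similarity complement", {
  s <- random_aa_seq(50)
  expect_equal(protein_distance(s, s), 0)
  expect_equal(protein_distance("AAAA", "CCCC"), 1)
  # hand-composed from oracle scores at 80% identity
  set.seed(9)
  s1 <- random_aa_seq(50)
  ch <- strsplit(s1, "")[[1]]
  mut <- sample(50, 10)
  ch[mut] <- sample(c("A", "R", "N", "D"), 10, replace = TRUE)
  s2 <- paste(ch, collapse = "")
  expected <- 1 - sw_dp_oracle(s1, s2) /
    sqrt(sw_dp_oracle(s1, s1) * sw_dp_oracle(s2, s2))
  expect_equal(protein_distance(s1, s2), expected)
  expect_gte(expected, 0)
  expect_lte(expected, 1)
})

test_that("heterodimer distance is symmetric in pair and chain order", {
  set.seed(15)
  for (k in 1:50) {
    seqs <- replicate(4, random_aa_seq(sample(15:35, 1)))
    p1 <- seqs[1:2]; p2 <- seqs[3:4]
    d <- heterodimer_distance(p1, p2)
    expect_equal(heterodimer_distance(rev(p1), p2), d)
    expect_equal(heterodimer_distance(p1, rev(p2)), d)
    expect_equal(heterodimer_distance(p2, p1), d)
    expect_gte(d, 0); expect_lte(d, 1)
    # brute force over both matchings
    dd <- function(a, b) protein_distance(a, b)
    expected <- 0.5 * min(dd(p1[1], p2[1]) + dd(p1[2], p2[2]),
                          dd(p1[1], p2[2]) + dd(p1[2], p2[1]))
    expect_equal(d, expected)
  }
  expect_equal(heterodimer_distance(c("ACDEF", "GHIKL"),
                                    c("ACDEF", "GHIKL")), 0)
})

test_that("the distance matrix matches elementwise recomputation", {
  set.seed(30)
  pairs <- tibble::tibble(accession = sprintf("P%d", 1:6),
                          seq_a = replicate(6, random_aa_seq(25)),
                          seq_b = replicate(6, random_aa_seq(25)))
  dm <- heterodimer_dist_matrix(pairs)
  expect_true(isSymmetric(dm))
  expect_equal(diag(dm), setNames(rep(0, 6), pairs$accession))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dm[i, j],
                 heterodimer_distance(c(pairs$seq_a[i], pairs$seq_b[i]),
                                      c(pairs$seq_a[j], pairs$seq_b[j])))
  }
})

test_that("single linkage memberships equal graph components at every cut", {
  set.seed(12)
  for (k in 1:20) {
    n <- 20
    P <- matrix(runif(2 * n), n)
    dmat <- as.matrix(dist(P))
    model <- single_linkage(dmat)
    for (t in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
      memb <- unname(cluster_membership(model, t))
      oracle <- graph_components_oracle(dmat, t)
      # identical partitions: the same-cluster relation matches pairwise
      expect_equal(outer(memb, memb, "==")[upper.tri(diag(n))],
                   outer(oracle, oracle, "==")[upper.tri(diag(n))],
                   label = sprintf("matrix %d cut %.2f", k, t))
    }
  }
})

test_that("simple merge geometries cluster as expected", {
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m <- single_linkage(d0)
  expect_equal(max(cluster_membership(m, 0.001)), 1)
  dmat <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  memb <- cluster_membership(single_linkage(dmat), 0.5)
  expect_equal(memb[["A"]], memb[["B"]])
  expect_false(memb[["A"]] == memb[["C"]])
  # the cut is strict: a merge exactly at the threshold does not join
  memb2 <- cluster_membership(single_linkage(dmat), 0.1)
  expect_equal(length(unique(memb2)), 3)
  expect_error(single_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("cluster count never increases with the separation threshold", {
  set.seed(5)
  dmat <- as.matrix(dist(matrix(runif(40), 20)))
  model <- single_linkage(dmat)
  ks <- vapply(seq(0.02, 1, by = 0.02), function(t)
    length(unique(cluster_membership(model, t))), numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("folds respect clusters and balance greedily", {
  # 10 singletons -> folds of two
  d <- matrix(1, 10, 10, dimnames = list(sprintf("x%d", 1:10),
                                         sprintf("x%d", 1:10)))
  diag(d) <- 0
  fa <- assign_folds(single_linkage(d), 0.5, n_folds = 5, seed = 3)
  expect_true(all(table(fa$fold) == 2))
  # one dominant cluster occupies a fold alone
  d2 <- matrix(1, 104, 104)
  d2[1:100, 1:100] <- 0
  diag(d2) <- 0
  rownames(d2) <- colnames(d2) <- sprintf("y%d", 1:104)
  fa2 <- assign_folds(single_linkage(d2), 0.5, n_folds = 5, seed = 3)
  big_fold <- fa2$fold[fa2$accession == "y1"]
  expect_equal(sum(fa2$fold == big_fold), 100)
  # many random clusters: never split, bounded imbalance
  set.seed(44)
  sizes <- sample(1:8, 200, replace = TRUE)
  memb <- setNames(rep(seq_along(sizes), sizes),
                   sprintf("z%d", seq_len(sum(sizes))))
  for (sd in c(1, 7, 99)) {
    fa3 <- assign_folds(memb, n_folds = 5, seed = sd)
    split_check <- tapply(fa3$fold, fa3$cluster,
                          function(f) length(unique(f)))
    expect_true(all(split_check == 1))
    fs <- table(fa3$fold)
    expect_lte(max(fs) - min(fs), max(sizes))
    # deterministic under the seed
    expect_identical(fa3, assign_folds(memb, n_folds = 5, seed = sd))
  }
  expect_error(assign_folds(memb[1:3], n_folds = 5, seed = 1), "clusters")
})
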