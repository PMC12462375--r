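# Independent oracles used to cross-check the package implementations.
# These are deliberately written as plain, slow, textbook versions that
# share no code with the implementation paths they verify.

# full-matrix Gotoh local alignment: gap of length L costs
# open + (L - 1) * extend
sw_dp_oracle <- function(s1, s2, mat = NULL, open = 11, extend = 1) {
  if (is.null(mat)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in s1 (move along j)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in s2 (move along i)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
    F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# O(n^2) enumeration of cross-chain element-pair counts
brute_rfscore <- function(structure, cutoff = 12) {
  a <- structure$atoms[structure$atoms$chain_role == "a", ]
  b <- structure$atoms[structure$atoms$chain_role == "b", ]
  counts <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    if (d <= cutoff) {
      key <- paste(sort(c(a$element[i], b$element[j])), collapse = "_")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  counts
}

# O(n^2) enumeration of residue-class contact pairs
brute_contacts <- function(structure, threshold) {
  cls <- function(rn) {
    tb <- residue_class_table()
    tb$class[match(rn, tb$residue_name)]
  }
  a <- structure$atoms[structure$atoms$chain_role == "a", ]
  b <- structure$atoms[structure$atoms$chain_role == "b", ]
  seen <- character(0)
  counts <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 + (a$z[i] - b$z[j])^2)
    if (d <= threshold) {
      rid <- paste(a$residue_index[i], b$residue_index[j])
      if (!(rid %in% seen)) {
        seen <- c(seen, rid)
        key <- paste(sort(c(cls(a$residue_name[i]), cls(b$residue_name[j]))),
                     collapse = "_")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  counts
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# connected components of the graph joining items at distance < t
graph_components_oracle <- function(dmat, t) {
  n <- nrow(dmat)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && dmat[i, j] < t && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# plain-R Shrake-Rupley with seeded uniform random sphere points,
# independent of the compiled golden-spiral implementation
sasa_r_oracle <- function(coords, radii, n_points = 960, probe = 1.4,
                          seed = 99) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n_points), n_points, 3)
  u <- u / sqrt(rowSums(u^2))
  er <- radii + probe
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    pts <- sweep(u * er[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
        (pts[, 3] - coords[j, 3])^2
      free <- free & d2 >= er[j]^2
      if (!any(free)) break
    }
    4 * pi * er[i]^2 * sum(free) / n_points
  }, numeric(1))
}

# simple two-chain structure from explicit atom specs: a list of
# (element, x, y, z, residue_name, residue_index) per chain
make_structure <- function(chain_a, chain_b, accession = "TEST") {
  mk <- function(df, role, id) {
    tibble::tibble(
      chain_role = role, chain_id = id,
      residue_index = df$residue_index, residue_name = df$residue_name,
      atom_name = paste0(df$element, seq_len(nrow(df))),
      element = df$element, x = df$x, y = df$y, z = df$z,
      is_hetatm = FALSE)
  }
  new_heterodimer(dplyr::bind_rows(mk(chain_a, "a", "A"), mk(chain_b, "b", "B")),
                  accession = accession)
}

# random blob structure for oracle comparisons: n_res residues per chain,
# one to three atoms each, scattered in a box
random_structure <- function(n_res = 10, seed = 1, box = 30) {
  set.seed(seed)
  mk_chain <- function(n) {
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      tibble::tibble(
        element = sample(c("C", "N", "O", "S"), k, replace = TRUE),
        x = runif(k, 0, box), y = runif(k, 0, box), z = runif(k, 0, box),
        residue_name = sample(residue_class_table()$residue_name, 1),
        residue_index = i)
    })
    dplyr::bind_rows(rows)
  }
  make_structure(mk_chain(n_res), mk_chain(n_res),
                 accession = sprintf("RND%03d", seed))
}

random_aa_seq <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}
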