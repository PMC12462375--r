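# Interface features: RF-score element-pair counts, residue-class contact
# counts and percent non-interacting surface (%NIS).

# ---- RF-score ----------------------------------------------------------

.cross_sq_dist <- function(A, B) {
  # |a - b|^2 for all rows of A x rows of B
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

.pair_label <- function(e1, e2) {
  lo <- pmin(e1, e2); hi <- pmax(e1, e2)
  paste(lo, hi, sep = "_")
}

#' Element-pair vocabulary of one or more structures
#'
#' @param structures A `heterodimer` or list of them.
#' @return Sorted character vector of unordered element-pair labels
#'   (`"C_N"`, ...) over the union of elements observed, frozen per
#'   experiment so train and test feature vectors align.
#' @export
rfscore_vocabulary <- function(structures) {
  if (inherits(structures, "heterodimer")) structures <- list(structures)
  elements <- sort(unique(unlist(lapply(structures, function(s) s$atoms$element))))
  grid <- expand.grid(e1 = elements, e2 = elements, stringsAsFactors = FALSE)
  grid <- grid[grid$e1 <= grid$e2, , drop = FALSE]
  sort(paste(grid$e1, grid$e2, sep = "_"))
}

#' RF-score interface atom-pair counts
#'
#' Counts every cross-chain heavy-atom pair separated by no more than
#' `cutoff` angstrom, binned by the unordered pair of chemical elements.
#'
#' @param structure A `heterodimer`.
#' @param cutoff Distance cutoff in angstrom (default 12, inclusive).
#' @param vocabulary Optional element-pair label vector fixing the vector
#'   layout; an observed pair outside it is an error. Defaults to the
#'   pairs formed by the structure's own elements.
#' @return Tibble with columns `pair` and `count`, one row per vocabulary
#'   pair (zeros included).
#' @export
rfscore_features <- function(structure, cutoff = 12, vocabulary = NULL) {
  a <- chain_atoms(structure, "a")
  b <- chain_atoms(structure, "b")
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty chain")
  if (is.null(vocabulary)) vocabulary <- rfscore_vocabulary(structure)
  d2 <- .cross_sq_dist(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  counts <- stats::setNames(numeric(length(vocabulary)), vocabulary)
  if (nrow(hit) > 0L) {
    lab <- .pair_label(a$element[hit[, 1]], b$element[hit[, 2]])
    tab <- table(lab)
    unknown <- setdiff(names(tab), vocabulary)
    if (length(unknown) > 0L)
      stop("element pair(s) outside the supplied vocabulary: ",
           paste(unknown, collapse = ", "))
    counts[names(tab)] <- as.numeric(tab)
  }
  tibble::tibble(pair = vocabulary, count = unname(counts))
}

#' RF-score feature table for a set of structures
#'
#' @param structures Named list of `heterodimer` objects (names are
#'   accessions; unnamed lists fall back to each structure's accession).
#' @inheritParams rfscore_features
#' @return Wide tibble: `accession` plus one count column per element-pair
#'   label in the frozen vocabulary.
#' @export
rfscore_table <- function(structures, cutoff = 12, vocabulary = NULL) {
  if (inherits(structures, "heterodimer")) structures <- list(structures)
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(s) s$accession, character(1))
  if (is.null(vocabulary)) vocabulary <- rfscore_vocabulary(structures)
  rows <- purrr::imap(structures, function(s, acc) {
    f <- rfscore_features(s, cutoff = cutoff, vocabulary = vocabulary)
    tibble::as_tibble(c(list(accession = acc),
                        stats::setNames(as.list(f$count), f$pair)))
  })
  dplyr::bind_rows(rows)
}

# ---- residue classes ---------------------------------------------------

#' Physicochemical residue classes
#'
#' Membership table assigning each standard residue to `charged`, `polar`
#' or `apolar`. This table is the single source of truth for contact
#' binning and %NIS and can be overridden wherever it is consumed; it is a
#' reimplementation choice (tryptophan in particular is placed with the
#' apolar class) and may diverge from other contact-based affinity
#' predictors.
#'
#' @return Tibble with columns `residue_name`, `class`.
#' @export
residue_class_table <- function() {
  tibble::tibble(
    residue_name = c("ASP", "GLU", "LYS", "ARG", "HIS",
                     "ASN", "GLN", "SER", "THR", "TYR", "CYS",
                     "ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "GLY", "TRP"),
    class = c(rep("charged", 5), rep("polar", 6), rep("apolar", 9)))
}

#' Classify a residue as charged, polar or apolar
#'
#' @param residue_name Character vector of 3-letter residue codes.
#' @param classes Membership table, defaulting to [residue_class_table()].
#' @param fallback Class assigned (with a warning) to codes absent from
#'   the table.
#' @return Character vector of classes.
#' @export
classify_residue <- function(residue_name, classes = residue_class_table(),
                             fallback = "apolar") {
  cl <- classes$class[match(residue_name, classes$residue_name)]
  if (anyNA(cl)) {
    warning("nonstandard residue(s) classified as '", fallback, "': ",
            paste(unique(residue_name[is.na(cl)]), collapse = ", "))
    cl[is.na(cl)] <- fallback
  }
  cl
}

.contact_class_pairs <- c("apolar_apolar", "apolar_charged", "apolar_polar",
                          "charged_charged", "charged_polar", "polar_polar")

#' Inter-residue contact counts by residue-class pair
#'
#' A residue of chain a and a residue of chain b are in contact when any
#' of their heavy-atom pairs lies within `threshold` angstrom. Each
#' contacting pair increments exactly one of the six unordered class-pair
#' bins (charged/polar/apolar). Only amino-acid residues are considered.
#'
#' @param structure A `heterodimer`.
#' @param threshold Contact distance in angstrom, within the grid
#'   \[3.5, 20\].
#' @param classes Residue-class membership table.
#' @return Tibble with columns `class_pair` (six rows) and `count`.
#' @export
prodigy_contacts <- function(structure, threshold,
                             classes = residue_class_table()) {
  if (threshold < 3.5 || threshold > 20)
    stop("contact threshold ", threshold, " outside the 3.5-20 angstrom grid")
  a <- chain_atoms(structure, "a"); a <- a[.is_amino(a$residue_name), ]
  b <- chain_atoms(structure, "b"); b <- b[.is_amino(b$residue_name), ]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty chain")
  d2 <- .cross_sq_dist(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d2 <= threshold^2, arr.ind = TRUE)
  counts <- stats::setNames(numeric(6), .contact_class_pairs)
  if (nrow(hit) > 0L) {
    rp <- dplyr::distinct(tibble::tibble(
      ra = a$residue_index[hit[, 1]], na = a$residue_name[hit[, 1]],
      rb = b$residue_index[hit[, 2]], nb = b$residue_name[hit[, 2]]))
    lab <- .pair_label(classify_residue(rp$na, classes),
                       classify_residue(rp$nb, classes))
    tab <- table(lab)
    counts[names(tab)] <- as.numeric(tab)
  }
  tibble::tibble(class_pair = .contact_class_pairs, count = unname(counts))
}

# ---- solvent accessibility and %NIS ------------------------------------

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# maximum accessible surface areas (angstrom^2) of residue X in an
# extended Gly-X-Gly tripeptide, used to normalize to relative
# accessibility (theoretical values of Tien et al. 2013)
.max_asa <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

.atom_radii <- function(element, default = 1.70) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- default
  unname(r)
}

#' Per-residue solvent-accessible surface area of the complex
#'
#' Shrake-Rupley SASA over all heavy atoms of the complex (both chains
#' plus attached groups as occluders), summed per amino-acid residue and
#' normalized by extended-tripeptide reference areas into relative
#' accessibility.
#'
#' @param structure A `heterodimer`.
#' @param n_points Sphere test points per atom (default 960).
#' @param probe Solvent probe radius in angstrom (default 1.4).
#' @return Tibble with one row per amino-acid residue: `chain_role`,
#'   `residue_index`, `residue_name`, `sasa`, `rel_accessibility`.
#' @export
residue_sasa <- function(structure, n_points = 960, probe = 1.4) {
  at <- structure$atoms
  area <- .sasa_shrake_rupley(as.matrix(at[, c("x", "y", "z")]),
                              .atom_radii(at$element),
                              n_points = as.integer(n_points), probe = probe)
  at$sasa <- area
  res <- at[.is_amino(at$residue_name), , drop = FALSE] |>
    dplyr::group_by(.data$chain_role, .data$residue_index, .data$residue_name) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop")
  ref <- .max_asa[res$residue_name]
  ref[is.na(ref)] <- .max_asa[["ALA"]]
  res$rel_accessibility <- res$sasa / ref
  res
}

#' Percent non-interacting surface by residue class
#'
#' Surface residues of the complex (relative accessibility at or above
#' `surface_cutoff`) form the non-interacting surface; the three
#' percentages are the class shares of those residues and sum to 100.
#'
#' @inheritParams residue_sasa
#' @param surface_cutoff Relative-accessibility cutoff defining a surface
#'   residue (default 0.05).
#' @param classes Residue-class membership table.
#' @return One-row tibble: `nis_polar`, `nis_apolar`, `nis_charged`.
#' @export
nis_percentages <- function(structure, surface_cutoff = 0.05,
                            n_points = 960, probe = 1.4,
                            classes = residue_class_table()) {
  res <- residue_sasa(structure, n_points = n_points, probe = probe)
  surf <- res[res$rel_accessibility >= surface_cutoff, , drop = FALSE]
  if (nrow(surf) == 0L) stop("structure has no surface residues")
  cl <- classify_residue(surf$residue_name, classes)
  tibble::tibble(
    nis_polar = 100 * mean(cl == "polar"),
    nis_apolar = 100 * mean(cl == "apolar"),
    nis_charged = 100 * mean(cl == "charged"))
}

#' Contact + %NIS feature table for a set of structures
#'
#' Assembles the nine-descriptor feature vector (six class-pair contact
#' counts at `threshold` plus the three %NIS percentages) per structure.
#' %NIS does not depend on the contact threshold, so precomputed values
#' can be passed when sweeping a threshold grid.
#'
#' @param structures Named list of `heterodimer` objects.
#' @param threshold Contact distance threshold in angstrom.
#' @param nis Optional precomputed tibble from [nis_table()].
#' @param classes Residue-class membership table.
#' @return Wide tibble: `accession`, six `contacts_*` columns, three
#'   `nis_*` columns.
#' @export
prodigy_table <- function(structures, threshold, nis = NULL,
                          classes = residue_class_table()) {
  if (inherits(structures, "heterodimer")) structures <- list(structures)
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(s) s$accession, character(1))
  if (is.null(nis)) nis <- nis_table(structures, classes = classes)
  rows <- purrr::imap(structures, function(s, acc) {
    ct <- prodigy_contacts(s, threshold, classes = classes)
    tibble::as_tibble(c(list(accession = acc),
                        stats::setNames(as.list(ct$count),
                                        paste0("contacts_", ct$class_pair))))
  })
  dplyr::left_join(dplyr::bind_rows(rows), nis, by = "accession")
}

#' @rdname prodigy_table
#' @inheritParams nis_percentages
#' @export
nis_table <- function(structures, surface_cutoff = 0.05, n_points = 960,
                      probe = 1.4, classes = residue_class_table()) {
  if (is.null(names(structures)))
    names(structures) <- vapply(structures, function(s) s$accession, character(1))
  dplyr::bind_rows(purrr::imap(structures, function(s, acc) {
    dplyr::bind_cols(tibble::tibble(accession = acc),
                     nis_percentages(s, surface_cutoff = surface_cutoff,
                                     n_points = n_points, probe = probe,
                                     classes = classes))
  }))
}
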