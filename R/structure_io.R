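# Parsing, filtering and writing of two-chain protein complexes.
#
# Filtering contract: hydrogens, waters and free-floating heteroatoms are
# removed; heteroatom groups covalently attached to a protein chain are
# kept with that chain.

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# amino-acid variants that occupy a chain position but are not one of the
# standard twenty; they contribute 'X' to the sequence
.aa_variants <- c("MSE", "SEC", "PYL", "SEP", "TPO", "PTR", "HYP",
                  "MLY", "CSO", "KCX", "CME", "UNK")

.water_names <- c("HOH", "WAT", "DOD", "H2O")

.is_amino <- function(residue_name) {
  residue_name %in% names(.aa3) | residue_name %in% .aa_variants
}

.is_hydrogen <- function(element, atom_name) {
  el <- toupper(trimws(element))
  known <- !is.na(el) & nzchar(el)
  hyd <- known & el %in% c("H", "D")
  # element column blank: fall back to the atom name, digits stripped
  stripped <- sub("^[0-9']*", "", trimws(atom_name))
  hyd[!known] <- substr(stripped[!known], 1, 1) %in% c("H", "D")
  hyd
}

#' Construct a heterodimer structure from an atom table
#'
#' Low-level constructor used by the reader and the synthetic generator.
#' The atom table must already satisfy the filtering contract (no
#' hydrogens, no waters).
#'
#' @param atoms Tibble with columns `chain_role` ("a"/"b"), `chain_id`,
#'   `residue_index`, `residue_name`, `atom_name`, `element`, `x`, `y`,
#'   `z`, `is_hetatm`.
#' @param accession Identifier string.
#' @param resolution Resolution in angstrom, or `NA`.
#' @return An object of class `heterodimer` with the atom table, the two
#'   chain sequences and metadata.
#' @export
new_heterodimer <- function(atoms, accession, resolution = NA_real_) {
  stopifnot(all(c("chain_role", "chain_id", "residue_index", "residue_name",
                  "atom_name", "element", "x", "y", "z", "is_hetatm") %in%
                  names(atoms)))
  if (!setequal(unique(atoms$chain_role), c("a", "b")))
    stop("a heterodimer needs exactly two chains with at least one atom each")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  structure(list(
    accession = accession,
    atoms = tibble::as_tibble(atoms),
    sequence_a = extract_sequence(atoms[atoms$chain_role == "a", ]),
    sequence_b = extract_sequence(atoms[atoms$chain_role == "b", ]),
    resolution = resolution
  ), class = "heterodimer")
}

#' @export
print.heterodimer <- function(x, ...) {
  cat(sprintf("<heterodimer %s> chain a: %d aa, chain b: %d aa, %d heavy atoms\n",
              x$accession, nchar(x$sequence_a), nchar(x$sequence_b),
              nrow(x$atoms)))
  invisible(x)
}

#' Chain atom tables of a heterodimer
#'
#' @param x A `heterodimer`.
#' @param role `"a"` or `"b"`.
#' @return Tibble of the atoms of one chain.
#' @export
chain_atoms <- function(x, role = c("a", "b")) {
  role <- match.arg(role)
  x$atoms[x$atoms$chain_role == role, , drop = FALSE]
}

#' Extract the one-letter amino-acid sequence of a chain
#'
#' One letter per amino-acid residue in residue-index order; nonstandard
#' amino acids map to `"X"`; covalently attached non-amino-acid groups
#' (sugars, cofactors) contribute no letter.
#'
#' @param chain Tibble of atoms for one chain (columns `residue_index`,
#'   `residue_name` at least).
#' @return A single amino-acid string.
#' @export
extract_sequence <- function(chain) {
  if (nrow(chain) == 0L) stop("empty chain")
  res <- dplyr::distinct(chain[order(chain$residue_index), ],
                         .data$residue_index, .data$residue_name)
  res <- res[.is_amino(res$residue_name), , drop = FALSE]
  if (nrow(res) == 0L) stop("chain has no amino-acid residues")
  letters1 <- .aa3[res$residue_name]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# connected components over an adjacency defined by inter-atom distance
# below `cutoff`; returns integer component label per row of `coords`
.distance_components <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  d <- as.matrix(stats::dist(coords))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (d[i, j] <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Read a two-chain protein complex from a PDB file
#'
#' Parses a PDB file (via the `bio3d` reader) and applies the filtering
#' rules: hydrogen atoms and atoms with missing coordinates are dropped;
#' water molecules and chemicals not covalently attached to a protein are
#' excluded; heteroatom groups are kept only when some atom of their
#' connected group lies within `attach_cutoff` of a protein heavy atom of
#' the same chain. Alternate locations other than `' '`/`'A'` are dropped.
#'
#' @param path Path to a PDB file.
#' @param chain_pair Optional character vector of two chain identifiers.
#'   Required when the file holds more than two protein chains; otherwise
#'   the two longest protein chains are chosen with a warning.
#' @param accession Identifier to store; defaults to the file name.
#' @param attach_cutoff Covalent-attachment distance in angstrom between
#'   heavy atoms (default 1.9, a generous covalent-bond upper bound).
#' @return A [new_heterodimer()] object.
#' @export
read_heterodimer <- function(path, chain_pair = NULL, accession = NULL,
                             attach_cutoff = 1.9) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(accession))
    accession <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- tibble::as_tibble(pdb$atom)
  at <- at[stats::complete.cases(at[, c("x", "y", "z")]), , drop = FALSE]
  at <- at[!(at$resid %in% .water_names), , drop = FALSE]
  at <- at[!.is_hydrogen(at$elesy, at$elety), , drop = FALSE]
  at$protein <- .is_amino(at$resid)

  chain_len <- at |>
    dplyr::filter(.data$protein) |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(n_res = dplyr::n_distinct(.data$resno)) |>
    dplyr::arrange(dplyr::desc(.data$n_res))
  if (nrow(chain_len) < 2L)
    stop("structural error: fewer than two protein chains in ", path)
  if (is.null(chain_pair)) {
    chain_pair <- chain_len$chain[1:2]
    if (nrow(chain_len) > 2L)
      warning("more than two protein chains; using the two longest: ",
              paste(chain_pair, collapse = ", "))
  }
  if (!all(chain_pair %in% chain_len$chain))
    stop("requested chain(s) not found or not protein: ",
         paste(setdiff(chain_pair, chain_len$chain), collapse = ", "))

  sel <- at[at$chain %in% chain_pair, , drop = FALSE]
  keep_rows <- lapply(chain_pair, function(ch) {
    cat_atoms <- sel[sel$chain == ch, , drop = FALSE]
    prot <- cat_atoms[cat_atoms$protein, , drop = FALSE]
    het <- cat_atoms[!cat_atoms$protein, , drop = FALSE]
    if (nrow(het) > 0L) {
      # expand connected heteroatom components; keep those attached to the
      # protein part of the same chain
      comp <- .distance_components(as.matrix(het[, c("x", "y", "z")]),
                                   attach_cutoff)
      pc <- as.matrix(prot[, c("x", "y", "z")])
      attached_atom <- vapply(seq_len(nrow(het)), function(i) {
        dx <- pc[, 1] - het$x[i]; dy <- pc[, 2] - het$y[i]; dz <- pc[, 3] - het$z[i]
        min(dx * dx + dy * dy + dz * dz) <= attach_cutoff^2
      }, logical(1))
      keep_comp <- unique(comp[attached_atom])
      het <- het[comp %in% keep_comp, , drop = FALSE]
    }
    dplyr::bind_rows(prot, het)
  })
  names(keep_rows) <- chain_pair

  to_atoms <- function(df, role) {
    tibble::tibble(
      chain_role = role, chain_id = df$chain,
      residue_index = as.integer(df$resno), residue_name = df$resid,
      atom_name = trimws(df$elety),
      element = toupper(ifelse(is.na(df$elesy) | !nzchar(trimws(df$elesy)),
                               substr(sub("^[0-9']*", "", trimws(df$elety)), 1, 1),
                               trimws(df$elesy))),
      x = df$x, y = df$y, z = df$z,
      is_hetatm = df$type == "HETATM")
  }
  atoms <- dplyr::bind_rows(to_atoms(keep_rows[[1]], "a"),
                            to_atoms(keep_rows[[2]], "b"))
  new_heterodimer(atoms, accession = accession)
}

#' Write a heterodimer back to PDB format
#'
#' Debug writer emitting fixed-column ATOM/HETATM records for the filtered
#' structure; the output is readable by [read_heterodimer()] and by
#' standard PDB software.
#'
#' @param x A `heterodimer`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_heterodimer <- function(x, path) {
  a <- x$atoms
  rec <- ifelse(a$is_hetatm, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(a$atom_name) >= 4, substr(a$atom_name, 1, 4),
                  sprintf(" %-3s", a$atom_name))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name4, a$residue_name,
                   substr(a$chain_id, 1, 1), a$residue_index,
                   a$x, a$y, a$z, 1.00, 0.00, a$element)
  ter_at <- max(which(a$chain_role == "a"))
  lines <- append(lines, "TER", after = ter_at)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
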