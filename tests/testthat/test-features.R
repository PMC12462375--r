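# RF-score pair counts, residue-class contacts and %NIS.

one_atom_chain <- function(element, x, y, z, res = "ALA", idx = 1) {
  tibble::tibble(element = element, x = x, y = y, z = z,
                 residue_name = res, residue_index = idx)
}

test_that("a single cross-chain pair is counted iff within the cutoff", {
  s <- make_structure(one_atom_chain("C", 0, 0, 0),
                      one_atom_chain("N", 0, 0, 5))
  f <- rfscore_features(s)
  expect_equal(f$count[f$pair == "C_N"], 1)
  expect_equal(sum(f$count), 1)
  s2 <- make_structure(one_atom_chain("C", 0, 0, 0),
                       one_atom_chain("N", 0, 0, 12.001))
  expect_equal(sum(rfscore_features(s2)$count), 0)
  # the boundary itself is inclusive
  s3 <- make_structure(one_atom_chain("C", 0, 0, 0),
                       one_atom_chain("N", 0, 0, 12))
  expect_equal(sum(rfscore_features(s3)$count), 1)
})

test_that("pair counts match brute-force enumeration on random structures", {
  for (sd in 1:50) {
    s <- random_structure(n_res = 8, seed = sd)
    got <- rfscore_features(s)
    oracle <- brute_rfscore(s)
    expect_equal(sum(got$count), sum(unlist(oracle)))
    for (key in names(oracle))
      expect_equal(got$count[got$pair == key], oracle[[key]],
                   label = sprintf("seed %d pair %s", sd, key))
  }
})

test_that("pair counts are invariant under rigid motion and chain swap", {
  s <- random_structure(n_res = 10, seed = 3)
  f0 <- rfscore_features(s)
  # random rotation + translation
  set.seed(11)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  shift <- c(5, -3, 8)
  at <- s$atoms
  P <- as.matrix(at[, c("x", "y", "z")]) %*% Q
  at$x <- P[, 1] + shift[1]; at$y <- P[, 2] + shift[2]; at$z <- P[, 3] + shift[3]
  f1 <- rfscore_features(new_heterodimer(at, "ROT"))
  expect_equal(f1$count, f0$count)
  # swap the chain roles
  at2 <- s$atoms
  at2$chain_role <- ifelse(at2$chain_role == "a", "b", "a")
  f2 <- rfscore_features(new_heterodimer(at2, "SWP"))
  expect_equal(f2$count, f0$count)
})

test_that("a fixed vocabulary rejects foreign elements and aligns tables", {
  s <- make_structure(one_atom_chain("SE", 0, 0, 0, res = "MET"),
                      one_atom_chain("N", 0, 0, 5))
  expect_error(rfscore_features(s, vocabulary = c("C_N", "C_C")), "SE")
  tab <- rfscore_table(list(s), vocabulary = c("C_N", "N_SE"))
  expect_equal(names(tab), c("accession", "C_N", "N_SE"))
  expect_equal(tab$N_SE, 1)
})

test_that("residue classes follow the membership table", {
  expect_equal(classify_residue(c("ASP", "SER", "LEU", "HIS", "TRP")),
               c("charged", "polar", "apolar", "charged", "apolar"))
  expect_warning(got <- classify_residue("XYZ"), "nonstandard")
  expect_equal(got, "apolar")
})

test_that("residue contacts respect the threshold and match enumeration", {
  s <- make_structure(one_atom_chain("C", 0, 0, 0, res = "ASP"),
                      one_atom_chain("C", 0, 0, 4, res = "LEU"))
  ct <- prodigy_contacts(s, 5.5)
  expect_equal(ct$count[ct$class_pair == "apolar_charged"], 1)
  expect_equal(sum(ct$count), 1)
  expect_equal(sum(prodigy_contacts(s, 3.5)$count), 0)
  expect_error(prodigy_contacts(s, 25), "grid")
  for (sd in 1:30) {
    s <- random_structure(n_res = 6, seed = 100 + sd)
    got <- prodigy_contacts(s, 5.5)
    oracle <- brute_contacts(s, 5.5)
    expect_equal(sum(got$count), sum(unlist(oracle)))
    for (key in names(oracle))
      expect_equal(got$count[got$class_pair == key], oracle[[key]])
  }
})

test_that("contact counts grow monotonically with the threshold", {
  s <- random_structure(n_res = 12, seed = 77)
  totals <- vapply(seq(3.5, 20, by = 1.5), function(t)
    sum(prodigy_contacts(s, t)$count), numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("%NIS reflects surface-residue class composition", {
  # a ring of residues, all solvent exposed
  ring <- function(classes_res) {
    n <- length(classes_res)
    th <- 2 * pi * seq_len(n) / n
    tibble::tibble(element = "C", x = 10 * cos(th), y = 10 * sin(th), z = 0,
                   residue_name = classes_res, residue_index = seq_len(n))
  }
  s <- make_structure(ring(rep(c("ASP", "LYS", "ARG"), 4)),
                      one_atom_chain("C", 0, 0, 40, res = "HIS"))
  nis <- nis_percentages(s)
  expect_equal(nis$nis_charged, 100)
  expect_equal(nis$nis_polar, 0)
  expect_equal(nis$nis_apolar, 0)
  s2 <- make_structure(ring(rep(c("ASP", "SER", "LEU"), 4)),
                       one_atom_chain("C", 0, 0, 40, res = "ASP"))
  nis2 <- nis_percentages(s2)
  expect_equal(nis2$nis_charged, 100 * 4 / 13, tolerance = 0.5)
  expect_equal(nis2$nis_polar + nis2$nis_apolar + nis2$nis_charged, 100)
})

test_that("compiled SASA agrees with an independent sphere-point oracle", {
  s <- generate_structure(random_aa_seq(8), random_aa_seq(8),
                          generator_config(interface_contact_target = 60),
                          seed = 21)
  coords <- as.matrix(s$atoms[, c("x", "y", "z")])
  radii <- kdcurate:::.atom_radii(s$atoms$element)
  mine <- kdcurate:::.sasa_shrake_rupley(coords, radii, 960L, 1.4)
  oracle <- sasa_r_oracle(coords, radii, 960, 1.4, seed = 5)
  # per-atom areas from two different point sets agree up to the
  # oracle's own Monte Carlo error (3 sigma ~ 5% of a sphere at 960
  # random points)
  expect_lt(max(abs(mine - oracle)) / (4 * pi * 3.1^2), 0.05)
  # and the derived %NIS agrees within one percentage point
  res <- residue_sasa(s)
  at <- s$atoms
  at$sasa <- oracle
  res_o <- dplyr::summarise(
    dplyr::group_by(at, chain_role, residue_index, residue_name),
    sasa = sum(sasa), .groups = "drop")
  ref <- kdcurate:::.max_asa[res_o$residue_name]
  surf_o <- res_o[res_o$sasa / ref >= 0.05, ]
  cl <- classify_residue(surf_o$residue_name)
  nis_o <- c(polar = 100 * mean(cl == "polar"),
             apolar = 100 * mean(cl == "apolar"),
             charged = 100 * mean(cl == "charged"))
  nis <- nis_percentages(s)
  expect_equal(nis$nis_polar, nis_o[["polar"]], tolerance = 1)
  expect_equal(nis$nis_apolar, nis_o[["apolar"]], tolerance = 1)
  expect_equal(nis$nis_charged, nis_o[["charged"]], tolerance = 1)
})

test_that("feature tables assemble contacts and %NIS per accession", {
  ss <- list(generate_structure(random_aa_seq(10), random_aa_seq(10),
                                generator_config(interface_contact_target = 80),
                                seed = 31, accession = "S1"),
             generate_structure(random_aa_seq(12), random_aa_seq(9),
                                generator_config(interface_contact_target = 80),
                                seed = 32, accession = "S2"))
  nis <- nis_table(ss, n_points = 240)
  tab <- prodigy_table(ss, threshold = 6.5, nis = nis)
  expect_equal(nrow(tab), 2)
  expect_equal(ncol(tab), 10)  # accession + 6 contacts + 3 nis
  expect_true(all(tab$nis_polar >= 0 & tab$nis_polar <= 100))
})
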