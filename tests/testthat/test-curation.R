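# KD parsing, category classification and dataset-subset construction.

test_that("KD tokens normalize to molar values with printed precision", {
  got <- parse_kd_token(c("Kd=1.5nM", "Kd=2.49uM", "Kd=740nM", "Kd=0.50mM"))
  expect_equal(got$value_molar, c(1.5e-9, 2.49e-6, 7.4e-7, 5e-4))
  expect_equal(got$sig_figs, c(2L, 3L, 2L, 2L))
  expect_equal(got$significand, c(1.5, 2.49, 7.4, 5), tolerance = 1e-9)
  expect_equal(got$exponent, c(-9L, -6L, -7L, -4L))
  expect_error(parse_kd_token("Kd=5xM"), "unknown")
  expect_error(parse_kd_token("IC50=5nM"), "unparseable")
})

make_entry <- function(db, lit, match = TRUE, multi = "", prec = 3,
                       acc = "XXXX") {
  tibble::tibble(accession = acc, db_kd = db, lit_kd = lit,
                 construct_match = match,
                 multisite_kd_2 = multi, precision = prec)
}

test_that("rule cascade reproduces the worked category examples", {
  # database value exactly equals the literature value for the construct
  expect_equal(as.character(
    categorize_entries(make_entry("2.49e-7", "2.49e-7"))$category), "Match")
  # value agrees except for a 10^3 unit slip
  units <- categorize_entries(make_entry("1.5e-7", "1.5e-10"))
  expect_equal(as.character(units$category), "Units")
  expect_gte(abs(units$log10_delta), 3)
  # database stores the lower-precision figure value next to a more
  # precise table value for the same construct
  approx <- categorize_entries(dplyr::bind_rows(
    make_entry("8e-7", "7.4e-7", prec = 2),
    make_entry("8e-7", "8e-7", prec = 1)))
  expect_equal(as.character(approx$category), "Approximate")
  expect_equal(approx$corrected_molar, 7.4e-7)
  # database value matches a measurement for a different construct
  diffh <- categorize_entries(dplyr::bind_rows(
    make_entry("1.1e-6", "1.3e-6", match = TRUE),
    make_entry("1.1e-6", "1.1e-6", match = FALSE)))
  expect_equal(as.character(diffh$category), "DifferentHeterodimer")
  expect_equal(diffh$corrected_molar, 1.3e-6)
  # no literature value for the deposited construct
  expect_equal(as.character(
    categorize_entries(make_entry("1e-8", "1e-8", match = FALSE))$category),
    "NoKD")
  # two-site model in the literature
  expect_equal(as.character(
    categorize_entries(make_entry("1.2e-8", "1.2e-8", multi = "2.5e-6"))$category),
    "MultisiteKD")
})

test_that("Units fires only for matching significands three orders apart", {
  # 10^6 slip also counts
  expect_equal(as.character(
    categorize_entries(make_entry("1.5e-4", "1.5e-10"))$category), "Units")
  # same order of magnitude, different value: not Units
  expect_equal(as.character(
    categorize_entries(make_entry("2.5e-7", "1.5e-7"))$category),
    "DifferentHeterodimer")
  # different significand three orders apart: not Units
  expect_equal(as.character(
    categorize_entries(make_entry("2.5e-7", "1.5e-10"))$category),
    "DifferentHeterodimer")
  # 10^2 apart with equal significand: not Units
  expect_equal(as.character(
    categorize_entries(make_entry("1.5e-8", "1.5e-10"))$category),
    "DifferentHeterodimer")
})

test_that("categorize is pure and order-preserving", {
  cur <- dplyr::bind_rows(
    make_entry("1e-7", "1e-7", acc = "B2"),
    make_entry("2e-7", "2e-10", acc = "A1"))
  r1 <- categorize_entries(cur)
  r2 <- categorize_entries(cur)
  expect_identical(r1, r2)
  expect_equal(r1$accession, c("B2", "A1"))
})

test_that("error rate counts non-Match records as a percentage", {
  cats <- factor(rep(c("Match", "Units", "Approximate"), c(7, 2, 1)),
                 levels = curation_categories())
  expect_equal(error_rate(cats)$percent, 30)
  expect_equal(error_rate(cats, include_approximate = FALSE)$percent, 20)
  expect_equal(error_rate(rep("Match", 13))$percent, 0)
  expect_error(error_rate(character(0)), "no categorized")
  # seeded random assignment agrees with a direct tally
  set.seed(4)
  cats <- sample(curation_categories(), 97, replace = TRUE)
  expect_equal(error_rate(cats)$n_errors, sum(cats != "Match"))
})

test_that("subset construction drops and corrects the right records", {
  set.seed(8)
  truth <- tibble::tibble(accession = sprintf("S%03d", 1:262),
                          true_log10_kd = runif(262, -11, -4))
  inj <- inject_errors(truth, seed = 3)
  cat_tbl <- categorize_entries(inj$curation)
  subs <- build_subsets(cat_tbl)
  sizes <- table(subs$subset)
  expect_equal(unname(sizes[["FullCorrection"]]), 236)
  expect_equal(unname(sizes[["NoKDOnly"]]), 238)
  expect_equal(unname(sizes[["UnitsOnly"]]), 262)
  expect_equal(unname(sizes[["DifferentHeterodimerOnly"]]), 262)
  expect_equal(unname(sizes[["PDBBind"]]), 262)
  # Units-corrected subset replaces exactly the Units records
  units_acc <- cat_tbl$accession[cat_tbl$category == "Units"]
  uo <- subs[subs$subset == "UnitsOnly", ]
  pb <- subs[subs$subset == "PDBBind", ]
  changed <- uo$accession[uo$train_log10_kd !=
                            pb$train_log10_kd[match(uo$accession, pb$accession)]]
  expect_setequal(changed, units_acc)
})

test_that("an all-Match table yields five identical subsets", {
  cur <- dplyr::bind_rows(lapply(1:10, function(i)
    make_entry(sprintf("%de-8", i), sprintf("%de-8", i),
               acc = sprintf("M%02d", i))))
  subs <- build_subsets(categorize_entries(cur))
  expect_true(all(table(subs$subset) == 10))
  wide <- tidyr::pivot_wider(subs, id_cols = "accession",
                             names_from = "subset",
                             values_from = "train_log10_kd")
  for (nm in subset_names()[-1])
    expect_equal(wide[[nm]], wide$FullCorrection)
})

test_that("index files round-trip through the reader", {
  idx <- tibble::tibble(accession = c("1ABC", "2DEF"),
                        kd_token = c("Kd=3.2nM", "Kd=15uM"))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment line",
               sprintf("%s  2.00  2020  %s  // ref", idx$accession,
                       idx$kd_token),
               "3GHI  1.80  2019  Ki=4nM  // skipped"), path)
  expect_message(read_pdbbind_index(path), "non-Kd")
  got <- suppressMessages(read_pdbbind_index(path))
  expect_equal(got$accession, idx$accession)
  expect_equal(got$value_molar, c(3.2e-9, 1.5e-5))
})

test_that("audit tallies categories and prints the error rate", {
  set.seed(8)
  truth <- tibble::tibble(accession = sprintf("S%03d", 1:50),
                          true_log10_kd = runif(50, -11, -4))
  inj <- inject_errors(truth, c(NoKD = 0.1, Units = 0.06), seed = 2)
  aud <- curation_audit(inj$curation)
  expect_s3_class(tidy(aud), "tbl_df")
  expect_equal(sum(aud$counts$n), 50)
  g <- glance(aud)
  expect_equal(g$n_NoKD, 5)
  expect_equal(g$n_Units, 3)
  expect_equal(g$n_errors, 8)
})
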