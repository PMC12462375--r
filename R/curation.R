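#' @useDynLib kdcurate, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# ---- KD value parsing --------------------------------------------------

.kd_unit_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6,
                      "μM" = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15)

# significant figures of a printed decimal number ("740" -> 2, "0.50" -> 2,
# "2.49" -> 3); trailing zeros without a decimal point are not significant
.sig_figs_of <- function(num_str) {
  mant <- sub("[eE][+-]?[0-9]+$", "", num_str)
  mant <- sub("^[+-]", "", mant)
  digits <- gsub("\\.", "", mant)
  digits <- sub("^0+", "", digits)
  if (!grepl("\\.", mant)) digits <- sub("0+$", "", digits)
  n <- nchar(digits)
  max(n, 1L)
}

#' Parse a molar value written as text, keeping its printed precision
#'
#' Decomposes a KD value such as `"7.4e-07"` or `"0.5"` into molar value,
#' significand in `[1, 10)`, decimal exponent and the number of significant
#' figures implied by the printed digits.
#'
#' @param x Character vector of decimal or scientific-notation numbers.
#' @return A tibble with columns `value_molar`, `significand`, `exponent`
#'   and `sig_figs`, one row per element of `x`.
#' @export
parse_molar_value <- function(x) {
  stopifnot(is.character(x))
  value <- as.numeric(x)
  if (any(is.na(value)) || any(value <= 0)) {
    stop("KD values must be positive numbers; offending input: ",
         paste(x[is.na(value) | value <= 0], collapse = ", "))
  }
  exponent <- floor(log10(value) + 1e-12)
  significand <- value / 10^exponent
  # guard against floating-point landing exactly on 10
  roll <- significand >= 10 - 1e-9
  exponent[roll] <- exponent[roll] + 1L
  significand[roll] <- significand[roll] / 10
  tibble::tibble(
    value_molar = value,
    significand = significand,
    exponent = as.integer(exponent),
    sig_figs = vapply(x, .sig_figs_of, integer(1), USE.NAMES = FALSE)
  )
}

#' Parse PDBBind-style KD tokens
#'
#' Tokens look like `"Kd=1.5nM"` or `"Kd=2.49uM"`. The value is normalized
#' to molar units and the printed precision is recorded.
#'
#' @param token Character vector of `Kd=<value><unit>` tokens; recognized
#'   units are M, mM, uM (or the Greek mu), nM, pM and fM.
#' @return A tibble with columns `token`, `value_molar`, `significand`,
#'   `exponent`, `sig_figs`.
#' @examples
#' parse_kd_token(c("Kd=1.5nM", "Kd=740nM"))
#' @export
parse_kd_token <- function(token) {
  stopifnot(is.character(token))
  m <- regmatches(token, regexec(
    "^K[di]=~?([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)([A-Za-zµμ]+)$",
    token))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable KD token(s): ", paste(token[bad], collapse = ", "))
  num <- vapply(m, `[`, character(1), 2L)
  unit <- vapply(m, `[`, character(1), 3L)
  unknown <- !(unit %in% names(.kd_unit_factors))
  if (any(unknown)) stop("unknown KD unit(s): ", paste(unique(unit[unknown]), collapse = ", "))
  value <- as.numeric(num) * unname(.kd_unit_factors[unit])
  if (any(value <= 0)) stop("non-positive KD value in token(s): ",
                            paste(token[value <= 0], collapse = ", "))
  parsed <- parse_molar_value(num)
  tibble::tibble(
    token = token,
    value_molar = value,
    significand = parsed$significand,
    exponent = as.integer(floor(log10(value) + 1e-12) +
                            (parsed$significand >= 10 - 1e-9)),
    sig_figs = parsed$sig_figs
  )
}

#' Read a PDBBind-style index file
#'
#' Parses the whitespace-separated layout of `INDEX_general_PP.<year>`
#' files: accession, resolution, year, a `Kd=<value><unit>` token and a
#' free-text citation. Comment lines start with `#`. Only `Kd=` rows are
#' admitted (Ki and IC50 rows are skipped with a message).
#'
#' @param path Path to the index file.
#' @return A tibble with columns `accession`, `resolution`, `year`,
#'   `kd_token`, `value_molar`, `log10_kd`.
#' @export
read_pdbbind_index <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(fields, function(f) length(f) >= 4 && grepl("^Kd=", f[[4]]), logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    message(n_skipped, " non-Kd row(s) skipped while reading ", path)
  fields <- fields[ok]
  kd <- parse_kd_token(vapply(fields, `[`, character(1), 4L))
  tibble::tibble(
    accession = vapply(fields, `[`, character(1), 1L),
    resolution = suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L))),
    year = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L))),
    kd_token = kd$token,
    value_molar = kd$value_molar,
    log10_kd = log10(kd$value_molar)
  )
}

# ---- curation table ----------------------------------------------------

#' Read a curation table pairing database and literature KD records
#'
#' The exchange format is a CSV with one row per literature KD record:
#' `accession`, `db_kd` (database value, printed form), `lit_kd`
#' (literature value, printed form), `construct_match` (does the measured
#' construct match the deposited structure), `multisite_kd_2` (second KD of
#' a two-site binding model, empty otherwise), `precision` (significant
#' figures of the literature value as printed).
#'
#' @param path Path to the CSV file.
#' @return A tibble in the curation-table schema, KD columns kept as text
#'   so printed precision survives.
#' @export
read_curation_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    accession = "character", db_kd = "character", lit_kd = "character",
    construct_match = "logical", multisite_kd_2 = "character",
    precision = "integer"))
  tibble::as_tibble(df)
}

#' @rdname read_curation_table
#' @param tbl Curation tibble to write.
#' @export
write_curation_table <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.rel_eq <- function(a, b, tol) {
  is.finite(a) & is.finite(b) & abs(a - b) <= tol * pmax(abs(a), abs(b))
}

#' Curation categories
#'
#' The six categories used to label database KD values against the
#' literature: `Match` (database value exactly agrees with the primary
#' literature value for the deposited construct), `NoKD` (the literature
#' reports no KD for the deposited construct), `DifferentHeterodimer` (the
#' database value belongs to a different complex), `Approximate` (the
#' database stores a lower-precision version of the literature value),
#' `Units` (the value agrees except for a factor of 10^3k, a unit
#' transcription slip), `MultisiteKD` (the literature reports a two-site
#' model with two KDs while the database stores one).
#'
#' @return Character vector of the six category names.
#' @export
curation_categories <- function() {
  c("Match", "NoKD", "DifferentHeterodimer", "Approximate", "Units", "MultisiteKD")
}

# categorize one accession's literature records against its database value
.categorize_one <- function(db, lit, tol_exact = 1e-9, tol_loose = 1e-6) {
  matching <- lit[lit$construct_match & !is.na(lit$lit_molar), , drop = FALSE]
  nonmatching <- lit[!lit$construct_match & !is.na(lit$lit_molar), , drop = FALSE]
  res <- function(category, corrected = NA_real_, unresolved = FALSE) {
    list(category = category, corrected = corrected, unresolved = unresolved)
  }
  if (nrow(matching) == 0L) return(res("NoKD"))
  if (any(!is.na(matching$multisite_molar))) return(res("MultisiteKD"))
  # the primary literature value is the most precise one
  primary_i <- order(-matching$precision)[1L]
  primary <- matching$lit_molar[primary_i]
  if (.rel_eq(db$value_molar, primary, tol_exact))
    return(res("Match", primary))
  ratio <- abs(log10(db$value_molar / matching$lit_molar))
  units_hit <- .rel_eq(db$significand,
                       parse_molar_value(sprintf("%.15g", matching$lit_molar))$significand,
                       tol_loose) &
    (abs(ratio - 3) < 1e-6 | abs(ratio - 6) < 1e-6 | abs(ratio - 9) < 1e-6)
  if (any(units_hit)) return(res("Units", matching$lit_molar[which(units_hit)[1L]]))
  rounded <- signif(primary, db$sig_figs)
  approx_hit <- .rel_eq(db$value_molar, rounded, tol_exact) ||
    any(.rel_eq(db$value_molar, matching$lit_molar[-primary_i], tol_exact))
  if (approx_hit) return(res("Approximate", primary))
  if (nrow(nonmatching) > 0L &&
      any(.rel_eq(db$value_molar, nonmatching$lit_molar, tol_loose)))
    return(res("DifferentHeterodimer", primary))
  res("DifferentHeterodimer", primary, unresolved = TRUE)
}

#' Classify database KD records into curation categories
#'
#' Applies a deterministic rule cascade per accession: no
#' matching-construct literature value -> `NoKD`; a two-site record ->
#' `MultisiteKD`; exact agreement with the primary (most precise)
#' matching-construct value -> `Match`; agreeing significand with a
#' 10^3k-fold discrepancy -> `Units`; agreement after rounding the primary
#' value to the database's printed precision, or exact agreement with an
#' alternative lower-precision value for the same construct ->
#' `Approximate`; agreement with a value measured for a different construct
#' -> `DifferentHeterodimer`; anything else falls through to
#' `DifferentHeterodimer` flagged `unresolved`.
#'
#' @param curation A curation tibble as returned by
#'   [read_curation_table()].
#' @return A tibble with one row per accession: `accession`, `category`
#'   (factor over [curation_categories()]), `db_molar`, `corrected_molar`
#'   (the literature value, `NA` for `NoKD`/`MultisiteKD`), `log10_delta`
#'   (database minus corrected, log10 molar) and `unresolved`.
#' @export
categorize_entries <- function(curation) {
  stopifnot(all(c("accession", "db_kd", "lit_kd", "construct_match",
                  "multisite_kd_2", "precision") %in% names(curation)))
  out <- curation |>
    dplyr::group_by(.data$accession) |>
    dplyr::group_map(function(g, key) {
      db <- parse_molar_value(g$db_kd[1L])
      has_lit <- !is.na(g$lit_kd) & nzchar(g$lit_kd)
      lit <- tibble::tibble(
        lit_molar = ifelse(has_lit, suppressWarnings(as.numeric(g$lit_kd)), NA_real_),
        construct_match = g$construct_match,
        multisite_molar = suppressWarnings(as.numeric(g$multisite_kd_2)),
        precision = ifelse(is.na(g$precision), 1L, g$precision))
      lit <- lit[!is.na(lit$lit_molar), , drop = FALSE]
      if (nrow(lit) == 0L && !any(has_lit))
        warning("accession ", key$accession,
                " has no literature KD records; classified NoKD", call. = FALSE)
      r <- .categorize_one(db, lit)
      tibble::tibble(
        accession = key$accession,
        category = r$category,
        db_molar = db$value_molar,
        corrected_molar = r$corrected,
        unresolved = r$unresolved)
    }) |>
    dplyr::bind_rows()
  out$category <- factor(out$category, levels = curation_categories())
  out$log10_delta <- log10(out$db_molar) - log10(out$corrected_molar)
  # keep input order
  out[match(unique(curation$accession), out$accession), , drop = FALSE]
}

#' Curation error rate
#'
#' Fraction of categorized records whose database KD value is not
#' supported by the literature, i.e. category other than `Match`. Whether
#' `Approximate` counts as an error is configurable; the default counts it
#' (an approximate value is not the value the literature prints).
#'
#' @param categories A tibble from [categorize_entries()], or a factor /
#'   character vector of categories.
#' @param include_approximate Count `Approximate` records as errors?
#' @return One-row tibble: `n`, `n_errors`, `fraction`, `percent`
#'   (rounded to two decimals).
#' @export
error_rate <- function(categories, include_approximate = TRUE) {
  if (is.data.frame(categories)) categories <- categories$category
  categories <- as.character(categories)
  if (length(categories) == 0L) stop("no categorized entries supplied")
  good <- "Match"
  if (!include_approximate) good <- c(good, "Approximate")
  n <- length(categories)
  n_err <- sum(!categories %in% good)
  tibble::tibble(n = n, n_errors = n_err, fraction = n_err / n,
                 percent = round(100 * n_err / n, 2))
}

#' Build the five evaluation subsets
#'
#' Materializes the five dataset variants used to measure the impact of
#' curation errors. `FullCorrection` drops `NoKD` and `MultisiteKD`
#' records and trains on literature values; `NoKDOnly` drops `NoKD`
#' records and trains on database values; `UnitsOnly` and
#' `DifferentHeterodimerOnly` keep all records, correcting only the named
#' category; `PDBBind` keeps all records with database values untouched.
#' Evaluation targets are always the corrected (literature) values where
#' they exist, with the database value as fallback for records whose
#' literature value is absent.
#'
#' @param categories A tibble from [categorize_entries()].
#' @return A tibble with columns `subset`, `accession`, `train_log10_kd`,
#'   `eval_log10_kd`.
#' @export
build_subsets <- function(categories) {
  ct <- categories
  db <- log10(ct$db_molar)
  lit <- log10(ct$corrected_molar)
  evalv <- ifelse(is.na(lit), db, lit)
  cat <- as.character(ct$category)
  one <- function(name, keep, train) {
    tibble::tibble(subset = name, accession = ct$accession[keep],
                   train_log10_kd = train[keep], eval_log10_kd = evalv[keep])
  }
  dplyr::bind_rows(
    one("FullCorrection", !(cat %in% c("NoKD", "MultisiteKD")),
        ifelse(is.na(lit), db, lit)),
    one("NoKDOnly", cat != "NoKD", db),
    one("UnitsOnly", rep(TRUE, nrow(ct)), ifelse(cat == "Units", lit, db)),
    one("DifferentHeterodimerOnly", rep(TRUE, nrow(ct)),
        ifelse(cat == "DifferentHeterodimer" & !is.na(lit), lit, db)),
    one("PDBBind", rep(TRUE, nrow(ct)), db)
  )
}

#' Names of the five evaluation subsets
#' @return Character vector in canonical order.
#' @export
subset_names <- function() {
  c("FullCorrection", "NoKDOnly", "UnitsOnly", "DifferentHeterodimerOnly", "PDBBind")
}

#' Audit a curation table
#'
#' Categorizes every record, tallies the categories, computes the error
#' rate, and assembles a per-record comparison of database and literature
#' log10(KD) values.
#'
#' @inheritParams categorize_entries
#' @inheritParams error_rate
#' @return An object of class `curation_audit`: a list with `records`
#'   (per-accession categories and log10 deltas), `counts` (per-category
#'   tallies) and `error` (the [error_rate()] row).
#' @export
curation_audit <- function(curation, include_approximate = TRUE) {
  records <- categorize_entries(curation)
  counts <- records |>
    dplyr::count(.data$category, name = "n", .drop = FALSE)
  structure(list(records = records, counts = counts,
                 error = error_rate(records, include_approximate)),
            class = "curation_audit")
}

#' @export
print.curation_audit <- function(x, ...) {
  cat("Curation audit of", x$error$n, "records\n")
  cat(sprintf("  not supported by the literature: %d (%.2f%%)\n",
              x$error$n_errors, x$error$percent))
  for (i in seq_len(nrow(x$counts)))
    cat(sprintf("  %-22s %4d\n", as.character(x$counts$category[i]), x$counts$n[i]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.curation_audit <- function(x, ...) x$records

#' Write the per-record audit report as CSV
#'
#' One row per accession: category, database and corrected molar values,
#' and the log10 discrepancy.
#'
#' @param audit A `curation_audit` (or the tibble from
#'   [categorize_entries()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(audit, path) {
  rec <- if (inherits(audit, "curation_audit")) audit$records else audit
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @export
glance.curation_audit <- function(x, ...) {
  dplyr::bind_cols(
    x$error,
    tidyr::pivot_wider(x$counts, names_from = "category", values_from = "n",
                       names_prefix = "n_"))
}
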