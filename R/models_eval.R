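# Affinity models (random forest on element-pair counts, AIC-stepwise
# linear on contact/%NIS descriptors) and their evaluation under repeated
# cluster-respecting cross-validation.

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param subsample_fraction Fraction of training rows (sampled without
#'   replacement) used per tree (default 0.5).
#' @param mtry_fraction Fraction of features tried at each split; the
#'   default 1 considers every feature.
#' @param nodesize Minimum terminal-node size (regression default 5).
#' @return List of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100, subsample_fraction = 0.5,
                          mtry_fraction = 1, nodesize = 5) {
  stopifnot(n_trees >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  structure(list(n_trees = n_trees, subsample_fraction = subsample_fraction,
                 mtry_fraction = mtry_fraction, nodesize = nodesize),
            class = "forest_config")
}

#' Train the random-forest affinity model
#'
#' Variance-reduction regression forest: each tree is grown on a seeded
#' random subset of the training rows (without replacement), and the
#' prediction is the mean over trees.
#'
#' @param features Data frame / tibble of numeric features (an
#'   `accession` column, if present, is dropped).
#' @param targets Numeric vector of log10(KD) training targets.
#' @param config A [forest_config()].
#' @param seed Integer seed.
#' @return Object of class `kd_forest` with a `predict` method.
#' @export
train_forest <- function(features, targets, config = forest_config(), seed = 1) {
  X <- as.data.frame(features)
  X$accession <- NULL
  stopifnot(nrow(X) == length(targets), all(is.finite(targets)))
  if (nrow(X) < 2) stop("need at least two training rows")
  if (stats::sd(targets) == 0) {
    warning("constant training target; forest predicts the constant")
    return(structure(list(constant = targets[1], config = config),
                     class = "kd_forest"))
  }
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = X, y = targets,
    ntree = config$n_trees,
    replace = FALSE,
    sampsize = max(2L, floor(config$subsample_fraction * nrow(X))),
    mtry = max(1L, floor(config$mtry_fraction * ncol(X))),
    nodesize = config$nodesize))
  structure(list(fit = fit, config = config, features = names(X)),
            class = "kd_forest")
}

#' @export
predict.kd_forest <- function(object, newdata, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(as.data.frame(newdata))))
  X <- as.data.frame(newdata)
  X$accession <- NULL
  unname(stats::predict(object$fit, X))
}

#' Stepwise-selection configuration
#'
#' @param threshold_grid Contact-distance grid in angstrom (default 3.5
#'   to 20 in steps of 0.5).
#' @return List of class `stepwise_config`; selection direction is
#'   forward-and-backward and the criterion is AIC, both fixed.
#' @export
stepwise_config <- function(threshold_grid = seq(3.5, 20, by = 0.5)) {
  structure(list(threshold_grid = threshold_grid, direction = "both",
                 criterion = "AIC"), class = "stepwise_config")
}

#' AIC-stepwise linear affinity model over a contact-threshold grid
#'
#' For every contact-distance threshold in the grid, runs
#' forward-and-backward stepwise selection (criterion
#' `n log(RSS/n) + 2(k+1)`, the default of [stats::step()] for linear
#' models) over the supplied descriptors, then returns the threshold and
#' feature set with the smallest training AIC. The threshold is selected
#' on training data only, so it is never informed by the test fold.
#'
#' @param feature_tables Named list of feature tibbles, one per threshold
#'   (names are the threshold values); each must contain the same rows in
#'   the same order (an `accession` column is dropped).
#' @param targets Numeric training targets.
#' @param config A [stepwise_config()]; thresholds absent from
#'   `feature_tables` are skipped.
#' @return Object of class `kd_stepwise`: chosen `threshold`, `features`,
#'   fitted `lm`, and `aic`.
#' @export
stepwise_linear <- function(feature_tables, targets, config = stepwise_config()) {
  stopifnot(length(feature_tables) > 0, !is.null(names(feature_tables)))
  grid <- intersect(as.character(config$threshold_grid), names(feature_tables))
  if (length(grid) == 0) stop("no feature table matches the threshold grid")
  best <- NULL
  for (th in grid) {
    X <- as.data.frame(feature_tables[[th]])
    X$accession <- NULL
    if (nrow(X) != length(targets)) stop("feature/target length mismatch at threshold ", th)
    if (length(targets) <= ncol(X) + 1)
      stop("too few training rows (", length(targets), ") for ",
           ncol(X), " candidate features")
    df <- data.frame(.y = targets, X, check.names = FALSE)
    null_fit <- stats::lm(.y ~ 1, data = df)
    scope <- stats::reformulate(sprintf("`%s`", names(X)))
    fit <- stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                       direction = "both", trace = 0)
    aic <- stats::extractAIC(fit)[2]
    if (is.null(best) || aic < best$aic) {
      best <- list(threshold = as.numeric(th),
                   features = setdiff(all.vars(stats::formula(fit)), ".y"),
                   fit = fit, aic = aic)
    }
  }
  structure(best, class = "kd_stepwise")
}

#' @export
predict.kd_stepwise <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)
  X$accession <- NULL
  unname(stats::predict(object$fit, X))
}

#' @export
print.kd_stepwise <- function(x, ...) {
  cat(sprintf("<kd_stepwise> threshold %.1f A, AIC %.2f, features: %s\n",
              x$threshold, x$aic,
              if (length(x$features)) paste(x$features, collapse = ", ")
              else "(intercept only)"))
  invisible(x)
}

#' Pearson correlation between predictions and measurements
#'
#' @param x,y Equal-length numeric vectors, length at least 3, neither
#'   constant.
#' @return The product-moment correlation.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector; correlation undefined")
  stats::cor(x, y)
}

#' One-tailed Welch's t-test
#'
#' Tests the alternative `mean(sample_a) > mean(sample_b)` with unequal
#' variances and Welch-Satterthwaite degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors, each of length at least 2,
#'   with positive variance in at least one.
#' @return Upper-tail p-value.
#' @export
welch_one_tailed <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  stopifnot(na >= 2, nb >= 2)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  se2 <- va / na + vb / nb
  t_stat <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  stats::pt(t_stat, df = df, lower.tail = FALSE)
}

# deterministic derived seeds: a small multiplicative hash over the
# master seed and stream indices, kept below 2^31
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (v in idx) h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  as.integer(h)
}

#' Run the repeated cluster-CV evaluation experiment
#'
#' For every (subset, separation threshold, trial): assigns
#' cluster-respecting five-fold splits with a trial-specific derived
#' seed, trains the model on four folds using the subset's training
#' targets, predicts the held-out fold, pools the full set of held-out
#' predictions of the trial, and records one pooled Pearson correlation
#' against the evaluation targets (the literature-corrected values for
#' every subset). With `cv = "naive"` folds are drawn over individual
#' records instead, ignoring clusters.
#'
#' @param subsets Long tibble from [build_subsets()] (columns `subset`,
#'   `accession`, `train_log10_kd`, `eval_log10_kd`), or any subset of its
#'   rows.
#' @param features For `model = "forest"`, a wide feature tibble with an
#'   `accession` column; for `model = "stepwise"`, a named list of such
#'   tibbles keyed by contact threshold.
#' @param dmat Heterodimer distance matrix over (at least) all accessions
#'   involved.
#' @param separation_thresholds Minimum cluster-separation thresholds to
#'   evaluate (default 0.1-0.6).
#' @param n_trials Number of independent trials (default 100).
#' @param model `"forest"` or `"stepwise"`.
#' @param n_folds Folds per trial (default 5).
#' @param seed Master seed; all per-trial randomness is derived from it.
#' @param cv `"cluster"` (default) or `"naive"`.
#' @param forest A [forest_config()].
#' @param stepwise A [stepwise_config()].
#' @return Object of class `kd_experiment` wrapping a tibble with columns
#'   `subset`, `model`, `cv`, `separation`, `trial`, `pearson_r`.
#' @export
run_experiment <- function(subsets, features, dmat,
                           separation_thresholds = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                           n_trials = 100, model = c("forest", "stepwise"),
                           n_folds = 5, seed = 1, cv = c("cluster", "naive"),
                           forest = forest_config(), stepwise = stepwise_config()) {
  model <- match.arg(model)
  cv <- match.arg(cv)
  get_rows <- function(tbl, acc) tbl[match(acc, tbl$accession), , drop = FALSE]
  results <- list()
  for (subset_name in unique(subsets$subset)) {
    sub <- subsets[subsets$subset == subset_name, , drop = FALSE]
    acc <- sub$accession
    cm <- if (cv == "cluster")
      single_linkage(dmat[acc, acc, drop = FALSE]) else NULL
    for (sep in separation_thresholds) {
      memb <- if (cv == "cluster") cluster_membership(cm, sep)
      else stats::setNames(seq_along(acc), acc)  # every record its own unit
      if (length(unique(memb)) < n_folds) {
        message("skipping subset ", subset_name, " at separation ", sep,
                ": fewer clusters than folds")
        next
      }
      for (trial in seq_len(n_trials)) {
        # the fold seed is independent of the subset name so that two
        # subsets holding identical records are split identically
        fseed <- derive_seed(seed, round(100 * sep), trial)
        folds <- assign_folds(memb, n_folds = n_folds, seed = fseed)
        pred <- rep(NA_real_, length(acc))
        for (f in seq_len(n_folds)) {
          test_i <- which(folds$fold == f)
          train_i <- which(folds$fold != f)
          if (length(test_i) == 0L) next
          y_train <- sub$train_log10_kd[train_i]
          if (model == "forest") {
            fit <- train_forest(get_rows(features, acc[train_i]), y_train,
                                config = forest,
                                seed = derive_seed(fseed, f))
            pred[test_i] <- stats::predict(fit, get_rows(features, acc[test_i]))
          } else {
            train_tabs <- lapply(features, get_rows, acc = acc[train_i])
            fit <- stepwise_linear(train_tabs, y_train, config = stepwise)
            test_tab <- get_rows(features[[as.character(fit$threshold)]],
                                 acc[test_i])
            pred[test_i] <- stats::predict(fit, test_tab)
          }
        }
        results[[length(results) + 1L]] <- tibble::tibble(
          subset = subset_name, model = model, cv = cv, separation = sep,
          trial = trial,
          pearson_r = pearson(pred, sub$eval_log10_kd))
      }
    }
  }
  structure(list(trials = dplyr::bind_rows(results),
                 n_trials = n_trials, n_folds = n_folds, seed = seed),
            class = "kd_experiment")
}

#' @export
print.kd_experiment <- function(x, ...) {
  cat(sprintf("<kd_experiment> %d pooled-correlation trials (%d subsets x %d separations x %d trials/cell)\n",
              nrow(x$trials), length(unique(x$trials$subset)),
              length(unique(x$trials$separation)), x$n_trials))
  invisible(x)
}

#' @export
tidy.kd_experiment <- function(x, ...) x$trials

#' @export
glance.kd_experiment <- function(x, ...) {
  x$trials |>
    dplyr::summarise(mean_r = mean(.data$pearson_r),
                     sd_r = stats::sd(.data$pearson_r),
                     n_cells = dplyr::n_distinct(.data$subset, .data$separation),
                     n_trials = dplyr::n_distinct(.data$trial))
}

#' Summarize an experiment and compare subsets against a reference
#'
#' Aggregates the per-trial pooled correlations to mean and standard
#' deviation per (subset, model, separation) cell and attaches the
#' one-tailed Welch p-value for the alternative that the cell's mean
#' correlation exceeds the reference subset's at the same separation.
#'
#' @param x A `kd_experiment` (or its `trials` tibble).
#' @param reference Reference subset name (default `"PDBBind"`).
#' @return Tibble: `subset`, `model`, `cv`, `separation`, `mean_r`,
#'   `sd_r`, `n_trials`, `welch_p`.
#' @export
summarize_experiment <- function(x, reference = "PDBBind") {
  trials <- if (inherits(x, "kd_experiment")) x$trials else x
  summ <- trials |>
    dplyr::group_by(.data$subset, .data$model, .data$cv, .data$separation) |>
    dplyr::summarise(mean_r = mean(.data$pearson_r),
                     sd_r = stats::sd(.data$pearson_r),
                     n_trials = dplyr::n(), .groups = "drop")
  welch <- function(subset, model, cv, separation) {
    if (subset == reference) return(NA_real_)
    a <- trials$pearson_r[trials$subset == subset & trials$model == model &
                            trials$cv == cv & trials$separation == separation]
    b <- trials$pearson_r[trials$subset == reference & trials$model == model &
                            trials$cv == cv & trials$separation == separation]
    if (length(b) < 2 || length(a) < 2) return(NA_real_)
    welch_one_tailed(a, b)
  }
  summ$welch_p <- purrr::pmap_dbl(
    summ[, c("subset", "model", "cv", "separation")], welch)
  summ
}
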