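#' Inverse-probability class weights for imbalanced exposures
#'
#' Rare exposures dominate this setting (some below 3% prevalence), so the
#' minority class is overweighted: every individual in class k receives
#' weight N / (2 n_k). Weights sum to N, each class carries half the total
#' weight, and balanced labels give unit weights.
#'
#' @param labels Binary (0/1) vector; both classes must be present.
#' @return Numeric weight vector, same length as `labels`.
#' @examples
#' imbalance_weights(c(1, 0, 0, 0))
#' @export
imbalance_weights <- function(labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to weight them.",
          class = "jembuild_single_class")
  }
  n <- n1 + n0
  ifelse(labels == 1L, n / (2 * n1), n / (2 * n0))
}

#' Default hyperparameter grids
#'
#' Desk-scale default grids for the three tree-based families; override via
#' the `grid` argument of [tune_learner()] for larger searches.
#'
#' @param family `"tree"` (CART via rpart), `"forest"` (ranger) or
#'   `"boosted"` (xgboost).
#' @return A tibble, one row per grid point.
#' @export
default_grid <- function(family = c("tree", "forest", "boosted")) {
  family <- match.arg(family)
  switch(family,
    tree = tidyr::expand_grid(maxdepth = c(2L, 4L, 8L, 30L),
                              minbucket = c(5L, 20L)),
    forest = tidyr::expand_grid(num_trees = c(200L, 500L),
                                mtry_rule = c("sqrt", "third")),
    boosted = tidyr::expand_grid(max_depth = c(2L, 4L), eta = c(0.1, 0.3),
                                 nrounds = c(100L, 300L))
  )
}

fit_family <- function(family, design, labels, weights, params, seed = 1L) {
  y <- as.integer(labels)
  if (family == "tree") {
    # probability tree: an anova fit on the 0/1 outcome splits on impurity
    # reduction and returns leaf means, i.e. weighted exposed fractions --
    # a saturated unweighted fit therefore reproduces group frequencies
    df <- data.frame(.y = y, design, check.names = FALSE)
    ctrl <- rpart::rpart.control(
      maxdepth = min(params$maxdepth, 30L),
      minbucket = params$minbucket,
      minsplit = max(2L, 2L * params$minbucket),
      cp = 0, xval = 0
    )
    m <- rpart::rpart(.y ~ ., data = df, weights = weights,
                      method = "anova", control = ctrl)
    list(model = m, predict = function(newdesign) {
      nd <- as.data.frame(newdesign, check.names = FALSE)
      pmin(pmax(unname(predict(m, nd)), 0), 1)
    })
  } else if (family == "forest") {
    mtry <- if (identical(params$mtry_rule, "third")) {
      max(1L, floor(ncol(design) / 3))
    } else {
      max(1L, floor(sqrt(ncol(design))))
    }
    df <- data.frame(design, check.names = FALSE)
    m <- ranger::ranger(
      x = df, y = factor(y, levels = c(0L, 1L)),
      num.trees = params$num_trees, mtry = mtry, probability = TRUE,
      case.weights = weights, num.threads = 1L, seed = seed,
      respect.unordered.factors = TRUE
    )
    list(model = m, predict = function(newdesign) {
      nd <- data.frame(newdesign, check.names = FALSE)
      unname(predict(m, data = nd,
                     num.threads = 1L)$predictions[, "1"])
    })
  } else if (family == "boosted") {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(design), label = y,
                                   weight = weights)
    m <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L),
      data = dtrain, nrounds = params$nrounds, verbose = 0
    )
    cols <- colnames(design)
    list(model = m, predict = function(newdesign) {
      unname(predict(m, xgboost::xgb.DMatrix(as.matrix(newdesign[, cols,
                                                                 drop = FALSE]))))
    })
  } else {
    abort(sprintf("Unknown learner family '%s'.", family))
  }
}

# fold assignment: unstratified first; redrawn with class stratification if
# any held-out fold lacks a class (fragile at rare exposures)
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  ok <- all(vapply(seq_len(k), function(f) {
    length(unique(labels[folds == f])) == 2L &&
      length(unique(labels[folds != f])) == 2L
  }, logical(1)))
  if (ok) return(folds)
  folds <- integer(n)
  withr::with_seed(seed + 1L, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  bad <- vapply(seq_len(k), function(f) {
    length(unique(labels[folds == f])) < 2L
  }, logical(1))
  if (any(bad)) {
    abort("A cross-validation fold lacks a class even after stratification.",
          class = "jembuild_degenerate_fold")
  }
  folds
}

#' Tune a tree-based learner by cross-validated AUC
#'
#' Evaluates every grid point by k-fold cross-validation on the learning
#' data (mean held-out AUC of predicted probabilities), selects the
#' maximizing point, and refits it on all learning data. Folds are drawn
#' once from the seed; ties go to the earliest grid row so selection is
#' deterministic.
#'
#' @param family `"tree"`, `"forest"` or `"boosted"`.
#' @param design Numeric indicator matrix (rows = records), e.g. from
#'   [dummy_encode()].
#' @param labels Binary 0/1 outcome vector.
#' @param weights Case weights; default [imbalance_weights()] of `labels`.
#' @param grid Hyperparameter tibble; default [default_grid()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment and stochastic learners.
#'
#' @return An object of class `jem_learner`: the refitted model plus
#'   `cv_results` (grid with mean CV AUC), `cv_auc` (winning mean AUC),
#'   `params`, `family`, and the training design's column metadata.
#' @export
tune_learner <- function(family, design, labels,
                         weights = imbalance_weights(labels),
                         grid = default_grid(family), folds = 10L,
                         seed = 1L) {
  family <- match.arg(family, c("tree", "forest", "boosted"))
  stopifnot(nrow(design) == length(labels), nrow(grid) >= 1, folds >= 2)
  labels <- as.integer(as.logical(labels))
  fold_id <- make_folds(labels, folds, seed)
  cv_auc <- vapply(seq_len(nrow(grid)), function(gi) {
    params <- as.list(grid[gi, ])
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- fit_family(family, design[tr, , drop = FALSE], labels[tr],
                        weights[tr], params, seed = seed + f)
      auc_roc(fit$predict(design[!tr, , drop = FALSE]), labels[!tr])
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(cv_auc)
  params <- as.list(grid[best, ])
  fit <- fit_family(family, design, labels, weights, params, seed = seed)
  structure(
    list(
      family = family, params = params, fit = fit,
      cv_auc = cv_auc[best],
      cv_results = bind_cols(grid, tibble(cv_auc = cv_auc)),
      columns = colnames(design), seed = seed
    ),
    class = "jem_learner"
  )
}

#' @export
print.jem_learner <- function(x, ...) {
  cat(sprintf("<jem_learner> %s | CV AUC %.3f\n", x$family, x$cv_auc))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  if (!is.null(x$variable_set)) {
    cat(sprintf("  variable set: pcs_depth=%s naf_depth=%s\n",
                format(x$variable_set$pcs_depth),
                format(x$variable_set$naf_depth)))
  }
  invisible(x)
}

encode_like <- function(columns, data, pcs_depth, naf_depth) {
  out <- matrix(0, nrow = nrow(data), ncol = length(columns),
                dimnames = list(NULL, columns))
  blocks <- list()
  if (!is.na(pcs_depth)) {
    blocks[[paste0("pcs", pcs_depth)]] <- pcs_level(data$pcs, pcs_depth)
  }
  if (!is.na(naf_depth)) {
    blocks[[paste0("naf", naf_depth)]] <- naf_level(data$naf, naf_depth)
  }
  for (nm in names(blocks)) {
    v <- paste0(nm, "_", blocks[[nm]])
    block_cols <- columns[startsWith(columns, paste0(nm, "_"))]
    if (length(block_cols) > 0) {
      unseen <- !(v %in% block_cols)
      if (any(unseen)) {
        bad <- unique(v[unseen])
        abort(
          sprintf("Code value(s) unseen in training for block %s: %s.",
                  nm, paste(sub("^[a-z0-9]+_", "", bad), collapse = ", ")),
          class = "jembuild_unrepresentable_group"
        )
      }
      out[cbind(seq_len(nrow(data)), match(v, columns))] <- 1
    }
  }
  out
}

#' Tune across the 23 occupational-variable sets
#'
#' Runs [tune_learner()] once per candidate variable set (the 23
#' combinations of occupation and sector truncation depths) and keeps the
#' model whose cross-validated AUC is highest — the most informative set.
#' AUC ties go to the set with fewer design columns. Sets whose design is
#' empty (all indicator columns constant) are skipped.
#'
#' @param data Learning-sample tibble with `pcs`, `naf` and the exposure
#'   column (dichotomized, complete case).
#' @param exposure Exposure column name.
#' @param family,grid,folds,seed As in [tune_learner()].
#' @param sets Variable sets to consider; default
#'   [enumerate_variable_sets()].
#' @param weighted Apply [imbalance_weights()] (default `TRUE`).
#' @return The winning `jem_learner`, with `variable_set` and
#'   `set_results` (per-set CV AUC) attached.
#' @export
select_variable_set <- function(data, exposure,
                                family = c("tree", "forest", "boosted"),
                                sets = enumerate_variable_sets(),
                                grid = default_grid(family), folds = 10L,
                                seed = 1L, weighted = TRUE) {
  family <- match.arg(family)
  labels <- data[[exposure]]
  stopifnot(!anyNA(labels))
  weights <- if (weighted) imbalance_weights(labels) else rep(1, length(labels))
  fits <- purrr::map(seq_len(nrow(sets)), function(i) {
    ps <- sets$pcs_depth[i]; ns <- sets$naf_depth[i]
    tryCatch({
      design <- dummy_encode(data, ps, ns)
      fit <- tune_learner(family, design, labels, weights, grid, folds, seed)
      fit$variable_set <- list(pcs_depth = ps, naf_depth = ns)
      fit
    }, jembuild_empty_design = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) {
    abort("Every variable set produced an empty design.",
          class = "jembuild_empty_design")
  }
  fits <- fits[keep]
  aucs <- vapply(fits, function(f) f$cv_auc, numeric(1))
  ncols <- vapply(fits, function(f) length(f$columns), numeric(1))
  best <- order(-aucs, ncols)[1]
  out <- fits[[best]]
  out$set_results <- bind_cols(
    sets[keep, ], tibble(cv_auc = aucs, n_columns = as.integer(ncols))
  )
  out
}

#' Predict exposure probability per occupational group
#'
#' All members of a group share one design row at the model's truncation
#' depths, so the model's score is constant within group; this returns that
#' per-group score. Groups carrying a code value never seen in training are
#' not representable and raise an error.
#'
#' @param model A `jem_learner` from [select_variable_set()] (or
#'   [tune_learner()] with a `variable_set` attached).
#' @param groups Tibble with one row per group and columns `pcs`, `naf`
#'   (plus any identifier columns, which are passed through).
#' @return `groups` with an added `probability` column.
#' @export
predict_group_probabilities <- function(model, groups) {
  stopifnot(inherits(model, "jem_learner"), !is.null(model$variable_set))
  vs <- model$variable_set
  design <- encode_like(model$columns, groups, vs$pcs_depth, vs$naf_depth)
  groups$probability <- model$fit$predict(design)
  as_tibble(groups)
}

#' Compare the frequency method with tree-based learners
#'
#' The method-comparison harness: on one shared 70/30 split, each requested
#' method produces per-group exposure scores on the learning sample
#' (group-based frequencies, or tuned tree/forest/boosted probabilities
#' with the most informative variable set), the scores are thresholded by
#' the same F1-optimal scan rule, and test-set AUC is reported per method
#' with a paired bootstrap percentile interval (resampling test
#' individuals). Output is forest-plot ready; see [autoplot.jem_comparison()].
#'
#' @param data Cohort tibble (as in [build_jem()]).
#' @param exposures Character vector of exposure columns to compare.
#' @param methods Subset of `c("frequency", "tree", "forest", "boosted")`.
#' @param specs Exposure specifications; default [exposure_specs()].
#' @param variant Group-keying variant (default `"standard"`).
#' @param learning_fraction,seed Split parameters.
#' @param min_group_size Group-retention floor (default 11).
#' @param sets Variable sets searched for the learners; default all 23.
#' @param folds CV folds for tuning (default 10).
#' @param grids Named list of hyperparameter grids per family; default
#'   [default_grid()] each.
#' @param n_boot Bootstrap resamples for the AUC interval (default 500).
#' @return A tibble of class `jem_comparison`: one row per exposure x
#'   method with `auc`, `auc_lo`, `auc_hi`, `optimal_cutoff`, `kappa`,
#'   `f1`, plus `pcs_depth`/`naf_depth` for the learners. Failures are
#'   recorded in the `failures` attribute, not fatal.
#' @export
compare_methods <- function(data, exposures,
                            methods = c("frequency", "tree", "forest", "boosted"),
                            specs = exposure_specs(),
                            variant = "standard",
                            learning_fraction = 0.7, seed = 1L,
                            min_group_size = 11L,
                            sets = enumerate_variable_sets(),
                            folds = 10L, grids = NULL, n_boot = 500L) {
  methods <- match.arg(methods, several.ok = TRUE)
  data <- normalize_cohort_codes(data)
  data <- add_group_key(data, variant)
  data <- dichotomize_exposures(data, specs)
  data <- split_cohort(data, learning_fraction, seed)
  grouped <- filter(data, .data$groupable)

  rows <- list(); fails <- list()
  for (e in exposures) {
    cc <- complete_case(grouped, e)
    ex <- exclude_small_groups(cc, min_size = min_group_size)
    learning <- filter(ex$records, .data$split == "learning")
    # groups with no learning-sample member cannot be scored by any method;
    # their test members are unassigned and left out of the comparison
    test <- filter(ex$records, .data$split == "test",
                   .data$group_key %in% unique(learning$group_key))
    boot_idx <- withr::with_seed(
      seed + 17L,
      lapply(seq_len(n_boot), function(i) sample.int(nrow(test), replace = TRUE))
    )
    group_tab <- distinct(select(learning, "group_key", "pcs", "naf"))
    for (m in methods) {
      res <- tryCatch({
        scores <- if (m == "frequency") {
          freq <- estimate_frequencies(learning, e)
          apply_frequencies(test, freq)$frequency
        } else {
          fit <- select_variable_set(
            learning, e, family = m, sets = sets,
            grid = grids[[m]] %||% default_grid(m),
            folds = folds, seed = seed
          )
          gp <- predict_group_probabilities(fit, group_tab)
          gp$probability[match(test$group_key, gp$group_key)]
        }
        sc <- scores; tr <- test[[e]]
        scan <- threshold_scan(sc, tr)
        thr <- select_threshold(scan)
        perf <- evaluate_column(sc, tr, thr)
        boots <- vapply(boot_idx, function(ii) {
          t2 <- tr[ii]
          if (length(unique(t2)) < 2L) return(NA_real_)
          auc_roc(sc[ii], t2)
        }, numeric(1))
        ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
        out <- tibble(
          exposure = e, method = m, auc = perf$auc,
          auc_lo = ci[1], auc_hi = ci[2],
          optimal_cutoff = thr, kappa = perf$kappa, f1 = perf$f1,
          sensitivity = perf$sensitivity, specificity = perf$specificity,
          pcs_depth = NA_integer_, naf_depth = NA_integer_
        )
        if (m != "frequency") {
          out$pcs_depth <- fit$variable_set$pcs_depth
          out$naf_depth <- fit$variable_set$naf_depth
        }
        out
      }, error = function(err) {
        fails[[length(fails) + 1L]] <<- tibble(
          exposure = e, method = m, error = conditionMessage(err)
        )
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- purrr::list_rbind(rows)
  attr(out, "failures") <- purrr::list_rbind(fails)
  attr(out, "seed") <- seed
  attr(out, "n_boot") <- n_boot
  class(out) <- c("jem_comparison", class(out))
  out
}
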