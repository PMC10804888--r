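#' Stratified cross-validation fold plans
#'
#' @description
#' Builds a `k`-fold partition of the trials for each of `runs` repetitions.
#' Folds are class-stratified (fold sizes per class differ by at most one
#' trial) and mix trials across subjects, mirroring a mixed-subject
#' evaluation in which every fold draws from all recording sessions. Each
#' run re-randomizes the partition under a seed derived deterministically
#' from `seed`, so the full plan is reproducible while runs differ.
#'
#' @param trials a `trial_set`, `plv_tensor`, factor of labels, or integer
#'   label vector.
#' @param k fold count (canonically 9).
#' @param runs number of repetitions (canonically 15).
#' @param seed integer master seed.
#' @return An object of class `fold_plan`: list with `k`, `runs`, `seed`,
#'   `run_seeds` and `assignments` (per run, an integer vector giving each
#'   trial's fold in `1..k`).
#' @export
make_folds <- function(trials, k = 9L, runs = 15L, seed = 1L) {
  y <- if (inherits(trials, "trial_set") || inherits(trials, "plv_tensor"))
    trials$labels else as.factor(trials)
  n <- length(y)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the trial count (", n, ")", call. = FALSE)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, runs)
  assignments <- lapply(run_seeds, function(rs) {
    set.seed(rs)
    fold <- integer(n)
    for (cl in levels(y)) {
      ix <- sample(which(y == cl))
      # deal class members round-robin from a random starting fold so that
      # per-class remainders do not always land in fold 1
      fold[ix] <- 1L + (sample.int(k, 1) + seq_along(ix) - 2L) %% k
    }
    fold
  })
  structure(list(k = as.integer(k), runs = as.integer(runs),
                 seed = as.integer(seed), run_seeds = run_seeds,
                 assignments = assignments),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", x$k, "-fold x ", x$runs, " runs over ",
      length(x$assignments[[1]]), " trials (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Multiclass classification metrics
#'
#' @description
#' Computes the metric suite reported for every evaluation: accuracy, macro
#' and micro F1, macro and micro precision, and one-vs-rest ROC-AUC (macro =
#' unweighted mean over classes, micro = pooled over all class/trial
#' decisions). For single-label multiclass predictions micro-F1 and
#' micro-precision are identically equal to accuracy; that identity is a
#' structural property of the pooled counts and is preserved exactly here.
#' Macro averages treat classes without positive predictions as
#' contributing 0. If some class is absent from `y_true`, its one-vs-rest
#' AUC is undefined; the macro AUC then averages the defined classes and
#' the record is flagged via `auc_defined = FALSE`.
#'
#' @param y_true true labels (factor).
#' @param y_pred predicted labels (factor with the same levels).
#' @param y_scores optional `n x K` score matrix (rows sum to 1) for the
#'   AUC metrics; without it the AUCs are `NA`.
#' @return Named list with `accuracy`, `f1_macro`, `f1_micro`,
#'   `precision_macro`, `precision_micro`, `auc_macro`, `auc_micro`,
#'   `auc_defined`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred, y_scores = NULL) {
  y_true <- as.factor(y_true)
  y_pred <- factor(y_pred, levels = levels(y_true))
  stopifnot(length(y_true) == length(y_pred))
  K <- nlevels(y_true)
  C <- table(true = y_true, pred = y_pred)
  tp <- diag(C)
  fp <- colSums(C) - tp
  fn <- rowSums(C) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  acc <- sum(tp) / length(y_true)
  # pooled (micro) counts: every false positive is some class's false
  # negative, so micro precision = micro recall = micro F1 = accuracy
  micro <- sum(tp) / (sum(tp) + sum(fp))

  auc_macro <- auc_micro <- NA_real_
  auc_defined <- FALSE
  if (!is.null(y_scores)) {
    stopifnot(nrow(y_scores) == length(y_true), ncol(y_scores) == K)
    per_class <- rep(NA_real_, K)
    for (c in seq_len(K)) {
      pos <- y_true == levels(y_true)[c]
      if (any(pos) && any(!pos))
        per_class[c] <- binary_auc(pos, y_scores[, c])
    }
    auc_defined <- all(!is.na(per_class))
    if (any(!is.na(per_class))) auc_macro <- mean(per_class, na.rm = TRUE)
    onehot <- outer(as.character(y_true), levels(y_true), "==")
    auc_micro <- binary_auc(as.vector(onehot), as.vector(y_scores))
    if (!auc_defined)
      warning("ROC-AUC undefined for some class (absent from y_true)")
  }
  list(accuracy = acc, f1_macro = mean(f1), f1_micro = micro,
       precision_macro = mean(prec), precision_micro = micro,
       auc_macro = auc_macro, auc_micro = auc_micro,
       auc_defined = auc_defined, n = length(y_true))
}

# one-vs-rest binary AUC via pROC
binary_auc <- function(positive, score) {
  r <- pROC::roc(response = factor(positive, levels = c(FALSE, TRUE)),
                 predictor = as.numeric(score), quiet = TRUE,
                 direction = "<")
  as.numeric(pROC::auc(r))
}

#' Cross-validated training and evaluation
#'
#' @description
#' Trains one model per (run, fold) cell of the fold plan — on all trials
#' outside the fold, evaluated on the held-out fold — and assembles the
#' per-fold metric suite of [compute_metrics()] plus aggregates. Any
#' per-trial preprocessing (standardization, embedding, PLV) is computed
#' strictly per trial, so no statistic crosses the fold boundary. Per-cell
#' training seeds are derived from the fold plan's run seeds and recorded.
#'
#' @param x input container or array accepted by [cnnm()].
#' @param builder function `(input_shape, class_count) -> model_spec`, e.g.
#'   `function(s, k) build_adj_cnnm(s, k)`.
#' @param config a [train_config()]; its `seed` is re-derived per cell.
#' @param fold_plan a [make_folds()] plan over the same trials.
#' @param y optional labels for array input.
#' @param verbose print one line per cell.
#' @return An object of class `eval_report`: list with `per_fold` (one row
#'   per run x fold), `aggregate` (means of all metrics plus `accuracy_sd`,
#'   the standard deviation of fold-level accuracies pooled across runs)
#'   and `meta`.
#' @export
run_cv <- function(x, builder, config, fold_plan, y = NULL, verbose = FALSE) {
  inp <- as_model_input(x)
  if (is.null(y)) y <- inp$labels
  if (is.null(y)) stop("labels required", call. = FALSE)
  y <- as.factor(y)
  n <- dim(inp$x)[4]
  stopifnot(inherits(fold_plan, "fold_plan"),
            length(fold_plan$assignments[[1]]) == n)
  K <- nlevels(y)
  spec <- builder(dim(inp$x)[1:3], K)
  rows <- list()
  for (r in seq_len(fold_plan$runs)) {
    fold_of <- fold_plan$assignments[[r]]
    for (f in seq_len(fold_plan$k)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      cell_config <- config
      cell_config$seed <- (fold_plan$run_seeds[r] + 7919L * f) %% 2147483647L
      fit <- nn_train(spec, inp$x[, , , train, drop = FALSE],
                      as.integer(y)[train], cell_config)
      probs <- nn_predict_probs(spec, fit$params,
                                inp$x[, , , test, drop = FALSE])
      if (length(unique(y[test])) < K)
        warning("fold ", f, " run ", r, " is missing a class; ",
                "AUC flagged undefined")
      m <- compute_metrics(y[test], factor(levels(y)[max.col(probs)],
                                           levels = levels(y)), probs)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, fold = f, seed = cell_config$seed, n_test = m$n,
        accuracy = m$accuracy, f1_macro = m$f1_macro, f1_micro = m$f1_micro,
        precision_macro = m$precision_macro, precision_micro = m$precision_micro,
        auc_macro = m$auc_macro, auc_micro = m$auc_micro,
        auc_defined = m$auc_defined)
      if (verbose)
        message(sprintf("run %d fold %d: acc %.3f", r, f, m$accuracy))
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "f1_macro", "f1_micro", "precision_macro",
                   "precision_micro", "auc_macro", "auc_micro")
  aggregate <- as.list(colMeans(per_fold[metric_cols], na.rm = TRUE))
  aggregate$accuracy_sd <- stats::sd(per_fold$accuracy)
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 meta = list(model = spec$name, k = fold_plan$k,
                             runs = fold_plan$runs, seed = fold_plan$seed,
                             n = n, classes = levels(y))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregate
  cat("<eval_report> ", x$meta$model, ": ", x$meta$k, "-fold x ",
      x$meta$runs, " runs, n = ", x$meta$n, "\n", sep = "")
  cat(sprintf(paste0("  F1(Ma) %.4f  F1(Mi) %.4f  Prec(Ma) %.4f  Prec(Mi) %.4f\n",
                     "  AUC(Ma) %s  AUC(Mi) %s  Accuracy %.4f  SD %.3f\n"),
              a$f1_macro, a$f1_micro, a$precision_macro, a$precision_micro,
              if (is.na(a$auc_macro)) "NA" else sprintf("%.4f", a$auc_macro),
              if (is.na(a$auc_micro)) "NA" else sprintf("%.4f", a$auc_micro),
              a$accuracy, a$accuracy_sd))
  invisible(x)
}

#' Tabulate an evaluation report
#'
#' One-row data frame of the aggregate metrics (the layout used for the
#' report tables); `rbind` several to compare models or bands.
#'
#' @param report an `eval_report`.
#' @param label row label (defaults to the model name).
#' @return A one-row data frame.
#' @export
report_row <- function(report, label = NULL) {
  a <- report$aggregate
  data.frame(model = label %||% report$meta$model,
             f1_macro = a$f1_macro, f1_micro = a$f1_micro,
             precision_macro = a$precision_macro,
             precision_micro = a$precision_micro,
             auc_macro = a$auc_macro, auc_micro = a$auc_micro,
             accuracy = a$accuracy, sd = a$accuracy_sd)
}

#' Packaged hyperparameter grids
#'
#' @description
#' The three canonical tuning grids: `"adj_filters"` varies the structural
#' net's filter count over 32/64/128/256 at kernel 22x45; `"adj_kernels"`
#' varies the kernel width over 22/45/65/85 at 64 filters; `"plv"` crosses
#' the filter pairs (8,16), (32,64), (128,256), (256,512) with kernel sizes
#' 2x2 and 3x3 (8 rows).
#'
#' @param which grid name.
#' @return A data frame, one row per configuration.
#' @export
default_grid <- function(which = c("adj_filters", "adj_kernels", "plv")) {
  which <- match.arg(which)
  switch(which,
    adj_filters = data.frame(filters = c(32L, 64L, 128L, 256L),
                             kernel_h = 22L, kernel_w = 45L),
    adj_kernels = data.frame(filters = 64L, kernel_h = 22L,
                             kernel_w = c(22L, 45L, 65L, 85L)),
    plv = {
      pairs <- rbind(c(8L, 16L), c(32L, 64L), c(128L, 256L), c(256L, 512L))
      g <- expand.grid(pair = seq_len(nrow(pairs)), kernel = c(2L, 3L))
      data.frame(filters1 = pairs[g$pair, 1], filters2 = pairs[g$pair, 2],
                 kernel = g$kernel)
    })
}

#' Hyperparameter-grid cross-validation harness
#'
#' @description
#' Runs [run_cv()] once per grid row and tabulates the aggregate metrics,
#' flagging the best row by accuracy. Rows whose configuration is invalid
#' for the input shape are marked failed and the sweep continues. Grids for
#' the structural model carry columns `filters`, `kernel_h`, `kernel_w`;
#' grids for the PLV model carry `filters1`, `filters2`, `kernel` (see
#' [default_grid()]).
#'
#' @param x input container or array accepted by [cnnm()].
#' @param grid data frame of configurations.
#' @param model `"adj"` or `"plv"` — which builder the grid parameterizes.
#' @param config a [train_config()].
#' @param fold_plan a [make_folds()] plan.
#' @param y optional labels for array input.
#' @param verbose print progress.
#' @return A data frame: grid columns plus aggregate metrics, `failed`, and
#'   logical `best`.
#' @export
hyperparameter_grid <- function(x, grid, model = c("adj", "plv"),
                                config, fold_plan, y = NULL, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  out <- grid
  out$accuracy <- out$sd <- out$f1_macro <- out$f1_micro <- NA_real_
  out$failed <- FALSE
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    builder <- if (model == "adj") {
      function(shape, K) build_adj_cnnm(shape, K, filters = row$filters,
                                        kernel = c(row$kernel_h, row$kernel_w))
    } else {
      function(shape, K) build_plv_cnnm(shape, K,
                                        filters = c(row$filters1, row$filters2),
                                        kernel = c(row$kernel, row$kernel))
    }
    rep_i <- tryCatch(
      run_cv(x, builder, config, fold_plan, y = y, verbose = FALSE),
      error = function(e) e)
    if (inherits(rep_i, "error")) {
      out$failed[i] <- TRUE
      if (verbose) message("row ", i, " failed: ", conditionMessage(rep_i))
      next
    }
    out$accuracy[i] <- rep_i$aggregate$accuracy
    out$sd[i] <- rep_i$aggregate$accuracy_sd
    out$f1_macro[i] <- rep_i$aggregate$f1_macro
    out$f1_micro[i] <- rep_i$aggregate$f1_micro
    if (verbose) message("row ", i, ": acc ", round(out$accuracy[i], 4))
  }
  out$best <- !out$failed & !is.na(out$accuracy) &
    out$accuracy == max(out$accuracy, na.rm = TRUE)
  out
}
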