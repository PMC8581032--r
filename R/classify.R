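# Classification protocol: moment summarization of per-subject AR
# coefficient cells, supervised dimensionality reduction with neighborhood
# component analysis (NCA), z-normalization, grid-searched AdaBoost over
# decision-tree base learners, and nested stratified cross-validation
# reporting accuracy, MCC and AUC.

#' Moment summary of per-subject coefficient cells
#'
#' Replaces each subject's raw per-trial AR coefficients by four moments per
#' cell and coefficient: skewness, excess kurtosis, mean and sample SD (in
#' that column order). `mixed` mode has one cell per subject (12 values);
#' `by_response_type` has up to four (48 values). Cells with fewer than two
#' fits get SD/skewness/kurtosis 0 by convention; cells a subject lacks
#' entirely are `NA` and are mean-imputed inside the classifier's training
#' folds.
#'
#' @param fits Per-segment fit tibble (see [fit_cohort_adjustments()]).
#' @param mode `"mixed"` or `"by_response_type"`.
#' @return Wide tibble: `subject_id`, `group`, then
#'   `<cell>_<coef>_<moment>` columns in fixed order.
#' @export
summarize_adjustment <- function(fits, mode = c("mixed", "by_response_type")) {
  mode <- match.arg(mode)
  cells <- if (mode == "mixed") "mixed" else
    c("go_pos", "go_neg", "nogo_pos", "nogo_neg")
  tbl <- adjustment_feature_table(fits, mode)
  if (mode == "mixed") tbl$cell <- "mixed" else tbl$cell <- tbl$response_type

  subjects <- dplyr::distinct(fits, .data$subject_id, .data$group)
  col_order <- as.vector(t(outer(
    cells,
    as.vector(t(outer(c("alpha", "theta1", "theta2"),
                      c("skew", "kurt", "mean", "sd"), paste, sep = "_"))),
    paste, sep = "_"
  )))

  long <- purrr::map(seq_len(nrow(tbl)), function(i) {
    purrr::map(c("alpha", "theta1", "theta2"), function(coef) {
      m <- moment_summary(tbl[[coef]][[i]])
      tibble::tibble(
        subject_id = tbl$subject_id[i], cell = tbl$cell[i],
        name = paste(tbl$cell[i], coef, c("skew", "kurt", "mean", "sd"),
                     sep = "_"),
        value = m
      )
    }) %>% bind_rows()
  }) %>% bind_rows()

  wide <- tidyr::pivot_wider(select(long, -"cell"),
                             names_from = "name", values_from = "value")
  missing_cols <- setdiff(col_order, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_
  subjects %>%
    left_join(wide, by = "subject_id") %>%
    select(dplyr::all_of(c("subject_id", "group", col_order)))
}

# skewness, excess kurtosis, mean, sd of one coefficient list; degenerate
# cells (n < 2 or zero spread) get 0 for the shape moments by convention
moment_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(rep(NA_real_, 4))
  if (length(x) < 2 || sd(x) == 0) return(c(0, 0, mean(x), 0))
  c(e1071::skewness(x, type = 1), e1071::kurtosis(x, type = 1),
    mean(x), sd(x))
}

#' The eight spatial features reported as group-discriminative
#'
#' The fixed "significant" spatial subset appended to the reduced
#' gaze-adjustment features in the combined classification input: sample
#' entropy of gaze velocity, average acceleration, fixation-time SD, sample
#' entropies of step distance and angle, and the kernel-density, sample and
#' spectral entropies of the gaze-to-stimulus difference.
#'
#' @return Character vector of 8 feature names.
#' @export
significant_spatial_features <- function() {
  c("velocity_sen", "acceleration_avg", "fixation_var", "distance_sen",
    "angle_sen", "gaze_obj_en", "gaze_obj_sen", "gaze_obj_spe")
}

#' AdaBoost hyperparameter grid
#'
#' The grid searched during training: decision-tree depth in {1, 3, 5, 7},
#' maximum leaves in {3, 5, 7}, number of boosting rounds in
#' {15, 25, 50, 75}, learning rate in {0.5, 0.75}; the fraction of features
#' available to each tree is fixed at 0.5.
#'
#' @param max_depth,max_leaf,n_estimators,learning_rate Candidate values.
#' @param feature_fraction Fixed per-tree feature fraction.
#' @return A `model_grid` list.
#' @export
model_grid <- function(max_depth = c(1, 3, 5, 7), max_leaf = c(3, 5, 7),
                       n_estimators = c(15, 25, 50, 75),
                       learning_rate = c(0.5, 0.75),
                       feature_fraction = 0.5) {
  structure(
    list(max_depth = max_depth, max_leaf = max_leaf,
         n_estimators = n_estimators, learning_rate = learning_rate,
         feature_fraction = feature_fraction),
    class = "model_grid"
  )
}

# ---- Neighborhood component analysis ------------------------------------

#' Fit a neighborhood-component-analysis reduction
#'
#' Learns a linear map to `n_components` dimensions maximizing the expected
#' leave-one-out accuracy of a stochastic (softmax-over-distances) nearest
#' neighbor classifier. Initialized from principal components and optimized
#' with BFGS; the procedure is deterministic for fixed inputs, so refitting
#' with the same data and seed gives an identical transform.
#'
#' @param X Numeric matrix (rows = subjects), already z-normalized.
#' @param y Class labels.
#' @param n_components Output dimension (default 5).
#' @param max_iter BFGS iteration cap (default 100).
#' @param seed Accepted for interface stability; the fit itself is
#'   deterministic.
#' @return An `nca_fit` with the `n_components x ncol(X)` matrix `A`; use
#'   [predict()] to transform new rows.
#' @export
nca_fit <- function(X, y, n_components = 5, max_iter = 100, seed = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X)
  d <- ncol(X)
  if (n_components > d || n_components > qr(X)$rank) {
    abort("`n_components` exceeds the rank of the input matrix")
  }
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  objective <- function(avec) {
    A <- matrix(avec, n_components, d)
    Z <- X %*% t(A)
    D <- as.matrix(stats::dist(Z))^2
    D <- D - apply(D + diag(Inf, n), 1, min)  # stabilize the softmax
    K <- exp(-D)
    diag(K) <- 0
    P <- K / pmax(rowSums(K), .Machine$double.xmin)
    sum(P[same])
  }
  gradient <- function(avec) {
    A <- matrix(avec, n_components, d)
    Z <- X %*% t(A)
    D <- as.matrix(stats::dist(Z))^2
    D <- D - apply(D + diag(Inf, n), 1, min)
    K <- exp(-D)
    diag(K) <- 0
    P <- K / pmax(rowSums(K), .Machine$double.xmin)
    p_i <- rowSums(P * same)
    W <- P * p_i - P * same          # W_ij weights on x_ij x_ij^T
    L <- diag(rowSums(W)) + diag(colSums(W)) - W - t(W)
    G <- t(X) %*% L %*% X            # sum_ij W_ij (x_i - x_j)(x_i - x_j)^T
    as.vector(2 * (A %*% G))
  }

  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  A0 <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  opt <- optim(as.vector(A0), fn = objective, gr = gradient,
               method = "BFGS",
               control = list(fnscale = -1, maxit = max_iter))
  structure(
    list(A = matrix(opt$par, n_components, d), n_components = n_components,
         value = opt$value, converged = opt$convergence == 0,
         feature_names = colnames(X)),
    class = "nca_fit"
  )
}

#' @export
predict.nca_fit <- function(object, newdata, ...) {
  as.matrix(newdata) %*% t(object$A)
}

#' Reduce a feature matrix with NCA
#'
#' Convenience wrapper around [nca_fit()] returning both the reduced matrix
#' and the reusable transform.
#'
#' @inheritParams nca_fit
#' @return List with `X` (the `n x n_components` reduced matrix) and `fit`.
#' @export
reduce_nca <- function(X, y, n_components = 5, seed = NULL) {
  fit <- nca_fit(X, y, n_components = n_components, seed = seed)
  list(X = predict(fit, X), fit = fit)
}

# ---- AdaBoost over decision trees ---------------------------------------

#' Fit a multi-class AdaBoost ensemble of decision trees
#'
#' SAMME boosting of `rpart` classification trees. Each round fits a tree on
#' the weighted sample using a random subset of `feature_fraction` of the
#' columns, prunes it to at most `max_leaf` leaves, and reweights the
#' misclassified rows. Rounds whose weighted error reaches the random-guess
#' bound `1 - 1/K` stop the ensemble early; a zero-error round dominates and
#' also stops it.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels (2 or more classes).
#' @param n_estimators Boosting rounds (default 50).
#' @param learning_rate Shrinkage on the round weights (default 1).
#' @param max_depth,max_leaf Tree size limits.
#' @param feature_fraction Fraction of features offered to each tree.
#' @param seed Integer seed for the per-round feature subsets; `NULL` uses
#'   the current RNG state.
#' @return An `adaboost` model; see [predict.adaboost()].
#' @export
adaboost_fit <- function(X, y, n_estimators = 50, learning_rate = 1,
                         max_depth = 3, max_leaf = 7,
                         feature_fraction = 0.5, seed = NULL) {
  run <- function() {
    X <- as.matrix(X)
    colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
    y <- droplevels(as.factor(y))
    K <- nlevels(y)
    n <- nrow(X)
    if (K < 2) {
      return(structure(list(trees = list(), alphas = numeric(),
                            features = list(), levels = levels(y),
                            constant = levels(y)[1]),
                       class = "adaboost"))
    }
    w <- rep(1 / n, n)
    n_feat <- max(1L, round(feature_fraction * ncol(X)))
    ctrl <- rpart::rpart.control(
      maxdepth = max_depth, minsplit = 2, minbucket = 1, cp = 0,
      xval = 0, maxcompete = 0, maxsurrogate = 0, usesurrogate = 0
    )
    trees <- list()
    alphas <- numeric()
    feats <- list()
    for (b in seq_len(n_estimators)) {
      fi <- sort(sample.int(ncol(X), n_feat))
      df <- data.frame(.y = y, X[, fi, drop = FALSE], check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                          method = "class", control = ctrl)
      fit <- prune_to_leaves(fit, max_leaf)
      pred <- predict(fit, df, type = "class")
      err <- sum(w[pred != y])
      if (err >= 1 - 1 / K) break        # no better than guessing: stop
      err <- max(err, 1e-10)
      alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
      trees[[length(trees) + 1]] <- fit
      alphas <- c(alphas, alpha)
      feats[[length(feats) + 1]] <- fi
      if (err <= 1e-10) break            # perfect round dominates: stop
      w <- w * exp(alpha * (pred != y))
      w <- w / sum(w)
    }
    structure(
      list(trees = trees, alphas = alphas, features = feats,
           levels = levels(y), constant = NULL),
      class = "adaboost"
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# prune an rpart tree so it has at most `max_leaf` terminal nodes
prune_to_leaves <- function(fit, max_leaf) {
  cpt <- fit$cptable
  if (is.null(cpt)) return(fit)
  ok <- which(cpt[, "nsplit"] <= max_leaf - 1)
  row <- ok[which.max(cpt[ok, "nsplit"])]
  if (cpt[row, "nsplit"] == max(cpt[, "nsplit"])) return(fit)
  rpart::prune(fit, cp = cpt[row, "CP"])
}

#' Predict from an AdaBoost ensemble
#'
#' Class scores are the alpha-weighted votes of the trees, normalized to
#' probabilities.
#'
#' @param object An `adaboost` model.
#' @param newdata Feature matrix with the training columns.
#' @param type `"prob"` (default) or `"class"`.
#' @param n_estimators Use only the first `n_estimators` rounds (staged
#'   prediction); default all.
#' @param ... Unused.
#' @return Probability matrix (columns = classes) or a factor of classes.
#' @export
predict.adaboost <- function(object, newdata, type = c("prob", "class"),
                             n_estimators = NULL, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  colnames(newdata) <- colnames(newdata) %||%
    paste0("f", seq_len(ncol(newdata)))
  n <- nrow(newdata)
  K <- length(object$levels)
  scores <- matrix(0, n, K, dimnames = list(NULL, object$levels))
  if (!is.null(object$constant) || length(object$trees) == 0) {
    scores[, 1] <- 1
  } else {
    use <- seq_len(min(n_estimators %||% length(object$trees),
                       length(object$trees)))
    for (b in use) {
      df <- as.data.frame(newdata[, object$features[[b]], drop = FALSE])
      pred <- predict(object$trees[[b]], df, type = "class")
      scores[cbind(seq_len(n), as.integer(factor(pred, object$levels)))] <-
        scores[cbind(seq_len(n), as.integer(factor(pred, object$levels)))] +
        object$alphas[b]
    }
  }
  denom <- rowSums(scores)
  prob <- scores / ifelse(denom == 0, 1, denom)
  prob[denom == 0, ] <- 1 / K
  if (type == "prob") prob else
    factor(object$levels[max.col(prob, ties.method = "first")],
           levels = object$levels)
}

# ---- Metrics -------------------------------------------------------------

#' Confusion matrix of counts
#'
#' @param actual,predicted Label vectors.
#' @param levels Class levels fixing row/column order.
#' @return `K x K` integer matrix, rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted,
                             levels = sort(unique(c(actual, predicted)))) {
  table(factor(actual, levels), factor(predicted, levels))
}

#' Matthews correlation coefficient
#'
#' Binary MCC from the 2 x 2 confusion table; for more classes the
#' generalized multi-class correlation form is used (which reduces to the
#' binary formula for K = 2). An undefined denominator (e.g. all
#' predictions in one class) returns 0 by convention.
#'
#' @param cm Confusion matrix of counts, rows = actual, columns = predicted
#'   (see [confusion_matrix()]).
#' @return Value in `[-1, 1]`.
#' @export
#' @examples
#' mcc(matrix(c(26, 1, 5, 20), 2, 2))  # TN 26, FN 1, FP 5, TP 20
mcc <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  p <- colSums(cm)
  t_ <- rowSums(cm)
  denom <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t_^2))
  if (denom == 0) {
    inform("MCC denominator is 0 (degenerate table); returning 0")
    return(0)
  }
  (c_ * s - sum(p * t_)) / denom
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals its members round-robin over the folds, so
#' every fold holds every class.
#'
#' @param y Class labels.
#' @param k Number of folds (default 3); every class must have at least `k`
#'   members.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(y, k = 3, seed = NULL) {
  run <- function() {
    y <- as.factor(y)
    if (any(table(y) < k)) {
      abort(sprintf("every class needs at least %d members for %d-fold stratification",
                    k, k))
    }
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- Nested cross-validated training and evaluation ----------------------

#' Train and evaluate the boosted classifier under nested stratified CV
#'
#' Outer stratified `folds`-fold cross-validation; within each training
#' fold, missing values are imputed with training-fold column means,
#' z-normalization parameters are fitted, the columns flagged in
#' `reduce_cols` are reduced to `n_components` dimensions with NCA, and the
#' AdaBoost hyperparameters are chosen by inner stratified `folds`-fold
#' accuracy over [model_grid()]. Nothing fitted ever sees the held-out
#' fold. The held-out fold is scored with accuracy (%), MCC and AUC (from
#' class probabilities; macro one-vs-rest for three classes), and the fold
#' confusion matrices are pooled and row-normalized to percentages.
#'
#' Setting `nested = FALSE` fits imputation, z-normalization and NCA on all
#' rows before the CV loop — a compatibility mode that inflates
#' small-sample scores and is off by default.
#'
#' @param X Numeric feature matrix, rows = subjects.
#' @param y Class labels; the positive class for the 0.5 probability
#'   threshold is `positive` (default: the last factor level).
#' @param grid A [model_grid()].
#' @param folds Outer and inner fold count (default 3).
#' @param seed Integer seed driving fold assignment and feature subsets.
#' @param reduce_cols Column indices (or names) to reduce with NCA; `NULL`
#'   reduces nothing.
#' @param n_components NCA output dimension (default 5).
#' @param threshold Probability threshold converting the positive-class
#'   probability to a class (binary only, default 0.5).
#' @param positive Positive class label.
#' @param nested Keep preprocessing inside the training folds (default
#'   `TRUE`).
#' @return A `classification_report`; see [tidy.classification_report()],
#'   [glance.classification_report()] and
#'   [autoplot.classification_report()].
#' @export
train_eval_cv <- function(X, y, grid = model_grid(), folds = 3, seed = 1,
                          reduce_cols = NULL, n_components = 5,
                          threshold = 0.5, positive = NULL, nested = TRUE) {
  X <- as.matrix(X)
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  positive <- positive %||% levels(y)[nlevels(y)]
  if (is.character(reduce_cols)) reduce_cols <- match(reduce_cols, colnames(X))

  fold_id <- stratified_folds(y, folds, seed = seed)
  inner_seed <- (seed %% 1000003L) + 1L

  if (!nested) {
    prep_all <- fit_fold_prep(X, y, seq_len(nrow(X)), reduce_cols,
                              n_components)
  }

  with_seed(inner_seed, {
    combos <- expand.grid(max_depth = grid$max_depth,
                          max_leaf = grid$max_leaf,
                          learning_rate = grid$learning_rate)
    per_fold <- list()
    cm_pooled <- matrix(0, nlevels(y), nlevels(y),
                        dimnames = list(levels(y), levels(y)))
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      prep <- if (nested) {
        fit_fold_prep(X, y, tr, reduce_cols, n_components)
      } else {
        prep_all
      }
      Xtr <- prep$transform(X[tr, , drop = FALSE])
      Xte <- prep$transform(X[te, , drop = FALSE])
      ytr <- y[tr]

      best <- grid_search_inner(Xtr, ytr, grid, combos, folds)
      model <- adaboost_fit(Xtr, ytr,
                            n_estimators = best$n_estimators,
                            learning_rate = best$learning_rate,
                            max_depth = best$max_depth,
                            max_leaf = best$max_leaf,
                            feature_fraction = grid$feature_fraction)
      prob <- predict(model, Xte, type = "prob")
      pred <- classify_prob(prob, levels(y), positive, threshold)
      cm <- confusion_matrix(y[te], pred, levels(y))
      cm_pooled <- cm_pooled + cm
      per_fold[[f]] <- tibble::tibble(
        fold = f,
        accuracy = 100 * mean(pred == y[te]),
        mcc = mcc(cm),
        auc = fold_auc(y[te], prob, positive),
        max_depth = best$max_depth, max_leaf = best$max_leaf,
        n_estimators = best$n_estimators,
        learning_rate = best$learning_rate
      )
    }
    folds_tbl <- bind_rows(per_fold)
    structure(
      list(
        folds = folds_tbl,
        accuracy = mean(folds_tbl$accuracy), accuracy_sd = sd(folds_tbl$accuracy),
        mcc = mean(folds_tbl$mcc), mcc_sd = sd(folds_tbl$mcc),
        auc = mean(folds_tbl$auc, na.rm = TRUE),
        auc_sd = sd(folds_tbl$auc, na.rm = TRUE),
        confusion_counts = cm_pooled,
        confusion_pct = 100 * cm_pooled / pmax(rowSums(cm_pooled), 1),
        seed = seed, positive = positive, threshold = threshold,
        nested = nested, n = nrow(X), p = ncol(X)
      ),
      class = "classification_report"
    )
  })
}

# imputation + z-normalization (+ optional NCA on `reduce_cols`) fitted on
# the rows `tr` only; returns a transform closure applicable to any rows
fit_fold_prep <- function(X, y, tr, reduce_cols, n_components) {
  mu_imp <- colMeans(X[tr, , drop = FALSE], na.rm = TRUE)
  mu_imp[is.nan(mu_imp)] <- 0
  impute <- function(M) {
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- mu_imp[j]
    M
  }
  Xtr <- impute(X[tr, , drop = FALSE])
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  znorm <- function(M) scale(M, center = ctr, scale = scl)

  nca <- NULL
  if (!is.null(reduce_cols)) {
    nca <- nca_fit(znorm(Xtr)[, reduce_cols, drop = FALSE], y[tr],
                   n_components = n_components)
  }
  transform <- function(M) {
    Z <- znorm(impute(M))
    if (is.null(nca)) return(unclass(Z))
    red <- predict(nca, Z[, reduce_cols, drop = FALSE])
    colnames(red) <- paste0("nca", seq_len(ncol(red)))
    keep <- Z[, -reduce_cols, drop = FALSE]
    unclass(cbind(red, keep))
  }
  list(transform = transform, nca = nca)
}

# inner stratified CV over the hyperparameter grid; boosting rounds are
# evaluated as staged prefixes of one ensemble fitted at the largest value
grid_search_inner <- function(Xtr, ytr, grid, combos, folds) {
  inner_id <- stratified_folds(ytr, folds)
  n_stage <- sort(grid$n_estimators)
  acc <- matrix(0, nrow(combos), length(n_stage))
  for (g in seq_len(folds)) {
    itr <- which(inner_id != g)
    ite <- which(inner_id == g)
    for (ci in seq_len(nrow(combos))) {
      model <- adaboost_fit(
        Xtr[itr, , drop = FALSE], ytr[itr],
        n_estimators = max(n_stage),
        learning_rate = combos$learning_rate[ci],
        max_depth = combos$max_depth[ci],
        max_leaf = combos$max_leaf[ci],
        feature_fraction = grid$feature_fraction
      )
      for (si in seq_along(n_stage)) {
        pred <- predict(model, Xtr[ite, , drop = FALSE], type = "class",
                        n_estimators = n_stage[si])
        acc[ci, si] <- acc[ci, si] + mean(pred == ytr[ite])
      }
    }
  }
  best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  list(max_depth = combos$max_depth[best[1]],
       max_leaf = combos$max_leaf[best[1]],
       learning_rate = combos$learning_rate[best[1]],
       n_estimators = n_stage[best[2]])
}

classify_prob <- function(prob, levels, positive, threshold) {
  if (length(levels) == 2) {
    neg <- setdiff(levels, positive)
    factor(ifelse(prob[, positive] >= threshold, positive, neg),
           levels = levels)
  } else {
    factor(levels[max.col(prob, ties.method = "first")], levels = levels)
  }
}

fold_auc <- function(y_true, prob, positive) {
  classes <- colnames(prob)
  if (length(classes) == 2) {
    if (length(unique(y_true)) < 2) return(NA_real_)
    r <- pROC::roc(response = y_true == positive,
                   predictor = prob[, positive],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    return(as.numeric(pROC::auc(r)))
  }
  aucs <- vapply(classes, function(cl) {
    if (length(unique(y_true == cl)) < 2) return(NA_real_)
    r <- pROC::roc(response = y_true == cl, predictor = prob[, cl],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %d subjects, %d features, seed %d%s\n  accuracy %.1f +/- %.1f %%, MCC %.2f +/- %.2f, AUC %.2f +/- %.2f\n",
    x$n, x$p, x$seed, if (x$nested) "" else " [non-nested]",
    x$accuracy, x$accuracy_sd, x$mcc, x$mcc_sd, x$auc, x$auc_sd
  ))
  cat("  pooled confusion (row %):\n")
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' Tidy a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return One row per fold: metrics and selected hyperparameters.
#' @export
tidy.classification_report <- function(x, ...) x$folds

#' One-row summary of a classification report
#'
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return One-row tibble of mean and SD of accuracy, MCC and AUC.
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, accuracy_sd = x$accuracy_sd,
    mcc = x$mcc, mcc_sd = x$mcc_sd, auc = x$auc, auc_sd = x$auc_sd,
    folds = nrow(x$folds), n = x$n, p = x$p, seed = x$seed
  )
}

# ---- Input assembly ------------------------------------------------------

#' Assemble a classification input matrix
#'
#' Builds the feature matrix for one classification modality:
#' \describe{
#'   \item{`spatial`}{the 24 spatial features.}
#'   \item{`gaze_adjustment`}{the 12 mixed-cell moment summaries, NCA-reduced
#'     to `n_components`.}
#'   \item{`response_type_gaze`}{the 48 by-response-type summaries,
#'     NCA-reduced to `n_components`.}
#'   \item{`response_type_gaze_significant`}{the reduced by-type summaries
#'     plus the 8 discriminative spatial features (13 columns).}
#'   \item{`response_type_gaze_significant_performance`}{as above plus the 6
#'     game-performance features (19 columns).}
#' }
#' This standalone assembler fits imputation, z-normalization and NCA on
#' all rows — use it for column contracts and exploration; [classify_cohort()]
#' refits those steps inside each training fold.
#'
#' @param summary_tbl Output of [summarize_adjustment()] in the matching
#'   mode (`mixed` for `gaze_adjustment`, `by_response_type` otherwise).
#' @param spatial_tbl Output of [extract_cohort_features()].
#' @param mode Modality name (see above).
#' @param significant Either `"fixed_list"` (the fixed 8-feature subset of
#'   [significant_spatial_features()]) or a character vector of feature
#'   names (e.g. the current run's BH-significant set).
#' @param n_components NCA dimension (default 5).
#' @param seed Passed to [nca_fit()].
#' @return Numeric matrix with subject ids as row names and the class
#'   labels as attribute `"labels"` (typical first).
#' @export
assemble_input <- function(summary_tbl, spatial_tbl,
                           mode = c("spatial", "gaze_adjustment",
                                    "response_type_gaze",
                                    "response_type_gaze_significant",
                                    "response_type_gaze_significant_performance"),
                           significant = "fixed_list", n_components = 5,
                           seed = NULL) {
  mode <- match.arg(mode)
  blocks <- build_feature_blocks(summary_tbl, spatial_tbl, mode, significant)
  X <- blocks$X
  y <- blocks$y
  if (is.null(blocks$reduce_cols)) {
    out <- X
  } else {
    prep <- fit_fold_prep(X, y, seq_len(nrow(X)), blocks$reduce_cols,
                          n_components)
    out <- prep$transform(X)
  }
  rownames(out) <- blocks$subject_id
  attr(out, "labels") <- y
  attr(out, "mode") <- mode
  out
}

# shared block construction: full matrix + indices of the columns to reduce
build_feature_blocks <- function(summary_tbl, spatial_tbl, mode,
                                 significant = "fixed_list") {
  perf <- c("go_pos_pct", "go_neg_pct", "nogo_pos_pct", "nogo_neg_pct",
            "rt_mean", "rt_var")
  sig <- if (identical(significant, "fixed_list")) {
    significant_spatial_features()
  } else {
    significant
  }
  if (mode == "spatial") {
    X <- as.matrix(spatial_tbl[, spatial_feature_names()])
    return(list(X = X, y = spatial_tbl$group,
                subject_id = spatial_tbl$subject_id, reduce_cols = NULL))
  }
  adj_cols <- setdiff(names(summary_tbl), c("subject_id", "group"))
  merged <- left_join(summary_tbl,
                      select(spatial_tbl, -"group"), by = "subject_id")
  extra <- switch(mode,
    gaze_adjustment = character(),
    response_type_gaze = character(),
    response_type_gaze_significant = sig,
    response_type_gaze_significant_performance = c(sig, perf)
  )
  X <- as.matrix(merged[, c(adj_cols, extra), drop = FALSE])
  list(X = X, y = merged$group, subject_id = merged$subject_id,
       reduce_cols = seq_along(adj_cols))
}

#' Cross-validated classification of a cohort
#'
#' End-to-end protocol for one modality: builds the feature blocks from the
#' spatial feature table and the AR coefficient summaries, binarizes the
#' labels (`typical` vs the pooled `asd` groups) unless `three_class`, and
#' runs leakage-free nested CV with [train_eval_cv()].
#'
#' @param spatial_tbl Output of [extract_cohort_features()].
#' @param fits Per-segment AR fits from [fit_cohort_adjustments()].
#' @param mode Modality (see [assemble_input()]).
#' @param three_class Keep the three group labels (default `FALSE`: typical
#'   vs pooled ASD).
#' @param significant `"fixed_list"` or a feature-name vector.
#' @inheritParams train_eval_cv
#' @return A `classification_report`.
#' @export
classify_cohort <- function(spatial_tbl, fits,
                            mode = "response_type_gaze_significant",
                            three_class = FALSE,
                            significant = "fixed_list",
                            grid = model_grid(), folds = 3, seed = 1,
                            n_components = 5, threshold = 0.5,
                            nested = TRUE) {
  summary_mode <- if (mode == "gaze_adjustment") "mixed" else
    "by_response_type"
  summary_tbl <- summarize_adjustment(fits, summary_mode)
  blocks <- build_feature_blocks(summary_tbl, spatial_tbl, mode, significant)
  y <- if (three_class) {
    factor(blocks$y, levels = c("typical", "asd_no_adhd", "asd_adhd"))
  } else {
    factor(ifelse(blocks$y == "typical", "typical", "asd"),
           levels = c("typical", "asd"))
  }
  train_eval_cv(blocks$X, y, grid = grid, folds = folds, seed = seed,
                reduce_cols = blocks$reduce_cols,
                n_components = n_components, threshold = threshold,
                positive = if (three_class) NULL else "asd",
                nested = nested)
}
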