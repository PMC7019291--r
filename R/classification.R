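# The wet/dry classification study: per-index Euclidean-norm scaling,
# leave-one-subject-out cross-validation with dry up-sampling, nine
# classifier families with frozen hyperparameters, pooled confusion
# metrics, and the exhaustive feature-subset sweep.

#' Classifier specification
#'
#' One of the nine model families with its fixed hyperparameters:
#' LDA; QDA (covariances shrunk by 1e-6 * trace/d for invertibility on
#' small up-sampled classes); unregularized logistic regression (with a
#' tiny-ridge fallback under perfect separation); SVMs with cubic kernel
#' (C = 1) and Gaussian kernels of scale 0.66 ("fine") and 2.6 ("medium",
#' both C = 1); 1-nearest-neighbor; a CART decision tree (Gini, minimum
#' leaf 1); and a random-subspace ensemble of 30 1-NN learners on
#' ceiling(d/2) features each (SE-KNN).
#'
#' @param family one of `"LDA"`, `"QDA"`, `"Logistic"`, `"CubicSVM"`,
#'   `"FineGaussianSVM"`, `"MediumGaussianSVM"`, `"KNN"`, `"DT"`,
#'   `"SE_KNN"`.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("LDA", "QDA", "Logistic", "CubicSVM",
                                       "FineGaussianSVM", "MediumGaussianSVM",
                                       "KNN", "DT", "SE_KNN")) {
  family <- match.arg(family)
  hp <- switch(family,
    LDA = list(),
    QDA = list(shrinkage = 1e-6),
    Logistic = list(ridge_fallback = 1e-3),
    CubicSVM = list(cost = 1, degree = 3, coef0 = 1, gamma = 1),
    FineGaussianSVM = list(cost = 1, kernel_scale = 0.66),
    MediumGaussianSVM = list(cost = 1, kernel_scale = 2.6),
    KNN = list(k = 1),
    DT = list(minbucket = 1),
    SE_KNN = list(learning_cycles = 30, k = 1))
  structure(list(family = family, hyperparameters = hp),
            class = "classifier_spec")
}

#' All nine classifier specifications
#' @return named list of `classifier_spec` objects.
#' @export
all_classifiers <- function() {
  fams <- c("LDA", "QDA", "Logistic", "CubicSVM", "FineGaussianSVM",
            "MediumGaussianSVM", "KNN", "DT", "SE_KNN")
  stats::setNames(lapply(fams, classifier_spec), fams)
}

#' Scale feature columns to the Euclidean norm of each index
#'
#' Each feature column is divided by its Euclidean (L2) norm computed on
#' the fitting rows; the same divisor is applied to held-out rows, so no
#' information leaks from validation folds into the scaling.
#'
#' @param table feature table (data.frame).
#' @param fit_rows integer/logical row subset on which norms are computed.
#' @param feature_cols columns to scale.
#' @return list with `table` (scaled) and `divisors` (named vector).
#' @export
scale_features <- function(table, fit_rows = seq_len(nrow(table)),
                           feature_cols) {
  if (length(fit_rows) == 0) stop("fit_rows must be non-empty")
  divisors <- vapply(feature_cols, function(cn) {
    sqrt(sum(table[[cn]][fit_rows]^2))
  }, numeric(1))
  zero <- names(divisors)[divisors == 0]
  if (length(zero)) {
    stop("zero-norm feature column(s): ", paste(zero, collapse = ", "))
  }
  for (cn in feature_cols) table[[cn]] <- table[[cn]] / divisors[[cn]]
  list(table = table, divisors = divisors)
}

#' Up-sample the dry class to balance training data
#'
#' Replicates dry rows until the dry count matches the wet count: whole
#' replications first, then the first `remainder` dry rows once more. In
#' the study structure (48 wet, 16 dry per training fold) this is an exact
#' triplication, equivalent to weighting the dry class three-fold.
#'
#' @param table training feature table with a `label` column.
#' @return balanced table.
#' @export
upsample_dry <- function(table) {
  dry <- which(table$label == "dry")
  wet <- which(table$label == "wet")
  if (length(dry) == 0) stop("no dry rows to up-sample")
  if (length(dry) >= length(wet)) return(table)
  reps <- length(wet) %/% length(dry)
  rem <- length(wet) %% length(dry)
  idx <- c(wet, rep(dry, reps), dry[seq_len(rem)])
  table[sort(idx), , drop = FALSE]
}

# --- model families ------------------------------------------------------

.qda_fit <- function(x, y, shrinkage) {
  classes <- levels(y)
  fit <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    S <- stats::cov(xi)
    S <- S + diag(shrinkage * sum(diag(S)) / ncol(x) + 1e-12, ncol(x))
    list(mu = colMeans(xi), Sinv = solve(S),
         logdet = determinant(S, logarithm = TRUE)$modulus,
         logprior = log(nrow(xi) / nrow(x)))
  })
  names(fit) <- classes
  fit
}

.qda_predict <- function(fit, x) {
  scores <- sapply(fit, function(f) {
    d <- sweep(x, 2, f$mu)
    -0.5 * rowSums((d %*% f$Sinv) * d) - 0.5 * as.numeric(f$logdet) +
      f$logprior
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  names(fit)[max.col(scores, ties.method = "first")]
}

.se_knn_predict <- function(train_x, train_y, test_x, cycles, seed) {
  set.seed(seed)
  d <- ncol(train_x)
  m <- ceiling(d / 2)
  votes <- matrix(0L, nrow(test_x), 2,
                  dimnames = list(NULL, levels(train_y)))
  for (b in seq_len(cycles)) {
    feats <- sample.int(d, m)
    pred <- class::knn(train_x[, feats, drop = FALSE],
                       test_x[, feats, drop = FALSE], train_y, k = 1)
    for (cl in levels(train_y)) votes[, cl] <- votes[, cl] + (pred == cl)
  }
  levels(train_y)[max.col(votes, ties.method = "first")]
}

#' Fit a classifier and predict held-out rows
#'
#' Trains the specified family on scaled features and predicts wet/dry
#' labels for the test rows. Deterministic given `seed` (used by the
#' subspace ensemble's feature draws and any distance-tie breaks).
#'
#' @param spec a `classifier_spec`.
#' @param train training feature table (scaled, both classes present).
#' @param test_rows held-out feature table (same columns).
#' @param feature_cols feature columns to use (d >= 1).
#' @param seed integer seed.
#' @return character vector of predicted labels ("wet"/"dry").
#' @export
fit_predict <- function(spec, train, test_rows, feature_cols, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (length(feature_cols) == 0) stop("feature subset is empty")
  y <- factor(train$label, levels = c("dry", "wet"))
  if (nlevels(droplevels(y)) < 2) stop("training set contains a single class")
  xtr <- as.matrix(train[, feature_cols, drop = FALSE])
  xte <- as.matrix(test_rows[, feature_cols, drop = FALSE])
  hp <- spec$hyperparameters
  set.seed(seed)
  pred <- switch(spec$family,
    LDA = {
      fit <- MASS::lda(xtr, grouping = y)
      as.character(stats::predict(fit, xte)$class)
    },
    QDA = .qda_predict(.qda_fit(xtr, y, hp$shrinkage), xte),
    Logistic = {
      df <- data.frame(.y = as.integer(y == "dry"), xtr)
      fit <- tryCatch(
        stats::glm(.y ~ ., data = df, family = stats::binomial()),
        warning = function(w) NULL)
      if (is.null(fit) || !fit$converged) {
        rf <- glmnet::glmnet(cbind(xtr, 0), as.integer(y == "dry"),
                             family = "binomial", alpha = 0,
                             lambda = hp$ridge_fallback)
        p <- stats::predict(rf, cbind(xte, 0), type = "response")
        ifelse(as.numeric(p) > 0.5, "dry", "wet")
      } else {
        p <- stats::predict(fit, data.frame(xte), type = "response")
        ifelse(p > 0.5, "dry", "wet")
      }
    },
    CubicSVM = {
      fit <- e1071::svm(xtr, y, kernel = "polynomial", degree = hp$degree,
                        gamma = hp$gamma, coef0 = hp$coef0, cost = hp$cost,
                        scale = FALSE)
      as.character(stats::predict(fit, xte))
    },
    FineGaussianSVM = ,
    MediumGaussianSVM = {
      fit <- e1071::svm(xtr, y, kernel = "radial",
                        gamma = 1 / hp$kernel_scale^2, cost = hp$cost,
                        scale = FALSE)
      as.character(stats::predict(fit, xte))
    },
    KNN = as.character(class::knn(xtr, xte, y, k = hp$k)),
    DT = {
      df <- data.frame(.y = y, xtr)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = hp$minbucket,
                            cp = 0, xval = 0))
      as.character(stats::predict(fit, data.frame(xte), type = "class"))
    },
    SE_KNN = .se_knn_predict(xtr, y, xte, hp$learning_cycles, seed))
  unname(pred)
}

#' Classification metrics from pooled confusion counts
#'
#' Dry is the positive class. Accuracy = (TP+TN)/total, error rate its
#' complement, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' FPR = FP/(TN+FP) = 1 - specificity, precision = TP/(TP+FP).
#'
#' @param tp,fn,tn,fp confusion counts: TP dry classified dry, FN dry
#'   classified wet, TN wet classified wet, FP wet classified dry.
#' @return list with accuracy, error_rate, sensitivity, fpr, specificity,
#'   precision (NA with `precision_undefined = TRUE` when nothing was
#'   classified dry).
#' @export
compute_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total <= 0) stop("empty confusion counts")
  acc <- (tp + tn) / total
  prec_undef <- (tp + fp) == 0
  list(accuracy = acc,
       error_rate = 1 - acc,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (prec_undef) NA_real_ else tp / (tp + fp),
       precision_undefined = prec_undef)
}

#' Feature columns of a subset within a data view
#'
#' In the single-stage and increment views a subset of the nine base
#' indices maps to its own columns; in the combined rest-and-test view
#' each base index contributes both its `_rest` and `_test` columns.
#'
#' @param view one of `"rest_only"`, `"test_only"`, `"increment"`,
#'   `"rest_and_test"`.
#' @param subset character vector of base index names.
#' @return character vector of feature column names.
#' @export
view_feature_cols <- function(view, subset) {
  view <- match.arg(view, c("rest_only", "test_only", "increment",
                            "rest_and_test"))
  if (view == "rest_and_test") {
    as.vector(t(outer(subset, c("_rest", "_test"), paste0)))
  } else {
    subset
  }
}

#' Build the four data-view feature tables
#'
#' From per-stage feature tables: rest only, test only, rest-to-test
#' increments (test minus rest), and both stages side by side (18
#' columns, suffixed `_rest`/`_test`).
#'
#' @param rest_table,test_table per-stage feature tables with matching
#'   (subject, measurement) rows.
#' @param indices base index columns.
#' @return named list of four data.frames, each carrying a `view`
#'   attribute.
#' @export
build_views <- function(rest_table, test_table, indices = index_names()) {
  stopifnot(all(rest_table$subject == test_table$subject),
            all(rest_table$measurement == test_table$measurement))
  meta <- rest_table[, c("subject", "measurement", "label")]
  inc <- meta
  both <- meta
  for (ix in indices) {
    inc[[ix]] <- test_table[[ix]] - rest_table[[ix]]
    both[[paste0(ix, "_rest")]] <- rest_table[[ix]]
    both[[paste0(ix, "_test")]] <- test_table[[ix]]
  }
  views <- list(rest_only = rest_table[, c(names(meta), indices)],
                test_only = test_table[, c(names(meta), indices)],
                increment = inc, rest_and_test = both)
  for (v in names(views)) attr(views[[v]], "view") <- v
  views
}

#' Leave-one-subject-out evaluation of one model
#'
#' For each subject, all of that subject's rows are held out; feature
#' scaling is fit on the remaining training rows only, the dry class is
#' up-sampled, the model is fit and the held-out rows predicted.
#' Predictions are pooled over all folds into one confusion table (a
#' per-fold average is ill-defined with a single dry sample per fold).
#'
#' @param view_table a data-view feature table (with `view` attribute).
#' @param subset base index subset (non-empty).
#' @param spec a `classifier_spec`.
#' @param seed integer seed (fold seeds are derived from it).
#' @param scale_scope `"fold"` (fit scaling on training rows only; no
#'   leakage) or `"global"` (fit once on all rows).
#' @return one-row data.frame of class `sweep_result`: view, family,
#'   subset, subset_mask, n_features, confusion counts and metrics.
#' @export
loso_evaluate <- function(view_table, subset, spec, seed = 1,
                          scale_scope = c("fold", "global")) {
  scale_scope <- match.arg(scale_scope)
  view <- attr(view_table, "view")
  if (is.null(view)) view <- "test_only"
  cs <- canonical_subset(subset)
  cols <- view_feature_cols(view, cs$names)
  if (length(cols) == 0) stop("feature subset is empty")
  subjects <- unique(view_table$subject)
  if (scale_scope == "global") {
    view_table <- scale_features(view_table, feature_cols = cols)$table
  }
  truth <- character(0); pred <- character(0)
  for (i in seq_along(subjects)) {
    hold <- view_table$subject == subjects[i]
    if (!any(hold)) stop("subject with no rows: ", subjects[i])
    train <- view_table[!hold, , drop = FALSE]
    test <- view_table[hold, , drop = FALSE]
    if (scale_scope == "fold") {
      sc <- scale_features(rbind(train, test),
                           fit_rows = seq_len(nrow(train)),
                           feature_cols = cols)
      train <- sc$table[seq_len(nrow(train)), , drop = FALSE]
      test <- sc$table[-seq_len(nrow(train)), , drop = FALSE]
    }
    train <- upsample_dry(train)
    p <- fit_predict(spec, train, test, cols, seed = seed + i)
    truth <- c(truth, test$label)
    pred <- c(pred, p)
  }
  tp <- sum(truth == "dry" & pred == "dry")
  fn <- sum(truth == "dry" & pred == "wet")
  tn <- sum(truth == "wet" & pred == "wet")
  fp <- sum(truth == "wet" & pred == "dry")
  m <- compute_metrics(tp, fn, tn, fp)
  out <- data.frame(view = view, family = spec$family,
                    subset = paste(cs$names, collapse = ";"),
                    subset_mask = cs$mask, n_features = length(cs$names),
                    tp = tp, fn = fn, tn = tn, fp = fp,
                    accuracy = m$accuracy, error_rate = m$error_rate,
                    sensitivity = m$sensitivity, fpr = m$fpr,
                    specificity = m$specificity, precision = m$precision)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Enumerate all non-empty subsets of the index set
#' @param indices base index names.
#' @return list of character vectors (2^n - 1 subsets).
#' @export
enumerate_subsets <- function(indices = index_names()) {
  unlist(lapply(seq_along(indices), function(k) {
    utils::combn(indices, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Exhaustive feature-subset sweep under LOSO
#'
#' Evaluates every non-empty subset of the base indices (511 of the 512
#' subsets; the empty set is skipped) for each classifier family, via
#' [loso_evaluate()]. Results are sorted by accuracy (descending), ties
#' broken by fewer features then lexicographic subset name.
#'
#' @param view_table a data-view feature table.
#' @param families list of `classifier_spec` (default all nine).
#' @param seed integer seed.
#' @param indices base index names to sweep over.
#' @param scale_scope passed to [loso_evaluate()].
#' @return data.frame of sweep results, one row per (family, subset).
#' @export
exhaustive_sweep <- function(view_table, families = all_classifiers(),
                             seed = 1, indices = index_names(),
                             scale_scope = "fold") {
  subsets <- enumerate_subsets(indices)
  rows <- vector("list", length(subsets) * length(families))
  i <- 0L
  for (fam in families) {
    for (ss in subsets) {
      i <- i + 1L
      rows[[i]] <- loso_evaluate(view_table, ss, fam, seed = seed,
                                 scale_scope = scale_scope)
    }
  }
  res <- do.call(rbind, rows)
  res[order(-res$accuracy, res$n_features, res$subset), , drop = FALSE]
}
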