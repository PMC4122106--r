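#' Confusion-matrix performance metrics
#'
#' Computes TP/FP/TN/FN and the four standard binary metrics:
#' specificity `TN/(FP+TN)`, sensitivity `TP/(TP+FN)`, accuracy
#' `(TP+TN)/n`, and Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any MCC
#' denominator factor is zero the coefficient is defined as 0 (with a note).
#' A rank-based AUC is included when decision values are supplied.
#'
#' @param truth factor/character of true classes (`"positive"`/`"negative"`);
#'   both classes must be present.
#' @param predicted predicted classes, same encoding and length.
#' @param decision_values optional numeric scores (higher = more positive)
#'   used for the AUC.
#' @return Object of class `metrics_report`: list with `TP`, `FP`, `TN`,
#'   `FN`, `specificity`, `sensitivity`, `accuracy`, `mcc` and `auc`
#'   (`NA` when no decision values are given).
#' @examples
#' truth <- rep(c("positive", "negative"), c(5, 5))
#' pred  <- c("positive", "positive", "positive", "negative", "negative",
#'            "negative", "negative", "negative", "negative", "positive")
#' compute_metrics(truth, pred)
#' @export
compute_metrics <- function(truth, predicted, decision_values = NULL) {
  truth <- as_class(truth)
  predicted <- as_class(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(unique(truth)) < 2L) {
    stop("truth contains a single class; metrics are undefined")
  }
  tp <- sum(truth == "positive" & predicted == "positive")
  fp <- sum(truth == "negative" & predicted == "positive")
  tn <- sum(truth == "negative" & predicted == "negative")
  fn <- sum(truth == "positive" & predicted == "negative")
  denom <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(denom == 0)) {
    message("MCC denominator factor is zero; MCC defined as 0")
    0
  } else {
    (tp * tn - fp * fn) / sqrt(prod(denom))
  }
  auc <- if (is.null(decision_values)) NA_real_ else
    roc_auc(truth, decision_values)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 specificity = tn / (fp + tn),
                 sensitivity = tp / (tp + fn),
                 accuracy = (tp + tn) / length(truth),
                 mcc = mcc,
                 auc = auc),
            class = "metrics_report")
}

as_class <- function(x) {
  x <- as.character(x)
  if (!all(x %in% c("positive", "negative"))) {
    stop("classes must be 'positive'/'negative'")
  }
  x
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d | SP=%.3f SE=%.3f ACC=%.3f MCC=%.3f",
              x$TP, x$FP, x$TN, x$FN, x$specificity, x$sensitivity,
              x$accuracy, x$mcc))
  if (!is.na(x$auc)) cat(sprintf(" AUC=%.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Rank-based area under the ROC curve
#'
#' The probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with ties credited one half — equivalent to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param truth true classes (`"positive"`/`"negative"`), both present.
#' @param scores numeric decision values, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, scores) {
  truth <- as_class(truth)
  if (length(truth) != length(scores)) {
    stop("truth and scores must have equal length")
  }
  pos <- truth == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("truth contains a single class; AUC is undefined")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- SVM plumbing ----------------------------------------------------------

# Learn per-feature scaling on the training matrix; constant features are
# dropped (z-scoring them is undefined) with a warning.
learn_scaling <- function(x, scale = TRUE) {
  if (!scale) {
    return(list(keep = colnames(x), center = NULL, sd = NULL))
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped before scaling: ",
            paste(utils::head(colnames(x)[!keep], 5L), collapse = ", "))
  }
  list(keep = colnames(x)[keep], center = mu[keep], sd = sdv[keep])
}

apply_scaling <- function(x, sc) {
  x <- x[, sc$keep, drop = FALSE]
  if (is.null(sc$center)) return(x)
  sweep(sweep(x, 2L, sc$center, "-"), 2L, sc$sd, "/")
}

# Fit an RBF SVM and return a closure predicting (class, decision value) with
# decision values oriented so that higher always means the positive class.
fit_rbf_svm <- function(x, y, cost, gamma) {
  y <- factor(as_class(y), levels = c("negative", "positive"))
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  function(newx) {
    pred <- stats::predict(fit, newx, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 orients the decision value toward the first training label it
    # saw; the column name "<a>/<b>" says positive values favour class <a>.
    if (startsWith(colnames(dv)[1L], "negative")) dv <- -dv
    list(class = as.character(pred), score = as.numeric(dv))
  }
}

#' Leave-one-out cross-validated predictions
#'
#' For each sample, trains an RBF-kernel SVM on the remaining `n - 1` samples
#' (re-learning the feature scaling on each fold's training part) and
#' predicts the held-out sample. Deterministic given inputs. Should a fold
#' lose one class entirely (possible only when a class has a single sample),
#' the fold's prediction falls back to the majority class of its training
#' part, with a warning.
#'
#' @param features numeric matrix, rows = samples, columns = features
#'   (genes); must have row and column names.
#' @param labels true classes (`"positive"`/`"negative"`), or a
#'   [sample_labels] matching the rows.
#' @param cost,gamma RBF SVM hyperparameters (both > 0).
#' @param scale z-score features by each fold's training statistics
#'   (default TRUE).
#' @return Data frame with columns `sample_id`, `truth`, `predicted`,
#'   `decision_value` (oriented so higher = positive).
#' @export
loocv_predict <- function(features, labels, cost, gamma, scale = TRUE) {
  labels <- labels_for_features(features, labels)
  n <- nrow(features)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pred <- character(n)
  dv <- numeric(n)
  for (i in seq_len(n)) {
    tr_x <- features[-i, , drop = FALSE]
    tr_y <- labels[-i]
    if (length(unique(tr_y)) < 2L) {
      maj <- names(which.max(table(tr_y)))
      warning("fold ", i, " lost one class; predicting training majority")
      pred[i] <- maj
      dv[i] <- if (maj == "positive") Inf else -Inf
      next
    }
    sc <- suppressWarnings(learn_scaling(tr_x, scale))
    if (length(sc$keep) == 0L) stop("all features constant within a fold")
    model <- fit_rbf_svm(apply_scaling(tr_x, sc), tr_y, cost, gamma)
    out <- model(apply_scaling(features[i, , drop = FALSE], sc))
    pred[i] <- out$class
    dv[i] <- out$score
  }
  data.frame(sample_id = rownames(features), truth = labels,
             predicted = pred, decision_value = dv,
             stringsAsFactors = FALSE, row.names = NULL)
}

labels_for_features <- function(features, labels) {
  if (is.null(rownames(features))) stop("features need row names (sample ids)")
  if (inherits(labels, "sample_labels")) {
    idx <- match(rownames(features), labels$sample_id)
    if (anyNA(idx)) {
      stop("samples without labels: ",
           paste(rownames(features)[is.na(idx)], collapse = ", "))
    }
    as.character(labels$class[idx])
  } else {
    as_class(labels)
  }
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates every (cost, gamma) pair by LOOCV on the training set and
#' returns the pair maximizing LOOCV accuracy. Ties are broken by higher
#' LOOCV MCC, then smaller cost, then smaller gamma, so the selection is
#' deterministic. The default grids are the libsvm-style powers of two,
#' cost in 2^-5 .. 2^15 and gamma in 2^-15 .. 2^3 (step 2^2).
#'
#' @inheritParams loocv_predict
#' @param c_grid,gamma_grid numeric vectors of candidate values.
#' @return Object of class `model_spec`: list with `cost`, `gamma`, the
#'   winning `accuracy` and `mcc`, and the full selection `trace` data frame.
#' @export
grid_search <- function(features, labels,
                        c_grid = default_c_grid(),
                        gamma_grid = default_gamma_grid(),
                        scale = TRUE) {
  if (length(c_grid) == 0L || length(gamma_grid) == 0L) {
    stop("empty hyperparameter grid")
  }
  grid <- expand.grid(cost = sort(c_grid), gamma = sort(gamma_grid))
  acc <- numeric(nrow(grid)); mcc <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cv <- loocv_predict(features, labels, grid$cost[k], grid$gamma[k],
                        scale = scale)
    m <- suppressMessages(compute_metrics(cv$truth, cv$predicted))
    acc[k] <- m$accuracy
    mcc[k] <- m$mcc
  }
  trace <- data.frame(cost = grid$cost, gamma = grid$gamma,
                      loocv_accuracy = acc, loocv_mcc = mcc)
  best <- order(-acc, -mcc, grid$cost, grid$gamma)[1L]
  structure(list(cost = grid$cost[best], gamma = grid$gamma[best],
                 accuracy = acc[best], mcc = mcc[best],
                 scale = scale, trace = trace),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: cost=%g gamma=%g (LOOCV ACC=%.3f MCC=%.3f)\n",
              x$cost, x$gamma, x$accuracy, x$mcc))
  invisible(x)
}

#' @rdname grid_search
#' @export
default_c_grid <- function() 2^seq(-5, 15, by = 2)

#' @rdname grid_search
#' @export
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

#' Train on one set, validate on another
#'
#' Training metrics are the LOOCV metrics of the chosen hyperparameters on
#' the training set; validation metrics come from a single model fit on the
#' full training set (features z-scored by the training statistics) and
#' applied to the test set. Feature columns must match exactly between sets.
#'
#' @param train_features,test_features sample x feature matrices with
#'   identical, identically ordered columns.
#' @param train_labels,test_labels classes for the respective rows.
#' @param spec a `model_spec` (or any list with `cost` and `gamma`).
#' @param scale z-score by training statistics (default TRUE).
#' @return List with `training` and `validation` [compute_metrics] reports
#'   (both including AUC) and the `spec` used.
#' @export
train_and_validate <- function(train_features, train_labels,
                               test_features, test_labels, spec,
                               scale = TRUE) {
  if (!identical(colnames(train_features), colnames(test_features))) {
    extra <- setdiff(colnames(train_features), colnames(test_features))
    miss <- setdiff(colnames(test_features), colnames(train_features))
    stop("feature columns differ between train and test",
         if (length(extra)) paste0("; only in train: ",
                                   paste(utils::head(extra, 5L), collapse = ", ")),
         if (length(miss)) paste0("; only in test: ",
                                  paste(utils::head(miss, 5L), collapse = ", ")),
         if (!length(extra) && !length(miss)) "; column order differs")
  }
  train_labels <- labels_for_features(train_features, train_labels)
  test_labels <- labels_for_features(test_features, test_labels)
  cv <- loocv_predict(train_features, train_labels, spec$cost, spec$gamma,
                      scale = scale)
  training <- suppressMessages(
    compute_metrics(cv$truth, cv$predicted, cv$decision_value))
  sc <- learn_scaling(train_features, scale)
  model <- fit_rbf_svm(apply_scaling(train_features, sc), train_labels,
                       spec$cost, spec$gamma)
  out <- model(apply_scaling(test_features, sc))
  validation <- suppressMessages(
    compute_metrics(test_labels, out$class, out$score))
  list(training = training, validation = validation, spec = spec)
}

#' Paired original/swap analysis with a fixed signature
#'
#' The original arm trains on set A and validates on set B; the swap arm
#' trains on B and validates on A. The same, pre-fixed gene signature is used
#' in both arms — the signature is never re-selected — while the (cost,
#' gamma) grid search is re-run independently per arm (set `reuse_spec =
#' TRUE` to carry the original arm's hyperparameters into the swap arm).
#' Agreement between the arms indicates that the signature, not a lucky
#' train/test split, carries the predictive information.
#'
#' @param setA,setB lists with elements `expr` (gene x sample numeric matrix)
#'   and `labels` (a [sample_labels]).
#' @param signature character vector of gene symbols; every gene must be
#'   present in both expression matrices.
#' @param c_grid,gamma_grid hyperparameter grids (see [grid_search]).
#' @param scale z-score features (default TRUE).
#' @param reuse_spec reuse the original arm's (cost, gamma) for the swap arm
#'   instead of re-optimizing (default FALSE).
#' @return Object of class `analysis_report`: list with `signature` and the
#'   two arms `original` and `swap`, each a [train_and_validate] result.
#' @export
run_original_and_swap <- function(setA, setB, signature,
                                  c_grid = default_c_grid(),
                                  gamma_grid = default_gamma_grid(),
                                  scale = TRUE, reuse_spec = FALSE) {
  signature <- toupper(as.character(signature))
  if (length(signature) == 0L) stop("empty signature")
  fa <- signature_features(setA, signature, "setA")
  fb <- signature_features(setB, signature, "setB")

  spec_orig <- grid_search(fa$x, fa$y, c_grid, gamma_grid, scale = scale)
  original <- train_and_validate(fa$x, fa$y, fb$x, fb$y, spec_orig,
                                 scale = scale)
  spec_swap <- if (reuse_spec) spec_orig else
    grid_search(fb$x, fb$y, c_grid, gamma_grid, scale = scale)
  swap <- train_and_validate(fb$x, fb$y, fa$x, fa$y, spec_swap,
                             scale = scale)
  structure(list(signature = signature, original = original, swap = swap),
            class = "analysis_report")
}

signature_features <- function(set, signature, what) {
  if (!is.list(set) || is.null(set$expr) || is.null(set$labels)) {
    stop(what, " must be a list with elements expr and labels")
  }
  expr <- set$expr
  rownames(expr) <- toupper(rownames(expr))
  missing <- setdiff(signature, rownames(expr))
  if (length(missing) > 0L) {
    stop("signature gene(s) missing from ", what, ": ",
         paste(missing, collapse = ", "))
  }
  x <- t(expr[signature, , drop = FALSE])
  list(x = x, y = labels_for_features(x, set$labels))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report |", length(x$signature), "signature genes\n")
  for (arm in c("original", "swap")) {
    cat(sprintf("%-9s spec: cost=%g gamma=%g\n", arm,
                x[[arm]]$spec$cost, x[[arm]]$spec$gamma))
    cat("  training:   "); print(x[[arm]]$training)
    cat("  validation: "); print(x[[arm]]$validation)
  }
  invisible(x)
}
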