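#' Two-class sample labels
#'
#' Binds sample identifiers to a binary phenotype. Internally every labelled
#' sample is either `"positive"` or `"negative"`; `positive_class` records
#' the endpoint-specific name of the positive class (pCR, high-risk, PN, ...).
#'
#' @param sample_id character vector of sample identifiers (unique).
#' @param class character vector; values must be `"positive"`/`"negative"`
#'   or match `positive_class`/`negative_class`.
#' @param positive_class,negative_class endpoint-specific class names used to
#'   interpret `class` and label reports.
#' @return Object of class `sample_labels`: data frame with columns
#'   `sample_id` and `class` (factor, levels `negative`, `positive`);
#'   attribute `positive_class` keeps the original name.
#' @export
sample_labels <- function(sample_id, class,
                          positive_class = "positive",
                          negative_class = "negative") {
  sample_id <- as.character(sample_id)
  class <- as.character(class)
  if (length(sample_id) != length(class)) {
    stop("sample_id and class must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  cls <- ifelse(class %in% c("positive", positive_class), "positive",
         ifelse(class %in% c("negative", negative_class), "negative", NA))
  if (anyNA(cls)) {
    stop("unrecognized class values: ",
         paste(unique(class[is.na(cls)]), collapse = ", "))
  }
  cls <- factor(cls, levels = c("negative", "positive"))
  counts <- table(cls)
  if (any(counts < 2L)) {
    stop("each class needs at least 2 samples (got ",
         counts[["positive"]], " positive, ",
         counts[["negative"]], " negative)")
  }
  structure(data.frame(sample_id = sample_id, class = cls,
                       stringsAsFactors = FALSE),
            positive_class = positive_class,
            class = c("sample_labels", "data.frame"))
}

# Align labels to the columns of an expression matrix; samples in the matrix
# without a label are dropped with a warning (and vice versa labels must all
# be present).
align_labels <- function(expr, labels) {
  stopifnot(inherits(labels, "sample_labels"))
  missing_in_expr <- setdiff(labels$sample_id, colnames(expr))
  if (length(missing_in_expr) > 0L) {
    stop("labelled samples absent from expression matrix: ",
         paste(missing_in_expr, collapse = ", "))
  }
  unlabelled <- setdiff(colnames(expr), labels$sample_id)
  if (length(unlabelled) > 0L) {
    warning(length(unlabelled),
            " expression sample(s) have no label and are dropped")
  }
  expr <- expr[, labels$sample_id, drop = FALSE]
  list(expr = expr,
       positive = labels$sample_id[labels$class == "positive"],
       negative = labels$sample_id[labels$class == "negative"])
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (rows = features, cols = samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs row and column names")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate row ids in expression")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids in expression")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  invisible(expr)
}

#' Row-wise pooled-variance two-sample t-test
#'
#' Computes the classical Student (equal-variance) two-sample t statistic and
#' two-sided p-value for every row of an expression matrix between the
#' positive and negative groups, with `n1 + n2 - 2` degrees of freedom and no
#' multiple-testing adjustment. Welch's unequal-variance variant is available
#' behind a flag.
#'
#' Degenerate rows: zero pooled variance with equal group means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means gives an infinite
#' statistic and `p = 0` with a warning.
#'
#' @param expr numeric matrix, rows = probesets or genes, columns = samples.
#' @param labels a [sample_labels] object covering the columns.
#' @param welch use Welch's test instead of pooled variance (default FALSE).
#' @return Data frame with columns `id`, `t`, `p` in the row order of `expr`.
#' @export
two_sample_t <- function(expr, labels, welch = FALSE) {
  check_expression(expr)
  al <- align_labels(expr, labels)
  x <- al$expr[, al$positive, drop = FALSE]
  y <- al$expr[, al$negative, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  } else {
    pooled <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- pooled * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2L, nrow(expr))
  }
  diff <- m1 - m2
  tstat <- ifelse(se2 > 0, diff / sqrt(se2),
                  ifelse(diff == 0, 0, sign(diff) * Inf))
  degenerate <- se2 == 0 & diff != 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " row(s) with zero pooled variance but unequal means; p set to 0")
  }
  p <- ifelse(is.infinite(tstat), 0,
              2 * stats::pt(abs(tstat), df, lower.tail = FALSE))
  p[se2 == 0 & diff == 0] <- 1
  data.frame(id = rownames(expr), t = unname(tstat), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Row-wise fold changes between two groups
#'
#' With log2-scale input (the default for series-matrix intensities),
#' `log2FC = mean(positive) - mean(negative)` and `FC = 2^log2FC`. With
#' linear-scale input, `FC = mean(positive) / mean(negative)`; rows whose
#' group mean is not strictly positive are an error, since the ratio is
#' undefined.
#'
#' @inheritParams two_sample_t
#' @param scale `"log2"` (default) or `"linear"`.
#' @return Data frame with columns `id`, `fold_change`, `log2_fc`.
#' @export
fold_changes <- function(expr, labels, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  check_expression(expr)
  al <- align_labels(expr, labels)
  m_pos <- rowMeans(al$expr[, al$positive, drop = FALSE])
  m_neg <- rowMeans(al$expr[, al$negative, drop = FALSE])
  if (scale == "log2") {
    lfc <- m_pos - m_neg
    fc <- 2^lfc
  } else {
    bad <- m_pos <= 0 | m_neg <= 0
    if (any(bad)) {
      stop("non-positive group mean on linear scale for row(s): ",
           paste(utils::head(rownames(al$expr)[bad], 5L), collapse = ", "))
    }
    fc <- m_pos / m_neg
    lfc <- log2(fc)
  }
  data.frame(id = rownames(expr), fold_change = unname(fc),
             log2_fc = unname(lfc), stringsAsFactors = FALSE)
}

#' Collapse probesets to unique gene symbols
#'
#' Affymetrix arrays interrogate many genes with several probesets. For each
#' annotated gene symbol this keeps the single probeset with the largest
#' absolute log2 fold change between the two phenotype groups (ties go to the
#' lexicographically smallest probeset id, for determinism). Collapsing is
#' therefore endpoint-dependent by construction and requires labels.
#' Unannotated probesets are dropped and counted in the report.
#'
#' @param expr probeset-level numeric matrix (rows = probesets).
#' @param annotation data frame with columns `probeset_id`, `symbol`
#'   (probeset ids unique; symbols upper-cased on use).
#' @param labels a [sample_labels].
#' @param scale passed to [fold_changes].
#' @return List with `expr` (gene-level matrix, rows = symbols), `report`
#'   (data frame `gene`, `probeset`, `log2_fc`), and `n_unannotated`.
#' @export
collapse_probesets <- function(expr, annotation, labels,
                               scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  check_expression(expr)
  if (!all(c("probeset_id", "symbol") %in% names(annotation))) {
    stop("annotation needs columns probeset_id and symbol")
  }
  if (anyDuplicated(annotation$probeset_id)) {
    stop("duplicate probeset_id in annotation")
  }
  if (missing(labels) || is.null(labels)) {
    stop("labels are required: the collapsed probeset is chosen by fold change")
  }
  ann <- data.frame(probeset_id = as.character(annotation$probeset_id),
                    symbol = toupper(as.character(annotation$symbol)),
                    stringsAsFactors = FALSE)
  ann <- ann[!is.na(ann$symbol) & nzchar(ann$symbol), , drop = FALSE]
  ann <- ann[ann$probeset_id %in% rownames(expr), , drop = FALSE]
  n_unannotated <- sum(!rownames(expr) %in% ann$probeset_id)
  if (nrow(ann) == 0L) stop("no annotated probesets present in the matrix")

  fc <- fold_changes(expr[ann$probeset_id, , drop = FALSE], labels, scale)
  ann$abs_lfc <- abs(fc$log2_fc)
  ann$log2_fc <- fc$log2_fc
  # max |log2FC| per symbol; ties -> smallest probeset id
  ord <- order(ann$symbol, -ann$abs_lfc, ann$probeset_id)
  ann <- ann[ord, , drop = FALSE]
  chosen <- ann[!duplicated(ann$symbol), , drop = FALSE]
  gene_expr <- expr[chosen$probeset_id, , drop = FALSE]
  rownames(gene_expr) <- chosen$symbol
  list(expr = gene_expr,
       report = data.frame(gene = chosen$symbol,
                           probeset = chosen$probeset_id,
                           log2_fc = chosen$log2_fc,
                           stringsAsFactors = FALSE, row.names = NULL),
       n_unannotated = n_unannotated)
}

#' Per-gene differential expression table
#'
#' Convenience wrapper combining [two_sample_t] and [fold_changes] on a
#' gene-level matrix.
#'
#' @inheritParams fold_changes
#' @param welch passed to [two_sample_t].
#' @return Object of class `deg_table`: data frame with columns `gene`, `t`,
#'   `p`, `fold_change`, `log2_fc`.
#' @export
deg_stats <- function(expr, labels, scale = c("log2", "linear"),
                      welch = FALSE) {
  scale <- match.arg(scale)
  tt <- two_sample_t(expr, labels, welch = welch)
  fc <- fold_changes(expr, labels, scale)
  out <- data.frame(gene = tt$id, t = tt$t, p = tt$p,
                    fold_change = fc$fold_change, log2_fc = fc$log2_fc,
                    stringsAsFactors = FALSE)
  structure(out, class = c("deg_table", "data.frame"))
}

#' Select differentially expressed genes
#'
#' Keeps rows with `p < p_cut` (strict). When `fc_cut` is given, additionally
#' requires `FC > fc_cut` or `FC < 1/fc_cut` (both strict); the conventional
#' pair is 1.5 and 0.667. Output rows are ordered by ascending p, ties by
#' symbol; the result is a subset of the input and re-applying the same cuts
#' is idempotent.
#'
#' @param stats a `deg_table` from [deg_stats] (or any data frame with
#'   columns `gene`, `p`, `fold_change`).
#' @param p_cut p-value cutoff in (0, 1), strict (default 0.05).
#' @param fc_cut fold-change cutoff > 1, strict on both sides, or `NULL` to
#'   filter on p only.
#' @return The selected subset, same columns, re-ordered; empty with a
#'   warning when nothing passes.
#' @export
select_degs <- function(stats, p_cut = 0.05, fc_cut = NULL) {
  if (!all(c("gene", "p", "fold_change") %in% names(stats))) {
    stop("stats needs columns gene, p, fold_change")
  }
  if (!is.numeric(p_cut) || p_cut <= 0 || p_cut >= 1) {
    stop("p_cut must lie in (0, 1)")
  }
  keep <- stats$p < p_cut
  if (!is.null(fc_cut)) {
    if (!is.numeric(fc_cut) || fc_cut <= 1) stop("fc_cut must exceed 1")
    keep <- keep & (stats$fold_change > fc_cut |
                    stats$fold_change < 1 / fc_cut)
  }
  out <- stats[keep, , drop = FALSE]
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no gene passes the DEG filters")
  out
}

#' Dichotomize survival at a milestone cutoff
#'
#' Converts overall survival into a binary endpoint: patients who died before
#' the cutoff are positive (high-risk); patients surviving at least the
#' cutoff — regardless of later censoring — are negative (low-risk); patients
#' censored before the cutoff carry no usable milestone information and are
#' excluded. The default cutoff is the one-year milestone (365 days).
#'
#' @param clinical data frame with columns `sample_id`, `time_days`
#'   (non-negative) and `event` (1/TRUE = death observed, 0/FALSE = censored).
#' @param cutoff_days positive milestone in days (default 365).
#' @param positive_class name recorded for the positive class
#'   (default `"high-risk"`).
#' @return List with `labels` (a [sample_labels] over the retained patients)
#'   and `excluded` (character vector of excluded sample ids).
#' @export
dichotomize_survival <- function(clinical, cutoff_days = 365,
                                 positive_class = "high-risk") {
  if (!all(c("sample_id", "time_days", "event") %in% names(clinical))) {
    stop("clinical needs columns sample_id, time_days, event")
  }
  if (!is.numeric(cutoff_days) || cutoff_days <= 0) {
    stop("cutoff_days must be positive")
  }
  time <- as.numeric(clinical$time_days)
  if (any(time < 0)) stop("negative survival times")
  event <- as.logical(clinical$event)
  status <- ifelse(time >= cutoff_days, "negative",
            ifelse(event, "positive", "excluded"))
  excluded <- as.character(clinical$sample_id[status == "excluded"])
  keep <- status != "excluded"
  labels <- sample_labels(clinical$sample_id[keep], status[keep],
                          positive_class = positive_class,
                          negative_class = "low-risk")
  attr(labels, "positive_class") <- positive_class
  list(labels = labels, excluded = excluded)
}
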