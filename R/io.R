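#' Read a GEO series MATRIX file
#'
#' Parses the GEO text export: lines starting with `!` are metadata
#' (`!Key<TAB>value...`), and the expression table sits between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers with
#' sample ids in its header row. Quoted identifiers are unquoted; values are
#' parsed as reals; ragged table rows are an error reporting the line number.
#'
#' @param path path to a series MATRIX text file (uncompressed).
#' @return List with `expr` (numeric matrix, probesets x samples) and
#'   `metadata` (named list of character vectors).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("series matrix table markers missing or malformed in ", path)
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  meta_lines <- lines[seq_len(begin - 1L)]
  meta_lines <- meta_lines[startsWith(meta_lines, "!")]
  metadata <- list()
  for (ln in meta_lines) {
    parts <- unquote(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    key <- sub("^!", "", parts[1L])
    metadata[[key]] <- c(metadata[[key]], parts[-1L])
  }
  tbl <- lines[(begin + 1L):(end - 1L)]
  cells <- strsplit(tbl, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- begin + which(widths != widths[1L])[1L]
    stop("ragged series matrix table at line ", bad, " of ", path)
  }
  header <- unquote(cells[[1L]])
  body <- cells[-1L]
  ids <- unquote(vapply(body, `[`, character(1L), 1L))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(header) - 1L,
                   dimnames = list(ids, header[-1L]))
  for (i in seq_along(body)) {
    values[i, ] <- as.numeric(unquote(body[[i]][-1L]))
  }
  if (anyNA(values)) stop("non-numeric or missing expression values in ", path)
  list(expr = values, metadata = metadata)
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: set id, description, then member symbols.
#' Duplicate members within a line are de-duplicated with a warning;
#' duplicate set ids are an error; a line without members is an error.
#' Symbols are upper-cased by [pathway_collection].
#'
#' @param path path to a GMT file.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line(s) without members: ",
         paste(which(short), collapse = ", "))
  }
  ids <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- vapply(fields, `[`, character(1L), 2L)
  members <- lapply(fields, function(f) toupper(f[-(1:2)]))
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1L)))
  if (n_dup > 0L) {
    warning(n_dup, " duplicate member(s) within GMT lines de-duplicated")
  }
  pathway_collection(ids, descs, lapply(members, unique))
}

#' Write a pathway collection as GMT
#'
#' @param pathways a [pathway_collection].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  lines <- vapply(seq_along(pathways$ids), function(k) {
    paste(c(pathways$ids[k], pathways$names[k], pathways$members[[k]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a plain TSV expression matrix
#'
#' The first column holds feature ids (header `id`), remaining columns one
#' sample each.
#'
#' @param path file path.
#' @return `read_expression_tsv`: numeric matrix with feature row names and
#'   sample column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path)
  rownames(mat) <- as.character(df[[1L]])
  check_expression(mat)
  mat
}

#' @rdname read_expression_tsv
#' @param expr numeric matrix to write.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression(expr)
  df <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "set")
  if (!all(need %in% names(df))) {
    stop("sample sheet needs columns sample_id and set (train/test)")
  }
  if (!all(df$set %in% c("train", "test"))) {
    stop("sample sheet 'set' column must be train/test")
  }
  df
}

#' Run the full signature-discovery and evaluation pipeline
#'
#' Chains every stage of the workflow on files from disk: read expression
#' (TSV or series MATRIX), collapse probesets to genes, compute t/fold-change
#' statistics on the training set, select DEGs, build the gene-pathway
#' bipartite network, score the DEGs by weighted projection, filter the
#' signature at the score threshold, then run the paired original/swap SVM
#' analysis with LOOCV grid search. All intermediate tables, the model specs
#' and a stage-count log are written into `output_dir`.
#'
#' Labels come either from a `class` column in the sample sheet or, when
#' `clinical` is given, from milestone dichotomization of survival (patients
#' censored before the milestone are excluded).
#'
#' @param expression path to a probeset-level expression TSV (or series
#'   MATRIX file when `format = "series_matrix"`).
#' @param annotation path to a probeset annotation TSV
#'   (`probeset_id`, `symbol`).
#' @param gmt path to the pathway GMT file.
#' @param samples path to a sample sheet TSV with columns `sample_id`, `set`
#'   (train/test) and, unless `clinical` is given, `class`.
#' @param output_dir directory for outputs (created if needed).
#' @param positive_class name of the positive class in the sample sheet.
#' @param clinical optional path to a survival TSV (`sample_id`, `time_days`,
#'   `event`); triggers milestone dichotomization.
#' @param milestone_days milestone cutoff for dichotomization (default 365).
#' @param format `"tsv"` (default) or `"series_matrix"`.
#' @param scale_input `"log2"` (default) or `"linear"` expression scale.
#' @param p_cut,fc_cut DEG filter cutoffs (see [select_degs]).
#' @param score_threshold signature score cutoff (default 1).
#' @param c_grid,gamma_grid SVM hyperparameter grids.
#' @param scale_features z-score features before the SVM (default TRUE).
#' @return Invisibly, a list with the `analysis_report`, the `signature`,
#'   the score table, the DEG table and the stage `counts`.
#' @export
run_pipeline <- function(expression, annotation, gmt, samples, output_dir,
                         positive_class = "positive",
                         clinical = NULL, milestone_days = 365,
                         format = c("tsv", "series_matrix"),
                         scale_input = c("log2", "linear"),
                         p_cut = 0.05, fc_cut = NULL, score_threshold = 1,
                         c_grid = default_c_grid(),
                         gamma_grid = default_gamma_grid(),
                         scale_features = TRUE) {
  format <- match.arg(format)
  scale_input <- match.arg(scale_input)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, fun) {
    tryCatch(fun, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  expr <- stage("read expression", {
    if (format == "series_matrix") read_series_matrix(expression)$expr
    else read_expression_tsv(expression)
  })
  ann <- stage("read annotation", utils::read.delim(annotation,
                                                    stringsAsFactors = FALSE))
  pathways <- stage("read GMT", read_gmt(gmt))
  sheet <- stage("read sample sheet", read_sample_sheet(samples))
  note("input: ", nrow(expr), " probesets x ", ncol(expr), " samples; ",
       length(pathways), " pathways")

  excluded <- character(0)
  if (!is.null(clinical)) {
    clin <- stage("read clinical", utils::read.delim(clinical,
                                                     stringsAsFactors = FALSE))
    dich <- stage("dichotomize survival",
                  dichotomize_survival(clin, milestone_days,
                                       positive_class = positive_class))
    labels_all <- dich$labels
    excluded <- dich$excluded
    note("milestone dichotomization at ", milestone_days, " days: ",
         sum(labels_all$class == "positive"), " positive, ",
         sum(labels_all$class == "negative"), " negative, ",
         length(excluded), " excluded")
  } else {
    if (!"class" %in% names(sheet)) {
      stop("sample sheet needs a class column when no clinical table is given")
    }
    labels_all <- sample_labels(sheet$sample_id, sheet$class,
                                positive_class = positive_class)
  }
  sheet <- sheet[sheet$sample_id %in% labels_all$sample_id, , drop = FALSE]
  split_labels <- function(which_set) {
    ids <- sheet$sample_id[sheet$set == which_set]
    idx <- labels_all$sample_id %in% ids
    sample_labels(labels_all$sample_id[idx],
                  as.character(labels_all$class[idx]))
  }
  train_labels <- stage("split train labels", split_labels("train"))
  test_labels <- stage("split test labels", split_labels("test"))
  note("samples: ", nrow(train_labels), " train, ", nrow(test_labels),
       " test")

  collapsed <- stage("collapse probesets", suppressWarnings(
    collapse_probesets(expr[, labels_all$sample_id, drop = FALSE],
                       ann, train_labels, scale = scale_input)))
  gene_expr <- collapsed$expr
  note("collapsed ", nrow(expr), " probesets -> ", nrow(gene_expr),
       " genes (", collapsed$n_unannotated, " unannotated dropped)")

  train_expr <- gene_expr[, train_labels$sample_id, drop = FALSE]
  test_expr <- gene_expr[, test_labels$sample_id, drop = FALSE]

  stats_tab <- stage("differential expression",
                     deg_stats(train_expr, train_labels, scale = scale_input))
  degs <- stage("select DEGs", select_degs(stats_tab, p_cut, fc_cut))
  note("DEG selection (p < ", p_cut,
       if (!is.null(fc_cut)) paste0(", FC > ", fc_cut, " or < ",
                                    round(1 / fc_cut, 3)),
       "): ", nrow(degs), " of ", nrow(stats_tab), " genes")

  net <- stage("build bipartite network",
               build_bipartite_network(degs$gene, pathways))
  scores <- stage("score genes", gene_scores(net))
  signature <- stage("filter signature",
                     filter_signature(scores, score_threshold))
  note("bipartite scoring: ", sum(net$gene_degree > 0),
       " DEGs connected to pathways; signature (score >= ",
       score_threshold, "): ", length(signature), " genes")
  if (length(signature) == 0L) {
    stop("pipeline stage 'filter signature' failed: empty signature",
         call. = FALSE)
  }

  report <- stage("original/swap analysis", run_original_and_swap(
    list(expr = train_expr, labels = train_labels),
    list(expr = test_expr, labels = test_labels),
    signature, c_grid = c_grid, gamma_grid = gamma_grid,
    scale = scale_features))
  note("original arm: cost=", report$original$spec$cost,
       " gamma=", report$original$spec$gamma,
       "; swap arm: cost=", report$swap$spec$cost,
       " gamma=", report$swap$spec$gamma)

  # outputs
  out <- function(f) file.path(output_dir, f)
  utils::write.table(stats_tab, out("deg_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(scores), out("gene_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(signature, out("signature.txt"))
  export_edge_list(net, scores, out("edge_list.tsv"))
  write_metrics_tsv(report, out("metrics.tsv"))
  jsonlite::write_json(
    list(original = report$original$spec[c("cost", "gamma", "accuracy", "mcc")],
         swap = report$swap$spec[c("cost", "gamma", "accuracy", "mcc")]),
    out("model_specs.json"), auto_unbox = TRUE, digits = NA)
  counts <- c(probesets = nrow(expr), genes = nrow(gene_expr),
              degs = nrow(degs), signature = length(signature))
  note("stage counts: ", paste(names(counts), counts, sep = "=",
                               collapse = ", "))
  writeLines(log_lines, out("pipeline_log.txt"))
  invisible(list(report = report, signature = signature, scores = scores,
                 degs = degs, counts = counts, excluded = excluded))
}

#' Write an analysis report as a metrics TSV
#'
#' One row per arm x phase (original/swap x training/validation) with the
#' confusion counts, SP, SE, ACC, MCC and AUC, plus the arm's (cost, gamma).
#'
#' @param report an `analysis_report` from [run_original_and_swap].
#' @param path output path.
#' @return Invisibly, the data frame written.
#' @export
write_metrics_tsv <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  rows <- list()
  for (arm in c("original", "swap")) {
    for (phase in c("training", "validation")) {
      m <- report[[arm]][[phase]]
      rows[[paste(arm, phase)]] <- data.frame(
        analysis = arm, phase = phase,
        TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
        SP = round(m$specificity, 6), SE = round(m$sensitivity, 6),
        ACC = round(m$accuracy, 6), MCC = round(m$mcc, 6),
        AUC = round(m$auc, 6),
        cost = report[[arm]]$spec$cost, gamma = report[[arm]]$spec$gamma,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
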