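#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic two-class microarray
#' study. The defaults emulate a modest clinical cohort profiled on an
#' Affymetrix-style platform: 2000 genes measured by 2 probesets each,
#' 60 samples per phenotype class, log2 intensities around 7 with per-probe
#' Gaussian noise of 0.5, 10% of genes differential with a mean log2 shift of
#' 2, and 20 pathways of 29-150 members drawn entirely from the planted
#' differential genes so that pathway connectivity carries real signal.
#' Survival follows an exponential model whose hazard is several-fold higher
#' in the positive (high-risk) class, with independent exponential censoring.
#'
#' @param n_genes number of genes.
#' @param n_probes_per_gene probesets per gene (fixed integer).
#' @param n_samples_per_class samples in each phenotype class.
#' @param frac_de fraction of genes planted as differential.
#' @param effect_size mean absolute log2 shift of differential genes in the
#'   positive class (sign random per gene).
#' @param noise_sd per-probe Gaussian noise standard deviation (log2 units).
#' @param probe_offset_sd standard deviation of the fixed per-probe additive
#'   offset (log2 units), emulating probe affinity differences.
#' @param n_pathways number of synthetic gene sets.
#' @param pathway_size_range integer range (min, max) of set sizes.
#' @param frac_de_in_pathways fraction of each set's members drawn from the
#'   planted differential genes; the rest come from non-differential genes.
#' @param baseline_scale mean survival (days) of the negative class.
#' @param hazard_multiplier hazard ratio of the positive class.
#' @param censoring_rate rate (1/days) of the independent exponential
#'   censoring process.
#' @param seed mandatory integer seed; every simulation is deterministic
#'   given the config.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_probes_per_gene = 2,
                       n_samples_per_class = 60,
                       frac_de = 0.1,
                       effect_size = 2,
                       noise_sd = 0.5,
                       probe_offset_sd = 0.3,
                       n_pathways = 20,
                       pathway_size_range = c(29, 150),
                       frac_de_in_pathways = 1,
                       baseline_scale = 600,
                       hazard_multiplier = 6,
                       censoring_rate = 1 / 2000,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_genes = as.integer(n_genes),
              n_probes_per_gene = as.integer(n_probes_per_gene),
              n_samples_per_class = as.integer(n_samples_per_class),
              frac_de = frac_de, effect_size = effect_size,
              noise_sd = noise_sd, probe_offset_sd = probe_offset_sd,
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              frac_de_in_pathways = frac_de_in_pathways,
              baseline_scale = baseline_scale,
              hazard_multiplier = hazard_multiplier,
              censoring_rate = censoring_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes > 0, cfg$n_probes_per_gene > 0,
            cfg$n_samples_per_class > 1, cfg$n_pathways > 0,
            cfg$frac_de >= 0, cfg$frac_de <= 1,
            cfg$frac_de_in_pathways >= 0, cfg$frac_de_in_pathways <= 1,
            cfg$effect_size >= 0, cfg$noise_sd > 0,
            cfg$probe_offset_sd >= 0,
            length(cfg$pathway_size_range) == 2L,
            cfg$pathway_size_range[1L] > 0,
            cfg$pathway_size_range[1L] <= cfg$pathway_size_range[2L],
            cfg$baseline_scale > 0, cfg$hazard_multiplier > 0,
            cfg$censoring_rate >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate probeset-level two-class expression
#'
#' Draws one log2 baseline per gene (N(7, 1.5)); planted differential genes
#' are shifted by +/- `effect_size` in the positive class; each probeset adds
#' a fixed offset (N(0, `probe_offset_sd`)) plus independent per-sample noise
#' (N(0, `noise_sd`)). Sample ids are `S001..`; probeset ids are
#' `G0001_P1..`; gene symbols are `G0001..`. Deterministic per seed.
#'
#' @param config a [sim_config].
#' @return List with `expr` (probeset x sample matrix), `annotation`
#'   (data frame `probeset_id`, `symbol`), `labels` (a [sample_labels]) and
#'   `truth` (list: `de_genes`, `effects` named vector, `probe_map`,
#'   `classes` named vector).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  np <- config$n_probes_per_gene
  ns <- config$n_samples_per_class
  genes <- sprintf("G%0*d", max(4L, nchar(ng)), seq_len(ng))
  samples <- sprintf("S%03d", seq_len(2L * ns))
  classes <- stats::setNames(rep(c("positive", "negative"), each = ns),
                             samples)

  n_de <- round(config$frac_de * ng)
  de_genes <- if (n_de > 0) sort(sample(genes, n_de)) else character(0)
  effects <- stats::setNames(numeric(ng), genes)
  if (n_de > 0) {
    effects[de_genes] <- sample(c(-1, 1), n_de, replace = TRUE) *
      config$effect_size
  }
  baseline <- stats::setNames(stats::rnorm(ng, mean = 7, sd = 1.5), genes)

  # gene value per sample: baseline + class shift for DE genes
  gene_mat <- matrix(baseline, nrow = ng, ncol = 2L * ns,
                     dimnames = list(genes, samples))
  gene_mat[, classes == "positive"] <-
    gene_mat[, classes == "positive"] + effects

  probe_ids <- as.vector(t(outer(genes, seq_len(np),
                                 function(g, k) paste0(g, "_P", k))))
  probe_gene <- rep(genes, each = np)
  probe_offset <- stats::rnorm(length(probe_ids), 0, config$probe_offset_sd)
  expr <- gene_mat[probe_gene, , drop = FALSE] + probe_offset +
    matrix(stats::rnorm(length(probe_ids) * 2L * ns, 0, config$noise_sd),
           nrow = length(probe_ids))
  rownames(expr) <- probe_ids

  list(expr = expr,
       annotation = data.frame(probeset_id = probe_ids, symbol = probe_gene,
                               stringsAsFactors = FALSE),
       labels = sample_labels(samples, unname(classes)),
       truth = list(de_genes = de_genes, effects = effects,
                    probe_map = stats::setNames(probe_gene, probe_ids),
                    classes = classes))
}

#' Simulate a pathway collection enriched for planted genes
#'
#' Builds `n_pathways` gene sets with sizes uniform in `pathway_size_range`.
#' A fraction `frac_de_in_pathways` of each set's members is sampled from the
#' planted differential genes and the remainder from non-differential genes;
#' sets may overlap. Uses a seed offset from the config seed so expression
#' and pathways can be generated in either order.
#'
#' @param config a [sim_config].
#' @param truth the `truth` element of [simulate_expression].
#' @return A [pathway_collection]; the set of planted differential genes that
#'   are members of at least one pathway is attached as attribute
#'   `pathway_member_de_genes`.
#' @export
simulate_pathways <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  de_pool <- truth$de_genes
  all_genes <- names(truth$effects)
  non_de_pool <- setdiff(all_genes, de_pool)
  sizes <- sample(seq(config$pathway_size_range[1L],
                      config$pathway_size_range[2L]),
                  config$n_pathways, replace = TRUE)
  members <- vector("list", config$n_pathways)
  for (k in seq_len(config$n_pathways)) {
    n_de <- round(config$frac_de_in_pathways * sizes[k])
    n_other <- sizes[k] - n_de
    if (n_de > length(de_pool) || n_other > length(non_de_pool)) {
      stop("pathway size ", sizes[k], " exceeds available gene pools (",
           length(de_pool), " DE, ", length(non_de_pool), " non-DE)")
    }
    members[[k]] <- c(if (n_de > 0) sample(de_pool, n_de),
                      if (n_other > 0) sample(non_de_pool, n_other))
  }
  pc <- pathway_collection(sprintf("SP%02d", seq_len(config$n_pathways)),
                           sprintf("synthetic pathway %d",
                                   seq_len(config$n_pathways)),
                           members)
  attr(pc, "pathway_member_de_genes") <-
    sort(intersect(de_pool, unique(unlist(members))))
  pc
}

#' Simulate censored survival times
#'
#' Event times are exponential with mean `baseline_scale` days in the
#' negative class and hazard `hazard_multiplier`-fold higher in the positive
#' class; an independent exponential censoring process at `censoring_rate`
#' truncates observation. Seed offset by 2 from the config seed.
#'
#' @param config a [sim_config].
#' @param truth the `truth` element of [simulate_expression].
#' @return Data frame with columns `sample_id`, `time_days`, `event`
#'   (1 = death observed, 0 = censored).
#' @export
simulate_clinical_survival <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  classes <- truth$classes
  n <- length(classes)
  hazard <- ifelse(classes == "positive",
                   config$hazard_multiplier / config$baseline_scale,
                   1 / config$baseline_scale)
  death <- stats::rexp(n, rate = hazard)
  censor <- if (config$censoring_rate > 0) {
    stats::rexp(n, rate = config$censoring_rate)
  } else {
    rep(Inf, n)
  }
  data.frame(sample_id = names(classes),
             time_days = round(pmin(death, censor), 1),
             event = as.integer(death <= censor),
             stringsAsFactors = FALSE)
}

#' Write a complete synthetic study to disk
#'
#' Generates a full fixture — probeset expression TSV, probeset annotation
#' TSV, pathway GMT, clinical survival TSV, a sample sheet with a
#' deterministic half/half train/test split within each class, and a ground
#' truth JSON — exercising every pipeline stage without any download.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param config optional [sim_config]; defaults to `sim_config(seed = seed)`.
#' @return Invisibly, a named list of the written file paths plus the
#'   in-memory `truth`.
#' @export
end_to_end_fixture <- function(dir, seed, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  pc <- simulate_pathways(config, sim$truth)
  clinical <- simulate_clinical_survival(config, sim$truth)

  # deterministic split: odd positions train, even positions test, per class
  cls <- sim$truth$classes
  samples <- names(cls)
  setcol <- character(length(samples))
  for (cl in c("positive", "negative")) {
    idx <- which(cls == cl)
    setcol[idx] <- rep(c("train", "test"), length.out = length(idx))
  }
  sheet <- data.frame(sample_id = samples, class = unname(cls),
                      set = setcol, stringsAsFactors = FALSE)

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    clinical = file.path(dir, "clinical.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(sim$expr, paths$expression)
  utils::write.table(sim$annotation, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(pc, paths$gmt)
  utils::write.table(clinical, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sheet, paths$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_out <- list(
    seed = config$seed,
    de_genes = sim$truth$de_genes,
    pathway_member_de_genes = attr(pc, "pathway_member_de_genes"),
    effects = as.list(sim$truth$effects[sim$truth$de_genes]),
    classes = as.list(sim$truth$classes)
  )
  jsonlite::write_json(truth_out, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, list(truth = sim$truth, pathways = pc)))
}
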