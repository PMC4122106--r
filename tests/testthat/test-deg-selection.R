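test_that("pooled t-test matches the classical hand computation and t.test", {
  mat <- two_group_matrix(list(g1 = c(1, 2, 3, 4, 5, 6)))
  labels <- small_labels(3, 3)
  res <- two_sample_t(mat, labels)
  # pooled sd = 1, se = sqrt(2/3): t = -3/0.8165 = -3.6742, df = 4
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-6)
  expect_equal(res$p, ref$p.value, tolerance = 1e-6)
})

test_that("row-wise t and p agree with t.test across random rows", {
  set.seed(11)
  n1 <- 5; n2 <- 7
  mat <- matrix(rnorm(40 * (n1 + n2)), nrow = 40,
                dimnames = list(sprintf("g%d", 1:40),
                                sprintf("S%d", 1:(n1 + n2))))
  labels <- small_labels(n1, n2)
  res <- two_sample_t(mat, labels)
  for (i in c(1, 7, 23, 40)) {
    ref <- t.test(mat[i, 1:n1], mat[i, (n1 + 1):(n1 + n2)],
                  var.equal = TRUE)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }
  # Welch variant matches Welch t.test
  resw <- two_sample_t(mat, labels, welch = TRUE)
  refw <- t.test(mat[3, 1:n1], mat[3, (n1 + 1):(n1 + n2)])
  expect_equal(resw$t[3], unname(refw$statistic), tolerance = 1e-10)
  expect_equal(resw$p[3], refw$p.value, tolerance = 1e-10)
})

test_that("t-test degenerate rows follow the stated conventions", {
  mat <- two_group_matrix(list(flat = c(2, 2, 2, 2, 2, 2),
                               split = c(1, 1, 1, 2, 2, 2)))
  labels <- small_labels(3, 3)
  expect_warning(res <- two_sample_t(mat, labels), "zero pooled variance")
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$p[2], 0)
  expect_true(is.infinite(res$t[2]))
})

test_that("t-test invariances: shift, sample order, label swap", {
  set.seed(12)
  mat <- matrix(rnorm(10 * 9), nrow = 10,
                dimnames = list(sprintf("g%d", 1:10), sprintf("S%d", 1:9)))
  labels <- small_labels(4, 5)
  base <- two_sample_t(mat, labels)
  shifted <- two_sample_t(mat + 100, labels)
  expect_equal(base$t, shifted$t, tolerance = 1e-9)

  perm <- sample(colnames(mat))
  reordered <- two_sample_t(mat[, perm], labels)
  expect_equal(base$t, reordered$t, tolerance = 1e-12)

  swapped_labels <- sample_labels(labels$sample_id,
                                  ifelse(labels$class == "positive",
                                         "negative", "positive"))
  swapped <- two_sample_t(mat, swapped_labels)
  expect_equal(base$t, -swapped$t, tolerance = 1e-12)
  expect_equal(base$p, swapped$p, tolerance = 1e-12)
})

test_that("fold changes follow the scale conventions", {
  mat <- two_group_matrix(list(up = c(3, 3, 3, 2, 2, 2),
                               flat = c(5, 5, 5, 5, 5, 5),
                               down = c(1, 1, 1, 1.585, 1.585, 1.585)))
  labels <- small_labels(3, 3)
  fc <- fold_changes(mat, labels)
  expect_equal(fc$fold_change[1], 2)
  expect_equal(fc$log2_fc[1], 1)
  expect_equal(fc$fold_change[2], 1)
  expect_equal(fc$log2_fc[2], 0)
  expect_equal(fc$fold_change[3], 2^(-0.585), tolerance = 1e-9)
  expect_lt(fc$fold_change[3], 1.5)  # sits inside the excluded FC band
  expect_equal(log2(fc$fold_change), fc$log2_fc, tolerance = 1e-9)

  # linear scale: ratio of group means; non-positive mean is an error
  lin <- fold_changes(two_group_matrix(list(g = c(4, 4, 2, 2))),
                      small_labels(2, 2), scale = "linear")
  expect_equal(lin$fold_change, 2)
  expect_error(
    fold_changes(two_group_matrix(list(bad = c(1, 1, -2, 0))),
                 small_labels(2, 2), scale = "linear"),
    "non-positive.*bad")
})

test_that("label swap inverts fold change", {
  set.seed(13)
  mat <- matrix(rnorm(8 * 8, 6), nrow = 8,
                dimnames = list(sprintf("g%d", 1:8), sprintf("S%d", 1:8)))
  labels <- small_labels(4, 4)
  swapped <- sample_labels(labels$sample_id,
                           ifelse(labels$class == "positive",
                                  "negative", "positive"))
  a <- fold_changes(mat, labels)
  b <- fold_changes(mat, swapped)
  expect_equal(a$fold_change, 1 / b$fold_change, tolerance = 1e-12)
  expect_equal(a$log2_fc, -b$log2_fc, tolerance = 1e-12)
})

test_that("probeset collapse keeps the highest |log2FC| probeset per gene", {
  # gene X measured by two probesets: weak (0.2) and strong (0.9) shifts
  mat <- two_group_matrix(list(
    ps_a = c(7.2, 7.2, 7.2, 7.0, 7.0, 7.0),   # |lfc| = 0.2
    ps_b = c(7.9, 7.9, 7.9, 7.0, 7.0, 7.0),   # |lfc| = 0.9
    ps_c = c(5.0, 5.0, 5.0, 5.8, 5.8, 5.8)))  # gene Y, single probeset
  ann <- data.frame(probeset_id = c("ps_a", "ps_b", "ps_c"),
                    symbol = c("X", "X", "Y"))
  labels <- small_labels(3, 3)
  out <- collapse_probesets(mat, ann, labels)
  expect_equal(sort(rownames(out$expr)), c("X", "Y"))
  expect_equal(out$report$probeset[out$report$gene == "X"], "ps_b")
  expect_equal(out$report$probeset[out$report$gene == "Y"], "ps_c")
  expect_equal(out$n_unannotated, 0)
  expect_equal(unname(out$expr["X", ]), unname(mat["ps_b", ]))

  # tie on |log2FC| -> lexicographically smallest probeset id
  mat2 <- two_group_matrix(list(ps_2 = c(3, 3, 2, 2),
                                ps_1 = c(5, 5, 4, 4)))
  ann2 <- data.frame(probeset_id = c("ps_2", "ps_1"),
                     symbol = c("Z", "Z"))
  out2 <- collapse_probesets(mat2, ann2, small_labels(2, 2))
  expect_equal(out2$report$probeset, "ps_1")

  # unannotated probesets counted, labels mandatory
  ann3 <- data.frame(probeset_id = "ps_a", symbol = "X")
  out3 <- collapse_probesets(mat, ann3, labels)
  expect_equal(out3$n_unannotated, 2)
  expect_error(collapse_probesets(mat, ann, NULL), "labels are required")
})

test_that("collapse yields one row per annotated symbol with maximal |lfc|", {
  set.seed(14)
  sim <- simulate_expression(sim_config(n_genes = 40, n_probes_per_gene = 3,
                                        n_samples_per_class = 5, seed = 14))
  out <- collapse_probesets(sim$expr, sim$annotation, sim$labels)
  expect_equal(nrow(out$expr), 40)
  expect_false(anyDuplicated(rownames(out$expr)) > 0)
  fc_all <- fold_changes(sim$expr, sim$labels)
  lfc <- setNames(abs(fc_all$log2_fc), fc_all$id)
  for (g in sample(rownames(out$expr), 5)) {
    probes <- sim$annotation$probeset_id[sim$annotation$symbol == g]
    chosen <- out$report$probeset[out$report$gene == g]
    expect_equal(unname(lfc[chosen]), max(lfc[probes]))
  }
})

test_that("DEG selection applies strict cuts and is idempotent", {
  tab <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    t = 0, p = c(0.04, 0.04, 0.051, 0.04, 0.049),
    fold_change = c(1.6, 1.5, 2.0, 0.5, 0.667),
    log2_fc = 0)
  kept <- select_degs(tab, 0.05, 1.5)
  # B fails FC == 1.5 exactly (strict), C fails p, E fails FC == 0.667 band
  expect_equal(sort(kept$gene), c("A", "D"))
  expect_identical(select_degs(kept, 0.05, 1.5)$gene, kept$gene)
  # p-only mode keeps everything under 0.05
  expect_equal(sort(select_degs(tab, 0.05)$gene), c("A", "B", "D", "E"))
  # ordering: ascending p, then symbol
  expect_equal(select_degs(tab, 0.05)$gene, c("A", "B", "D", "E"))
  expect_warning(empty <- select_degs(tab, 1e-6), "no gene passes")
  expect_equal(nrow(empty), 0)
  expect_error(select_degs(tab, 0.05, 1), "fc_cut")
  expect_error(select_degs(tab, 1.2), "p_cut")
})

test_that("survival milestone dichotomization partitions patients", {
  clin <- data.frame(
    sample_id = sprintf("P%d", 1:8),
    time_days = c(200, 400, 100, 365, 50, 800, 20, 364),
    event = c(1, 0, 0, 0, 1, 1, 1, 0))
  out <- dichotomize_survival(clin, 365)
  lab <- setNames(as.character(out$labels$class), out$labels$sample_id)
  expect_equal(unname(lab["P1"]), "positive")   # died before milestone
  expect_equal(unname(lab["P2"]), "negative")   # survived past, censored
  expect_false("P3" %in% names(lab))            # censored early -> excluded
  expect_equal(unname(lab["P4"]), "negative")   # exactly 365: low-risk
  expect_equal(sort(out$excluded), c("P3", "P8"))
  # partition: every patient in exactly one bucket
  expect_equal(sort(c(names(lab), out$excluded)), sort(clin$sample_id))
  expect_equal(attr(out$labels, "positive_class"), "high-risk")
  expect_error(dichotomize_survival(
    data.frame(sample_id = "a", time_days = -1, event = 1)), "negative")
})
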