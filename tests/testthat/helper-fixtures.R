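# Shared fixtures, all built in code.

# the 3-gene/2-pathway worked example: A in both pathways, B and C in one each
toy_collection <- function() {
  pathway_collection(c("P1", "P2"), c("pathway one", "pathway two"),
                     list(c("A", "B"), c("A", "C")))
}

toy_network <- function() {
  build_bipartite_network(c("A", "B", "C"), toy_collection())
}

# random bipartite network over n genes and m pathways with edge density p;
# guaranteed valid (may contain degree-0 genes and pathways on purpose)
random_network <- function(n, m, density = 0.2) {
  genes <- sprintf("G%03d", seq_len(n))
  members <- lapply(seq_len(m), function(l) {
    mem <- genes[stats::runif(n) < density]
    if (length(mem) == 0L) mem <- sample(genes, 1L)
    mem
  })
  pc <- pathway_collection(sprintf("P%02d", seq_len(m)),
                           sprintf("pw %d", seq_len(m)), members)
  build_bipartite_network(genes, pc)
}

# two well-separated Gaussian clouds: 2*n samples x p features
separable_features <- function(n = 10, p = 3, delta = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p, 0, 1), n, p),
             matrix(rnorm(n * p, delta, 1), n, p))
  rownames(x) <- sprintf("S%02d", seq_len(2 * n))
  colnames(x) <- sprintf("F%d", seq_len(p))
  list(x = x, y = rep(c("negative", "positive"), each = n))
}

# small expression matrix with explicit group means for hand checks
two_group_matrix <- function(rows) {
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(rows)
  colnames(mat) <- sprintf("S%d", seq_len(ncol(mat)))
  mat
}

small_labels <- function(n_pos, n_neg) {
  sample_labels(sprintf("S%d", seq_len(n_pos + n_neg)),
                rep(c("positive", "negative"), c(n_pos, n_neg)))
}
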