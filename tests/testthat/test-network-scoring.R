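test_that("toy network degrees, weights and scores match hand computation", {
  net <- toy_network()
  expect_equal(unname(net$gene_degree), c(2, 1, 1))
  expect_equal(unname(net$pathway_degree), c(2, 2))

  # A spreads 1/2 to each pathway, B and C spread 1 each: w = (1.5, 1.5)
  expect_equal(unname(pathway_weights(net)), c(1.5, 1.5))

  # each pathway returns w/2 per member: s_A = 1.5, s_B = s_C = 0.75
  sc <- gene_scores(net)
  expect_equal(sc$gene, c("A", "B", "C"))
  expect_equal(sc$score, c(1.5, 0.75, 0.75))
  expect_equal(sc$rank, 1:3)
  expect_equal(filter_signature(sc, 1), "A")
})

test_that("singleton and disjoint networks behave at the boundaries", {
  pc1 <- pathway_collection("P1", "only", list("A"))
  net1 <- build_bipartite_network("A", pc1)
  expect_equal(unname(net1$adjacency), matrix(1L, 1, 1))
  expect_equal(unname(pathway_weights(net1)), 1)
  expect_equal(gene_scores(net1)$score, 1)           # kept at threshold 1
  expect_equal(unname(projection_matrix(net1)), matrix(1, 1, 1))

  # no overlap at all: adjacency zero, pathway degree 0, weight 0, scores 0
  pc2 <- pathway_collection("P1", "only", list("C"))
  net2 <- build_bipartite_network(c("A", "B"), pc2)
  expect_true(all(net2$adjacency == 0L))
  expect_equal(unname(net2$pathway_degree), 0)
  expect_equal(unname(pathway_weights(net2)), 0)
  expect_equal(gene_scores(net2)$score, c(0, 0))
  expect_equal(unname(score_via_projection(net2)$score), c(0, 0))
})

test_that("n genes sharing one exclusive pathway all score s0", {
  n <- 7
  genes <- sprintf("G%d", seq_len(n))
  pc <- pathway_collection("P1", "shared", list(genes))
  net <- build_bipartite_network(genes, pc)
  expect_equal(unname(pathway_weights(net)), n)  # every gene spreads 1
  expect_equal(gene_scores(net)$score, rep(1, n))
  expect_equal(sort(filter_signature(gene_scores(net), 1)), sort(genes))
})

test_that("construction rejects bad input", {
  expect_error(build_bipartite_network(c("A", "a", "B"), toy_collection()),
               "duplicate gene symbols.*A")
  expect_error(pathway_collection(character(0), character(0), list()),
               "empty")
  expect_error(pathway_collection(c("P1", "P1"), c("x", "y"),
                                  list("A", "B")), "duplicate pathway ids")
  expect_error(pathway_collection("P1", "x", list(character(0))),
               "empty member sets")
})

test_that("gene symbols are case-normalized when matching pathway members", {
  pc <- pathway_collection("P1", "mixed case", list(c("tp53", "Kras")))
  net <- build_bipartite_network(c("TP53", "KRAS", "egfr"), pc)
  expect_equal(unname(net$gene_degree), c(1, 1, 0))
})

test_that("two-step and projection scores agree on random networks", {
  set.seed(101)
  for (i in 1:30) {
    net <- random_network(sample(5:200, 1), sample(2:30, 1),
                          density = runif(1, 0.02, 0.4))
    s0 <- sample(c(1, 1, 2, 0.5), 1)
    two_step <- gene_scores(net, s0)
    direct <- score_via_projection(net, s0)
    expect_equal(two_step$score, direct$score, tolerance = 1e-12)
    expect_identical(two_step$gene, direct$gene)
  }
})

test_that("score mass is conserved and C is column-stochastic", {
  set.seed(202)
  for (i in 1:30) {
    net <- random_network(sample(5:150, 1), sample(2:25, 1),
                          density = runif(1, 0.02, 0.4))
    s0 <- sample(c(1, 3, 0.25), 1)
    sc <- gene_scores(net, s0)
    n_connected <- sum(net$gene_degree > 0)
    expect_equal(sum(sc$score), s0 * n_connected, tolerance = 1e-9)
    expect_true(all(sc$score >= 0))
    expect_true(all(pathway_weights(net, s0) >= 0))

    cmat <- projection_matrix(net)
    expect_true(all(cmat >= 0))
    cs <- colSums(cmat)
    expect_equal(unname(cs[net$gene_degree > 0]),
                 rep(1, n_connected), tolerance = 1e-9)
    expect_true(all(cs[net$gene_degree == 0] == 0))
    expect_true(all(cmat[net$gene_degree == 0, ] == 0))
  }
})

test_that("adding an edge to a fresh pathway never lowers that gene's score", {
  set.seed(303)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    genes <- sprintf("G%02d", seq_len(n))
    base_members <- lapply(1:4, function(l) {
      mem <- genes[runif(n) < 0.3]
      if (!length(mem)) genes[1]
      else mem
    })
    g <- sample(genes, 1)
    pc0 <- pathway_collection(sprintf("P%d", 1:4), sprintf("p%d", 1:4),
                              base_members)
    pc1 <- pathway_collection(sprintf("P%d", 1:5), sprintf("p%d", 1:5),
                              c(base_members, list(g)))
    s_before <- gene_scores(build_bipartite_network(genes, pc0))
    s_after <- gene_scores(build_bipartite_network(genes, pc1))
    before <- s_before$score[s_before$gene == g]
    after <- s_after$score[s_after$gene == g]
    expect_gte(after, before - 1e-12)
  }
})

test_that("relabeling genes permutes scores identically", {
  set.seed(404)
  net_genes <- sprintf("G%02d", 1:20)
  members <- lapply(1:5, function(l) sample(net_genes, sample(3:10, 1)))
  pc <- pathway_collection(sprintf("P%d", 1:5), sprintf("p%d", 1:5), members)
  sc1 <- gene_scores(build_bipartite_network(net_genes, pc))
  perm <- sample(net_genes)
  sc2 <- gene_scores(build_bipartite_network(perm, pc))
  s1 <- setNames(sc1$score, sc1$gene)
  s2 <- setNames(sc2$score, sc2$gene)
  expect_equal(s1[net_genes], s2[net_genes])
})

test_that("filter_signature handles thresholds, ties and emptiness", {
  net <- toy_network()
  sc <- gene_scores(net)
  # inclusive lower bound 0 keeps everything, including degree-0 genes
  pc <- pathway_collection("P1", "x", list("A"))
  net2 <- build_bipartite_network(c("A", "B"), pc)
  expect_equal(sort(filter_signature(gene_scores(net2), 0)), c("A", "B"))
  # ties broken by ascending symbol after descending score
  expect_equal(filter_signature(sc, 0.5), c("A", "B", "C"))
  expect_warning(out <- filter_signature(sc, 99), "empty")
  expect_length(out, 0)
})

test_that("full pathway-degree mode divides by total membership", {
  # pathway P1 has 4 members but only 2 are in the gene list
  pc <- pathway_collection("P1", "big", list(c("A", "B", "X", "Y")))
  net_ind <- build_bipartite_network(c("A", "B"), pc, "induced")
  net_full <- build_bipartite_network(c("A", "B"), pc, "full")
  expect_equal(unname(net_ind$pathway_degree), 2)
  expect_equal(unname(net_full$pathway_degree), 4)
  expect_equal(gene_scores(net_ind)$score, c(1, 1))
  expect_equal(gene_scores(net_full)$score, c(0.5, 0.5))
})

test_that("edge list export round-trips the adjacency", {
  net <- toy_network()
  sc <- gene_scores(net)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(net, sc, path)
  edges <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(edges), 4)  # toy network has 4 edges
  expect_equal(names(edges), c("gene", "pathway_id", "gene_score",
                               "gene_degree", "pathway_degree"))
  # reconstruct adjacency from exported rows
  adj <- matrix(0L, 3, 2, dimnames = dimnames(net$adjacency))
  for (k in seq_len(nrow(edges))) {
    adj[edges$gene[k], edges$pathway_id[k]] <- 1L
  }
  expect_identical(adj, net$adjacency)
  # per-row annotations are consistent
  expect_equal(edges$gene_score[edges$gene == "A"], c(1.5, 1.5))
  expect_equal(edges$gene_degree[edges$gene == "A"], c(2, 2))

  # zero-adjacency network exports a header-only file
  pc0 <- pathway_collection("P1", "x", list("Z"))
  net0 <- build_bipartite_network(c("A", "B"), pc0)
  path0 <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(net0, gene_scores(net0), path0)
  expect_equal(nrow(read.delim(path0)), 0)
})

test_that("the packaged KEGG cancer pathway list is intact", {
  kegg <- kegg_cancer_pathways()
  expect_equal(nrow(kegg), 20)
  expect_true(all(grepl("^hsa052", kegg$pathway_id)))
  expect_equal(range(kegg$n_genes), c(29, 327))
})
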