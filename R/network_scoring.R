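#' Create a pathway collection
#'
#' A pathway collection holds named gene sets (e.g. KEGG pathways). Gene
#' symbols are upper-cased on construction so that membership tests are
#' case-insensitive, which matters when mixing HUGO symbols from annotation
#' tables with symbols from GMT files.
#'
#' @param ids character vector of unique pathway identifiers (e.g.
#'   `"hsa05200"`).
#' @param names character vector of human-readable pathway names, same length
#'   as `ids`.
#' @param members list of character vectors, one per pathway, each giving the
#'   member gene symbols. Empty member sets are rejected.
#' @return An object of class `pathway_collection`: a list with elements
#'   `ids`, `names` and `members` (members upper-cased, de-duplicated).
#' @examples
#' pc <- pathway_collection(c("P1", "P2"), c("one", "two"),
#'                          list(c("A", "B"), c("A", "C")))
#' @export
pathway_collection <- function(ids, names, members) {
  ids <- as.character(ids)
  names <- as.character(names)
  if (length(ids) == 0L) stop("pathway collection is empty")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(names) != length(ids) || length(members) != length(ids)) {
    stop("ids, names and members must have equal length")
  }
  members <- lapply(members, function(m) unique(toupper(as.character(m))))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    stop("pathways with empty member sets: ",
         paste(ids[empty], collapse = ", "))
  }
  structure(list(ids = ids, names = names, members = members),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection with", length(x$ids), "gene sets\n")
  cat("  sizes:", paste(range(lengths(x$members)), collapse = "-"),
      "(min-max)\n")
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$ids)

#' Build a gene-pathway bipartite network
#'
#' Constructs the bipartite network N(G, P, E) over a supplied gene list
#' (typically a DEG list) and a pathway collection. An edge connects gene
#' `g` to pathway `p` when `g` is a member of `p`; edges never connect two
#' genes or two pathways. Pathways with no connected gene are retained with
#' degree zero.
#'
#' Pathway degrees are, by default, counted within the induced subnetwork:
#' only the supplied genes contribute to a pathway's degree, so the scores
#' downstream reflect connectivity among the DEGs themselves. Setting
#' `pathway_degree = "full"` instead uses each pathway's full membership
#' size as its degree, which dilutes the weight returned per member by the
#' pathway's total size.
#'
#' @param genes character vector of gene symbols (case-insensitive, must be
#'   unique after upper-casing).
#' @param pathways a [pathway_collection].
#' @param pathway_degree `"induced"` (default) or `"full"`; see Details.
#' @return An object of class `bipartite_network`: list with `genes`,
#'   `pathways` (ids), `pathway_names`, `adjacency` (n genes x m pathways
#'   0/1 matrix), `gene_degree`, `pathway_degree`.
#' @examples
#' pc <- pathway_collection(c("P1", "P2"), c("one", "two"),
#'                          list(c("A", "B"), c("A", "C")))
#' net <- build_bipartite_network(c("A", "B", "C"), pc)
#' net$gene_degree   # A:2, B:1, C:1
#' @export
build_bipartite_network <- function(genes, pathways,
                                    pathway_degree = c("induced", "full")) {
  pathway_degree <- match.arg(pathway_degree)
  if (!inherits(pathways, "pathway_collection")) {
    stop("`pathways` must be a pathway_collection")
  }
  genes <- toupper(as.character(genes))
  if (length(genes) == 0L) stop("gene list is empty")
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols after case-normalization: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  n <- length(genes)
  m <- length(pathways$ids)
  adj <- matrix(0L, nrow = n, ncol = m,
                dimnames = list(genes, pathways$ids))
  for (l in seq_len(m)) {
    adj[genes %in% pathways$members[[l]], l] <- 1L
  }
  p_deg <- if (pathway_degree == "induced") {
    colSums(adj)
  } else {
    lengths(pathways$members)
  }
  names(p_deg) <- pathways$ids
  structure(list(genes = genes,
                 pathways = pathways$ids,
                 pathway_names = pathways$names,
                 adjacency = adj,
                 gene_degree = rowSums(adj),
                 pathway_degree = p_deg,
                 degree_mode = pathway_degree),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat("bipartite_network:", length(x$genes), "genes x",
      length(x$pathways), "pathways,", sum(x$adjacency), "edges",
      sprintf("(%s pathway degrees)\n", x$degree_mode))
  invisible(x)
}

#' First propagation step: pathway weights
#'
#' Each gene holds an initial score `s0` and spreads it equally over the
#' pathways it belongs to; a pathway's weight is the total it receives,
#' `w_l = sum_j a_jl * s0 / k(g_j)`. Genes of degree zero hold nothing to
#' spread and contribute nothing (no division by zero), so the weights sum
#' to `s0` times the number of connected genes.
#'
#' @param net a [build_bipartite_network] result.
#' @param s0 positive initial score per gene (default 1).
#' @return named numeric vector of pathway weights, length m.
#' @export
pathway_weights <- function(net, s0 = 1) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0) {
    stop("s0 must be a single positive number")
  }
  spread <- ifelse(net$gene_degree > 0, s0 / net$gene_degree, 0)
  w <- as.numeric(crossprod(net$adjacency, spread))
  names(w) <- net$pathways
  w
}

#' Second propagation step: gene scores
#'
#' Each pathway returns its accumulated weight equally to its member genes:
#' `s_i = sum_l a_il * w_l / k(p_l)`. Pathways of degree zero hold no weight
#' and contribute nothing; genes of degree zero receive exactly 0. The total
#' score is conserved: `sum_i s_i = s0 * #{genes with degree >= 1}` (when
#' pathway degrees are induced-subnetwork degrees).
#'
#' @inheritParams pathway_weights
#' @return An object of class `gene_score_table`: a data frame with columns
#'   `gene`, `score`, `rank`, sorted by descending score (ties broken by
#'   ascending symbol); attribute `s0` records the initial score.
#' @examples
#' pc <- pathway_collection(c("P1", "P2"), c("one", "two"),
#'                          list(c("A", "B"), c("A", "C")))
#' net <- build_bipartite_network(c("A", "B", "C"), pc)
#' gene_scores(net)   # A: 1.5, B: 0.75, C: 0.75
#' @export
gene_scores <- function(net, s0 = 1) {
  w <- pathway_weights(net, s0)
  ret <- ifelse(net$pathway_degree > 0, w / net$pathway_degree, 0)
  s <- as.numeric(net$adjacency %*% ret)
  new_gene_score_table(net$genes, s, s0)
}

new_gene_score_table <- function(genes, scores, s0) {
  ord <- order(-scores, genes)
  tab <- data.frame(gene = genes[ord],
                    score = scores[ord],
                    rank = seq_along(genes),
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(tab, s0 = s0, class = c("gene_score_table", "data.frame"))
}

#' Weighted one-mode projection matrix
#'
#' The two propagation steps compose into a single linear map on the gene
#' side: `c_ij = (1 / k(g_j)) * sum_l a_il * a_jl / k(p_l)`. Over connected
#' genes the matrix is column-stochastic (each column sums to 1); rows and
#' columns of degree-zero genes are zero, as are contributions through
#' degree-zero pathways.
#'
#' @inheritParams pathway_weights
#' @return n x n numeric matrix `C` with genes as dimnames.
#' @export
projection_matrix <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  inv_kp <- ifelse(net$pathway_degree > 0, 1 / net$pathway_degree, 0)
  inv_kg <- ifelse(net$gene_degree > 0, 1 / net$gene_degree, 0)
  a <- net$adjacency
  # C = A diag(1/kp) A^T diag(1/kg)
  cmat <- (a %*% (inv_kp * t(a))) * rep(inv_kg, each = length(net$genes))
  dimnames(cmat) <- list(net$genes, net$genes)
  cmat
}

#' Gene scores through the projection matrix
#'
#' Computes `C %*% (s0 * 1)` directly from [projection_matrix]. Algebraically
#' identical to the two-step [gene_scores]; kept as an independent route so
#' the two can be cross-checked.
#'
#' @inheritParams pathway_weights
#' @return A `gene_score_table` (see [gene_scores]).
#' @export
score_via_projection <- function(net, s0 = 1) {
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0) {
    stop("s0 must be a single positive number")
  }
  cmat <- projection_matrix(net)
  s <- as.numeric(cmat %*% rep(s0, length(net$genes)))
  new_gene_score_table(net$genes, s, s0)
}

#' Filter a signature at a score threshold
#'
#' Keeps the genes whose propagated score reaches the threshold (inclusive,
#' `score >= threshold`), in descending score order with ties broken by
#' ascending symbol. The conventional cutoff is 1: a gene that gets back at
#' least the unit resource it spread is considered well-embedded among the
#' cancer-related pathways.
#'
#' @param scores a `gene_score_table` from [gene_scores] or
#'   [score_via_projection].
#' @param threshold finite numeric cutoff, inclusive (default 1).
#' @return Character vector of gene symbols; empty (with a warning) when no
#'   gene reaches the threshold.
#' @export
filter_signature <- function(scores, threshold = 1) {
  stopifnot(inherits(scores, "gene_score_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    stop("threshold must be a single finite number")
  }
  keep <- scores$gene[scores$score >= threshold]
  if (length(keep) == 0L) {
    warning("no gene reaches score threshold ", threshold,
            "; signature is empty")
  }
  keep
}

#' Export the bipartite network as an edge list
#'
#' Writes one TSV row per edge with columns `gene`, `pathway_id`,
#' `gene_score`, `gene_degree`, `pathway_degree`, suitable for rendering the
#' network in external graph tools.
#'
#' @param net a `bipartite_network`.
#' @param scores the matching `gene_score_table`.
#' @param destination output file path.
#' @return Invisibly, the edge data frame that was written.
#' @export
export_edge_list <- function(net, scores, destination) {
  stopifnot(inherits(net, "bipartite_network"),
            inherits(scores, "gene_score_table"))
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  score_of <- stats::setNames(scores$score, scores$gene)
  edges <- data.frame(
    gene = net$genes[idx[, 1L]],
    pathway_id = net$pathways[idx[, 2L]],
    gene_score = unname(score_of[net$genes[idx[, 1L]]]),
    gene_degree = unname(net$gene_degree[idx[, 1L]]),
    pathway_degree = unname(net$pathway_degree[idx[, 2L]]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene, edges$pathway_id), , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(edges, destination, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write edge list to '", destination, "': ",
         conditionMessage(ok))
  }
  invisible(edges)
}

#' The 20 cancer-related KEGG pathways
#'
#' Returns the identifiers, names and reported gene counts of the 20
#' cancer-related KEGG signaling pathways (hsa05200..hsa05223) used to build
#' the gene-pathway bipartite network: six pan-cancer overview pathways plus
#' fourteen cancer-type-specific ones. Memberships are not shipped (KEGG
#' membership must be supplied by the user as a GMT file); this table is the
#' reference list of which pathways to use.
#'
#' @return Data frame with columns `pathway_id`, `pathway_name`, `n_genes`.
#' @export
kegg_cancer_pathways <- function() {
  path <- system.file("extdata", "kegg_cancer_pathways.tsv",
                      package = "pathsig", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
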