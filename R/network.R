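#' Mutational-similarity network among single-cell clones
#'
#' Joins two clones by an edge when their genetic distance is significantly
#' smaller than expected under the per-locus allele-shuffling null
#' ([randomize_genotypes()]): each clone pair's permutation p-value is the
#' fraction of null distances as small as the observed one, with the null
#' pooled across pairs and randomized matrices (per-locus-normalized
#' distances are exchangeable across pairs under the shuffling null, and
#' pooling gives p-value resolution `1 / (pairs x permutations)`, fine
#' enough for Benjamini-Hochberg correction across pairs). Edges are kept at
#' level `alpha` after BH correction. Node weights record the mean
#' intra-tissue distance of each clone's tissue (used as circle diameters
#' in network renderings); anatomical layout is left to the renderer.
#'
#' @param x A [genotype_matrix()] with `tissue` (and ideally `side`) labels.
#' @param alpha Significance level in (0, 1) after BH correction.
#' @param n_permutations Number of randomized matrices for the null
#'   (a warning is issued below 100).
#' @param seed Integer seed.
#' @return A list of class `similarity_network`:
#'   \describe{
#'     \item{nodes}{Data frame: `clone`, `tissue`, `side`, `weight`.}
#'     \item{edges}{Significant clone pairs: `from`, `to`, `distance`, `p`,
#'       `p_adjusted`.}
#'     \item{pairs}{All pairs with their p-values (for threshold scans).}
#'     \item{alpha, n_permutations}{Settings used.}
#'   }
#' @export
build_similarity_network <- function(x, alpha = 0.05, n_permutations = 200,
                                     seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-value resolution is coarse")
  dm <- distance_matrix(x)
  n <- nrow(dm$d)
  ut <- upper.tri(dm$d)
  obs <- dm$d[ut]
  valid <- !is.na(obs)
  null_pool <- numeric(0)
  for (b in seq_len(n_permutations)) {
    rx <- randomize_genotypes(x, seed = derive_seed(seed, b))
    null_b <- distance_matrix(rx)$d[ut]
    null_pool <- c(null_pool, null_b[!is.na(null_b)])
  }
  if (length(null_pool) == 0 || stats::sd(null_pool) == 0) {
    # degenerate null: no basis for significance, no edges
    p <- ifelse(valid, 1, NA_real_)
  } else {
    sorted_null <- sort(null_pool)
    hits <- findInterval(obs, sorted_null)  # null values <= obs
    p <- ifelse(valid, (1 + hits) / (length(sorted_null) + 1), NA_real_)
  }
  padj <- stats::p.adjust(p, method = "BH")
  idx_i <- row(dm$d)[ut]; idx_j <- col(dm$d)[ut]
  smp <- dm$samples
  pairs <- data.frame(from = smp$clone[idx_i], to = smp$clone[idx_j],
                      distance = obs, p = p, p_adjusted = padj,
                      stringsAsFactors = FALSE)
  edges <- pairs[!is.na(padj) & padj <= alpha, , drop = FALSE]
  rownames(edges) <- NULL

  tissue <- smp$tissue %||% rep(NA_character_, n)
  weight <- rep(NA_real_, n)
  for (tis in unique(tissue[!is.na(tissue)])) {
    member <- which(tissue == tis)
    if (length(member) >= 2) {
      vals <- dm$d[member, member][upper.tri(diag(length(member)))]
      weight[member] <- mean(vals, na.rm = TRUE)
    }
  }
  nodes <- data.frame(clone = smp$clone, tissue = tissue,
                      side = smp$side %||% NA_character_,
                      weight = weight, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, pairs = pairs,
                 alpha = alpha, n_permutations = n_permutations),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("mutational-similarity network: ", nrow(x$nodes), " clones, ",
      nrow(x$edges), " significant edge(s) at BH alpha = ", x$alpha,
      " (", x$n_permutations, " permutations)\n", sep = "")
  invisible(x)
}

# tissue-level edge keys of a network (undirected, sorted labels)
tissue_edge_keys <- function(nw, mapping = NULL) {
  smp <- nw$nodes
  tis <- smp$tissue[match(nw$edges$from, smp$clone)]
  tis2 <- smp$tissue[match(nw$edges$to, smp$clone)]
  if (!is.null(mapping)) {
    tis <- ifelse(tis %in% names(mapping), mapping[tis], tis)
    tis2 <- ifelse(tis2 %in% names(mapping), mapping[tis2], tis2)
  }
  unique(paste(pmin(tis, tis2), pmax(tis, tis2), sep = "--"))
}

#' Conserved tissue-level relationships between two similarity networks
#'
#' Aggregates each network's clone-pair edges to the tissue level and
#' returns the tissue relationships present in both individuals — the
#' conserved (orange-line) relationships of a two-individual comparison.
#'
#' @param nw1,nw2 [build_similarity_network()] results.
#' @param tissue_mapping Optional named character vector translating
#'   `nw2`'s tissue labels into `nw1`'s vocabulary.
#' @return Data frame of conserved tissue pairs: `tissue_a`, `tissue_b`.
#' @export
compare_networks <- function(nw1, nw2, tissue_mapping = NULL) {
  stopifnot(inherits(nw1, "similarity_network"),
            inherits(nw2, "similarity_network"))
  k1 <- tissue_edge_keys(nw1)
  k2 <- tissue_edge_keys(nw2, mapping = tissue_mapping)
  conserved <- intersect(k1, k2)
  if (!length(conserved))
    return(data.frame(tissue_a = character(0), tissue_b = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(conserved, "--", fixed = TRUE)
  data.frame(tissue_a = vapply(parts, `[`, "", 1),
             tissue_b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Export a similarity network as edge list and GraphML
#'
#' @param nw A [build_similarity_network()] result.
#' @param path Output path for the edge-list TSV.
#' @param graphml_path Optional path for a GraphML export.
#' @param conserved Optional data frame from [compare_networks()]; matching
#'   edges are flagged in a `conserved` attribute column.
#' @return `path`, invisibly.
#' @export
write_network <- function(nw, path, graphml_path = NULL, conserved = NULL) {
  stopifnot(inherits(nw, "similarity_network"))
  edges <- nw$edges
  if (!is.null(conserved) && nrow(edges)) {
    smp <- nw$nodes
    key <- paste(pmin(smp$tissue[match(edges$from, smp$clone)],
                      smp$tissue[match(edges$to, smp$clone)]),
                 pmax(smp$tissue[match(edges$from, smp$clone)],
                      smp$tissue[match(edges$to, smp$clone)]), sep = "--")
    ckey <- paste(pmin(conserved$tissue_a, conserved$tissue_b),
                  pmax(conserved$tissue_a, conserved$tissue_b), sep = "--")
    edges$conserved <- key %in% ckey
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nw$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
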