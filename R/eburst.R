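#' Configuration for modified eBURST clustering
#'
#' Clones whose pairwise genetic distance does not exceed `threshold` are
#' linked; clonal complexes are the connected components of the resulting
#' graph. The default threshold of 0.2 corresponds to cells separated by 15
#' divisions at a mutation rate of 0.013 per locus per division
#' (0.013 x 15 = 0.195, rounded to 0.2).
#'
#' @param threshold Distance threshold (>= 0; default 0.2).
#' @param clock A [clock_model()] used to report the division-equivalent of
#'   the threshold (default mu = 0.013).
#' @return An `eburst_config` list.
#' @export
eburst_config <- function(threshold = 0.2, clock = clock_model(0.013)) {
  if (threshold < 0) stop("'threshold' must be >= 0")
  stopifnot(inherits(clock, "clock_model"))
  structure(list(threshold = threshold, clock = clock),
            class = "eburst_config")
}

#' Division-equivalent of the eBURST distance threshold
#'
#' @param config An [eburst_config()].
#' @return The number of cell divisions whose expected distance equals the
#'   threshold (`threshold / mu`).
#' @examples
#' threshold_in_divisions(eburst_config(0.195, clock_model(0.013)))  # 15
#' @export
threshold_in_divisions <- function(config) {
  stopifnot(inherits(config, "eburst_config"))
  config$threshold / config$clock$mu
}

#' Modified eBURST clustering of clones into clonal complexes
#'
#' Links every pair of clones with defined distance `<= threshold`
#' (undefined distances are treated as unlinked) and groups clones into
#' clonal complexes as connected components (single linkage, classical
#' eBURST semantics). The founder of each complex is the member with the
#' largest number of within-threshold links; ties are broken by the
#' smallest mean distance to the other members, then by clone id.
#'
#' @param dm A [distance_matrix()] result.
#' @param config An [eburst_config()].
#' @return A list of class `clonal_complexes`: `complexes` (list, each with
#'   `members`, `founder`, `links` data frame of linked pairs and their
#'   distances, `link_counts`), `singletons` (clone ids), `config`.
#' @export
build_clonal_complexes <- function(dm, config = eburst_config()) {
  stopifnot(inherits(dm, "polyg_dist"))
  D <- dm$d
  n <- nrow(D)
  clones <- rownames(D)
  adj <- !is.na(D) & D <= config$threshold
  diag(adj) <- FALSE
  if (n == 0)
    return(structure(list(complexes = list(), singletons = character(0),
                          config = config), class = "clonal_complexes"))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  complexes <- list()
  singletons <- character(0)
  for (k in seq_len(comp$no)) {
    members <- clones[comp$membership == k]
    if (length(members) == 1) { singletons <- c(singletons, members); next }
    sub <- adj[members, members, drop = FALSE]
    link_counts <- rowSums(sub)
    mean_dist <- vapply(members, function(m)
      mean(D[m, setdiff(members, m)], na.rm = TRUE), numeric(1))
    ord <- order(-link_counts, mean_dist, members)
    founder <- members[ord[1]]
    pairs <- which(sub & upper.tri(sub), arr.ind = TRUE)
    links <- data.frame(from = members[pairs[, 1]], to = members[pairs[, 2]],
                        distance = D[cbind(members[pairs[, 1]],
                                           members[pairs[, 2]])],
                        stringsAsFactors = FALSE)
    complexes[[length(complexes) + 1]] <-
      list(members = members, founder = founder, links = links,
           link_counts = link_counts)
  }
  structure(list(complexes = complexes, singletons = singletons,
                 config = config), class = "clonal_complexes")
}

#' @export
print.clonal_complexes <- function(x, ...) {
  sizes <- vapply(x$complexes, function(cc) length(cc$members), integer(1))
  cat("modified eBURST at threshold ", x$config$threshold,
      " (", round(threshold_in_divisions(x$config), 1),
      " division-equivalents at mu = ", x$config$clock$mu, ")\n", sep = "")
  cat(length(x$complexes), " clonal complex(es)",
      if (length(sizes)) paste0(" of sizes ",
                                paste(sort(sizes, decreasing = TRUE),
                                      collapse = ", ")),
      "; ", length(x$singletons), " singleton(s)\n", sep = "")
  invisible(x)
}

#' Links joining clones from different tissues or body sides
#'
#' Enumerates the within-complex links that connect clones with different
#' tissue labels or opposite sides — the signal used to flag candidate cell
#' migration between spatially separated tissues.
#'
#' @param complexes A [build_clonal_complexes()] result.
#' @param samples Data frame with `clone`, `tissue`, `side` columns.
#' @return Data frame of links: `from`, `to`, `distance`, `from_tissue`,
#'   `to_tissue`, `from_side`, `to_side`, `cross_tissue`, `cross_side`.
#' @export
cross_tissue_links <- function(complexes, samples) {
  stopifnot(inherits(complexes, "clonal_complexes"))
  links <- do.call(rbind, lapply(complexes$complexes, `[[`, "links"))
  empty <- data.frame(from = character(0), to = character(0),
                      distance = numeric(0), from_tissue = character(0),
                      to_tissue = character(0), from_side = character(0),
                      to_side = character(0), cross_tissue = logical(0),
                      cross_side = logical(0), stringsAsFactors = FALSE)
  if (is.null(links) || nrow(links) == 0) return(empty)
  idx_f <- match(links$from, samples$clone)
  idx_t <- match(links$to, samples$clone)
  links$from_tissue <- samples$tissue[idx_f]
  links$to_tissue <- samples$tissue[idx_t]
  links$from_side <- samples$side[idx_f]
  links$to_side <- samples$side[idx_t]
  links$cross_tissue <- links$from_tissue != links$to_tissue
  links$cross_side <- links$from_side != links$to_side
  out <- links[links$cross_tissue | links$cross_side, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write clonal complexes as TSV tables
#'
#' Emits a membership table (complex id, member, founder flag, link count)
#' and, optionally, a graph edge list for rendering population snapshots.
#'
#' @param x A [build_clonal_complexes()] result.
#' @param path Output path for the membership TSV.
#' @param edges_path Optional path for the edge-list TSV.
#' @return `path`, invisibly.
#' @export
write_clonal_complexes <- function(x, path, edges_path = NULL) {
  stopifnot(inherits(x, "clonal_complexes"))
  rows <- list()
  for (k in seq_along(x$complexes)) {
    cc <- x$complexes[[k]]
    rows[[k]] <- data.frame(complex = k, member = cc$members,
                            founder = cc$members == cc$founder,
                            link_count = as.integer(cc$link_counts),
                            stringsAsFactors = FALSE)
  }
  if (length(x$singletons))
    rows[[length(rows) + 1]] <- data.frame(
      complex = NA_integer_, member = x$singletons, founder = FALSE,
      link_count = 0L, stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex = integer(0), member = character(0),
               founder = logical(0), link_count = integer(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(edges_path)) {
    edges <- do.call(rbind, lapply(x$complexes, `[[`, "links"))
    if (is.null(edges))
      edges <- data.frame(from = character(0), to = character(0),
                          distance = numeric(0))
    utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
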