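#' Run the full phylogenetic fate-mapping analysis
#'
#' One entry point orchestrating the whole pipeline: ingest (or simulate) a
#' genotype matrix, assign parental alleles, estimate the zygote consensus,
#' summarize mutation profiles, compute the genetic distance matrix and
#' tissue-level summaries, cluster clones into eBURST clonal complexes,
#' optionally build the permutation-calibrated similarity network and the
#' tree-shape null comparison, and record a reproducibility manifest.
#'
#' @param genotypes A [genotype_matrix()] (or a path readable by
#'   [read_genotype_table()]). Exactly one of `genotypes` and `sim` must be
#'   given.
#' @param sim A [lineage_config()]; when given, input data are simulated.
#' @param samples Optional sample sheet (path or data frame) when
#'   `genotypes` is a path.
#' @param clock A [clock_model()] for division-equivalent reporting.
#' @param eburst_threshold Distance threshold for clonal complexes.
#' @param alpha BH-corrected significance level for network edges.
#' @param n_permutations Permutations for the network null; `0` skips the
#'   network stage.
#' @param n_randomizations Randomized matrices for the tree-shape null; `0`
#'   skips the tree-shape stage.
#' @param seed Integer seed controlling every stochastic stage.
#' @return An object of class `fatemap`; see [print.fatemap()],
#'   [summary.fatemap()], [plot.fatemap()] and [write_fatemap_report()].
#' @examples
#' fm <- fatemap(sim = lineage_config(n_loci = 30, cells_per_tissue = 4,
#'                                    seed = 2),
#'               n_permutations = 0, n_randomizations = 0)
#' fm
#' @export
fatemap <- function(genotypes = NULL, sim = NULL, samples = NULL,
                    clock = clock_model(0.013), eburst_threshold = 0.2,
                    alpha = 0.05, n_permutations = 200,
                    n_randomizations = 0, seed = 1L) {
  if (is.null(genotypes) == is.null(sim))
    stop("supply exactly one of 'genotypes' and 'sim'")
  seed <- as.integer(seed)
  simulation <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "lineage_config"))
    simulation <- simulate_lineage(sim)
    gm <- simulation$genotypes
  } else {
    gm <- if (is.character(genotypes))
      read_genotype_table(genotypes, samples = samples) else genotypes
    stopifnot(inherits(gm, "genotype_matrix"))
  }

  gm <- assign_parental_alleles(gm)
  zygote <- consensus_genotype(gm)
  mutations <- identify_somatic_mutations(gm, zygote)
  dm <- distance_matrix(gm)
  zygote_dist <- distance_to_reference(gm, zygote)
  has_labels <- !is.null(gm$samples$tissue) && !is.null(gm$samples$side)
  tissue_summary <- if (has_labels)
    tissue_distance_summary(dm, zygote_distances = zygote_dist) else NULL

  ebc <- eburst_config(eburst_threshold, clock)
  complexes <- build_clonal_complexes(dm, ebc)
  migration <- if (has_labels) cross_tissue_links(complexes, gm$samples)
               else NULL

  network <- if (n_permutations > 0)
    build_similarity_network(gm, alpha = alpha,
                             n_permutations = n_permutations,
                             seed = derive_seed(seed, 1)) else NULL

  shape <- NULL
  if (n_randomizations > 0) {
    tree <- build_distance_tree(dm)
    shape <- shape_null_comparison(tree, gm,
                                   n_randomizations = n_randomizations,
                                   seed = derive_seed(seed, 2))
  }

  settings <- list(clock_mu = clock$mu, eburst_threshold = eburst_threshold,
                   alpha = alpha, n_permutations = n_permutations,
                   n_randomizations = n_randomizations, seed = seed,
                   simulated = !is.null(sim),
                   sim_config = if (!is.null(sim)) unclass(sim) else NULL)
  manifest <- list(
    package = "polygfate",
    version = as.character(utils::packageVersion("polygfate")),
    seed = seed,
    settings_hash = hash_object(settings),
    n_clones = nrow(gm$a1), n_loci = length(gm$loci),
    n_complexes = length(complexes$complexes),
    n_singletons = length(complexes$singletons),
    n_network_edges = if (!is.null(network)) nrow(network$edges) else NA,
    total_mutant_alleles = sum(mutations$per_clone$n_mutant_alleles))

  structure(list(genotypes = gm, zygote = zygote, mutations = mutations,
                 distances = dm, zygote_distances = zygote_dist,
                 tissue_summary = tissue_summary, complexes = complexes,
                 migration_links = migration, network = network,
                 shape = shape, simulation = simulation,
                 settings = settings, manifest = manifest),
            class = "fatemap")
}

# stable md5 of an R object (serialized to a temp file; version pinned)
hash_object <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(obj, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' @describeIn fatemap Compact overview of the analysis.
#' @param x,object A `fatemap` object.
#' @param ... Ignored.
#' @export
print.fatemap <- function(x, ...) {
  cat("polyG phylogenetic fate map\n")
  cat("  clones: ", nrow(x$genotypes$a1), ", loci: ",
      length(x$genotypes$loci),
      if (x$settings$simulated) " (simulated)", "\n", sep = "")
  pc <- x$mutations$per_clone
  cat(sprintf("  mutated markers per cell: %.1f%% (mean), %.2f mutant alleles/locus/cell\n",
              100 * mean(pc$fraction_mutated, na.rm = TRUE),
              x$mutations$mean_mutant_alleles_per_locus_per_cell))
  off <- x$distances$d[upper.tri(x$distances$d)]
  cat(sprintf("  mean pairwise distance: %.3f; mean distance to zygote: %.3f\n",
              mean(off, na.rm = TRUE), mean(x$zygote_distances, na.rm = TRUE)))
  cat("  clonal complexes: ", length(x$complexes$complexes), " (threshold ",
      x$settings$eburst_threshold, "), singletons: ",
      length(x$complexes$singletons), "\n", sep = "")
  if (!is.null(x$network))
    cat("  network edges: ", nrow(x$network$edges), " at BH alpha = ",
        x$network$alpha, "\n", sep = "")
  if (!is.null(x$shape))
    cat(sprintf("  N-bar: observed %.2f vs null %.2f (p_lower %.3g)\n",
                mean(x$shape$observed$nbar), mean(x$shape$null$nbar),
                x$shape$p_lower[["nbar"]]))
  invisible(x)
}

#' @describeIn fatemap Detailed summaries (mutation profile, tissue
#'   distances, complexes, migration links).
#' @export
summary.fatemap <- function(object, ...) {
  print(object)
  if (!is.null(object$tissue_summary)) {
    cat("\ntissue distance summary:\n")
    print(format(as.data.frame(object$tissue_summary), digits = 3))
  }
  if (!is.null(object$migration_links) && nrow(object$migration_links)) {
    cat("\ncross-tissue / contralateral links:\n")
    print(object$migration_links[, c("from", "to", "distance",
                                     "from_tissue", "to_tissue")])
  }
  invisible(object)
}

#' @describeIn fatemap Diagnostic panels: mutant markers per cell,
#'   distance-to-zygote by tissue, pairwise distance heatmap, UPGMA tree.
#' @export
plot.fatemap <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pc <- x$mutations$per_clone
  graphics::hist(100 * pc$fraction_mutated, breaks = 20,
                 main = "mutated markers per cell", xlab = "% of loci",
                 col = "grey80")
  if (!is.null(x$genotypes$samples$tissue)) {
    graphics::boxplot(split(x$zygote_distances, x$genotypes$samples$tissue),
                      main = "distance to zygote", ylab = "distance",
                      las = 2)
  } else {
    graphics::hist(x$zygote_distances, breaks = 20,
                   main = "distance to zygote", xlab = "distance")
  }
  graphics::image(x$distances$d, main = "pairwise distances", axes = FALSE)
  tryCatch({
    tree <- build_distance_tree(x$distances)
    ape::plot.phylo(tree, cex = 0.5, main = "UPGMA tree")
  }, error = function(e) invisible(NULL))
  invisible(x)
}

#' Write a fate-map report bundle
#'
#' Writes every pipeline output as plain-text files into a directory:
#' genotypes and sample sheet, distance matrix, tissue summary, clonal
#' complexes and edge list, network edge list, shape-statistic
#' distributions, and a JSON manifest carrying the seed and settings hash
#' so any file can be regenerated from the manifest alone.
#'
#' @param x A [fatemap()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fatemap_report <- function(x, dir) {
  stopifnot(inherits(x, "fatemap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_genotype_table(x$genotypes, fp("genotypes.tsv"),
                       samples_path = fp("samples.tsv"))
  write_distance_matrix(x$distances, fp("distance.tsv"))
  utils::write.table(
    data.frame(clone = names(x$zygote_distances),
               distance_to_zygote = x$zygote_distances),
    fp("zygote_distance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$tissue_summary))
    utils::write.table(as.data.frame(x$tissue_summary),
                       fp("tissue_summary.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_clonal_complexes(x$complexes, fp("complexes.tsv"),
                         edges_path = fp("complex_edges.tsv"))
  if (!is.null(x$network))
    write_network(x$network, fp("network_edges.tsv"))
  if (!is.null(x$shape)) {
    utils::write.table(x$shape$null, fp("shape_null.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(x$shape$observed, fp("shape_observed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(x$simulation))
    ape::write.tree(x$simulation$tree, fp("truth_tree.nwk"))
  jsonlite::write_json(x$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Translates a YAML file with keys matching [fatemap()]'s arguments
#' (plus an optional nested `sim:` block matching [lineage_config()]) into
#' a list ready for `do.call(fatemap, ...)`.
#'
#' @param path Path to the YAML configuration.
#' @return Named list of `fatemap()` arguments.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    sim_args <- cfg$sim
    if (!is.null(sim_args$commitment_schedule))
      sim_args$commitment_schedule <-
        do.call(rbind, lapply(sim_args$commitment_schedule, as.data.frame))
    cfg$sim <- do.call(lineage_config, sim_args)
  }
  if (!is.null(cfg$clock_mu)) {
    cfg$clock <- clock_model(cfg$clock_mu)
    cfg$clock_mu <- NULL
  }
  if (!is.null(cfg$genotypes) == !is.null(cfg$sim))
    stop("config must set exactly one of 'genotypes' and 'sim'")
  cfg
}
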