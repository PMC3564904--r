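#' Configuration for a simulated branching cell lineage
#'
#' Describes the developmental scenario the simulator emulates: synchronous
#' cell divisions from the zygote, stepwise length mutations at polyG loci,
#' commitment of tissue/side progenitor pools at set generations, terminal
#' sampling of clones per tissue, split-clone duplicates as internal
#' controls, and missing genotype calls.
#'
#' Defaults follow the study design the package targets: 110 polyG loci, a
#' per-locus per-division mutation rate of 0.011 (within the observed
#' 0.010-0.013 range), about 40 mitotic generations from zygote to sampled
#' cell, six labelled tissue/side pools (muscle fibroblasts and preadipocytes
#' from a broad mixed mesodermal pool committed early; brain vascular
#' endothelium from a small pool committed later), and roughly 100 sampled
#' cells in total.
#'
#' @param n_loci Number of polyG loci genotyped.
#' @param mu Mutation rate per locus per division (both alleles combined);
#'   each mutation hits one of the two alleles uniformly at random.
#' @param step_probabilities Named numeric vector over length changes in bp
#'   (names are signed integers); must sum to 1. Default: +/-1 bp with equal
#'   probability.
#' @param n_generations Mitotic generations from zygote to sampling.
#' @param commitment_schedule Data frame with columns `tissue`, `side`,
#'   `generation` (commitment generation), `pool_size` (progenitor pool
#'   size); one row per tissue/side pool.
#' @param cells_per_tissue Clones sampled per schedule row.
#' @param missing_rate Per-allele probability that a call is missing ("X").
#' @param split_clone_pairs Number of sampled clones duplicated as
#'   split-clone internal controls.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return A `lineage_config` list, validated.
#' @export
lineage_config <- function(n_loci = 110,
                           mu = 0.011,
                           step_probabilities = c("-1" = 0.5, "1" = 0.5),
                           n_generations = 40,
                           commitment_schedule = default_commitment_schedule(),
                           cells_per_tissue = 16,
                           missing_rate = 0.05,
                           split_clone_pairs = 3,
                           seed = 1L) {
  cfg <- list(n_loci = as.integer(n_loci), mu = mu,
              step_probabilities = step_probabilities,
              n_generations = as.integer(n_generations),
              commitment_schedule = as.data.frame(commitment_schedule),
              cells_per_tissue = as.integer(cells_per_tissue),
              missing_rate = missing_rate,
              split_clone_pairs = as.integer(split_clone_pairs),
              seed = as.integer(seed))
  validate_lineage_config(cfg)
  class(cfg) <- "lineage_config"
  cfg
}

#' @rdname lineage_config
#' @export
default_commitment_schedule <- function() {
  data.frame(
    tissue = rep(c("fibroblast", "preadipocyte", "endothelium"), each = 2),
    side = rep(c("left", "right"), 3),
    generation = c(7L, 7L, 7L, 7L, 13L, 13L),
    pool_size = c(20L, 20L, 20L, 20L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

validate_lineage_config <- function(cfg) {
  if (cfg$mu < 0 || cfg$mu > 1) stop("'mu' must lie in [0, 1]")
  if (cfg$n_loci < 1) stop("'n_loci' must be positive")
  if (cfg$n_generations < 1) stop("'n_generations' must be positive")
  sp <- cfg$step_probabilities
  if (is.null(names(sp)) || anyNA(suppressWarnings(as.integer(names(sp)))))
    stop("'step_probabilities' must be named by signed integer bp changes")
  if (any(as.integer(names(sp)) == 0)) stop("step of 0 bp is not a mutation")
  if (any(sp < 0) || abs(sum(sp) - 1) > 1e-8)
    stop("'step_probabilities' must be non-negative and sum to 1")
  sch <- cfg$commitment_schedule
  need <- c("tissue", "side", "generation", "pool_size")
  if (!all(need %in% names(sch)))
    stop("commitment schedule needs columns: ", paste(need, collapse = ", "))
  if (any(sch$pool_size < 1)) stop("pool sizes must be >= 1")
  if (any(sch$generation >= cfg$n_generations))
    stop("commitment generation must be < n_generations")
  if (any(sch$generation < 1)) stop("commitment generation must be >= 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (cfg$cells_per_tissue < 1) stop("'cells_per_tissue' must be >= 1")
  if (cfg$split_clone_pairs < 0) stop("'split_clone_pairs' must be >= 0")
  invisible(cfg)
}

# Draw zygote (founder) diploid allele lengths for each locus. Founders are
# either homozygous or heterozygous with well-separated alleles, as typical
# for inherited polyG tract length polymorphisms.
draw_zygote <- function(n_loci) {
  f1 <- sample(90:180, n_loci, replace = TRUE)
  het <- stats::runif(n_loci) < 0.7
  f2 <- f1 + ifelse(het, sample(3:10, n_loci, replace = TRUE), 0L)
  rbind(as.integer(f1), as.integer(f2))
}

# Sample `k` distinct lineage paths (0/1 matrices, one row per cell) of
# `depth` bits; each bit selects a daughter cell at one synchronous division.
sample_paths <- function(k, depth) {
  paths <- matrix(sample(0:1, k * depth, replace = TRUE), nrow = k)
  repeat {
    key <- apply(paths, 1, paste, collapse = "")
    dup <- duplicated(key)
    if (!any(dup)) break
    paths[dup, ] <- sample(0:1, sum(dup) * depth, replace = TRUE)
  }
  paths
}

# Recursively build a rooted tree (trie) from distinct 0/1 path matrices.
# Returns nested lists: list(gen =, tip =, children = list()).
build_trie <- function(paths, idx, depth, total_depth) {
  if (length(idx) == 1 && depth == total_depth)
    return(list(gen = depth, tip = idx, children = NULL))
  d <- depth
  # advance through divisions where all lineages take the same daughter
  while (d < total_depth) {
    bits <- paths[idx, d + 1]
    if (length(idx) > 1 && length(unique(bits)) > 1) break
    if (length(idx) == 1) { d <- total_depth; break }
    d <- d + 1
  }
  if (length(idx) == 1)
    return(list(gen = total_depth, tip = idx, children = NULL))
  bits <- paths[idx, d + 1]
  kids <- lapply(split(idx, bits), function(sub)
    build_trie(paths, sub, d + 1, total_depth))
  list(gen = d, tip = NA_integer_, children = unname(kids))
}

# Flatten a trie into an ape "phylo" tree with edge lengths in cell
# divisions, plus the generation of each node.
trie_to_phylo <- function(trie, tip_labels) {
  n_tip <- length(tip_labels)
  env <- new.env()
  env$edges <- list(); env$next_internal <- n_tip + 1L

  walk <- function(node) {
    if (is.null(node$children)) return(c(node$tip, node$gen))
    id <- env$next_internal; env$next_internal <- env$next_internal + 1L
    for (child in node$children) {
      res <- walk(child)
      env$edges[[length(env$edges) + 1]] <-
        c(id, res[1], res[2] - node$gen, node$gen, res[2])
    }
    c(id, node$gen)
  }
  root <- walk(trie)
  em <- do.call(rbind, env$edges)
  tree <- list(edge = em[, 1:2, drop = FALSE],
               edge.length = em[, 3],
               Nnode = env$next_internal - n_tip - 1L,
               tip.label = tip_labels)
  # divisions shared by every sampled cell before the first split are kept
  # as a root edge
  if (root[2] > 0) tree$root.edge <- root[2]
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  tree
}

# Drop stepwise mutations along each edge of the trie, returning per-tip
# genotypes and mutation-event records. Synchronous divisions: the number of
# events per locus on an edge of b divisions is Binomial(b, mu).
drop_mutations <- function(trie, zygote, cfg) {
  L <- cfg$n_loci
  steps <- as.integer(names(cfg$step_probabilities))
  pr <- as.numeric(cfg$step_probabilities)
  tips_a1 <- list(); tips_a2 <- list(); tips_events <- list()
  events <- list()

  walk <- function(node, geno, ev_count, parent_gen) {
    b <- node$gen - parent_gen
    if (b > 0 && cfg$mu > 0) {
      k <- stats::rbinom(L, b, cfg$mu)
      hit <- which(k > 0)
      for (l in hit) {
        for (e in seq_len(k[l])) {
          slot <- sample.int(2L, 1L)
          step <- if (length(steps) == 1) steps else
            sample(steps, 1L, prob = pr)
          geno[slot, l] <- geno[slot, l] + step
          events[[length(events) + 1]] <<-
            data.frame(locus = l, slot = slot, step = step,
                       tip = node$tip, gen_to = node$gen)
        }
      }
      ev_count <- ev_count + k
    }
    if (is.null(node$children)) {
      tips_a1[[node$tip]] <<- geno[1, ]
      tips_a2[[node$tip]] <<- geno[2, ]
      tips_events[[node$tip]] <<- ev_count
    } else {
      for (child in node$children) walk(child, geno, ev_count, node$gen)
    }
  }
  walk(trie, zygote, integer(L), 0L)
  list(a1 = do.call(rbind, tips_a1), a2 = do.call(rbind, tips_a2),
       events = do.call(rbind, tips_events),
       event_table = if (length(events)) do.call(rbind, events) else NULL)
}

#' Simulate a branching cell lineage with polyG mutation accumulation
#'
#' Generates a ground-truth cell lineage: synchronous divisions from the
#' zygote, commitment of tissue/side progenitor pools at scheduled
#' generations, stepwise mutation accumulation at every division, terminal
#' sampling of clones, split-clone duplication, and missing-data masking.
#' Deterministic given `config$seed`.
#'
#' @param config A [lineage_config()].
#' @return A list of class `polyg_simulation` with elements:
#'   \describe{
#'     \item{genotypes}{[genotype_matrix()] of sampled clones with tissue,
#'       side and split-pair labels.}
#'     \item{tree}{Ground-truth genealogy of the sampled cells as an ape
#'       `phylo` tree, edge lengths in cell divisions (split-clone
#'       duplicates share their original's tip).}
#'     \item{truth}{List: `separations` (true pairwise mitotic separations,
#'       path length through the MRCA), `tip_events` (clones x loci counts
#'       of mutation events on the path from the zygote), `zygote` (2 x loci
#'       founder alleles), `events` (flat event table),
#'       `genotypes_premasking` (genotype matrix before missing-data
#'       masking).}
#'     \item{config}{The configuration used.}
#'   }
#' @examples
#' sim <- simulate_lineage(lineage_config(n_loci = 20, cells_per_tissue = 4,
#'                                        split_clone_pairs = 1, seed = 7))
#' sim$genotypes
#' @export
simulate_lineage <- function(config) {
  validate_lineage_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    sch <- cfg$commitment_schedule
    G <- cfg$n_generations
    for (r in seq_len(nrow(sch)))
      if (sch$pool_size[r] > 2^sch$generation[r])
        stop("infeasible sampling: pool size ", sch$pool_size[r],
             " exceeds the ", 2^sch$generation[r], " cells alive at ",
             "commitment generation ", sch$generation[r],
             " (", sch$tissue[r], "/", sch$side[r], ")")

    zygote <- draw_zygote(cfg$n_loci)

    paths <- NULL; meta <- NULL
    for (r in seq_len(nrow(sch))) {
      gc_r <- sch$generation[r]
      pool <- sample_paths(sch$pool_size[r], gc_r)
      member <- sample.int(sch$pool_size[r], cfg$cells_per_tissue,
                           replace = TRUE)
      suffix <- matrix(sample(0:1, cfg$cells_per_tissue * (G - gc_r),
                              replace = TRUE), nrow = cfg$cells_per_tissue)
      tip_paths <- cbind(pool[member, , drop = FALSE], suffix)
      paths <- rbind(paths, tip_paths)
      meta <- rbind(meta, data.frame(
        tissue = rep(sch$tissue[r], cfg$cells_per_tissue),
        side = rep(sch$side[r], cfg$cells_per_tissue),
        stringsAsFactors = FALSE))
    }
    # enforce globally distinct sampled cells (collisions are vanishingly
    # rare for realistic generation counts)
    repeat {
      key <- apply(paths, 1, paste, collapse = "")
      dup <- duplicated(key)
      if (!any(dup)) break
      paths[dup, (ncol(paths) - 3):ncol(paths)] <-
        sample(0:1, 4 * sum(dup), replace = TRUE)
    }

    n <- nrow(paths)
    clone_ids <- sprintf("%s_%s_%02d", abbreviate(meta$tissue, 4), substr(meta$side, 1, 1),
                         stats::ave(seq_len(n), paste(meta$tissue, meta$side),
                                    FUN = seq_along))

    trie <- build_trie(paths, seq_len(n), 0L, G)
    tree <- trie_to_phylo(trie, clone_ids)
    mut <- drop_mutations(trie, zygote, cfg)

    # true pairwise mitotic separations: path length through the MRCA
    lcp <- matrix(G, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      diff <- which(paths[i, ] != paths[j, ])
      lcp[i, j] <- lcp[j, i] <- if (length(diff)) diff[1] - 1L else G
    }
    sep <- 2 * (G - lcp)
    diag(sep) <- 0

    samples <- data.frame(clone = clone_ids, tissue = meta$tissue,
                          side = meta$side, split_pair = NA_character_,
                          stringsAsFactors = FALSE)
    a1 <- mut$a1; a2 <- mut$a2
    tip_events <- mut$events

    # split-clone duplicates: identical genotype, genuinely the same cell
    if (cfg$split_clone_pairs > 0) {
      pick <- sample.int(n, min(cfg$split_clone_pairs, n))
      for (p in pick) {
        pid <- paste0("sp_", samples$clone[p])
        samples$split_pair[p] <- pid
        samples <- rbind(samples, data.frame(
          clone = paste0(samples$clone[p], "_dup"), tissue = samples$tissue[p],
          side = samples$side[p], split_pair = pid, stringsAsFactors = FALSE))
        a1 <- rbind(a1, a1[p, ]); a2 <- rbind(a2, a2[p, ])
        tip_events <- rbind(tip_events, tip_events[p, ])
        sep <- rbind(cbind(sep, sep[, p]), c(sep[p, ], 0))
      }
    }
    m <- nrow(a1)
    dimnames(sep) <- list(samples$clone, samples$clone)
    loci <- sprintf("pG%03d", seq_len(cfg$n_loci))
    rownames(a1) <- rownames(a2) <- samples$clone
    colnames(a1) <- colnames(a2) <- loci
    pre <- genotype_matrix(a1, a2, samples = samples, loci = loci)

    if (cfg$missing_rate > 0) {
      a1[stats::runif(length(a1)) < cfg$missing_rate] <- NA_integer_
      a2[stats::runif(length(a2)) < cfg$missing_rate] <- NA_integer_
    }
    gm <- genotype_matrix(a1, a2, samples = samples, loci = loci)

    colnames(zygote) <- loci
    structure(list(
      genotypes = gm,
      tree = tree,
      truth = list(separations = sep, tip_events = tip_events,
                   zygote = zygote, events = mut$event_table,
                   genotypes_premasking = pre),
      config = cfg), class = "polyg_simulation")
  })
}

#' @export
print.polyg_simulation <- function(x, ...) {
  cat("simulated polyG lineage: ", nrow(x$genotypes$a1), " clones, ",
      x$config$n_loci, " loci, ", x$config$n_generations,
      " generations, mu = ", x$config$mu, "\n", sep = "")
  invisible(x)
}

#' Configuration for the in-vitro subcloning mutation-rate assay
#'
#' Mirrors the experimental rate assay: single cells isolated from a parental
#' clone and passaged for a defined number of population doublings before
#' re-genotyping.
#'
#' @param n_subclones Number of subclones (default 12).
#' @param doublings Population doublings each subclone undergoes (default 20).
#' @param n_loci polyG loci genotyped (default 110).
#' @param mu True mutation rate per locus per division.
#' @param step_probabilities As in [lineage_config()].
#' @param seed Integer seed.
#' @return A validated `subclone_config` list.
#' @export
subclone_config <- function(n_subclones = 12, doublings = 20, n_loci = 110,
                            mu = 0.012,
                            step_probabilities = c("-1" = 0.5, "1" = 0.5),
                            seed = 1L) {
  cfg <- list(n_subclones = as.integer(n_subclones),
              doublings = as.integer(doublings),
              n_loci = as.integer(n_loci), mu = mu,
              step_probabilities = step_probabilities,
              seed = as.integer(seed))
  if (any(c(cfg$n_subclones, cfg$doublings, cfg$n_loci) < 1))
    stop("all counts must be positive")
  if (cfg$mu < 0 || cfg$mu > 1) stop("'mu' must lie in [0, 1]")
  class(cfg) <- "subclone_config"
  cfg
}

#' Simulate the subcloning mutation-rate experiment
#'
#' Generates a parental genotype and `n_subclones` descendant genotypes, each
#' accumulating stepwise mutations over `doublings` divisions. The first row
#' of the result is the parent.
#'
#' @param config A [subclone_config()].
#' @return A [genotype_matrix()] (rows: `parent`, `subclone_01`, ...) with
#'   attribute `truth` holding the true per-subclone x locus mutation-event
#'   counts.
#' @export
simulate_subclone_experiment <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "subclone_config"))
  with_seed(cfg$seed, {
    L <- cfg$n_loci
    steps <- as.integer(names(cfg$step_probabilities))
    pr <- as.numeric(cfg$step_probabilities)
    parent <- draw_zygote(L)
    a1 <- matrix(parent[1, ], cfg$n_subclones + 1, L, byrow = TRUE)
    a2 <- matrix(parent[2, ], cfg$n_subclones + 1, L, byrow = TRUE)
    truth <- matrix(0L, cfg$n_subclones, L)
    for (s in seq_len(cfg$n_subclones)) {
      k <- stats::rbinom(L, cfg$doublings, cfg$mu)
      truth[s, ] <- k
      for (l in which(k > 0)) for (e in seq_len(k[l])) {
        slot <- sample.int(2L, 1L)
        step <- if (length(steps) == 1) steps else sample(steps, 1L, prob = pr)
        if (slot == 1) a1[s + 1, l] <- a1[s + 1, l] + step
        else a2[s + 1, l] <- a2[s + 1, l] + step
      }
    }
    ids <- c("parent", sprintf("subclone_%02d", seq_len(cfg$n_subclones)))
    rownames(a1) <- rownames(a2) <- ids
    colnames(a1) <- colnames(a2) <- sprintf("pG%03d", seq_len(L))
    gm <- genotype_matrix(a1, a2,
                          samples = data.frame(clone = ids,
                                               role = c("parent",
                                                        rep("subclone",
                                                            cfg$n_subclones)),
                                               stringsAsFactors = FALSE))
    attr(gm, "truth") <- truth
    gm
  })
}

#' Simulate triplicate fragment-analysis peak profiles for one genotype
#'
#' Emulates capillary-electrophoresis traces for a single clone x locus call:
#' a dominant peak per true allele, PCR stutter one bp below each allele at a
#' configurable relative intensity, multiplicative intensity noise, and weak
#' baseline peaks. Three independent replicates are produced, matching the
#' triplicate PCR design used to suppress stutter artifacts. With
#' `inconsistent = TRUE` one replicate is corrupted so that a caller
#' requiring triplicate agreement returns an ambiguous call.
#'
#' @param alleles Integer vector of two allele lengths (bp).
#' @param stutter_ratio Stutter peak intensity relative to its parent peak.
#' @param peak_intensity Mean fluorescence (U) of a heterozygous allele peak.
#' @param noise_sd Relative (multiplicative) intensity noise SD.
#' @param baseline Maximum intensity of background peaks.
#' @param inconsistent If `TRUE`, replicate 2 gains a spurious high peak.
#' @param seed Integer seed.
#' @return A list of class `peak_triplicate`: three data frames with columns
#'   `size` and `intensity`.
#' @examples
#' tri <- simulate_peak_profiles(c(106, 103), stutter_ratio = 0.2, seed = 1)
#' call_locus_genotype(tri)
#' @export
simulate_peak_profiles <- function(alleles, stutter_ratio = 0.15,
                                   peak_intensity = 3e4, noise_sd = 0.05,
                                   baseline = 1500, inconsistent = FALSE,
                                   seed = NULL) {
  stopifnot(length(alleles) == 2, all(alleles > 0))
  alleles <- as.integer(alleles)
  with_seed(seed, {
    reps <- lapply(1:3, function(r) {
      sizes <- intensities <- numeric(0)
      for (a in alleles) {
        main <- peak_intensity * max(stats::rnorm(1, 1, noise_sd), 0.2)
        sizes <- c(sizes, a); intensities <- c(intensities, main)
        if (stutter_ratio > 0) {
          sizes <- c(sizes, a - 1L)
          intensities <- c(intensities, stutter_ratio * main)
        }
      }
      # weak background peaks away from the allele range
      bg_sizes <- alleles[1] + sample(c(-8:-4, 4:8), 2)
      sizes <- c(sizes, bg_sizes)
      intensities <- c(intensities, stats::runif(2, 0, baseline))
      if (inconsistent && r == 2) {
        sizes <- c(sizes, max(alleles) + 2L)
        intensities <- c(intensities, 0.9 * peak_intensity)
      }
      agg <- tapply(intensities, sizes, sum)
      data.frame(size = as.integer(names(agg)),
                 intensity = as.numeric(agg), row.names = NULL)
    })
    structure(reps, class = "peak_triplicate")
  })
}
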