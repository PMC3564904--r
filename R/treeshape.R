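# Topological (unit-branch) depth of every tip: the number of internal
# nodes, root included, on the tip-to-root path.
tip_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  tr <- stats::reorder(tree, "cladewise")
  depth <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2]] <- depth[tr$edge[e, 1]] + 1
  depth[seq_len(n)]
}

#' N-bar tree-imbalance statistic
#'
#' The mean, over tips, of the number of internal nodes on the path from the
#' tip to the root, counting the root. Balanced trees give small values
#' (exactly `k` for the complete bifurcating tree with `2^k` tips, e.g. 4
#' for 16 tips); the fully pectinate caterpillar with `n` tips attains the
#' maximum `(n - 1)(n + 2) / (2n)` (7.43 for 14 tips). Multifurcating trees
#' are handled directly.
#'
#' @param tree A rooted `phylo` tree with >= 2 tips.
#' @return The N-bar statistic (numeric).
#' @examples
#' nbar(ape::stree(16, "balanced"))  # 4
#' nbar(ape::stree(14, "left"))      # 7.4286
#' @export
nbar <- function(tree) {
  if (length(tree$tip.label) < 2)
    stop("N-bar is undefined for single-tip trees")
  mean(tip_depths(tree))
}

#' Colless' imbalance statistic
#'
#' The sum over internal nodes of the absolute difference between the tip
#' counts of the two daughter clades; zero for maximally balanced trees and
#' `(n - 1)(n - 2) / 2` for the n-tip caterpillar. Requires a bifurcating
#' tree: multifurcations are either rejected or randomly resolved.
#'
#' @param tree A rooted `phylo` tree with >= 2 tips.
#' @param multifurcations `"reject"` (error on polytomies) or `"resolve"`
#'   (random bifurcating resolution, seeded).
#' @param seed Seed for random resolution.
#' @return A list of class `shape_statistics`: `colless_raw` (integer),
#'   `colless_normalized` (raw divided by its caterpillar maximum; `NA` for
#'   n < 3), `n_tips`.
#' @export
colless <- function(tree, multifurcations = c("reject", "resolve"),
                    seed = NULL) {
  multifurcations <- match.arg(multifurcations)
  n <- length(tree$tip.label)
  if (n < 2) stop("Colless' index is undefined for single-tip trees")
  kids <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  if (any(kids > 2)) {
    if (multifurcations == "reject")
      stop("tree contains multifurcations; use multifurcations = \"resolve\"")
    tree <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  }
  tr <- stats::reorder(tree, "postorder")
  cnt <- c(rep(1L, n), integer(tree$Nnode))
  raw <- 0L
  children <- split(tr$edge[, 2], tr$edge[, 1])
  for (e in seq_len(nrow(tr$edge)))
    cnt[tr$edge[e, 1]] <- cnt[tr$edge[e, 1]] + cnt[tr$edge[e, 2]]
  for (node in names(children)) {
    ch <- children[[node]]
    if (length(ch) == 2) raw <- raw + abs(cnt[ch[1]] - cnt[ch[2]])
  }
  structure(list(colless_raw = as.integer(raw),
                 colless_normalized = if (n > 2)
                   raw / ((n - 1) * (n - 2) / 2) else NA_real_,
                 n_tips = n),
            class = "shape_statistics")
}

#' @export
print.shape_statistics <- function(x, ...) {
  cat("Colless Ic = ", x$colless_raw, " (normalized ",
      format(x$colless_normalized, digits = 4), ") on ", x$n_tips,
      " tips\n", sep = "")
  invisible(x)
}

#' Randomize genotypes by per-locus allele shuffling
#'
#' Independently at each locus, permutes the assignment of genotype calls
#' (allele pairs, including missing alleles) to clones. The per-locus allele
#' multiset is preserved exactly, while any lineage signal linking loci is
#' destroyed — the randomization used to build null distributions for
#' network significance and tree-shape comparisons.
#'
#' @param x A [genotype_matrix()].
#' @param seed Integer seed.
#' @return A `genotype_matrix` with shuffled calls.
#' @export
randomize_genotypes <- function(x, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- nrow(x$a1)
  if (n < 2) return(x)
  with_seed(seed, {
    a1 <- x$a1; a2 <- x$a2
    for (l in seq_len(ncol(a1))) {
      perm <- sample.int(n)
      a1[, l] <- a1[perm, l]
      a2[, l] <- a2[perm, l]
    }
    genotype_matrix(a1, a2, samples = x$samples, loci = x$loci)
  })
}

#' Recode genotypes as single-digit characters for Bayesian inference
#'
#' Converts each parental allele slot of each locus into one standard-data
#' character column: alleles are mapped to digits 0-9 by descending
#' frequency (0 is the modal allele; frequency ties broken toward the
#' smaller length); if more than 10 distinct alleles occur, the rarest are
#' merged into digit 9; missing alleles become `"?"`. Runs
#' [assign_parental_alleles()] first when slots are not yet assigned.
#'
#' @param x A [genotype_matrix()].
#' @return A list of class `polyg_characters`: `characters` (character
#'   matrix, clones x (2 x loci), columns `<locus>_s1`, `<locus>_s2`) and
#'   `codes` (per-column named map from allele length to digit).
#' @export
recode_for_phylogenetics <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(attr(x, "founders")) && nrow(x$a1) >= 2)
    x <- assign_parental_alleles(x)
  n <- nrow(x$a1); L <- length(x$loci)
  cols <- character(0)
  chars <- matrix("?", n, 2 * L)
  codes <- list()
  for (l in seq_len(L)) for (s in 1:2) {
    v <- if (s == 1) x$a1[, l] else x$a2[, l]
    cname <- paste0(x$loci[l], "_s", s)
    cols <- c(cols, cname)
    obs <- v[!is.na(v)]
    j <- (l - 1) * 2 + s
    if (length(obs)) {
      tab <- table(obs)
      ord <- order(-as.numeric(tab), as.integer(names(tab)))
      lens <- as.integer(names(tab))[ord]
      digit <- pmin(seq_along(lens) - 1L, 9L)
      names(digit) <- lens
      chars[, j] <- ifelse(is.na(v), "?",
                           as.character(digit[as.character(v)]))
      codes[[cname]] <- digit
    } else {
      codes[[cname]] <- integer(0)
    }
  }
  dimnames(chars) <- list(x$samples$clone, cols)
  structure(list(characters = chars, codes = codes),
            class = "polyg_characters")
}

#' Write a standard-datatype NEXUS file for external Bayesian inference
#'
#' Emits the recoded character matrix as a NEXUS DATA block
#' (DATATYPE=STANDARD, MISSING=?), optionally followed by a MrBayes command
#' block recording the settings used for tree inference (gamma rate
#' variation with a uniform(0.05, 50) shape prior and a symmetric Dirichlet
#' fixed to infinity). Bayesian MCMC itself is delegated to MrBayes; this
#' package only writes its input and reads back resulting trees.
#'
#' @param chars A [recode_for_phylogenetics()] result, or a character
#'   matrix.
#' @param path Output path.
#' @param mrbayes_block If `TRUE`, append the MrBayes command block.
#' @param ngen MCMC generations recorded in the command block.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(chars, path, mrbayes_block = TRUE, ngen = 6e7) {
  m <- if (inherits(chars, "polyg_characters")) chars$characters else chars
  taxa <- gsub("[^A-Za-z0-9_.]", "_", rownames(m))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)), con)
  writeLines("  FORMAT DATATYPE=STANDARD GAP=- MISSING=? SYMBOLS=\"0123456789\";",
             con)
  writeLines("  MATRIX", con)
  pad <- max(nchar(taxa)) + 2
  for (i in seq_len(nrow(m)))
    writeLines(paste0(formatC(taxa[i], width = -pad),
                      paste(m[i, ], collapse = "")), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  if (mrbayes_block) {
    writeLines(c("BEGIN MRBAYES;",
                 "  lset rates=gamma;",
                 "  prset shapepr=uniform(0.05,50);",
                 "  prset symdirihyperpr=fixed(infinity);",
                 sprintf("  mcmc ngen=%d;", as.integer(ngen)),
                 "END;"), con)
  }
  invisible(path)
}

#' Read a standard-datatype NEXUS character matrix
#'
#' Minimal reader for the MATRIX block written by [write_nexus()] (one taxon
#' per line, contiguous character string). Round-trips with the writer.
#'
#' @param path Path to the NEXUS file.
#' @return Character matrix (taxa x characters).
#' @export
read_nexus_characters <- function(path) {
  lines <- readLines(path)
  start <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (!length(start)) stop("no MATRIX block found in ", path)
  taxa <- character(0); seqs <- character(0)
  for (i in (start[1] + 1):length(lines)) {
    line <- trimws(lines[i])
    if (line == ";" || grepl("^END", line, ignore.case = TRUE)) break
    if (line == "") next
    parts <- strsplit(line, "\\s+")[[1]]
    taxa <- c(taxa, parts[1])
    seqs <- c(seqs, paste(parts[-1], collapse = ""))
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- taxa
  m
}

#' Build a rooted tree from a distance matrix by UPGMA
#'
#' Average-linkage agglomerative clustering of the genetic distance matrix,
#' returned as a rooted `phylo` tree. Serves as the package's built-in
#' distance-based tree builder so that tree-shape analysis runs end to end
#' without external Bayesian inference.
#'
#' @param dm A [distance_matrix()] result or a symmetric numeric matrix.
#' @param method Agglomeration method (only `"upgma"`, i.e. average
#'   linkage).
#' @return A rooted `phylo` tree with branch lengths on the distance scale.
#' @export
build_distance_tree <- function(dm, method = "upgma") {
  D <- if (inherits(dm, "polyg_dist")) dm$d else as.matrix(dm)
  if (any(is.na(D[upper.tri(D)])))
    stop("distance matrix contains undefined pairs; cannot build a tree")
  if (!identical(method, "upgma")) stop("only UPGMA is supported")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)
}

#' Compare tree shape against the randomized-genotype null
#'
#' Computes N-bar and Colless' statistics for trees supported by the
#' observed genotypes and for trees rebuilt from `n_randomizations`
#' randomized genotype matrices ([randomize_genotypes()]); randomized trees
#' are reconstructed with [build_distance_tree()] on the shuffled matrix.
#' Growth processes with equal division rates across lineages yield
#' symmetric trees, so a downward shift of the observed N-bar relative to
#' the null indicates unbiased lineage commitment.
#'
#' @param observed_trees A `phylo` tree or list of them (e.g. posterior
#'   samples from external Bayesian inference, or the package's UPGMA
#'   tree).
#' @param x The observed [genotype_matrix()] used to generate the null.
#' @param n_randomizations Number of randomized genotype matrices.
#' @param seed Integer seed.
#' @return A list of class `shape_null_comparison`: `observed` and `null`
#'   data frames (`nbar`, `colless_raw`, `colless_normalized`),
#'   `mean_shift` (observed minus null mean, per statistic), and `p_lower`
#'   (rank-based one-sided p that the observed mean statistic is as small
#'   as or smaller than the null's).
#' @export
shape_null_comparison <- function(observed_trees, x, n_randomizations = 100,
                                  seed = 1L) {
  if (inherits(observed_trees, "phylo"))
    observed_trees <- list(observed_trees)
  if (n_randomizations < 10)
    warning("fewer than 10 randomizations: the null is poorly resolved")
  stat_row <- function(tree, sd_seed) {
    cs <- colless(tree, multifurcations = "resolve", seed = sd_seed)
    data.frame(nbar = nbar(tree), colless_raw = cs$colless_raw,
               colless_normalized = cs$colless_normalized)
  }
  obs <- do.call(rbind, lapply(seq_along(observed_trees), function(i)
    stat_row(observed_trees[[i]], derive_seed(seed, i))))
  null <- do.call(rbind, lapply(seq_len(n_randomizations), function(b) {
    rx <- randomize_genotypes(x, seed = derive_seed(seed, 1000 + b))
    tree <- build_distance_tree(distance_matrix(rx))
    stat_row(tree, derive_seed(seed, 2000 + b))
  }))
  mean_shift <- colMeans(obs) - colMeans(null)
  p_lower <- vapply(names(obs), function(s)
    (1 + sum(null[[s]] <= mean(obs[[s]]))) / (n_randomizations + 1),
    numeric(1))
  structure(list(observed = obs, null = null, mean_shift = mean_shift,
                 p_lower = p_lower),
            class = "shape_null_comparison")
}

#' @export
print.shape_null_comparison <- function(x, ...) {
  cat("tree-shape comparison vs randomized-genotype null\n")
  cat(sprintf("observed mean N-bar %.3f vs null %.3f (shift %+.3f, p_lower %.3g)\n",
              mean(x$observed$nbar), mean(x$null$nbar),
              x$mean_shift[["nbar"]], x$p_lower[["nbar"]]))
  cat(sprintf("observed mean Colless %.1f vs null %.1f (shift %+.1f, p_lower %.3g)\n",
              mean(x$observed$colless_raw), mean(x$null$colless_raw),
              x$mean_shift[["colless_raw"]], x$p_lower[["colless_raw"]]))
  invisible(x)
}
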