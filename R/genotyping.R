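#' Intensity thresholds for triplicate genotype calling
#'
#' Thresholds used to classify fragment-analysis peak patterns. Writing
#' `I1`, `I2`, `I3` for the highest, second- and third-highest peak
#' intensities in one replicate, a call is homozygous when
#' `|I2 - I3| <= intensity_gap`, heterozygous when `|I2 - I3| >=
#' intensity_gap` and `I2 > het_ratio * I1`, and ambiguous otherwise.
#'
#' @param intensity_gap Intensity gap in fluorescence units (default `1e4`).
#' @param het_ratio Minimum second-peak to top-peak ratio for a heterozygous
#'   call (default `0.8`).
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(intensity_gap = 1e4, het_ratio = 0.8) {
  if (intensity_gap <= 0) stop("'intensity_gap' must be > 0")
  if (het_ratio <= 0 || het_ratio >= 1) stop("'het_ratio' must be in (0, 1)")
  structure(list(intensity_gap = intensity_gap, het_ratio = het_ratio),
            class = "call_thresholds")
}

# Call one replicate: returns list(allele_a, allele_b, status).
call_one_replicate <- function(profile, thresholds) {
  if (is.null(profile) || nrow(profile) == 0)
    return(list(allele_a = NA_integer_, allele_b = NA_integer_,
                status = "ambiguous"))
  ord <- order(-profile$intensity, profile$size)
  sizes <- profile$size[ord]
  ints <- profile$intensity[ord]
  # fewer than three peaks: pad with zero-intensity sentinels
  while (length(ints) < 3) { ints <- c(ints, 0); sizes <- c(sizes, NA) }
  gap <- abs(ints[2] - ints[3])
  if (gap <= thresholds$intensity_gap) {
    list(allele_a = sizes[1], allele_b = sizes[1], status = "homozygous")
  } else if (ints[2] > thresholds$het_ratio * ints[1]) {
    ab <- sort(c(sizes[1], sizes[2]), decreasing = TRUE)
    list(allele_a = ab[1], allele_b = ab[2], status = "heterozygous")
  } else {
    list(allele_a = sizes[1], allele_b = NA_integer_, status = "ambiguous")
  }
}

#' Call a diploid genotype from triplicate peak profiles
#'
#' Applies the intensity rules of [call_thresholds()] to each of the three
#' replicate profiles independently; the final call is made only when all
#' three replicates agree exactly. Non-reproducible patterns are assigned
#' ambiguously: the top-peak allele is retained when it is consistent across
#' replicates (a `"106/X"`-style call), otherwise both alleles are missing.
#'
#' @param triplicate A `peak_triplicate` (see [simulate_peak_profiles()]) or
#'   a list of three data frames with columns `size` and `intensity`.
#' @param thresholds A [call_thresholds()].
#' @return A list of class `genotype_call`: `allele_a`, `allele_b` (bp or
#'   `NA`), `status` (`"homozygous"`, `"heterozygous"`, `"ambiguous"`).
#' @examples
#' prof <- data.frame(size = c(106, 101, 98), intensity = c(3e4, 5e3, 3e3))
#' call_locus_genotype(list(prof, prof, prof))
#' @export
call_locus_genotype <- function(triplicate, thresholds = call_thresholds()) {
  if (length(triplicate) != 3)
    stop("a peak triplicate must contain exactly three replicates")
  calls <- lapply(triplicate, call_one_replicate, thresholds = thresholds)
  same <- function(a, b) identical(a$status, b$status) &&
    identical(a$allele_a, b$allele_a) && identical(a$allele_b, b$allele_b)
  if (same(calls[[1]], calls[[2]]) && same(calls[[2]], calls[[3]]) &&
      calls[[1]]$status != "ambiguous") {
    out <- calls[[1]]
  } else {
    tops <- vapply(calls, function(cl) as.integer(cl$allele_a), integer(1))
    top <- if (!anyNA(tops) && length(unique(tops)) == 1) tops[1]
           else NA_integer_
    out <- list(allele_a = top, allele_b = NA_integer_, status = "ambiguous")
  }
  out$allele_a <- as.integer(out$allele_a)
  out$allele_b <- as.integer(out$allele_b)
  structure(out, class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(format_call(x$allele_a, x$allele_b), " (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Call a genotype matrix from a long table of peak profiles
#'
#' @param peaks Data frame (or path to a TSV) with columns `clone`, `locus`,
#'   `replicate`, `size`, `intensity`.
#' @param thresholds A [call_thresholds()].
#' @return A [genotype_matrix()] of the calls.
#' @export
call_genotype_table <- function(peaks, thresholds = call_thresholds()) {
  if (is.character(peaks))
    peaks <- utils::read.table(peaks, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  need <- c("clone", "locus", "replicate", "size", "intensity")
  if (!all(need %in% names(peaks)))
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  clones <- unique(peaks$clone)
  loci <- unique(peaks$locus)
  a1 <- a2 <- matrix(NA_integer_, length(clones), length(loci),
                     dimnames = list(clones, loci))
  for (cl in clones) for (lo in loci) {
    sub <- peaks[peaks$clone == cl & peaks$locus == lo, ]
    tri <- lapply(1:3, function(r) sub[sub$replicate == r,
                                       c("size", "intensity")])
    call <- call_locus_genotype(tri, thresholds)
    a1[cl, lo] <- call$allele_a
    a2[cl, lo] <- call$allele_b
  }
  genotype_matrix(a1, a2)
}

#' Assign alleles to parental (founder) origins
#'
#' For each locus, infers the two inherited founder allele lengths as the two
#' most frequent lengths observed across all clones (a single founder if the
#' locus is homozygous throughout), then routes each clone's alleles to the
#' founder slot minimizing the implied mutational deviation, so that the
#' total number of mutations needed to explain the matrix is minimized.
#' Ties are broken toward the more frequent founder.
#'
#' @param x A [genotype_matrix()].
#' @return The matrix with allele slots reordered so slot 1 descends from
#'   founder 1 and slot 2 from founder 2, and an attribute `founders`: a
#'   data frame with per-locus `founder1`, `founder2` lengths and an
#'   `all_missing` flag (founders undefined for loci with no calls).
#' @export
assign_parental_alleles <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x$a1) < 2) stop("parental assignment requires >= 2 clones")
  L <- length(x$loci)
  a1 <- x$a1; a2 <- x$a2
  founders <- data.frame(locus = x$loci, founder1 = NA_integer_,
                         founder2 = NA_integer_, all_missing = FALSE,
                         stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    pool <- c(a1[, l], a2[, l])
    pool <- pool[!is.na(pool)]
    if (!length(pool)) { founders$all_missing[l] <- TRUE; next }
    tab <- table(pool)
    ord <- order(-as.numeric(tab), as.integer(names(tab)))
    lens <- as.integer(names(tab))[ord]
    f1 <- lens[1]
    f2 <- if (length(lens) >= 2) lens[2] else f1
    founders$founder1[l] <- f1
    founders$founder2[l] <- f2
    for (i in seq_len(nrow(a1))) {
      p <- a1[i, l]; q <- a2[i, l]
      if (is.na(p) && is.na(q)) next
      if (is.na(p) || is.na(q)) {
        k <- if (is.na(p)) q else p
        if (abs(k - f1) <= abs(k - f2)) { a1[i, l] <- k; a2[i, l] <- NA }
        else { a1[i, l] <- NA; a2[i, l] <- k }
      } else {
        keep <- abs(p - f1) + abs(q - f2)
        swap <- abs(q - f1) + abs(p - f2)
        if (swap < keep) { a1[i, l] <- q; a2[i, l] <- p }
      }
    }
  }
  out <- genotype_matrix(a1, a2, samples = x$samples, loci = x$loci)
  attr(out, "founders") <- founders
  out
}

#' Consensus genotype of a set of clones
#'
#' Per locus and per allele slot, the modal non-missing allele over the
#' chosen clones; frequency ties are broken toward the smaller allele
#' length. Applied to all clones this estimates the zygote genotype; applied
#' to the clones of one tissue it gives the tissue consensus. For
#' slot-resolved consensus run [assign_parental_alleles()] first.
#'
#' @param x A [genotype_matrix()].
#' @param clones Optional subset of clone ids or indices (default: all).
#' @return Integer matrix with rows `slot1`, `slot2` and one column per
#'   locus; `NA` where a slot has no non-missing calls.
#' @export
consensus_genotype <- function(x, clones = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(clones)) clones <- seq_len(nrow(x$a1))
  if (is.character(clones)) clones <- match(clones, x$samples$clone)
  if (!length(clones)) stop("clone subset must be nonempty")
  modal <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)
  }
  s1 <- apply(x$a1[clones, , drop = FALSE], 2, modal)
  s2 <- apply(x$a2[clones, , drop = FALSE], 2, modal)
  out <- rbind(slot1 = s1, slot2 = s2)
  colnames(out) <- x$loci
  storage.mode(out) <- "integer"
  out
}

#' Identify somatic mutations against a reference genotype
#'
#' A mutation is any non-missing allele that differs from the reference
#' allele of its parental slot. Summaries are diploid-aware: the per-clone
#' mutant-allele count can reach two per locus.
#'
#' @param x A [genotype_matrix()] (ideally slot-assigned via
#'   [assign_parental_alleles()]).
#' @param reference A 2 x loci allele matrix, e.g. from
#'   [consensus_genotype()]; defaults to the consensus over all clones.
#' @return A list with:
#'   \describe{
#'     \item{per_clone}{Data frame: `clone`, `n_mutant_alleles`,
#'       `n_mutated_loci`, `n_loci_evaluable`, `fraction_mutated`.}
#'     \item{per_locus}{Data frame: `locus`, `n_distinct_mutant_alleles`.}
#'     \item{mean_mutant_alleles_per_locus_per_cell}{Total mutant-allele
#'       calls divided by clones x loci.}
#'   }
#' @export
identify_somatic_mutations <- function(x, reference = consensus_genotype(x)) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (ncol(reference) != length(x$loci))
    stop("reference must cover the matrix loci")
  n <- nrow(x$a1); L <- length(x$loci)
  ref1 <- matrix(reference[1, ], n, L, byrow = TRUE)
  ref2 <- matrix(reference[2, ], n, L, byrow = TRUE)
  mut1 <- !is.na(x$a1) & !is.na(ref1) & x$a1 != ref1
  mut2 <- !is.na(x$a2) & !is.na(ref2) & x$a2 != ref2
  eval1 <- !is.na(x$a1) & !is.na(ref1)
  eval2 <- !is.na(x$a2) & !is.na(ref2)
  evaluable <- eval1 | eval2
  mutated <- mut1 | mut2
  per_clone <- data.frame(
    clone = x$samples$clone,
    n_mutant_alleles = rowSums(mut1) + rowSums(mut2),
    n_mutated_loci = rowSums(mutated),
    n_loci_evaluable = rowSums(evaluable),
    stringsAsFactors = FALSE)
  per_clone$fraction_mutated <-
    ifelse(per_clone$n_loci_evaluable > 0,
           per_clone$n_mutated_loci / per_clone$n_loci_evaluable, NA_real_)
  distinct <- integer(L)
  for (l in seq_len(L)) {
    v1 <- unique(x$a1[mut1[, l], l])
    v2 <- unique(x$a2[mut2[, l], l])
    distinct[l] <- length(v1) + length(v2)
  }
  list(per_clone = per_clone,
       per_locus = data.frame(locus = x$loci,
                              n_distinct_mutant_alleles = distinct,
                              stringsAsFactors = FALSE),
       mean_mutant_alleles_per_locus_per_cell =
         sum(per_clone$n_mutant_alleles) / (n * L))
}

#' Estimate the per-locus per-division mutation rate from a subcloning assay
#'
#' Pools new mutations across subclones and loci: the estimate is the total
#' number of new mutations (per allele slot, the absolute bp difference from
#' the parent, i.e. the minimal number of single-bp slippage events) divided
#' by subclones x doublings x usable loci. The standard error is computed
#' from the spread of per-subclone rates.
#'
#' @param x A [genotype_matrix()] whose first row (or the row named
#'   `"parent"`) is the parental clone and remaining rows are subclones,
#'   e.g. from [simulate_subclone_experiment()].
#' @param doublings Number of divisions each subclone underwent.
#' @param parent Clone id or index of the parental genotype.
#' @return A list: `rate` (pooled estimate), `se`, `n_new_mutations`,
#'   `per_subclone` data frame (`clone`, `n_new_mutations`, `n_loci`,
#'   `rate`).
#' @export
estimate_mutation_rate <- function(x, doublings, parent = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (doublings <= 0) stop("'doublings' must be positive")
  if (is.character(parent)) parent <- match(parent, x$samples$clone)
  if (is.na(parent)) stop("parent clone not found")
  p1 <- x$a1[parent, ]; p2 <- x$a2[parent, ]
  subs <- setdiff(seq_len(nrow(x$a1)), parent)
  if (!length(subs)) stop("no subclones present")
  per <- lapply(subs, function(i) {
    d1 <- abs(x$a1[i, ] - p1)   # NA where either allele missing
    d2 <- abs(x$a2[i, ] - p2)
    usable <- (!is.na(d1)) + (!is.na(d2))
    n_loci <- sum(usable) / 2   # slot pairs -> locus equivalents
    muts <- sum(d1, na.rm = TRUE) + sum(d2, na.rm = TRUE)
    data.frame(clone = x$samples$clone[i], n_new_mutations = muts,
               n_loci = n_loci, rate = if (n_loci > 0)
                 muts / (doublings * n_loci) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  denom <- doublings * sum(per$n_loci)
  if (denom == 0) stop("no usable loci shared between parent and subclones")
  rate <- sum(per$n_new_mutations) / denom
  rates <- per$rate[!is.na(per$rate)]
  se <- if (length(rates) > 1) stats::sd(rates) / sqrt(length(rates))
        else NA_real_
  list(rate = rate, se = se, n_new_mutations = sum(per$n_new_mutations),
       per_subclone = per)
}
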