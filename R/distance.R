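#' Diploid per-locus genetic distance between two genotypes
#'
#' Per locus, the contribution is the smaller of the two possible allele
#' pairings of the summed absolute length differences (in bp). Loci where
#' the pair jointly has more than one missing allele are excluded; with
#' exactly one missing allele the known allele of the incomplete call is
#' compared against the closer of the counterpart's two alleles. The total
#' is divided by the number of usable loci, so the distance is normalized
#' per locus examined for that pair.
#'
#' @param ga,gb 2 x loci allele matrices (rows are allele slots, `NA` marks
#'   a missing allele), e.g. from [clone_genotype()] or
#'   [consensus_genotype()]. Must share the locus set.
#' @return A list: `distance` (per-locus normalized; `NA` if no locus is
#'   usable), `n_usable_loci`.
#' @examples
#' ga <- rbind(c(106L, 200L), c(108L, 200L))
#' gb <- rbind(c(106L, 200L), c(106L, 202L))
#' pairwise_distance(ga, gb)  # (2 + 2) / 2 = 2
#' @export
pairwise_distance <- function(ga, gb) {
  if (!all(dim(ga) == c(2, ncol(gb))))
    stop("genotypes must be 2 x loci matrices over the same locus set")
  total <- 0; usable <- 0L
  for (l in seq_len(ncol(ga))) {
    a <- ga[, l]; b <- gb[, l]
    n_miss <- sum(is.na(a)) + sum(is.na(b))
    if (n_miss > 1) next
    if (n_miss == 0) {
      contrib <- min(abs(a[1] - b[1]) + abs(a[2] - b[2]),
                     abs(a[1] - b[2]) + abs(a[2] - b[1]))
    } else {
      if (anyNA(a)) { k <- a[!is.na(a)]; cc <- b } else { k <- b[!is.na(b)]; cc <- a }
      contrib <- min(abs(k - cc[1]), abs(k - cc[2]))
    }
    total <- total + contrib
    usable <- usable + 1L
  }
  list(distance = if (usable > 0) total / usable else NA_real_,
       n_usable_loci = usable)
}

#' All pairwise genetic distances among clones
#'
#' Applies the rules of [pairwise_distance()] to every clone pair, fully
#' vectorized per locus. Pairs with no usable locus get `NA` ("undefined")
#' and are flagged for exclusion downstream. Note the resulting distance is
#' a symmetric premetric: the triangle inequality is not guaranteed because
#' different pairs can be normalized over different usable-locus sets.
#'
#' @param x A [genotype_matrix()].
#' @return An object of class `polyg_dist`: list with `d` (symmetric matrix,
#'   zero diagonal), `n_usable_loci` (per-pair usable locus counts),
#'   `samples` (the clone metadata).
#' @export
distance_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- nrow(x$a1)
  if (n < 2) stop("distance matrix requires >= 2 clones")
  S <- matrix(0, n, n)
  U <- matrix(0L, n, n)
  for (l in seq_len(ncol(x$a1))) {
    x1 <- as.numeric(x$a1[, l]); x2 <- as.numeric(x$a2[, l])
    m <- is.na(x1) + is.na(x2)
    M <- outer(m, m, "+")
    use <- M <= 1
    contrib <- matrix(0, n, n)
    # both genotypes complete: minimum over the two allele pairings
    same <- abs(outer(x1, x1, "-")) + abs(outer(x2, x2, "-"))
    cross <- abs(outer(x1, x2, "-")) + abs(outer(x2, x1, "-"))
    full <- outer(m == 0, m == 0, "&")
    contrib[full] <- pmin(same, cross)[full]
    # exactly one allele missing in the pair: known allele vs the closer
    # counterpart allele
    if (any(m == 1)) {
      k <- ifelse(m == 1, ifelse(is.na(x1), x2, x1), NA_real_)
      near <- pmin(abs(outer(x1, k, "-")), abs(outer(x2, k, "-")))
      half <- outer(m == 0, m == 1, "&")   # [i complete, j one-missing]
      contrib[half] <- near[half]
      contrib[t(half)] <- t(near)[t(half)]
    }
    contrib[!use] <- 0
    S <- S + contrib
    U <- U + use
  }
  D <- ifelse(U > 0, S / U, NA_real_)
  diag(D) <- 0
  dimnames(D) <- dimnames(U) <- list(x$samples$clone, x$samples$clone)
  structure(list(d = D, n_usable_loci = U, samples = x$samples),
            class = "polyg_dist")
}

#' @export
print.polyg_dist <- function(x, ...) {
  n <- nrow(x$d)
  off <- x$d[upper.tri(x$d)]
  cat("polyG genetic distance matrix: ", n, " clones\n", sep = "")
  cat(sprintf("mean pairwise distance %.3f (range %.3f-%.3f), %d undefined pair(s)\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' Distances of every clone to a reference genotype
#'
#' Typically used against the all-clones consensus, which stands in for the
#' zygote.
#'
#' @param x A [genotype_matrix()].
#' @param reference 2 x loci allele matrix (default: consensus over all
#'   clones, the zygote estimate).
#' @return Named numeric vector of per-locus normalized distances.
#' @export
distance_to_reference <- function(x, reference = consensus_genotype(x)) {
  stopifnot(inherits(x, "genotype_matrix"))
  out <- vapply(seq_len(nrow(x$a1)), function(i)
    pairwise_distance(clone_genotype(x, i), reference)$distance, numeric(1))
  names(out) <- x$samples$clone
  out
}

#' Molecular-clock model linking distance and cell divisions
#'
#' Under a constant per-division mutation rate, the expected per-locus
#' genetic distance between two cells is `mu` times their mitotic
#' separation: distance = mutation rate x number of cell divisions (x number
#' of loci, which is 1 for per-locus normalized distances).
#'
#' @param mu Mutation rate per locus per division (must be > 0).
#' @return A `clock_model` list.
#' @export
clock_model <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu <= 0)
    stop("'mu' must be a single positive number")
  structure(list(mu = mu), class = "clock_model")
}

#' @rdname clock_model
#' @param d Per-locus genetic distance (>= 0).
#' @param clock A `clock_model`.
#' @return `divisions_from_distance()`: the implied number of cell
#'   divisions `d / mu`; `distance_from_divisions()`: the expected distance
#'   `mu * s`.
#' @examples
#' distance_from_divisions(15, clock_model(0.013))  # 0.195, approx 0.2
#' divisions_from_distance(0.2, clock_model(0.010)) # 20
#' @export
divisions_from_distance <- function(d, clock) {
  stopifnot(inherits(clock, "clock_model"))
  if (any(d < 0, na.rm = TRUE)) stop("distances must be >= 0")
  d / clock$mu
}

#' @rdname clock_model
#' @param s Number of cell divisions.
#' @export
distance_from_divisions <- function(s, clock) {
  stopifnot(inherits(clock, "clock_model"))
  s * clock$mu
}

# -- exact big-integer helpers (decimal digit vectors, little-endian) -------

big_from_int <- function(x) {
  if (x == 0) return(0L)
  digits <- integer(0)
  while (x > 0) { digits <- c(digits, x %% 10L); x <- x %/% 10L }
  digits
}

big_mul_small <- function(big, m) {
  res <- integer(length(big) + 16)
  carry <- 0
  for (i in seq_along(big)) {
    v <- big[i] * m + carry
    res[i] <- v %% 10L
    carry <- v %/% 10L
  }
  i <- length(big)
  while (carry > 0) {
    i <- i + 1
    res[i] <- carry %% 10L
    carry <- carry %/% 10L
  }
  res[seq_len(max(i, length(big)))]
}

#' Count possible rooted cell lineage histories
#'
#' The number of distinct rooted, binary, leaf-labelled lineage histories
#' for `n` cells: `(2n-3)! / (2^(n-2) (n-2)!)`, i.e. the double factorial
#' `(2n-3)!!`, evaluated exactly. Grows super-exponentially: 15 histories
#' for 4 cells, 135,135 for 8, and beyond 10^15 already at 16.
#'
#' @param n Number of cells (>= 2).
#' @param exact If `TRUE`, return the exact value as a decimal string
#'   (arbitrary precision); otherwise return a double, which is exact up to
#'   2^53 (n <= 16) and a close approximation beyond.
#' @return Numeric count, or a character string when `exact = TRUE`.
#' @examples
#' count_lineage_histories(4)              # 15
#' count_lineage_histories(8)              # 135135
#' count_lineage_histories(30, exact = TRUE)
#' @export
count_lineage_histories <- function(n, exact = FALSE) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 2 || n != round(n))
    stop("'n' must be a single integer >= 2")
  terms <- seq(1, 2 * n - 3, by = 2)   # 1 x 3 x 5 x ... x (2n-3)
  if (exact) {
    big <- big_from_int(1L)
    for (m in terms) big <- big_mul_small(big, m)
    big <- big[seq_len(max(which(big != 0), 1))]
    return(paste(rev(big), collapse = ""))
  }
  prod(as.numeric(terms))
}

#' Tissue-level summaries of genetic distance
#'
#' For each tissue/side group: the mean and SEM of intra-tissue pairwise
#' distances, of inter-tissue distances (pairs with exactly one member in
#' the group), of member-to-zygote distances, and — per tissue type — of
#' left-to-right cross-side pairs. Each group mean is tested against the
#' global mean of all pairwise distances with a two-sided one-sample t-test
#' over the contributing pair values.
#'
#' @param dm A [distance_matrix()] result whose `samples` carry `tissue` and
#'   `side` columns.
#' @param zygote_distances Optional named vector of clone-to-zygote
#'   distances ([distance_to_reference()]).
#' @return A data frame of class `tissue_distance_summary`: `tissue`,
#'   `side`, `metric`, `mean`, `sem`, `n`, `p_value`.
#' @export
tissue_distance_summary <- function(dm, zygote_distances = NULL) {
  stopifnot(inherits(dm, "polyg_dist"))
  smp <- dm$samples
  if (is.null(smp$tissue) || is.null(smp$side))
    stop("samples must carry 'tissue' and 'side' labels")
  n <- nrow(dm$d)
  ut <- upper.tri(dm$d)
  all_vals <- dm$d[ut]
  global_mean <- mean(all_vals, na.rm = TRUE)
  idx_i <- row(dm$d)[ut]; idx_j <- col(dm$d)[ut]

  summarize <- function(vals) {
    vals <- vals[!is.na(vals)]
    m <- if (length(vals)) mean(vals) else NA_real_
    sem <- if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals))
           else NA_real_
    p <- if (length(vals) > 1 && stats::sd(vals) > 0)
      stats::t.test(vals, mu = global_mean)$p.value else NA_real_
    c(mean = m, sem = sem, n = length(vals), p_value = p)
  }

  rows <- list()
  groups <- unique(smp[, c("tissue", "side")])
  for (g in seq_len(nrow(groups))) {
    tis <- groups$tissue[g]; sd_ <- groups$side[g]
    member <- smp$tissue == tis & smp$side == sd_
    in_i <- member[idx_i]; in_j <- member[idx_j]
    intra <- summarize(all_vals[in_i & in_j])
    inter <- summarize(all_vals[xor(in_i, in_j)])
    rows[[length(rows) + 1]] <- data.frame(
      tissue = tis, side = sd_, metric = c("intra_tissue", "inter_tissue"),
      mean = c(intra["mean"], inter["mean"]),
      sem = c(intra["sem"], inter["sem"]),
      n = c(intra["n"], inter["n"]),
      p_value = c(intra["p_value"], inter["p_value"]),
      stringsAsFactors = FALSE)
    if (!is.null(zygote_distances)) {
      zv <- zygote_distances[smp$clone[member]]
      zs <- summarize(zv)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tis, side = sd_, metric = "to_zygote",
        mean = zs["mean"], sem = zs["sem"], n = zs["n"],
        p_value = zs["p_value"], stringsAsFactors = FALSE)
    }
  }
  for (tis in unique(smp$tissue)) {
    left <- smp$tissue == tis & smp$side == "left"
    right <- smp$tissue == tis & smp$side == "right"
    if (!any(left) || !any(right)) next
    lr <- (left[idx_i] & right[idx_j]) | (right[idx_i] & left[idx_j])
    s <- summarize(all_vals[lr])
    rows[[length(rows) + 1]] <- data.frame(
      tissue = tis, side = NA_character_, metric = "left_to_right",
      mean = s["mean"], sem = s["sem"], n = s["n"], p_value = s["p_value"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "global_mean") <- global_mean
  class(out) <- c("tissue_distance_summary", "data.frame")
  out
}

#' Pearson correlation of tissue-pair distances between two individuals
#'
#' Given matched vectors of distances for the same tissue pairs measured in
#' two individuals, quantifies how conserved the tissue relationships are.
#'
#' @param x,y Numeric vectors of tissue-pair distances, matched by position
#'   (>= 3 pairs).
#' @return A list: `r` (Pearson correlation), `r_squared`, `p` (two-sided),
#'   `n`.
#' @export
cross_individual_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 shared tissue pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param dm A [distance_matrix()] result.
#' @param path Output path.
#' @param format `"tsv"` (square, with header) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  stopifnot(inherits(dm, "polyg_dist"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(clone = rownames(dm$d), dm$d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm$d)), con)
    for (i in seq_len(nrow(dm$d)))
      writeLines(paste(formatC(rownames(dm$d)[i], width = -10),
                       paste(sprintf("%.6f", dm$d[i, ]), collapse = " ")),
                 con)
  }
  invisible(path)
}
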