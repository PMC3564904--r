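#' Genotype matrix of single-cell clones at polyG loci
#'
#' The central container of the package: diploid allele-length calls (in bp)
#' for a set of clonally expanded single cells across a panel of polyguanine
#' loci. Each call occupies two allele slots; a missing allele (an "X" call in
#' fragment analysis) is stored as `NA`. Clone metadata (tissue, body side,
#' mouse of origin, split-clone pair id) travel with the matrix.
#'
#' @param a1,a2 Integer matrices (clones x loci) holding the two allele
#'   lengths per call; `NA` marks a missing allele. Must share dimensions.
#' @param samples Data frame of clone metadata with at least a `clone`
#'   column; optional columns `tissue`, `side`, `mouse`, `split_pair`.
#'   Row order must match the rows of `a1`.
#' @param loci Character vector of locus identifiers (defaults to the column
#'   names of `a1`).
#' @return An object of class `genotype_matrix`.
#' @examples
#' a1 <- matrix(c(106L, 106L), 2, 1, dimnames = list(c("c1", "c2"), "L1"))
#' a2 <- matrix(c(103L, 104L), 2, 1, dimnames = list(c("c1", "c2"), "L1"))
#' gm <- genotype_matrix(a1, a2, data.frame(clone = c("c1", "c2")))
#' gm
#' @export
genotype_matrix <- function(a1, a2, samples = NULL, loci = colnames(a1)) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices 'a1' and 'a2' must have identical dimensions")
  n <- nrow(a1)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (anyDuplicated(loci)) stop("locus ids must be unique")
  if (is.null(samples)) {
    ids <- rownames(a1)
    if (is.null(ids)) ids <- paste0("clone", seq_len(n))
    samples <- data.frame(clone = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples)
  if (is.null(samples$clone)) stop("'samples' must contain a 'clone' column")
  samples$clone <- as.character(samples$clone)
  if (nrow(samples) != n)
    stop("'samples' must have one row per clone (", n, " expected)")
  if (anyDuplicated(samples$clone)) stop("clone ids must be unique")
  dimnames(a1) <- dimnames(a2) <- list(samples$clone, loci)
  structure(
    list(a1 = a1, a2 = a2, samples = samples, loci = as.character(loci)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("polyG genotype matrix: ", nrow(x$a1), " clones x ", length(x$loci),
      " loci\n", sep = "")
  miss <- mean(is.na(x$a1) | is.na(x$a2))
  cat(sprintf("calls with >=1 missing allele: %.1f%%\n", 100 * miss))
  extra <- intersect(c("tissue", "side", "mouse"), names(x$samples))
  if (length(extra))
    for (col in extra) {
      tab <- table(x$samples[[col]])
      cat(col, ": ", paste0(names(tab), " (", tab, ")", collapse = ", "),
          "\n", sep = "")
    }
  if (!is.null(attr(x, "founders")))
    cat("parental allele slots assigned\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Subset a genotype matrix by clones and/or loci
#'
#' @param x A [genotype_matrix()].
#' @param i Clone index (integer, logical, or clone ids).
#' @param j Locus index (integer, logical, or locus ids).
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected clones and loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  if (is.character(i)) i <- match(i, x$samples$clone)
  gm <- genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                        samples = x$samples[i, , drop = FALSE])
  f <- attr(x, "founders")
  if (!is.null(f)) attr(gm, "founders") <- f[j, , drop = FALSE]
  gm
}

#' Extract one clone's genotype as a 2 x loci allele matrix
#'
#' @param x A [genotype_matrix()].
#' @param clone Clone id or row index.
#' @return Integer matrix with two rows (allele slots) and one column per
#'   locus; `NA` marks missing alleles.
#' @export
clone_genotype <- function(x, clone) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.character(clone)) clone <- match(clone, x$samples$clone)
  if (is.na(clone)) stop("unknown clone")
  rbind(x$a1[clone, ], x$a2[clone, ])
}

format_call <- function(a, b) {
  fa <- ifelse(is.na(a), "X", as.character(a))
  fb <- ifelse(is.na(b), "X", as.character(b))
  paste0(fa, "/", fb)
}

#' Read a genotype table
#'
#' Parses a rectangular tab- or comma-separated table with clones as rows and
#' loci as columns, cells written as `"106/105"`, `"106/X"` or `"X/X"`
#' (the layout used for the per-mouse genotype data tables). An optional
#' sidecar sample sheet supplies clone metadata.
#'
#' @param path Path to the genotype table. The first column must hold clone
#'   ids.
#' @param samples Optional path to a TSV sample sheet with a `clone` column
#'   and metadata columns (`tissue`, `side`, `mouse`, `split_pair`), or a
#'   data frame of the same shape.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, samples = NULL, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  loci <- colnames(raw)
  clones <- rownames(raw)
  n <- nrow(raw); L <- ncol(raw)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  pat <- "^([0-9]+|X)/([0-9]+|X)$"
  for (j in seq_len(L)) {
    cell <- as.character(raw[[j]])
    ok <- grepl(pat, cell)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("unparseable genotype cell '", cell[bad], "' at clone '",
           clones[bad], "', locus '", loci[j], "'")
    }
    p1 <- sub(pat, "\\1", cell)
    p2 <- sub(pat, "\\2", cell)
    k1 <- p1 != "X"; k2 <- p2 != "X"
    a1[k1, j] <- as.integer(p1[k1])
    a2[k2, j] <- as.integer(p2[k2])
  }
  rownames(a1) <- rownames(a2) <- clones
  colnames(a1) <- colnames(a2) <- loci
  smp <- data.frame(clone = clones, stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    sheet <- if (is.data.frame(samples)) samples else
      utils::read.table(samples, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    if (is.null(sheet$clone)) stop("sample sheet must contain a 'clone' column")
    idx <- match(clones, sheet$clone)
    if (anyNA(idx))
      stop("sample sheet is missing clones: ",
           paste(clones[is.na(idx)], collapse = ", "))
    smp <- sheet[idx, , drop = FALSE]
    rownames(smp) <- NULL
  }
  genotype_matrix(a1, a2, samples = smp, loci = loci)
}

#' Write a genotype table (with optional sample sheet)
#'
#' Inverse of [read_genotype_table()]: cells are written as `"a/b"` with
#' missing alleles as `"X"`. Round-trips losslessly.
#'
#' @param x A [genotype_matrix()].
#' @param path Output path for the genotype table.
#' @param samples_path Optional path for the sample-sheet TSV.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, samples_path = NULL, sep = "\t") {
  stopifnot(inherits(x, "genotype_matrix"))
  cells <- matrix(format_call(x$a1, x$a2), nrow = nrow(x$a1),
                  dimnames = dimnames(x$a1))
  df <- data.frame(clone = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
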