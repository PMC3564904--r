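# Independent oracles and fixture builders, written separately from the
# package implementation.

# Brute-force diploid distance: literal translation of the rules, loop form.
oracle_pair_distance <- function(ga, gb) {
  total <- 0
  usable <- 0
  for (l in seq_len(ncol(ga))) {
    alleles <- c(ga[1, l], ga[2, l], gb[1, l], gb[2, l])
    n_missing <- sum(is.na(alleles))
    if (n_missing > 1) next
    if (n_missing == 0) {
      pairing1 <- abs(ga[1, l] - gb[1, l]) + abs(ga[2, l] - gb[2, l])
      pairing2 <- abs(ga[1, l] - gb[2, l]) + abs(ga[2, l] - gb[1, l])
      best <- min(pairing1, pairing2)
    } else {
      if (is.na(ga[1, l]) || is.na(ga[2, l])) {
        known <- ga[!is.na(ga[, l]), l]
        other <- gb[, l]
      } else {
        known <- gb[!is.na(gb[, l]), l]
        other <- ga[, l]
      }
      best <- min(abs(known - other[1]), abs(known - other[2]))
    }
    total <- total + best
    usable <- usable + 1
  }
  if (usable == 0) NA_real_ else total / usable
}

# Union-find connected components of a thresholded distance graph.
oracle_components <- function(D, threshold) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(D[i, j]) && D[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Recursive Colless index: sum over internal nodes of |tips left - tips right|.
oracle_colless <- function(tree) {
  n <- length(tree$tip.label)
  children_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tip_count <- function(node) {
    if (node <= n) return(1L)
    sum(vapply(children_of(node), tip_count, integer(1)))
  }
  walk <- function(node) {
    if (node <= n) return(0L)
    ch <- children_of(node)
    stopifnot(length(ch) == 2)
    abs(tip_count(ch[1]) - tip_count(ch[2])) + walk(ch[1]) + walk(ch[2])
  }
  walk(n + 1L)
}

# Random diploid genotype pair with controllable missingness, for distance
# oracle sweeps.
random_genotype_pair <- function(missing_prob = 0.15) {
  L <- sample(1:6, 1)
  draw <- function() {
    m <- matrix(sample(95:115, 2 * L, replace = TRUE), nrow = 2)
    m[matrix(runif(2 * L) < missing_prob, nrow = 2)] <- NA_integer_
    m
  }
  list(ga = draw(), gb = draw())
}

# Tissue-level undirected edge keys of a similarity network (independent of
# the package's internal helper).
tissue_edge_keys_for_test <- function(nw) {
  t1 <- nw$nodes$tissue[match(nw$edges$from, nw$nodes$clone)]
  t2 <- nw$nodes$tissue[match(nw$edges$to, nw$nodes$clone)]
  unique(paste(pmin(t1, t2), pmax(t1, t2), sep = "--"))
}

# Random genotype matrix fixture.
random_gm <- function(n = 12, L = 15, missing_prob = 0.05, tissues = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- sample(95:110, L, replace = TRUE)
  a1 <- matrix(rep(base, each = n) + sample(-2:2, n * L, replace = TRUE), n, L)
  a2 <- matrix(rep(base + 4, each = n) + sample(-2:2, n * L, replace = TRUE),
               n, L)
  a1[matrix(runif(n * L) < missing_prob, n, L)] <- NA_integer_
  a2[matrix(runif(n * L) < missing_prob, n, L)] <- NA_integer_
  smp <- data.frame(clone = sprintf("c%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  if (!is.null(tissues)) {
    smp$tissue <- rep_len(tissues, n)
    smp$side <- rep_len(c("left", "right"), n)
  }
  rownames(a1) <- rownames(a2) <- smp$clone
  colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(L))
  genotype_matrix(a1, a2, samples = smp)
}
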