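test_that("N-bar matches closed forms on balanced and pectinate trees", {
  # complete balanced tree with 2^k tips: N-bar = k
  for (k in 1:6)
    expect_equal(nbar(ape::stree(2^k, "balanced")), k)
  # caterpillar with n tips: N-bar = (n - 1)(n + 2) / (2n)
  for (n in 3:50)
    expect_equal(nbar(ape::stree(n, "left")),
                 (n - 1) * (n + 2) / (2 * n))
  # the two-tip tree (caterpillar = balanced) has N-bar 1
  expect_equal(nbar(ape::stree(2, "balanced")), 1)
  expect_equal(round(nbar(ape::stree(14, "left")), 2), 7.43)
  single <- ape::read.tree(text = "(a);")
  expect_error(nbar(single), "single-tip")
})

test_that("N-bar handles multifurcations directly", {
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_equal(nbar(star), 1)
  mixed <- ape::read.tree(text = "((a,b,c),d);")
  expect_equal(nbar(mixed), (2 + 2 + 2 + 1) / 4)
})

test_that("Colless index matches closed forms and the recursive oracle", {
  expect_identical(colless(ape::stree(8, "balanced"))$colless_raw, 0L)
  for (n in c(4, 6, 10, 20)) {
    cs <- colless(ape::stree(n, "left"))
    expect_identical(cs$colless_raw, as.integer((n - 1) * (n - 2) / 2))
    expect_equal(cs$colless_normalized, 1)
  }
  expect_identical(colless(ape::stree(6, "left"))$colless_raw, 10L)
  # random bifurcating trees vs independent recursion
  set.seed(55)
  for (i in 1:25) {
    tree <- ape::rtree(sample(4:12, 1))
    expect_identical(colless(tree)$colless_raw, oracle_colless(tree),
                     info = paste("tree", i))
  }
  # multifurcations: rejected in strict mode, resolvable with a seed
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_error(colless(star), "multifurcations")
  r1 <- colless(star, multifurcations = "resolve", seed = 1)
  r2 <- colless(star, multifurcations = "resolve", seed = 1)
  expect_identical(r1$colless_raw, r2$colless_raw)
})

test_that("genotype randomization preserves per-locus allele multisets", {
  gm <- random_gm(n = 15, L = 10, missing_prob = 0.2, seed = 6)
  r <- randomize_genotypes(gm, seed = 11)
  for (l in seq_len(10)) {
    before <- sort(unname(c(gm$a1[, l], gm$a2[, l])), na.last = TRUE)
    after <- sort(unname(c(r$a1[, l], r$a2[, l])), na.last = TRUE)
    expect_identical(after, before)
  }
  # allele pairs travel together
  key_before <- sort(paste(gm$a1[, 3], gm$a2[, 3]))
  key_after <- sort(paste(r$a1[, 3], r$a2[, 3]))
  expect_identical(key_after, key_before)
  # reproducible given the seed; single clone unchanged
  expect_identical(randomize_genotypes(gm, seed = 11)$a1, r$a1)
  one <- gm[1, ]
  expect_identical(randomize_genotypes(one, seed = 5)$a1, one$a1)
})

test_that("randomization destroys the lineage signal", {
  # single-progenitor tissues: every intra-tissue pair coalesces after
  # commitment, giving structural (not sampling-driven) tissue cohesion
  sim <- simulate_lineage(lineage_config(
    n_loci = 80, cells_per_tissue = 8, split_clone_pairs = 0,
    commitment_schedule = data.frame(tissue = c("fib", "end"),
                                     side = "left",
                                     generation = c(10L, 10L),
                                     pool_size = c(1L, 1L)),
    n_generations = 20, missing_rate = 0, seed = 44))
  gm <- sim$genotypes
  gap <- function(g) {
    dm <- distance_matrix(g)
    tis <- g$samples$tissue
    ut <- upper.tri(dm$d)
    same <- outer(tis, tis, "==")[ut]
    mean(dm$d[ut][!same]) - mean(dm$d[ut][same])
  }
  observed_gap <- gap(gm)
  null_gaps <- vapply(1:20, function(b)
    gap(randomize_genotypes(gm, seed = b)), numeric(1))
  expect_gt(observed_gap, max(abs(null_gaps)))
  expect_lt(abs(mean(null_gaps)), observed_gap / 4)
})

test_that("recoding maps alleles to digits by descending frequency", {
  a1 <- matrix(c(rep(106L, 5), rep(105L, 3), 107L), ncol = 1)
  gm <- genotype_matrix(a1, a1 + 10L,
                        data.frame(clone = paste0("c", 1:9)))
  rec <- recode_for_phylogenetics(gm)
  col <- rec$characters[, 1]
  expect_identical(unname(col[1:5]), rep("0", 5))
  expect_identical(unname(col[6:8]), rep("1", 3))
  expect_identical(unname(col[9]), "2")
  # constant column is all zeros; the missing allele slot becomes "?"
  # (parental assignment routes the 106 alleles to the founder-106 slot)
  a1 <- matrix(rep(106L, 4), ncol = 1); a1[2] <- NA
  gm <- genotype_matrix(a1, matrix(rep(103L, 4), ncol = 1),
                        data.frame(clone = paste0("c", 1:4)))
  rec <- recode_for_phylogenetics(gm)
  expect_identical(unname(rec$characters[, 1]), rep("0", 4))
  expect_identical(unname(rec$characters[, 2]), c("0", "?", "0", "0"))
})

test_that("NEXUS standard-datatype files round-trip", {
  gm <- random_gm(n = 6, L = 5, missing_prob = 0.15, seed = 31)
  rec <- recode_for_phylogenetics(gm)
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus(rec, path)
  txt <- readLines(path)
  expect_identical(txt[1], "#NEXUS")
  expect_true(any(grepl("DATATYPE=STANDARD", txt)))
  expect_true(any(grepl("shapepr=uniform\\(0.05,50\\)", txt)))
  back <- read_nexus_characters(path)
  expect_identical(unname(back), unname(rec$characters))
  expect_identical(rownames(back), rownames(rec$characters))
})

test_that("UPGMA trees recover known structure deterministically", {
  # three taxa: the close pair forms the cherry
  D <- matrix(c(0, 0.1, 0.4, 0.1, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- build_distance_tree(D)
  cherry <- ape::prop.part(tree)
  expect_true(any(vapply(cherry, function(p)
    setequal(tree$tip.label[p], c("a", "b")), logical(1))))
  # ultrametric matrix from a known tree: exact topology recovery
  set.seed(10)
  true_tree <- ape::rcoal(8)
  D <- ape::cophenetic.phylo(true_tree)
  rec <- build_distance_tree(D)
  expect_equal(phangorn::RF.dist(rec, true_tree, rooted = TRUE), 0)
  # permuting input labels permutes tips only
  perm <- sample(8)
  rec2 <- build_distance_tree(D[perm, perm])
  expect_equal(phangorn::RF.dist(rec2, rec, rooted = TRUE), 0)
  # undefined distances are refused
  Dna <- D; Dna[1, 2] <- Dna[2, 1] <- NA
  expect_error(build_distance_tree(Dna), "undefined")
})

test_that("shape null comparison returns calibrated distributions", {
  gm <- random_gm(n = 16, L = 25, missing_prob = 0, seed = 91)
  dm <- distance_matrix(gm)
  tree <- build_distance_tree(dm)
  expect_warning(shape_null_comparison(tree, gm, n_randomizations = 5,
                                       seed = 1), "fewer than 10")
  res <- shape_null_comparison(tree, gm, n_randomizations = 30, seed = 2)
  expect_identical(nrow(res$null), 30L)
  expect_identical(nrow(res$observed), 1L)
  # genotypes without lineage signal: observed shape is typical of the null
  expect_gt(res$p_lower[["nbar"]], 0.01)
})
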