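small_schedule <- function() {
  data.frame(tissue = rep(c("fib", "end"), each = 2),
             side = rep(c("left", "right"), 2),
             generation = c(5L, 5L, 8L, 8L), pool_size = c(6L, 6L, 3L, 3L),
             stringsAsFactors = FALSE)
}

test_that("config invariants are enforced", {
  expect_error(lineage_config(mu = 1.5), "mu")
  expect_error(lineage_config(step_probabilities = c("-1" = 0.4, "1" = 0.4)),
               "sum to 1")
  expect_error(lineage_config(step_probabilities = c("0" = 1)), "not a mutation")
  sch <- small_schedule(); sch$generation[1] <- 45L
  expect_error(lineage_config(commitment_schedule = sch), "n_generations")
  sch <- small_schedule(); sch$pool_size[1] <- 0L
  expect_error(lineage_config(commitment_schedule = sch), "pool")
})

test_that("a zero mutation rate reproduces the zygote in every clone", {
  cfg <- lineage_config(n_loci = 25, mu = 0, missing_rate = 0,
                        commitment_schedule = small_schedule(),
                        cells_per_tissue = 5, split_clone_pairs = 0,
                        n_generations = 12, seed = 3)
  sim <- simulate_lineage(cfg)
  z <- sim$truth$zygote
  for (i in seq_len(nrow(sim$genotypes$a1))) {
    expect_identical(unname(sim$genotypes$a1[i, ]), unname(z[1, ]))
    expect_identical(unname(sim$genotypes$a2[i, ]), unname(z[2, ]))
  }
  dm <- distance_matrix(sim$genotypes)
  expect_true(all(dm$d == 0))
})

test_that("simulation is bit-identical given the seed", {
  cfg <- lineage_config(n_loci = 30, cells_per_tissue = 6,
                        commitment_schedule = small_schedule(),
                        n_generations = 15, seed = 99)
  s1 <- simulate_lineage(cfg)
  s2 <- simulate_lineage(cfg)
  expect_identical(s1$genotypes$a1, s2$genotypes$a1)
  expect_identical(s1$genotypes$a2, s2$genotypes$a2)
  expect_identical(s1$truth$separations, s2$truth$separations)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("mutation events accumulate at the configured per-division rate", {
  cfg <- lineage_config(seed = 17)  # 110 loci, mu 0.011, 40 generations
  sim <- simulate_lineage(cfg)
  per_tip <- rowSums(sim$truth$tip_events)
  expected <- 0.011 * 40 * 110
  # single-tip SD is ~sqrt(expected); tips share ancestry, so use a
  # conservative effective sample size of 10 for the 3-SE band
  tol <- 3 * sqrt(expected) / sqrt(10)
  expect_lt(abs(mean(per_tip) - expected), tol)
})

test_that("true tree, separations and genotypes are mutually consistent", {
  cfg <- lineage_config(n_loci = 40, cells_per_tissue = 5,
                        commitment_schedule = small_schedule(),
                        n_generations = 14, split_clone_pairs = 0,
                        missing_rate = 0, seed = 21)
  sim <- simulate_lineage(cfg)
  sep <- sim$truth$separations
  expect_true(isSymmetric(sep))
  expect_true(all(diag(sep) == 0))
  expect_true(all(sep[upper.tri(sep)] > 0))
  expect_true(all(sep %% 2 == 0))  # synchronous divisions, common depth
  # patristic distances on the truth tree (edge lengths in divisions)
  # must equal the path-length separations
  pat <- ape::cophenetic.phylo(sim$tree)
  ids <- rownames(sep)
  expect_equal(unname(pat[ids, ids]), unname(sep))
})

test_that("split-clone duplicates are identical before masking", {
  cfg <- lineage_config(n_loci = 30, cells_per_tissue = 5,
                        commitment_schedule = small_schedule(),
                        n_generations = 12, split_clone_pairs = 2,
                        missing_rate = 0.1, seed = 8)
  sim <- simulate_lineage(cfg)
  pre <- sim$truth$genotypes_premasking
  smp <- pre$samples
  pairs <- split(smp$clone, smp$split_pair)
  expect_length(pairs, 2)
  for (p in pairs) {
    expect_length(p, 2)
    d <- pairwise_distance(clone_genotype(pre, p[1]),
                           clone_genotype(pre, p[2]))
    expect_identical(d$distance, 0)
  }
})

test_that("infeasible progenitor pools raise an explicit error", {
  sch <- data.frame(tissue = "fib", side = "left", generation = 2L,
                    pool_size = 10L)
  cfg <- lineage_config(commitment_schedule = sch, n_generations = 10)
  expect_error(simulate_lineage(cfg), "infeasible sampling")
})

test_that("mean distance tracks mu * separation in the linear clock regime", {
  cfg <- lineage_config(
    n_loci = 3000, mu = 0.013, n_generations = 10, missing_rate = 0,
    split_clone_pairs = 0, cells_per_tissue = 8,
    commitment_schedule = data.frame(tissue = "t",
                                     side = c("left", "right"),
                                     generation = c(5L, 5L),
                                     pool_size = c(4L, 4L)),
    seed = 31)
  sim <- simulate_lineage(cfg)
  dm <- distance_matrix(sim$genotypes)
  sep <- sim$truth$separations
  ut <- upper.tri(sep)
  for (s in unique(sep[ut])) {
    vals <- dm$d[ut][sep[ut] == s]
    if (length(vals) < 5) next             # too few pairs to average noise
    d_mean <- mean(vals)
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(d_mean, 0.013 * s + 3 * se + 0.002)  # never above the clock
    if (0.013 * s >= 0.04 && 0.013 * s <= 0.11)    # linear regime
      expect_lt(abs(d_mean / (0.013 * s) - 1), 0.07)
  }
})

test_that("subclone experiment matches its Bernoulli expectation", {
  cfg0 <- subclone_config(mu = 0, seed = 4)
  g0 <- simulate_subclone_experiment(cfg0)
  expect_true(all(g0$a1 == g0$a1[rep(1, nrow(g0$a1)), ]))
  expect_identical(sum(attr(g0, "truth")), 0L)

  cfg <- subclone_config(mu = 0.012, n_subclones = 12, doublings = 20,
                         n_loci = 110, seed = 5)
  g <- simulate_subclone_experiment(cfg)
  total_events <- sum(attr(g, "truth"))
  expect_lt(abs(total_events - 316.8), 3 * sqrt(316.8))
  g2 <- simulate_subclone_experiment(cfg)
  expect_identical(g$a1, g2$a1)
})

test_that("peak profiles round-trip through the genotype caller", {
  # clean homozygote without stutter: one dominant peak
  tri <- simulate_peak_profiles(c(106, 106), stutter_ratio = 0, seed = 1)
  for (rep in tri) expect_identical(rep$size[which.max(rep$intensity)], 106L)
  call <- call_locus_genotype(tri)
  expect_identical(call$status, "homozygous")
  expect_identical(call$allele_a, 106L)

  # heterozygote with stutter is recovered
  call <- call_locus_genotype(
    simulate_peak_profiles(c(106, 103), stutter_ratio = 0.2, seed = 2))
  expect_identical(call$status, "heterozygous")
  expect_setequal(c(call$allele_a, call$allele_b), c(106L, 103L))

  # replicate-inconsistent noise forces an ambiguous call
  call <- call_locus_genotype(
    simulate_peak_profiles(c(106, 103), stutter_ratio = 0.2,
                           inconsistent = TRUE, seed = 3))
  expect_identical(call$status, "ambiguous")
})
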