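profile <- function(sizes, intensities)
  data.frame(size = as.integer(sizes), intensity = intensities)

test_that("single-replicate intensity rules classify the documented patterns", {
  th <- call_thresholds()  # gap 1e4 U, het ratio 0.8
  # near-equal 2nd and 3rd peaks: homozygote
  tri <- rep(list(profile(c(106, 101, 98), c(30000, 5000, 3000))), 3)
  call <- call_locus_genotype(tri, th)
  expect_identical(call$status, "homozygous")
  expect_identical(c(call$allele_a, call$allele_b), c(106L, 106L))
  # strong second peak above 0.8 of the top: heterozygote
  tri <- rep(list(profile(c(106, 105, 99), c(30000, 26000, 4000))), 3)
  call <- call_locus_genotype(tri, th)
  expect_identical(call$status, "heterozygous")
  expect_identical(c(call$allele_a, call$allele_b), c(106L, 105L))
  # in-between pattern: ambiguous with the top allele retained
  tri <- rep(list(profile(c(106, 104, 99), c(30000, 16000, 2000))), 3)
  call <- call_locus_genotype(tri, th)
  expect_identical(call$status, "ambiguous")
  expect_identical(call$allele_a, 106L)
  expect_true(is.na(call$allele_b))
})

test_that("non-reproducible triplicates are assigned ambiguously", {
  hom <- profile(c(106, 101, 98), c(30000, 5000, 3000))
  het <- profile(c(106, 105, 99), c(30000, 26000, 4000))
  call <- call_locus_genotype(list(hom, het, hom))
  expect_identical(call$status, "ambiguous")
  expect_identical(call$allele_a, 106L)   # shared top allele survives
  # replicates with different top peaks lose both alleles
  other <- profile(c(110, 104, 99), c(30000, 5000, 3000))
  call <- call_locus_genotype(list(hom, other, hom))
  expect_true(is.na(call$allele_a) && is.na(call$allele_b))
  # short or empty replicates are padded / treated as ambiguous
  call <- call_locus_genotype(list(profile(106, 30000), profile(106, 30000),
                                   profile(106, 30000)))
  expect_identical(call$status, "homozygous")
  call <- call_locus_genotype(list(hom, hom, profile(integer(0), numeric(0))))
  expect_identical(call$status, "ambiguous")
})

test_that("parental allele assignment minimizes implied mutations", {
  mk <- function(a1, a2) genotype_matrix(
    matrix(a1, ncol = 1), matrix(a2, ncol = 1),
    data.frame(clone = paste0("c", seq_along(a1))))
  # uniform heterozygote: founders are the two lengths, zero mutations
  gm <- assign_parental_alleles(mk(c(106L, 106L, 106L), c(103L, 103L, 103L)))
  f <- attr(gm, "founders")
  expect_setequal(c(f$founder1, f$founder2), c(103L, 106L))
  # one deviant allele maps onto the nearer founder (one mutation, 107<-106)
  gm <- assign_parental_alleles(mk(c(106L, 107L, 106L), c(103L, 103L, 103L)))
  f <- attr(gm, "founders")
  expect_setequal(c(f$founder1, f$founder2), c(103L, 106L))
  slot106 <- if (f$founder1 == 106L) gm$a1 else gm$a2
  expect_identical(unname(slot106[, 1]), c(106L, 107L, 106L))
  # homozygous-only locus: both founders equal
  gm <- assign_parental_alleles(mk(c(106L, 106L), c(106L, 106L)))
  f <- attr(gm, "founders")
  expect_identical(c(f$founder1, f$founder2), c(106L, 106L))
  # all-missing locus is flagged
  gm <- assign_parental_alleles(mk(c(NA, NA), c(NA, NA)))
  expect_true(attr(gm, "founders")$all_missing)
})

test_that("consensus takes the per-slot mode with the smaller-length tie-break", {
  a1 <- matrix(c(106L, 106L, 106L, 106L, 106L, 105L, 105L), ncol = 1)
  a2 <- matrix(rep(103L, 7), ncol = 1)
  gm <- genotype_matrix(a1, a2, data.frame(clone = paste0("c", 1:7)))
  cons <- consensus_genotype(gm)
  expect_identical(unname(cons[, 1]), c(106L, 103L))
  # tie 3 vs 3 goes to the smaller length
  a1 <- matrix(c(106L, 106L, 106L, 105L, 105L, 105L), ncol = 1)
  gm <- genotype_matrix(a1, a1, data.frame(clone = paste0("c", 1:6)))
  expect_identical(unname(consensus_genotype(gm)[1, 1]), 105L)
  # identical rows: consensus is idempotent
  gm <- random_gm(n = 1, L = 6, missing_prob = 0, seed = 5)
  rep5 <- genotype_matrix(gm$a1[rep(1, 5), ], gm$a2[rep(1, 5), ],
                          data.frame(clone = paste0("c", 1:5)))
  cons <- consensus_genotype(rep5)
  expect_identical(unname(cons[1, ]), unname(gm$a1[1, ]))
  expect_identical(unname(cons[2, ]), unname(gm$a2[1, ]))
})

test_that("somatic mutation summaries count per allele slot", {
  gm <- random_gm(n = 10, L = 110, missing_prob = 0, seed = 11)
  ref <- consensus_genotype(gm)
  # the reference itself carries no mutations
  ref_gm <- genotype_matrix(matrix(ref[1, ], 2, 110, byrow = TRUE),
                            matrix(ref[2, ], 2, 110, byrow = TRUE),
                            data.frame(clone = c("r1", "r2")))
  res <- identify_somatic_mutations(ref_gm, ref)
  expect_true(all(res$per_clone$n_mutant_alleles == 0))
  expect_true(all(res$per_clone$fraction_mutated == 0))
  # a clone differing at exactly 3 of 110 loci
  a1 <- matrix(ref[1, ], 1, 110); a2 <- matrix(ref[2, ], 1, 110)
  a1[1, c(4, 40, 90)] <- a1[1, c(4, 40, 90)] + 1L
  one <- genotype_matrix(rbind(a1, matrix(ref[1, ], 1, 110)),
                         rbind(a2, matrix(ref[2, ], 1, 110)),
                         data.frame(clone = c("mut", "wt")))
  res <- identify_somatic_mutations(one, ref)
  expect_equal(res$per_clone$fraction_mutated[1], 3 / 110)
  expect_identical(res$per_clone$n_mutant_alleles[1], 3)
  expect_identical(sum(res$per_locus$n_distinct_mutant_alleles), 3L)
})

test_that("mutation-rate estimator reproduces the pooled-ratio arithmetic", {
  # parent + 12 subclones at 110 loci; plant 22 single-bp changes per
  # subclone -> 264 new mutations -> 264 / (12 * 20 * 110) = 0.010
  L <- 110
  parent1 <- rep(106L, L); parent2 <- rep(103L, L)
  a1 <- matrix(parent1, 13, L, byrow = TRUE)
  a2 <- matrix(parent2, 13, L, byrow = TRUE)
  set.seed(42)
  for (s in 2:13) {
    loci <- sample(L, 22)
    a1[s, loci] <- a1[s, loci] + sample(c(-1L, 1L), 22, replace = TRUE)
  }
  gm <- genotype_matrix(a1, a2, data.frame(clone = c("parent",
                                                     sprintf("s%02d", 1:12))))
  est <- estimate_mutation_rate(gm, doublings = 20, parent = "parent")
  expect_equal(est$rate, 0.010)
  expect_equal(est$n_new_mutations, 264)
  expect_equal(nrow(est$per_subclone), 12)
  # no new mutations -> rate 0
  gm0 <- genotype_matrix(matrix(parent1, 3, L, byrow = TRUE),
                         matrix(parent2, 3, L, byrow = TRUE),
                         data.frame(clone = c("parent", "s1", "s2")))
  expect_equal(estimate_mutation_rate(gm0, doublings = 20)$rate, 0)
  expect_error(estimate_mutation_rate(gm, doublings = 0), "positive")
})

test_that("simulated rate assay recovers the true mutation rate", {
  g <- simulate_subclone_experiment(subclone_config(mu = 0.012, seed = 7))
  est <- estimate_mutation_rate(g, doublings = 20, parent = "parent")
  expect_lt(abs(est$rate - 0.012), 3 * est$se)
})

test_that("random genotypes survive the peak-simulation/calling round trip", {
  set.seed(9)
  for (i in 1:25) {
    if (runif(1) < 0.4) {
      alleles <- rep(sample(95:115, 1), 2)
    } else {
      a <- sample(95:115, 1)
      alleles <- c(a, a - sample(2:6, 1))
    }
    tri <- simulate_peak_profiles(alleles, stutter_ratio = 0.15,
                                  seed = 1000 + i)
    call <- call_locus_genotype(tri)
    expect_false(call$status == "ambiguous")
    expect_setequal(c(call$allele_a, call$allele_b), unique(alleles))
  }
})

test_that("long peak tables are called into a genotype matrix", {
  rows <- list()
  for (cl in c("c1", "c2")) for (lo in c("L1", "L2")) {
    alleles <- if (cl == "c1") c(106L, 103L) else c(106L, 106L)
    tri <- simulate_peak_profiles(alleles, stutter_ratio = 0.15,
                                  seed = nchar(cl) + nchar(lo) +
                                    match(cl, c("c1", "c2")) * 10 +
                                    match(lo, c("L1", "L2")))
    for (r in 1:3)
      rows[[length(rows) + 1]] <- data.frame(
        clone = cl, locus = lo, replicate = r,
        size = tri[[r]]$size, intensity = tri[[r]]$intensity)
  }
  peaks <- do.call(rbind, rows)
  gm <- call_genotype_table(peaks)
  expect_identical(dim(gm), c(2L, 2L))
  expect_setequal(c(gm$a1["c1", "L1"], gm$a2["c1", "L1"]), c(106L, 103L))
  expect_identical(c(gm$a1["c2", "L2"], gm$a2["c2", "L2"]), c(106L, 106L))
})
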