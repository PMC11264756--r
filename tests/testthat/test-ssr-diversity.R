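test_that("locus summaries reproduce the closed-form diversity statistics", {
  # biallelic with p = (0.5, 0.5): He 0.5, PIC 0.375
  g2 <- genotype_matrix(rbind(c("a"), c("b")), rbind(c("a"), c("b")),
                        c("i1", "i2"), "L1")
  s2 <- locus_summaries(g2)
  expect_equal(s2$He, 0.5)
  expect_equal(s2$PIC, 0.375)
  expect_equal(s2$Ho, 0)
  expect_equal(s2$allele_count, 2L)

  # four equifrequent alleles: He 0.75, PIC 0.703125
  g4 <- genotype_matrix(rbind("a", "c"), rbind("b", "d"),
                        c("i1", "i2"), "L1")
  s4 <- locus_summaries(g4)
  expect_equal(s4$He, 0.75)
  expect_equal(s4$PIC, 0.703125)
  expect_equal(s4$Ho, 1)

  # monomorphic: everything zero except data-driven Ho
  g1 <- genotype_matrix(rbind("a", "a"), rbind("a", "a"),
                        c("i1", "i2"), "L1")
  s1 <- locus_summaries(g1)
  expect_equal(s1$He, 0); expect_equal(s1$PIC, 0); expect_equal(s1$Ho, 0)

  # all-missing locus excluded with warning
  gm <- genotype_matrix(cbind(c("a", "b"), c(NA, NA)),
                        cbind(c("a", "b"), c(NA, NA)),
                        c("i1", "i2"), c("L1", "L2"))
  expect_warning(sm <- locus_summaries(gm), "L2")
  expect_equal(sm$locus, "L1")
})

test_that("PIC never exceeds He and both vanish exactly for monomorphic loci", {
  for (s in 1:10) {
    sim <- simulate_genotypes(n_pops = 2, n_per_pop = 8, n_loci = 12,
                              fst = 0.1, seed = 100 + s)
    su <- locus_summaries(sim$genotypes)
    expect_true(all(su$PIC <= su$He + 1e-12))
    mono <- su$allele_count == 1L
    expect_true(all(su$He[mono] == 0) && all(su$PIC[mono] == 0))
    expect_true(all(su$He[!mono] > 0) && all(su$PIC[!mono] > 0))
    expect_true(all(su$He <= 1 - 1 / su$allele_count + 1e-12))
  }
})

test_that("panel summaries aggregate allele counts correctly", {
  su <- locus_summaries(genotypes_with_counts(c(2, 5)))
  expect_equal(panel_summary(su)$mean_alleles_per_locus, 3.5)
  su1 <- locus_summaries(genotypes_with_counts(2))
  expect_equal(panel_summary(su1)$mean_alleles_per_locus, 2)
  expect_equal(panel_summary(su1)$total_alleles, 2L)
})

test_that("band presence/absence scores convert to diploid calls", {
  x <- data.frame(
    individual = c("i1", "i1", "i2", "i3", "i3", "i3"),
    locus = "L1",
    band = c("a", "b", "a", "a", "b", "c"),
    present = c(1, 1, 1, 1, 1, 0))
  g <- bands_to_genotypes(x)
  expect_equal(unname(g$a1["i1", "L1"]), "a")
  expect_equal(unname(g$a2["i1", "L1"]), "b")
  expect_equal(unname(g$a1["i2", "L1"]), "a")   # single band: homozygote
  expect_equal(unname(g$a2["i2", "L1"]), "a")
  expect_equal(unname(g$a1["i3", "L1"]), "a")   # third band not scored
  x$present[6] <- 1
  expect_error(bands_to_genotypes(x), "diploid")
})

test_that("genotype tables round-trip through CSV", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,L1,L2", "i1,a/b,c/c", "i2,b/b,", "i3,a/a,c/d"), f)
  g <- read_genotypes(f)
  expect_equal(unname(g$a1["i1", "L1"]), "a")
  expect_equal(unname(g$a2["i1", "L1"]), "b")
  expect_true(is.na(g$a1["i2", "L2"]))
  su <- locus_summaries(g)
  expect_equal(su$allele_count, c(2L, 2L))
})

test_that("identical populations carry no among-population information", {
  # both populations composed of the same calls
  a1 <- rbind("a", "a", "b", "a", "a", "b")
  a2 <- rbind("a", "b", "b", "a", "b", "b")
  g <- genotype_matrix(cbind(a1), cbind(a2), paste0("i", 1:6), "L1")
  pops <- setNames(rep(c("p1", "p2"), each = 3), paste0("i", 1:6))
  res <- shannon_amova(g, pops, permutations = 99, seed = 1)
  expect_equal(res$I_among, 0, tolerance = 1e-12)
  expect_equal(res$table$G[1], 0, tolerance = 1e-9)
  expect_gt(res$table$p[1], 0.5)
})

test_that("fixed alternative alleles give ln(2) mutual information and 100% among-population variance", {
  a <- rbind("a", "a", "a", "b", "b", "b")
  g <- genotype_matrix(cbind(a), cbind(a), paste0("i", 1:6), "L1")
  pops <- setNames(rep(c("p1", "p2"), each = 3), paste0("i", 1:6))
  res <- shannon_amova(g, pops, permutations = 199, seed = 2)
  expect_equal(res$I_among, log(2), tolerance = 1e-12)
  expect_equal(res$table$G[1], 2 * 12 * log(2), tolerance = 1e-9)
  expect_equal(res$table$pct[1], 100, tolerance = 1e-9)
  expect_lt(res$table$p[1], 0.15)  # 10 distinct splits of 6 into 3+3
})

test_that("Shannon AMOVA identities hold and permutation P values are seed-stable", {
  for (s in 1:5) {
    sim <- simulate_genotypes(n_pops = 3, n_per_pop = c(5, 6, 7),
                              n_loci = 10, fst = 0.15, seed = 200 + s,
                              missing_rate = 0.05)
    res <- shannon_amova(sim$genotypes, sim$populations,
                         permutations = 99, seed = 42)
    tab <- res$table
    expect_equal(tab$G[3], tab$G[1] + tab$G[2], tolerance = 1e-9)
    expect_equal(tab$variance[3], tab$variance[1] + tab$variance[2],
                 tolerance = 1e-9)
    expect_equal(tab$pct[1] + tab$pct[2], 100, tolerance = 1e-9)
    expect_equal(tab$df[3], tab$df[1] + tab$df[2])
    expect_equal(tab$df[1], 2)
    expect_equal(tab$df[2], 18 - 3)
    expect_gte(res$I_among, 0)
    res2 <- shannon_amova(sim$genotypes, sim$populations,
                          permutations = 99, seed = 42)
    expect_identical(res$table$p, res2$table$p)
  }
})

test_that("AMOVA table assembly reproduces totals and proportions from components", {
  tab <- amova_table(2, 14, 33.72, 19.82, 3.84, 1.59,
                     p_among = 0.001, p_within = 0.001)
  expect_equal(tab$G[3], 53.54)
  expect_equal(tab$variance[3], 5.43)
  expect_equal(tab$df[3], 16)
  expect_equal(tab$pct[1], 100 * 3.84 / 5.43, tolerance = 1e-12)
  expect_equal(tab$pct[1] + tab$pct[2], 100, tolerance = 1e-12)
})

test_that("Evanno delta-K follows the second-difference definition", {
  # hand-constructed means (-5000, -4000, -3900) with sd(L(2)) = 10
  d <- 10 / sqrt(2)
  runs <- data.frame(
    K = rep(1:3, each = 2),
    lnP = c(-5005, -4995, -4000 - d, -4000 + d, -3905, -3895))
  ek <- evanno_delta_k(runs)
  expect_equal(ek$mean_lnP, c(-5000, -4000, -3900))
  expect_equal(ek$sd_lnP[2], 10, tolerance = 1e-12)
  expect_equal(ek$deltaK[2], abs(-3900 - 2 * (-4000) + (-5000)) / 10,
               tolerance = 1e-12)
  expect_equal(ek$deltaK[2], 90, tolerance = 1e-12)
  expect_true(is.na(ek$deltaK[1]) && is.na(ek$deltaK[3]))

  # linear mean trajectory: zero second difference everywhere
  lin <- data.frame(K = rep(1:4, each = 3),
                    lnP = rep(c(-8000, -7000, -6000, -5000), each = 3) +
                      rep(c(-1, 0, 1), 4))
  ekl <- evanno_delta_k(lin)
  expect_equal(ekl$deltaK[2:3], c(0, 0))

  # invariance to permuting replicates within K
  perm <- runs[c(2, 1, 4, 3, 6, 5), ]
  expect_equal(evanno_delta_k(perm)$deltaK, ek$deltaK)

  # sd = 0 at an interior K is flagged
  degen <- data.frame(K = rep(1:3, each = 2),
                      lnP = c(-5005, -4995, -4000, -4000, -3905, -3895))
  expect_warning(ekd <- evanno_delta_k(degen), "undefined")
  expect_true(is.na(ekd$deltaK[2]))
})
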