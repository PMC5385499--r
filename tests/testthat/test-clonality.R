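test_that("MLG partition matches exact and wildcard duplicates", {
  x <- random_table(n_sites = 1, n_per = 6, L = 8, n_alleles = 6, seed = 2)
  # make 1 and 2 identical at all loci; 3 identical to 1 except one missing
  x$a1[2, ] <- x$a1[1, ]; x$a2[2, ] <- x$a2[1, ]
  x$a1[3, ] <- x$a1[1, ]; x$a2[3, ] <- x$a2[1, ]
  x$a1[3, 5] <- NA; x$a2[3, 5] <- NA
  rep <- find_mlgs(x)
  expect_equal(rep$mlg[1], rep$mlg[2])
  expect_equal(rep$mlg[1], rep$mlg[3])  # wildcard policy bridges the gap
  expect_equal(rep$sites$N, 6L)
  expect_equal(rep$sites$G, 4L)
  # individuals beyond max_missing are singletons flagged unassessed
  x$a1[4, 1:3] <- NA; x$a2[4, 1:3] <- NA
  rep2 <- find_mlgs(x, max_missing = 1L)
  expect_true(rep2$unassessed[4])
  expect_equal(sum(rep2$mlg == rep2$mlg[4]), 1L)
})

test_that("MLG sizes partition each site", {
  for (seed in 1:4) {
    x <- random_table(n_sites = 2, n_per = 8, L = 5, n_alleles = 3,
                      seed = seed)
    rep <- find_mlgs(x)
    per_site <- tapply(rep$mlg, rep$site, function(m) length(m))
    expect_equal(as.vector(per_site), rep$sites$N)
    expect_true(all(rep$sites$G <= rep$sites$N))
    expect_true(all(rep$sites$R >= 0 & rep$sites$R <= 1, na.rm = TRUE))
  }
})

test_that("P_gen follows Hardy-Weinberg genotype probabilities", {
  f1 <- list(c("100" = 0.5, "102" = 0.5))
  expect_equal(p_gen(matrix(c(100, 100), 2, 1), f1), 0.25)
  f2 <- list(c("100" = 0.5, "102" = 0.5), c("200" = 0.5, "202" = 0.5))
  expect_equal(p_gen(matrix(c(100, 102, 200, 202), 2, 2), f2), 0.25)
  # missing locus contributes factor 1
  expect_equal(p_gen(matrix(c(100, 102, NA, NA), 2, 2), f2), 0.5)
  expect_error(p_gen(matrix(c(104, 104), 2, 1), f1), "absent")
})

test_that("P_gen over all genotypes at two biallelic loci sums to one", {
  # enumeration oracle: the 9 two-locus genotypes partition probability
  p <- 0.3; q <- 0.6
  f <- list(c("10" = p, "12" = 1 - p), c("20" = q, "22" = 1 - q))
  gts1 <- list(c(10, 10), c(10, 12), c(12, 12))
  gts2 <- list(c(20, 20), c(20, 22), c(22, 22))
  total <- 0
  for (g1 in gts1) for (g2 in gts2)
    total <- total + p_gen(rbind(c(g1[1], g2[1]), c(g1[2], g2[2])), f)
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("P_sex is the binomial tail and behaves monotonically", {
  expect_equal(p_sex(0, 2, 35), 0)
  expect_equal(p_sex(1, 5, 35), 1)
  expect_equal(p_sex(0.01, 2, 35), 1 - 0.99^34, tolerance = 1e-12)
  # Monte-Carlo cross-check of the tail probability
  set.seed(1)
  mc <- mean(rbinom(1e5, 34, 0.01) >= 1)
  expect_equal(p_sex(0.01, 2, 35), mc, tolerance = 5e-3)
  # monotone nonincreasing in copy number, nondecreasing in P_gen
  ps <- sapply(2:6, function(k) p_sex(0.05, k, 30))
  expect_true(all(diff(ps) <= 0))
  pg <- sapply(c(0.01, 0.05, 0.2, 0.8), function(p) p_sex(p, 3, 30))
  expect_true(all(diff(pg) >= 0))
  expect_error(p_sex(1.2, 2, 10), "p_gen")
})

test_that("genotypic richness matches the published worked examples", {
  # printed survey counts: N=34, G=20 -> 0.58; N=37, G=9 -> 0.22
  expect_equal(round(genotypic_richness(34, 20), 2), 0.58)
  expect_equal(round(genotypic_richness(37, 9), 2), 0.22)
  expect_equal(genotypic_richness(10, 10), 1)
  expect_equal(genotypic_richness(10, 1), 0)
  expect_true(is.na(genotypic_richness(1, 1)))
})

test_that("clone condensation keeps one representative per MLG per site", {
  x <- random_table(n_sites = 2, n_per = 10, L = 6, n_alleles = 8, seed = 4)
  # duplicate a genotype within site 1 and across both sites
  for (i in c(2, 3)) { x$a1[i, ] <- x$a1[1, ]; x$a2[i, ] <- x$a2[1, ] }
  x$a1[11, ] <- x$a1[1, ]; x$a2[11, ] <- x$a2[1, ]
  rep <- find_mlgs(x)
  cond <- condense_clones(x, rep)
  # within-site clones collapse, cross-site copy retained in its own site
  expect_equal(n_ind(cond), 10L - 2L + 10L)
  expect_true("i011" %in% cond$individuals)
  # idempotence, and R = 1 after condensation
  cond2 <- condense_clones(cond)
  expect_identical(cond2$a1, cond$a1)
  expect_true(all(find_mlgs(cond)$sites$R == 1))
  # fully sexual site: identity
  y <- random_table(n_sites = 1, n_per = 8, L = 6, n_alleles = 10, seed = 5)
  expect_equal(n_ind(condense_clones(y)), n_ind(y))
})

test_that("clone probabilities populate repeated MLGs from site frequencies", {
  x <- random_table(n_sites = 1, n_per = 12, L = 5, n_alleles = 4, seed = 6)
  x$a1[2, ] <- x$a1[1, ]; x$a2[2, ] <- x$a2[1, ]
  rep <- clone_probabilities(x, find_mlgs(x))
  dup <- rep$mlg_table[rep$mlg_table$size > 1, ]
  expect_true(nrow(dup) >= 1)
  expect_true(all(dup$p_gen > 0 & dup$p_gen < 1))
  expect_true(all(dup$p_sex >= 0 & dup$p_sex <= 1))
  # singletons carry no probabilities
  expect_true(all(is.na(rep$mlg_table$p_sex[rep$mlg_table$size == 1])))
})

test_that("simulated clonality drives genotypic richness down", {
  mean_R <- sapply(c(0, 0.25, 0.5, 0.75), function(cl) {
    cfg <- sim_config(n_demes = 2, deme_size = 40, generations = 60,
                      migration = 0.02, clonality = cl, n_loci = 6,
                      mu = 2e-3, sample_n = 20)
    sim <- simulate_population(cfg, seed = 100 + round(100 * cl))
    mean(find_mlgs(sim$table)$sites$R, na.rm = TRUE)
  })
  expect_true(cor(mean_R, c(0, 0.25, 0.5, 0.75), method = "spearman") < 0)
  expect_equal(mean_R[1], 1, tolerance = 0.02)
})

test_that("MLG partition matches the simulator's clonal-lineage truth", {
  cfg <- sim_config(n_demes = 2, deme_size = 40, generations = 50,
                    migration = 0.02, clonality = 0.5, n_loci = 8,
                    mu = 0, sample_n = 20)
  sim <- simulate_population(cfg, seed = 11)
  rep <- find_mlgs(sim$table)
  truth <- sim$truth$lineage
  # with mu = 0, clonemates (same lineage) must share an MLG
  for (ln in unique(truth)) {
    members <- which(truth == ln)
    if (length(members) > 1)
      expect_length(unique(rep$mlg[members]), 1L)
  }
})
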