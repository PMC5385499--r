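test_that("theta hits its fixed points", {
  # identical genotype lists in both sites: theta ~ 0 (may be slightly
  # negative for the unbiased estimator)
  x <- random_table(n_sites = 1, n_per = 30, L = 3, n_alleles = 4, seed = 41)
  a1 <- rbind(x$a1, x$a1); a2 <- rbind(x$a2, x$a2)
  y <- genotype_table(a1, a2, sprintf("i%03d", 1:60), x$loci,
                      rep(c("A", "B"), each = 30), 3L)
  expect_lt(abs(theta_wc(y)$theta), 0.05)
  # two fixed populations: theta = 1
  a1 <- matrix(rep(c(100L, 104L), each = 8), 16, 1)
  z <- genotype_table(a1, a1, sprintf("i%02d", 1:16), "L1",
                      rep(c("A", "B"), each = 8))
  expect_equal(theta_wc(z)$theta, 1)
  expect_error(theta_wc(genotype_table(matrix(1L, 4, 1), matrix(1L, 4, 1),
                                       paste0("i", 1:4), "L",
                                       rep(c("A", "B"), 2))),
               "no usable variation")
})

test_that("theta equals the independent variance-components oracle", {
  # 20 random small tables, agreement to 1e-10 against a literal
  # sums-of-squares ANOVA implementation
  for (seed in 1:20) {
    x <- random_table(n_sites = sample(2:4, 1), n_per = sample(5:12, 1),
                      L = 2, n_alleles = sample(2:5, 1), seed = 1000 + seed,
                      diverge = 0.5)
    got <- tryCatch(theta_wc(x)$theta, error = function(e) NA_real_)
    want <- theta_anova_oracle(x)
    if (!is.na(got) && is.finite(want))
      expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("G'ST spans 0 for shared and 1 for disjoint fixed alleles", {
  # identical allele frequencies across sites
  x <- random_table(n_sites = 1, n_per = 30, L = 2, n_alleles = 3, seed = 43)
  y <- genotype_table(rbind(x$a1, x$a1), rbind(x$a2, x$a2),
                      sprintf("i%03d", 1:60), x$loci,
                      rep(c("A", "B"), each = 30), 3L)
  expect_lt(abs(gst_hedrick(y)$gst_std), 0.08)
  # each site fixed for its own allele: maximal standardized differentiation
  k <- 3
  a1 <- matrix(rep(c(100L, 104L, 108L), each = 6), 18, 1)
  z <- genotype_table(a1, a1, sprintf("i%02d", 1:18), "L1",
                      rep(c("A", "B", "C"), each = 6))
  expect_equal(gst_hedrick(z)$gst_std, 1, tolerance = 1e-10)
  expect_equal(d_jost(z)$d, 1, tolerance = 1e-10)
})

test_that("G'ST and D match direct evaluation from tabulated frequencies", {
  x <- random_table(n_sites = 2, n_per = 10, L = 1, n_alleles = 4,
                    seed = 44, diverge = 0.3)
  # independent formula route: Nei-Chesser corrected HS/HT from first
  # principles on the allele count table
  cnt <- allele_freqs(x, 1)
  ni <- cnt$genes / 2
  k <- 2
  p <- cnt$freq
  ho <- sapply(levels(x$site), function(s) {
    sel <- x$site == s
    mean(x$a1[sel, 1] != x$a2[sel, 1])
  })
  ntil <- k / sum(1 / ni)
  Ho <- mean(ho)
  HS <- (ntil / (ntil - 1)) * (1 - mean(rowSums(p^2)) - Ho / (2 * ntil))
  HT <- 1 - sum(colMeans(p)^2) + HS / (k * ntil) - Ho / (2 * k * ntil)
  gst <- (HT - HS) / HT
  gmax <- ((k - 1) * (1 - HS)) / (k - 1 + HS)
  expect_equal(gst_hedrick(x)$gst_std, gst / gmax, tolerance = 1e-12)
  expect_equal(d_jost(x)$d, (k / (k - 1)) * (HT - HS) / (1 - HS),
               tolerance = 1e-12)
})

test_that("the three statistics vanish on a panmictic split", {
  set.seed(46)
  x <- hwe_table(n = 100, L = 6, n_alleles = 8, groups = 2)
  expect_lt(abs(theta_wc(x)$theta), 0.02)
  expect_lt(abs(gst_hedrick(x)$gst_std), 0.05)
  expect_lt(abs(d_jost(x)$d), 0.05)
})

test_that("permutation p-values follow the +1 smoothed convention", {
  x <- random_table(n_sites = 2, n_per = 8, L = 2, n_alleles = 3, seed = 47,
                    diverge = 0.2)
  res <- permute_significance(theta_wc, x, n_perm = 99, seed = 5)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  # reproducible under a fixed seed
  res2 <- permute_significance(theta_wc, x, n_perm = 99, seed = 5)
  expect_identical(res$p, res2$p)
  expect_error(permute_significance(theta_wc, x,
                                    grouping = rep("A", n_ind(x)),
                                    n_perm = 99), "degenerate")
  expect_error(permute_significance(theta_wc, x, n_perm = 50), ">= 99")
  # label swap of two identical sites: observed theta is in the bulk of the
  # permutation null, p should be large
  y <- genotype_table(rbind(x$a1, x$a1), rbind(x$a2, x$a2),
                      sprintf("i%03d", seq_len(2 * n_ind(x))), x$loci,
                      rep(c("A", "B"), each = n_ind(x)), 3L)
  expect_gt(permute_significance(theta_wc, y, n_perm = 199, seed = 1)$p, 0.2)
})

test_that("pairwise matrices are symmetric and site-order invariant", {
  x <- random_table(n_sites = 3, n_per = 8, L = 2, n_alleles = 4, seed = 48,
                    diverge = 0.4)
  pw <- pairwise_diff(x, "theta", n_perm = 99, seed = 2)
  expect_equal(pw$value, t(pw$value))
  expect_equal(unname(diag(pw$value)), rep(0, 3))
  expect_true(all(pw$p[upper.tri(pw$p)] > 0 & pw$p[upper.tri(pw$p)] <= 1))
  # reordering sites permutes, not changes, the matrix
  ord <- c(3, 1, 2)
  x2 <- subset_individuals(x, order(match(as.integer(x$site), ord)))
  x2$site <- factor(as.character(x2$site), levels = levels(x$site)[ord])
  pw2 <- pairwise_diff(x2, "theta", n_perm = 99, seed = 2)
  expect_equal(pw2$value[rownames(pw$value), colnames(pw$value)], pw$value,
               tolerance = 1e-12)
  # display formatting floors at zero with stars
  dt <- dual_triangle(pw, pw)
  expect_true(all(diag(dt) == "-"))
  expect_false(any(grepl("^-0", dt)))
})

test_that("AMOVA components satisfy the algebraic identities", {
  x <- random_table(n_sites = 4, n_per = 8, L = 3, n_alleles = 4, seed = 49,
                    diverge = 0.4)
  grp <- factor(rep(c("g1", "g2"), each = 16))
  am <- amova(x, grp, n_perm = 99, seed = 3)
  # sums of squares decompose the total
  expect_equal(am$ss[["total"]],
               am$ss[["among_groups"]] + am$ss[["among_sites"]] +
                 am$ss[["within_sites"]], tolerance = 1e-9)
  expect_true(all(am$phi >= -1 & am$phi <= 1, na.rm = TRUE))
  expect_true(all(am$p > 0 & am$p <= 1))
  # all sites identical: components ~ 0
  y0 <- random_table(n_sites = 1, n_per = 24, L = 3, n_alleles = 4, seed = 50)
  a1 <- do.call(rbind, replicate(4, y0$a1, simplify = FALSE))
  a2 <- do.call(rbind, replicate(4, y0$a2, simplify = FALSE))
  y <- genotype_table(a1, a2, sprintf("i%03d", 1:96), y0$loci,
                      rep(c("s1", "s2", "s3", "s4"), each = 24), 3L)
  amy <- amova(y, factor(rep(c("g1", "g2"), each = 48)), n_perm = 99,
               seed = 4)
  expect_lt(abs(amy$phi[["Phi_ST"]]), 0.08)
})

test_that("collapsing the hierarchy reduces AMOVA to a single level", {
  # each group holds exactly one site: Phi_ST from the two-level model
  # equals the one-level ratio on the same distances
  x <- random_table(n_sites = 3, n_per = 8, L = 2, n_alleles = 4, seed = 51,
                    diverge = 0.4)
  d2 <- mismatch_dist(x)
  two <- clonepop:::amova_components(d2, x$site, factor(as.character(x$site)))
  # independent one-level computation
  N <- n_ind(x); S <- 3
  ss_tot <- sum(d2) / (2 * N)
  ss_w <- sum(sapply(levels(x$site), function(s) {
    sel <- which(x$site == s); sum(d2[sel, sel]) / (2 * length(sel))
  }))
  ni <- as.numeric(table(x$site))
  n0 <- (N - sum(ni^2) / N) / (S - 1)
  ms_a <- (ss_tot - ss_w) / (S - 1); ms_w <- ss_w / (N - S)
  sa <- (ms_a - ms_w) / n0
  expect_equal(two$phi[["Phi_ST"]], sa / (sa + ms_w), tolerance = 1e-6)
})

test_that("PCoA reproduces planted geometry", {
  # three sites at mutual distance 1: an equilateral triangle, two equal
  # positive eigenvalues
  d <- matrix(1, 3, 3) - diag(3)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  pc <- pcoa(d)
  expect_equal(pc$eig[1], pc$eig[2], tolerance = 1e-9)
  expect_equal(as.numeric(dist(pc$coords)), rep(1, 3), tolerance = 1e-9)
  # round trip from planted 2-D coordinates
  set.seed(6)
  pts <- matrix(rnorm(12), 6, 2)
  d2 <- as.matrix(dist(pts))
  pc2 <- pcoa(d2)
  expect_equal(as.matrix(dist(pc2$coords[, 1:2])), unname(d2),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA separates depth-stratified clusters", {
  cfg <- preset_study("desmophyllum_like", scale = 0.4)
  sim <- simulate_population(cfg, seed = 21,
                             metadata_template = attr(cfg, "metadata_template"))
  pw <- pairwise_diff(sim$table, "theta", n_perm = 99, seed = 1)
  pc <- pcoa(pmax(pw$value, 0))
  km <- kmeans(pc$coords[, 1:2], 3, nstart = 20)
  truth <- factor(sim$metadata$stratum)
  tab <- table(km$cluster, truth)
  # agreement of the best label matching (3 clusters, small case)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  acc <- max(sapply(perms, function(p) sum(diag(tab[p, ])))) / 9
  expect_gte(acc, 8 / 9)
})

test_that("Mantel IBD recovers exact proportionality and stays calibrated", {
  md <- site_metadata(data.frame(
    site_id = paste0("s", 1:6), seamount = "x", region = "r",
    lat = -44 + (1:6) * 0.5, lon = 147 + (1:6) * 0.3,
    depth_m = 1200, stratum = "mid", fished = FALSE))
  # distance-proportional differentiation: perfect positive Mantel
  dkm <- matrix(0, 6, 6, dimnames = list(md$site_id, md$site_id))
  for (i in 1:6) for (j in 1:6)
    dkm[i, j] <- geosphere::distHaversine(c(md$lon[i], md$lat[i]),
                                          c(md$lon[j], md$lat[j])) / 1000
  fst <- dkm / max(dkm) * 0.2
  ibd <- mantel_ibd(fst, md, n_perm = 199, seed = 1)
  expect_equal(ibd$r2, 1, tolerance = 1e-9)
  expect_lt(ibd$p, 0.05)
  expect_error(mantel_ibd(fst[1:3, 1:3], md), ">= 4 sites")
  expect_error(mantel_ibd(`rownames<-`(fst, paste0("q", 1:6)), md),
               "missing coordinates")
})
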