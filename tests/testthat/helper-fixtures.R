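# shared generators and independent oracles for the test suite

# random genotype table: iid alleles per locus, optional per-site frequency
# divergence and missingness
random_table <- function(n_sites = 2, n_per = 10, L = 3, n_alleles = 4,
                         miss = 0, seed = NULL, diverge = 0) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_sites * n_per
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  site <- rep(sprintf("s%02d", seq_len(n_sites)), each = n_per)
  for (l in seq_len(L)) {
    alleles <- 100L + 3L * seq_len(n_alleles)
    base <- rgamma(n_alleles, 2); base <- base / sum(base)
    for (s in seq_len(n_sites)) {
      p <- base
      if (diverge > 0) {
        p <- rgamma(n_alleles, base / diverge); p <- p / sum(p)
      }
      sel <- which(site == sprintf("s%02d", s))
      a1[sel, l] <- sample(alleles, length(sel), TRUE, p)
      a2[sel, l] <- sample(alleles, length(sel), TRUE, p)
    }
  }
  if (miss > 0) {
    hit <- matrix(runif(n * L) < miss, n, L)
    a1[hit] <- NA_integer_; a2[hit] <- NA_integer_
  }
  genotype_table(a1, a2, sprintf("i%03d", seq_len(n)),
                 sprintf("L%02d", seq_len(L)), site, 3L)
}

# iid HWE genotypes for one panmictic pool split into arbitrary groups
hwe_table <- function(n = 100, L = 5, n_alleles = 6, groups = 2) {
  a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    p <- rgamma(n_alleles, 1.5); p <- p / sum(p)
    al <- 100L + 2L * seq_len(n_alleles)
    a1[, l] <- sample(al, n, TRUE, p)
    a2[, l] <- sample(al, n, TRUE, p)
  }
  genotype_table(a1, a2, sprintf("i%03d", seq_len(n)),
                 sprintf("L%02d", seq_len(L)),
                 rep(sprintf("g%d", seq_len(groups)), length.out = n), 2L)
}

# --- independent Weir-Cockerham oracle -------------------------------------
# literal three-level ANOVA sums of squares on allele-copy indicators,
# a computational route disjoint from the package's closed-form components
theta_anova_oracle <- function(x, grouping = x$site) {
  grouping <- droplevels(factor(grouping))
  num <- 0; den <- 0
  for (li in seq_len(n_loci(x))) {
    a1 <- x$a1[, li]; a2 <- x$a2[, li]
    ok <- !is.na(a1)
    g <- droplevels(grouping[ok])
    if (nlevels(g) < 2) next
    aa1 <- a1[ok]; aa2 <- a2[ok]
    alleles <- sort(unique(c(aa1, aa2)))
    if (length(alleles) < 2) next
    ni <- as.numeric(table(g))
    N <- sum(ni); r <- nlevels(g)
    nbar <- N / r
    nc <- (N - sum(ni^2) / N) / (r - 1)
    for (al in alleles) {
      xdos <- (aa1 == al) + (aa2 == al)
      pg <- tapply(xdos, g, mean) / 2
      pw <- sum(ni * pg) / N
      SSG <- sum(xdos * (2 - xdos) / 2)
      SSI <- 2 * sum((xdos / 2 - pg[as.integer(g)])^2)
      SSP <- 2 * sum(ni * (pg - pw)^2)
      MSP <- SSP / (r - 1); MSI <- SSI / (N - r); MSG <- SSG / N
      sa <- (MSP - MSI) / (2 * nc)
      sb <- (MSI - MSG) / 2
      sc <- MSG
      num <- num + sa; den <- den + sa + sb + sc
    }
  }
  num / den
}

# --- brute-force rarefaction oracle ----------------------------------------
# mean number of distinct alleles over all C(2n, g) gene subsamples
richness_bruteforce <- function(genes, g) {
  combs <- utils::combn(length(genes), g)
  mean(apply(combs, 2, function(ix) length(unique(genes[ix]))))
}

# tiny deterministic two-site table used by several format tests
tiny_table <- function() {
  a1 <- matrix(c(120L, 120L, 130L, 120L,
                 201L, 203L, 201L, NA), 4, 2)
  a2 <- matrix(c(130L, 120L, 130L, 140L,
                 203L, 203L, 201L, NA), 4, 2)
  genotype_table(a1, a2, c("a1", "a2", "b1", "b2"), c("locA", "locB"),
                 c("siteA", "siteA", "siteB", "siteB"),
                 repeat_unit = c(10L, 2L))
}

# 3-SE agreement between the HWE chain and enumeration, with a sequential
# confirmation: a config exceeding 3 Monte-Carlo SEs on the standard chain
# is re-examined with a 10x longer chain at the same 3-SE rule, so that
# false alarms from chain noise (expected a handful per hundred configs)
# vanish while any genuine bias still fails decisively.
expect_chain_matches_enumeration <- function(n11, n12, n22, seed,
                                             iterations = 10000L) {
  exact <- exact_hwe_enumerate(n11, n12, n22)
  a1 <- c(rep(1L, n11), rep(1L, n12), rep(2L, n22))
  a2 <- c(rep(1L, n11), rep(2L, n12), rep(2L, n22))
  res <- exact_hwe(a1, a2, iterations = iterations,
                   dememorization = 1000L, seed = seed)
  if (abs(res$p - exact) >= 3 * max(res$se, 1e-3)) {
    res <- exact_hwe(a1, a2, iterations = 10L * iterations,
                     dememorization = 5000L, seed = seed + 1L)
  }
  testthat::expect_lt(abs(res$p - exact), 3 * max(res$se, 5e-4))
}
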