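#' Weir & Cockerham's theta (F_ST)
#'
#' The WC (1984) estimator from the variance components `a` (among groups),
#' `b` (among individuals within groups) and `c` (within individuals),
#' computed per allele per locus and summed:
#' `theta = sum(a) / sum(a + b + c)`. Raw estimates are returned unmodified
#' (they can be slightly negative near zero differentiation).
#'
#' @param x a [genotype_table()].
#' @param grouping factor over individuals (default: site of each
#'   individual).
#' @return A list: `theta`, per-locus components `a`, `b`, `c`.
#' @export
theta_wc <- function(x, grouping = x$site) {
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 2L) stop("need at least two groups")
  asum <- bsum <- csum <- 0
  per_locus <- matrix(NA_real_, n_loci(x), 3,
                      dimnames = list(x$loci, c("a", "b", "c")))
  for (li in seq_len(n_loci(x))) {
    comp <- wc_locus_components(x$a1[, li], x$a2[, li], grouping)
    if (is.null(comp)) next
    per_locus[li, ] <- c(comp$a, comp$b, comp$c)
    asum <- asum + comp$a; bsum <- bsum + comp$b; csum <- csum + comp$c
  }
  den <- asum + bsum + csum
  if (!is.finite(den) || den == 0)
    stop("theta undefined: no usable variation in any locus")
  list(theta = asum / den, components = per_locus)
}

# WC 1984 a, b, c summed over the alleles of one locus
wc_locus_components <- function(a1, a2, grouping) {
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  a1 <- a1[ok]; a2 <- a2[ok]; g <- droplevels(grouping[ok])
  r <- nlevels(g)
  if (r < 2L) return(NULL)
  ni <- as.numeric(tabulate(g, r))
  if (any(ni < 1)) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  gi <- as.integer(g)
  A <- length(alleles)
  c1 <- match(a1, alleles); c2 <- match(a2, alleles)
  i1 <- gi + r * (c1 - 1L); i2 <- gi + r * (c2 - 1L)
  cnt <- matrix(tabulate(i1, r * A) + tabulate(i2, r * A), r, A)
  het <- c1 != c2
  hetc <- matrix(tabulate(i1[het], r * A) + tabulate(i2[het], r * A), r, A)
  p <- cnt / (2 * ni)
  h <- hetc / ni
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = sum(a), b = sum(b), c = sum(cc))
}

# Nei & Chesser (1983) corrected H_S and H_T for one locus
nei_chesser <- function(a1, a2, grouping) {
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  a1 <- a1[ok]; a2 <- a2[ok]; g <- droplevels(grouping[ok])
  k <- nlevels(g)
  if (k < 2L) return(NULL)
  ni <- as.numeric(tabulate(g, k))
  if (any(ni < 1)) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  gi <- as.integer(g)
  A <- length(alleles)
  c1 <- match(a1, alleles); c2 <- match(a2, alleles)
  cnt <- matrix(tabulate(gi + k * (c1 - 1L), k * A) +
                  tabulate(gi + k * (c2 - 1L), k * A), k, A)
  p <- cnt / (2 * ni)
  ho <- as.numeric(tabulate(gi[c1 != c2], k)) / ni
  ntil <- k / sum(1 / ni)                      # harmonic mean sample size
  Ho <- mean(ho)
  HS <- (ntil / (ntil - 1)) * (1 - mean(rowSums(p^2)) - Ho / (2 * ntil))
  pbar <- colMeans(p)
  HT <- 1 - sum(pbar^2) + HS / (k * ntil) - Ho / (2 * k * ntil)
  list(HS = HS, HT = HT, k = k)
}

#' Hedrick's standardized G'ST
#'
#' `G_ST` from Nei-Chesser corrected `H_S`, `H_T` (averaged over loci),
#' standardized by its maximum given the within-site diversity:
#' `G'_ST = G_ST (k - 1 + H_S) / ((k - 1)(1 - H_S))`.
#'
#' @inheritParams theta_wc
#' @return A list: `gst_std` (G'_ST), `gst`, `HS`, `HT`.
#' @export
gst_hedrick <- function(x, grouping = x$site) {
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 2L) stop("need at least two groups")
  hs <- ht <- numeric(0); k <- NA_integer_
  for (li in seq_len(n_loci(x))) {
    nch <- nei_chesser(x$a1[, li], x$a2[, li], grouping)
    if (is.null(nch)) next
    hs <- c(hs, nch$HS); ht <- c(ht, nch$HT); k <- nch$k
  }
  if (!length(hs)) stop("no usable loci")
  HS <- mean(hs); HT <- mean(ht)
  if (HT <= 0) stop("H_T = 0: G'_ST undefined")
  gst <- (HT - HS) / HT
  gst_max <- ((k - 1) * (1 - HS)) / (k - 1 + HS)
  list(gst_std = gst / gst_max, gst = gst, HS = HS, HT = HT)
}

#' Jost's D
#'
#' Per locus `D = (k/(k-1)) (H_T - H_S)/(1 - H_S)` with Nei-Chesser
#' corrected heterozygosities; combined across loci by the harmonic mean of
#' the per-locus values (the convention for D). When some per-locus D are
#' not positive the harmonic mean is undefined and the arithmetic mean is
#' used instead (reported via the `combined` field).
#'
#' @inheritParams theta_wc
#' @return A list: `d` (multi-locus D), `per_locus`, `combined`
#'   (`"harmonic"` or `"arithmetic"`).
#' @export
d_jost <- function(x, grouping = x$site) {
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 2L) stop("need at least two groups")
  ds <- numeric(0)
  for (li in seq_len(n_loci(x))) {
    nch <- nei_chesser(x$a1[, li], x$a2[, li], grouping)
    if (is.null(nch)) next
    if (nch$HS >= 1) next
    ds <- c(ds, (nch$k / (nch$k - 1)) * (nch$HT - nch$HS) / (1 - nch$HS))
  }
  if (!length(ds)) stop("no usable loci: D undefined")
  if (all(ds > 0)) {
    list(d = 1 / mean(1 / ds), per_locus = ds, combined = "harmonic")
  } else {
    list(d = mean(ds), per_locus = ds, combined = "arithmetic")
  }
}

#' Permutation significance for a differentiation statistic
#'
#' Permutes individuals among groups holding group sizes fixed and computes
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)` (one-tailed: large values
#' of the statistic indicate differentiation). Seeded and reproducible.
#'
#' @param stat_fn function `(x, grouping) -> list` whose first element is
#'   the scalar statistic (e.g. [theta_wc()], [gst_hedrick()], [d_jost()]).
#' @param x a [genotype_table()].
#' @param grouping factor over individuals.
#' @param n_perm number of permutations (>= 99; default 9999).
#' @param seed integer seed.
#' @return A list: `observed`, `p`, `n_perm`, `seed`.
#' @export
permute_significance <- function(stat_fn, x, grouping = x$site,
                                 n_perm = 9999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  grouping <- droplevels(factor(grouping))
  if (nlevels(grouping) < 2L) stop("degenerate grouping: one group")
  obs <- stat_fn(x, grouping)[[1]]
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(grouping)
    val <- tryCatch(stat_fn(x, perm)[[1]], error = function(e) NA_real_)
    if (!is.na(val) && val >= obs) ge <- ge + 1L
  }
  list(observed = obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm,
       seed = seed)
}

#' Pairwise differentiation matrices with permutation p-values
#'
#' Computes a statistic and its permutation p-value for every pair of sites.
#' Raw estimates are stored (possibly negative); use `floor_zero = TRUE`
#' when formatting display tables.
#'
#' @param x a [genotype_table()].
#' @param stat one of `"theta"`, `"gst"`, `"djost"`.
#' @param n_perm permutations per pair (default 9999; use fewer for large
#'   surveys).
#' @param seed integer seed.
#' @return A list of class `pairwise_diff`: `statistic`, `value` and `p`
#'   (symmetric site x site matrices, zero/NA diagonal), `n_perm`, `seed`.
#' @export
pairwise_diff <- function(x, stat = c("theta", "gst", "djost"),
                          n_perm = 9999L, seed = 1L) {
  stat <- match.arg(stat)
  fn <- switch(stat, theta = theta_wc, gst = gst_hedrick, djost = d_jost)
  sites <- levels(x$site)
  m <- length(sites)
  val <- matrix(0, m, m, dimnames = list(sites, sites))
  pm <- matrix(NA_real_, m, m, dimnames = list(sites, sites))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      sub <- subset_individuals(x, x$site %in% sites[c(i, j)])
      res <- permute_significance(fn, sub, sub$site, n_perm = n_perm,
                                  seed = seed + i * m + j)
      val[i, j] <- val[j, i] <- res$observed
      pm[i, j] <- pm[j, i] <- res$p
    }
  }
  structure(list(statistic = stat, value = val, p = pm, n_perm = n_perm,
                 seed = seed),
            class = "pairwise_diff")
}

#' Dual-triangle display matrix
#'
#' Formats two pairwise results in the conventional joint layout: the first
#' statistic below the diagonal, the second above, estimates floored at 0
#' and starred by permutation significance (* p<0.05, ** p<0.01,
#' *** p<0.001).
#'
#' @param lower,upper `pairwise_diff` objects over the same sites.
#' @return A character matrix.
#' @export
dual_triangle <- function(lower, upper) {
  stopifnot(identical(rownames(lower$value), rownames(upper$value)))
  m <- nrow(lower$value)
  out <- matrix("-", m, m, dimnames = dimnames(lower$value))
  star <- function(p) if (is.na(p)) "" else
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    src <- if (i > j) lower else upper
    out[i, j] <- paste0(sprintf("%.3f", max(0, src$value[i, j])),
                        star(src$p[i, j]))
  }
  out
}
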