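#' Observed and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of scored individuals that are heterozygous; `He` is
#' Nei's unbiased expected heterozygosity `(2n/(2n-1)) (1 - sum p_i^2)`.
#'
#' @param a1,a2 integer vectors of the two alleles per individual at one
#'   locus (`NA` = missing).
#' @return A list with `n` (scored individuals), `Ho`, `He`, `Na`.
#' @export
heterozygosity <- function(a1, a2) {
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n == 0L) return(list(n = 0L, Ho = NA_real_, He = NA_real_, Na = 0L))
  het <- a1[ok] != a2[ok]
  alleles <- c(a1[ok], a2[ok])
  p <- table(alleles) / (2 * n)
  He <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
  list(n = n, Ho = mean(het), He = He, Na = length(p))
}

#' Weir & Cockerham's inbreeding coefficient f (F_IS)
#'
#' Small-f from the WC (1984) variance components `b` (among individuals
#' within sites) and `c` (within individuals), summed over alleles:
#' `f = 1 - sum(c) / sum(b + c)`. For a single site this reduces to the
#' classic estimator based on the excess of homozygotes.
#'
#' @param a1,a2 allele vectors at one locus for the individuals of one site.
#' @return `F_IS`, or `NA` when the locus carries no variation.
#' @export
f_is <- function(a1, a2) {
  comp <- fis_components(a1, a2)
  if (is.null(comp) || comp$den <= 0) return(NA_real_)
  1 - comp$csum / comp$den
}

# per-locus b, c components (single site); used for multi-locus F_IS too
fis_components <- function(a1, a2) {
  ok <- !is.na(a1)
  n <- sum(ok)
  if (n < 2L) return(NULL)
  a1 <- a1[ok]; a2 <- a2[ok]
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)
  bsum <- 0; csum <- 0
  for (al in alleles) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    hbar <- mean((a1 == al) != (a2 == al))   # het freq for this allele
    b <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    cc <- hbar / 2
    bsum <- bsum + b; csum <- csum + cc
  }
  list(bsum = bsum, csum = csum, den = bsum + csum)
}

#' Multi-locus F_IS for one site (components summed over loci)
#'
#' @param x a [genotype_table()].
#' @param site site id.
#' @return `F_IS` across loci.
#' @export
f_is_multilocus <- function(x, site) {
  sel <- x$site == site
  comps <- lapply(seq_len(n_loci(x)), function(li)
    fis_components(x$a1[sel, li], x$a2[sel, li]))
  comps <- comps[!vapply(comps, is.null, logical(1))]
  if (!length(comps)) return(NA_real_)
  den <- sum(vapply(comps, `[[`, numeric(1), "den"))
  if (den <= 0) return(NA_real_)
  1 - sum(vapply(comps, `[[`, numeric(1), "csum")) / den
}

#' Rarefied allelic richness
#'
#' The FSTAT-style rarefaction estimator: the expected number of distinct
#' alleles in a subsample of `g` genes,
#' `A_r(g) = sum_i [1 - C(2n - N_i, g) / C(2n, g)]`,
#' with `N_i` the count of allele `i` among the `2n` genes scored.
#'
#' @param a1,a2 allele vectors at one locus for one site.
#' @param g number of genes to rarefy to (>= 2); conventionally the smallest
#'   per-site gene count among the sites being compared.
#' @return `A_r(g)`.
#' @export
allelic_richness <- function(a1, a2, g) {
  if (g < 2) stop("g must be >= 2")
  obs <- c(a1, a2); obs <- obs[!is.na(obs)]
  n2 <- length(obs)
  if (g > n2) stop("g exceeds the genes scored (", n2, ")")
  cnt <- table(obs)
  sum(1 - exp(lchoose(n2 - cnt, g) - lchoose(n2, g)))
}

#' Private alleles per site
#'
#' An allele is private to a site iff it is observed there and in no other
#' site. Counts are totalled over loci; the mean frequency of private
#' alleles within their home site (`p(1)`) feeds the private-allele gene-flow
#' estimator.
#'
#' @param x a [genotype_table()].
#' @return A list: `counts` (named per-site private-allele counts), `mean`,
#'   `se` across sites, and `p1` (mean within-site frequency of private
#'   alleles), `detail` (data.frame site/locus/allele/freq).
#' @export
private_alleles <- function(x) {
  sites <- levels(x$site)
  if (length(sites) < 2L)
    warning("single site: every allele is trivially private")
  counts <- stats::setNames(integer(length(sites)), sites)
  det <- list()
  for (li in seq_len(n_loci(x))) {
    af <- allele_freqs(x, li)
    present <- af$count > 0
    priv <- which(colSums(present) == 1L)
    for (a in priv) {
      s <- which(present[, a])
      counts[s] <- counts[s] + 1L
      det[[length(det) + 1L]] <- data.frame(
        site = sites[s], locus = x$loci[li],
        allele = af$alleles[a], freq = af$freq[s, a])
    }
  }
  detail <- if (length(det)) do.call(rbind, det) else
    data.frame(site = character(), locus = character(),
               allele = integer(), freq = numeric())
  list(counts = counts,
       mean = mean(counts),
       se = stats::sd(counts) / sqrt(length(counts)),
       p1 = if (nrow(detail)) mean(detail$freq) else NA_real_,
       detail = detail)
}

#' Bonferroni significance flags for a family of tests
#'
#' Flags `p <= alpha / m` where `m` is the family size: all defined
#' locus-by-site tests of one dataset.
#'
#' @param p numeric vector of p-values (NA = undefined test, not counted in
#'   the family).
#' @param alpha family-wise level (default 0.05).
#' @return A list with `threshold`, `m`, and logical `flag` (NA where the
#'   test was undefined).
#' @export
bonferroni <- function(p, alpha = 0.05) {
  m <- sum(!is.na(p))
  if (m == 0L) stop("empty test family")
  thr <- alpha / m
  list(threshold = thr, m = m, flag = ifelse(is.na(p), NA, p <= thr))
}

#' Per-site, per-locus diversity table
#'
#' For every site x locus: n scored, Na, Ho, unbiased He, F_IS, and the exact
#' HWE p-value (with Monte-Carlo SE and deficit/excess direction) where the
#' test is defined. Site-mean rows aggregate over loci and add rarefied
#' allelic richness at `g` genes (default: smallest per-site gene count over
#' all site x locus cells with data) and private-allele counts.
#'
#' @param x a [genotype_table()].
#' @param hwe_iter,hwe_demem Markov-chain length and dememorization for the
#'   exact HWE test.
#' @param g rarefaction gene count; `NULL` = smallest gene count observed.
#' @param seed integer seed for the HWE chains.
#' @return A list with `by_locus` (data.frame), `by_site` (data.frame with
#'   means, `A_r`, private alleles), and `hwe_family_size`.
#' @export
diversity_summary <- function(x, hwe_iter = 10000L, hwe_demem = 1000L,
                              g = NULL, seed = 1L) {
  sites <- levels(x$site)
  rows <- list()
  genes_min <- Inf
  for (s in sites) {
    sel <- x$site == s
    for (li in seq_len(n_loci(x))) {
      h <- heterozygosity(x$a1[sel, li], x$a2[sel, li])
      if (h$n > 0) genes_min <- min(genes_min, 2 * h$n)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, locus = x$loci[li], n = h$n, Na = h$Na,
        Ho = h$Ho, He = h$He,
        F_IS = f_is(x$a1[sel, li], x$a2[sel, li]))
    }
  }
  by_locus <- do.call(rbind, rows)

  # exact HWE tests where defined
  by_locus$hwe_p <- NA_real_; by_locus$hwe_se <- NA_real_
  by_locus$direction <- NA_character_
  k <- 0L
  for (s in sites) {
    sel <- x$site == s
    for (li in seq_len(n_loci(x))) {
      k <- k + 1L
      res <- tryCatch(
        exact_hwe(x$a1[sel, li], x$a2[sel, li],
                  iterations = hwe_iter, dememorization = hwe_demem,
                  seed = seed + k),
        error = function(e) NULL)
      if (!is.null(res)) {
        by_locus$hwe_p[k] <- res$p
        by_locus$hwe_se[k] <- res$se
        by_locus$direction[k] <- res$direction
      }
    }
  }
  bf <- bonferroni(by_locus$hwe_p)
  by_locus$hwe_significant <- bf$flag

  if (is.null(g)) g <- max(2, if (is.finite(genes_min)) genes_min else 2)
  pa <- private_alleles(x)
  by_site <- do.call(rbind, lapply(sites, function(s) {
    sel <- x$site == s
    sub <- by_locus[by_locus$site == s, ]
    ar <- mean(vapply(seq_len(n_loci(x)), function(li) {
      tryCatch(allelic_richness(x$a1[sel, li], x$a2[sel, li], g),
               error = function(e) NA_real_)
    }, numeric(1)), na.rm = TRUE)
    data.frame(site = s, n = max(sub$n), mean_Na = mean(sub$Na),
               mean_Ho = mean(sub$Ho, na.rm = TRUE),
               mean_He = mean(sub$He, na.rm = TRUE),
               F_IS = f_is_multilocus(x, s),
               A_r = ar, private = unname(pa$counts[s]))
  }))
  list(by_locus = by_locus, by_site = by_site,
       hwe_family_size = bf$m, hwe_threshold = bf$threshold,
       rarefaction_g = g)
}

#' Compare diversity between fished and unfished sites
#'
#' One-way fixed-effects ANOVA per metric (rarefied allelic richness and
#' expected heterozygosity) across sites grouped by the fished flag of their
#' seamount, reported with group means and standard errors.
#'
#' @param by_site per-site data.frame with columns `site`, `A_r`, `mean_He`
#'   (as from [diversity_summary()]).
#' @param fished named logical vector (site -> fished flag).
#' @return A data.frame with one row per metric: group means +/- SE, F, p.
#' @export
compare_fished <- function(by_site, fished) {
  fl <- fished[by_site$site]
  if (anyNA(fl)) stop("fished flag missing for some sites")
  if (length(unique(fl)) < 2L) stop("both fished and unfished sites required")
  if (any(table(fl) < 2L)) stop("each group needs >= 2 sites")
  one <- function(y, metric) {
    fit <- stats::aov(y ~ factor(fl))
    an <- summary(fit)[[1]]
    if (stats::var(y) < 1e-20) {  # degenerate: no variation at all
      an$`F value`[1] <- 0; an$`Pr(>F)`[1] <- 1
    }
    grp <- function(v) c(mean = mean(y[fl == v]),
                         se = stats::sd(y[fl == v]) / sqrt(sum(fl == v)))
    f <- grp(TRUE); u <- grp(FALSE)
    data.frame(metric = metric,
               fished_mean = f["mean"], fished_se = f["se"],
               unfished_mean = u["mean"], unfished_se = u["se"],
               F = an$`F value`[1], p = an$`Pr(>F)`[1],
               row.names = NULL)
  }
  rbind(one(by_site$A_r, "allelic_richness"),
        one(by_site$mean_He, "expected_heterozygosity"))
}
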