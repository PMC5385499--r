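#' Exact Hardy-Weinberg test by Markov chain
#'
#' The probability-test variant of the exact HWE test: conditional on the
#' observed allele counts, the p-value is the total conditional probability
#' of genotype tables no more probable than the observed one. The conditional
#' probability of a table with genotype counts `n_ab` and `h` heterozygotes is
#' Levene's
#' `P = n! prod_a(m_a!) 2^h / ((2n)! prod_{a<=b} n_ab!)`,
#' with `m_a` the allele counts. The p-value is estimated by the
#' Guo & Thompson (1992) Markov chain over tables with fixed allele counts:
#' repeatedly pick two individuals (allele pairs) and propose re-pairing
#' their four alleles, accepting by the Metropolis rule; after
#' `dememorization` burn-in switches, the p-value is the fraction of visited
#' tables whose probability does not exceed the observed one.
#'
#' @param a1,a2 allele vectors at one locus for the individuals of one site.
#' @param iterations chain length used for estimation (default 10000).
#' @param dememorization burn-in switches (default 1000).
#' @param seed integer seed for the chain.
#' @return A list: `p` (estimated p-value), `se` (Monte-Carlo standard error
#'   from batch means), `direction` (`"deficit"` if Ho < He else
#'   `"excess"`), `n`, `k` (allele count).
#' @export
exact_hwe <- function(a1, a2, iterations = 10000L, dememorization = 1000L,
                      seed = 1L) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2L) stop("need at least 2 scored individuals")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) stop("monomorphic locus: exact HWE test undefined")
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)

  h <- heterozygosity(a1, a2)
  direction <- if (isTRUE(h$Ho < h$He)) "deficit" else "excess"

  # pair list representation; genotype counts tracked incrementally
  pairs <- cbind(pmin(i1, i2), pmax(i1, i2))
  gcount <- matrix(0L, k, k)
  for (r in seq_len(n)) {
    gcount[pairs[r, 1], pairs[r, 2]] <- gcount[pairs[r, 1], pairs[r, 2]] + 1L
  }
  # table log-probability up to constants: h*log2 - sum(lfactorial(n_ab));
  # used only for the probability-test comparison. The chain itself runs on
  # labeled individuals, where the stationary weight reduces to 2^h.
  logw <- function(gc) {
    het <- sum(gc[upper.tri(gc)])
    het * log(2) - sum(lfactorial(gc[upper.tri(gc, diag = TRUE)]))
  }
  cur <- logw(gcount)
  obs <- cur
  nhet <- sum(pairs[, 1] != pairs[, 2])

  set.seed(seed)
  total <- dememorization + iterations
  le_obs <- logical(iterations)
  eps <- 1e-9
  pick <- matrix(sample.int(n, 2L * total, replace = TRUE), ncol = 2L)
  uacc <- stats::runif(total)
  uside <- stats::runif(total)

  # the two alternative matchings of the four alleles held by two genotypes
  matchings <- function(g1, g2) {
    list(list(sort(c(g1[1], g2[1])), sort(c(g1[2], g2[2]))),
         list(sort(c(g1[1], g2[2])), sort(c(g1[2], g2[1]))))
  }
  same_pairset <- function(m, q1, q2) {
    (all(m[[1]] == q1) && all(m[[2]] == q2)) ||
      (all(m[[1]] == q2) && all(m[[2]] == q1))
  }
  # Metropolis-Hastings on genotype-count tables: the proposal picks two
  # random individuals and one of the two re-pairings of their four alleles,
  # so the proposal probability of a table move is proportional to
  # picks(A,B) * m, with picks the ordered ways of drawing the two source
  # genotype categories and m the number of re-pairings landing on the same
  # target table; the acceptance ratio corrects for both.
  for (t in seq_len(total)) {
    i <- pick[t, 1]; j <- pick[t, 2]
    if (i != j) {
      g1 <- pairs[i, ]; g2 <- pairs[j, ]
      ms <- matchings(g1, g2)
      prop <- if (uside[t] < 0.5) ms[[1]] else ms[[2]]
      p1 <- prop[[1]]; p2 <- prop[[2]]
      if (!same_pairset(list(g1, g2), p1, p2)) {
        dhet <- (p1[1] != p1[2]) + (p2[1] != p2[2]) -
          (g1[1] != g1[2]) - (g2[1] != g2[2])
        sameAB <- all(g1 == g2); sameCD <- all(p1 == p2)
        nA <- gcount[g1[1], g1[2]]; nB <- gcount[g2[1], g2[2]]
        # target-state counts of the new categories
        tmp <- gcount
        tmp[g1[1], g1[2]] <- tmp[g1[1], g1[2]] - 1L
        tmp[g2[1], g2[2]] <- tmp[g2[1], g2[2]] - 1L
        tmp[p1[1], p1[2]] <- tmp[p1[1], p1[2]] + 1L
        tmp[p2[1], p2[2]] <- tmp[p2[1], p2[2]] + 1L
        nC <- tmp[p1[1], p1[2]]; nD <- tmp[p2[1], p2[2]]
        # pi ratio: 2^dh * prod(old counts!)/prod(new counts!)
        lr <- dhet * log(2) +
          log(nA) + log(if (sameAB) nB - 1 else nB) -
          log(nC) - log(if (sameCD) nD - 1 else nD)
        picks_f <- if (sameAB) nA * (nA - 1) else 2 * nA * nB
        picks_r <- if (sameCD) nC * (nC - 1) else 2 * nC * nD
        m_f <- sum(vapply(ms, same_pairset, logical(1), p1, p2))
        ms_rev <- matchings(p1, p2)
        m_r <- sum(vapply(ms_rev, same_pairset, logical(1), g1, g2))
        lr <- lr + log(picks_r * m_r) - log(picks_f * m_f)
        if (log(uacc[t]) < lr) {
          gcount <- tmp
          cur <- logw(gcount)
          nhet <- nhet + dhet
          pairs[i, ] <- p1; pairs[j, ] <- p2
        }
      }
    }
    if (t > dememorization) le_obs[t - dememorization] <- cur <= obs + eps
  }
  p <- mean(le_obs)
  # batch-means SE accounts for chain autocorrelation
  nb <- 50L
  bs <- floor(iterations / nb)
  bm <- vapply(seq_len(nb), function(b)
    mean(le_obs[((b - 1L) * bs + 1L):(b * bs)]), numeric(1))
  se <- stats::sd(bm) / sqrt(nb)
  list(p = p, se = se, direction = direction, n = n, k = k)
}

#' Exact HWE p-value by full enumeration (two alleles)
#'
#' Direct summation of Levene's conditional distribution over every genotype
#' table compatible with the observed allele counts at a biallelic locus.
#' Exact and deterministic; practical for small samples, and the reference
#' the Markov-chain estimate is validated against.
#'
#' @param n11,n12,n22 observed genotype counts (allele 1 homozygote,
#'   heterozygote, allele 2 homozygote).
#' @return The exact probability-test p-value.
#' @export
exact_hwe_enumerate <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  m1 <- 2L * n11 + n12           # allele-1 count
  if (m1 == 0L || m1 == 2L * n)
    stop("monomorphic locus: exact HWE test undefined")
  logp <- function(h) {          # h = heterozygote count, parity fixed
    a11 <- (m1 - h) / 2; a22 <- n - a11 - h
    lfactorial(n) - lfactorial(a11) - lfactorial(h) - lfactorial(a22) +
      h * log(2) + lfactorial(m1) + lfactorial(2L * n - m1) -
      lfactorial(2L * n)
  }
  hs <- seq(m1 %% 2L, min(m1, 2L * n - m1), by = 2L)
  lp <- vapply(hs, logp, numeric(1))
  p_obs <- lp[match(n12, hs)]
  if (is.na(p_obs)) stop("genotype counts inconsistent with allele counts")
  sum(exp(lp[lp <= p_obs + 1e-9]))
}
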