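#' Effective migrant number from F_ST (Wright's formula)
#'
#' `N_e m = 1/F_ST - 1`, the form used in classic island-model summaries of
#' microsatellite surveys. The standard island-model rearrangement
#' `N_e m = (1 - F_ST)/(4 F_ST)` is available via `form = "island"`; the two
#' differ by roughly a factor of 4 at small F_ST, so the choice must be
#' reported alongside the estimate.
#'
#' @param fst F_ST estimate in `(0, 1]`.
#' @param form `"wright"` (default) or `"island"`.
#' @return `N_e m`; `Inf` (with a warning) when `fst <= 0`, where gene flow
#'   is effectively unbounded.
#' @export
nem_wright <- function(fst, form = c("wright", "island")) {
  form <- match.arg(form)
  if (fst > 1) stop("F_ST cannot exceed 1")
  if (fst <= 0) {
    warning("F_ST <= 0: gene flow unbounded")
    return(Inf)
  }
  switch(form,
         wright = 1 / fst - 1,
         island = (1 - fst) / (4 * fst))
}

# Slatkin's (1985) log-log regression of mean private-allele frequency on
# N_e m, fitted at reference sample sizes 10, 25, 50: ln p(1) = a ln(Nm) + b
slatkin_coefficients <- data.frame(
  n = c(10, 25, 50),
  a = c(-0.505, -0.577, -0.611),
  b = c(-2.440, -2.609, -2.585))

#' Gene flow from private alleles (Barton-Slatkin method)
#'
#' Inverts Slatkin's regression of the log mean private-allele frequency
#' `p(1)` on `ln(N_e m)`, using the published coefficients for reference
#' sample sizes 10, 25 and 50 and log-linear interpolation to the data's
#' mean per-site sample size.
#'
#' @param x a [genotype_table()].
#' @param p1 optionally, a precomputed mean private-allele frequency
#'   (otherwise computed from `x` via [private_alleles()]).
#' @param mean_n optionally, the mean per-site sample size (individuals).
#' @return A list: `nem`, `p1`, `mean_n`; `nem = Inf` flagged when no
#'   private alleles exist.
#' @export
nem_private <- function(x = NULL, p1 = NULL, mean_n = NULL) {
  if (is.null(p1)) {
    pa <- private_alleles(x)
    p1 <- pa$p1
    if (is.null(mean_n)) mean_n <- mean(table(x$site))
  }
  if (is.null(mean_n)) stop("mean_n required when p1 is supplied directly")
  if (is.na(p1) || p1 <= 0) {
    warning("no private alleles: N_e m unbounded")
    return(list(nem = Inf, p1 = p1, mean_n = mean_n))
  }
  co <- slatkin_coefficients
  nem_at <- function(row) exp((log(p1) - co$b[row]) / co$a[row])
  ns <- co$n
  if (mean_n <= ns[1]) {
    nem <- nem_at(1)
  } else if (mean_n >= ns[length(ns)]) {
    nem <- nem_at(nrow(co))
  } else {
    hi <- which(ns >= mean_n)[1]; lo <- hi - 1L
    w <- (log(mean_n) - log(ns[lo])) / (log(ns[hi]) - log(ns[lo]))
    nem <- exp((1 - w) * log(nem_at(lo)) + w * log(nem_at(hi)))
  }
  list(nem = nem, p1 = p1, mean_n = mean_n)
}

#' Contemporary effective population size by the LD method
#'
#' Waples & Do's (2008) linkage-disequilibrium estimator from a single
#' sample: the mean squared allelic correlation `r^2` over all pairs of loci
#' and alleles (Burrows' composite disequilibrium on unordered genotypes),
#' corrected for the sample-size expectation under random mating
#' (Waples 2006): `E[r^2] = 1/S + 3.19/S^2` for `S >= 30`, else
#' `0.0018 + 0.907/S + 4.44/S^2`. The drift component `r2' = r2 - E[r2]`
#' converts to
#' `N_e = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')` for `S >= 30`
#' (`N_e = (0.308 + sqrt(0.308^2 - 2.08 r2')) / (2 r2')` below), with
#' `r2' <= 0` reported as infinite. Alleles rarer than `freq_cutoff` are
#' excluded. A parametric chi-square confidence interval on `r^2` (degrees
#' of freedom = number of allele-pair comparisons) is transformed to the Ne
#' scale.
#'
#' @param x a [genotype_table()] (a single site; pass a subset for per-site
#'   estimates), or `NULL` when `a1`/`a2` matrices are given.
#' @param freq_cutoff minimum allele frequency retained (default 0.02).
#' @param ci confidence level (default 0.95).
#' @return A list of class `ne_estimate`: `ne` (possibly `Inf`), `ci`
#'   (2-vector), `r2`, `r2_drift`, `expected_r2`, `n` (harmonic mean sample
#'   size over locus pairs), `n_comparisons`.
#' @export
ld_ne <- function(x, freq_cutoff = 0.02, ci = 0.95) {
  L <- n_loci(x)
  if (L < 2L) stop("need >= 2 loci")
  n <- n_ind(x)
  if (n < 10L) warning("n < 10: LD-Ne will be very noisy")
  # per-locus retained alleles and dosage matrices
  dosages <- vector("list", L)
  for (li in seq_len(L)) {
    a <- x$a1[, li]; b <- x$a2[, li]
    obs <- c(a, b); obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    f <- table(obs) / length(obs)
    keep <- as.integer(names(f)[f >= freq_cutoff & f <= 1 - freq_cutoff])
    if (length(keep) < 1L) next
    m <- sapply(keep, function(al) (a == al) + (b == al))
    dosages[[li]] <- matrix(m, ncol = length(keep))
  }
  usable <- which(!vapply(dosages, is.null, logical(1)) &
                    vapply(dosages, function(d) !is.null(d) && ncol(d) > 0,
                           logical(1)))
  if (length(usable) < 2L) stop("fewer than 2 usable polymorphic loci")
  r2s <- numeric(0); ns <- numeric(0)
  for (ii in seq_along(usable)[-1]) {
    for (jj in seq_len(ii - 1L)) {
      l1 <- usable[ii]; l2 <- usable[jj]
      d1 <- dosages[[l1]]; d2 <- dosages[[l2]]
      okpair <- stats::complete.cases(d1[, 1], d2[, 1])
      S <- sum(okpair)
      if (S < 5L) next
      for (u in seq_len(ncol(d1))) for (v in seq_len(ncol(d2))) {
        g1 <- d1[okpair, u]; g2 <- d2[okpair, v]
        p <- mean(g1) / 2; q <- mean(g2) / 2
        if (p <= 0 || p >= 1 || q <= 0 || q >= 1) next
        delta <- (S / (S - 1)) * (mean(g1 * g2) / 2 - 2 * p * q)
        r2s <- c(r2s, delta^2 / (p * (1 - p) * q * (1 - q)))
        ns <- c(ns, S)
      }
    }
  }
  if (!length(r2s)) stop("no allele-pair comparisons available")
  r2 <- mean(r2s)
  S <- length(ns) / sum(1 / ns)              # harmonic mean sample size
  er2 <- if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  r2d <- r2 - er2
  ne_from <- function(r2d) {
    if (!is.finite(r2d) || r2d <= 0) return(Inf)
    if (S >= 30) {
      disc <- 1 / 9 - 2.76 * r2d
      if (disc < 0) disc <- 0
      (1 / 3 + sqrt(disc)) / (2 * r2d)
    } else {
      disc <- 0.308^2 - 2.08 * r2d
      if (disc < 0) disc <- 0
      (0.308 + sqrt(disc)) / (2 * r2d)
    }
  }
  J <- length(r2s)
  alpha <- 1 - ci
  lo_r2 <- J * r2 / stats::qchisq(alpha / 2, J, lower.tail = FALSE)
  hi_r2 <- J * r2 / stats::qchisq(1 - alpha / 2, J, lower.tail = FALSE)
  structure(
    list(ne = ne_from(r2d), ci = c(ne_from(hi_r2 - er2), ne_from(lo_r2 - er2)),
         r2 = r2, r2_drift = r2d, expected_r2 = er2, n = S,
         n_comparisons = J, freq_cutoff = freq_cutoff),
    class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmtne <- function(v) if (is.infinite(v)) "Inf" else sprintf("%.1f", v)
  cat("<ne_estimate> Ne =", fmtne(x$ne),
      sprintf("(%s, %s); r2 = %.5f, E[r2] = %.5f, n = %.1f, comparisons = %d\n",
              fmtne(x$ci[1]), fmtne(x$ci[2]), x$r2, x$expected_r2, x$n,
              x$n_comparisons))
  invisible(x)
}
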