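#' Van Oosterhout null-allele frequency estimate
#'
#' From the excess of apparent homozygotes at one site x locus:
#' `r = (He - Ho) / (1 + He)`, with `He` the unbiased expected and `Ho` the
#' observed heterozygosity. Negative estimates are truncated to 0 (r is a
#' frequency).
#'
#' When null homozygotes drop out of the sample entirely (scored as missing
#' data), this estimator carries a mild downward bias; the Chakraborty
#' variant `r = (He - Ho)/(He + Ho)`, which assumes exactly that dropout
#' model, is available via `method = "chakraborty"`.
#'
#' @param a1,a2 allele vectors at one locus for one site.
#' @param method `"oosterhout"` (default) or `"chakraborty"`.
#' @return Estimated null frequency `r`, `NA` if He is undefined.
#' @export
estimate_null_freq <- function(a1, a2, method = c("oosterhout", "chakraborty")) {
  method <- match.arg(method)
  h <- heterozygosity(a1, a2)
  if (h$n == 0L || is.na(h$He) || h$Na < 2L) return(NA_real_)
  if (h$n < 10L)
    warning("n = ", h$n, " < 10: null-frequency estimate will be noisy")
  max(0, switch(method,
                oosterhout = (h$He - h$Ho) / (1 + h$He),
                chakraborty = (h$He - h$Ho) / (h$He + h$Ho)))
}

#' Null-frequency matrix over sites and loci
#'
#' @param x a [genotype_table()].
#' @return sites x loci matrix of Van Oosterhout `r` estimates.
#' @export
null_freq_matrix <- function(x) {
  sites <- levels(x$site)
  r <- matrix(NA_real_, length(sites), n_loci(x),
              dimnames = list(sites, x$loci))
  for (s in seq_along(sites)) {
    sel <- x$site == sites[s]
    for (li in seq_len(n_loci(x)))
      r[s, li] <- suppressWarnings(
        estimate_null_freq(x$a1[sel, li], x$a2[sel, li]))
  }
  r
}

#' Flag loci likely to carry null alleles
#'
#' A locus is flagged iff its estimated null frequency exceeds `threshold`
#' in at least `min_sites` sites; by default `min_sites` is a majority of the
#' sites where the locus is polymorphic (where `r` is defined).
#'
#' @param r sites x loci matrix from [null_freq_matrix()].
#' @param threshold null-frequency cutoff per site (default 0.05).
#' @param min_sites minimum qualifying sites; `NULL` = majority rule.
#' @return Named logical vector per locus.
#' @export
flag_null_loci <- function(r, threshold = 0.05, min_sites = NULL) {
  vapply(seq_len(ncol(r)), function(li) {
    def <- !is.na(r[, li])
    ms <- if (is.null(min_sites)) floor(sum(def) / 2) + 1L else min_sites
    sum(r[def, li] > threshold) >= ms && sum(def) > 0L
  }, logical(1)) |> stats::setNames(colnames(r))
}

#' Apply the null-allele correction to a genotype table
#'
#' At each flagged locus and site, the expected number of apparent
#' homozygotes that are really heterozygous for a null allele is recoded as
#' visible-allele / null-allele heterozygotes. The synthetic null allele is
#' labelled largest observed allele + one repeat unit (shifted by further
#' repeats if that size is already in use, with a warning). For an apparent
#' homozygote `a/a`, the probability of being a hidden `a/null` under HWE is
#' `2r / (p_a + 2r)`; the expected count per visible allele is recoded,
#' choosing which individuals deterministically under `seed`. Unflagged loci
#' are untouched.
#'
#' @param x a [genotype_table()].
#' @param r null-frequency matrix (default recomputed).
#' @param flags per-locus logical flags (default recomputed).
#' @param seed integer seed controlling which homozygotes are recoded.
#' @return An adjusted `genotype_table`.
#' @export
apply_oosterhout <- function(x, r = null_freq_matrix(x),
                             flags = flag_null_loci(r), seed = 1L) {
  a1 <- x$a1; a2 <- x$a2
  sites <- levels(x$site)
  set.seed(seed)
  for (li in which(flags)) {
    obs <- c(a1[, li], a2[, li]); obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    null_lab <- max(obs) + x$repeat_unit[li]
    while (null_lab %in% obs) {
      warning("null label collides with an observed allele at ",
              x$loci[li], "; shifting by one more repeat")
      null_lab <- null_lab + x$repeat_unit[li]
    }
    for (s in sites) {
      rs <- r[s, li]
      if (is.na(rs) || rs <= 0) next
      sel <- which(x$site == s)
      af <- c(table(c(a1[sel, li], a2[sel, li])))
      af <- af / sum(af)
      hom <- sel[!is.na(a1[sel, li]) & a1[sel, li] == a2[sel, li]]
      if (!length(hom)) next
      for (al in unique(a1[hom, li])) {
        cand <- hom[a1[hom, li] == al]
        pa <- af[as.character(al)]
        n_recode <- round(length(cand) * 2 * rs / (pa + 2 * rs))
        if (n_recode > 0L) {
          chosen <- cand[sample.int(length(cand), min(n_recode, length(cand)))]
          a2[chosen, li] <- as.integer(null_lab)
        }
      }
    }
  }
  genotype_table(a1, a2, x$individuals, x$loci, x$site, x$repeat_unit)
}
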