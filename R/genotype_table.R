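#' Diploid multilocus genotype table
#'
#' The central container of the package: unordered diploid allele calls
#' (integer fragment sizes in bp) for a set of individuals scored at a set of
#' microsatellite loci, together with the assignment of each individual to a
#' sampling site. Missing data are per individual, per locus (both allele
#' slots `NA`); partial single-allele calls are not representable, following
#' GenePop convention.
#'
#' Internally the calls are held as two integer matrices `a1`, `a2`
#' (individuals x loci) with `a1 <= a2` wherever scored, so that comparison of
#' genotypes is order-independent by construction.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes in bp;
#'   `NA` in both marks a missing call. Rows are individuals, columns loci.
#' @param individuals character vector of unique individual ids.
#' @param loci character vector of unique locus names.
#' @param site factor or character vector assigning each individual to a site.
#' @param repeat_unit integer vector of per-locus repeat-unit lengths (bp);
#'   recycled if length 1.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, individuals, loci, site,
                           repeat_unit = 3L) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individuals); L <- length(loci)
  if (!all(dim(a1) == c(n, L)) || !all(dim(a2) == c(n, L)))
    stop("allele matrices must be individuals x loci")
  if (anyDuplicated(individuals))
    stop("duplicate individual ids: ",
         paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  if (anyDuplicated(loci)) stop("duplicate locus names")
  if (length(site) != n) stop("'site' must have one entry per individual")
  miss1 <- is.na(a1); miss2 <- is.na(a2)
  if (any(miss1 != miss2))
    stop("half-missing genotypes are not representable; both alleles must be NA")
  if (any(a1[!miss1] <= 0L) || any(a2[!miss2] <= 0L))
    stop("allele sizes must be positive integers")
  # canonical order within the pair
  swap <- !miss1 & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  repeat_unit <- as.integer(rep_len(repeat_unit, L))
  if (any(repeat_unit < 1L)) stop("repeat units must be >= 1 bp")
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  structure(
    list(a1 = a1, a2 = a2,
         individuals = as.character(individuals),
         loci = as.character(loci),
         site = factor(site),
         repeat_unit = stats::setNames(repeat_unit, loci)),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", n_ind(x), " individuals, ", n_loci(x),
      " loci, ", nlevels(x$site), " sites\n", sep = "")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  tab <- table(x$site)
  cat("  site sizes: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Numbers of individuals, loci and sites
#' @param x a `genotype_table`.
#' @return An integer.
#' @export
n_ind <- function(x) length(x$individuals)

#' @rdname n_ind
#' @export
n_loci <- function(x) length(x$loci)

#' @rdname n_ind
#' @export
site_sizes <- function(x) table(droplevels(x$site))

#' Subset a genotype table by individuals
#'
#' Keeps genotypes, site assignment and locus attributes of the retained
#' individuals untouched; site levels with no remaining members are dropped.
#'
#' @param x a `genotype_table`.
#' @param keep logical/integer/character index of individuals to retain.
#' @return A `genotype_table`.
#' @export
subset_individuals <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$individuals)
  a1 <- x$a1[keep, , drop = FALSE]
  genotype_table(a1, x$a2[keep, , drop = FALSE],
                 individuals = rownames(a1), loci = x$loci,
                 site = droplevels(x$site[keep]),
                 repeat_unit = x$repeat_unit)
}

#' Per-site allele frequencies and gene counts for one locus
#'
#' @param x a `genotype_table`.
#' @param locus locus name or index.
#' @return A list with `freq` (sites x alleles matrix of frequencies summing
#'   to 1 per site over observed alleles), `count` (same shape, raw allele
#'   counts), and `genes` (genes scored per site, i.e. 2 x individuals).
#' @export
allele_freqs <- function(x, locus) {
  li <- if (is.character(locus)) match(locus, x$loci) else as.integer(locus)
  if (is.na(li) || li < 1L || li > n_loci(x)) stop("unknown locus: ", locus)
  alleles <- sort(unique(c(x$a1[, li], x$a2[, li])))
  alleles <- alleles[!is.na(alleles)]
  sites <- levels(x$site)
  count <- matrix(0L, length(sites), length(alleles),
                  dimnames = list(sites, as.character(alleles)))
  for (s in seq_along(sites)) {
    sel <- x$site == sites[s]
    obs <- c(x$a1[sel, li], x$a2[sel, li])
    obs <- obs[!is.na(obs)]
    if (length(obs)) {
      t <- table(factor(obs, levels = alleles))
      count[s, ] <- as.integer(t)
    }
  }
  genes <- rowSums(count)
  freq <- count / ifelse(genes > 0, genes, 1)
  list(freq = freq, count = count, genes = genes, alleles = alleles)
}

#' Summarise allele content per locus
#'
#' @param x a `genotype_table`.
#' @return A data.frame with one row per locus: `locus`, `n_alleles`,
#'   `repeat_unit`, `n_scored` (individuals with a call at the locus).
#' @export
locus_summary <- function(x) {
  data.frame(
    locus = x$loci,
    n_alleles = vapply(seq_len(n_loci(x)), function(li) {
      length(unique(stats::na.omit(c(x$a1[, li], x$a2[, li]))))
    }, integer(1)),
    repeat_unit = unname(x$repeat_unit),
    n_scored = colSums(!is.na(x$a1)),
    row.names = NULL)
}

#' Remove small sites from a genotype table
#'
#' Sites whose sample size does not exceed `min_n` are dropped, along with
#' their individuals. The default `min_n = 12` keeps sites with n > 12, the
#' usual inclusion rule for per-site statistical analysis of sled-sampled
#' coral collections.
#'
#' @param x a `genotype_table`.
#' @param min_n sites with n <= `min_n` are removed (strict rule).
#' @return A filtered `genotype_table`.
#' @export
filter_min_n <- function(x, min_n = 12L) {
  stopifnot(min_n >= 0)
  tab <- table(x$site)
  keep_sites <- names(tab)[tab > min_n]
  if (length(keep_sites) == 0L)
    stop("no site exceeds min_n = ", min_n, "; empty result")
  subset_individuals(x, x$site %in% keep_sites)
}

#' Snap raw allele sizes to the locus repeat lattice
#'
#' Fragment-size binning: each allele at a locus is replaced by the nearest
#' point of the lattice `anchor + k * repeat_unit`, where the anchor is the
#' modal raw allele of the locus (ties between lattice points round toward
#' the anchor). Idempotent on already-binned data.
#'
#' @param x a `genotype_table` with per-locus repeat units set.
#' @return A `genotype_table` with binned allele sizes.
#' @export
bin_alleles <- function(x) {
  a1 <- x$a1; a2 <- x$a2
  for (li in seq_len(n_loci(x))) {
    ru <- x$repeat_unit[li]
    obs <- c(a1[, li], a2[, li]); obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    tab <- table(obs)
    anchor <- as.integer(names(tab)[which.max(tab)])
    snap <- function(a) {
      k <- (a - anchor) / ru
      # ties (half-integer k) round toward the anchor, i.e. truncate
      anchor + as.integer(ru * ifelse(abs(k - trunc(k)) == 0.5,
                                      trunc(k), round(k)))
    }
    a1[, li] <- ifelse(is.na(a1[, li]), NA_integer_, snap(a1[, li]))
    a2[, li] <- ifelse(is.na(a2[, li]), NA_integer_, snap(a2[, li]))
  }
  genotype_table(a1, a2, x$individuals, x$loci, x$site, x$repeat_unit)
}
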