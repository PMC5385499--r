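#' Partition individuals into multilocus genotypes (MLGs)
#'
#' Two individuals belong to the same MLG iff they are identical at every
#' locus at which both are scored, and each has at most `max_missing` missing
#' loci; matching is closed transitively, so an individual with one missing
#' locus can bridge two complete profiles. Individuals with more than
#' `max_missing` missing loci are kept as singletons and flagged
#' "unassessed" (their profile is too incomplete to claim clonemates).
#'
#' @param x a [genotype_table()].
#' @param max_missing maximum missing loci for an individual to take part in
#'   clone matching (default 1).
#' @return A `clone_report`: list with `mlg` (integer MLG id per individual),
#'   `unassessed` (logical per individual), `sites` (per-site `N`, `G`,
#'   `NgN`, `R`), and `mlg_table` (one row per MLG: size, sites, members).
#' @export
find_mlgs <- function(x, max_missing = 1L) {
  n <- n_ind(x); L <- n_loci(x)
  if (n == 0L) stop("empty table")
  nmiss <- rowSums(is.na(x$a1))
  eligible <- nmiss <= max_missing

  # wildcard match: identical wherever both scored
  matches <- function(i, j) {
    both <- !is.na(x$a1[i, ]) & !is.na(x$a1[j, ])
    all(x$a1[i, both] == x$a1[j, both] & x$a2[i, both] == x$a2[j, both])
  }
  # union-find for transitive closure
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idx <- which(eligible)
  if (length(idx) > 1L) {
    # exact-profile groups collapse first (cheap); the quadratic wildcard
    # pass then only has to bridge profiles that differ by missing loci
    key <- apply(cbind(x$a1, x$a2), 1, paste, collapse = "/")
    for (k in unique(key[idx])) {
      grp <- idx[key[idx] == k]
      for (j in grp[-1]) parent[find(j)] <- find(grp[1])
    }
    heads <- idx[!duplicated(key[idx])]
    incomplete <- idx[nmiss[idx] > 0L]
    pairs_i <- unique(c(heads, incomplete))
    for (ai in seq_along(pairs_i)) {
      i <- pairs_i[ai]
      for (aj in seq_len(ai - 1L)) {
        j <- pairs_i[aj]
        ri <- find(i); rj <- find(j)
        if (ri != rj && matches(i, j)) parent[ri] <- rj
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  mlg <- match(root, unique(root))

  rep_out <- structure(
    list(mlg = mlg, unassessed = !eligible, site = x$site,
         individuals = x$individuals),
    class = "clone_report")
  rep_out$sites <- site_genotypic_summary(rep_out)
  rep_out$mlg_table <- mlg_summary(rep_out)
  rep_out
}

site_genotypic_summary <- function(rep) {
  sites <- levels(rep$site)
  out <- data.frame(site = sites, N = NA_integer_, G = NA_integer_,
                    NgN = NA_real_, R = NA_real_)
  for (s in seq_along(sites)) {
    sel <- rep$site == sites[s]
    N <- sum(sel)
    G <- length(unique(rep$mlg[sel]))
    out$N[s] <- N; out$G[s] <- G
    out$NgN[s] <- G / N
    out$R[s] <- genotypic_richness(N, G)
  }
  out
}

mlg_summary <- function(rep) {
  ids <- sort(unique(rep$mlg))
  data.frame(
    mlg = ids,
    size = vapply(ids, function(m) sum(rep$mlg == m), integer(1)),
    sites = vapply(ids, function(m)
      paste(sort(unique(as.character(rep$site[rep$mlg == m]))),
            collapse = ";"), character(1)),
    members = vapply(ids, function(m)
      paste(rep$individuals[rep$mlg == m], collapse = ";"), character(1)),
    row.names = NULL)
}

#' @export
print.clone_report <- function(x, ...) {
  cat("<clone_report> ", length(x$mlg), " individuals, ",
      length(unique(x$mlg)), " MLGs\n", sep = "")
  print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Probability of a multilocus genotype under random mating
#'
#' P_gen: the product over scored loci of the Hardy-Weinberg genotype
#' probability (`p^2` for a homozygote, `2 p q` for a heterozygote) computed
#' from site-level allele frequencies of the full, unclone-corrected sample.
#' Missing loci contribute a factor of 1.
#'
#' @param genotype a 2-row matrix or list of allele pairs: `genotype[1, l]`,
#'   `genotype[2, l]` are the two alleles at locus `l` (`NA` = missing).
#' @param freqs a list per locus of named allele-frequency vectors (names =
#'   allele sizes), as from [allele_freqs()] for the site of occurrence.
#' @return A probability.
#' @export
p_gen <- function(genotype, freqs) {
  genotype <- as.matrix(genotype)
  L <- ncol(genotype)
  if (length(freqs) != L) stop("one frequency vector needed per locus")
  p <- 1
  for (l in seq_len(L)) {
    a <- genotype[1, l]; b <- genotype[2, l]
    if (is.na(a)) next
    f <- freqs[[l]]
    fa <- f[as.character(a)]; fb <- f[as.character(b)]
    if (anyNA(c(fa, fb)))
      stop("allele absent from the frequency table at locus ", l,
           " (frequencies must come from the same sample)")
    p <- p * if (a == b) fa^2 else 2 * fa * fb
  }
  unname(p)
}

#' Probability that repeats of a genotype arose by sexual reproduction
#'
#' Given one observed copy of an MLG with genotype probability `p_gen` in a
#' sample of `N`, the chance that at least `n_copies - 1` of the remaining
#' `N - 1` individuals carry the same genotype through independent sexual
#' events: the upper binomial tail `Pr[X >= n_copies - 1]`,
#' `X ~ Binomial(N - 1, p_gen)`.
#'
#' @param p_gen genotype probability in `[0, 1]`.
#' @param n_copies observed copy number of the MLG (>= 2).
#' @param N sample size (>= n_copies).
#' @return A probability.
#' @export
p_sex <- function(p_gen, n_copies, N) {
  if (p_gen < 0 || p_gen > 1) stop("p_gen must be in [0, 1]")
  stopifnot(n_copies >= 2, N >= n_copies)
  stats::pbinom(n_copies - 2L, size = N - 1L, prob = p_gen,
                lower.tail = FALSE)
}

#' Genotypic richness
#'
#' `R = (G - 1) / (N - 1)`: 0 when every individual shares one genotype,
#' 1 when all `N` genotypes are unique.
#'
#' @param N number of samples (>= 2 for a defined value).
#' @param G number of unique multilocus genotypes, `1 <= G <= N`.
#' @return `R`, or `NA` when `N < 2`.
#' @export
genotypic_richness <- function(N, G) {
  stopifnot(G >= 1, G <= N)
  if (N < 2) return(NA_real_)
  (G - 1) / (N - 1)
}

#' Attach P_gen and P_sex to the repeated MLGs of a clone report
#'
#' For each MLG observed more than once, computes P_gen from the allele
#' frequencies of the site(s) where it occurs (full sample, clones included)
#' and the binomial-tail P_sex for its copy number. An MLG spanning several
#' sites is evaluated against the pooled frequencies of those sites.
#'
#' @param x the [genotype_table()] the report was computed on.
#' @param rep a `clone_report` from [find_mlgs()].
#' @return The report with `mlg_table` gaining `p_gen` and `p_sex` columns.
#' @export
clone_probabilities <- function(x, rep) {
  tab <- rep$mlg_table
  tab$p_gen <- NA_real_; tab$p_sex <- NA_real_
  af <- lapply(seq_len(n_loci(x)), function(li) allele_freqs(x, li))
  for (r in seq_len(nrow(tab))) {
    if (tab$size[r] < 2L) next
    members <- which(rep$mlg == tab$mlg[r])
    i <- members[which.min(rowSums(is.na(x$a1[members, , drop = FALSE])))]
    sites <- unique(as.character(rep$site[members]))
    freqs <- lapply(af, function(a) {
      cnt <- colSums(a$count[sites, , drop = FALSE])
      tot <- sum(cnt)
      stats::setNames(if (tot > 0) cnt / tot else cnt, colnames(a$count))
    })
    g <- rbind(x$a1[i, ], x$a2[i, ])
    pg <- p_gen(g, freqs)
    Nsites <- sum(rep$site %in% sites)
    tab$p_gen[r] <- pg
    tab$p_sex[r] <- p_sex(pg, tab$size[r], Nsites)
  }
  rep$mlg_table <- tab
  rep
}

#' Condense clones to one representative per site
#'
#' Within each site, every MLG keeps exactly one representative individual
#' (the lexicographically lowest id, for determinism); an MLG spanning two
#' sites keeps one representative in each. Used before gene-flow analyses so
#' that differentiation reflects sexual propagules, not clonal spread.
#' Idempotent.
#'
#' @param x a [genotype_table()].
#' @param rep a `clone_report` computed on `x` (default: computed here).
#' @return A condensed `genotype_table`.
#' @export
condense_clones <- function(x, rep = find_mlgs(x)) {
  if (length(rep$mlg) != n_ind(x))
    stop("clone report does not match the table")
  keep <- logical(n_ind(x))
  key <- paste(rep$mlg, x$site)
  for (k in unique(key)) {
    members <- which(key == k)
    keep[members[order(x$individuals[members])[1]]] <- TRUE
  }
  subset_individuals(x, keep)
}
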