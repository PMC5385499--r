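#' Pairwise allele-mismatch distances between individuals
#'
#' Per locus the distance between two diploid genotypes is the number of
#' allele copies not shared (0, 1 or 2, counting multiplicity); distances
#' sum over loci scored in both individuals. This is the squared-distance
#' analogue used by allele-frequency AMOVA.
#'
#' @param x a [genotype_table()].
#' @return A symmetric numeric matrix (individuals x individuals).
#' @export
mismatch_dist <- function(x) {
  n <- n_ind(x)
  d <- matrix(0, n, n, dimnames = list(x$individuals, x$individuals))
  for (li in seq_len(n_loci(x))) {
    a <- x$a1[, li]; b <- x$a2[, li]
    ok <- !is.na(a)
    a[!ok] <- 0L; b[!ok] <- 0L   # sentinel; rows/cols masked below
    # allele pairs are stored in canonical (sorted) order, so multiset
    # equality is elementwise equality; otherwise any shared allele = 1 copy
    eq <- function(u, v) outer(u, v, "==")
    m_aa <- eq(a, a); m_ab <- eq(a, b); m_ba <- eq(b, a); m_bb <- eq(b, b)
    ident <- m_aa & m_bb
    any_shared <- m_aa | m_ab | m_ba | m_bb
    ov <- matrix(0L, n, n)
    ov[any_shared] <- 1L
    ov[ident] <- 2L
    dd <- 2L - ov
    dd[!ok, ] <- 0L; dd[, !ok] <- 0L
    d <- d + dd
  }
  diag(d) <- 0
  d
}

#' Hierarchical AMOVA (groups / sites / individuals)
#'
#' Excoffier-style analysis of molecular variance on allele-mismatch
#' distances at two spatial levels: among groups (e.g. seamounts), among
#' sites within groups, and within sites. Variance components are obtained
#' from the nested sums of squares; Phi-statistics are their standardized
#' ratios. Permutation p-values: whole sites are shuffled among groups for
#' `Phi_CT`; individuals are shuffled among sites within groups for
#' `Phi_SC`; individuals are shuffled among all sites for `Phi_ST`.
#'
#' @param x a [genotype_table()].
#' @param group factor over individuals giving the upper level (e.g.
#'   seamount of each individual's site).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return A list of class `amova_result`: `components` (sigma2 for the
#'   three levels), `phi` (`Phi_CT`, `Phi_SC`, `Phi_ST`), `p` (permutation
#'   p-values), `ss`, `df`.
#' @export
amova <- function(x, group, n_perm = 999L, seed = 1L) {
  site <- droplevels(x$site)
  group <- droplevels(factor(group))
  if (length(group) != n_ind(x)) stop("group must cover all individuals")
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  d2 <- mismatch_dist(x)
  obs <- amova_components(d2, site, group)
  set.seed(seed)
  cnt <- c(ct = 0L, sc = 0L, st = 0L)
  site_group <- tapply(as.character(group), site, `[`, 1)
  for (b in seq_len(n_perm)) {
    # Phi_CT: permute whole sites among groups
    pg <- sample(unname(site_group))
    g_ct <- factor(pg[as.integer(site)], levels = levels(group))
    v <- amova_components(d2, site, g_ct)
    if (!is.na(v$phi["Phi_CT"]) && v$phi["Phi_CT"] >= obs$phi["Phi_CT"])
      cnt["ct"] <- cnt["ct"] + 1L
    # Phi_SC: permute individuals among sites within their group
    s_sc <- site
    for (gl in levels(group)) {
      sel <- which(group == gl)
      s_sc[sel] <- sample(site[sel])
    }
    v <- amova_components(d2, s_sc, group)
    if (!is.na(v$phi["Phi_SC"]) && v$phi["Phi_SC"] >= obs$phi["Phi_SC"])
      cnt["sc"] <- cnt["sc"] + 1L
    # Phi_ST: permute individuals among all sites
    s_st <- sample(site)
    g_st <- factor(unname(site_group)[as.integer(s_st)],
                   levels = levels(group))
    v <- amova_components(d2, s_st, g_st)
    if (!is.na(v$phi["Phi_ST"]) && v$phi["Phi_ST"] >= obs$phi["Phi_ST"])
      cnt["st"] <- cnt["st"] + 1L
  }
  obs$p <- c(Phi_CT = (1 + cnt[["ct"]]) / (1 + n_perm),
             Phi_SC = (1 + cnt[["sc"]]) / (1 + n_perm),
             Phi_ST = (1 + cnt[["st"]]) / (1 + n_perm))
  obs$n_perm <- n_perm; obs$seed <- seed
  class(obs) <- "amova_result"
  obs
}

# variance components from squared distances for a site-within-group design
amova_components <- function(d2, site, group) {
  site <- droplevels(site)
  N <- nrow(d2)
  S <- nlevels(site); G <- nlevels(droplevels(group))
  ss_within <- function(sel) {
    if (length(sel) < 2L) return(0)
    sum(d2[sel, sel]) / (2 * length(sel))
  }
  SS_total <- sum(d2) / (2 * N)
  SS_wp <- sum(vapply(levels(site), function(s)
    ss_within(which(site == s)), numeric(1)))
  site_group <- tapply(as.character(group), site, `[`, 1)
  SS_g <- sum(vapply(unique(site_group), function(gl)
    ss_within(which(group == gl)), numeric(1)))
  SS_as <- SS_g - SS_wp          # among sites within groups
  SS_ag <- SS_total - SS_g       # among groups

  ni <- as.numeric(table(site))
  ng <- as.numeric(table(droplevels(factor(group))))
  sum_ni2_by_g <- vapply(levels(droplevels(factor(group))), function(gl) {
    s_in_g <- names(site_group)[site_group == gl]
    sum(ni[match(s_in_g, levels(site))]^2) /
      sum(ni[match(s_in_g, levels(site))])
  }, numeric(1))
  n1 <- (N - sum(sum_ni2_by_g)) / (S - G)
  n2 <- (sum(sum_ni2_by_g) - sum(ni^2) / N) / (G - 1)
  n3 <- (N - sum(ng^2) / N) / (G - 1)

  df <- c(among_groups = G - 1, among_sites = S - G, within_sites = N - S)
  MS_ag <- if (df[[1]] > 0) SS_ag / df[[1]] else NA_real_
  MS_as <- if (df[[2]] > 0) SS_as / df[[2]] else NA_real_
  MS_wp <- SS_wp / df[[3]]
  sig_c <- unname(MS_wp)
  # no within-group site replication: the among-sites level vanishes and
  # the design collapses to a single level (Phi_SC undefined)
  collapsed <- S == G
  sig_b <- if (collapsed) 0 else
    if (!is.na(MS_as)) unname((MS_as - sig_c) / n1) else NA_real_
  sig_a <- if (!is.na(MS_ag) && !is.na(sig_b))
    unname((MS_ag - sig_c - (if (collapsed) 0 else n2) * sig_b) / n3)
  else NA_real_
  tot <- sum(c(sig_a, sig_b, sig_c), na.rm = TRUE)
  phi <- c(
    Phi_CT = if (is.na(sig_a)) NA_real_ else sig_a / tot,
    Phi_SC = if (collapsed || is.na(sig_b)) NA_real_ else
      sig_b / (sig_b + sig_c),
    Phi_ST = if (is.na(sig_a) || is.na(sig_b)) NA_real_ else
      (sig_a + sig_b) / tot)
  list(components = c(among_groups = sig_a, among_sites = sig_b,
                      within_sites = sig_c),
       phi = phi,
       ss = c(among_groups = SS_ag, among_sites = SS_as,
              within_sites = SS_wp, total = SS_total),
       df = df)
}
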