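#' Fit the admixture model for one K by Gibbs sampling
#'
#' A Bayesian mixture model of genotype origin: each cluster k has its own
#' allele-frequency profile per locus (independent Dirichlet(1) priors), and
#' each individual an ancestry vector `q` drawn from Dirichlet(alpha), with
#' `alpha` learned by a Metropolis step. Latent allele-copy assignments are
#' Gibbs-sampled conditional on frequencies and ancestry. The no-admixture
#' variant assigns whole individuals to single clusters. Missing genotypes
#' are skipped in the likelihood.
#'
#' This sampler uses independent (not correlated) cluster allele-frequency
#' priors - a deliberate simplification relative to some admixture software;
#' its accuracy surface is recovery on simulated data.
#'
#' @param x a [genotype_table()] (clone-condensed or raw, caller's choice).
#' @param K number of clusters (>= 1).
#' @param burnin,iterations MCMC control (desk-scale defaults 5000/50000).
#' @param seed integer seed.
#' @param model `"admixture"` (default) or `"no_admixture"`.
#' @param alpha initial Dirichlet concentration for ancestry (default 1).
#' @param thin record every `thin`-th post-burn-in sweep (default 10).
#' @return A list: `Q` (individuals x K posterior-mean ancestry), `loglik`
#'   (recorded data log-likelihood trace), `mean_loglik`, `alpha`, `K`.
#' @export
fit_admixture <- function(x, K, burnin = 5000L, iterations = 50000L,
                          seed = 1L, model = c("admixture", "no_admixture"),
                          alpha = 1.0, thin = 10L) {
  model <- match.arg(model)
  if (K > n_ind(x)) stop("K exceeds the number of individuals")
  enc <- encode_alleles(x)
  set.seed(seed)
  res <- .gibbs_admixture(enc$geno, enc$nalleles, as.integer(K),
                          as.integer(burnin), as.integer(iterations),
                          alpha, model == "admixture", as.integer(thin))
  rownames(res$Q) <- x$individuals
  list(Q = res$Q, loglik = res$loglik_trace, mean_loglik = res$mean_loglik,
       alpha = res$alpha, K = K, model = model, seed = seed)
}

# integer allele codes 1..J per locus; 0 = missing; columns (l1c1,l1c2,l2c1,...)
encode_alleles <- function(x) {
  L <- n_loci(x)
  geno <- matrix(0L, n_ind(x), 2L * L)
  nalleles <- integer(L)
  for (li in seq_len(L)) {
    alleles <- sort(unique(stats::na.omit(c(x$a1[, li], x$a2[, li]))))
    nalleles[li] <- max(1L, length(alleles))
    c1 <- match(x$a1[, li], alleles); c2 <- match(x$a2[, li], alleles)
    geno[, 2L * li - 1L] <- ifelse(is.na(c1), 0L, c1)
    geno[, 2L * li] <- ifelse(is.na(c2), 0L, c2)
  }
  list(geno = geno, nalleles = nalleles)
}

#' Replicate admixture runs over a range of K
#'
#' Independent seeded replicates per K; replicate Q matrices are aligned to
#' the first replicate by greedy column matching (maximal column
#' correlation) before averaging, and the per-K mean and sd of the data
#' log-likelihood feed the Evanno table.
#'
#' @param x a [genotype_table()].
#' @param K_range integer vector of K values (e.g. `1:6`).
#' @param n_reps replicates per K (>= 3 for a usable sd; default 10).
#' @param burnin,iterations,thin MCMC control per run.
#' @param seed integer base seed; run r of K uses `seed + 1000*K + r`.
#' @param model passed to [fit_admixture()].
#' @return A list of class `cluster_scan`: per-K entries with `Q` (aligned,
#'   averaged), `L_mean`, `L_sd`, `replicates`; plus `selection` (the
#'   Evanno/L(K) table from [evanno_delta_k()]).
#' @export
run_replicates <- function(x, K_range, n_reps = 10L, burnin = 5000L,
                           iterations = 50000L, thin = 10L, seed = 1L,
                           model = "admixture") {
  runs <- list()
  for (K in K_range) {
    reps <- lapply(seq_len(n_reps), function(r)
      fit_admixture(x, K, burnin = burnin, iterations = iterations,
                    seed = seed + 1000L * K + r, model = model, thin = thin))
    Qs <- lapply(reps, `[[`, "Q")
    Qal <- Qs[[1]]
    if (length(Qs) > 1L)
      for (r in 2:length(Qs)) Qal <- Qal + align_q(Qs[[r]], Qs[[1]])
    Qavg <- Qal / length(Qs)
    Ls <- vapply(reps, `[[`, numeric(1), "mean_loglik")
    runs[[as.character(K)]] <- list(
      K = K, Q = Qavg, L_mean = mean(Ls), L_sd = stats::sd(Ls),
      L_reps = Ls)
  }
  ltab <- data.frame(
    K = as.integer(names(runs)),
    L_mean = vapply(runs, `[[`, numeric(1), "L_mean"),
    L_sd = vapply(runs, `[[`, numeric(1), "L_sd"),
    row.names = NULL)
  structure(list(runs = runs, selection = evanno_delta_k(ltab)),
            class = "cluster_scan")
}

# permute columns of Q to best match ref (greedy by correlation)
align_q <- function(Q, ref) {
  K <- ncol(Q)
  if (K == 1L) return(Q)
  cc <- suppressWarnings(stats::cor(Q, ref))
  cc[!is.finite(cc)] <- 0
  # greedy assignment: repeatedly take the highest remaining correlation
  # between an unused source column (row of cc) and unfilled target column
  perm <- integer(K)
  used <- logical(K)
  ord <- order(cc, decreasing = TRUE)
  for (o in ord) {
    i <- (o - 1L) %% K + 1L; j <- (o - 1L) %/% K + 1L
    if (!used[i] && perm[j] == 0L) { perm[j] <- i; used[i] <- TRUE }
    if (all(perm > 0L)) break
  }
  perm[perm == 0L] <- which(!used)
  Q[, perm, drop = FALSE]
}

#' Evanno's delta-K and L(K) selection table
#'
#' `deltaK = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, defined for interior K
#' with positive replicate sd. Both criteria (the K maximising deltaK and
#' the L(K) plateau) are reported; no single K is auto-selected, since the
#' two can legitimately disagree.
#'
#' @param ltab data.frame with columns `K`, `L_mean`, `L_sd` for
#'   consecutive K.
#' @return The table with a `deltaK` column and attributes
#'   `K_deltaK` (argmax of deltaK) and `K_Lmax` (argmax of `L_mean`).
#' @export
evanno_delta_k <- function(ltab) {
  ltab <- ltab[order(ltab$K), ]
  m <- nrow(ltab)
  ltab$deltaK <- NA_real_
  if (m >= 3L) {
    for (i in 2:(m - 1L)) {
      if (!is.na(ltab$L_sd[i]) && ltab$L_sd[i] > 0)
        ltab$deltaK[i] <- abs(ltab$L_mean[i + 1] - 2 * ltab$L_mean[i] +
                                ltab$L_mean[i - 1]) / ltab$L_sd[i]
    }
  }
  attr(ltab, "K_deltaK") <- if (all(is.na(ltab$deltaK))) NA_integer_ else
    ltab$K[which.max(ltab$deltaK)]
  attr(ltab, "K_Lmax") <- ltab$K[which.max(ltab$L_mean)]
  ltab
}

#' Export genotypes in STRUCTURE format
#'
#' One row per individual per allele copy (two rows per individual), with
#' the site index as the second column and -9 for missing, for users who
#' want to run the original program.
#'
#' @param x a [genotype_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(x$loci, collapse = "\t"), con)
  for (i in seq_len(n_ind(x))) {
    for (row in 1:2) {
      al <- if (row == 1) x$a1[i, ] else x$a2[i, ]
      al <- ifelse(is.na(al), -9L, al)
      writeLines(paste(c(x$individuals[i], as.integer(x$site[i]), al),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
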