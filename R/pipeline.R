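#' Run the full analysis pipeline
#'
#' Orchestrates the study-replica workflow on either a simulation preset or
#' a GenePop file plus metadata CSV: clone report (computed on all sites,
#' before any size filter), diversity and exact-HWE tables, null-allele
#' screen and (when loci are flagged) the adjusted dataset, clone
#' condensation and the n > `min_n` inclusion filter, global and pairwise
#' differentiation with permutation significance, AMOVA over
#' seamounts/sites, PCoA of the pairwise theta matrix, Mantel
#' isolation-by-distance, gene-flow and LD-Ne estimates, and an admixture
#' scan over a K range with the Evanno table. All outputs are written as
#' TSV under `out_dir`, plus a machine-readable JSON manifest of the main
#' statistics with the seeds used.
#'
#' When null alleles are flagged, the differentiation stage runs on both the
#' raw and the adjusted data for comparison.
#'
#' @param genepop,metadata input file paths (mutually exclusive with
#'   `preset`).
#' @param preset a simulation preset name for [preset_study()].
#' @param out_dir output directory (created).
#' @param seed master integer seed.
#' @param min_n site-inclusion threshold (keep n > min_n), default 12.
#' @param n_perm permutations for differentiation tests (default 999 at
#'   desk scale; set 9999 for final tables).
#' @param K_range K values for the clustering scan (default 1:4).
#' @param cluster_reps,cluster_burnin,cluster_iter clustering MCMC control.
#' @param scale preset scale factor (see [preset_study()]).
#' @return The manifest (a list), invisibly; side effect: report files.
#' @export
run_pipeline <- function(genepop = NULL, metadata = NULL, preset = NULL,
                         out_dir, seed = 1L, min_n = 12L, n_perm = 999L,
                         K_range = 1:4, cluster_reps = 3L,
                         cluster_burnin = 500L, cluster_iter = 2000L,
                         scale = 0.5) {
  if (is.null(preset) == is.null(genepop))
    stop("supply exactly one input source: preset or genepop+metadata")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  manifest <- list(seed = seed, input = if (is.null(preset)) genepop else preset)
  on_fail <- function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(preset)) {
      cfg <- preset_study(preset, scale = scale)
      sim <- simulate_population(cfg, seed = seed,
                                 metadata_template = attr(cfg, "metadata_template"))
      x <- sim$table; md <- sim$metadata
    } else {
      md <- read_site_metadata(metadata)
      x <- read_genepop(genepop, site_names = md$site_id)
    }

    stage <- "clonality"
    rep0 <- find_mlgs(x)
    rep0 <- clone_probabilities(x, rep0)
    write_tsv(rep0$sites, file.path(out_dir, "clone_sites.tsv"))
    write_tsv(rep0$mlg_table, file.path(out_dir, "clone_mlgs.tsv"))
    manifest$clonality <- list(
      mean_R = mean(rep0$sites$R, na.rm = TRUE),
      n_mlg = length(unique(rep0$mlg)),
      max_p_sex = suppressWarnings(
        max(rep0$mlg_table$p_sex, na.rm = TRUE)))

    stage <- "diversity_hwe"
    dv <- diversity_summary(x, hwe_iter = 2000L, hwe_demem = 200L,
                            seed = seed)
    write_tsv(dv$by_locus, file.path(out_dir, "diversity_by_locus.tsv"))
    write_tsv(dv$by_site, file.path(out_dir, "diversity_by_site.tsv"))
    manifest$diversity <- list(
      mean_Ho = mean(dv$by_site$mean_Ho, na.rm = TRUE),
      mean_He = mean(dv$by_site$mean_He, na.rm = TRUE),
      hwe_tests = dv$hwe_family_size,
      hwe_significant = sum(dv$by_locus$hwe_significant, na.rm = TRUE))
    fished <- stats::setNames(md$fished, md$site_id)
    anova_tab <- tryCatch(compare_fished(dv$by_site, fished),
                          error = function(e) NULL)
    if (!is.null(anova_tab)) {
      write_tsv(anova_tab, file.path(out_dir, "fished_anova.tsv"))
      manifest$fished_anova <- stats::setNames(
        as.list(anova_tab$p), anova_tab$metric)
    }

    stage <- "null_alleles"
    rmat <- null_freq_matrix(x)
    flags <- flag_null_loci(rmat)
    write_tsv(data.frame(site = rownames(rmat), rmat, check.names = FALSE),
              file.path(out_dir, "null_freqs.tsv"))
    manifest$null_alleles <- list(flagged = names(flags)[flags])
    datasets <- list(raw = x)
    if (any(flags)) {
      adj <- apply_oosterhout(x, rmat, flags, seed = seed)
      write_genepop(adj, file.path(out_dir, "adjusted.genepop"))
      datasets$adjusted <- adj
    }

    manifest$differentiation <- list()
    for (variant in names(datasets)) {
      stage <- paste0("differentiation_", variant)
      xv <- datasets[[variant]]
      xc <- condense_clones(xv)
      xf <- tryCatch(filter_min_n(xc, min_n), error = function(e) NULL)
      if (is.null(xf) || nlevels(xf$site) < 2L) next
      th <- permute_significance(theta_wc, xf, n_perm = n_perm, seed = seed)
      gs <- permute_significance(gst_hedrick, xf, n_perm = n_perm,
                                 seed = seed + 1L)
      dj <- permute_significance(d_jost, xf, n_perm = n_perm,
                                 seed = seed + 2L)
      manifest$differentiation[[variant]] <- list(
        theta = th$observed, theta_p = th$p,
        gst_std = gs$observed, gst_p = gs$p,
        d_jost = dj$observed, d_p = dj$p,
        n_sites = nlevels(xf$site))
      if (variant == "raw") {
        pw_th <- pairwise_diff(xf, "theta", n_perm = n_perm, seed = seed)
        pw_dj <- pairwise_diff(xf, "djost", n_perm = n_perm, seed = seed)
        utils::write.table(dual_triangle(pw_th, pw_dj),
                           file.path(out_dir, "pairwise_matrix.tsv"),
                           sep = "\t", quote = FALSE, col.names = NA)
        pc <- pcoa(pmax(pw_th$value, 0))
        write_tsv(data.frame(site = rownames(pc$coords), pc$coords),
                  file.path(out_dir, "pcoa_coords.tsv"))
        manifest$pcoa_frac1 <- pc$frac[1]

        stage <- "amova"
        seam <- stats::setNames(md$seamount, md$site_id)
        grp <- factor(seam[as.character(xf$site)])
        am <- tryCatch(amova(xf, grp, n_perm = min(n_perm, 499L),
                             seed = seed),
                       error = function(e) NULL)
        if (!is.null(am)) manifest$amova <- list(
          phi = as.list(am$phi), p = as.list(am$p))

        stage <- "ibd"
        ibd <- tryCatch(mantel_ibd(pw_th$value, md,
                                   n_perm = min(n_perm, 999L), seed = seed),
                        error = function(e) NULL)
        if (!is.null(ibd)) manifest$ibd <- list(r2 = ibd$r2, p = ibd$p)

        stage <- "geneflow_ne"
        manifest$geneflow <- list(
          nem_wright = if (th$observed > 0) nem_wright(th$observed) else Inf,
          nem_island = if (th$observed > 0)
            nem_wright(th$observed, form = "island") else Inf,
          nem_private = suppressWarnings(nem_private(xf)$nem))
        ne <- lapply(levels(xf$site), function(s) {
          tryCatch(suppressWarnings(
            ld_ne(subset_individuals(xf, xf$site == s))),
            error = function(e) NULL)
        })
        nes <- vapply(ne, function(e) if (is.null(e)) NA_real_ else e$ne,
                      numeric(1))
        write_tsv(data.frame(site = levels(xf$site),
                             ne = ifelse(is.infinite(nes), "Inf",
                                         format(nes, digits = 6))),
                  file.path(out_dir, "ldne_by_site.tsv"))
        manifest$ldne <- list(
          finite_harmonic_mean = if (any(is.finite(nes))) {
            v <- nes[is.finite(nes) & nes > 0]
            if (length(v)) length(v) / sum(1 / v) else NA_real_
          } else NA_real_,
          n_infinite = sum(is.infinite(nes)))
      }
    }

    stage <- "clustering"
    xc <- condense_clones(datasets$raw)
    scan <- run_replicates(xc, K_range, n_reps = cluster_reps,
                           burnin = cluster_burnin,
                           iterations = cluster_iter, thin = 10L,
                           seed = seed)
    write_tsv(scan$selection, file.path(out_dir, "evanno.tsv"))
    for (K in names(scan$runs)) {
      q <- scan$runs[[K]]$Q
      write_tsv(data.frame(individual = rownames(q), q),
                file.path(out_dir, sprintf("qmatrix_K%s.tsv", K)))
    }
    manifest$clustering <- list(
      K_deltaK = attr(scan$selection, "K_deltaK"),
      K_Lmax = attr(scan$selection, "K_Lmax"))

    stage <- "manifest"
    manifest$version <- as.character(utils::packageVersion("clonepop"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }, error = on_fail)
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published per-site genotypic counts for the clonal coral survey
#'
#' The per-site sample sizes (`N`) and unique multilocus genotype counts
#' (`Ng`) printed for the 17 Solenosmilia variabilis collection sites of the
#' Southern Ocean seamount survey whose structure this package's presets
#' emulate. Used as worked-example input for [genotypic_richness()].
#'
#' @return A data.frame with columns `site`, `N`, `Ng`.
#' @export
study_genotypic_counts <- function() {
  path <- system.file("extdata", "svariabilis_genotypic_counts.tsv",
                      package = "clonepop")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write reduced-scale preset datasets for test and demonstration use
#'
#' Emits both study presets at reduced scale (at most 200 individuals
#' each) as GenePop + metadata CSV + truth JSON under `out_dir`, and
#' returns the md5 hashes of the files so callers can pin them.
#' Deterministic under `seed`.
#'
#' @param out_dir output directory (created).
#' @param seed integer seed.
#' @return Named character vector of md5 hashes, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (preset in c("solenosmilia_like", "desmophyllum_like")) {
    cfg <- preset_study(preset, scale = 0.4)
    sim <- simulate_population(cfg, seed = seed,
                               metadata_template = attr(cfg, "metadata_template"))
    stopifnot(n_ind(sim$table) <= 200L)
    gp <- file.path(out_dir, paste0(preset, ".genepop"))
    md <- file.path(out_dir, paste0(preset, "_metadata.csv"))
    tj <- file.path(out_dir, paste0(preset, "_truth.json"))
    write_genepop(sim$table, gp)
    utils::write.csv(sim$metadata, md, row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, preset = preset,
           lineage = unname(sim$truth$lineage),
           config = list(n_demes = cfg$n_demes, deme_size = cfg$deme_size,
                         clonality = cfg$clonality, n_loci = cfg$n_loci)),
      tj, auto_unbox = TRUE, digits = 10)
    paths <- c(paths, gp, md, tj)
  }
  invisible(tools::md5sum(paths))
}
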