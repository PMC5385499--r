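test_that("genotype tables store unordered allele pairs and reject bad input", {
  x <- tiny_table()
  expect_equal(n_ind(x), 4L)
  expect_equal(n_loci(x), 2L)
  # (a,b) and (b,a) are the same call: construction canonicalises order
  expect_true(all(x$a1[!is.na(x$a1)] <= x$a2[!is.na(x$a2)]))
  expect_error(genotype_table(matrix(1L), matrix(NA_integer_), "i", "L", "s"),
               "half-missing")
  expect_error(genotype_table(matrix(0L), matrix(5L), "i", "L", "s"),
               "positive")
  expect_error(
    genotype_table(matrix(1L, 2, 1), matrix(1L, 2, 1), c("i", "i"),
                   "L", c("s", "s")),
    "duplicate")
})

test_that("GenePop round trip preserves arbitrary tables exactly", {
  for (seed in 1:5) {
    x <- random_table(n_sites = 3, n_per = 6, L = 4, miss = 0.1, seed = seed)
    path <- withr::local_tempfile(fileext = ".gen")
    write_genepop(x, path)
    y <- read_genepop(path, repeat_units = 3L, site_names = levels(x$site))
    expect_identical(y$a1, x$a1)
    expect_identical(y$a2, x$a2)
    expect_identical(as.character(y$site), as.character(x$site))
    expect_identical(y$individuals, x$individuals)
  }
})

test_that("GenePop parser enforces format rules", {
  path <- withr::local_tempfile(fileext = ".gen")
  # mixed digit widths within the file
  writeLines(c("title", "locA", "locB", "Pop",
               "ind1 , 0000 120130", "ind2 , 1201 120130"), path)
  expect_error(read_genepop(path), "width")
  # empty Pop block
  writeLines(c("title", "locA", "Pop", "Pop", "ind1 , 120130"), path)
  expect_error(read_genepop(path), "empty Pop block")
  # duplicate ids
  writeLines(c("title", "locA", "Pop", "ind1 , 120130", "ind1 , 120120"),
             path)
  expect_error(read_genepop(path), "duplicate")
  # 2-digit coding parses and site id defaults to last individual per block
  writeLines(c("title", "locA", "Pop", "x1 , 1213", "x2 , 1212",
               "Pop", "y1 , 1313"), path)
  y <- read_genepop(path)
  expect_equal(unname(y$a1[1, 1]), 12L)
  expect_equal(levels(y$site), c("x2", "y1"))
  expect_error(write_genepop(y, path, digits = 3, title = "t"), NA)
})

test_that("writer refuses unrepresentable alleles and empty tables", {
  x <- tiny_table()
  x$a2[1, 1] <- 1500L
  expect_error(write_genepop(x, tempfile()), "not representable")
  expect_error(write_genepop(subset_individuals(tiny_table(), integer(0)),
                             tempfile()))
})

test_that("single-genotype file contains the expected 6-digit field", {
  x <- genotype_table(matrix(150L), matrix(150L), "ind1", "locA", "s1")
  path <- withr::local_tempfile()
  write_genepop(x, path)
  expect_true(any(grepl("150150", readLines(path))))
})

test_that("binning snaps to the modal-anchor lattice with ties toward anchor", {
  # repeat 2, anchor 150 (modal), raw 151 -> 150
  a1 <- matrix(c(150L, 150L, 151L), 3, 1)
  x <- genotype_table(a1, a1, paste0("i", 1:3), "L1", rep("s", 3),
                      repeat_unit = 2L)
  b <- bin_alleles(x)
  expect_equal(unname(b$a1[3, 1]), 150L)
  # repeat 4, anchor 100, raw 102 is equidistant from 100 and 104: tie
  # rounds toward the anchor
  a1 <- matrix(c(100L, 100L, 102L), 3, 1)
  x <- genotype_table(a1, a1, paste0("i", 1:3), "L1", rep("s", 3),
                      repeat_unit = 4L)
  expect_equal(unname(bin_alleles(x)$a1[3, 1]), 100L)
  # idempotence on arbitrary tables
  y <- random_table(seed = 7, miss = 0.05)
  expect_identical(bin_alleles(bin_alleles(y)), bin_alleles(y))
})

test_that("binning recovers the lattice from jittered fragment sizes", {
  set.seed(3)
  cfg <- sim_config(n_demes = 2, deme_size = 30, generations = 30,
                    migration = 0.05, n_loci = 4, sample_n = 15)
  sim <- simulate_population(cfg, seed = 9)
  x <- sim$table
  jit <- x
  shift <- matrix(sample(c(-1L, 0L, 1L), n_ind(x) * n_loci(x), TRUE,
                         prob = c(0.2, 0.6, 0.2)), n_ind(x))
  jit$a1 <- x$a1 + ifelse(is.na(x$a1), 0L, shift)
  jit$a2 <- x$a2 + ifelse(is.na(x$a2), 0L, shift)
  jit <- genotype_table(jit$a1, jit$a2, x$individuals, x$loci, x$site,
                        x$repeat_unit)
  binned <- bin_alleles(jit)
  agree <- mean(binned$a1 == x$a1, na.rm = TRUE)
  expect_gt(agree, 0.99)
})

test_that("the site-size filter is strict and leaves survivors untouched", {
  x <- random_table(n_sites = 2, n_per = 13, seed = 1)
  # shrink one site to exactly 12: with min_n = 12 only the 13-site remains
  x <- subset_individuals(x, -1L)
  expect_equal(unname(sort(as.vector(site_sizes(x)))), c(12L, 13L))
  f <- filter_min_n(x, 12L)
  expect_equal(nlevels(f$site), 1L)
  expect_equal(n_ind(f), 13L)
  expect_identical(f$a1, x$a1[x$site == levels(f$site), ])
  # min_n = 0 is the identity
  expect_equal(n_ind(filter_min_n(x, 0L)), n_ind(x))
  # removing everything is an explicit error
  expect_error(filter_min_n(x, 100L), "empty result")
  # property: no surviving site at or below the threshold
  for (seed in 1:5) {
    y <- random_table(n_sites = 4, n_per = sample(5:15, 1), seed = seed)
    thr <- sample(4:14, 1)
    ff <- tryCatch(filter_min_n(y, thr), error = function(e) NULL)
    if (!is.null(ff)) expect_true(all(site_sizes(ff) > thr))
  }
})

test_that("metadata validation catches out-of-range values", {
  md <- data.frame(site_id = c("a", "b"), seamount = "x", region = "r",
                   lat = c(-44, -45), lon = c(147, 148),
                   depth_m = c(1000, 1200), stratum = "mid",
                   fished = c(TRUE, FALSE))
  expect_s3_class(site_metadata(md), "site_metadata")
  bad <- md; bad$lat[1] <- 95
  expect_error(site_metadata(bad), "latitude")
  bad <- md; bad$depth_m[2] <- -5
  expect_error(site_metadata(bad), "depth")
  bad <- md; bad$site_id[2] <- "a"
  expect_error(site_metadata(bad), "duplicate")
})
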