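#' Read a GenePop genotype file
#'
#' Parses the classic GenePop text format: a title line, locus names (one per
#' line or comma-separated on one line), then population blocks introduced by
#' a line whose first word is "Pop" (case-insensitive), with individual lines
#' of the form `name , g1 g2 ...`. Alleles may be coded with 2 or 3 digits
#' per allele; the digit width is auto-detected from the file and applied
#' uniformly. The all-zero code marks a missing genotype.
#'
#' Pop blocks are anonymous in the format; site ids are taken from
#' `site_names` in block order when supplied, otherwise from the name of the
#' last individual in each block (the convention most GenePop writers follow).
#'
#' @param path path to a GenePop file.
#' @param repeat_units named integer vector (locus -> repeat unit in bp) or a
#'   single value recycled over loci.
#' @param site_names optional character vector naming the Pop blocks in order.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, repeat_units = 3L, site_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) < 3L) stop("not a GenePop file: too few lines")
  lines <- lines[nonblank]
  is_pop <- grepl("^\\s*pop\\b", lines, ignore.case = TRUE) &
    !grepl(",", lines)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("not a GenePop file: no Pop delimiter after locus names")
  # locus names: lines 2 .. first_pop-1, each possibly comma-separated
  loci <- unlist(strsplit(lines[2:(first_pop - 1L)], ","))
  loci <- trimws(loci)
  loci <- loci[loci != ""]
  if (!length(loci)) stop("no locus names found")

  pop_of_line <- cumsum(is_pop)
  if (any(diff(which(is_pop)) == 1L) || is_pop[length(is_pop)])
    stop("empty Pop block")

  names <- character(0); gstr <- list(); popid <- integer(0)
  for (i in seq_along(lines)) {
    if (i < first_pop || is_pop[i]) next
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2L)
      stop("line ", nonblank[i], ": expected 'name , genotypes'")
    nm <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(geno) != length(loci))
      stop("line ", nonblank[i], ": ", length(geno), " genotype fields for ",
           length(loci), " loci")
    names <- c(names, nm); gstr[[length(gstr) + 1L]] <- geno
    popid <- c(popid, pop_of_line[i])
  }
  if (anyDuplicated(names))
    stop("duplicate individual ids: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))

  widths <- unique(nchar(unlist(gstr)))
  if (length(widths) != 1L || !(widths %in% c(4L, 6L))) {
    bad <- which(vapply(gstr, function(g)
      length(unique(nchar(g))) > 1L || !all(nchar(g) %in% c(4L, 6L)),
      logical(1)))[1]
    stop("mixed or invalid allele digit widths (genotype field widths ",
         paste(widths, collapse = "/"), "), first bad individual line: ",
         names[bad])
  }
  w <- widths / 2L
  n <- length(names); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- gstr[[i]]
    x1 <- as.integer(substr(g, 1L, w))
    x2 <- as.integer(substr(g, w + 1L, 2L * w))
    if (anyNA(x1) || anyNA(x2))
      stop("non-numeric genotype field for individual ", names[i])
    half <- xor(x1 == 0L, x2 == 0L)
    if (any(half))
      stop("half-missing genotype (one allele zero) for individual ",
           names[i], " at locus ", loci[which(half)[1]])
    miss <- x1 == 0L & x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }

  npop <- max(popid)
  if (is.null(site_names)) {
    site_names <- vapply(seq_len(npop),
                         function(p) names[max(which(popid == p))],
                         character(1))
  }
  if (length(site_names) != npop)
    stop("site_names has length ", length(site_names), " but file has ",
         npop, " Pop blocks")
  ru <- if (!is.null(names(repeat_units)))
    repeat_units[loci] else rep_len(repeat_units, L)
  if (anyNA(ru)) stop("repeat_units missing for some loci")
  genotype_table(a1, a2, names, loci, site_names[popid], ru)
}

#' Write a genotype table as a GenePop file
#'
#' Alleles are written in 3-digit coding by default (microsatellite fragment
#' sizes run to several hundred bp); 2-digit coding is available for small
#' allele labels. `read_genepop(write_genepop(x))` reproduces `x` exactly:
#' allele pairs, missingness and the site partition.
#'
#' @param x a [genotype_table()].
#' @param path output file path.
#' @param digits allele digit width, 2 or 3.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, digits = 3L, title = "clonepop export") {
  if (n_loci(x) == 0L) stop("cannot write a table with no loci")
  if (n_ind(x) == 0L) stop("cannot write a table with no individuals")
  digits <- as.integer(digits)
  stopifnot(digits %in% c(2L, 3L))
  amax <- suppressWarnings(max(c(x$a1, x$a2), na.rm = TRUE))
  if (is.finite(amax) && amax > 10^digits - 1)
    stop("allele ", amax, " not representable in ", digits, "-digit coding")
  fmt <- function(a) ifelse(is.na(a), strrep("0", digits),
                            formatC(a, width = digits, flag = "0"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci, con)
  for (s in levels(x$site)) {
    writeLines("Pop", con)
    for (i in which(x$site == s)) {
      g <- paste0(fmt(x$a1[i, ]), fmt(x$a2[i, ]))
      writeLines(paste(x$individuals[i], ",", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read per-site metadata
#'
#' Sidecar CSV with header
#' `site_id,seamount,region,lat,lon,depth_m,stratum,fished` supplying, in Pop
#' block order, the named sites of a survey: seamount and region membership,
#' coordinates (decimal degrees), depth (m), depth stratum (shallow/mid/deep;
#' a category rather than a function of depth, because survey strata can have
#' gaps) and whether the seamount was fished.
#'
#' @param path CSV path.
#' @return A validated data.frame of class `site_metadata`.
#' @export
read_site_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  site_metadata(md)
}

#' Validate a site metadata table
#'
#' @param md data.frame with columns `site_id`, `seamount`, `region`, `lat`,
#'   `lon`, `depth_m`, `stratum`, `fished`.
#' @return `md` with class `site_metadata`.
#' @export
site_metadata <- function(md) {
  need <- c("site_id", "seamount", "region", "lat", "lon", "depth_m",
            "stratum", "fished")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$site_id)) stop("duplicate site_id in metadata")
  if (any(md$lat < -90 | md$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(md$lon < -180 | md$lon > 180)) stop("longitude outside [-180, 180]")
  if (any(md$depth_m <= 0)) stop("depth_m must be positive")
  md$fished <- as.logical(md$fished)
  if (anyNA(md$fished)) stop("fished flag must be logical")
  class(md) <- c("site_metadata", "data.frame")
  md
}
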