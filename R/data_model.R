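#' @useDynLib haplopaint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile cor prcomp rbeta runif rbinom rpois rnorm
#'   setNames var median
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Core containers
# ---------------------------------------------------------------------------

#' Construct a genotype matrix for inbred lines
#'
#' Genotypes of biallelic SNPs in effectively homozygous lines are stored as a
#' single haploid allele copy per sample: an integer matrix with samples in
#' rows and SNPs in columns, entries 0, 1 or `NA` (missing).
#'
#' @param calls matrix coercible to integer with entries in `{0, 1, NA}`;
#'   rownames are sample ids, colnames are SNP ids (both mandatory, unique).
#' @return an object of class `genotype_matrix` (an integer matrix).
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, NA, 1L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("m1", "m2"))))
#' n_samples(g); n_snps(g)
#' @export
genotype_matrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("genotype_matrix requires sample ids (rownames) and SNP ids (colnames)")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample id: ", rownames(calls)[duplicated(rownames(calls))][1L])
  if (anyDuplicated(colnames(calls)))
    stop("duplicate SNP id: ", colnames(calls)[duplicated(colnames(calls))][1L])
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad))
    stop("genotype calls must be 0, 1 or NA; found ", calls[which(bad)[1L]])
  structure(calls, class = c("genotype_matrix", "matrix", "array"))
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
n_samples <- function(g) nrow(g)

#' @rdname genotype_matrix
#' @export
n_snps <- function(g) ncol(g)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(g) rownames(g)

#' @rdname genotype_matrix
#' @export
snp_ids <- function(g) colnames(g)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

# subsetting keeps the class and drops nothing
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  class(out) <- c("genotype_matrix", "matrix", "array")
  out
}

#' Construct a genetic map
#'
#' @param map data.frame with columns `snp_id`, `chrom`, `cM` (non-negative
#'   positions on a consensus map).  SNPs within a chromosome need not be
#'   pre-sorted; map-aware operations sort by cM.
#' @return a `genetic_map` data.frame.
#' @export
genetic_map <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "cM")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("genetic map is missing column(s): ",
                         paste(miss, collapse = ", "))
  map <- map[need]
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$cM <- as.numeric(map$cM)
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP id in map: ", map$snp_id[duplicated(map$snp_id)][1L])
  if (anyNA(map$cM) || any(map$cM < 0))
    stop("map positions must be non-negative cM values")
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Construct sample metadata
#'
#' Donors carry a geographic subpopulation id; recipients carry a year (and
#' optionally State) of release from which a breeding period is derived.
#'
#' @param meta data.frame with columns `sample_id`, `role` (`"donor"` or
#'   `"recipient"`) and optionally `subpop_id`, `country`, `year`, `state`.
#' @param bounds a [period_bounds()] used to derive `period` for recipients
#'   with a known year.
#' @return a `sample_metadata` data.frame with a derived `period` column.
#' @export
sample_metadata <- function(meta, bounds = period_bounds()) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (opt in c("subpop_id", "country", "year", "state"))
    if (is.null(meta[[opt]])) meta[[opt]] <- NA
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  if (!all(meta$role %in% c("donor", "recipient")))
    stop("role must be 'donor' or 'recipient'")
  meta$subpop_id <- suppressWarnings(as.integer(meta$subpop_id))
  meta$year <- suppressWarnings(as.integer(meta$year))
  bad_donor <- meta$role == "donor" & is.na(meta$subpop_id)
  if (any(bad_donor))
    stop("donor(s) lacking subpop_id: ",
         paste(head(meta$sample_id[bad_donor], 3L), collapse = ", "))
  no_year <- meta$role == "recipient" & is.na(meta$year)
  if (any(no_year))
    warning(sum(no_year), " recipient(s) lack year of release; ",
            "excluded from period analyses")
  meta$period <- ifelse(is.na(meta$year), NA_integer_,
                        assign_period(meta$year, bounds))
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Period boundaries for recipient release years
#'
#' Breeding periods are delimited by two cut years; the defaults split a
#' release-year range into pre-1920, 1921-1970 and post-1970 periods.  The
#' boundary year itself falls in the earlier period (1920 is period 1, 1970 is
#' period 2).
#'
#' @param cut1,cut2 boundary years, `cut1 < cut2`.
#' @export
period_bounds <- function(cut1 = 1920L, cut2 = 1970L) {
  cut1 <- as.integer(cut1); cut2 <- as.integer(cut2)
  if (!is.finite(cut1) || !is.finite(cut2) || cut1 >= cut2)
    stop("period bounds must satisfy cut1 < cut2")
  structure(list(cut1 = cut1, cut2 = cut2), class = "period_bounds")
}

#' Assign a breeding period from a year of release
#'
#' @param year integer vector of release years.
#' @param bounds a [period_bounds()].
#' @return integer vector in `{1, 2, 3}` (`NA` years give `NA`).
#' @examples
#' assign_period(c(1840, 1920, 1921, 1970, 1971))
#' @export
assign_period <- function(year, bounds = period_bounds()) {
  stopifnot(inherits(bounds, "period_bounds"))
  year <- as.integer(year)
  out <- ifelse(year <= bounds$cut1, 1L, ifelse(year <= bounds$cut2, 2L, 3L))
  out[is.na(year)] <- NA_integer_
  out
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read genotypes from CSV or VCF
#'
#' The CSV dialect is: first column sample id, remaining columns one SNP each,
#' cells in `{0, 1, NA}`.  For VCF, the GT field is read; haploid calls and
#' homozygous diploid calls map to 0/1, heterozygous calls in these inbred
#' lines are set missing (with a warning), and non-biallelic sites are skipped
#' with a warning.
#'
#' @param path file path.
#' @param format `"csv"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         csv = read_genotypes_csv(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_csv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("genotype CSV needs a sample id column plus >=1 SNP")
  ids <- dt[[1L]]
  m <- as.matrix(dt[-1L])
  rownames(m) <- ids
  genotype_matrix(m)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  if (any(multi)) {
    warning(sum(multi), " non-biallelic site(s) skipped")
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  # rows = variants, cols = samples; recode to haploid 0/1/NA
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0", "0/0")] <- 0L
    out[x %in% c("1", "1/1")] <- 1L
    het <- x %in% c("0/1", "1/0")
    if (any(het)) attr(out, "n_het") <- sum(het)
    out
  }
  coded <- apply(gt, 2L, code)
  n_het <- sum(gt %in% c("0/1", "1/0", "0|1", "1|0"))
  if (n_het > 0L)
    warning(n_het, " heterozygous call(s) set to missing (inbred lines)")
  m <- t(matrix(as.integer(coded), nrow = nrow(gt),
                dimnames = list(rownames(gt), colnames(gt))))
  genotype_matrix(m)
}

#' Write genotypes to the package CSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(sample_id = rownames(g), unclass(g)[, , drop = FALSE],
                   check.names = FALSE)
  data.table::fwrite(df, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a genetic map (TSV/CSV with columns snp_id, chrom, cM)
#' @param path file path.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  genetic_map(data.table::fread(path, data.table = FALSE))
}

#' @rdname read_map
#' @param map a `genetic_map`.
#' @export
write_map <- function(map, path) {
  data.table::fwrite(as.data.frame(map), path, sep = "\t")
  invisible(path)
}

#' Read sample metadata (CSV with header sample_id, role, subpop_id, country,
#' year, state)
#' @param path file path.
#' @param bounds a [period_bounds()].
#' @export
read_metadata <- function(path, bounds = period_bounds()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_metadata(data.table::fread(path, data.table = FALSE), bounds)
}

#' @rdname read_metadata
#' @param meta a `sample_metadata`.
#' @export
write_metadata <- function(meta, path) {
  data.table::fwrite(as.data.frame(meta), path)
  invisible(path)
}

# internal: map subset aligned to a genotype matrix, sorted chrom/cM
map_for <- function(g, map) {
  stopifnot(inherits(map, "genetic_map"))
  missing_map <- setdiff(colnames(g), map$snp_id)
  if (length(missing_map))
    stop("SNP(s) absent from map: ", paste(head(missing_map, 3L), collapse = ", "))
  m <- map[match(colnames(g), map$snp_id), , drop = FALSE]
  m$col <- seq_len(ncol(g))
  m[order(m$chrom, m$cM, m$col), , drop = FALSE]
}
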