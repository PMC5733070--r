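# Sliding-window haplotype diversity, pairwise r^2, background-LD threshold,
# LD-decay block size, and the LD-based effective population size.

#' Sliding-window haplotype spectra
#'
#' Windows of `w` consecutive SNPs (map order, never spanning chromosomes)
#' advance by `step` SNPs.  Within a window, samples with any missing call
#' are excluded from that window's spectrum; the spectrum is the frequency
#' table of the observed haplotype strings.
#'
#' @param g a [genotype_matrix()].
#' @param map a [genetic_map()] covering the SNPs of `g`.
#' @param w window size in SNPs (default 15).
#' @param step slide in SNPs (default 1).
#' @return list of spectra: each has `chrom`, `start` (SNP index on the
#'   chromosome), `start_cM`, `end_cM`, `n` (samples used) and `p`
#'   (haplotype frequencies, summing to 1).
#' @export
window_spectra <- function(g, map, w = 15L, step = 1L) {
  m <- unclass(g)
  mm <- map_for(g, map)
  out <- list()
  for (cc in split(mm, mm$chrom)) {
    S <- nrow(cc)
    if (S < w) {
      warning("chromosome ", cc$chrom[1L], " has fewer than ", w,
              " SNPs; skipped")
      next
    }
    starts <- seq(1L, S - w + 1L, by = step)
    for (st in starts) {
      cols <- cc$col[st:(st + w - 1L)]
      sub <- m[, cols, drop = FALSE]
      complete <- rowSums(is.na(sub)) == 0L
      if (!any(complete)) next  # all samples missing: window skipped
      strs <- apply(sub[complete, , drop = FALSE], 1L, paste0, collapse = "")
      tab <- table(strs)
      out[[length(out) + 1L]] <- list(
        chrom = cc$chrom[1L], start = st,
        start_cM = cc$cM[st], end_cM = cc$cM[st + w - 1L],
        n = sum(complete), p = as.numeric(tab) / sum(tab))
    }
  }
  out
}

#' Haplotype heterozygosity of a window spectrum
#'
#' `HHe = 1 - sum(p_i^2)` over the haplotype frequencies `p_i`.
#'
#' @param spectrum a spectrum from [window_spectra()] or a numeric frequency
#'   vector summing to 1.
#' @export
hhe <- function(spectrum) {
  p <- spectrum_freqs(spectrum)
  1 - sum(p^2)
}

#' Effective number of haplotypes of a window spectrum
#'
#' `HAe = 1 / sum(p_i^2)`, the reciprocal of haplotype homozygosity, so that
#' `HAe = 1 / (1 - HHe)` exactly.
#'
#' @inheritParams hhe
#' @export
hae <- function(spectrum) {
  p <- spectrum_freqs(spectrum)
  1 / sum(p^2)
}

spectrum_freqs <- function(spectrum) {
  p <- if (is.list(spectrum)) spectrum$p else spectrum
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    stop("haplotype frequencies must be positive and sum to 1")
  p
}

#' Mean haplotype diversity over all windows
#'
#' @inheritParams window_spectra
#' @return list(mean_hhe, mean_hae, n_windows).
#' @export
haplotype_diversity <- function(g, map, w = 15L, step = 1L) {
  sp <- window_spectra(g, map, w, step)
  if (!length(sp)) stop("no usable windows")
  h <- vapply(sp, hhe, 0)
  a <- vapply(sp, hae, 0)
  list(mean_hhe = mean(h), mean_hae = mean(a), n_windows = length(sp))
}

#' Pairwise r-squared between SNPs
#'
#' `r^2 = D^2 / (p_A p_a p_B p_b)` with `D = p_AB - p_A p_B` over
#' pairwise-complete haploid samples (equivalently the squared Pearson
#' correlation of the allele indicators).  Monomorphic pairs and pairs with
#' fewer than `min_complete` shared samples are skipped.
#'
#' @param g a [genotype_matrix()].
#' @param map a [genetic_map()]; required to define scope and distances.
#' @param scope `"intra_chrom"` (same-chromosome pairs, with cM distance) or
#'   `"inter_chrom"` (unlinked pairs, distance `NA`).
#' @param max_pairs optional cap: pairs are subsampled with `seed`.
#' @param min_complete minimum pairwise-complete samples (default 10).
#' @param seed seed used when subsampling pairs.
#' @return data.frame (snp1, snp2, chrom1, chrom2, dist_cM, r2).
#' @export
pairwise_r2 <- function(g, map, scope = c("intra_chrom", "inter_chrom"),
                        max_pairs = 1e6, min_complete = 10L, seed = 1L) {
  scope <- match.arg(scope)
  m <- unclass(g)
  mm <- map_for(g, map)
  chrom_of <- mm$chrom[match(seq_len(ncol(m)), mm$col)]
  pos_of <- mm$cM[match(seq_len(ncol(m)), mm$col)]
  idx <- pair_index(chrom_of, scope, max_pairs, seed)
  if (nrow(idx) == 0L) return(data.frame())
  r2 <- r2_pairs(m, idx, min_complete)
  out <- data.frame(snp1 = colnames(m)[idx[, 1L]],
                    snp2 = colnames(m)[idx[, 2L]],
                    chrom1 = chrom_of[idx[, 1L]], chrom2 = chrom_of[idx[, 2L]],
                    dist_cM = ifelse(chrom_of[idx[, 1L]] == chrom_of[idx[, 2L]],
                                     abs(pos_of[idx[, 1L]] - pos_of[idx[, 2L]]),
                                     NA_real_),
                    r2 = r2, stringsAsFactors = FALSE)
  out[!is.na(out$r2), , drop = FALSE]
}

# enumerate (or subsample) pair indices for a scope
pair_index <- function(chrom_of, scope, max_pairs, seed) {
  S <- length(chrom_of)
  same <- scope == "intra_chrom"
  if (same) {
    by_chr <- split(seq_len(S), chrom_of)
    idx <- do.call(rbind, lapply(by_chr, function(ix) {
      if (length(ix) < 2L) return(NULL)
      t(utils::combn(ix, 2L))
    }))
  } else {
    # count cross-chromosome pairs; sample lazily if the product is large
    n_total <- choose(S, 2)
    if (is.finite(max_pairs) && n_total > 4 * max_pairs) {
      set.seed(as.integer(seed))
      i <- sample.int(S, 4 * max_pairs, replace = TRUE)
      j <- sample.int(S, 4 * max_pairs, replace = TRUE)
      keep <- i < j & chrom_of[i] != chrom_of[j]
      idx <- unique(cbind(i[keep], j[keep]))
    } else {
      idx <- t(utils::combn(seq_len(S), 2L))
      idx <- idx[chrom_of[idx[, 1L]] != chrom_of[idx[, 2L]], , drop = FALSE]
    }
  }
  if (is.null(idx)) return(matrix(integer(0), 0, 2))
  if (is.finite(max_pairs) && nrow(idx) > max_pairs) {
    set.seed(as.integer(seed))
    idx <- idx[sample.int(nrow(idx), max_pairs), , drop = FALSE]
  }
  idx
}

# r^2 for an index matrix of column pairs; complete-data fast path via
# correlation, pairwise-complete loop otherwise
r2_pairs <- function(m, idx, min_complete) {
  if (!anyNA(m)) {
    sds <- apply(m, 2L, stats::sd)
    r2 <- rep(NA_real_, nrow(idx))
    poly <- sds[idx[, 1L]] > 0 & sds[idx[, 2L]] > 0
    if (any(poly)) {
      ms <- scale(m)
      n <- nrow(m)
      r <- colSums(ms[, idx[poly, 1L], drop = FALSE] *
                     ms[, idx[poly, 2L], drop = FALSE]) / (n - 1)
      r2[poly] <- pmin(r^2, 1)
    }
    if (nrow(m) < min_complete) r2[] <- NA_real_
    return(r2)
  }
  vapply(seq_len(nrow(idx)), function(k) {
    x <- m[, idx[k, 1L]]; y <- m[, idx[k, 2L]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_complete) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    min(cor(x, y)^2, 1)
  }, 0)
}

#' Background (unlinked) LD threshold
#'
#' The empirical 99th percentile of inter-chromosomal r-squared values, using
#' the linear-interpolation quantile definition (R type 7).
#'
#' @param r2_values numeric vector of unlinked r-squared values (>= 100).
#' @param prob quantile level (default 0.99).
#' @export
background_threshold <- function(r2_values, prob = 0.99) {
  r2_values <- r2_values[!is.na(r2_values)]
  if (length(r2_values) < 100L) stop("need >= 100 unlinked r2 values")
  unname(quantile(r2_values, prob, type = 7))
}

#' LD-decay block size from binned intra-chromosomal r-squared
#'
#' Mean r-squared in `bin_width`-cM distance bins is smoothed by a centred
#' moving average over `smooth_bins` bins; the block size is the first point
#' at which the smoothed curve drops below the background threshold,
#' linearly interpolated between adjacent bin midpoints.
#'
#' @param ld data.frame from [pairwise_r2()] (intra-chromosomal scope).
#' @param r2_star background threshold from [background_threshold()].
#' @param bin_width bin width in cM (default 1).
#' @param smooth_bins moving-average window in bins (odd, default 3).
#' @return list(block_cM, flag, curve); `flag` is `"ok"`,
#'   `"below_threshold_everywhere"` (block 0) or `"never_crosses"`
#'   (block reported as max distance).
#' @export
ld_block_size <- function(ld, r2_star, bin_width = 1, smooth_bins = 3L) {
  stopifnot(!is.null(ld$dist_cM), !is.null(ld$r2))
  ld <- ld[!is.na(ld$dist_cM), , drop = FALSE]
  bin <- floor(ld$dist_cM / bin_width)
  mids <- (sort(unique(bin)) + 0.5) * bin_width
  mean_r2 <- tapply(ld$r2, bin, mean)[as.character(sort(unique(bin)))]
  n_pairs <- tapply(ld$r2, bin, length)[as.character(sort(unique(bin)))]
  sm <- moving_average(as.numeric(mean_r2), smooth_bins)
  curve <- data.frame(mid_cM = mids, mean_r2 = as.numeric(mean_r2),
                      smoothed = sm, n_pairs = as.integer(n_pairs))
  if (sm[1L] < r2_star)
    return(list(block_cM = 0, flag = "below_threshold_everywhere",
                curve = curve))
  below <- which(sm < r2_star)
  if (!length(below))
    return(list(block_cM = max(mids), flag = "never_crosses", curve = curve))
  k <- below[1L]
  x0 <- mids[k - 1L]; x1 <- mids[k]
  y0 <- sm[k - 1L]; y1 <- sm[k]
  block <- x0 + (y0 - r2_star) / (y0 - y1) * (x1 - x0)
  list(block_cM = block, flag = "ok", curve = curve)
}

moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  half <- (k - 1L) %/% 2L
  vapply(seq_along(x), function(i) {
    ix <- max(1L, i - half):min(length(x), i + half)
    mean(x[ix], na.rm = TRUE)
  }, 0)
}

#' LD-based effective population size
#'
#' Mean r-squared over qualifying locus pairs is inverted through the drift
#' expectation `E[r^2] ~ 1/(3 Ne) + 1/S` (random mating, S haploid copies):
#' `Ne = 1 / (3 (rbar2 - 1/S))`.  The `"waples"` variant applies the Waples
#' (2006) second-order sampling correction `E[r^2_sample] = 1/S + 3.19/S^2`
#' and quadratic inversion `Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`.
#' When a map is supplied, intra-chromosomal pairs closer than `min_dist_cM`
#' are excluded (the method assumes unlinked loci).
#'
#' @param g a [genotype_matrix()] with no missing calls (impute first).
#' @param maf_cutoff loci with MAF below this are excluded (default 0.05).
#' @param map optional [genetic_map()] used to exclude tightly linked pairs.
#' @param min_dist_cM linkage exclusion distance (default 50).
#' @param method `"first_order"` (default) or `"waples"`.
#' @param max_pairs cap on locus pairs (subsampled with `seed`).
#' @param seed seed for pair subsampling.
#' @return an `ne_estimate`: list(ne, rbar2, S, n_pairs, method, flag);
#'   `ne` is `Inf` (flagged) when `rbar2` does not exceed the sampling term.
#' @export
ne_ld <- function(g, maf_cutoff = 0.05, map = NULL, min_dist_cM = 50,
                  method = c("first_order", "waples"),
                  max_pairs = 2e5, seed = 1L) {
  method <- match.arg(method)
  g <- filter_maf(g, min_maf = maf_cutoff)
  m <- unclass(g)
  S <- nrow(m)
  if (S < 10L) stop("need >= 10 samples")
  if (ncol(m) < 2L) stop("need >= 2 loci after MAF filtering")
  if (is.null(map)) {
    chrom_of <- rep("un", ncol(m))
    idx <- pair_index(chrom_of, "intra_chrom", max_pairs, seed)
  } else {
    mm <- map_for(g, map)
    chrom_of <- mm$chrom[match(seq_len(ncol(m)), mm$col)]
    pos_of <- mm$cM[match(seq_len(ncol(m)), mm$col)]
    idx <- pair_index(chrom_of, "inter_chrom", max_pairs, seed)
    # also admit widely separated same-chromosome pairs
    idx2 <- pair_index(chrom_of, "intra_chrom", max_pairs, seed)
    if (nrow(idx2)) {
      far <- abs(pos_of[idx2[, 1L]] - pos_of[idx2[, 2L]]) >= min_dist_cM
      idx <- rbind(idx, idx2[far, , drop = FALSE])
    }
  }
  r2 <- r2_pairs(m, idx, min_complete = 10L)
  r2 <- r2[!is.na(r2)]
  if (!length(r2)) stop("no usable locus pairs")
  rbar2 <- mean(r2)
  if (method == "first_order") {
    drift <- rbar2 - 1 / S
    if (drift <= 0)
      return(ne_result(Inf, rbar2, S, length(r2), method, "infinite"))
    ne <- 1 / (3 * drift)
  } else {
    r2p <- rbar2 - 1 / S - 3.19 / S^2
    if (r2p <= 0 || 1 / 9 - 2.76 * r2p < 0)
      return(ne_result(Inf, rbar2, S, length(r2), method, "infinite"))
    ne <- (1 / 3 + sqrt(1 / 9 - 2.76 * r2p)) / (2 * r2p)
  }
  ne_result(ne, rbar2, S, length(r2), method, "ok")
}

ne_result <- function(ne, rbar2, S, n_pairs, method, flag) {
  structure(list(ne = ne, rbar2 = rbar2, S = S, n_pairs = n_pairs,
                 method = method, flag = flag), class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD-based Ne = %.2f (rbar2 = %.5f, S = %d, %d pairs, %s)\n",
              x$ne, x$rbar2, x$S, x$n_pairs, x$method))
  invisible(x)
}
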