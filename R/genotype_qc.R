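# Genotype QC: intensity-based calling, missingness and MAF filters,
# LD-kNN imputation, and donor/recipient SNP intersection.

#' Call genotypes from two-channel intensities
#'
#' Each (Theta, NormR) point is assigned the label of the nearest cluster
#' under SD-scaled Euclidean distance (each axis standardised by the cluster's
#' own SD).  Points whose nearest cluster lies farther than `max_z` SD units,
#' or that are equidistant (within `tie_tol`) from two clusters, are set
#' missing.
#'
#' @param intensities data.frame (sample_id, snp_id, theta, norm_r).
#' @param model a `cluster_model` (see [cluster_model_default()]).
#' @param max_z outlier cutoff in SD units (default 4).
#' @param tie_tol distances closer than this are ties (default 1e-9).
#' @return a [genotype_matrix()]; samples x SNPs present in the intensities.
#' @export
call_genotypes <- function(intensities, model, max_z = 4, tie_tol = 1e-9) {
  stopifnot(inherits(model, "cluster_model"))
  snps <- unique(intensities$snp_id)
  known <- snps %in% names(model)
  if (!all(known)) {
    warning(sum(!known), " SNP(s) absent from cluster model dropped")
    snps <- snps[known]
    intensities <- intensities[intensities$snp_id %in% snps, , drop = FALSE]
  }
  samples <- unique(intensities$sample_id)
  calls <- matrix(NA_integer_, length(samples), length(snps),
                  dimnames = list(samples, snps))
  by_snp <- split(intensities, intensities$snp_id)
  for (s in names(by_snp)) {
    d <- by_snp[[s]]
    cl <- model[[s]]
    z <- sapply(seq_len(nrow(cl)), function(j)
      sqrt(((d$theta - cl$theta[j]) / cl$sd_theta[j])^2 +
             ((d$norm_r - cl$norm_r[j]) / cl$sd_norm_r[j])^2))
    z <- matrix(z, nrow = nrow(d))
    best <- max.col(-z, ties.method = "first")
    zmin <- z[cbind(seq_len(nrow(z)), best)]
    # second-smallest distance for the tie rule
    z2 <- apply(z, 1L, function(v) sort(v)[2L])
    lab <- cl$label[best]
    lab[zmin > max_z] <- NA_integer_
    lab[abs(z2 - zmin) <= tie_tol] <- NA_integer_
    calls[cbind(match(d$sample_id, samples), match(s, snps))] <- lab
  }
  genotype_matrix(calls)
}

#' Remove SNPs with too much missing data
#'
#' SNPs whose missing fraction is strictly greater than `max_missing_frac`
#' are removed (a SNP at exactly the threshold is kept); column order is
#' preserved.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing_frac threshold (default 0.5).
#' @export
filter_missing <- function(g, max_missing_frac = 0.5) {
  frac <- colMeans(is.na(unclass(g)))
  g[, frac <= max_missing_frac, drop = FALSE]
}

#' Remove SNPs with low minor allele frequency in a reference subset
#'
#' MAF is computed over `reference_samples` only (by default all samples);
#' SNPs with MAF strictly below `min_maf` are removed, so a SNP at exactly
#' the threshold is kept.
#'
#' @param g a [genotype_matrix()].
#' @param min_maf threshold (default 0.05).
#' @param reference_samples character vector of sample ids (default all).
#' @export
filter_maf <- function(g, min_maf = 0.05, reference_samples = NULL) {
  if (is.null(reference_samples)) reference_samples <- rownames(g)
  ref <- unclass(g)[rownames(g) %in% reference_samples, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference sample subset is empty")
  p <- colMeans(ref, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing in reference: treated as monomorphic
  g[, maf >= min_maf, drop = FALSE]
}

#' LD-kNN imputation of missing genotype calls
#'
#' Each missing call at SNP `t` in sample `i` is replaced by the winning
#' allele in an inverse-squared-distance weighted vote among the `l_samples`
#' samples most concordant with `i`, concordance being the mismatch fraction
#' at the `k_snps` SNPs most correlated (r^2) with `t`.
#' Observed calls are never altered.  A SNP with no usable neighbours falls
#' back to its overall major allele (flagged in attribute `fallback`).
#'
#' @param g a [genotype_matrix()] with at least `k_snps + 1` SNPs.
#' @param k_snps LD neighbourhood size (default 30).
#' @param l_samples nearest samples used for the vote (default 10).
#' @return a [genotype_matrix()] with no missing entries.
#' @export
impute_ldknni <- function(g, k_snps = 30L, l_samples = 10L) {
  m <- unclass(g)
  if (ncol(m) <= k_snps) stop("need more than k_snps SNPs to impute")
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(g)
  r2 <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
  diag(r2) <- -Inf
  r2[is.na(r2)] <- -Inf
  major <- as.integer(round(colMeans(m, na.rm = TRUE)))
  major[is.na(major)] <- 0L
  out <- m
  fallback <- character(0)
  for (t in unique(miss[, 2L])) {
    nb <- order(r2[, t], decreasing = TRUE)[seq_len(k_snps)]
    nb <- nb[is.finite(r2[nb, t])]
    rows <- miss[miss[, 2L] == t, 1L]
    for (i in rows) {
      if (length(nb) == 0L) {
        out[i, t] <- major[t]
        fallback <- c(fallback, paste0(rownames(m)[i], ":", colnames(m)[t]))
        next
      }
      cand <- which(!is.na(m[, t]))
      cand <- cand[cand != i]
      if (length(cand) == 0L) {
        out[i, t] <- major[t]
        fallback <- c(fallback, paste0(rownames(m)[i], ":", colnames(m)[t]))
        next
      }
      xi <- m[i, nb]
      dd <- vapply(cand, function(j) {
        ok <- !is.na(xi) & !is.na(m[j, nb])
        if (!any(ok)) return(1)
        mean(xi[ok] != m[j, nb][ok])
      }, 0)
      ord <- order(dd)[seq_len(min(l_samples, length(cand)))]
      near <- cand[ord]
      votes <- m[near, t]
      # inverse-squared-distance weights: an exact duplicate dominates the vote
      w <- 1 / (dd[ord]^2 + 1e-10)
      s1 <- sum(w[votes == 1L]); s0 <- sum(w[votes == 0L])
      out[i, t] <- if (s1 > s0) 1L else if (s0 > s1) 0L else major[t]
    }
  }
  res <- genotype_matrix(out)
  if (length(fallback)) attr(res, "fallback") <- fallback
  res
}

#' Restrict donor and recipient panels to their shared SNP set
#'
#' @param donor,recipient [genotype_matrix()] objects.
#' @return list of the two matrices restricted to the shared SNPs in the
#'   donor panel's order.
#' @export
intersect_snps <- function(donor, recipient) {
  shared <- intersect(colnames(donor), colnames(recipient))
  if (length(shared) == 0L) stop("donor and recipient panels share no SNPs")
  shared <- colnames(donor)[colnames(donor) %in% shared]
  list(donor = donor[, shared, drop = FALSE],
       recipient = recipient[, shared, drop = FALSE])
}
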