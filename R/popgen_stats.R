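# Differentiation and relatedness statistics for haploid allele copies:
# Nei (1972) distance, neighbour-joining, Weir-Cockerham Fst (haploid
# variance-component formulation), AMOVA and PCA.

# cap used when J_xy = 0 makes Nei's distance infinite
NEI_INF_CAP <- -log(.Machine$double.xmin)

# allele-1 frequency per group per locus; list(freq = G x L matrix, n = counts)
group_freqs <- function(g, groups) {
  groups <- as.factor(groups)
  m <- unclass(g)
  obs <- !is.na(m)
  mz <- m; mz[!obs] <- 0L
  f <- rowsum(mz, groups)
  n <- rowsum(obs + 0L, groups)
  list(freq = f / ifelse(n == 0L, NA_real_, n), n = n,
       labels = levels(groups))
}

#' Nei's (1972) standard genetic distance between groups
#'
#' `D = -ln(J_xy / sqrt(J_x J_y))` with the gene-identity terms `J` averaged
#' over loci; loci with no non-missing call in either group are skipped
#' pairwise.  A pair with `J_xy = 0` (fixed for opposite alleles everywhere)
#' is infinite and reported as the capped sentinel
#' `-log(.Machine$double.xmin)` with attribute `infinite` naming the pairs.
#' The Nei (1978) unbiased variant is available via `variant`.
#'
#' @param g a [genotype_matrix()].
#' @param groups factor-like of length `n_samples(g)`; each sample may be its
#'   own group (the default) for an all-individuals tree.
#' @param variant `"1972"` (default) or `"1978"` (unbiased, uses sample sizes).
#' @return a symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(g, groups = rownames(g), variant = c("1972", "1978")) {
  variant <- match.arg(variant)
  gf <- group_freqs(g, groups)
  p <- gf$freq; n <- gf$n
  G <- nrow(p)
  D <- matrix(0, G, G, dimnames = list(gf$labels, gf$labels))
  inf_pairs <- character(0)
  for (i in seq_len(G - 1L)) for (j in (i + 1L):G) {
    ok <- !is.na(p[i, ]) & !is.na(p[j, ])
    if (!any(ok)) {
      D[i, j] <- D[j, i] <- NA_real_
      next
    }
    jx <- p[i, ok]^2 + (1 - p[i, ok])^2
    jy <- p[j, ok]^2 + (1 - p[j, ok])^2
    if (variant == "1978") {
      # small-sample correction of homozygosity for haploid copies
      ni <- n[i, ok]; nj <- n[j, ok]
      jx <- pmax((ni * jx - 1) / pmax(ni - 1, 1), 0)
      jy <- pmax((nj * jy - 1) / pmax(nj - 1, 1), 0)
    }
    jxy <- p[i, ok] * p[j, ok] + (1 - p[i, ok]) * (1 - p[j, ok])
    num <- mean(jxy); den <- sqrt(mean(jx) * mean(jy))
    if (num <= 0 || den <= 0) {
      D[i, j] <- D[j, i] <- NEI_INF_CAP
      inf_pairs <- c(inf_pairs, paste(gf$labels[i], gf$labels[j], sep = ":"))
    } else {
      D[i, j] <- D[j, i] <- max(-log(num / den), 0)
    }
  }
  if (length(inf_pairs)) attr(D, "infinite") <- inf_pairs
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via \pkg{ape}); negative branch
#' lengths are clamped to zero.
#'
#' @param d symmetric distance matrix with ids as dimnames.
#' @return an [ape::nj()] `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbour joining needs >= 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` tree.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Weir-Cockerham Fst for haploid allele copies
#'
#' Each inbred line contributes one allele copy.  Per locus the one-way
#' variance components are estimated from the among/within mean squares with
#' the unequal-sample-size coefficient `n_c`, and the multi-locus estimate is
#' the ratio of sums `sum(a) / sum(a + b)`.  Monomorphic loci contribute
#' nothing; the estimate can be slightly negative and is reported as computed.
#'
#' @param g a [genotype_matrix()].
#' @param labels population label per sample.
#' @param pairs optional 2-column matrix / data.frame of population pairs; if
#'   given, a data.frame of pairwise estimates is returned.
#' @return single estimate: list(estimate, a, b) with per-locus components;
#'   with `pairs`: data.frame (pop1, pop2, fst).
#' @export
wc_fst <- function(g, labels, pairs = NULL) {
  labels <- as.factor(labels)
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    out <- data.frame(pop1 = as.character(pairs[[1L]]),
                      pop2 = as.character(pairs[[2L]]),
                      fst = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(out))) {
      keep <- labels %in% c(out$pop1[k], out$pop2[k])
      out$fst[k] <- wc_fst(g[keep, , drop = FALSE],
                           droplevels(labels[keep]))$estimate
    }
    return(out)
  }
  m <- unclass(g)
  pops <- levels(labels)
  r <- length(pops)
  if (r < 2L) stop("need >= 2 populations")
  obs <- !is.na(m)
  n_il <- rowsum(obs + 0L, labels)                    # r x L sample sizes
  x_il <- rowsum(ifelse(obs, m, 0L), labels)          # allele-1 counts
  if (any(rowSums(n_il >= 2L) == 0L))
    stop("population(s) with < 2 non-missing calls at every locus: ",
         paste(pops[rowSums(n_il >= 2L) == 0L], collapse = ", "))
  p_il <- x_il / ifelse(n_il == 0L, NA_real_, n_il)
  L <- ncol(m)
  a <- b <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    use <- which(n_il[, l] > 0L)
    if (length(use) < 2L) next
    n_i <- n_il[use, l]; p_i <- p_il[use, l]
    N <- sum(n_i); rr <- length(use)
    pbar <- sum(n_i * p_i) / N
    if (pbar <= 0 || pbar >= 1) { a[l] <- 0; b[l] <- 0; next }  # monomorphic
    MSA <- sum(n_i * (p_i - pbar)^2) / (rr - 1)
    MSW <- sum(n_i * p_i * (1 - p_i)) / (N - rr)
    n_c <- (N - sum(n_i^2) / N) / (rr - 1)
    a[l] <- (MSA - MSW) / n_c
    b[l] <- MSW
  }
  keep <- !is.na(a) & (a + b) != 0
  est <- sum(a[keep]) / sum(a[keep] + b[keep])
  list(estimate = est, a = a, b = b)
}

#' Average pairwise Weir-Cockerham Fst over all population pairs
#'
#' @inheritParams wc_fst
#' @export
average_pairwise_fst <- function(g, labels) {
  labels <- as.factor(labels)
  pops <- levels(labels)
  prs <- t(utils::combn(pops, 2L))
  mean(wc_fst(g, labels, pairs = prs)$fst)
}

#' Analysis of molecular variance (AMOVA) for haploid allele copies
#'
#' Distances are squared Euclidean allele differences (number of differing
#' loci over the shared non-missing set, scaled to the full locus count).
#' Sums of squares are partitioned over the nested design region >
#' subpopulation > within, variance components follow the standard nested
#' ANOVA expectations with unequal-size coefficients, and p-values come from
#' permutation: samples among subpopulations (within component structure) and
#' whole subpopulations among regions (region component).
#'
#' @param g a [genotype_matrix()].
#' @param subpop subpopulation label per sample.
#' @param region optional region label per sample (constant within subpop).
#'   With no region (or a single region) a one-level design is fitted.
#' @param n_perm permutation replicates for p-values (default 999; 0 skips).
#' @param seed seed for the permutations.
#' @return an `amova_result`: data.frame of components (source, df, SS, MS,
#'   variance, percent, p) plus the distance matrix used.
#' @export
amova <- function(g, subpop, region = NULL, n_perm = 999L, seed = 1L) {
  m <- unclass(g)
  d2 <- allele_dist2(m)
  subpop <- as.factor(subpop)
  one_level <- is.null(region) || length(unique(region)) < 2L
  if (!one_level) {
    region <- as.factor(region)
    tab <- table(subpop, region)
    if (any(rowSums(tab > 0L) > 1L))
      stop("region labels must be constant within subpopulation")
  }
  comp <- if (one_level) amova_one_level(d2, subpop)
          else amova_two_level(d2, subpop, region)
  if (n_perm > 0L) {
    set.seed(as.integer(seed))
    obs <- comp$variance
    exceed <- integer(nrow(comp))
    n_sub <- 0L
    for (b in seq_len(n_perm)) {
      perm_sub <- sample(subpop)
      cb <- if (one_level) amova_one_level(d2, perm_sub) else {
        # permute samples among subpops within the whole panel for the
        # subpop/within components, and whole subpops among regions for the
        # region component
        amova_two_level(d2, perm_sub,
                        region[sample(length(region))])
      }
      exceed <- exceed + (cb$variance >= obs)
      n_sub <- n_sub + 1L
    }
    comp$p <- (1 + exceed) / (n_perm + 1)
    comp$p[comp$source == "within"] <- NA_real_
  } else comp$p <- NA_real_
  structure(list(components = comp, dist2 = d2), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(x$components, row.names = FALSE)
  invisible(x)
}

# squared Euclidean allele-difference distance matrix (pairwise-complete,
# rescaled to the full locus count)
allele_dist2 <- function(m) {
  L <- ncol(m)
  if (!anyNA(m)) {
    cp <- tcrossprod(m)
    sq <- diag(cp)
    return(outer(sq, sq, "+") - 2 * cp)
  }
  n <- nrow(m)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    d2[i, j] <- d2[j, i] <- if (any(ok))
      sum((m[i, ok] - m[j, ok])^2) * L / sum(ok) else NA_real_
  }
  d2
}

ss_within_groups <- function(d2, f) {
  f <- as.factor(f)
  sum(vapply(levels(f), function(lv) {
    ix <- which(f == lv)
    if (length(ix) < 2L) return(0)
    sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
  }, 0))
}

amova_one_level <- function(d2, subpop) {
  N <- nrow(d2)
  G <- nlevels(subpop)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_w <- ss_within_groups(d2, subpop)
  ss_a <- ss_t - ss_w
  df_a <- G - 1L; df_w <- N - G
  ms_a <- ss_a / df_a; ms_w <- ss_w / df_w
  n_g <- tabulate(subpop)
  n0 <- (N - sum(n_g^2) / N) / df_a
  v_w <- ms_w
  v_a <- (ms_a - ms_w) / n0
  v <- c(v_a, v_w)
  data.frame(source = c("among_subpops", "within"),
             df = c(df_a, df_w), SS = c(ss_a, ss_w), MS = c(ms_a, ms_w),
             variance = v, percent = 100 * v / sum(v),
             stringsAsFactors = FALSE)
}

amova_two_level <- function(d2, subpop, region) {
  N <- nrow(d2)
  P <- nlevels(droplevels(subpop)); R <- nlevels(droplevels(region))
  subpop <- droplevels(subpop); region <- droplevels(region)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_wp <- ss_within_groups(d2, subpop)          # within subpops
  ss_wr <- ss_within_groups(d2, region)          # within regions
  ss_ar <- ss_t - ss_wr                          # among regions
  ss_ap <- ss_wr - ss_wp                         # among subpops within regions
  df_ar <- R - 1L; df_ap <- P - R; df_wp <- N - P
  ms_ar <- ss_ar / df_ar; ms_ap <- ss_ap / df_ap; ms_wp <- ss_wp / df_wp
  n_p <- tabulate(subpop)
  N_r <- tabulate(region)
  # unequal-size coefficients of the nested design
  sum_np2_by_r <- vapply(levels(region), function(rv) {
    ix <- subpop[region == rv]
    sum(table(ix)^2) / sum(region == rv)
  }, 0)
  n1 <- (N - sum(sum_np2_by_r)) / df_ap
  n2 <- (sum(sum_np2_by_r) - sum(n_p^2) / N) / df_ar
  n3 <- (N - sum(N_r^2) / N) / df_ar
  v_c <- ms_wp
  v_b <- (ms_ap - v_c) / n1
  v_a <- (ms_ar - v_c - n2 * v_b) / n3
  v <- c(v_a, v_b, v_c)
  data.frame(source = c("among_regions", "among_subpops_within_regions",
                        "within"),
             df = c(df_ar, df_ap, df_wp), SS = c(ss_ar, ss_ap, ss_wp),
             MS = c(ms_ar, ms_ap, ms_wp),
             variance = v, percent = 100 * v / sum(v),
             stringsAsFactors = FALSE)
}

#' Principal component analysis of a genotype matrix
#'
#' Columns are centred (no missing calls allowed; run after imputation or set
#' `mean_fill = TRUE`) and decomposed by SVD via [stats::prcomp()].
#'
#' @param g a [genotype_matrix()].
#' @param n_components number of PCs to return.
#' @param mean_fill replace missing calls by the column mean first.
#' @return list(scores, variance_proportion).
#' @export
pca_genotypes <- function(g, n_components = 2L, mean_fill = FALSE) {
  m <- unclass(g) * 1.0
  if (anyNA(m)) {
    if (!mean_fill) stop("missing calls present; impute first or mean_fill = TRUE")
    mu <- colMeans(m, na.rm = TRUE)
    ix <- which(is.na(m), arr.ind = TRUE)
    m[ix] <- mu[ix[, 2L]]
  }
  keep <- apply(m, 2L, function(x) var(x) > 0)
  pr <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       variance_proportion = (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)])
}
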