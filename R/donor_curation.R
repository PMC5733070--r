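# Reduce a worldwide donor panel to differentiated geographic subpopulations
# and test the resulting Fst increase against a random-subset null.

#' Curate a donor panel into differentiated geographic subpopulations
#'
#' Four documented passes on a clustering of the allele-difference distances:
#' (1) cut the tree into `n_clusters` clusters (average-linkage clustering of
#' the same distances the neighbour-joining tree is built from);
#' (2) drop clusters whose majority-subpopulation fraction is below
#' `purity_threshold` (reason `admixed_cluster`);
#' (3) per subpopulation keep the core cluster holding most of its members
#' and drop stragglers elsewhere (reason `outlier_accession`);
#' (4) drop accessions whose `nn_k` nearest neighbours are majority foreign
#' (reason `foreign_cluster`).
#' A subpopulation that would fall below `min_subpop` members is retained
#' unfiltered with a warning.
#'
#' @param g donor [genotype_matrix()].
#' @param metadata donor [sample_metadata()] with `subpop_id`.
#' @param n_clusters tree-cut size (default: number of subpopulations).
#' @param purity_threshold majority fraction below which a cluster is admixed
#'   (default 0.6).
#' @param nn_k nearest-neighbour set size for pass 4 (default 5).
#' @param min_subpop minimum retained subpopulation size (default 8).
#' @return list(genotypes, report) where report is a `curation_report`:
#'   removed (sample_id, reason), retained_sizes, fst_before, fst_after.
#' @export
curate_donors <- function(g, metadata, n_clusters = NULL,
                          purity_threshold = 0.6, nn_k = 5L, min_subpop = 8L) {
  pop <- metadata$subpop_id[match(rownames(g), metadata$sample_id)]
  if (anyNA(pop)) stop("every donor needs a subpop_id")
  pop <- as.integer(pop)
  if (is.null(n_clusters)) n_clusters <- length(unique(pop))
  d2 <- allele_dist2(unclass(g))
  hc <- stats::hclust(stats::as.dist(sqrt(d2)), method = "average")
  cl <- stats::cutree(hc, k = n_clusters)

  removed <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_set <- rep(FALSE, nrow(g))

  # pass 2: admixed clusters
  for (c_id in unique(cl)) {
    ix <- which(cl == c_id)
    maj <- max(table(pop[ix])) / length(ix)
    if (maj < purity_threshold) {
      drop_set[ix] <- TRUE
      removed <- rbind(removed, data.frame(
        sample_id = rownames(g)[ix], reason = "admixed_cluster",
        stringsAsFactors = FALSE))
    }
  }

  # pass 3: per-subpop core cluster
  for (p in unique(pop)) {
    ix <- which(pop == p & !drop_set)
    if (!length(ix)) next
    tab <- table(cl[ix])
    core <- as.integer(names(tab)[which.max(tab)])
    out <- ix[cl[ix] != core]
    if (length(out)) {
      drop_set[out] <- TRUE
      removed <- rbind(removed, data.frame(
        sample_id = rownames(g)[out], reason = "outlier_accession",
        stringsAsFactors = FALSE))
    }
  }

  # pass 4: nearest-neighbour purity among survivors
  surv <- which(!drop_set)
  if (length(surv) > nn_k) {
    dd <- sqrt(d2)[surv, surv, drop = FALSE]
    diag(dd) <- Inf
    foreign <- vapply(seq_along(surv), function(i) {
      nb <- order(dd[i, ])[seq_len(nn_k)]
      mean(pop[surv[nb]] != pop[surv[i]]) > 0.5
    }, TRUE)
    if (any(foreign)) {
      out <- surv[foreign]
      drop_set[out] <- TRUE
      removed <- rbind(removed, data.frame(
        sample_id = rownames(g)[out], reason = "foreign_cluster",
        stringsAsFactors = FALSE))
    }
  }

  # guard: never shrink a subpop below min_subpop - retain it unfiltered
  for (p in unique(pop)) {
    ix <- which(pop == p)
    if (sum(!drop_set[ix]) < min_subpop) {
      warning("subpopulation ", p, " would fall below ", min_subpop,
              " members; retained unfiltered")
      drop_set[ix] <- FALSE
      removed <- removed[!removed$sample_id %in% rownames(g)[ix], , drop = FALSE]
    }
  }

  keep <- !drop_set
  fst_before <- average_pairwise_fst(g, pop)
  fst_after <- average_pairwise_fst(g[keep, , drop = FALSE], pop[keep])
  report <- structure(list(
    removed = removed,
    retained_sizes = table(pop[keep]),
    fst_before = fst_before, fst_after = fst_after), class = "curation_report")
  list(genotypes = g[keep, , drop = FALSE], report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("curation: removed %d accessions (%s); avg pairwise Fst %.4f -> %.4f\n",
              nrow(x$removed),
              paste(names(table(x$removed$reason)), table(x$removed$reason),
                    sep = "=", collapse = ", "),
              x$fst_before, x$fst_after))
  invisible(x)
}

#' Random-subset null for the curated-panel Fst increase
#'
#' Per replicate, each subpopulation receives a without-replacement random
#' sample of the size it has in the curated set; the average pairwise Fst
#' over all subpopulation pairs is recorded.  The empirical p-value uses the
#' +1 correction `p = (1 + #{null >= observed}) / (n_reps + 1)`; a
#' normal-approximation p-value from the null mean and SD is also reported.
#'
#' @param g full donor [genotype_matrix()].
#' @param metadata donor [sample_metadata()].
#' @param target_sizes named integer vector: curated size per subpop id.
#' @param observed_fst the curated panel's average pairwise Fst.
#' @param n_reps replicates (default 100).
#' @param seed integer seed.
#' @return list(mean, sd, p_empirical, p_normal, null_values).
#' @export
random_subset_null <- function(g, metadata, target_sizes, observed_fst,
                               n_reps = 100L, seed = 1L) {
  pop <- metadata$subpop_id[match(rownames(g), metadata$sample_id)]
  avail <- table(pop)
  ids <- names(target_sizes)
  short <- ids[target_sizes > as.integer(avail[ids])]
  if (length(short) || anyNA(avail[ids]))
    stop("target size exceeds availability for subpop(s): ",
         paste(short, collapse = ", "))
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_reps), function(b) {
    take <- unlist(lapply(ids, function(p) {
      ix <- which(pop == as.integer(p))
      ix[sample.int(length(ix), target_sizes[[p]])]
    }))
    average_pairwise_fst(g[take, , drop = FALSE], pop[take])
  }, 0)
  mu <- mean(vals); s <- stats::sd(vals)
  p_emp <- (1 + sum(vals >= observed_fst)) / (n_reps + 1)
  p_norm <- if (s > 0) stats::pnorm(observed_fst, mu, s, lower.tail = FALSE)
            else as.numeric(observed_fst <= mu)
  list(mean = mu, sd = s, p_empirical = p_emp, p_normal = p_norm,
       null_values = vals)
}
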