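# In-silico chromosome painting: a haploid Li-Stephens copying-model HMM in
# which each recipient genome is an imperfect mosaic of donor haplotypes.
# Copying proportions per donor subpopulation are fitted by EM; replicate
# state paths are sampled from the fitted model and reduced to a per-SNP
# modal-donor consensus.

#' Build a copying model over a donor haplotype panel
#'
#' States are donor haplotypes; the stationary probability of (re)copying
#' haplotype `j` is `f[pop(j)] / n[pop(j)]` where `f` are the per-subpop
#' copying proportions.  Over `d` cM the chain stays on the current haplotype
#' with probability `exp(-rho d)`, otherwise redraws from those weights.
#' Emission is `1 - theta` on an allele match and `theta` on a mismatch.
#'
#' @param donors donor [genotype_matrix()] (one haploid copy per line).
#' @param donor_pops integer subpopulation id per donor sample.
#' @param f named copying proportions per subpop (default uniform; must sum
#'   to 1).
#' @param rho switch-rate scale per cM (> 0, default 0.1).
#' @param theta miscopy (mismatch) rate in (0, 0.5); default is the
#'   Watterson-style rate `w / (2 (H + w))` with `w = 1 / sum_{i<H} 1/i`
#'   for `H` donor haplotypes.
#' @param n_em_steps EM iterations used by [fit_em()] (default 20).
#' @return a `copying_model`.
#' @export
copying_model <- function(donors, donor_pops, f = NULL, rho = 0.1,
                          theta = NULL, n_em_steps = 20L) {
  stopifnot(inherits(donors, "genotype_matrix"))
  donor_pops <- as.integer(donor_pops)
  if (length(donor_pops) != nrow(donors))
    stop("donor_pops must label every donor haplotype")
  pops <- sort(unique(donor_pops))
  if (length(pops) < 2L) stop("donor panel must span >= 2 subpopulations")
  if (rho <= 0) stop("rho must be > 0")
  H <- nrow(donors)
  if (is.null(theta)) {
    w <- 1 / sum(1 / seq_len(H - 1L))
    theta <- w / (2 * (H + w))
  }
  if (theta <= 0 || theta >= 0.5) stop("theta must be in (0, 0.5)")
  if (is.null(f)) f <- setNames(rep(1 / length(pops), length(pops)),
                                as.character(pops))
  f <- f[as.character(pops)]
  if (anyNA(f) || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("f must be named by subpop, non-negative, and sum to 1")
  structure(list(donors = donors, donor_pops = donor_pops, pops = pops,
                 f = f, rho = rho, theta = theta,
                 n_em_steps = as.integer(n_em_steps)),
            class = "copying_model")
}

#' @export
print.copying_model <- function(x, ...) {
  cat(sprintf("copying_model: %d donor haplotypes, %d subpops, rho=%.3g/cM, theta=%.3g\n",
              nrow(x$donors), length(x$pops), x$rho, x$theta))
  print(round(x$f, 4))
  invisible(x)
}

# accept a 1-row genotype_matrix or a call vector; reorder by name when named
align_recipient <- function(recipient, model) {
  if (inherits(recipient, "genotype_matrix")) {
    stopifnot(nrow(recipient) == 1L)
    recipient <- unclass(recipient)[1L, ]
  }
  if (!is.null(names(recipient))) {
    if (!all(colnames(model$donors) %in% names(recipient)))
      stop("recipient is missing model SNPs")
    recipient <- recipient[colnames(model$donors)]
  } else if (length(recipient) != ncol(model$donors))
    stop("unnamed recipient must match the donor SNP count")
  as.integer(recipient)
}

# per-haplotype stationary copying weights f_{pop}/n_{pop}
hap_weights <- function(model) {
  n_pop <- table(factor(model$donor_pops, levels = model$pops))
  unname(model$f[as.character(model$donor_pops)] /
           as.numeric(n_pop[as.character(model$donor_pops)]))
}

# split the model's SNPs into chromosome blocks with stay probabilities
chrom_blocks <- function(model, map) {
  mm <- map_for(model$donors, map)
  lapply(split(mm, mm$chrom), function(cc) {
    list(chrom = cc$chrom[1L], cols = cc$col, snp_id = cc$snp_id, cM = cc$cM,
         stay = exp(-model$rho * diff(cc$cM)))
  })
}

#' Fit copying proportions by expectation-maximisation
#'
#' Runs exactly `model$n_em_steps` EM iterations.  The E-step runs scaled
#' forward-backward under the current model for every recipient and
#' chromosome; the M-step sets each subpopulation's copying proportion to its
#' expected share of (re)copy choice events, which is the exact maximiser of
#' the expected complete-data log-likelihood, so the total log-likelihood is
#' non-decreasing across steps.
#'
#' @param model a [copying_model()].
#' @param recipients recipient [genotype_matrix()] on the model's SNPs.
#' @param map a [genetic_map()].
#' @return the fitted `copying_model` with `loglik_trace` (log-likelihood
#'   under the proportions entering each step) attached.
#' @export
fit_em <- function(model, recipients, map) {
  stopifnot(inherits(model, "copying_model"))
  if (!identical(colnames(recipients), colnames(model$donors)))
    stop("recipients and donors must carry the same SNPs in the same order ",
         "(run intersect_snps first)")
  blocks <- chrom_blocks(model, map)
  donors_m <- unclass(model$donors)
  recip_m <- unclass(recipients)
  pop_f <- factor(model$donor_pops, levels = model$pops)
  trace <- numeric(model$n_em_steps)
  for (step in seq_len(model$n_em_steps)) {
    w <- hap_weights(model)
    total_ll <- 0
    draws <- numeric(nrow(donors_m))
    for (r in seq_len(nrow(recip_m))) {
      for (bl in blocks) {
        res <- .ls_posterior(donors_m[, bl$cols, drop = FALSE],
                             recip_m[r, bl$cols], w, bl$stay, model$theta)
        total_ll <- total_ll + res$loglik
        draws <- draws + res$draws
      }
    }
    trace[step] <- total_ll
    f_new <- tapply(draws, pop_f, sum)
    f_new[is.na(f_new)] <- 0
    model$f <- setNames(as.numeric(f_new) / sum(f_new),
                        as.character(model$pops))
  }
  model$loglik_trace <- trace
  model
}

#' Per-SNP copying posterior for one recipient
#'
#' Scaled forward-backward under the model, marginalised from donor
#' haplotypes to donor subpopulations; the posterior sums to 1 at every SNP.
#' Missing recipient calls give an uninformative emission.
#'
#' @param recipient a haploid call vector named by SNP id, or a single-row
#'   [genotype_matrix()].
#' @param model a [copying_model()].
#' @param map a [genetic_map()].
#' @return list(posterior [SNPs x subpops], snp (data.frame snp_id, chrom,
#'   cM), loglik).
#' @export
forward_backward <- function(recipient, model, map) {
  recipient <- align_recipient(recipient, model)
  blocks <- chrom_blocks(model, map)
  donors_m <- unclass(model$donors)
  w <- hap_weights(model)
  pop_ind <- outer(model$donor_pops, model$pops, "==") + 0
  out <- list(); snp <- list(); ll <- 0
  for (bl in blocks) {
    res <- .ls_posterior(donors_m[, bl$cols, drop = FALSE],
                         recipient[bl$cols], w, bl$stay, model$theta)
    out[[length(out) + 1L]] <- res$gamma %*% pop_ind
    snp[[length(snp) + 1L]] <- data.frame(snp_id = bl$snp_id,
                                          chrom = bl$chrom, cM = bl$cM,
                                          stringsAsFactors = FALSE)
    ll <- ll + res$loglik
  }
  posterior <- do.call(rbind, out)
  colnames(posterior) <- as.character(model$pops)
  snp <- do.call(rbind, snp)
  rownames(posterior) <- snp$snp_id
  list(posterior = posterior, snp = snp, loglik = ll)
}

#' Sample replicate copying paths for one recipient
#'
#' Each replicate is one full state path drawn by stochastic backward
#' sampling from the scaled forward recursion (so replicates are exact draws
#' from the path posterior); per-SNP donor-subpopulation labels are
#' accumulated into counts.
#'
#' @inheritParams forward_backward
#' @param n_replicates number of sampled paths (default 100).
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @return a `painting_counts`: list(counts [SNPs x subpops, each row summing
#'   to `n_replicates`], snp, n_replicates).
#' @export
sample_paintings <- function(recipient, model, map, n_replicates = 100L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  recipient <- align_recipient(recipient, model)
  blocks <- chrom_blocks(model, map)
  donors_m <- unclass(model$donors)
  w <- hap_weights(model)
  pop_index <- match(model$donor_pops, model$pops)
  out <- list(); snp <- list()
  for (bl in blocks) {
    fwd <- .ls_forward(donors_m[, bl$cols, drop = FALSE],
                       recipient[bl$cols], w, bl$stay, model$theta)
    out[[length(out) + 1L]] <- .ls_sample_paths(fwd$alpha, w, bl$stay,
                                                pop_index,
                                                length(model$pops),
                                                as.integer(n_replicates))
    snp[[length(snp) + 1L]] <- data.frame(snp_id = bl$snp_id,
                                          chrom = bl$chrom, cM = bl$cM,
                                          stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, out)
  colnames(counts) <- as.character(model$pops)
  snp <- do.call(rbind, snp)
  rownames(counts) <- snp$snp_id
  structure(list(counts = counts, snp = snp,
                 n_replicates = as.integer(n_replicates)),
            class = "painting_counts")
}

#' Replicate-consensus donor assignment per SNP
#'
#' The modal donor subpopulation over the replicate counts; ties are broken
#' toward the smallest subpop id and flagged.
#'
#' @param counts a `painting_counts` from [sample_paintings()].
#' @return data.frame (snp_id, chrom, cM, modal_subpop, support, tie).
#' @export
consensus <- function(counts) {
  stopifnot(inherits(counts, "painting_counts"))
  cm <- counts$counts
  pops <- as.integer(colnames(cm))
  best <- max.col(cm, ties.method = "first")  # first = smallest pop id
  mx <- cm[cbind(seq_len(nrow(cm)), best)]
  tie <- rowSums(cm == mx) > 1L
  data.frame(snp_id = counts$snp$snp_id, chrom = counts$snp$chrom,
             cM = counts$snp$cM, modal_subpop = pops[best],
             support = mx / counts$n_replicates, tie = tie,
             stringsAsFactors = FALSE)
}

#' Summarise consensus ancestry by recipient and by group
#'
#' Recipient proportions are the fraction of SNP loci assigned to each donor
#' subpopulation (SNPs weighted equally).  Group proportions are the mean
#' over the recipients in each group; per-locus group profiles are the
#' fraction of the group's recipients assigned to each subpopulation at each
#' locus.
#'
#' @param consensus_list named list of [consensus()] data.frames (names are
#'   recipient sample ids).
#' @param metadata [sample_metadata()] covering the recipients.
#' @param group_by `"recipient"`, `"period"`, `"state"` or `"year"`.
#' @return an `ancestry_summary`: list(pops, recipient_proportions
#'   [recipients x subpops], group_proportions, group_profiles, snp).
#' @export
summarize_ancestry <- function(consensus_list, metadata,
                               group_by = c("period", "recipient", "state",
                                            "year")) {
  group_by <- match.arg(group_by)
  pops <- sort(unique(unlist(lapply(consensus_list,
                                    function(x) x$modal_subpop))))
  S <- nrow(consensus_list[[1L]])
  prop <- t(vapply(consensus_list, function(x) {
    tab <- table(factor(x$modal_subpop, levels = pops))
    as.numeric(tab) / S
  }, numeric(length(pops))))
  colnames(prop) <- as.character(pops)
  ids <- names(consensus_list)
  grp <- if (group_by == "recipient") ids else {
    gv <- metadata[[if (group_by == "period") "period" else group_by]]
    as.character(gv[match(ids, metadata$sample_id)])
  }
  keep <- !is.na(grp)
  groups <- sort(unique(grp[keep]))
  group_prop <- do.call(rbind, lapply(groups, function(gname) {
    colMeans(prop[grp == gname & keep, , drop = FALSE])
  }))
  rownames(group_prop) <- groups
  group_profiles <- lapply(groups, function(gname) {
    members <- consensus_list[which(grp == gname & keep)]
    prof <- matrix(0, S, length(pops),
                   dimnames = list(members[[1L]]$snp_id, as.character(pops)))
    for (m in members) {
      ix <- cbind(seq_len(S), match(m$modal_subpop, pops))
      prof[ix] <- prof[ix] + 1
    }
    prof / length(members)
  })
  names(group_profiles) <- groups
  structure(list(pops = pops, recipient_proportions = prop,
                 group_proportions = group_prop,
                 group_profiles = group_profiles,
                 snp = consensus_list[[1L]][c("snp_id", "chrom", "cM")],
                 group_by = group_by),
            class = "ancestry_summary")
}

#' Paint a recipient panel against a donor panel
#'
#' End-to-end painting: build the copying model (optionally excluding donor
#' subpopulations), fit copying proportions by EM, sample replicate paths
#' for every recipient, and form the per-SNP consensus.
#'
#' @param donors donor [genotype_matrix()].
#' @param metadata donor [sample_metadata()] with `subpop_id`.
#' @param recipients recipient [genotype_matrix()] (same SNPs as donors).
#' @param map a [genetic_map()].
#' @param exclude integer subpop ids to drop from the panel before fitting
#'   (cleaner painting); at least 2 subpops must remain.
#' @param n_replicates replicate paths per recipient (default 100).
#' @param n_em_steps EM iterations (default 20).
#' @param rho,theta model parameters (see [copying_model()]).
#' @param seed integer seed governing the replicate sampling.
#' @return list(model, consensus (named list per recipient), counts (named
#'   list of `painting_counts`), exclude).
#' @export
paint_panel <- function(donors, metadata, recipients, map, exclude = NULL,
                        n_replicates = 100L, n_em_steps = 20L, rho = 0.1,
                        theta = NULL, seed = 1L) {
  pop <- metadata$subpop_id[match(rownames(donors), metadata$sample_id)]
  if (anyNA(pop)) stop("every donor needs a subpop_id")
  if (!is.null(exclude)) {
    keep <- !(pop %in% exclude)
    if (length(unique(pop[keep])) < 2L)
      stop("exclusion leaves fewer than 2 donor subpopulations")
    donors <- donors[keep, , drop = FALSE]
    pop <- pop[keep]
  }
  model <- copying_model(donors, pop, rho = rho, theta = theta,
                         n_em_steps = n_em_steps)
  model <- fit_em(model, recipients, map)
  set.seed(as.integer(seed))
  counts <- lapply(seq_len(nrow(recipients)), function(r)
    sample_paintings(unclass(recipients)[r, ], model, map,
                     n_replicates = n_replicates, seed = NULL))
  names(counts) <- rownames(recipients)
  cons <- lapply(counts, consensus)
  list(model = model, consensus = cons, counts = counts, exclude = exclude)
}

#' Cleaner painting: repaint with suspect donor subpopulations removed
#'
#' Donor subpopulations whose apparent contribution is suspected to reflect
#' recent gene flow among donors (pseudo-ancestry) are removed from the
#' panel; the copying proportions are refitted and all downstream outputs
#' regenerated, labelled with the exclusion set.
#'
#' @inheritParams paint_panel
#' @export
cleaner_painting <- function(donors, metadata, recipients, map, exclude,
                             ...) {
  paint_panel(donors, metadata, recipients, map, exclude = exclude, ...)
}

#' Detect genomic regions whose major ancestor is not the focal donor
#'
#' A locus is deviant when the focal subpopulation's per-locus group fraction
#' falls below `dominance_frac`; maximal runs of at least `min_snps`
#' consecutive deviant loci on a chromosome become regions, annotated with
#' every subpopulation whose mean in-region fraction exceeds `report_frac`.
#'
#' @param profile per-locus group profile matrix (SNPs x subpops) from
#'   [summarize_ancestry()] `group_profiles`.
#' @param snp data.frame (snp_id, chrom, cM) aligned with `profile` rows.
#' @param focal_subpop focal subpop id (e.g. the dominant donor).
#' @param min_snps minimum run length (default 3).
#' @param dominance_frac focal fraction below which a locus is deviant
#'   (default 0.5).
#' @param report_frac report subpops above this mean in-region fraction
#'   (default 0.2).
#' @return data.frame (chrom, start_cM, end_cM, start_snp, end_snp, n_snps,
#'   focal_mean, dominant_subpops).
#' @export
detect_deviant_regions <- function(profile, snp, focal_subpop, min_snps = 3L,
                                   dominance_frac = 0.5, report_frac = 0.2) {
  focal <- as.character(focal_subpop)
  if (!focal %in% colnames(profile))
    stop("focal subpop ", focal, " absent from profile")
  out <- list()
  for (ch in unique(snp$chrom)) {
    ix <- which(snp$chrom == ch)
    ix <- ix[order(snp$cM[ix])]
    dev <- profile[ix, focal] < dominance_frac
    r <- rle(dev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_snps)) {
      rows <- ix[starts[k]:ends[k]]
      means <- colMeans(profile[rows, , drop = FALSE])
      dom <- setdiff(names(means)[means > report_frac], focal)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_cM = snp$cM[rows[1L]],
        end_cM = snp$cM[rows[length(rows)]],
        start_snp = snp$snp_id[rows[1L]],
        end_snp = snp$snp_id[rows[length(rows)]],
        n_snps = length(rows), focal_mean = means[focal],
        dominant_subpops = paste(sort(as.integer(dom)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_cM = numeric(0),
                      end_cM = numeric(0), start_snp = character(0),
                      end_snp = character(0), n_snps = integer(0),
                      focal_mean = numeric(0),
                      dominant_subpops = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
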