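# Synthetic inputs with the statistical structure the analysis assumes:
# Balding-Nichols donor subpopulations with within-subpop haplotype sharing,
# mosaic recipients with recorded truth, Wright-Fisher drift panels and
# two-channel intensity clouds.

#' Simulate differentiated donor subpopulations
#'
#' Allele frequencies follow the Balding-Nichols model: an ancestral frequency
#' `p ~ U(0.05, 0.95)` per SNP and subpopulation frequencies
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` so the expected Fst among subpopulations is
#' `F`.  Founder haplotypes are drawn site-wise from the subpopulation
#' frequencies and then recombined within each subpopulation for `g`
#' generations (random pairing, complementary recombinant offspring), which
#' creates the haplotype sharing a copying model needs while leaving the
#' subpopulation allele frequencies -- and hence the design Fst -- untouched.
#'
#' @param K number of subpopulations (>= 2).
#' @param F_target differentiation parameter, `0 < F < 1` (scalar or length-K).
#' @param n_snps total SNPs, split evenly across chromosomes.
#' @param n_chromosomes,map_length_cM chromosome count and cM length of each.
#' @param n_per_pop haploid samples per subpopulation.
#' @param g generations of within-subpopulation mixing (default 20).
#' @param n_founders distinct founder haplotypes per subpopulation (default
#'   `n_per_pop`).  Fewer founders than samples duplicates founder
#'   haplotypes, creating within-subpopulation LD and haplotype sharing (as
#'   in real breeding panels) at the cost of extra founder-sampling drift in
#'   the realised allele frequencies.
#' @param seed integer seed; results are reproducible given the seed.
#' @return list with `genotypes` ([genotype_matrix()]), `map`
#'   ([genetic_map()]), `metadata` ([sample_metadata()]) and the per-SNP
#'   subpopulation allele frequencies in `freqs`.
#' @export
simulate_donor_pops <- function(K, F_target, n_snps, n_chromosomes = 1L,
                                map_length_cM = 100, n_per_pop = 30L,
                                g = 20L, n_founders = n_per_pop, seed = 1L) {
  if (K < 2L) stop("K must be >= 2: differentiation undefined for one pop")
  if (any(F_target <= 0) || any(F_target >= 1)) stop("F must be in (0, 1)")
  if (n_founders < 2L) stop("need >= 2 founders per subpopulation")
  F_target <- rep_len(F_target, K)
  set.seed(as.integer(seed))
  map <- uniform_map(n_snps, n_chromosomes, map_length_cM)
  p_anc <- runif(n_snps, 0.05, 0.95)
  freqs <- matrix(NA_real_, n_snps, K)
  haps <- vector("list", K)
  # all founders are drawn before any mixing so the founder world (and the
  # realised allele frequencies) is invariant to g
  for (k in seq_len(K)) {
    Fk <- F_target[k]
    pk <- rbeta(n_snps, p_anc * (1 - Fk) / Fk, (1 - p_anc) * (1 - Fk) / Fk)
    # guard degenerate Beta draws so loci stay usable
    pk <- pmin(pmax(pk, 1e-6), 1 - 1e-6)
    freqs[, k] <- pk
    founders <- matrix(rbinom(n_founders * n_snps, 1L,
                              rep(pk, each = n_founders)),
                       nrow = n_founders, ncol = n_snps)
    haps[[k]] <- if (n_founders == n_per_pop) founders
                 else founders[sample.int(n_founders, n_per_pop,
                                          replace = TRUE), , drop = FALSE]
  }
  for (k in seq_len(K))
    for (gen in seq_len(g)) haps[[k]] <- mix_generation(haps[[k]], map)
  calls <- do.call(rbind, haps)
  ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("D%02d_%03d", k, seq_len(n_per_pop))))
  dimnames(calls) <- list(ids, map$snp_id)
  meta <- sample_metadata(data.frame(
    sample_id = ids, role = "donor",
    subpop_id = rep(seq_len(K), each = n_per_pop),
    country = sprintf("country_%02d", rep(seq_len(K), each = n_per_pop)),
    stringsAsFactors = FALSE))
  list(genotypes = genotype_matrix(calls), map = map, metadata = meta,
       freqs = freqs)
}

# uniform SNP placement on the cM map, sorted within chromosome
uniform_map <- function(n_snps, n_chromosomes, map_length_cM) {
  chrom_of <- sort(rep_len(seq_len(n_chromosomes), n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom_of), function(ix)
    sort(runif(length(ix), 0, map_length_cM))))
  genetic_map(data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = sprintf("chr%02d", chrom_of),
    cM = as.numeric(pos), stringsAsFactors = FALSE))
}

# One generation of within-subpopulation mixing that creates haplotype
# sharing without drift: haplotypes are paired at random and each pair is
# replaced by two complementary recombinants (crossovers ~ Poisson(L/100 Morgans)
# per chromosome), so per-locus allele counts are preserved exactly and the
# subpopulation allele frequencies stay at their Balding-Nichols draws.
mix_generation <- function(h, map) {
  n <- nrow(h)
  out <- h
  perm <- sample.int(n)
  n_pair <- n %/% 2L
  chroms <- split(seq_len(nrow(map)), map$chrom)
  for (cols in chroms) {
    pos <- map$cM[cols]
    L <- max(pos)
    for (k in seq_len(n_pair)) {
      i <- perm[2L * k - 1L]; j <- perm[2L * k]
      nx <- rpois(1L, L / 100)
      if (nx == 0L) {
        src <- rep(sample(c(TRUE, FALSE), 1L), length(cols))
      } else {
        cuts <- sort(runif(nx, 0, L))
        seg <- findInterval(pos, cuts)
        src <- (seg + sample(0:1, 1L)) %% 2L == 0L
      }
      out[i, cols] <- ifelse(src, h[i, cols], h[j, cols])
      out[j, cols] <- ifelse(src, h[j, cols], h[i, cols])
    }
  }
  out
}

#' Simulate mosaic recipients from a donor panel
#'
#' Each recipient chromosome is tiled by segments whose breakpoints follow a
#' Poisson process with `breakpoint_rate` per cM; each segment copies one
#' donor haplotype from a subpopulation drawn by `proportions`, with per-site
#' miscopy noise `epsilon` (allele flips).  The returned truth records every
#' segment, the per-recipient ancestry proportions (in cM) and the true donor
#' subpopulation of every SNP.
#'
#' @param donors a [genotype_matrix()] of donor haplotypes.
#' @param map the donors' [genetic_map()].
#' @param metadata donor [sample_metadata()] (for subpop ids).
#' @param proportions named numeric weights per subpop id, summing to 1.
#' @param breakpoint_rate expected breakpoints per cM (> 0).
#' @param n_recipients number of recipients.
#' @param epsilon per-site allele-flip probability (default 0.002).
#' @param seed integer seed.
#' @return list with `genotypes` (recipients), `truth` (a `mosaic_truth`:
#'   `segments` data.frame, `proportions` matrix, `snp_pop` matrix of the true
#'   subpop per recipient x SNP).
#' @export
simulate_mosaic_recipients <- function(donors, map, metadata, proportions,
                                       breakpoint_rate = 0.05,
                                       n_recipients = 20L,
                                       epsilon = 0.002, seed = 1L) {
  stopifnot(inherits(donors, "genotype_matrix"))
  if (breakpoint_rate <= 0) stop("breakpoint_rate must be > 0")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (nrow(donors) == 0L) stop("donor panel is empty")
  pops <- as.integer(names(proportions))
  if (anyNA(pops)) stop("proportions must be named by subpop id")
  pop_of <- metadata$subpop_id[match(rownames(donors), metadata$sample_id)]
  hap_by_pop <- split(seq_len(nrow(donors)), pop_of)
  absent <- setdiff(as.character(pops), names(hap_by_pop))
  if (length(absent)) stop("no donor haplotypes for subpop(s): ",
                           paste(absent, collapse = ", "))
  set.seed(as.integer(seed))
  m <- map_for(donors, map)
  chroms <- split(m, m$chrom)
  S <- ncol(donors)
  calls <- matrix(NA_integer_, n_recipients, S)
  snp_pop <- matrix(NA_integer_, n_recipients, S)
  segs <- list()
  prop <- matrix(0, n_recipients, length(pops),
                 dimnames = list(NULL, as.character(pops)))
  total_cM <- sum(vapply(chroms, function(cc) max(cc$cM), 0))
  for (r in seq_len(n_recipients)) {
    for (cc in chroms) {
      L <- max(cc$cM)
      nb <- rpois(1L, breakpoint_rate * L)
      cuts <- sort(runif(nb, 0, L))
      bounds <- c(0, cuts, L + 1e-9)
      for (s in seq_len(length(bounds) - 1L)) {
        a <- bounds[s]; b <- bounds[s + 1L]
        pop <- pops[sample.int(length(pops), 1L, prob = proportions)]
        hap <- hap_by_pop[[as.character(pop)]]
        hap <- hap[sample.int(length(hap), 1L)]
        in_seg <- cc$cM >= a & cc$cM < b
        cols <- cc$col[in_seg]
        if (length(cols)) {
          v <- unclass(donors)[hap, cols]
          if (epsilon > 0) {
            flip <- runif(length(v)) < epsilon
            v[flip] <- 1L - v[flip]
          }
          calls[r, cols] <- v
          snp_pop[r, cols] <- pop
        }
        segs[[length(segs) + 1L]] <- data.frame(
          recipient = r, chrom = cc$chrom[1L], start_cM = a,
          end_cM = min(b, L), subpop = pop, donor_hap = rownames(donors)[hap],
          stringsAsFactors = FALSE)
        prop[r, as.character(pop)] <- prop[r, as.character(pop)] + (min(b, L) - a)
      }
    }
  }
  prop <- prop / total_cM
  ids <- sprintf("R%03d", seq_len(n_recipients))
  dimnames(calls) <- list(ids, colnames(donors))
  rownames(snp_pop) <- ids
  colnames(snp_pop) <- colnames(donors)
  truth <- structure(list(segments = do.call(rbind, segs),
                          proportions = prop, snp_pop = snp_pop),
                     class = "mosaic_truth")
  list(genotypes = genotype_matrix(calls), truth = truth)
}

#' Simulate Wright-Fisher drift at unlinked loci
#'
#' A monoecious diploid population of `true_Ne` individuals (2 `true_Ne`
#' haploid copies) drifts for `n_generations` of random mating; loci are
#' unlinked (free recombination in gamete formation).  `n_sampled` haploid
#' copies from the final generation are returned, supporting recovery tests
#' for the LD-based effective-size estimator.
#'
#' @param true_Ne effective (census) size in diploid individuals.
#' @param n_generations generations of drift (0 returns the founders).
#' @param n_loci unlinked loci; founder frequencies `~ U(0.1, 0.9)`.
#' @param n_sampled haploid copies sampled (<= 2 * true_Ne).
#' @param seed integer seed.
#' @return a [genotype_matrix()] of `n_sampled` haploid copies.
#' @export
simulate_wright_fisher <- function(true_Ne, n_generations, n_loci,
                                   n_sampled, seed = 1L) {
  if (n_sampled > 2L * true_Ne)
    stop("n_sampled exceeds 2 * true_Ne haploid copies")
  set.seed(as.integer(seed))
  n_cop <- 2L * true_Ne
  p0 <- runif(n_loci, 0.1, 0.9)
  pop <- matrix(rbinom(n_cop * n_loci, 1L, rep(p0, each = n_cop)),
                nrow = n_cop, ncol = n_loci)
  for (gen in seq_len(n_generations)) {
    # each offspring copy is a gamete: pick a parent individual, then at each
    # locus take either of its two copies (free recombination)
    parent <- sample.int(true_Ne, n_cop, replace = TRUE)
    a <- pop[2L * parent - 1L, , drop = FALSE]
    b <- pop[2L * parent, , drop = FALSE]
    pick <- matrix(runif(n_cop * n_loci) < 0.5, n_cop, n_loci)
    pop <- ifelse(pick, a, b)
  }
  take <- sample.int(n_cop, n_sampled)
  out <- pop[take, , drop = FALSE]
  dimnames(out) <- list(sprintf("wf%04d", seq_len(n_sampled)),
                        sprintf("locus%05d", seq_len(n_loci)))
  genotype_matrix(out)
}

#' Default two-cluster intensity model for biallelic SNPs
#'
#' @param snp_ids SNP identifiers.
#' @param theta0,theta1 Theta centers of the allele-0 and allele-1 clusters.
#' @param norm_r NormR center shared by both clusters.
#' @param sd_theta,sd_norm_r per-axis cluster standard deviations.
#' @return a `cluster_model`: per SNP a data.frame of clusters
#'   (label, theta, norm_r, sd_theta, sd_norm_r).
#' @export
cluster_model_default <- function(snp_ids, theta0 = 0.15, theta1 = 0.85,
                                  norm_r = 1.0, sd_theta = 0.05,
                                  sd_norm_r = 0.1) {
  if (sd_theta <= 0 || sd_norm_r <= 0) stop("cluster SDs must be > 0")
  one <- data.frame(label = c(0L, 1L), theta = c(theta0, theta1),
                    norm_r = c(norm_r, norm_r),
                    sd_theta = sd_theta, sd_norm_r = sd_norm_r)
  structure(setNames(rep(list(one), length(snp_ids)), snp_ids),
            class = "cluster_model")
}

#' Simulate two-channel intensity clouds around genotype clusters
#'
#' Each call's (Theta, NormR) point is drawn from a Gaussian around its
#' genotype's cluster center with `noise_sd` scaling the model SDs.
#'
#' @param g a [genotype_matrix()] (missing calls get no intensity row).
#' @param model a `cluster_model` covering the SNPs of `g`.
#' @param noise_sd multiplier on the model SDs (0 puts points at the centers).
#' @param seed integer seed.
#' @return data.frame (sample_id, snp_id, theta, norm_r).
#' @export
simulate_intensities <- function(g, model, noise_sd = 1, seed = 1L) {
  stopifnot(inherits(model, "cluster_model"))
  set.seed(as.integer(seed))
  rows <- lapply(colnames(g), function(s) {
    cl <- model[[s]]
    if (is.null(cl)) stop("SNP absent from cluster model: ", s)
    calls <- unclass(g)[, s]
    keep <- !is.na(calls)
    ix <- match(calls[keep], cl$label)
    data.frame(sample_id = rownames(g)[keep], snp_id = s,
               theta = cl$theta[ix] + rnorm(sum(keep), 0, noise_sd * cl$sd_theta[ix]),
               norm_r = cl$norm_r[ix] + rnorm(sum(keep), 0, noise_sd * cl$sd_norm_r[ix]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
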