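# small builders used across test files

# genotype matrix from a plain matrix, auto-naming samples/SNPs
gm <- function(m, samples = NULL, snps = NULL) {
  m <- as.matrix(m)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(snps)) snps <- sprintf("m%03d", seq_len(ncol(m)))
  dimnames(m) <- list(samples, snps)
  genotype_matrix(m)
}

# evenly spaced single- or multi-chromosome map for n SNPs
tiny_map <- function(n, n_chrom = 1L, length_cM = 100, snps = NULL) {
  if (is.null(snps)) snps <- sprintf("m%03d", seq_len(n))
  chrom <- sort(rep_len(seq_len(n_chrom), n))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(ix)
    seq(0, length_cM, length.out = length(ix))))
  genetic_map(data.frame(snp_id = snps, chrom = paste0("chr", chrom),
                         cM = as.numeric(pos)))
}

donor_meta <- function(ids, pops) {
  sample_metadata(data.frame(sample_id = ids, role = "donor",
                             subpop_id = pops, stringsAsFactors = FALSE))
}

# per-SNP painting accuracy of a consensus against mosaic truth
consensus_accuracy <- function(consensus_list, truth) {
  mean(vapply(names(consensus_list), function(id) {
    cons <- consensus_list[[id]]
    mean(cons$modal_subpop == truth$snp_pop[id, cons$snp_id])
  }, 0))
}
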