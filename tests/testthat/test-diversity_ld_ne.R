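test_that("window construction counts, spans and missing policy are right", {
  don <- simulate_donor_pops(K = 2, F_target = 0.2, n_snps = 20,
                             n_per_pop = 10, g = 2, seed = 2)
  sp <- window_spectra(don$genotypes, don$map, w = 15, step = 1)
  expect_length(sp, 6L)   # 20 - 15 + 1
  # identical samples: single haplotype with p = 1 in every window
  m <- matrix(rep(c(0L, 1L), 10)[1:20], 10, 20, byrow = TRUE)
  dimnames(m) <- list(sprintf("s%02d", 1:10), don$map$snp_id)
  sp1 <- window_spectra(genotype_matrix(m), don$map, w = 15)
  expect_true(all(vapply(sp1, function(x) identical(x$p, 1), TRUE)))
  # a sample with a missing call is dropped from that window only
  m2 <- unclass(don$genotypes)
  m2[1, 3] <- NA
  sp2 <- window_spectra(gm(m2, rownames(m2), colnames(m2)), don$map, w = 15)
  expect_equal(sp2[[1]]$n, 19L)
  expect_equal(sp2[[6]]$n, 20L)
  # windows never span chromosomes; short chromosomes are skipped (one
  # warning per short chromosome)
  map2 <- tiny_map(20, n_chrom = 2, snps = don$map$snp_id)
  wns <- testthat::capture_warnings(
    sp3 <- window_spectra(don$genotypes, map2, w = 15))
  expect_length(wns, 2L)
  expect_match(wns, "fewer than 15", all = TRUE)
  expect_length(sp3, 0L)
})

test_that("a designed 5/3/2 window yields the spectrum (0.5, 0.3, 0.2)", {
  hapA <- rep(0L, 15); hapB <- rep(1L, 15); hapC <- rep(c(0L, 1L), 8)[1:15]
  m <- rbind(matrix(hapA, 5, 15, byrow = TRUE),
             matrix(hapB, 3, 15, byrow = TRUE),
             matrix(hapC, 2, 15, byrow = TRUE))
  dimnames(m) <- list(sprintf("s%02d", 1:10), sprintf("m%03d", 1:15))
  sp <- window_spectra(genotype_matrix(m), tiny_map(15), w = 15)
  expect_length(sp, 1L)
  expect_equal(sort(sp[[1]]$p, decreasing = TRUE), c(0.5, 0.3, 0.2))
  expect_equal(hhe(sp[[1]]), 1 - 0.38)
  expect_equal(hae(sp[[1]]), 1 / 0.38)
})

test_that("HHe and HAe evaluate their formulas and the exact identity", {
  expect_equal(hhe(c(0.5, 0.5)), 0.5)
  expect_equal(hae(c(0.5, 0.5)), 2)
  expect_equal(hhe(rep(0.1, 10)), 0.9)
  expect_equal(hae(rep(0.25, 4)), 4)
  # brute-force dictionary counting agrees on random fixtures, and
  # HAe = 1 / (1 - HHe) holds exactly window by window
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(rbinom(12 * 15, 1, 0.5), 12, 15)
    dimnames(m) <- list(sprintf("s%02d", 1:12), sprintf("m%03d", 1:15))
    sp <- window_spectra(genotype_matrix(m), tiny_map(15), w = 15)[[1]]
    ref <- oracle_window_hhe(m)
    expect_equal(hhe(sp), ref$hhe, tolerance = 1e-12)
    expect_equal(hae(sp), ref$hae, tolerance = 1e-12)
    expect_equal(hae(sp), 1 / (1 - hhe(sp)), tolerance = 1e-12)
  }
  expect_error(hhe(c(0.5, 0.4)), "sum to 1")
})

test_that("r2 matches the D-based formula, its bounds and symmetries", {
  # designed haplotype counts AB=40, Ab=10, aB=10, ab=40
  x <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 10, 40))
  y <- rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40))
  m <- cbind(A = x, B = y, C = x)  # C duplicates A
  rownames(m) <- sprintf("s%03d", 1:100)
  map <- genetic_map(data.frame(snp_id = c("A", "B", "C"),
                                chrom = "chr1", cM = c(0, 10, 20)))
  ld <- pairwise_r2(genotype_matrix(m), map, "intra_chrom")
  r_ab <- ld$r2[(ld$snp1 == "A" & ld$snp2 == "B") |
                  (ld$snp1 == "B" & ld$snp2 == "A")]
  expect_equal(r_ab, 0.36, tolerance = 1e-12)
  expect_equal(r_ab, oracle_r2(x, y), tolerance = 1e-12)
  # identical copy of a locus -> r2 = 1
  r_ac <- ld$r2[(ld$snp1 == "A" & ld$snp2 == "C") |
                  (ld$snp1 == "C" & ld$snp2 == "A")]
  expect_equal(r_ac, 1)
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1))
  # allele relabelling invariance
  m2 <- m; m2[, "B"] <- 1L - m2[, "B"]
  ld2 <- pairwise_r2(genotype_matrix(m2), map, "intra_chrom")
  expect_equal(sort(ld2$r2), sort(ld$r2), tolerance = 1e-12)
})

test_that("independent loci show r2 near the 1/n sampling floor", {
  set.seed(44)
  n <- 1000
  m <- matrix(rbinom(n * 40, 1, 0.5), n, 40)
  dimnames(m) <- list(sprintf("s%04d", 1:n), sprintf("m%03d", 1:40))
  map <- tiny_map(40, n_chrom = 2)
  ld <- pairwise_r2(genotype_matrix(m), map, "inter_chrom", max_pairs = 100,
                    seed = 1)
  expect_lt(mean(ld$r2), 0.005)
})

test_that("background threshold is the documented type-7 quantile", {
  vals <- seq(0, 0.99, by = 0.01)
  expect_equal(background_threshold(vals),
               unname(quantile(vals, 0.99, type = 7)))
  expect_equal(background_threshold(rep(0.3, 150)), 0.3)
  expect_error(background_threshold(runif(50)), ">= 100")
  # null simulation: threshold lands in the 3-5/n band
  set.seed(9)
  n <- 200
  m <- matrix(rbinom(n * 60, 1, 0.5), n, 60)
  dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("m%03d", 1:60))
  ld <- pairwise_r2(genotype_matrix(m), tiny_map(60, n_chrom = 3),
                    "inter_chrom", seed = 2)
  thr <- background_threshold(ld$r2)
  expect_gt(thr, 1 / n)
  expect_lt(thr, 8 / n)
})

test_that("LD block size inverts a constructed exponential decay", {
  # build synthetic pair data directly on the curve r2(d) = a exp(-d/l) + base
  a <- 0.5; l <- 10; base <- 0.05
  d <- rep(seq(0.5, 59.5, by = 1), each = 50)
  r2 <- a * exp(-d / l) + base
  ld <- data.frame(dist_cM = d, r2 = r2)
  thr <- 0.2
  analytic <- -l * log((thr - base) / a)   # 12.04 cM
  res <- ld_block_size(ld, thr, bin_width = 1, smooth_bins = 3)
  expect_equal(res$flag, "ok")
  expect_lt(abs(res$block_cM - analytic), 1)
  # threshold above the whole curve -> block 0, flagged
  res0 <- ld_block_size(ld, 0.9)
  expect_equal(res0$block_cM, 0)
  expect_equal(res0$flag, "below_threshold_everywhere")
  # threshold below the asymptote -> never crosses
  resN <- ld_block_size(ld, 0.01)
  expect_equal(resN$flag, "never_crosses")
})

test_that("mean HHe does not decrease as the founder count grows", {
  mean_hhe <- vapply(c(4L, 10L, 25L), function(nf) {
    mean(vapply(1:3, function(s) {
      don <- simulate_donor_pops(K = 2, F_target = 0.2, n_snps = 120,
                                 n_per_pop = 25, g = 5, n_founders = nf,
                                 seed = 300 + s)
      haplotype_diversity(don$genotypes, don$map, w = 15)$mean_hhe
    }, 0))
  }, 0)
  expect_true(all(diff(mean_hhe) >= 0))
})

test_that("block size grows when mosaics break less often", {
  blocks <- vapply(c(0.2, 0.01), function(rate) {
    don <- simulate_donor_pops(K = 2, F_target = 0.5, n_snps = 300,
                               n_chromosomes = 2, map_length_cM = 100,
                               n_per_pop = 10, g = 2, seed = 5)
    rec <- simulate_mosaic_recipients(don$genotypes, don$map, don$metadata,
                                      c(`1` = 0.5, `2` = 0.5),
                                      breakpoint_rate = rate,
                                      n_recipients = 60, epsilon = 0, seed = 6)
    intra <- pairwise_r2(rec$genotypes, don$map, "intra_chrom",
                         max_pairs = 3e4, seed = 1)
    inter <- pairwise_r2(rec$genotypes, don$map, "inter_chrom",
                         max_pairs = 3e4, seed = 1)
    thr <- background_threshold(inter$r2)
    res <- ld_block_size(intra, thr, bin_width = 2)
    res$block_cM
  }, 0)
  expect_gt(blocks[2], blocks[1])
})

test_that("the first-order Ne formula inverts exactly and flags infinities", {
  # the reported estimate is exactly the inversion of the reported rbar2
  # (so rbar2 = 1/30 + 1/S gives Ne = 10 by construction of the formula)
  gwf <- simulate_wright_fisher(30, 20, 400, 40, seed = 8)
  est0 <- ne_ld(gwf, maf_cutoff = 0.05)
  expect_equal(est0$ne, 1 / (3 * (est0$rbar2 - 1 / est0$S)), tolerance = 1e-12)
  set.seed(3)
  m <- matrix(rbinom(2000 * 30, 1, 0.5), 2000, 30)
  dimnames(m) <- list(sprintf("s%04d", 1:2000), sprintf("m%02d", 1:30))
  est <- ne_ld(genotype_matrix(m), maf_cutoff = 0.05)
  # with S = 2000 samples of truly independent loci, rbar2 ~ 1/S and the
  # drift signal is ~0: the estimate must be huge or flagged infinite
  expect_true(est$flag == "infinite" || est$ne > 2000)
})

test_that("map-aware Ne excludes tightly linked pairs", {
  don <- simulate_donor_pops(K = 2, F_target = 0.2, n_snps = 80,
                             n_chromosomes = 2, map_length_cM = 120,
                             n_per_pop = 20, g = 3, seed = 19)
  est <- ne_ld(don$genotypes, map = don$map, min_dist_cM = 50)
  expect_s3_class(est, "ne_estimate")
  expect_gt(est$n_pairs, 0)
  # waples mode runs and reports its method
  estw <- ne_ld(don$genotypes, method = "waples")
  expect_equal(estw$method, "waples")
})
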