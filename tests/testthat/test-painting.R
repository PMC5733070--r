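# shared small panel for HMM tests
toy_panel <- function(seed = 101, K = 2, n_snps = 120, n_per_pop = 8,
                      F_target = 0.4) {
  don <- simulate_donor_pops(K = K, F_target = F_target, n_snps = n_snps,
                             n_per_pop = n_per_pop, g = 4, seed = seed)
  list(don = don,
       model = copying_model(don$genotypes, don$metadata$subpop_id))
}

test_that("copying model validates its parameters", {
  p <- toy_panel()
  don <- p$don
  expect_error(copying_model(don$genotypes, rep(1L, nrow(don$genotypes))),
               ">= 2 subpopulations")
  expect_error(copying_model(don$genotypes, don$metadata$subpop_id,
                             rho = -1), "rho")
  expect_error(copying_model(don$genotypes, don$metadata$subpop_id,
                             f = c(`1` = 0.7, `2` = 0.7)), "sum to 1")
  # Watterson-style default miscopy rate is small and in range
  expect_gt(p$model$theta, 0)
  expect_lt(p$model$theta, 0.05)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(202)
  for (rep in 1:6) {
    H <- sample(2:4, 1); S <- sample(3:6, 1)
    don <- matrix(rbinom(H * S, 1, 0.5), H, S)
    rec <- rbinom(S, 1, 0.5)
    if (rep %% 2 == 0) rec[sample(S, 1)] <- NA       # missing recipient call
    pops <- sort(rep_len(1:2, H))
    f <- c(`1` = 0.65, `2` = 0.35)
    w <- unname(f[as.character(pops)] / tabulate(pops)[pops])
    stay <- exp(-0.1 * runif(S - 1, 0.5, 4))
    theta <- 0.03
    ref <- oracle_enum_posterior(don, rec, w, stay, theta)
    res <- haplopaint:::.ls_posterior(don, as.integer(rec), w, stay, theta)
    expect_lt(max(abs(res$gamma - ref$gamma)), 1e-10)
    expect_lt(abs(res$loglik - ref$loglik), 1e-10)
    # posterior rows are normalised
    expect_lt(max(abs(rowSums(res$gamma) - 1)), 1e-8)
  }
})

test_that("posterior concentrates on the true donor in the identity case", {
  # dense map so the unavoidable chromosome-end ambiguity (a competing
  # haplotype can be entered with a single switch near an edge) covers only
  # a small fraction of sites
  p <- toy_panel(seed = 303, n_snps = 400, n_per_pop = 10)
  don <- p$don
  model <- copying_model(don$genotypes, don$metadata$subpop_id,
                         rho = 0.1, theta = 0.001)
  hap <- 3L  # a pop-1 haplotype copied verbatim
  rec <- unclass(don$genotypes)[hap, ]
  fb <- forward_backward(rec, model, don$map)
  expect_lt(max(abs(rowSums(fb$posterior) - 1)), 1e-8)
  expect_gt(mean(fb$posterior[, "1"] >= 0.99), 0.95)
})

test_that("the rho -> 0 limit paints one donor genome-wide", {
  p <- toy_panel(seed = 404, n_snps = 60)
  don <- p$don
  model <- copying_model(don$genotypes, don$metadata$subpop_id,
                         rho = 1e-9, theta = 0.01)
  rec <- unclass(don$genotypes)[2L, ]
  fb <- forward_backward(rec, model, don$map)
  # posterior effectively constant across SNPs
  expect_lt(max(apply(fb$posterior, 2, function(x) diff(range(x)))), 1e-4)
})

test_that("EM increases the likelihood and recovers planted mixtures", {
  don <- simulate_donor_pops(K = 2, F_target = 0.3, n_snps = 300,
                             n_chromosomes = 2, map_length_cM = 150,
                             n_per_pop = 15, g = 8, seed = 55)
  rec <- simulate_mosaic_recipients(don$genotypes, don$map, don$metadata,
                                    c(`1` = 0.5, `2` = 0.5),
                                    breakpoint_rate = 0.03,
                                    n_recipients = 12, epsilon = 0.002,
                                    seed = 56)
  model <- copying_model(don$genotypes, don$metadata$subpop_id,
                         n_em_steps = 20)
  fit <- fit_em(model, rec$genotypes, don$map)
  expect_length(fit$loglik_trace, 20L)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  truth <- colMeans(rec$truth$proportions)
  expect_lt(max(abs(fit$f - truth[names(fit$f)])), 0.05)
  # recipients drawn 100% from pop 1
  rec1 <- simulate_mosaic_recipients(don$genotypes, don$map, don$metadata,
                                     c(`1` = 1.0), breakpoint_rate = 0.03,
                                     n_recipients = 6, epsilon = 0,
                                     seed = 57)
  fit1 <- fit_em(model, rec1$genotypes, don$map)
  expect_gte(fit1$f[["1"]], 0.95)
})

test_that("path sampling is deterministic, degenerate when forced, and
           consistent with the marginal posterior", {
  p <- toy_panel(seed = 606, n_snps = 80)
  don <- p$don
  model <- copying_model(don$genotypes, don$metadata$subpop_id, theta = 0.01)
  rec <- unclass(don$genotypes)[1L, ]
  c1 <- sample_paintings(rec, model, don$map, n_replicates = 50, seed = 3)
  c2 <- sample_paintings(rec, model, don$map, n_replicates = 50, seed = 3)
  expect_identical(c1$counts, c2$counts)
  expect_true(all(rowSums(c1$counts) == 50L))
  # near-deterministic fixture: recipient == a donor, tiny theta, others far
  m <- rbind(h1 = rep(0L, 30), h2 = rep(1L, 30),
             h3 = rep(1L, 30), h4 = rep(1L, 30))
  colnames(m) <- sprintf("m%03d", 1:30)
  map <- tiny_map(30)
  dm <- copying_model(genotype_matrix(m), c(1L, 2L, 2L, 2L), theta = 1e-4)
  cc <- sample_paintings(rep(0L, 30), dm, map, n_replicates = 40, seed = 1)
  expect_true(all(cc$counts[, "1"] == 40L))
  # empirical label frequencies approach the marginal posterior
  big <- sample_paintings(unclass(don$genotypes)[5L, ], model, don$map,
                          n_replicates = 1000, seed = 9)
  fb <- forward_backward(unclass(don$genotypes)[5L, ], model, don$map)
  tv <- max(abs(big$counts / 1000 - fb$posterior))
  expect_lt(tv, 0.05)
})

test_that("consensus takes the modal donor and flags ties to the smaller id", {
  counts <- structure(list(
    counts = matrix(c(60L, 40L, 50L, 50L), 2, 2, byrow = TRUE,
                    dimnames = list(c("m001", "m002"), c("8", "22"))),
    snp = data.frame(snp_id = c("m001", "m002"), chrom = "chr1",
                     cM = c(0, 1)),
    n_replicates = 100L), class = "painting_counts")
  cons <- consensus(counts)
  expect_equal(cons$modal_subpop, c(8L, 8L))
  expect_equal(cons$support, c(0.6, 0.5))
  expect_equal(cons$tie, c(FALSE, TRUE))
  counts$counts <- matrix(c(40L, 60L, 30L, 70L), 2, 2, byrow = TRUE,
                          dimnames = list(c("m001", "m002"), c("8", "22")))
  expect_equal(consensus(counts)$modal_subpop, c(22L, 22L))
})

test_that("ancestry summaries roll up by recipient and by group", {
  cons_a <- data.frame(snp_id = sprintf("m%02d", 1:10), chrom = "chr1",
                       cM = 1:10, modal_subpop = rep(22L, 10),
                       support = 1, tie = FALSE)
  cons_b <- cons_a
  cons_b$modal_subpop <- rep(c(8L, 22L), 5)
  meta <- sample_metadata(data.frame(
    sample_id = c("rA", "rB"), role = "recipient", year = c(1900, 1990),
    state = c("NSW", "WA")))
  summ <- summarize_ancestry(list(rA = cons_a, rB = cons_b), meta, "period")
  expect_equal(summ$recipient_proportions["rA", "22"], 1.0)
  expect_equal(summ$recipient_proportions["rB", "8"], 0.5)
  expect_equal(rownames(summ$group_proportions), c("1", "3"))
  # per-locus group profiles are distributions at every locus
  expect_true(all(abs(rowSums(summ$group_profiles[["1"]]) - 1) < 1e-12))
  # state grouping
  summ2 <- summarize_ancestry(list(rA = cons_a, rB = cons_b), meta, "state")
  expect_equal(rownames(summ2$group_proportions), c("NSW", "WA"))
})

test_that("cleaner painting with an empty exclusion equals standard painting", {
  don <- simulate_donor_pops(K = 3, F_target = 0.3, n_snps = 150,
                             n_per_pop = 10, g = 4, seed = 71)
  rec <- simulate_mosaic_recipients(don$genotypes, don$map, don$metadata,
                                    c(`1` = 0.6, `2` = 0.4),
                                    breakpoint_rate = 0.03,
                                    n_recipients = 4, epsilon = 0, seed = 72)
  a <- paint_panel(don$genotypes, don$metadata, rec$genotypes, don$map,
                   n_replicates = 20, n_em_steps = 5, seed = 5)
  b <- cleaner_painting(don$genotypes, don$metadata, rec$genotypes, don$map,
                        exclude = integer(0), n_replicates = 20,
                        n_em_steps = 5, seed = 5)
  expect_identical(lapply(a$consensus, `[[`, "modal_subpop"),
                   lapply(b$consensus, `[[`, "modal_subpop"))
  # excluding the true major donor reassigns its mass elsewhere
  cexcl <- cleaner_painting(don$genotypes, don$metadata, rec$genotypes,
                            don$map, exclude = 1L, n_replicates = 20,
                            n_em_steps = 5, seed = 5)
  expect_false("1" %in% colnames(cexcl$counts[[1]]$counts))
  expect_gt(cexcl$model$f[["2"]], 0.4)
  expect_error(paint_panel(don$genotypes, don$metadata, rec$genotypes,
                           don$map, exclude = c(1L, 2L)),
               "fewer than 2")
})

test_that("deviant-region detection applies the run-length rule", {
  # profile over one chromosome: focal pop 22 everywhere except two dips
  S <- 30
  prof <- cbind(`8` = rep(0, S), `22` = rep(1, S))
  snp <- data.frame(snp_id = sprintf("m%02d", 1:S), chrom = "chr1",
                    cM = seq(0, 29))
  expect_equal(nrow(detect_deviant_regions(prof, snp, 22)), 0L)
  # dips of length 2 (ignored) and 5 (reported) under min_snps = 3
  prof[3:4, ] <- rep(c(1, 0), each = 2)
  prof[10:14, ] <- rep(c(1, 0), each = 5)
  regions <- detect_deviant_regions(prof, snp, 22, min_snps = 3)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$start_cM, 9)
  expect_equal(regions$end_cM, 13)
  expect_equal(regions$n_snps, 5L)
  expect_equal(regions$dominant_subpops, "8")
  expect_error(detect_deviant_regions(prof, snp, 99), "absent")
})

test_that("painting accuracy rises with donor differentiation", {
  accs <- vapply(c(0.05, 0.3), function(Ft) {
    mean(vapply(1:3, function(s) {
      don <- simulate_donor_pops(K = 2, F_target = Ft, n_snps = 250,
                                 map_length_cM = 150, n_per_pop = 12,
                                 g = 6, seed = 900 + s)
      rec <- simulate_mosaic_recipients(don$genotypes, don$map,
                                        don$metadata,
                                        c(`1` = 0.5, `2` = 0.5),
                                        breakpoint_rate = 0.02,
                                        n_recipients = 6, epsilon = 0.002,
                                        seed = 950 + s)
      painted <- paint_panel(don$genotypes, don$metadata, rec$genotypes,
                             don$map, n_replicates = 30, n_em_steps = 5,
                             seed = s)
      consensus_accuracy(painted$consensus, rec$truth)
    }, 0))
  }, 0)
  expect_gte(accs[2], accs[1])
})
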