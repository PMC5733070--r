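# Independent brute-force oracles.  These deliberately take the slow, direct
# route (path enumeration, per-sample loops, dictionary counting) so they
# share no code path with the package implementations they check.

# exhaustive-path posterior of the copying HMM (H^S paths; keep H, S tiny)
oracle_enum_posterior <- function(don, rec, w, stay, theta) {
  H <- nrow(don); S <- ncol(don)
  emit <- function(dn, rc) {
    if (is.na(rc)) return(1)
    if (is.na(dn)) return(0.5)
    if (dn == rc) 1 - theta else theta
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), S)))
  pp <- apply(paths, 1L, function(z) {
    p <- w[z[1L]] * emit(don[z[1L], 1L], rec[1L])
    for (s in 2:S) {
      tr <- (1 - stay[s - 1L]) * w[z[s]] +
        if (z[s] == z[s - 1L]) stay[s - 1L] else 0
      p <- p * tr * emit(don[z[s], s], rec[s])
    }
    p
  })
  gamma <- sapply(seq_len(H), function(j)
    sapply(seq_len(S), function(s) sum(pp[paths[, s] == j]) / sum(pp)))
  list(gamma = gamma, loglik = log(sum(pp)))
}

# Weir-Cockerham Fst for haploid copies via per-sample ANOVA loops
oracle_fst <- function(m, labels) {
  labels <- as.character(labels)
  pops <- unique(labels)
  num <- den <- 0
  for (l in seq_len(ncol(m))) {
    x <- m[, l]
    ok <- !is.na(x)
    lab <- labels[ok]; x <- x[ok]
    use <- unique(lab)
    if (length(use) < 2L) next
    N <- length(x)
    grand <- mean(x)
    if (grand <= 0 || grand >= 1) next
    ssa <- ssw <- 0
    sizes <- numeric(0)
    for (p in use) {
      xp <- x[lab == p]
      sizes <- c(sizes, length(xp))
      ssa <- ssa + length(xp) * (mean(xp) - grand)^2
      ssw <- ssw + sum((xp - mean(xp))^2)
    }
    r <- length(use)
    msa <- ssa / (r - 1)
    msw <- ssw / (N - r)
    nc <- (N - sum(sizes^2) / N) / (r - 1)
    a <- (msa - msw) / nc
    num <- num + a
    den <- den + a + msw
  }
  num / den
}

# within/among haplotype diversity by dictionary counting of window strings
oracle_window_hhe <- function(m) {
  strs <- apply(m, 1L, paste0, collapse = "")
  counts <- table(strs)
  p <- as.numeric(counts) / sum(counts)
  list(hhe = 1 - sum(p^2), hae = 1 / sum(p^2), p = sort(p, decreasing = TRUE))
}

# r^2 from the 2x2 haplotype table, D^2 / (pA pa pB pb)
oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x); pB <- mean(y)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Nei (1972) distance straight from two allele-frequency vectors
oracle_nei <- function(px, py) {
  jx <- mean(px^2 + (1 - px)^2)
  jy <- mean(py^2 + (1 - py)^2)
  jxy <- mean(px * py + (1 - px) * (1 - py))
  -log(jxy / sqrt(jx * jy))
}

# one-level AMOVA via explicit pair loops on squared allele distances
oracle_amova_one <- function(m, labels) {
  labels <- as.character(labels)
  N <- nrow(m)
  d2 <- matrix(0, N, N)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N)
    d2[i, j] <- d2[j, i] <- sum((m[i, ] - m[j, ])^2)
  ss_t <- 0
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) ss_t <- ss_t + d2[i, j]
  ss_t <- ss_t / N
  pops <- unique(labels)
  ss_w <- 0
  sizes <- numeric(0)
  for (p in pops) {
    ix <- which(labels == p)
    sizes <- c(sizes, length(ix))
    if (length(ix) > 1L)
      for (a in seq_len(length(ix) - 1L)) for (b in (a + 1L):length(ix))
        ss_w <- ss_w + d2[ix[a], ix[b]] / length(ix)
  }
  G <- length(pops)
  ss_a <- ss_t - ss_w
  ms_a <- ss_a / (G - 1); ms_w <- ss_w / (N - G)
  n0 <- (N - sum(sizes^2) / N) / (G - 1)
  v_w <- ms_w
  v_a <- (ms_a - ms_w) / n0
  c(among = v_a, within = v_w, pct_among = 100 * v_a / (v_a + v_w))
}
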