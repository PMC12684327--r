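# Shared fixtures and independent oracles. Oracles deliberately re-derive
# quantities from first principles (counting, enumeration, quadrature), not
# by calling the implementation under test.

make_gm <- function(dosages, sites = NULL, pos = NULL, chrom = "chr1", ...) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); L <- ncol(dosages)
  if (is.null(sites)) sites <- rep("siteA", n)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  variants <- data.frame(chrom = chrom, pos = as.integer(pos),
                         id = sprintf("s%04d", seq_len(L)), ref = "A", alt = "T",
                         QUAL = 100, ...)
  samples <- data.frame(sample_id = sprintf("i%03d", seq_len(n)),
                        site = sites, group = sites)
  geno_matrix(dosages, variants, samples)
}

random_gm <- function(n = 6, L = 50, n_sites = 2, miss = 0, seed = 1) {
  withr::with_seed(seed, {
    p <- runif(L, 0.1, 0.9)
    d <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
    if (miss > 0) d[runif(n * L) < miss] <- NA
    make_gm(d, sites = rep(paste0("site", seq_len(n_sites)), length.out = n))
  })
}

# brute-force per-group/per-locus H_O and unbiased H_E by explicit counting
oracle_het <- function(d) {
  x <- d[!is.na(d)]
  n <- length(x)
  if (n == 0) return(c(ho = NA, he = NA))
  p <- sum(x) / (2 * n)
  c(ho = mean(x == 1), he = if (n >= 2) 2 * p * (1 - p) * 2 * n / (2 * n - 1) else NA)
}

# Weir-Cockerham (1984) components, independent transliteration working on a
# list of per-population genotype vectors for a single locus
oracle_wc_locus <- function(pop_genos) {
  pops <- pop_genos[vapply(pop_genos, function(g) sum(!is.na(g)) > 0, TRUE)]
  r <- length(pops)
  if (r < 2) return(c(a = NA, b = NA, c = NA))
  n_i <- vapply(pops, function(g) sum(!is.na(g)), numeric(1))
  p_i <- vapply(pops, function(g) sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))), numeric(1))
  h_i <- vapply(pops, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  nbar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  pbar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / sum(n_i)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

oracle_wc_theta <- function(gm, grouping = gm$samples$site) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  comps <- sapply(seq_len(ncol(gm$dosages)), function(l) {
    oracle_wc_locus(lapply(groups, function(g) gm$dosages[grouping == g, l]))
  })
  valid <- apply(comps, 2, function(x) all(is.finite(x))) &
    colSums(comps) != 0
  # exclude monomorphic loci (all components zero / zero denominator)
  pbar <- colMeans(gm$dosages, na.rm = TRUE) / 2
  valid <- valid & pbar > 0 & pbar < 1
  sum(comps["a", valid]) / sum(colSums(comps[, valid, drop = FALSE]))
}

# definition-based BH: q_(i) = min_{k >= i} p_(k) * m / k
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- ok[order(p[ok])]
  ps <- p[ord]
  qs <- vapply(seq_len(m), function(i) min(ps[i:m] * m / (i:m)), numeric(1))
  out[ord] <- pmin(qs, 1)
  out
}

# Tajima's D, independent transliteration from the defining formulas
oracle_tajima <- function(d) {
  n <- 2 * nrow(d)
  p <- colSums(d) / n
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  pi_sum <- sum(n / (n - 1) * 2 * p[seg] * (1 - p[seg]))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# draw genotypes whose allele counts follow the neutral (1/k) site frequency
# spectrum: the regime in which E[Tajima's D] is near zero
neutral_sfs_gm <- function(n_ind, L, seed) {
  withr::with_seed(seed, {
    n <- 2 * n_ind
    k <- sample(seq_len(n - 1), L, replace = TRUE, prob = 1 / seq_len(n - 1))
    d <- vapply(k, function(kk) {
      al <- sample(c(rep(1L, kk), rep(0L, n - kk)))
      al[seq(1, n, 2)] + al[seq(2, n, 2)]
    }, integer(n_ind))  # individuals x loci
    make_gm(d)
  })
}

# exact Hardy-Weinberg permutation distribution of the heterozygote count
# (Levene): P(h het | n genotypes, k alt copies)
oracle_hwe_exact_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  k <- n1 + 2 * n2
  hs <- seq(k %% 2, min(k, 2 * n - k), by = 2)
  # unnormalised log weight per heterozygote count; constants cancel in the
  # explicit normalisation below
  logp <- vapply(hs, function(h) {
    na <- (k - h) / 2; nb <- n - na - h
    h * log(2) - lfactorial(na) - lfactorial(h) - lfactorial(nb)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  stat <- vapply(hs, function(h) {
    na <- (k - h) / 2; nb <- n - na - h
    p <- k / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- c(nb, h, na)
    sum((o[e > 0] - e[e > 0])^2 / e[e > 0])
  }, numeric(1))
  p_obs <- k / (2 * n)
  e <- n * c((1 - p_obs)^2, 2 * p_obs * (1 - p_obs), p_obs^2)
  o <- c(n0, n1, n2)
  s_obs <- sum((o[e > 0] - e[e > 0])^2 / e[e > 0])
  sum(pr[stat >= s_obs - 1e-12])
}

# numeric-quadrature marginal likelihood for the g-prior slope model:
# y ~ N(x b, s2 I), b ~ N(0, g s2 / (x'x)), p(s2) ~ 1/s2.
# Integrands are rescaled by a common log constant so both marginals are
# O(1); the constant cancels in the Bayes factor.
oracle_gprior_bf <- function(y, x, g) {
  n <- length(y)
  ls0 <- log(mean(y^2))
  logc <- sum(dnorm(y, 0, sqrt(exp(ls0)), log = TRUE))
  marg <- function(with_slope) {
    f <- function(ls) {
      s2 <- exp(ls)
      if (with_slope) {
        v <- g * s2 / sum(x^2)
        half <- 12 * sqrt(v)
        integrate(function(b) {
          vapply(b, function(bb)
            exp(sum(dnorm(y, bb * x, sqrt(s2), log = TRUE)) +
                dnorm(bb, 0, sqrt(v), log = TRUE) - logc), numeric(1))
        }, -half, half, rel.tol = 1e-9)$value
        # the (1/s2) prior cancels the ds2 = s2 dls Jacobian
      } else {
        exp(sum(dnorm(y, 0, sqrt(s2), log = TRUE)) - logc)
      }
    }
    integrate(Vectorize(f), ls0 - 12, ls0 + 8, rel.tol = 1e-8,
              subdivisions = 400L)$value
  }
  marg(TRUE) / marg(FALSE)
}
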