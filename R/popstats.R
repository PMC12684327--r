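# Diversity, differentiation, Hardy-Weinberg, Tajima's D and kinship.
#
# Estimator conventions: H_E is the unbiased Nei estimator 2p(1-p)*2n/(2n-1);
# multilocus F_IS is ratio-of-sums 1 - sum(H_O)/sum(H_E); multilocus
# Weir-Cockerham theta is ratio-of-sums of the 1984 variance components;
# negative theta estimates are reported, not truncated.

# Per-group, per-locus called counts, alternate frequencies and het fractions.
group_locus_stats <- function(gm, grouping) {
  grouping <- as.character(grouping)
  stop_if_not(length(grouping) == nrow(gm$dosages), "grouping length mismatch")
  groups <- unique(grouping)
  L <- ncol(gm$dosages)
  n <- p <- h <- matrix(0, length(groups), L, dimnames = list(groups, colnames(gm$dosages)))
  for (k in seq_along(groups)) {
    d <- gm$dosages[grouping == groups[k], , drop = FALSE]
    called <- colSums(!is.na(d))
    n[k, ] <- called
    p[k, ] <- ifelse(called > 0, colSums(d, na.rm = TRUE) / (2 * called), NA_real_)
    h[k, ] <- ifelse(called > 0, colSums(d == 1L, na.rm = TRUE) / called, NA_real_)
  }
  list(groups = groups, n = n, p = p, h = h)
}

nei_he <- function(p, n) ifelse(n >= 2, 2 * p * (1 - p) * (2 * n) / (2 * n - 1), NA_real_)

#' Observed and expected heterozygosity per group
#'
#' H_O is the fraction of heterozygotes among called genotypes; H_E is the
#' unbiased estimator 2p(1-p) * 2n/(2n-1). Multilocus values are means over
#' loci callable in the group (H_E additionally needs >= 2 called
#' individuals at the locus).
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual (default: site).
#' @return list(groups, per_locus = list(H_O, H_E), multilocus data.frame).
#' @export
heterozygosities <- function(gm, grouping = gm$samples$site) {
  st <- group_locus_stats(gm, grouping)
  HO <- st$h
  HE <- nei_he(st$p, st$n)
  multi <- data.frame(group = st$groups,
                      n = as.integer(table(factor(as.character(grouping), levels = st$groups))),
                      H_O = rowMeans(HO, na.rm = TRUE),
                      H_E = rowMeans(HE, na.rm = TRUE))
  list(groups = st$groups, per_locus = list(H_O = HO, H_E = HE), multilocus = multi)
}

#' Multilocus inbreeding coefficient with permutation p-value
#'
#' F_IS = 1 - sum(H_O)/sum(H_E) over loci where H_E is defined (ratio of
#' sums). The p-value permutes alleles within each group among its
#' individuals (H_E is invariant under this permutation, so only H_O is
#' recomputed) and reports the one-sided probability of an F_IS at least as
#' large (heterozygote deficit).
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @param n_perm permutations (0 skips the test).
#' @param seed RNG seed.
#' @return data.frame(group, F_IS, p).
#' @export
fis <- function(gm, grouping = gm$samples$site, n_perm = 0, seed = 1L) {
  st <- group_locus_stats(gm, grouping)
  grouping <- as.character(grouping)
  HE <- nei_he(st$p, st$n)
  out <- data.frame(group = st$groups, F_IS = NA_real_, p = NA_real_)
  for (k in seq_along(st$groups)) {
    ok <- !is.na(HE[k, ])
    sum_he <- sum(HE[k, ok])
    if (!(sum_he > 0)) next
    sum_ho <- sum(st$h[k, ok])
    f_obs <- 1 - sum_ho / sum_he
    out$F_IS[k] <- f_obs
    if (n_perm > 0) {
      d <- gm$dosages[grouping == st$groups[k], ok, drop = FALSE]
      out$p[k] <- with_seed(seed + k, {
        f_perm <- vapply(seq_len(n_perm), function(b) {
          ho_b <- vapply(seq_len(ncol(d)), function(l) {
            x <- d[!is.na(d[, l]), l]
            al <- c(rep(0L, 2L * length(x) - sum(x)), rep(1L, sum(x)))
            s <- sample(al)
            i <- seq(1L, length(s), by = 2L)
            mean(s[i] != s[i + 1L])
          }, numeric(1))
          he_b <- HE[k, ok]  # invariant under allele permutation
          1 - sum(ho_b) / sum(he_b)
        }, numeric(1))
        (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
      })
    }
  }
  out
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random draw of `g` gene copies:
#' per locus A_R = sum over alleles of 1 - C(N - N_a, g)/C(N, g), where N is
#' the called gene-copy count and N_a the copy count of allele a. Loci where
#' any group has fewer than `g` called copies are excluded for all groups
#' (symmetric exclusion); the group value is the mean over included loci.
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @param g rarefaction size in gene copies (default 12).
#' @return list(per_group named vector, per_locus matrix, loci_included).
#' @export
allelic_richness <- function(gm, grouping = gm$samples$site, g = 12L) {
  stop_if_not(g >= 2, "g must be >= 2")
  st <- group_locus_stats(gm, grouping)
  N <- 2 * st$n
  include <- apply(N, 2L, min) >= g
  stop_if_not(any(include), "no locus has >= g called gene copies in every group")
  N_alt <- round(st$p * N)
  N_ref <- N - N_alt
  miss_prob <- function(Na) exp(lchoose(N - Na, g) - lchoose(N, g))
  AR <- (1 - miss_prob(N_ref)) + (1 - miss_prob(N_alt))
  AR[, !include] <- NA_real_
  per_group <- rowMeans(AR[, include, drop = FALSE])
  list(per_group = per_group, per_locus = AR, loci_included = which(include))
}

#' Nucleotide diversity per accessible site
#'
#' pi = sum over SNPs of the unbiased per-locus heterozygosity
#' 2p(1-p) * 2n/(2n-1), divided by the accessible sequence length `L`
#' (invariant sites contribute zero, so `L` sets the per-site scale).
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @param accessible_sites_L accessible sequence length; must be at least the
#'   number of SNPs.
#' @return named vector of per-group pi.
#' @export
nucleotide_diversity <- function(gm, grouping = gm$samples$site, accessible_sites_L) {
  stop_if_not(accessible_sites_L > 0, "accessible_sites_L must be positive")
  stop_if_not(accessible_sites_L >= ncol(gm$dosages),
              "accessible_sites_L is smaller than the number of SNPs")
  st <- group_locus_stats(gm, grouping)
  HE <- nei_he(st$p, st$n)
  rowSums(HE, na.rm = TRUE) / accessible_sites_L
}

#' Tajima's D per group with normal-approximation p-value
#'
#' Computed from unphased diploid genotypes treating the 2n gene copies of a
#' group as the sample; loci with missing calls in the group are dropped.
#' D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1)) with the standard constants
#' a1, a2, b1, b2, c1, c2, e1, e2 from the gene-copy count. Groups with fewer
#' than 4 gene copies, or no segregating site, are flagged undefined.
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @return data.frame(group, n_copies, S, pi_sum, D, p, note).
#' @export
tajimas_d <- function(gm, grouping = gm$samples$site) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  out <- data.frame(group = groups, n_copies = NA_integer_, S = NA_integer_,
                    pi_sum = NA_real_, D = NA_real_, p = NA_real_, note = "")
  for (k in seq_along(groups)) {
    d <- gm$dosages[grouping == groups[k], , drop = FALSE]
    complete <- colSums(is.na(d)) == 0
    d <- d[, complete, drop = FALSE]
    n <- 2L * nrow(d)
    out$n_copies[k] <- n
    if (n < 4) { out$note[k] <- "sample size too small"; next }
    p <- colSums(d) / n
    seg <- p > 0 & p < 1
    S <- sum(seg)
    out$S[k] <- S
    if (S == 0) { out$note[k] <- "no segregating sites"; next }
    pi_sum <- sum((n / (n - 1)) * 2 * p[seg] * (1 - p[seg]))
    out$pi_sum[k] <- pi_sum
    cst <- tajima_constants(n)
    denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
    D <- (pi_sum - S / cst$a1) / denom
    out$D[k] <- D
    out$p[k] <- 2 * pnorm(-abs(D))
  }
  out
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Weir-Cockerham (1984) variance components per locus.
# n, p, h: populations x loci matrices of called individuals, alternate-allele
# frequency and observed het fraction. Returns per-locus a, b, c and validity.
wc_components <- function(n, p, h) {
  p0 <- ifelse(n > 0, p, 0); h0 <- ifelse(n > 0, h, 0)
  r <- colSums(n > 0)
  sum_n <- colSums(n)
  nbar <- sum_n / pmax(r, 1)
  sum_n2 <- colSums(n^2)
  nc <- ifelse(r > 1, (sum_n - sum_n2 / sum_n) / (r - 1), NA_real_)
  pbar <- colSums(n * p0) / sum_n
  s2 <- colSums(n * (p0 - rep(pbar, each = nrow(n)))^2) / ((pmax(r, 2) - 1) * nbar)
  hbar <- colSums(n * h0) / sum_n
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  valid <- r >= 2 & nbar > 1 & nc > 0 & pbar > 0 & pbar < 1
  list(a = a, b = b, c = cc, valid = valid)
}

#' Weir-Cockerham F_ST: multilocus theta, pairwise matrix, per-locus values
#'
#' Multilocus theta is ratio-of-sums sum(a)/sum(a+b+c) over loci polymorphic
#' in the compared set; monomorphic loci are excluded. Negative estimates are
#' kept (flagged in the pairwise matrix attribute), not truncated.
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @return list(theta = multilocus theta over all groups, pairwise = symmetric
#'   matrix of pairwise theta (diagonal 0), site_vs_rest = mean pairwise theta
#'   per group, per_locus = per-locus theta across all groups, components).
#' @export
wc_fst <- function(gm, grouping = gm$samples$site) {
  st <- group_locus_stats(gm, grouping)
  stop_if_not(length(st$groups) >= 2, "need at least two groups")
  comp <- wc_components(st$n, st$p, st$h)
  v <- comp$valid
  theta <- sum(comp$a[v]) / sum((comp$a + comp$b + comp$c)[v])
  per_locus <- ifelse(comp$valid, comp$a / (comp$a + comp$b + comp$c), NA_real_)

  gnames <- st$groups
  pw <- matrix(0, length(gnames), length(gnames), dimnames = list(gnames, gnames))
  for (i in seq_along(gnames)) for (j in seq_along(gnames)) {
    if (j <= i) next
    idx <- c(i, j)
    cij <- wc_components(st$n[idx, , drop = FALSE], st$p[idx, , drop = FALSE],
                         st$h[idx, , drop = FALSE])
    vv <- cij$valid
    pw[i, j] <- pw[j, i] <- sum(cij$a[vv]) / sum((cij$a + cij$b + cij$c)[vv])
  }
  svr <- rowSums(pw) / (ncol(pw) - 1)
  attr(pw, "negative_estimates") <- any(pw < 0)
  list(theta = theta, pairwise = pw, site_vs_rest = svr,
       per_locus = per_locus, components = comp)
}

#' Hardy-Weinberg equilibrium test per locus and group
#'
#' Chi-square statistic of observed genotype counts against Hardy-Weinberg
#' expectations, with the p-value obtained by Monte-Carlo permutation of the
#' group's alleles into genotypes (B = `n_perm`). Monomorphic loci get p = 1.
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @param n_perm Monte-Carlo permutations.
#' @param seed RNG seed.
#' @return list(p = groups x loci matrix, stat = chi-square statistics).
#' @export
hwe_test <- function(gm, grouping = gm$samples$site, n_perm = 1000L, seed = 1L) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  L <- ncol(gm$dosages)
  pmat <- stat <- matrix(NA_real_, length(groups), L,
                         dimnames = list(groups, colnames(gm$dosages)))
  hw_stat <- function(n0, n1, n2) {
    n <- n0 + n1 + n2
    p <- (2 * n2 + n1) / (2 * n)
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- c(n0, n1, n2)
    sum((o[e > 0] - e[e > 0])^2 / e[e > 0])
  }
  with_seed(seed, {
    for (k in seq_along(groups)) {
      d <- gm$dosages[grouping == groups[k], , drop = FALSE]
      for (l in seq_len(L)) {
        x <- d[!is.na(d[, l]), l]
        if (length(x) < 2) next
        n0 <- sum(x == 0L); n1 <- sum(x == 1L); n2 <- sum(x == 2L)
        alt <- 2L * n2 + n1
        if (alt == 0 || alt == 2 * length(x)) { pmat[k, l] <- 1; stat[k, l] <- 0; next }
        s_obs <- hw_stat(n0, n1, n2)
        stat[k, l] <- s_obs
        al <- c(rep(0L, 2L * length(x) - alt), rep(1L, alt))
        odd <- seq(1L, length(al), by = 2L)
        s_perm <- vapply(seq_len(n_perm), function(b) {
          s <- sample(al)
          h <- sum(s[odd] != s[odd + 1L])
          hom_alt <- (alt - h) / 2
          hw_stat(length(x) - h - hom_alt, h, hom_alt)
        }, numeric(1))
        pmat[k, l] <- (1 + sum(s_perm >= s_obs - 1e-12)) / (n_perm + 1)
      }
    }
    list(p = pmat, stat = stat)
  })
}

#' KING-robust pairwise kinship
#'
#' Between-family estimator from heterozygote and opposite-homozygote counts
#' over pairwise-complete loci:
#' phi = (N_het_het - 2 * N_IBS0) / (N_het_i + N_het_j).
#' Pairs sharing fewer than `min_loci` called loci are flagged low-confidence.
#' Classification bands follow the standard powers-of-two cutoffs
#' (>0.354 duplicate/MZ, (0.177, 0.354] first degree, (0.0884, 0.177] second
#' degree, otherwise unrelated).
#'
#' @param gm a `geno_matrix`.
#' @param min_loci minimum shared called loci for a confident estimate.
#' @return list(phi, n_shared, class, low_confidence) of symmetric matrices.
#' @export
king_kinship <- function(gm, min_loci = 100L) {
  d <- gm$dosages
  n <- nrow(d)
  stop_if_not(n >= 2, "need at least two individuals")
  het <- d == 1L
  ids <- gm$samples$sample_id
  phi <- nsh <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- !is.na(d[i, ]) & !is.na(d[j, ])
    hi <- sum(het[i, ] & shared); hj <- sum(het[j, ] & shared)
    hh <- sum(het[i, ] & het[j, ] & shared)
    ibs0 <- sum(shared & ((d[i, ] == 0L & d[j, ] == 2L) | (d[i, ] == 2L & d[j, ] == 0L)))
    phi[i, j] <- phi[j, i] <- if (hi + hj > 0) (hh - 2 * ibs0) / (hi + hj) else NA_real_
    nsh[i, j] <- nsh[j, i] <- sum(shared)
  }
  cls <- matrix(NA_character_, n, n, dimnames = list(ids, ids))
  cls[phi > 2^-1.5] <- "duplicate/MZ"
  cls[phi <= 2^-1.5 & phi > 2^-2.5] <- "1st-degree"
  cls[phi <= 2^-2.5 & phi > 2^-3.5] <- "2nd-degree"
  cls[phi <= 2^-3.5] <- "unrelated"
  list(phi = phi, n_shared = nsh, class = cls, low_confidence = nsh < min_loci)
}

#' Diversity summary table per group
#'
#' Convenience wrapper assembling N, rarefied allelic richness, H_O, H_E,
#' F_IS (with optional permutation p), Tajima's D and per-site nucleotide
#' diversity into one table per group.
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @param g rarefaction size in gene copies.
#' @param accessible_sites_L accessible length for the pi denominator.
#' @param n_perm permutations for the F_IS test (0 = none).
#' @param seed RNG seed.
#' @return data.frame, one row per group.
#' @export
diversity_summary <- function(gm, grouping = gm$samples$site, g = 12L,
                              accessible_sites_L = ncol(gm$dosages),
                              n_perm = 0, seed = 1L) {
  het <- heterozygosities(gm, grouping)
  ar <- tryCatch(allelic_richness(gm, grouping, g = g),
                 error = function(e) list(per_group = setNames(rep(NA_real_, length(het$groups)),
                                                               het$groups)))
  fis_tab <- fis(gm, grouping, n_perm = n_perm, seed = seed)
  td <- tajimas_d(gm, grouping)
  pi <- nucleotide_diversity(gm, grouping, accessible_sites_L)
  data.frame(group = het$multilocus$group, N = het$multilocus$n,
             A_R = as.numeric(ar$per_group[het$multilocus$group]),
             H_O = het$multilocus$H_O, H_E = het$multilocus$H_E,
             F_IS = fis_tab$F_IS[match(het$multilocus$group, fis_tab$group)],
             F_IS_p = fis_tab$p[match(het$multilocus$group, fis_tab$group)],
             Tajima_D = td$D[match(het$multilocus$group, td$group)],
             Tajima_D_p = td$p[match(het$multilocus$group, td$group)],
             pi = as.numeric(pi[het$multilocus$group]))
}
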