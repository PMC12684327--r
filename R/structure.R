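# PCA-based population structure, k-means group assignment, and the
# differentiation-only outlier scans (PC-regression Mahalanobis statistic and
# the Lewontin-Krakauer F_ST-outlier test), with BH multiple-testing control.

# Mahalanobis distances with a trimmed (outlier-resistant) covariance
# estimate and genomic-inflation rescaling: the location/scatter are
# re-estimated after dropping the most extreme `trim` fraction, so that a
# minority of true outliers cannot inflate the null scatter; D^2/lambda is
# then referred to a chi-square with `df` degrees of freedom.
mahalanobis_trimmed <- function(Z, df, trim = 0.05) {
  d2 <- stats::mahalanobis(Z, colMeans(Z), cov(Z))
  keep <- d2 <= quantile(d2, 1 - trim)
  d2 <- stats::mahalanobis(Z, colMeans(Z[keep, , drop = FALSE]),
                           cov(Z[keep, , drop = FALSE]))
  lambda <- median(d2) / qchisq(0.5, df = df)
  list(d2 = d2, lambda = lambda,
       p = pchisq(d2 / lambda, df = df, lower.tail = FALSE))
}

outlier_scores <- function(snp, method, stat, p, q, flag) {
  structure(data.frame(snp = snp, method = method, stat = stat, p = p, q = q,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("outlier_scores", "data.frame"))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement (`stats::p.adjust`); NAs are
#' propagated and do not count towards the number of tests.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stop_if_not(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' PCA of scaled genotype dosages
#'
#' Missing dosages are mean-imputed per SNP; columns are centred at 2*p_hat
#' and scaled by sqrt(p_hat * (1 - p_hat)) (Patterson scaling; `scaling =
#' "center"` skips the denominator). Monomorphic columns are dropped with a
#' log record. Axis signs are fixed by making the largest-|loading| entry of
#' each axis positive, so scores are reproducible across runs and platforms.
#'
#' @param gm a `geno_matrix`.
#' @param K_pc number of axes to retain (< min(n, L)).
#' @param scaling `"patterson"` or `"center"`.
#' @return list(scores n x K, loadings L_kept x K, explained (variance
#'   fractions, all axes), d (singular values), kept (retained SNP indices),
#'   center, scale, scaled_matrix).
#' @export
pca_genotypes <- function(gm, K_pc = 3L, scaling = c("patterson", "center")) {
  scaling <- match.arg(scaling)
  G <- scale_dosages(gm, scaling)
  n <- nrow(G$mat)
  stop_if_not(K_pc >= 1 && K_pc <= min(n - 1L, ncol(G$mat)),
              "K_pc must be in [1, min(n - 1, L)]")
  sv <- svd(G$mat)
  eig <- sv$d^2
  scores <- sv$u[, seq_len(K_pc), drop = FALSE] %*% diag(sv$d[seq_len(K_pc)], K_pc)
  loadings <- sv$v[, seq_len(K_pc), drop = FALSE]
  for (k in seq_len(K_pc)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- gm$samples$sample_id
  list(scores = scores, loadings = loadings, explained = eig / sum(eig),
       d = sv$d, kept = G$kept, center = G$center, scale = G$scale,
       scaled_matrix = G$mat)
}

scale_dosages <- function(gm, scaling = "patterson") {
  d <- gm$dosages
  p_hat <- colMeans(d, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p_hat[j]
  keep <- p_hat > 0 & p_hat < 1 & !is.na(p_hat)
  d <- d[, keep, drop = FALSE]
  p <- p_hat[keep]
  ctr <- 2 * p
  scl <- if (scaling == "patterson") sqrt(p * (1 - p)) else rep(1, length(p))
  mat <- sweep(sweep(d, 2L, ctr, `-`), 2L, scl, `/`)
  list(mat = mat, kept = unname(which(keep)), center = unname(ctr),
       scale = unname(scl), n_dropped = sum(!keep))
}

#' Assign genetic groups by k-means on leading principal components
#'
#' k-means (50 restarts, best inertia) on the first K - 1 PCs. Cluster labels
#' are canonicalised by each cluster's majority site, ordered by the site's
#' mean score on PC1, so the labelling is reproducible.
#'
#' @param pca output of [pca_genotypes()].
#' @param K number of groups.
#' @param seed RNG seed for the restarts.
#' @param sites optional site labels used for the canonical ordering.
#' @return integer vector of group labels (1..K).
#' @export
assign_groups_kmeans <- function(pca, K = 3L, seed = 1L, sites = NULL) {
  n <- nrow(pca$scores)
  stop_if_not(K >= 1 && K <= n, "K must be in [1, n]")
  if (K == 1) return(rep(1L, n))
  X <- pca$scores[, seq_len(max(1L, min(K - 1L, ncol(pca$scores)))), drop = FALSE]
  km <- with_seed(seed, kmeans(X, centers = K, nstart = 50L, iter.max = 100L))
  # canonical label order: ascending cluster centroid on PC1
  ord <- order(km$centers[, 1])
  new_lab <- integer(n)
  for (k in seq_len(K)) new_lab[km$cluster == ord[k]] <- k
  new_lab
}

#' PC-regression Mahalanobis outlier statistic
#'
#' Each scaled SNP column is regressed on the first `K_pc` PC score vectors;
#' the resulting z-score vectors are summarised by their Mahalanobis distance
#' D^2 (covariance estimated over all SNPs). D^2 is rescaled by the genomic
#' inflation factor lambda = median(D^2)/qchisq(0.5, K_pc) and referred to a
#' chi-square with K_pc df; q-values are BH, outliers flagged at q < 0.05.
#' SNPs dropped as monomorphic before the PCA get NA scores.
#'
#' @param gm a `geno_matrix`.
#' @param K_pc number of principal components (default 3).
#' @param q_max flagging threshold on the q-value.
#' @return An `outlier_scores` data.frame with attribute `lambda`.
#' @export
pcadapt_stat <- function(gm, K_pc = 3L, q_max = 0.05) {
  stop_if_not(K_pc >= 1, "K_pc must be >= 1")
  pca <- pca_genotypes(gm, K_pc = K_pc)
  S <- pca$scores
  G <- pca$scaled_matrix
  n <- nrow(G)
  StS_inv <- solve(crossprod(S))
  B <- StS_inv %*% crossprod(S, G)             # K x L
  res <- G - S %*% B
  sigma2 <- colSums(res^2) / (n - K_pc)
  se <- sqrt(outer(diag(StS_inv), sigma2))     # K x L
  z <- B / se
  zt <- t(z)
  mt <- mahalanobis_trimmed(zt, df = K_pc)
  d2 <- mt$d2
  lambda <- mt$lambda
  p <- mt$p

  L_all <- ncol(gm$dosages)
  stat <- p_all <- rep(NA_real_, L_all)
  stat[pca$kept] <- d2
  p_all[pca$kept] <- p
  q <- bh_qvalues(p_all)
  out <- outlier_scores(gm$variants$id, "pcadapt", stat, p_all, q,
                        !is.na(q) & q < q_max)
  attr(out, "lambda") <- lambda
  out
}

#' F_ST outlier test against the background differentiation
#'
#' Per-locus Weir-Cockerham F_ST is referred to the multilocus background
#' via the Lewontin-Krakauer statistic (k - 1) * F_ST / mean F_ST (k =
#' number of groups). Two null references are available:
#' \describe{
#'   \item{`"parametric"` (default)}{p-values from a Balding-Nichols
#'     parametric null matched to the data: ancestral frequencies resampled
#'     from the observed per-locus means, site frequencies drawn
#'     Beta-distributed at the estimated multilocus theta, genotypes
#'     binomial at the observed sample sizes. Simulated and observed loci
#'     are stratified by folded mean frequency, and the upper tail beyond
#'     the `tail_q` quantile is modelled by a generalized Pareto fit so
#'     small p-values are resolved beyond the Monte-Carlo floor. This is
#'     the same island-model logic Bayesian F_ST-outlier samplers build on,
#'     in closed desk-scale form, and it is calibrated under the null by
#'     construction.}
#'   \item{`"chisq"`}{the classical Lewontin-Krakauer reference:
#'     chi-square with `df_inflation * (k - 1)` df. Known to be
#'     over-dispersed on real and simulated island-model data; kept for
#'     comparison.}
#' }
#' Negative per-locus estimates are clipped at zero. q-values are BH,
#' outliers flagged at q < 0.05.
#'
#' @param gm a `geno_matrix`.
#' @param grouping population labels per individual.
#' @param q_max flagging threshold on the q-value.
#' @param p_mode `"parametric"` or `"chisq"` (see Details).
#' @param n_sim simulated null loci for the parametric mode.
#' @param n_bins mean-frequency strata for the parametric mode.
#' @param tail_q quantile above which the generalized Pareto tail is used.
#' @param seed RNG seed for the parametric null.
#' @param df_inflation df multiplier for the chi-square mode (1 = plain
#'   Lewontin-Krakauer).
#' @return An `outlier_scores` data.frame with attribute `fst_bar`.
#' @export
fst_outlier <- function(gm, grouping = gm$samples$site, q_max = 0.05,
                        p_mode = c("parametric", "chisq"),
                        n_sim = 300000L, n_bins = 25L, tail_q = 0.99,
                        seed = 1L, df_inflation = 1) {
  p_mode <- match.arg(p_mode)
  grouping <- as.character(grouping)
  k <- length(unique(grouping))
  stop_if_not(k >= 3, "need >= 3 groups for a stable background")
  w <- wc_fst(gm, grouping)
  fbar <- w$theta
  stop_if_not(is.finite(fbar) && fbar > 0, "mean F_ST must be positive")
  stat <- pmax(w$per_locus, 0) * (k - 1) / fbar
  if (p_mode == "chisq") {
    df <- df_inflation * (k - 1)
    p <- pchisq(pmax(w$per_locus, 0) * df / fbar, df = df, lower.tail = FALSE)
  } else {
    p <- bn_null_pvalues(gm, grouping, w, n_sim = n_sim, n_bins = n_bins,
                         tail_q = tail_q, seed = seed)
  }
  q <- bh_qvalues(p)
  out <- outlier_scores(gm$variants$id, "fst_outlier", stat, p, q,
                        !is.na(q) & q < q_max)
  attr(out, "fst_bar") <- fbar
  out
}

# Balding-Nichols parametric null for per-locus F_ST, stratified by folded
# mean frequency, with a generalized-Pareto upper tail (method-of-moments
# fit on exceedances over the tail_q quantile).
bn_null_pvalues <- function(gm, grouping, w, n_sim, n_bins, tail_q, seed) {
  st <- group_locus_stats(gm, grouping)
  k <- nrow(st$n)
  theta <- w$theta
  obs <- w$per_locus
  sum_n <- colSums(st$n)
  pbar_obs <- ifelse(sum_n > 0, colSums(st$n * ifelse(st$n > 0, st$p, 0)) / sum_n, NA)
  ni <- pmax(1L, round(rowMeans(st$n)))
  with_seed(seed, {
    p_anc <- sample(pbar_obs[!is.na(pbar_obs) & pbar_obs > 0 & pbar_obs < 1],
                    n_sim, replace = TRUE)
    P <- matrix(rbeta(k * n_sim, rep(p_anc * (1 - theta) / theta, each = k),
                      rep((1 - p_anc) * (1 - theta) / theta, each = k)),
                nrow = k)
    psim <- hsim <- matrix(0, k, n_sim)
    for (i in seq_len(k)) {
      d <- matrix(rbinom(ni[i] * n_sim, 2L, rep(P[i, ], each = ni[i])), nrow = ni[i])
      psim[i, ] <- colSums(d) / (2 * ni[i])
      hsim[i, ] <- colMeans(d == 1L)
    }
    cmp <- wc_components(matrix(ni, k, n_sim), psim, hsim)
    sim <- ifelse(cmp$valid, cmp$a / (cmp$a + cmp$b + cmp$c), NA)
    sim_pbar <- colMeans(psim)
    fold <- function(x) pmin(x, 1 - x)
    br <- quantile(fold(sim_pbar), seq(0, 1, length.out = n_bins + 1), na.rm = TRUE)
    br[1] <- -Inf; br[length(br)] <- Inf
    bin_sim <- cut(fold(sim_pbar), br, labels = FALSE)
    bin_obs <- cut(fold(pbar_obs), br, labels = FALSE)
    p <- rep(NA_real_, length(obs))
    for (bn in seq_len(n_bins)) {
      ss <- sort(sim[bin_sim == bn & !is.na(sim)])
      io <- which(bin_obs == bn & !is.na(obs))
      if (!length(io) || length(ss) < 100) next
      x <- obs[io]
      p_emp <- (1 + length(ss) - findInterval(x - 1e-12, ss)) / (1 + length(ss))
      u <- quantile(ss, tail_q)
      exc <- ss[ss > u] - u
      if (length(exc) >= 50 && var(exc) > 0) {
        m1 <- mean(exc); v1 <- var(exc)
        xi <- 0.5 * (1 - m1^2 / v1)
        sg <- 0.5 * m1 * (m1^2 / v1 + 1)
        gpd_sf <- function(y) {
          if (abs(xi) < 1e-8) return(exp(-y / sg))
          z <- 1 + xi * y / sg
          ifelse(z > 0, z^(-1 / xi), 0)
        }
        hi <- x > u
        p_tail <- (1 - tail_q) * vapply(pmax(x - u, 0), gpd_sf, numeric(1))
        p[io] <- ifelse(hi, p_tail, p_emp)
      } else {
        p[io] <- p_emp
      }
    }
    pmin(pmax(p, 1e-300), 1)
  })
}
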