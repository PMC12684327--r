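# Genotype-environment association: environmental-variable reduction, the RDA
# suite (fit, forward selection, variance partitioning, Mahalanobis outliers),
# latent factor mixed models, covariance-whitened Bayes factors, and the
# multi-method consensus.

#' Greedy decorrelation of environmental variables
#'
#' Variables are visited in a declared priority order; a variable is retained
#' only if its absolute Pearson correlation with every already-retained
#' variable stays at or below `threshold`. Constant variables are dropped with
#' a warning. The full decision trace is returned.
#'
#' @param env_sample matrix/data.frame of landscape points x variables (use
#'   many grid cells, not just the sites).
#' @param threshold absolute-correlation threshold (default 0.7).
#' @param priority variable order; earlier variables win conflicts.
#' @return list(retained, dropped, trace).
#' @export
decorrelate_vars <- function(env_sample, threshold = 0.7,
                             priority = colnames(env_sample)) {
  env_sample <- as.matrix(env_sample)
  stop_if_not(!is.null(colnames(env_sample)), "env_sample needs column names")
  stop_if_not(all(priority %in% colnames(env_sample)), "unknown variable in priority")
  retained <- character(0)
  trace <- list()
  for (v in priority) {
    x <- env_sample[, v]
    if (sd(x) == 0) {
      warning(sprintf("dropping constant variable %s", v))
      trace[[length(trace) + 1]] <- data.frame(var = v, action = "dropped",
                                               against = NA, r = NA_real_)
      next
    }
    r <- if (length(retained)) cor(x, env_sample[, retained, drop = FALSE])[1, ] else numeric(0)
    if (any(abs(r) > threshold)) {
      worst <- which.max(abs(r))
      trace[[length(trace) + 1]] <- data.frame(var = v, action = "dropped",
                                               against = retained[worst], r = r[worst])
    } else {
      retained <- c(retained, v)
      trace[[length(trace) + 1]] <- data.frame(var = v, action = "retained",
                                               against = NA, r = if (length(r)) max(abs(r)) else NA_real_)
    }
  }
  list(retained = retained, dropped = setdiff(priority, retained),
       trace = do.call(rbind, trace))
}

#' Fit a (partial) redundancy analysis
#'
#' Multivariate least squares of the column-centred response on the centred
#' predictors (both residualised on the conditioning block `Z` first, if
#' given), followed by an SVD of the fitted values. Eigenvalues are on the
#' variance scale (d^2/(n-1)); R^2 is the fitted fraction of the
#' (residualised) total sum of squares, adjusted by Ezekiel's formula; the
#' permutation p-value shuffles rows of the residualised response.
#' Axis signs are fixed (largest-|loading| entry positive).
#'
#' @param Y response matrix (rows = sites or individuals, columns = loci).
#' @param X predictor matrix/data.frame, standardised by the caller.
#' @param Z optional conditioning matrix.
#' @param n_perm permutations for the significance test (0 = skip).
#' @param seed RNG seed for permutations.
#' @return An `rda_model`: list with predictors, conditioning, coef
#'   (canonical coefficients: centred predictors -> axis scores), B
#'   (regression coefficients), eig, site_scores, loadings, total_inertia,
#'   conditional_inertia, constrained_inertia, residual_inertia, r2, adj_r2,
#'   perm_p, centers, snp_ids, model_id.
#' @export
rda_fit <- function(Y, X, Z = NULL, n_perm = 999L, seed = 1L) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stop_if_not(nrow(Y) == nrow(X), "Y and X must have matching rows")
  n <- nrow(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qz_rank <- 0L
  conditioning <- character(0)
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    stop_if_not(nrow(Z) == n, "Z rows must match Y")
    conditioning <- colnames(Z) %||% paste0("z", seq_len(ncol(Z)))
    Zc <- scale(Z, center = TRUE, scale = FALSE)
    qz <- qr(Zc)
    qz_rank <- qz$rank
    Yr <- qr.resid(qz, Yc)
    Xr <- qr.resid(qz, Xc)
    # predictors (numerically) inside the span of Z carry no residual signal;
    # keeping their noise-level residuals would fabricate constrained inertia
    ratio <- sqrt(colSums(Xr^2) / pmax(colSums(Xc^2), 1e-300))
    absorbed <- ratio < 1e-8
    Xr <- Xr[, !absorbed, drop = FALSE]
  } else {
    Yr <- Yc; Xr <- Xc
    absorbed <- rep(FALSE, ncol(Xc))
  }
  if (ncol(Xr) == 0) {
    # everything conditioned away: a valid degenerate model with zero
    # constrained inertia
    n <- nrow(Y)
    ss_tot <- sum(Yc^2); ss_resid_tot <- sum(Yr^2)
    model <- structure(list(
      predictors = colnames(X), conditioning = conditioning,
      coef = matrix(0, ncol(X), 0), B = matrix(0, ncol(X), ncol(Y)),
      eig = numeric(0),
      site_scores = matrix(0, n, 0), loadings = matrix(0, ncol(Y), 0),
      total_inertia = ss_tot / (n - 1),
      conditional_inertia = (ss_tot - ss_resid_tot) / (n - 1),
      constrained_inertia = 0, residual_inertia = ss_resid_tot / (n - 1),
      r2 = 0, adj_r2 = 0, perm_p = NA_real_, n = n,
      x_center = attr(Xc, "scaled:center"), y_center = attr(Yc, "scaled:center"),
      snp_ids = colnames(Y) %||% paste0("resp", seq_len(ncol(Y))),
      absorbed = colnames(X)
    ), class = "rda_model")
    model$model_id <- obj_fingerprint(list(dim(Y), model$predictors, "null"))
    return(model)
  }
  qx <- qr(Xr)
  if (qx$rank < ncol(Xr)) {
    bad <- colnames(Xr)[qx$pivot[(qx$rank + 1):ncol(Xr)]]
    stop(sprintf("rank-deficient predictors; collinear: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  B <- qr.coef(qx, Yr)
  Yhat <- qr.fitted(qx, Yr)
  ss_tot <- sum(Yc^2); ss_resid_tot <- sum(Yr^2); ss_fit <- sum(Yhat^2)
  r2 <- ss_fit / ss_resid_tot
  m <- qx$rank
  adj_r2 <- 1 - (1 - r2) * (n - 1 - qz_rank) / (n - 1 - qz_rank - m)

  sv <- svd(Yhat)
  kmax <- min(m, sum(sv$d > max(sv$d[1], 1e-300) * 1e-9))
  kmax <- max(kmax, 1L)
  d <- sv$d[seq_len(kmax)]
  U <- sv$u[, seq_len(kmax), drop = FALSE]
  V <- sv$v[, seq_len(kmax), drop = FALSE]
  for (k in seq_len(kmax)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  site_scores <- U %*% diag(d, kmax)
  coef_canon <- B %*% V

  perm_p <- NA_real_
  if (n_perm > 0) {
    perm_p <- with_seed(seed, {
      r2_perm <- vapply(seq_len(n_perm), function(b) {
        sum(qr.fitted(qx, Yr[sample.int(n), , drop = FALSE])^2) / ss_resid_tot
      }, numeric(1))
      (1 + sum(r2_perm >= r2)) / (n_perm + 1)
    })
  }

  model <- structure(list(
    predictors = colnames(X), conditioning = conditioning,
    coef = coef_canon, B = B, eig = d^2 / (n - 1),
    site_scores = site_scores, loadings = V,
    total_inertia = ss_tot / (n - 1),
    conditional_inertia = (ss_tot - ss_resid_tot) / (n - 1),
    constrained_inertia = ss_fit / (n - 1),
    residual_inertia = (ss_resid_tot - ss_fit) / (n - 1),
    r2 = r2, adj_r2 = adj_r2, perm_p = perm_p, n = n,
    x_center = attr(Xc, "scaled:center"), y_center = attr(Yc, "scaled:center"),
    snp_ids = colnames(Y) %||% paste0("resp", seq_len(ncol(Y))),
    absorbed = colnames(X)[absorbed]
  ), class = "rda_model")
  model$model_id <- obj_fingerprint(list(dim(Y), model$predictors, round(unname(model$coef), 8)))
  model
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("rda_model: %d predictors%s, %d axes; R2 = %.3f (adj %.3f)%s\n",
              length(x$predictors),
              if (length(x$conditioning)) sprintf(" | %d conditioning", length(x$conditioning)) else "",
              length(x$eig), x$r2, x$adj_r2,
              if (is.na(x$perm_p)) "" else sprintf(", perm p = %.4g", x$perm_p)))
  invisible(x)
}

#' Forward selection of predictors for RDA
#'
#' Starting from the null model, at each step the candidate maximising the
#' adjusted R^2 is tested by a marginal permutation test (partial RDA of the
#' candidate conditioned on the current selection); it is added only if
#' p < `alpha` and the cumulative adjusted R^2 does not exceed the full-model
#' adjusted R^2. Ties are broken by candidate order; candidates that would
#' make the design rank-deficient are skipped.
#'
#' @param Y response matrix.
#' @param candidates matrix of candidate predictors (named columns).
#' @param alpha marginal significance threshold (default 0.01).
#' @param n_perm permutations per marginal test (default 999).
#' @param seed RNG seed.
#' @param r2_scope apply the full-model adjusted-R^2 cap (default TRUE).
#'   When most candidates are pure noise the cap is a mean-zero comparison
#'   and can stop the selection before a genuine variable enters; turning it
#'   off leaves the permutation test as the only gate.
#' @return list(selected (ordered names), trace data.frame, adj_r2_full).
#' @export
forward_select <- function(Y, candidates, alpha = 0.01, n_perm = 999L, seed = 1L,
                           r2_scope = TRUE) {
  X <- as.matrix(candidates)
  stop_if_not(ncol(X) >= 1, "need at least one candidate")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  # full-model reference on a maximal independent subset of candidates
  qfull <- qr(scale(X, scale = FALSE))
  full_cols <- colnames(X)[qfull$pivot[seq_len(qfull$rank)]]
  adj_full <- rda_fit(Y, X[, full_cols, drop = FALSE], n_perm = 0)$adj_r2

  selected <- character(0)
  trace <- list()
  remaining <- colnames(X)
  step <- 0L
  repeat {
    step <- step + 1L
    best <- NULL
    for (v in remaining) {
      cols <- c(selected, v)
      if (qr(scale(X[, cols, drop = FALSE], scale = FALSE))$rank < length(cols)) next
      fit <- rda_fit(Y, X[, cols, drop = FALSE], n_perm = 0)
      if (is.null(best) || fit$adj_r2 > best$adj_r2 + 1e-12) {
        best <- list(var = v, adj_r2 = fit$adj_r2)
      }
    }
    if (is.null(best)) break
    marg <- rda_fit(Y, X[, best$var, drop = FALSE],
                    Z = if (length(selected)) X[, selected, drop = FALSE] else NULL,
                    n_perm = n_perm, seed = seed + step)
    accept <- marg$perm_p < alpha &&
      (!r2_scope || best$adj_r2 <= adj_full + 1e-8)
    trace[[step]] <- data.frame(step = step, var = best$var, adj_r2 = best$adj_r2,
                                p = marg$perm_p, accepted = accept)
    if (!accept) break
    selected <- c(selected, best$var)
    remaining <- setdiff(remaining, best$var)
    if (!length(remaining)) break
  }
  list(selected = selected, trace = do.call(rbind, trace), adj_r2_full = adj_full)
}

#' Variance partitioning among environment, geography and ancestry
#'
#' The constrained inertia of the full model (all three blocks) is decomposed
#' into pure fractions via three partial RDAs (each block conditioned on the
#' other two); the confounded fraction is the remainder. Pure fractions plus
#' the confounded fraction sum to the full-model constrained inertia by
#' construction; proportions of total and of explainable variance are
#' reported alongside permutation p-values.
#'
#' @param Y response matrix (sites x loci).
#' @param env,geog,genet predictor blocks (matrices with named columns).
#' @param n_perm permutations per model.
#' @param seed RNG seed.
#' @return list(table data.frame, models list).
#' @export
variance_partition <- function(Y, env, geog, genet, n_perm = 999L, seed = 1L) {
  blocks <- list(env = as.matrix(env), geog = as.matrix(geog), genet = as.matrix(genet))
  for (b in names(blocks)) {
    if (is.null(colnames(blocks[[b]])))
      colnames(blocks[[b]]) <- paste0(b, seq_len(ncol(blocks[[b]])))
  }
  Xall <- do.call(cbind, blocks)
  # collinearity across blocks is expected (that is what "confounded" means);
  # the full model runs on a maximal linearly independent column subset
  qa <- qr(scale(Xall, scale = FALSE))
  if (qa$rank < ncol(Xall)) Xall <- Xall[, qa$pivot[seq_len(qa$rank)], drop = FALSE]
  full <- rda_fit(Y, Xall, n_perm = n_perm, seed = seed)
  part <- lapply(seq_along(blocks), function(i) {
    rda_fit(Y, blocks[[i]], Z = do.call(cbind, blocks[-i]),
            n_perm = n_perm, seed = seed + i)
  })
  names(part) <- names(blocks)
  pure <- vapply(part, function(m) m$constrained_inertia, numeric(1))
  confounded <- full$constrained_inertia - sum(pure)
  tot <- full$total_inertia
  tab <- data.frame(
    fraction = c("full", paste0("pure_", names(blocks)), "confounded", "residual"),
    inertia = c(full$constrained_inertia, pure, confounded, full$residual_inertia),
    prop_total = c(full$constrained_inertia, pure, confounded, full$residual_inertia) / tot,
    prop_explainable = c(1, pure / full$constrained_inertia,
                         confounded / full$constrained_inertia, NA),
    p = c(full$perm_p, vapply(part, function(m) m$perm_p, numeric(1)), NA, NA)
  )
  list(table = tab, models = c(list(full = full), part))
}

#' RDA outlier detection by Mahalanobis distance of SNP loadings
#'
#' SNP loadings on the first `K_axes` constrained axes are summarised by a
#' Mahalanobis distance, rescaled by the genomic inflation factor
#' (median(D^2)/qchisq(0.5, K)), referred to a chi-square with `K_axes` df,
#' and flagged at the Bonferroni-adjusted level `alpha_bonf / n_SNPs`.
#'
#' @param model an `rda_model` (site-level RDA of allele frequencies).
#' @param K_axes number of leading axes (default 2).
#' @param alpha_bonf overall significance level before Bonferroni division.
#' @return An `outlier_scores` data.frame with attribute `lambda`.
#' @export
rda_outliers <- function(model, K_axes = 2L, alpha_bonf = 0.05) {
  stop_if_not(length(model$eig) >= K_axes,
              "model has %d constrained axes, need %d", length(model$eig), K_axes)
  V <- model$loadings[, seq_len(K_axes), drop = FALSE]
  L <- nrow(V)
  stop_if_not(L > K_axes, "fewer SNPs than axes")
  mt <- mahalanobis_trimmed(V, df = K_axes)
  q <- bh_qvalues(mt$p)
  out <- outlier_scores(model$snp_ids, "rda", mt$d2, mt$p, q,
                        mt$p < alpha_bonf / L)
  attr(out, "lambda") <- mt$lambda
  out
}

#' Variance-stabilised site allele frequencies
#'
#' Centre each locus at its across-population mean frequency and divide by
#' sqrt(pbar (1 - pbar)). On this scale every locus has comparable loading
#' variance in a constrained ordination, which is what the Mahalanobis
#' outlier scan assumes; use it as the response of the RDA passed to
#' [rda_outliers()]. Loci fixed across all populations are dropped.
#'
#' @param freqs an `allele_freq_table` (missing cells imputed at the locus
#'   mean) or a populations x loci matrix.
#' @return matrix populations x (polymorphic) loci; attribute `kept` holds
#'   the retained column indices.
#' @export
standardize_freqs <- function(freqs) {
  F0 <- if (inherits(freqs, "allele_freq_table")) freqs$freq else as.matrix(freqs)
  if (anyNA(F0)) {
    for (l in which(colSums(is.na(F0)) > 0))
      F0[is.na(F0[, l]), l] <- mean(F0[, l], na.rm = TRUE)
  }
  pbar <- colMeans(F0)
  keep <- pbar > 0 & pbar < 1
  out <- sweep(sweep(F0[, keep, drop = FALSE], 2L, pbar[keep], `-`),
               2L, sqrt(pbar[keep] * (1 - pbar[keep])), `/`)
  attr(out, "kept") <- which(keep)
  out
}

#' Latent factor mixed model association scan (one environmental variable)
#'
#' Ridge latent-factor estimation: the genotype matrix (mean-imputed, centred
#' columns) is projected off the environmental variable with a ridge
#' regularised hat matrix, `K` latent factors are taken as the leading left
#' singular vectors of that projection, and each locus is then regressed on
#' the variable plus the factors. Squared t-statistics are recalibrated by
#' the genomic inflation factor; q-values are BH, outliers flagged at
#' q < `q_max`. `K = 0` reduces to simple per-locus regression.
#'
#' @param gm a `geno_matrix`.
#' @param env_var environmental value per individual (site values propagated
#'   to individuals; see [env_for_individuals()]).
#' @param K number of latent factors (default 3).
#' @param ridge_lambda ridge penalty for the projection step.
#' @param q_max flagging threshold on the q-value.
#' @return An `outlier_scores` data.frame (stat = calibrated t statistic)
#'   with attributes `lambda` (inflation factor) and `effects`.
#' @export
lfmm_fit <- function(gm, env_var, K = 3L, ridge_lambda = 1e-5, q_max = 0.05) {
  G <- scale_dosages(gm, "center")
  Y <- G$mat
  n <- nrow(Y)
  stop_if_not(length(env_var) == n, "env_var must have one value per individual")
  stop_if_not(K >= 0 && K < min(n, ncol(Y)), "K must be in [0, min(n, L))")
  x <- as.numeric(scale(env_var))
  X <- matrix(x, ncol = 1)
  if (K > 0) {
    H <- X %*% solve(crossprod(X) + ridge_lambda, t(X))
    M <- Y - H %*% Y
    sv <- svd(M, nu = K, nv = 0)
    U <- sv$u[, seq_len(K), drop = FALSE]
    D <- cbind(1, X, U)
  } else {
    D <- cbind(1, X)
  }
  qd <- qr(D)
  coef <- qr.coef(qd, Y)
  res <- qr.resid(qd, Y)
  df <- n - ncol(D)
  sigma2 <- colSums(res^2) / df
  d2 <- diag(solve(crossprod(D)))[2]
  se <- sqrt(sigma2 * d2)
  tt <- coef[2, ] / se
  z2 <- tt^2
  lambda <- median(z2) / qchisq(0.5, df = 1)
  p <- pchisq(z2 / lambda, df = 1, lower.tail = FALSE)

  L_all <- ncol(gm$dosages)
  stat <- p_all <- eff <- rep(NA_real_, L_all)
  stat[G$kept] <- tt / sqrt(lambda)
  p_all[G$kept] <- p
  eff[G$kept] <- coef[2, ]
  q <- bh_qvalues(p_all)
  out <- outlier_scores(gm$variants$id, "lfmm", stat, p_all, q,
                        !is.na(q) & q < q_max)
  attr(out, "lambda") <- lambda
  attr(out, "effects") <- eff
  out
}

#' Propagate per-site environmental values to individuals
#'
#' @param landscape a `landscape` with named sites.
#' @param gm a `geno_matrix` whose samples carry site labels.
#' @param vars variables to extract (default all).
#' @return matrix individuals x variables.
#' @export
env_for_individuals <- function(landscape, gm, vars = landscape$var_names) {
  idx <- match(gm$samples$site, landscape$site_names)
  stop_if_not(!anyNA(idx), "samples reference sites absent from the landscape")
  landscape$site_env[idx, vars, drop = FALSE]
}

#' LFMM scan over several environmental variables
#'
#' Runs [lfmm_fit()] per variable and combines: a SNP is flagged if any
#' variable flags it; the reported p is the per-SNP minimum.
#'
#' @param gm a `geno_matrix`.
#' @param env_ind matrix individuals x variables.
#' @param K latent factors.
#' @param q_max flagging threshold per variable.
#' @return list(combined = `outlier_scores`, per_var = list).
#' @export
lfmm_scan <- function(gm, env_ind, K = 3L, q_max = 0.05) {
  env_ind <- as.matrix(env_ind)
  per_var <- lapply(seq_len(ncol(env_ind)), function(j)
    lfmm_fit(gm, env_ind[, j], K = K, q_max = q_max))
  names(per_var) <- colnames(env_ind) %||% paste0("env", seq_len(ncol(env_ind)))
  pmin_mat <- do.call(cbind, lapply(per_var, `[[`, "p"))
  flags <- do.call(cbind, lapply(per_var, `[[`, "flag"))
  stats <- do.call(cbind, lapply(per_var, function(s) abs(s$stat)))
  p_min <- apply(pmin_mat, 1L, function(r) if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
  combined <- outlier_scores(per_var[[1]]$snp, "lfmm",
                             apply(stats, 1L, max),
                             p_min, bh_qvalues(p_min),
                             rowSums(flags, na.rm = TRUE) > 0)
  list(combined = combined, per_var = per_var)
}

#' Covariance-whitened Bayes factors for SNP-environment association
#'
#' The population covariance matrix Omega is estimated as the covariance
#' across loci of standardised population allele frequencies
#' (p - pbar)/sqrt(pbar(1 - pbar)). Each locus and environmental variable is
#' whitened by Omega^(-1/2) and a closed-form Zellner g-prior Bayes factor
#' (g = number of populations) for slope-vs-null is computed on the whitened
#' regression: BF = (1+g)^(-1/2) * (1 - g/(1+g) R^2)^(-n/2). Results are in
#' decibels (10 log10 BF); a SNP is flagged when any variable reaches
#' `db_threshold` (default 15 dB).
#'
#' @param freqs an `allele_freq_table` (populations x SNPs).
#' @param env_site environmental values per population (standardised
#'   internally), rows aligned with the frequency table's populations.
#' @param g g-prior scale; default: number of populations (unit information).
#' @param ridge diagonal regularisation added when Omega is near-singular.
#' @param db_threshold flagging threshold in dB.
#' @return list(db = SNPs x variables matrix, omega, scores =
#'   `outlier_scores` (stat = max dB), g, imputed_cells).
#' @export
omega_bf <- function(freqs, env_site, g = NULL, ridge = 1e-6, db_threshold = 15) {
  F0 <- freqs$freq
  n_pop <- nrow(F0)
  imputed <- 0L
  if (anyNA(F0)) {
    for (l in which(colSums(is.na(F0)) > 0)) {
      m <- mean(F0[, l], na.rm = TRUE)
      imputed <- imputed + sum(is.na(F0[, l]))
      F0[is.na(F0[, l]), l] <- m
    }
  }
  pbar <- colMeans(F0)
  keep <- pbar > 0 & pbar < 1
  Ystd <- sweep(F0[, keep, drop = FALSE], 2L, pbar[keep], `-`)
  Ystd <- sweep(Ystd, 2L, sqrt(pbar[keep] * (1 - pbar[keep])), `/`)
  L <- ncol(Ystd)
  omega <- tcrossprod(Ystd) / L
  ev <- eigen(omega, symmetric = TRUE)
  if (min(ev$values) < ridge * max(ev$values)) {
    omega <- omega + diag(ridge * mean(diag(omega)), n_pop)
    ev <- eigen(omega, symmetric = TRUE)
  }
  C <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)

  X <- scale(as.matrix(env_site))
  stop_if_not(nrow(X) == n_pop, "env_site rows must match populations")
  if (is.null(g)) g <- n_pop
  Xw <- C %*% X
  Yw <- C %*% Ystd
  num <- crossprod(Xw, Yw)^2                      # vars x loci
  den <- outer(colSums(Xw^2), colSums(Yw^2))
  R2 <- num / den
  log10_bf <- (-0.5) * log10(1 + g) + (-n_pop / 2) * log10(1 - g / (1 + g) * R2)
  db_kept <- 10 * t(log10_bf)                     # loci x vars

  L_all <- ncol(F0)
  db <- matrix(NA_real_, L_all, ncol(X),
               dimnames = list(colnames(freqs$freq), colnames(env_site)))
  db[keep, ] <- db_kept
  max_db <- apply(db, 1L, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  scores <- outlier_scores(colnames(freqs$freq) %||% paste0("snp", seq_len(L_all)),
                           "bayes_factor", max_db, NA_real_, NA_real_,
                           !is.na(max_db) & max_db >= db_threshold)
  list(db = db, omega = omega, scores = scores, g = g, imputed_cells = imputed)
}

#' Multi-method consensus of outlier sets
#'
#' @param score_sets named list of `outlier_scores` (or data.frames with
#'   columns snp and flag), all indexed on the same SNP universe.
#' @param m_min minimum number of detecting methods for consensus membership.
#' @return list(table (per-SNP flags, n_methods, consensus), members (snp
#'   ids), venn (counts of every method-combination region), m_min).
#' @export
consensus <- function(score_sets, m_min = 4L) {
  stop_if_not(length(score_sets) >= 1, "need at least one score set")
  if (is.null(names(score_sets)))
    names(score_sets) <- vapply(score_sets, function(s) s$method[1], character(1))
  universe <- score_sets[[1]]$snp
  for (s in score_sets)
    stop_if_not(identical(s$snp, universe), "score sets are on different SNP universes")
  flags <- vapply(score_sets, function(s) {
    f <- s$flag; f[is.na(f)] <- FALSE; f
  }, logical(length(universe)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = length(universe))
  colnames(flags) <- names(score_sets)
  n_det <- rowSums(flags)
  tab <- data.frame(snp = universe, flags, n_methods = n_det,
                    consensus = n_det >= m_min, check.names = FALSE)
  M <- ncol(flags)
  pat <- apply(flags, 1L, function(r) paste(as.integer(r), collapse = ""))
  all_pat <- apply(expand.grid(rep(list(0:1), M))[, M:1, drop = FALSE], 1L,
                   paste, collapse = "")
  venn <- data.frame(pattern = all_pat,
                     count = as.integer(table(factor(pat, levels = all_pat))))
  list(table = tab, members = universe[n_det >= m_min], venn = venn, m_min = m_min)
}
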