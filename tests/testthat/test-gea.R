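test_that("variable decorrelation keeps one of each correlated set", {
  withr::with_seed(1, {
    x <- rnorm(500)
    env <- cbind(a = x, b = x, c = rnorm(500), d = rnorm(500))
  })
  res <- decorrelate_vars(env)
  expect_equal(res$retained, c("a", "c", "d"))
  withr::with_seed(2, env2 <- matrix(rnorm(500 * 4), ncol = 4,
                                     dimnames = list(NULL, letters[1:4])))
  expect_equal(decorrelate_vars(env2)$retained, letters[1:4])
  expect_warning(decorrelate_vars(cbind(env2, e = rep(1, 500))), "constant")

  # correlated factor structure: no retained pair above the threshold
  withr::with_seed(3, {
    f <- matrix(rnorm(800 * 2), ncol = 2)
    load <- matrix(rnorm(2 * 8), 2, 8)
    env3 <- f %*% load + 0.4 * matrix(rnorm(800 * 8), ncol = 8)
    colnames(env3) <- paste0("v", 1:8)
  })
  kept <- decorrelate_vars(env3)$retained
  cm <- abs(cor(env3[, kept])); diag(cm) <- 0
  expect_lt(max(cm), 0.7 + 1e-12)
})

test_that("rda_fit has exact limits and matches eigendecomposition oracles", {
  withr::with_seed(4, {
    X <- matrix(rnorm(11 * 3), 11, 3, dimnames = list(NULL, c("e1", "e2", "e3")))
    B <- matrix(rnorm(3 * 40), 3, 40)
    Y_exact <- scale(X %*% B, scale = FALSE)
  })
  m_exact <- rda_fit(Y_exact, X, n_perm = 0)
  expect_equal(m_exact$r2, 1, tolerance = 1e-10)
  expect_equal(m_exact$residual_inertia, 0, tolerance = 1e-10)

  withr::with_seed(5, Y <- matrix(rnorm(11 * 40), 11, 40))
  # explicit projection + eigendecomposition oracle
  m <- rda_fit(Y, X, n_perm = 199, seed = 1)
  Yc <- scale(Y, scale = FALSE); Xc <- scale(X, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  Yhat <- H %*% Yc
  ev <- eigen(tcrossprod(Yhat), symmetric = TRUE)$values / (nrow(Y) - 1)
  expect_equal(m$eig, ev[seq_along(m$eig)], tolerance = 1e-8)
  expect_equal(m$r2, sum(Yhat^2) / sum(Yc^2), tolerance = 1e-10)
  expect_equal(abs(m$site_scores),
               abs(Yhat %*% svd(Yhat)$v[, seq_along(m$eig)]), tolerance = 1e-8)

  # conditioning identities
  m_cond_self <- rda_fit(Y, X, Z = X, n_perm = 0)
  expect_lt(m_cond_self$constrained_inertia, 1e-10)
  expect_equal(rda_fit(Y, X, n_perm = 0)$eig, m$eig, tolerance = 1e-12)

  # rank deficiency is reported with the offending column
  expect_error(rda_fit(Y, cbind(X, e1b = X[, 1]), n_perm = 0), "collinear.*e1b")
})

test_that("rda_fit agrees with vegan as an independent cross-check", {
  skip_if_not_installed("vegan")
  withr::with_seed(6, {
    Y <- matrix(rnorm(12 * 30), 12, 30)
    X <- data.frame(a = rnorm(12), b = rnorm(12))
  })
  m <- rda_fit(Y, as.matrix(X), n_perm = 0)
  v <- vegan::rda(Y ~ a + b, data = X)
  expect_equal(m$eig, unname(v$CCA$eig), tolerance = 1e-8)
  expect_equal(m$r2, v$CCA$tot.chi / v$tot.chi, tolerance = 1e-8)
  expect_equal(m$adj_r2, vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-8)
})

test_that("forward selection keeps truly associated variables and rejects noise", {
  # with only noise alongside one real variable, the full-model adjusted-R^2
  # cap is a coin flip by construction (Ezekiel adjustment is mean-unbiased),
  # so the recovery property is assessed with the cap off; the cap's own
  # behaviour is asserted separately below
  picks <- vapply(1:5, function(s) {
    withr::with_seed(s, {
      x <- rnorm(30)
      Y <- outer(x, rnorm(60)) + matrix(rnorm(30 * 60), 30, 60)
      cand <- cbind(sig = x, matrix(rnorm(30 * 4), 30, 4,
                                    dimnames = list(NULL, paste0("n", 1:4))))
    })
    fs <- forward_select(Y, cand, alpha = 0.01, n_perm = 199, seed = s,
                         r2_scope = FALSE)
    (length(fs$selected) >= 1 && fs$selected[1] == "sig" &&
       !any(grepl("^n", fs$selected)))
  }, logical(1))
  expect_gte(sum(picks), 4)

  # the scope cap never lets the selection overshoot the full model
  withr::with_seed(77, {
    x <- rnorm(30)
    Y <- outer(x, rnorm(60)) + matrix(rnorm(30 * 60), 30, 60)
    cand <- cbind(sig = x, matrix(rnorm(30 * 4), 30, 4,
                                  dimnames = list(NULL, paste0("n", 1:4))))
  })
  fs_cap <- forward_select(Y, cand, alpha = 0.01, n_perm = 199, seed = 1)
  if (length(fs_cap$selected)) {
    final <- rda_fit(Y, cand[, fs_cap$selected, drop = FALSE], n_perm = 0)
    expect_lte(final$adj_r2, fs_cap$adj_r2_full + 1e-8)
  }

  nulls <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      Y <- matrix(rnorm(30 * 60), 30, 60)
      cand <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("n", 1:4)))
    })
    length(forward_select(Y, cand, alpha = 0.01, n_perm = 199, seed = s)$selected) == 0
  }, logical(1))
  expect_gte(sum(nulls), 4)

  # a duplicate of a selected variable can never enter (rank guard)
  withr::with_seed(7, {
    x <- rnorm(11)
    Y <- outer(x, rnorm(60)) * 2 + matrix(rnorm(11 * 60), 11, 60) * 0.2
    cand <- cbind(sig = x, sig_dup = x, noise = rnorm(11))
  })
  fs <- forward_select(Y, cand, n_perm = 199, seed = 1)
  expect_false("sig_dup" %in% fs$selected)
})

test_that("variance partitioning is additive and handles degenerate designs", {
  withr::with_seed(8, {
    q <- qr.Q(qr(matrix(rnorm(12 * 6), 12, 6)))
    env <- q[, 1:2]; geog <- q[, 3:4]; genet <- q[, 5:6]
    colnames(env) <- c("e1", "e2"); colnames(geog) <- c("g1", "g2")
    colnames(genet) <- c("k1", "k2")
    Y <- matrix(rnorm(12 * 30), 12, 30)
  })
  vp <- variance_partition(Y, env, geog, genet, n_perm = 99, seed = 1)
  tab <- vp$table
  pure <- tab$inertia[grepl("^pure", tab$fraction)]
  confounded <- tab$inertia[tab$fraction == "confounded"]
  full <- tab$inertia[tab$fraction == "full"]
  expect_equal(sum(pure) + confounded, full, tolerance = 1e-8)
  expect_lt(abs(confounded), 0.05 * full)  # orthogonal blocks barely share

  vp2 <- variance_partition(Y, env, env, genet, n_perm = 0, seed = 1)
  tab2 <- vp2$table
  expect_lt(tab2$inertia[tab2$fraction == "pure_env"], 1e-8)
  expect_lt(tab2$inertia[tab2$fraction == "pure_geog"], 1e-8)
  expect_equal(sum(tab2$inertia[grepl("^pure", tab2$fraction)]) +
                 tab2$inertia[tab2$fraction == "confounded"],
               tab2$inertia[tab2$fraction == "full"], tolerance = 1e-8)
})

test_that("RDA outlier distances match an explicit quadratic-form oracle", {
  fx <- default_fixture(seed = 9, n_loci = 500, beta = 2)
  fr <- allele_freqs_by_pop(fx$genotypes)
  se <- fx$landscape$site_env[match(rownames(fr$freq), fx$landscape$site_names), ]
  m <- rda_fit(standardize_freqs(fr), scale(se), n_perm = 0)
  sc <- rda_outliers(m, K_axes = 2)
  V <- m$loadings[, 1:2]
  d2_0 <- mahalanobis(V, colMeans(V), cov(V))
  keep <- d2_0 <= quantile(d2_0, 0.95)
  Cinv <- solve(cov(V[keep, ])); mu <- colMeans(V[keep, ])
  d2 <- apply(V, 1, function(r) drop(t(r - mu) %*% Cinv %*% (r - mu)))
  expect_equal(sc$stat, unname(d2), tolerance = 1e-8)
  expect_error(rda_outliers(m, K_axes = 10), "axes")
})

test_that("LFMM with K = 0 reduces to per-locus regression; latent factors calibrate it", {
  fx <- default_fixture(seed = 10, n_loci = 300, inds_per_site = 6)
  gm <- fx$genotypes
  env <- env_for_individuals(fx$landscape, gm)[, 1]
  sc <- lfmm_fit(gm, env, K = 0)
  lam <- attr(sc, "lambda")
  x <- as.numeric(scale(env))
  G <- landgen:::scale_dosages(gm, "center")
  for (j in c(1, 100, 300)) {
    t_lm <- summary(lm(G$mat[, j] ~ x))$coefficients["x", "t value"]
    expect_equal(sc$stat[j] * sqrt(lam), t_lm, tolerance = 1e-8)
  }
  expect_error(lfmm_fit(gm, env, K = 500), "K must be")
  expect_error(lfmm_fit(gm, env[-1], K = 0), "one value per individual")

  # confounded design: env parallel to structure; inflation factor corrects it
  fx2 <- default_fixture(seed = 11, n_loci = 2000, prop_adaptive = 0, F_group = 0.05)
  env2 <- env_for_individuals(fx2$landscape, fx2$genotypes)[, 1]
  sc2 <- lfmm_fit(fx2$genotypes, env2, K = 3)
  p <- sort(sc2$p[!is.na(sc2$p)])
  ks <- max(abs(p - (seq_along(p) - 0.5) / length(p)))
  expect_lt(ks, 1.628 / sqrt(length(p)))
})

test_that("whitened Bayes factors match quadrature and respect population relabeling", {
  fx <- default_fixture(seed = 12, n_loci = 400, beta = 2)
  fr <- allele_freqs_by_pop(fx$genotypes)
  se <- fx$landscape$site_env[match(rownames(fr$freq), fx$landscape$site_names), ]
  bf <- omega_bf(fr, se)
  expect_true(isSymmetric(bf$omega, tol = 1e-10))

  # quadrature oracle on the whitened regression, 50 loci
  ev <- eigen(bf$omega, symmetric = TRUE)
  C <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  pbar <- colMeans(fr$freq)
  Ystd <- sweep(sweep(fr$freq, 2, pbar, `-`), 2, sqrt(pbar * (1 - pbar)), `/`)
  x1 <- drop(C %*% scale(se)[, 1])
  withr::with_seed(1, loci <- sample(ncol(Ystd), 50))
  for (l in loci) {
    y <- drop(C %*% Ystd[, l])
    bf_num <- oracle_gprior_bf(y, x1, g = nrow(se))
    expect_equal(10^(bf$db[l, 1] / 10), bf_num, tolerance = 0.01)
  }

  # invariance under population relabeling
  perm <- c(4, 2, 9, 1, 7, 3, 11, 5, 10, 8, 6)
  fr_p <- fr; fr_p$freq <- fr$freq[perm, ]; fr_p$pops <- fr$pops[perm]
  bf_p <- omega_bf(fr_p, se[perm, ])
  expect_equal(bf_p$db, bf$db, tolerance = 1e-8)

  # weak whitened correlation means evidence for the null (negative dB): the
  # bulk of neutral loci against a non-driver variable sits below 0 dB
  neut <- setdiff(seq_len(ncol(fr$freq)), fx$truth$adaptive_loci)
  expect_lt(median(bf$db[neut, 2], na.rm = TRUE), 0)
  # and R^2 = 0 gives the closed-form floor -5 log10(1 + g)
  R2 <- cor(drop(C %*% Ystd[, 1]), x1)^2
  expect_gte(bf$db[1, 1], -5 * log10(1 + bf$g) - 1e-9)

  # planted loci on the driver variable dominate the neutral background
  ad <- fx$truth$adaptive_loci
  expect_gt(median(bf$db[ad, 1]), quantile(bf$db[-ad, 1], 0.95, na.rm = TRUE))
})

test_that("consensus counts, membership and Venn regions are exact", {
  snp <- sprintf("s%02d", 1:10)
  mk <- function(flags, method) data.frame(
    snp = snp, method = method, stat = 1, p = 0.5, q = 0.5, flag = flags)
  sets <- list(
    a = mk(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), "a"),
    b = mk(c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), "b"),
    c = mk(c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE), "c"))
  cons <- consensus(sets, m_min = 2)
  expect_equal(cons$members, "s01")
  expect_equal(consensus(sets, m_min = 1)$members, c("s01", "s02", "s03", "s04"))
  # disjoint flags never reach a 4-of-5 consensus
  sets5 <- lapply(1:5, function(i) mk(seq_along(snp) == i, paste0("m", i)))
  expect_length(consensus(sets5, m_min = 4)$members, 0)
  # region counts against brute-force enumeration
  withr::with_seed(13, {
    flags <- matrix(runif(10 * 3) < 0.4, 10, 3)
  })
  sets_r <- lapply(1:3, function(i) mk(flags[, i], paste0("m", i)))
  names(sets_r) <- paste0("m", 1:3)
  venn <- consensus(sets_r, m_min = 2)$venn
  for (r in seq_len(nrow(venn))) {
    pat <- as.integer(strsplit(venn$pattern[r], "")[[1]])
    expect_equal(venn$count[r],
                 sum(apply(flags, 1, function(f) all(as.integer(f) == pat))))
  }
  bad <- sets; bad$b$snp[1] <- "zzz"
  expect_error(consensus(bad), "different SNP universes")
})
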