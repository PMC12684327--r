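# A small self-contained offset scenario used by several tests: a landscape,
# truth-locus frequencies and an enriched RDA with a site-standardised
# climate, so canonical coefficients map site climate to axes exactly.
offset_scenario <- function(seed, n_loci = 800, beta = 1.5, noise_sd = 0.4,
                            shift = c(1, 0.3, 0, 0, 0)) {
  fx <- default_fixture(seed = seed, n_loci = n_loci, beta = beta)
  fr <- allele_freqs_by_pop(fx$genotypes)
  ord <- match(rownames(fr$freq), fx$landscape$site_names)
  std <- fit_standardizer(fx$landscape)
  cur_std <- standardize_climate(std, fx$landscape)
  cand <- fx$genotypes$variants$id[fx$truth$adaptive_loci]
  model <- enriched_rda(fr$freq[, fx$truth$adaptive_loci, drop = FALSE],
                        cur_std$site_env[ord, , drop = FALSE], n_perm = 0)
  fut <- simulate_future_climate(fx$landscape, shift, noise_sd = noise_sd,
                                 seed = seed + 500)
  list(fx = fx, fr = fr, ord = ord, std = std, cur_std = cur_std,
       fut = fut, model = model, cand = cand)
}

test_that("ensemble averaging is exact and reduces member noise", {
  ls <- simulate_landscape(c(10, 10), n_env = 2, n_sites = 3, seed = 1)
  expect_equal(ensemble_mean(list(ls, ls))$env, ls$env)
  neg <- ls; neg$env <- -ls$env
  expect_equal(max(abs(ensemble_mean(list(ls, neg))$env)), 0)
  mem <- lapply(1:4, function(i)
    simulate_future_climate(ls, c(0, 0), noise_sd = 1, seed = i))
  avg <- ensemble_mean(mem)
  v1 <- var(mem[[1]]$env[, 1] - ls$env[, 1])
  v4 <- var(avg$env[, 1] - ls$env[, 1])
  expect_gt(v1 / v4, 2.5); expect_lt(v1 / v4, 6)
  other <- simulate_landscape(c(8, 8), n_env = 2, n_sites = 3, seed = 2)
  expect_error(ensemble_mean(list(ls, other)), "grid mismatch")
})

test_that("the climate standardiser centres, scales and propagates shifts exactly", {
  ls <- simulate_landscape(c(12, 12), n_env = 3, n_sites = 4, seed = 2)
  std <- fit_standardizer(ls)
  cur <- standardize_climate(std, ls)
  expect_equal(unname(colMeans(cur$env)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(cur$env, 2, sd)), rep(1, 3), tolerance = 1e-12)
  fut <- simulate_future_climate(ls, c(2, 0, -1), noise_sd = 0)
  dif <- standardize_climate(std, fut)$env - cur$env
  expect_equal(unname(colMeans(dif)), unname(c(2, 0, -1) / std$sd), tolerance = 1e-12)
  flat <- ls; flat$env[, 2] <- 5
  expect_error(fit_standardizer(flat), "zero standard deviation.*env2")
})

test_that("projected compositions reproduce fitted site scores and are linear", {
  sc <- offset_scenario(seed = 31)
  # the model's predictors were site-centred internally; projection at the
  # training sites must return the fitted site scores
  comp <- project_composition(sc$model, sc$cur_std, K_axes = 2)
  site_cells <- sc$cur_std$site_cells[sc$ord]
  expect_equal(unname(comp$scores[site_cells, ]),
               unname(sc$model$site_scores[, 1:2]), tolerance = 1e-8)
  # linear in deviations from the training mean
  base <- sc$cur_std
  half <- base
  ctr <- rep(sc$model$x_center, each = nrow(base$env))
  half$env <- (base$env - ctr) * 0.5 + ctr
  comp_h <- project_composition(sc$model, half, K_axes = 2)
  expect_equal(comp_h$scores, comp$scores * 0.5, tolerance = 1e-10)
  bad <- base; bad$var_names <- paste0("x", 1:5); colnames(bad$env) <- bad$var_names
  expect_error(project_composition(sc$model, bad), "lacks model variable")
})

test_that("genomic offset has its closed-form limits and invariances", {
  sc <- offset_scenario(seed = 32)
  cur <- project_composition(sc$model, sc$cur_std, K_axes = 2, climate_id = "cur")
  off0 <- genomic_offset(cur, cur)
  expect_equal(max(off0$offset), 0)

  fut_std <- standardize_climate(sc$std, sc$fut)
  fut <- project_composition(sc$model, fut_std, K_axes = 2, climate_id = "fut")
  off <- genomic_offset(cur, fut)
  expect_true(all(off$offset >= 0))
  d <- cur$scores - fut$scores
  w <- cur$eig_frac
  expect_equal(off$offset, sqrt(d[, 1]^2 * w[1] + d[, 2]^2 * w[2]), tolerance = 1e-12)
  off_u <- genomic_offset(cur, fut, weights = "unit")
  expect_equal(off_u$offset, sqrt(rowSums(d^2)), tolerance = 1e-12)

  # single-axis model: offset is exactly sqrt(w1)*|delta score|
  m1 <- enriched_rda(sc$fr$freq[, sc$fx$truth$adaptive_loci, drop = FALSE],
                     sc$cur_std$site_env[sc$ord, 1, drop = FALSE], n_perm = 0)
  c1 <- project_composition(m1, sc$cur_std, K_axes = 1)
  f1 <- project_composition(m1, fut_std, K_axes = 1)
  o1 <- genomic_offset(c1, f1)
  expect_equal(o1$offset, abs(c1$scores[, 1] - f1$scores[, 1]), tolerance = 1e-12)

  # affine unit changes are absorbed by the standardiser
  aff <- function(ls) { ls$env <- sweep(sweep(ls$env, 2, c(1.8, 2, 0.5, 3, 1), `*`),
                                        2, c(32, -10, 5, 0, 100), `+`)
                        ls$site_env <- ls$env[ls$site_cells, , drop = FALSE]; ls }
  cur_a <- aff(sc$fx$landscape); fut_a <- aff(sc$fut)
  std_a <- fit_standardizer(cur_a)
  cur_std_a <- standardize_climate(std_a, cur_a)
  m_a <- enriched_rda(sc$fr$freq[, sc$fx$truth$adaptive_loci, drop = FALSE],
                      cur_std_a$site_env[sc$ord, , drop = FALSE], n_perm = 0)
  off_a <- genomic_offset(project_composition(m_a, cur_std_a, 2, "cur"),
                          project_composition(m_a, standardize_climate(std_a, fut_a), 2, "fut"))
  expect_equal(off_a$offset, off$offset, tolerance = 1e-8)

  # provenance guards
  other <- enriched_rda(sc$fr$freq[, sc$fx$truth$adaptive_loci[-1], drop = FALSE],
                        sc$cur_std$site_env[sc$ord, , drop = FALSE], n_perm = 0)
  cur_o <- project_composition(other, sc$cur_std, K_axes = 2)
  expect_error(genomic_offset(cur_o, fut), "different models")
})

test_that("offset scales monotonically with the climate shift", {
  sc <- offset_scenario(seed = 33)
  cur <- project_composition(sc$model, sc$cur_std, K_axes = 2)
  fut1_raw <- sc$fut
  fut2_raw <- sc$fut
  fut2_raw$env <- sc$fx$landscape$env + 2.5 * (sc$fut$env - sc$fx$landscape$env)
  fut2_raw$site_env <- fut2_raw$env[fut2_raw$site_cells, , drop = FALSE]
  o1 <- genomic_offset(cur, project_composition(sc$model,
                                                standardize_climate(sc$std, fut1_raw), 2))
  o2 <- genomic_offset(cur, project_composition(sc$model,
                                                standardize_climate(sc$std, fut2_raw), 2))
  expect_true(all(o2$offset >= o1$offset - 1e-12))
  expect_equal(o2$offset, 2.5 * o1$offset, tolerance = 1e-8)
})

test_that("coverage check flags exactly the cells outside the training range", {
  sc <- offset_scenario(seed = 34)
  train <- sc$cur_std$site_env
  cov <- coverage_check(train, sc$cur_std)
  E <- sc$cur_std$env[, colnames(train)]
  brute <- apply(E, 1, function(r) any(r < apply(train, 2, min) | r > apply(train, 2, max)))
  expect_equal(cov$flag, unname(brute))
  expect_equal(cov$fraction_flagged, mean(brute))
  site_cells <- sc$cur_std$site_cells
  expect_false(any(cov$flag[site_cells]))
  ext <- sc$cur_std
  ext$env[1, 1] <- max(train[, 1]) + 10
  cov2 <- coverage_check(train, ext)
  expect_true(cov2$flag[1])
  expect_match(cov2$offending[1], "env1")
})

test_that("vulnerability report ranks an exposed, low-diversity site first on both axes", {
  fx <- default_fixture(seed = 35, n_loci = 600)
  gm <- fx$genotypes
  cand_idx <- fx$truth$adaptive_loci
  cand <- gm$variants$id[cand_idx]
  # engineer site 1: nearly fixed at candidate loci (low adaptive capacity)
  s1 <- gm$samples$site == fx$landscape$site_names[1]
  gm$dosages[s1, cand_idx] <- 2L
  fr <- allele_freqs_by_pop(gm)
  ord <- match(rownames(fr$freq), fx$landscape$site_names)
  std <- fit_standardizer(fx$landscape)
  cur_std <- standardize_climate(std, fx$landscape)
  model <- enriched_rda(fr$freq[, cand_idx, drop = FALSE],
                        cur_std$site_env[ord, , drop = FALSE], n_perm = 0)
  # climate shifts only at site 1's grid cell
  fut <- fx$landscape
  cell1 <- fx$landscape$site_cells[1]
  fut$env[cell1, ] <- fut$env[cell1, ] + 8
  fut$site_env <- fut$env[fut$site_cells, , drop = FALSE]
  off <- genomic_offset(project_composition(model, cur_std, 2, "cur"),
                        project_composition(model, standardize_climate(std, fut), 2, "fut"))
  rep1 <- vulnerability_report(off, cand, gm, fx$landscape, g = 6)
  r1 <- rep1[rep1$group == fx$landscape$site_names[1], ]
  expect_equal(r1$offset_rank, 1)
  expect_equal(r1$diversity_rank, 1)
  # zero shift: offsets identically zero, capacity ranking still informative
  off0 <- genomic_offset(project_composition(model, cur_std, 2, "cur"),
                         project_composition(model, cur_std, 2, "cur2"))
  rep0 <- vulnerability_report(off0, cand, gm, fx$landscape, g = 6)
  expect_equal(max(rep0$offset), 0)
  expect_equal(rep0$diversity_rank[rep0$group == fx$landscape$site_names[1]], 1)
  # candidate-locus diversity equals a direct rerun on the same loci
  direct <- diversity_summary(subset_loci(gm, cand), gm$samples$site, g = 6,
                              accessible_sites_L = length(cand))
  expect_equal(rep1$H_E, direct$H_E[match(rep1$group, direct$group)], tolerance = 1e-12)
  expect_error(vulnerability_report(off, character(0), gm, fx$landscape), "empty")
})
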