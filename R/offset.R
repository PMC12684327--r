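# Adaptively-enriched RDA genomic offset: climate standardisation, ensemble
# averaging, projection of genomic composition over climate grids, the offset
# itself, climate-coverage validation and the vulnerability report.

#' Cell-wise mean of climate layers (GCM ensemble average)
#'
#' @param layers list of `landscape`s on identical grids with identical
#'   variables.
#' @return A `landscape`; a cell is missing if any member is missing there.
#' @export
ensemble_mean <- function(layers) {
  stop_if_not(length(layers) >= 1, "need at least one layer")
  ref <- layers[[1]]
  for (l in layers) {
    stop_if_not(identical(l$grid, ref$grid), "grid mismatch between ensemble members")
    stop_if_not(identical(l$var_names, ref$var_names), "variable mismatch between members")
  }
  out <- ref
  acc <- Reduce(`+`, lapply(layers, `[[`, "env"))
  out$env <- acc / length(layers)
  if (length(out$site_cells)) out$site_env <- out$env[out$site_cells, , drop = FALSE]
  out
}

#' Fit a climate standardiser on the current climate of a reference region
#'
#' Per-variable mean and standard deviation over the masked cells of the
#' current layer; the same transform is then applied to any layer with the
#' same variables (current and future alike), which is what makes genomic
#' compositions comparable through time.
#'
#' @param current a `landscape` (current climate).
#' @param region_mask logical vector over cells (default: all cells).
#' @return A `climate_standardizer`: list(mean, sd, var_names).
#' @export
fit_standardizer <- function(current, region_mask = NULL) {
  m <- region_mask %||% rep(TRUE, nrow(current$env))
  stop_if_not(sum(m) >= 2, "reference region needs at least two cells")
  sub <- current$env[m, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2L, sd)
  if (any(sdv == 0))
    stop(sprintf("zero standard deviation for variable(s): %s",
                 paste(current$var_names[sdv == 0], collapse = ", ")), call. = FALSE)
  structure(list(mean = mu, sd = sdv, var_names = current$var_names),
            class = "climate_standardizer")
}

#' Apply a climate standardiser to a landscape
#'
#' @param std a `climate_standardizer`.
#' @param landscape a `landscape` with the same variables.
#' @return The landscape with standardised `env` and `site_env`.
#' @export
standardize_climate <- function(std, landscape) {
  stop_if_not(identical(std$var_names, landscape$var_names),
              "standardiser and landscape variables differ")
  out <- landscape
  out$env <- sweep(sweep(landscape$env, 2L, std$mean, `-`), 2L, std$sd, `/`)
  if (length(out$site_cells)) out$site_env <- out$env[out$site_cells, , drop = FALSE]
  out
}

#' Adaptively enriched RDA of candidate-locus frequencies on climate
#'
#' Site-level allele frequencies of the consensus candidate loci regressed on
#' standardised current climate; a thin wrapper around [rda_fit()] that
#' checks the design is estimable and records which variables entered. Use
#' climate variables that have a future counterpart (time-invariant terrain
#' indices cannot enter an offset projection).
#'
#' @param candidate_freqs `allele_freq_table` or matrix (populations x
#'   candidate loci).
#' @param site_env_std standardised climate at the sites (populations x
#'   variables).
#' @param n_perm permutations for the model test.
#' @param seed RNG seed.
#' @return An `rda_model`.
#' @export
enriched_rda <- function(candidate_freqs, site_env_std, n_perm = 999L, seed = 1L) {
  Y <- if (inherits(candidate_freqs, "allele_freq_table")) candidate_freqs$freq else as.matrix(candidate_freqs)
  stop_if_not(ncol(Y) >= 1,
              "candidate set is empty: run the consensus step first (or lower m_min)")
  X <- as.matrix(site_env_std)
  stop_if_not(nrow(Y) > ncol(X),
              "need more sites (%d) than predictors (%d)", nrow(Y), ncol(X))
  if (anyNA(Y)) {
    for (l in which(colSums(is.na(Y)) > 0)) Y[is.na(Y[, l]), l] <- mean(Y[, l], na.rm = TRUE)
  }
  rda_fit(Y, X, n_perm = n_perm, seed = seed)
}

#' Project genomic composition scores over a climate grid
#'
#' score_k(cell) = sum_v coef[v, k] * (env_std_v(cell) - training mean of
#' env_std_v); at the training sites the projected scores equal the model's
#' fitted site scores. The climate layer must be standardised with the same
#' `climate_standardizer` the model's predictors were.
#'
#' @param model an `rda_model` from [enriched_rda()]/[rda_fit()].
#' @param climate_std a standardised `landscape` carrying the model's
#'   predictor variables.
#' @param K_axes number of axes to project (default 2).
#' @param climate_id label recorded for provenance (e.g. "current",
#'   "ssp245").
#' @return A `composition_scores`: list(scores cells x K, eig_frac, grid,
#'   model_id, climate_id).
#' @export
project_composition <- function(model, climate_std, K_axes = 2L, climate_id = "climate") {
  stop_if_not(all(model$predictors %in% climate_std$var_names),
              "climate layer lacks model variable(s): %s",
              paste(setdiff(model$predictors, climate_std$var_names), collapse = ", "))
  K <- min(K_axes, length(model$eig))
  stop_if_not(K >= 1, "model has no constrained axis")
  E <- climate_std$env[, model$predictors, drop = FALSE]
  Ec <- sweep(E, 2L, model$x_center, `-`)
  scores <- Ec %*% model$coef[, seq_len(K), drop = FALSE]
  structure(list(scores = scores,
                 eig_frac = model$eig[seq_len(K)] / sum(model$eig),
                 grid = climate_std$grid, model_id = model$model_id,
                 climate_id = climate_id),
            class = "composition_scores")
}

#' Genomic offset between two projected compositions
#'
#' offset(cell) = sqrt(sum_k w_k (cur_k - fut_k)^2), with w_k the eigenvalue
#' fraction of axis k (default) or 1 (unweighted). Both compositions must
#' come from the same model on the same grid.
#'
#' @param cur,fut `composition_scores` for current and future climate.
#' @param weights `"eigenvalue"` or `"unit"`.
#' @return An `offset_map`: list(offset per cell, grid, model_id,
#'   climate_ids, weights).
#' @export
genomic_offset <- function(cur, fut, weights = c("eigenvalue", "unit")) {
  weights <- match.arg(weights)
  stop_if_not(identical(cur$model_id, fut$model_id),
              "compositions come from different models")
  stop_if_not(identical(cur$grid, fut$grid), "compositions are on different grids")
  w <- if (weights == "eigenvalue") cur$eig_frac else rep(1, ncol(cur$scores))
  d <- cur$scores - fut$scores
  off <- sqrt(rowSums(sweep(d^2, 2L, w, `*`)))
  structure(list(offset = off, grid = cur$grid, model_id = cur$model_id,
                 climate_ids = c(cur$climate_id, fut$climate_id), weights = weights),
            class = "offset_map")
}

#' Flag grid cells outside the climate range the model was trained on
#'
#' A cell is an extrapolation cell if any model variable falls outside the
#' \[min, max\] range (optionally widened by `tolerance`) of the training-site
#' values. Flagged cells are reported, not masked.
#'
#' @param model_sites_env training-site climate (sites x variables,
#'   standardised like the grid).
#' @param climate_std standardised `landscape` to scan.
#' @param tolerance widening of the training range, in standardised units.
#' @return list(flag per cell, offending comma-joined variable names,
#'   fraction_flagged).
#' @export
coverage_check <- function(model_sites_env, climate_std, tolerance = 0) {
  E <- climate_std$env[, colnames(model_sites_env), drop = FALSE]
  lo <- apply(model_sites_env, 2L, min) - tolerance
  hi <- apply(model_sites_env, 2L, max) + tolerance
  out_lo <- sweep(E, 2L, lo, `<`)
  out_hi <- sweep(E, 2L, hi, `>`)
  bad <- out_lo | out_hi
  flag <- rowSums(bad) > 0
  offending <- apply(bad, 1L, function(r) paste(colnames(E)[r], collapse = ","))
  list(flag = flag, offending = offending, fraction_flagged = mean(flag))
}

#' Subset a geno_matrix to a set of loci
#'
#' @param gm a `geno_matrix`.
#' @param loci SNP ids (character) or column indices.
#' @return A `geno_matrix` restricted to those loci.
#' @export
subset_loci <- function(gm, loci) {
  idx <- if (is.character(loci)) match(loci, gm$variants$id) else as.integer(loci)
  stop_if_not(!anyNA(idx) && all(idx >= 1 & idx <= ncol(gm$dosages)),
              "unknown loci requested")
  keep <- rep(FALSE, ncol(gm$dosages)); keep[idx] <- TRUE
  subset_variants(gm, keep, "subset_loci")
}

#' Site vulnerability report: exposure (offset) and adaptive capacity
#'
#' Per site: the genomic offset at the site's grid cell, and diversity
#' statistics (H_O, H_E, F_IS, rarefied allelic richness, per-site pi)
#' computed on exactly the consensus candidate loci. Exposure and capacity
#' ranks are reported side by side, not aggregated into a single score
#' (offset_rank 1 = highest offset; diversity_rank 1 = lowest candidate-locus
#' H_E, i.e. least adaptive capacity).
#'
#' @param offset_map an `offset_map`.
#' @param consensus_members character vector of candidate SNP ids.
#' @param gm the (filtered) `geno_matrix`.
#' @param landscape the `landscape` carrying the site cells.
#' @param grouping population labels per individual (default: site).
#' @param g rarefaction size for allelic richness.
#' @param accessible_sites_L accessible length for pi (default: number of
#'   candidate loci).
#' @return data.frame, one row per group/site.
#' @export
vulnerability_report <- function(offset_map, consensus_members, gm, landscape,
                                 grouping = gm$samples$site, g = 12L,
                                 accessible_sites_L = length(consensus_members)) {
  stop_if_not(length(consensus_members) > 0, "consensus set is empty")
  sub <- subset_loci(gm, consensus_members)
  div <- diversity_summary(sub, grouping, g = g,
                           accessible_sites_L = accessible_sites_L)
  site_idx <- match(div$group, landscape$site_names)
  stop_if_not(!anyNA(site_idx), "grouping labels must be landscape sites")
  cells <- landscape$site_cells[site_idx]
  div$offset <- offset_map$offset[cells]
  div$offset_rank <- rank(-div$offset, ties.method = "min")
  div$diversity_rank <- rank(div$H_E, ties.method = "min")
  div
}
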