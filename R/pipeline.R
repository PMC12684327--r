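# End-to-end orchestration: simulate -> write/read fixture bundle -> filter ->
# diversity -> structure -> selection scans -> GEA -> consensus -> offset ->
# enrichment -> vulnerability report, with plain-file artifacts and JSON
# provenance. Every stage is also callable on its own through the exported
# module functions; this wrapper fixes the order and the bookkeeping.

#' Default pipeline configuration
#'
#' All analysis parameters at their standard values: LD pruning r2 = 0.4 in
#' 10 kb windows stepping 5 kb; missingness geno = 0 / mind = 0.1; K = 3
#' genetic clusters and latent factors; K_pc = 3 principal components for the
#' PC-regression scan; q < 0.05 outlier rule; |r| > 0.7 variable
#' decorrelation; forward selection at alpha = 0.01 with 999 permutations;
#' Bayes factor threshold 15 dB; RDA outliers on K = 2 axes at Bonferroni
#' 0.05; consensus at >= 4 methods; SNP-gene distance <= 1000 bp; GO Fisher
#' p < 0.01; allelic richness rarefied to 12 gene copies.
#'
#' @param n_loci,inds_per_site,prop_adaptive,beta,F_drift,F_group,n_sites,n_env,grid_shape,gradient_strength
#'   synthetic-study conditions (see [default_fixture()]).
#' @param n_perm permutations for RDA tests.
#' @param m_min consensus threshold (methods detecting).
#' @return Nested list of parameters.
#' @export
default_config <- function(n_loci = 5000L, inds_per_site = 8L, prop_adaptive = 0.01,
                           beta = 1.5, F_drift = 0.1, F_group = 0.05,
                           n_sites = 11L, n_env = 5L, grid_shape = c(40L, 40L),
                           gradient_strength = 2, n_perm = 999L, m_min = 4L) {
  list(
    sim = list(n_loci = n_loci, inds_per_site = inds_per_site,
               prop_adaptive = prop_adaptive, beta = beta, F_drift = F_drift,
               F_group = F_group, n_sites = n_sites, n_env = n_env,
               grid_shape = grid_shape, gradient_strength = gradient_strength,
               shift_moderate = c(1, 0.3, rep(0, n_env - 2)),
               severe_scale = 1.75, gcm_noise_sd = 0.3, n_gcm = 4L),
    params = list(r2_max = 0.4, window_bp = 10000, step_bp = 5000,
                  max_variant_missing = 0, max_sample_missing = 0.1,
                  K = 3L, K_pc = 3L, K_axes = 2L, bf_db = 15, q_max = 0.05,
                  alpha_bonf = 0.05, m_min = m_min, max_dist = 1000L,
                  g_rarefy = 12L, alpha_fs = 0.01, cor_threshold = 0.7,
                  n_perm = n_perm, n_env_points = 2000L)
  )
}

#' Run the full synthetic landscape-genomics pipeline
#'
#' Simulates the study, writes the fixture bundle, re-reads it through the
#' standard-format readers, filters, computes diversity and structure, runs
#' the five selection scans, forms the consensus, fits the adaptively
#' enriched RDA, projects genomic offset under a moderate and a severe
#' climate scenario, tests GO enrichment and writes the vulnerability
#' report. All artifacts are plain TSV/JSON/VCF files under `outdir`;
#' `provenance.json` records the seed, parameters and input hashes.
#'
#' @param outdir output directory.
#' @param seed single RNG seed; every stochastic step derives its stream
#'   from it.
#' @param config a [default_config()] list (possibly modified).
#' @return Invisible list with the in-memory results of every stage.
#' @export
run_pipeline <- function(outdir, seed = 1L, config = default_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params; sm <- config$sim
  tsv <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  ## simulate + fixture bundle
  fx <- default_fixture(seed = seed, n_loci = sm$n_loci,
                        inds_per_site = sm$inds_per_site,
                        prop_adaptive = sm$prop_adaptive, beta = sm$beta,
                        F_drift = sm$F_drift, F_group = sm$F_group,
                        n_sites = sm$n_sites, n_env = sm$n_env,
                        grid_shape = sm$grid_shape,
                        gradient_strength = sm$gradient_strength)
  scen <- list(moderate = sm$shift_moderate,
               severe = sm$shift_moderate * sm$severe_scale)
  futures <- lapply(names(scen), function(nm) {
    members <- lapply(seq_len(sm$n_gcm), function(i)
      simulate_future_climate(fx$landscape, scen[[nm]], noise_sd = sm$gcm_noise_sd,
                              seed = seed + 100L * match(nm, names(scen)) + i))
    ensemble_mean(members)
  })
  names(futures) <- names(scen)
  bundle <- write_fixture_bundle(fx$genotypes, fx$landscape, fx$truth,
                                 file.path(outdir, "bundle"),
                                 future = futures, seed = seed + 7L)

  ## read back through the standard readers, then filter
  gm <- read_vcf(bundle$vcf, bundle$samples)
  gm <- filter_info_thresholds(gm)
  gm <- filter_missingness(gm, p$max_variant_missing, p$max_sample_missing)
  gm <- exclude_intervals(gm, read_bed(bundle$te_bed))
  gm <- ld_prune(gm, p$r2_max, p$window_bp, p$step_bp)
  kin <- king_kinship(gm)

  ## diversity / differentiation
  div_group <- diversity_summary(gm, gm$samples$group, g = p$g_rarefy)
  div_site <- diversity_summary(gm, gm$samples$site, g = p$g_rarefy)
  fst <- wc_fst(gm, gm$samples$site)
  tsv(div_group, "diversity_groups.tsv"); tsv(div_site, "diversity_sites.tsv")
  tsv(data.frame(site = rownames(fst$pairwise), fst$pairwise, check.names = FALSE),
      "fst_pairwise.tsv")

  ## structure
  pca <- pca_genotypes(gm, K_pc = p$K_pc)
  clusters <- assign_groups_kmeans(pca, K = p$K, seed = seed + 21L)
  tsv(data.frame(sample_id = gm$samples$sample_id, site = gm$samples$site,
                 cluster = clusters, pca$scores), "pca_clusters.tsv")

  ## selection scans
  sc_pcadapt <- pcadapt_stat(gm, K_pc = p$K_pc, q_max = p$q_max)
  sc_fst <- fst_outlier(gm, gm$samples$site, q_max = p$q_max, seed = seed + 29L)

  ## GEA
  env_points <- fx$landscape$env[sample_env_points(nrow(fx$landscape$env),
                                                   p$n_env_points, seed + 33L), ,
                                 drop = FALSE]
  keep_vars <- decorrelate_vars(env_points, threshold = p$cor_threshold)$retained
  freqs <- allele_freqs_by_pop(gm, gm$samples$site)
  site_env <- fx$landscape$site_env[match(rownames(freqs$freq), fx$landscape$site_names),
                                    keep_vars, drop = FALSE]
  fs <- forward_select(freqs$freq, scale(site_env), alpha = p$alpha_fs,
                       n_perm = p$n_perm, seed = seed + 41L)
  gea_vars <- if (length(fs$selected)) fs$selected else keep_vars
  env_ind <- env_for_individuals(fx$landscape, gm, vars = gea_vars)
  sc_lfmm <- lfmm_scan(gm, env_ind, K = p$K, q_max = p$q_max)$combined
  sc_bf <- omega_bf(freqs, site_env[, gea_vars, drop = FALSE],
                    db_threshold = p$bf_db)$scores
  rda_scan <- rda_fit(standardize_freqs(freqs), scale(site_env[, gea_vars, drop = FALSE]),
                      n_perm = p$n_perm, seed = seed + 43L)
  sc_rda <- rda_outliers(rda_scan, K_axes = min(p$K_axes, length(rda_scan$eig)),
                         alpha_bonf = p$alpha_bonf)

  ## consensus
  sets <- list(pcadapt = sc_pcadapt, fst = sc_fst, lfmm = sc_lfmm,
               bayes_factor = sc_bf, rda = sc_rda)
  cons <- consensus(sets, m_min = p$m_min)
  tsv(cons$table, "consensus.tsv"); tsv(cons$venn, "venn_counts.tsv")

  ## variance partitioning (environment | geography | ancestry)
  geog <- as.matrix(fx$landscape$site_coords[match(rownames(freqs$freq),
                                                   fx$landscape$site_names), ])
  colnames(geog) <- c("lat", "lon")
  site_cluster <- vapply(rownames(freqs$freq), function(s) {
    cl <- clusters[gm$samples$site == s]
    as.numeric(names(sort(table(cl), decreasing = TRUE))[1])
  }, numeric(1))
  genet <- stats::model.matrix(~ factor(site_cluster))[, -1, drop = FALSE]
  vp <- tryCatch(variance_partition(freqs$freq, scale(site_env[, gea_vars, drop = FALSE]),
                                    scale(geog), genet,
                                    n_perm = p$n_perm, seed = seed + 47L),
                 error = function(e) NULL)
  if (!is.null(vp)) tsv(vp$table, "variance_partition.tsv")

  ## genomic offset (moderate + severe scenarios)
  std <- fit_standardizer(fx$landscape)
  cur_std <- standardize_climate(std, fx$landscape)
  cand <- cons$members
  offs <- NULL; vuln <- list(); erda <- NULL; covr <- NULL
  if (length(cand) > 0) {
    cand_freqs <- freqs$freq[, match(cand, colnames(freqs$freq)), drop = FALSE]
    erda <- enriched_rda(cand_freqs,
                         cur_std$site_env[match(rownames(freqs$freq), cur_std$site_names),
                                          gea_vars, drop = FALSE],
                         n_perm = p$n_perm, seed = seed + 51L)
    cur_comp <- project_composition(erda, cur_std, K_axes = p$K_axes, "current")
    covr <- coverage_check(cur_std$site_env[, gea_vars, drop = FALSE], cur_std)
    offs <- list()
    for (nm in names(futures)) {
      fut_std <- standardize_climate(std, futures[[nm]])
      fut_comp <- project_composition(erda, fut_std, K_axes = p$K_axes, nm)
      offs[[nm]] <- genomic_offset(cur_comp, fut_comp)
      vuln[[nm]] <- vulnerability_report(offs[[nm]], cand, gm, fx$landscape,
                                         gm$samples$site, g = p$g_rarefy)
      tsv(cbind(offset_grid_df(offs[[nm]]), extrapolation = covr$flag),
          sprintf("offset_%s.tsv", nm))
      tsv(vuln[[nm]], sprintf("vulnerability_%s.tsv", nm))
    }
  }

  ## GO enrichment of consensus candidates
  genes <- read_gff_genes(bundle$gff)
  go_map <- read_gene2go(bundle$gene2go)
  snp_gene <- map_snps_to_genes(gm, genes, max_dist = p$max_dist)
  go <- NULL
  if (length(cand) > 0) {
    cand_genes <- unique(snp_gene$gene_id[snp_gene$snp %in% cand])
    if (length(cand_genes) > 0) {
      go <- go_fisher(cand_genes, unique(genes$gene_id), go_map, alpha = 0.01)
      tsv(go, "go_enrichment.tsv")
    }
  }

  prov <- list(seed = seed, config = config,
               config_hash = obj_fingerprint(config),
               inputs = as.list(tools::md5sum(unlist(bundle[c("vcf", "samples", "te_bed",
                                                              "gff", "gene2go")]))),
               filter_log = gm$log,
               n_snps_postfilter = ncol(gm$dosages),
               n_consensus = length(cand))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(fixture = fx, bundle = bundle, genotypes = gm, kinship = kin,
                 diversity = list(group = div_group, site = div_site), fst = fst,
                 pca = pca, clusters = clusters,
                 scans = sets, consensus = cons, forward_selection = fs,
                 variance_partition = vp, enriched_rda = erda, offsets = offs,
                 coverage = covr, vulnerability = vuln,
                 snp_gene = snp_gene, go = go, provenance = prov))
}

sample_env_points <- function(n_cells, n_points, seed) {
  if (n_points >= n_cells) return(seq_len(n_cells))
  with_seed(seed, sample.int(n_cells, n_points))
}

offset_grid_df <- function(offset_map) {
  nc <- offset_map$grid[2]
  cells <- seq_along(offset_map$offset)
  data.frame(row = (cells - 1L) %/% nc + 1L, col = (cells - 1L) %% nc + 1L,
             offset = offset_map$offset)
}
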