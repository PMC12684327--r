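# Synthetic landscapes, genotypes and future climates.
#
# The generator gives every downstream stage a testable substrate with the
# statistical structure the analysis assumes: smooth environmental gradients,
# Balding-Nichols drift around ancestral allele frequencies (optionally with a
# latent group level), and a minority of adaptive loci whose per-site
# frequencies track one environmental variable on the logit scale.

#' Simulate a gridded environmental landscape with sampling sites
#'
#' Each environmental layer is a linear spatial gradient with a random
#' orientation plus smooth (Gaussian-filtered) noise. The gradient component
#' is standardised to unit spatial standard deviation and multiplied by
#' `gradient_strength`, the smoothed noise to `noise_sd`; `gradient_strength = 0`
#' therefore yields spatially uncorrelated-in-expectation layers, while large
#' values give layers almost perfectly correlated with the gradient axis.
#' Sampling sites are drawn uniformly over grid cells without replacement.
#'
#' @param grid_shape integer (rows, cols), both >= 4.
#' @param n_env number of environmental variables (>= 1).
#' @param n_sites number of sampling sites to place on the grid.
#' @param gradient_strength spatial-trend standard deviation (arbitrary units).
#' @param noise_sd standard deviation of the smoothed noise component.
#' @param smooth_sigma Gaussian smoothing radius (cells) for the noise field.
#' @param seed RNG seed; all output is a pure function of the arguments.
#' @param var_names labels for the environmental variables.
#' @return A `landscape`: list with `grid` (rows, cols), `env` (cells x n_env
#'   matrix, cell index = (row-1)*cols + col), `var_names`, `site_cells`,
#'   `site_coords` (row, col), `site_names`, and `site_env` (sites x n_env).
#'   The drawn gradient orientations are kept in attribute `gradient_theta`.
#' @export
simulate_landscape <- function(grid_shape = c(40L, 40L), n_env = 5L, n_sites = 11L,
                               gradient_strength = 2, noise_sd = 1,
                               smooth_sigma = 1.5, seed = 1L,
                               var_names = paste0("env", seq_len(n_env))) {
  stop_if_not(length(grid_shape) == 2 && all(grid_shape >= 4), "grid_shape must be at least (4, 4)")
  stop_if_not(n_env >= 1, "n_env must be >= 1")
  nr <- as.integer(grid_shape[1]); nc <- as.integer(grid_shape[2])
  n_cells <- nr * nc
  stop_if_not(n_sites <= n_cells, "more sites requested (%d) than grid cells (%d)", n_sites, n_cells)

  with_seed(seed, {
    # cell index = (row-1)*nc + col (row-major)
    coords <- cbind(row = rep(seq_len(nr), each = nc), col = rep(seq_len(nc), times = nr))
    env <- matrix(0, n_cells, n_env, dimnames = list(NULL, var_names))
    theta <- runif(n_env, 0, 2 * pi)
    for (v in seq_len(n_env)) {
      proj <- cos(theta[v]) * (coords[, "col"] - (nc + 1) / 2) / nc +
              sin(theta[v]) * (coords[, "row"] - (nr + 1) / 2) / nr
      if (sd(proj) > 0) proj <- proj / sd(proj)
      noise <- matrix(rnorm(n_cells), nr, nc)
      noise <- gaussian_blur(noise, smooth_sigma)
      noise <- as.vector(t(noise))  # row-major to match cell index
      if (sd(noise) > 0) noise <- noise / sd(noise)
      env[, v] <- gradient_strength * proj + noise_sd * noise
    }
    site_cells <- sample.int(n_cells, n_sites)
    site_coords <- data.frame(row = (site_cells - 1L) %/% nc + 1L,
                              col = (site_cells - 1L) %% nc + 1L)
    ls <- structure(list(
      grid = c(nr, nc),
      env = env,
      var_names = var_names,
      site_cells = site_cells,
      site_coords = site_coords,
      site_names = sprintf("site%02d", seq_len(n_sites)),
      site_env = env[site_cells, , drop = FALSE]
    ), class = "landscape")
    attr(ls, "gradient_theta") <- theta
    ls
  })
}

#' Grid-cell index for (row, col) positions of a landscape
#' @param landscape a `landscape`.
#' @param row,col integer vectors of grid positions.
#' @export
cell_index <- function(landscape, row, col) {
  nc <- landscape$grid[2]
  stop_if_not(all(row >= 1 & row <= landscape$grid[1] & col >= 1 & col <= nc),
              "position outside the grid")
  (as.integer(row) - 1L) * nc + as.integer(col)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d grid, %d env variables (%s), %d sites\n",
              x$grid[1], x$grid[2], ncol(x$env),
              paste(x$var_names, collapse = ", "), length(x$site_cells)))
  invisible(x)
}

#' Sampling design: individuals per site and latent group membership
#'
#' Groups are contiguous blocks of sites along the west-east (column) axis,
#' mirroring a longitudinal structuring of genetic groups; with
#' `n_groups = 3` they are labelled West/Central/East.
#'
#' @param landscape a `landscape` carrying the site coordinates.
#' @param inds_per_site diploid individuals per site (recycled to n_sites).
#' @param n_groups number of latent genetic groups.
#' @return A `site_design`: list(n_sites, inds_per_site, group_of_site, site_names).
#' @export
site_design <- function(landscape, inds_per_site = 8L, n_groups = 3L) {
  n_sites <- length(landscape$site_cells)
  inds <- rep_len(as.integer(inds_per_site), n_sites)
  stop_if_not(all(inds >= 1), "every site needs at least one individual")
  labels <- if (n_groups == 3) c("West", "Central", "East") else sprintf("G%d", seq_len(n_groups))
  ord <- order(landscape$site_coords$col, landscape$site_coords$row)
  grp <- character(n_sites)
  chunks <- split(ord, cut(seq_len(n_sites), n_groups, labels = FALSE))
  for (g in seq_along(chunks)) grp[chunks[[g]]] <- labels[g]
  structure(list(n_sites = n_sites, inds_per_site = inds,
                 group_of_site = grp, site_names = landscape$site_names),
            class = "site_design")
}

#' Simulate genotypes under Balding-Nichols drift with planted adaptive loci
#'
#' Ancestral alternate-allele frequencies are Uniform(0.05, 0.95). Neutral
#' per-site frequencies follow the Balding-Nichols model
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with `F = F_drift` (total site-level
#' differentiation). With `F_group > 0` a latent group level is inserted:
#' group frequencies drift from the ancestral value with `F_group`, sites
#' from their group with the within-group F solving
#' (1 - F_drift) = (1 - F_group)(1 - F_within), so the expected multilocus
#' site-level F_ST stays F_drift. Adaptive loci receive a logit shift
#' `beta * z` before site-level sampling, where `z` is the site value of the
#' driver variable standardised across sites. Genotypes are Binomial(2, p_site)
#' per individual. Loci monomorphic across all individuals are resampled up to
#' `max_resample` times, then kept and flagged.
#'
#' @param landscape a `landscape`.
#' @param design a `site_design`.
#' @param n_loci number of bi-allelic loci.
#' @param prop_adaptive proportion of loci given an environmental effect, in \[0, 1).
#' @param beta adaptive effect size, logit units per standardised env unit.
#' @param F_drift total site-level Balding-Nichols differentiation, in (0, 1).
#' @param F_group differentiation assigned to the latent group level, in
#'   \[0, F_drift); 0 disables the group level.
#' @param driver_var index (or indices, recycled) of the environmental variable
#'   each adaptive locus tracks.
#' @param max_resample resampling attempts for monomorphic loci.
#' @param seed RNG seed.
#' @return list(genotypes = `geno_matrix`, truth = `truth_table`). The truth
#'   table records adaptive locus indices, per-locus effect sizes (zero off
#'   the adaptive set), driver variables, the drift parameters and a
#'   monomorphic flag.
#' @export
simulate_genotypes <- function(landscape, design, n_loci = 5000L,
                               prop_adaptive = 0.01, beta = 1.5,
                               F_drift = 0.1, F_group = 0,
                               driver_var = 1L, max_resample = 10L, seed = 1L) {
  stop_if_not(prop_adaptive >= 0 && prop_adaptive < 1, "prop_adaptive must be in [0, 1)")
  stop_if_not(F_drift > 0 && F_drift < 1, "F_drift must be in (0, 1)")
  stop_if_not(F_group >= 0 && F_group < 1, "F_group must be in [0, 1)")
  if (F_group > 0) stop_if_not(F_group < F_drift, "F_group must be smaller than F_drift")
  n_sites <- design$n_sites
  stop_if_not(n_sites == length(landscape$site_cells), "design and landscape disagree on sites")

  n_ad <- round(n_loci * prop_adaptive)
  if (prop_adaptive > 0 && n_ad < 1) {
    warning("n_loci * prop_adaptive < 1; simulating zero adaptive loci")
    n_ad <- 0L
  }

  F_within <- if (F_group > 0) 1 - (1 - F_drift) / (1 - F_group) else F_drift
  z_env <- scale(landscape$site_env)  # sites x n_env, standardised across sites
  groups <- unique(design$group_of_site)
  g_of_site <- match(design$group_of_site, groups)
  n_ind <- sum(design$inds_per_site)
  site_of_ind <- rep(seq_len(n_sites), times = design$inds_per_site)

  with_seed(seed, {
    adaptive <- if (n_ad > 0) sort(sample.int(n_loci, n_ad)) else integer(0)
    drivers <- rep(NA_integer_, n_loci)
    if (n_ad > 0) drivers[adaptive] <- rep_len(as.integer(driver_var), n_ad)
    effects <- numeric(n_loci)
    effects[adaptive] <- beta

    draw_loci <- function(idx) {
      # returns list(p_anc, dosages submatrix n_ind x length(idx))
      L <- length(idx)
      p_anc <- runif(L, 0.05, 0.95)
      if (F_group > 0) {
        pg <- matrix(rbeta(length(groups) * L,
                           rep(p_anc, each = length(groups)) * (1 - F_group) / F_group,
                           rep(1 - p_anc, each = length(groups)) * (1 - F_group) / F_group),
                     nrow = length(groups))
      } else {
        pg <- matrix(rep(p_anc, each = length(groups)), nrow = length(groups))
      }
      m <- pg[g_of_site, , drop = FALSE]  # site-level means, n_sites x L
      # adaptive loci: the environment shifts the site-level mean frequency on
      # the logit scale before the drift draw
      is_ad <- idx %in% adaptive
      if (any(is_ad)) {
        cols <- which(is_ad)
        dv <- drivers[idx[cols]]
        shift <- z_env[, dv, drop = FALSE] * rep(effects[idx[cols]], each = n_sites)
        m[, cols] <- plogis(qlogis(pmin(pmax(m[, cols], 1e-9), 1 - 1e-9)) + shift)
      }
      m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
      p_site <- matrix(rbeta(n_sites * L, m * (1 - F_within) / F_within,
                             (1 - m) * (1 - F_within) / F_within),
                       nrow = n_sites)
      p_site <- pmin(pmax(p_site, 0), 1)
      P <- p_site[site_of_ind, , drop = FALSE]
      dos <- matrix(rbinom(n_ind * L, 2L, as.vector(P)), nrow = n_ind)
      list(p_anc = p_anc, dos = dos)
    }

    first <- draw_loci(seq_len(n_loci))
    dosages <- first$dos
    p_anc <- first$p_anc
    mono <- function(d) apply(d, 2L, function(x) length(unique(x)) == 1L)
    bad <- which(mono(dosages))
    tries <- 0L
    while (length(bad) > 0 && tries < max_resample) {
      redo <- draw_loci(bad)
      dosages[, bad] <- redo$dos
      p_anc[bad] <- redo$p_anc
      bad <- bad[mono(dosages[, bad, drop = FALSE])]
      tries <- tries + 1L
    }
    monomorphic <- logical(n_loci)
    monomorphic[bad] <- TRUE

    pos <- cumsum(sample(50:200, n_loci, replace = TRUE)) + 1000L
    variants <- data.frame(
      chrom = "chr1", pos = as.integer(pos),
      id = sprintf("snp%05d", seq_len(n_loci)),
      ref = "A", alt = "T",
      QUAL = 100, QD = 25, FS = 1, SOR = 1,
      stringsAsFactors = FALSE
    )
    sample_ids <- unlist(lapply(seq_len(n_sites), function(s)
      sprintf("%s_i%02d", design$site_names[s], seq_len(design$inds_per_site[s]))))
    samples <- data.frame(
      sample_id = sample_ids,
      site = design$site_names[site_of_ind],
      group = design$group_of_site[site_of_ind],
      stringsAsFactors = FALSE
    )
    gm <- geno_matrix(dosages, variants, samples)
    truth <- structure(list(
      adaptive_loci = adaptive,
      effect_sizes = effects,
      driver_var = drivers,
      F_drift = F_drift, F_group = F_group,
      monomorphic = monomorphic
    ), class = "truth_table")
    list(genotypes = gm, truth = truth)
  })
}

#' Simulate a future climate layer from a current landscape
#'
#' `future = current + shift + noise`, on the same grid and with the same
#' sites; per-site values are re-read off the shifted grid. Emulates one
#' global climate model (GCM) realisation; average several with
#' [ensemble_mean()].
#'
#' @param landscape current `landscape`.
#' @param shift_per_var numeric, one mean shift per environmental variable.
#' @param noise_sd standard deviation of cell-level noise added to each layer.
#' @param seed RNG seed.
#' @param shift_field optional cells x n_env matrix (or `landscape`) of
#'   spatially varying shifts added on top of `shift_per_var`; use it to give
#'   scenarios a shared spatial change pattern.
#' @return A `landscape` with shifted `env`/`site_env`.
#' @export
simulate_future_climate <- function(landscape, shift_per_var, noise_sd = 0, seed = 1L,
                                    shift_field = NULL) {
  n_env <- ncol(landscape$env)
  stop_if_not(length(shift_per_var) == n_env,
              "shift_per_var must have one entry per environmental variable (%d)", n_env)
  if (inherits(shift_field, "landscape")) shift_field <- shift_field$env
  if (!is.null(shift_field))
    stop_if_not(all(dim(shift_field) == dim(landscape$env)),
                "shift_field must match the climate grid")
  with_seed(seed, {
    fut <- landscape
    n_cells <- nrow(fut$env)
    fut$env <- fut$env + rep(shift_per_var, each = n_cells) +
      (shift_field %||% 0) +
      matrix(rnorm(n_cells * n_env, 0, noise_sd), n_cells, n_env)
    fut$site_env <- fut$env[fut$site_cells, , drop = FALSE]
    fut
  })
}

#' Default synthetic study: 11 sites, planted adaptive loci
#'
#' One call builds the landscape, design, genotypes and truth table used
#' throughout the package's examples and tests: an 11-site, 8-individuals-per-
#' site sample of 5,000 bi-allelic loci on a 40 x 40 grid with 5 environmental
#' variables, Balding-Nichols site differentiation F_ST = 0.1, and 1\% of
#' loci tracking the first environmental variable with effect size `beta`.
#' By default all differentiation is at the site level (the island model the
#' estimators and outlier nulls are built on); set `F_group > 0` to place
#' part of it on a 3-group latent level (distinct West/Central/East genetic
#' clusters, recoverable by [assign_groups_kmeans()]).
#'
#' @param seed RNG seed (landscape and genotypes derive distinct streams).
#' @param n_loci,inds_per_site,prop_adaptive,beta,F_drift,F_group,n_sites,n_env,grid_shape,gradient_strength
#'   overrides of the study conditions.
#' @return list(landscape, design, genotypes, truth).
#' @export
default_fixture <- function(seed = 1L, n_loci = 5000L, inds_per_site = 8L,
                            prop_adaptive = 0.01, beta = 1.5,
                            F_drift = 0.1, F_group = 0,
                            n_sites = 11L, n_env = 5L, grid_shape = c(40L, 40L),
                            gradient_strength = 2) {
  ls <- simulate_landscape(grid_shape = grid_shape, n_env = n_env, n_sites = n_sites,
                           gradient_strength = gradient_strength, seed = seed)
  dsn <- site_design(ls, inds_per_site = inds_per_site, n_groups = 3L)
  sim <- simulate_genotypes(ls, dsn, n_loci = n_loci, prop_adaptive = prop_adaptive,
                            beta = beta, F_drift = F_drift, F_group = F_group,
                            driver_var = 1L, seed = seed + 1000L)
  list(landscape = ls, design = dsn, genotypes = sim$genotypes, truth = sim$truth)
}

#' Write a fixture bundle (VCF, site map, env tables, GFF3, GO map, TE BED)
#'
#' Emits the on-disk shape the pipeline readers expect: a VCFv4.2 with one
#' pseudo-chromosome and positions spaced 50-200 bp apart (so LD windows are
#' exercisable), a sample/site TSV, current (and optionally future) gridded
#' and per-site environment TSVs with a JSON grid header, a toy GFF3 with
#' genes placed at known offsets from a subset of loci, a gene-to-GO-term TSV,
#' a transposable-element BED constructed to cover a known subset of variants,
#' and a JSON sidecar recording seeds and parameters.
#'
#' @param genotypes a `geno_matrix`.
#' @param landscape current `landscape`.
#' @param truth a `truth_table` (recorded in the sidecar).
#' @param outdir output directory (created if needed).
#' @param future optional future `landscape` (or named list of them).
#' @param n_genes genes to place in the toy GFF3.
#' @param te_fraction fraction of variants to cover with TE intervals.
#' @param seed RNG seed for gene/TE placement.
#' @return list of file paths plus `te_covered` (indices of variants inside a
#'   TE interval) and `gene_near_snp` (gene placement table).
#' @export
write_fixture_bundle <- function(genotypes, landscape, truth, outdir,
                                 future = NULL, n_genes = 100L,
                                 te_fraction = 0.05, seed = 1L) {
  gm <- genotypes
  n_loci <- nrow(gm$variants)
  stop_if_not(ncol(gm$dosages) == n_loci, "genotype matrix is inconsistent")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(outdir), "cannot create output directory %s", outdir)
  pth <- function(f) file.path(outdir, f)

  paths <- list(vcf = pth("genotypes.vcf"), samples = pth("samples.tsv"),
                env_sites = pth("env_sites_current.tsv"),
                env_grid = pth("env_grid_current.tsv"),
                grid_header = pth("env_grid_header.json"),
                gff = pth("genes.gff3"), gene2go = pth("gene2go.tsv"),
                te_bed = pth("te.bed"), params = pth("params.json"))

  write_vcf(gm, paths$vcf)

  smp <- gm$samples
  site_idx <- match(smp$site, landscape$site_names)
  smp$lon <- landscape$site_coords$col[site_idx]
  smp$lat <- landscape$site_coords$row[site_idx]
  write.table(smp, paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)

  env_sites <- data.frame(site = landscape$site_names,
                          row = landscape$site_coords$row,
                          col = landscape$site_coords$col,
                          landscape$site_env, check.names = FALSE)
  write.table(env_sites, paths$env_sites, sep = "\t", quote = FALSE, row.names = FALSE)
  write_env_grid(landscape, paths$env_grid)
  jsonlite::write_json(list(grid = landscape$grid, var_names = landscape$var_names),
                       paths$grid_header, auto_unbox = FALSE)

  if (!is.null(future)) {
    futs <- if (inherits(future, "landscape")) list(future = future) else future
    paths$env_grid_future <- character(0)
    for (nm in names(futs)) {
      fp <- pth(sprintf("env_grid_%s.tsv", nm))
      write_env_grid(futs[[nm]], fp)
      paths$env_grid_future <- c(paths$env_grid_future, fp)
    }
  }

  res <- with_seed(seed, {
    # toy genes: every k-th SNP gets a gene at a known offset (some inside,
    # some at the 1000-bp mapping boundary)
    k <- max(1L, n_loci %/% n_genes)
    gene_snps <- seq(1L, n_loci, by = k)[seq_len(min(n_genes, n_loci))]
    offsets <- sample(c(0L, 100L, 500L, 999L, 1000L, 1001L, 1500L),
                      length(gene_snps), replace = TRUE)
    gpos <- gm$variants$pos[gene_snps]
    gstart <- gpos + offsets; gstart[offsets == 0L] <- pmax(1L, gpos[offsets == 0L] - 100L)
    gend <- gstart + 399L
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_along(gene_snps)),
                        chrom = gm$variants$chrom[gene_snps],
                        start = gstart, end = gend,
                        snp_index = gene_snps, offset = offsets)
    gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end),
                                 strand = "+")
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$Name <- genes$gene_id
    rtracklayer::export(gr, paths$gff, format = "gff3")

    go_pool <- sprintf("GO:%07d", 1:20)
    g2g <- do.call(rbind, lapply(genes$gene_id, function(g) {
      data.frame(gene_id = g, go_id = sample(go_pool, sample(1:4, 1)))
    }))
    write.table(g2g, paths$gene2go, sep = "\t", quote = FALSE, row.names = FALSE)

    n_te <- max(1L, round(te_fraction * n_loci))
    te_snps <- sort(sample.int(n_loci, n_te))
    te <- data.frame(chrom = gm$variants$chrom[te_snps],
                     start = gm$variants$pos[te_snps] - 6L,   # 0-based half-open
                     end = gm$variants$pos[te_snps] + 5L)
    te_gr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start + 1L, te$end))
    rtracklayer::export(te_gr, paths$te_bed, format = "bed")
    # which variants fall inside a TE interval (by construction; spacing >= 50
    # bp keeps intervals from touching neighbouring SNPs)
    list(te_covered = te_snps, gene_near_snp = genes)
  })

  jsonlite::write_json(list(
    seed = seed, n_loci = n_loci, n_samples = nrow(gm$samples),
    adaptive_loci = truth$adaptive_loci, effect_sizes = truth$effect_sizes[truth$adaptive_loci],
    driver_var = truth$driver_var[truth$adaptive_loci],
    F_drift = truth$F_drift, F_group = truth$F_group,
    te_covered = res$te_covered
  ), paths$params, auto_unbox = TRUE)

  c(paths, res)
}

write_env_grid <- function(landscape, path) {
  nc <- landscape$grid[2]
  cells <- seq_len(nrow(landscape$env))
  df <- data.frame(row = (cells - 1L) %/% nc + 1L, col = (cells - 1L) %% nc + 1L,
                   landscape$env, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gridded environment TSV (with its JSON header) back as a landscape
#'
#' @param grid_path TSV written by [write_fixture_bundle()].
#' @param header_path JSON header with grid shape and variable names.
#' @param site_coords optional data.frame(row, col) of sites to re-attach.
#' @param site_names optional site labels.
#' @return A `landscape`.
#' @export
read_env_grid <- function(grid_path, header_path, site_coords = NULL, site_names = NULL) {
  hd <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  df <- read.delim(grid_path, check.names = FALSE)
  nr <- hd$grid[1]; nc <- hd$grid[2]
  env <- as.matrix(df[, hd$var_names, drop = FALSE])
  ord <- order(df$row, df$col)  # cell index = (row-1)*nc + col
  env <- env[ord, , drop = FALSE]
  ls <- structure(list(grid = c(nr, nc), env = env, var_names = hd$var_names,
                       site_cells = integer(0),
                       site_coords = data.frame(row = integer(0), col = integer(0)),
                       site_names = character(0),
                       site_env = env[integer(0), , drop = FALSE]),
                  class = "landscape")
  if (!is.null(site_coords)) {
    ls$site_cells <- cell_index(ls, site_coords$row, site_coords$col)
    ls$site_coords <- site_coords
    ls$site_names <- site_names %||% sprintf("site%02d", seq_len(nrow(site_coords)))
    ls$site_env <- env[ls$site_cells, , drop = FALSE]
  }
  ls
}
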