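write_tiny_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti001\ti002",
    "chr1\t100\tv1\tA\tT\t99\tPASS\tQD=30\tGT\t0/0\t0/1",
    "chr1\t200\tv2\tA\tT\t99\tPASS\tQD=30\tGT\t1/1\t./.",
    "chr1\t300\tv3\tA\tT,G\t99\tPASS\tQD=30\tGT\t0/1\t0/2",
    "chr1\t400\tv4\tA\tC\t99\tPASS\tQD=30\tGT\t0|1\t1|1"
  )
  writeLines(lines, path)
  path
}

tiny_site_map <- data.frame(sample_id = c("i001", "i002"),
                            site = c("siteA", "siteB"))

test_that("VCF reading converts GT to dosage, drops multi-allelic records", {
  path <- write_tiny_vcf(withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(path, tiny_site_map)
  expect_equal(ncol(gm$dosages), 3L)  # v3 excluded
  expect_equal(unname(gm$dosages[, "v1"]), c(0L, 1L))
  expect_equal(unname(gm$dosages[, "v2"]), c(2L, NA))
  expect_equal(unname(gm$dosages[, "v4"]), c(1L, 2L))
  expect_equal(gm$log[[1]]$n_multiallelic_removed, 1L)
  expect_equal(gm$variants$QD, rep(30, 3))
  expect_error(read_vcf(path, data.frame(sample_id = "i001", site = "siteA")),
               "absent from site map")
})

test_that("fixture bundles round-trip bit-exactly through the VCF reader", {
  fx <- default_fixture(seed = 8, n_loci = 300, inds_per_site = 4)
  outdir <- withr::local_tempdir()
  bundle <- write_fixture_bundle(fx$genotypes, fx$landscape, fx$truth, outdir)
  gm2 <- read_vcf(bundle$vcf, bundle$samples)
  expect_identical(unname(gm2$dosages), unname(fx$genotypes$dosages))
  expect_identical(gm2$variants$pos, fx$genotypes$variants$pos)
  expect_identical(gm2$samples$site, fx$genotypes$samples$site)
})

test_that("INFO threshold filters remove exactly the violating records", {
  d <- matrix(1L, 2, 6)
  gm <- make_gm(d, QD = c(1.9, 2.0, 25, 25, 25, 25),
                FS = c(1, 1, 61, 1, 1, 1), SOR = c(1, 1, 1, 3.1, 1, 1))
  gm$variants$QUAL <- c(100, 100, 100, 100, 49.9, 50)
  out <- filter_info_thresholds(gm)
  # QD=1.9, FS=61, SOR=3.1 and QUAL=49.9 each removed; boundary values kept
  expect_equal(out$variants$id, gm$variants$id[c(2, 6)])
  passing <- filter_info_thresholds(out)
  expect_identical(passing$dosages, out$dosages)
  gm_nofield <- make_gm(d)
  expect_error(filter_info_thresholds(gm_nofield, list(list("QD", "<", 2))), "absent")
  expect_equal(ncol(filter_info_thresholds(gm_nofield, list(list("QD", "<", 2)),
                                           on_missing = "keep")$dosages), 6)
})

test_that("threshold rules removing disjoint subsets match the set-algebra oracle", {
  gm <- random_gm(4, 30, seed = 3)
  gm$variants$QD <- rep(25, 30); gm$variants$QD[1:5] <- 1
  gm$variants$FS <- rep(1, 30); gm$variants$FS[6:9] <- 99
  gm$variants$SOR <- rep(1, 30); gm$variants$SOR[10:12] <- 9
  out <- filter_info_thresholds(gm)
  expect_equal(out$variants$id, gm$variants$id[setdiff(1:30, 1:12)])
  counts <- out$log[[length(out$log)]]$per_rule
  expect_equal(unname(unlist(counts[c("QD < 2", "FS > 60", "SOR > 3")])), c(5, 4, 3))
})

test_that("missingness filters apply variant rule first, then sample rule", {
  d <- matrix(1L, 10, 20)
  d[1, 1] <- NA          # removes SNP 1 under geno = 0
  gm <- make_gm(d)
  out <- filter_missingness(gm)
  expect_equal(ncol(out$dosages), 19)
  # with geno = 0 the survivors are fully observed, so mind cannot fire
  expect_equal(nrow(out$dosages), 10)
  # sample at exactly the threshold is kept; just above is removed
  d2 <- matrix(0L, 10, 20)
  d2[1, 1:2] <- NA   # 10% missing
  d2[2, 1:3] <- NA   # 15% missing
  out2 <- filter_missingness(make_gm(d2), max_variant_missing = 1, max_sample_missing = 0.1)
  expect_true("i001" %in% out2$samples$sample_id)
  expect_false("i002" %in% out2$samples$sample_id)
  full <- make_gm(matrix(1L, 4, 5))
  expect_identical(filter_missingness(full)$dosages, full$dosages)
  allmiss <- make_gm(matrix(NA_integer_, 3, 4))
  expect_error(filter_missingness(allmiss, max_variant_missing = 1), "missingness limit")
})

test_that("interval exclusion pins the BED boundary and matches brute force", {
  gm <- make_gm(matrix(1L, 2, 4), pos = c(99, 100, 101, 250))
  out <- exclude_intervals(gm, data.frame(chrom = "chr1", start = 99, end = 100))
  expect_equal(out$variants$pos, c(99L, 101L, 250L))  # only pos 100 covered
  expect_identical(exclude_intervals(gm, data.frame(chrom = character(0),
                                                    start = numeric(0),
                                                    end = numeric(0)))$variants$pos,
                   gm$variants$pos)
  expect_warning(exclude_intervals(gm, data.frame(chrom = "chrX", start = 1, end = 5)),
                 "unknown chromosomes")

  gm2 <- random_gm(3, 200, seed = 11)
  gm2$variants$pos <- sort(sample.int(5000, 200))
  withr::with_seed(4, {
    te <- data.frame(chrom = "chr1", start = sample.int(4900, 30))
    te$end <- te$start + sample.int(80, 30)
  })
  out2 <- exclude_intervals(gm2, te)
  covered <- vapply(gm2$variants$pos, function(p)
    any(te$start < p & p <= te$end), logical(1))
  expect_identical(out2$variants$id, gm2$variants$id[!covered])
  expect_identical(exclude_intervals(out2, te)$variants$id, out2$variants$id)
})

test_that("LD pruning removes later members of correlated pairs and is stable", {
  withr::with_seed(7, {
    x <- rbinom(40, 2, 0.5)
    d <- cbind(x, x, rbinom(40, 2, 0.5))
  })
  gm <- make_gm(d, pos = c(1000, 1100, 1200))
  out <- ld_prune(gm)
  expect_equal(out$variants$pos, c(1000L, 1200L))
  expect_error(ld_prune(gm, window_bp = 100, step_bp = 500), "window_bp")

  # independent columns survive
  gm0 <- random_gm(200, 60, seed = 5)
  gm0$variants$pos <- seq(100, by = 120, length.out = 60)
  expect_equal(ncol(ld_prune(gm0)$dosages), 60)

  # survivor guarantee, checked exhaustively, and idempotence
  fx <- default_fixture(seed = 2, n_loci = 400, inds_per_site = 4)
  pr <- ld_prune(fx$genotypes)
  pos <- pr$variants$pos
  r2 <- suppressWarnings(cor(pr$dosages))^2
  for (i in seq_len(ncol(r2) - 1)) for (j in (i + 1):ncol(r2)) {
    if (abs(pos[j] - pos[i]) < 10000 && !is.na(r2[i, j]))
      expect_lte(r2[i, j], 0.4)
  }
  expect_identical(ld_prune(pr)$variants$id, pr$variants$id)
})

test_that("per-population allele frequencies equal brute-force counting", {
  gm <- make_gm(matrix(c(0L, 1L, 2L), 3, 1), sites = rep("siteA", 3))
  expect_equal(unname(allele_freqs_by_pop(gm)$freq[1, 1]), 0.5)

  d <- matrix(c(NA, NA, NA, 0L, 1L, 2L), 3, 2)
  gm2 <- make_gm(d, sites = c("siteA", "siteA", "siteA"))
  ft <- allele_freqs_by_pop(gm2)
  expect_true(is.na(ft$freq[1, 1]))
  expect_equal(unname(ft$freq[1, 2]), 0.5)

  gm3 <- random_gm(12, 40, n_sites = 3, miss = 0.1, seed = 9)
  ft3 <- allele_freqs_by_pop(gm3)
  for (s in unique(gm3$samples$site)) {
    d <- gm3$dosages[gm3$samples$site == s, , drop = FALSE]
    for (l in c(1, 17, 40)) {
      x <- d[!is.na(d[, l]), l]
      expected <- if (length(x)) sum(x) / (2 * length(x)) else NA_real_
      expect_equal(unname(ft3$freq[s, l]), expected)
    }
  }
  expect_true(all(ft3$freq >= 0 & ft3$freq <= 1, na.rm = TRUE))
})
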