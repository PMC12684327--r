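# Genotype container, VCF/BED I/O, variant and sample filters, LD pruning,
# per-population allele frequencies. All filters only remove rows/columns and
# append machine-readable counts to the object's log; surviving dosages are
# never altered, so every filter is idempotent.

#' Construct a genotype matrix
#'
#' @param dosages integer matrix, individuals x SNPs, values 0/1/2 or NA.
#' @param variants data.frame with at least chrom, pos (1-based), id, ref, alt;
#'   additional numeric columns (QUAL, QD, FS, SOR, ...) are treated as INFO
#'   fields by [filter_info_thresholds()].
#' @param samples data.frame with at least sample_id and site (optionally
#'   group, lon, lat).
#' @param log list of filter/event records carried along the pipeline.
#' @return A `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, samples, log = list()) {
  stop_if_not(ncol(dosages) == nrow(variants),
              "dosage columns (%d) != variant rows (%d)", ncol(dosages), nrow(variants))
  stop_if_not(nrow(dosages) == nrow(samples),
              "dosage rows (%d) != sample rows (%d)", nrow(dosages), nrow(samples))
  ok <- is.na(dosages) | dosages %in% 0:2
  stop_if_not(all(ok), "dosages must be 0/1/2 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    stop_if_not(!is.unsorted(p, strictly = TRUE),
                "positions must be strictly increasing within %s", ch)
  }
  mode(dosages) <- "integer"
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples, log = log),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs, %d sites, %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$samples$site)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

subset_variants <- function(gm, keep, stage, ...) {
  gm$log <- log_event(gm$log, stage, n_before = ncol(gm$dosages),
                      n_removed = sum(!keep), ...)
  gm$dosages <- gm$dosages[, keep, drop = FALSE]
  gm$variants <- gm$variants[keep, , drop = FALSE]
  rownames(gm$variants) <- NULL
  gm
}

subset_samples <- function(gm, keep, stage, ...) {
  gm$log <- log_event(gm$log, stage, n_before = nrow(gm$dosages),
                      n_removed = sum(!keep), removed = gm$samples$sample_id[!keep], ...)
  gm$dosages <- gm$dosages[keep, , drop = FALSE]
  gm$samples <- gm$samples[keep, , drop = FALSE]
  rownames(gm$samples) <- NULL
  gm
}

#' Write a geno_matrix as VCFv4.2
#'
#' Diploid unphased GT plus numeric variant columns (other than pos/QUAL)
#' emitted as INFO fields.
#'
#' @param gm a `geno_matrix`.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  info_cols <- setdiff(names(v)[vapply(v, is.numeric, TRUE)], c("pos", "QUAL"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(v$chrom)),
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", info_cols, info_cols),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
                   gm$samples$sample_id), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$dosages), ncol(gm$dosages))
  nz <- !is.na(gm$dosages)
  gt[nz] <- gt_code[gm$dosages[nz] + 1L]
  info <- if (length(info_cols)) {
    apply(as.matrix(v[info_cols]), 1L, function(r)
      paste(sprintf("%s=%s", info_cols, format(r, trim = TRUE, scientific = FALSE)), collapse = ";"))
  } else rep(".", nrow(v))
  qual <- if ("QUAL" %in% names(v)) format(v$QUAL, trim = TRUE, scientific = FALSE) else "."
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, qual, "PASS", info, "GT",
                sep = "\t")
  body <- paste(body, apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a geno_matrix
#'
#' Diploid GT fields become alternate-allele dosages (0/1/2), `./.` becomes
#' NA. Records with more than one ALT allele are dropped and counted in the
#' log. QUAL and any numeric INFO field declared in the header are kept as
#' variant columns.
#'
#' @param path VCF file (plain or gzipped).
#' @param site_map data.frame (sample_id, site, ...) or path to such a TSV;
#'   every VCF sample must be present.
#' @return A `geno_matrix`.
#' @export
read_vcf <- function(path, site_map) {
  stop_if_not(file.exists(path), "VCF not found: %s", path)
  if (is.character(site_map)) site_map <- read.delim(site_map, stringsAsFactors = FALSE)
  stop_if_not(all(c("sample_id", "site") %in% names(site_map)),
              "site_map needs sample_id and site columns")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) vcf <- vcf[!multi, ]
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_count <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
    out <- suppressWarnings(as.integer(a1) + as.integer(a2))
    out
  }
  dos <- t(apply(gt, 2L, alt_count))  # samples x snps
  colnames(dos) <- rownames(gt)

  unknown <- setdiff(rownames(dos), site_map$sample_id)
  stop_if_not(length(unknown) == 0, "samples absent from site map: %s",
              paste(unknown, collapse = ", "))
  samples <- site_map[match(rownames(dos), site_map$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         QUAL = suppressWarnings(as.numeric(fix$QUAL)),
                         stringsAsFactors = FALSE)
  meta <- vcfR::queryMETA(vcf)
  info_ids <- sub("^INFO=ID=", "", grep("^INFO=ID=", unlist(meta), value = TRUE))
  info_ids <- unique(sub(",.*$", "", info_ids))
  for (id in info_ids) {
    val <- suppressWarnings(vcfR::extract.info(vcf, element = id, as.numeric = TRUE))
    if (!all(is.na(val))) variants[[id]] <- val
  }
  geno_matrix(dos, variants, samples,
              log = list(list(stage = "read_vcf", path = path,
                              n_multiallelic_removed = n_multi,
                              n_kept = nrow(variants))))
}

#' Remove variants failing INFO/QUAL threshold rules
#'
#' Each rule is `list(field, op, cutoff)` meaning "remove the variant if
#' `field op cutoff` holds" -- e.g. `list("QUAL", "<", 50)` removes variants
#' with QUAL below 50. Defaults reproduce the hard filters QUAL < 50,
#' QD < 2, FS > 60, SOR > 3.
#'
#' @param gm a `geno_matrix`.
#' @param rules list of list(field, op, cutoff); op is one of `<`, `<=`, `>`, `>=`.
#' @param on_missing `"error"` (strict: a rule naming an absent field or an NA
#'   value fails) or `"keep"` (lenient: missing values never trigger removal).
#' @return Filtered `geno_matrix`; per-rule removal counts in the log.
#' @export
filter_info_thresholds <- function(gm, rules = list(list("QUAL", "<", 50),
                                                    list("QD", "<", 2),
                                                    list("FS", ">", 60),
                                                    list("SOR", ">", 3)),
                                   on_missing = c("error", "keep")) {
  on_missing <- match.arg(on_missing)
  remove <- rep(FALSE, ncol(gm$dosages))
  counts <- list()
  for (r in rules) {
    field <- r[[1]]; op <- match.fun(r[[2]]); cutoff <- r[[3]]
    if (!field %in% names(gm$variants)) {
      if (on_missing == "error") stop_if_not(FALSE, "INFO field %s absent", field)
      counts[[paste(field, r[[2]], cutoff)]] <- 0L
      next
    }
    val <- gm$variants[[field]]
    hit <- op(val, cutoff)
    if (anyNA(hit)) {
      if (on_missing == "error") stop_if_not(FALSE, "INFO field %s has missing values", field)
      hit[is.na(hit)] <- FALSE
    }
    counts[[paste(field, r[[2]], cutoff)]] <- sum(hit & !remove)
    remove <- remove | hit
  }
  subset_variants(gm, !remove, "filter_info_thresholds", per_rule = counts)
}

#' Filter by per-variant then per-sample missingness
#'
#' The variant filter (`max_variant_missing`, default 0: any missing call
#' removes the SNP) is applied first; sample missingness is then computed on
#' the surviving variants (`max_sample_missing`, default 0.1). The order is
#' recorded in the log.
#'
#' @param gm a `geno_matrix`.
#' @param max_variant_missing maximum tolerated missing fraction per variant.
#' @param max_sample_missing maximum tolerated missing fraction per sample.
#' @return Filtered `geno_matrix`.
#' @export
filter_missingness <- function(gm, max_variant_missing = 0, max_sample_missing = 0.1) {
  stop_if_not(max_variant_missing >= 0 && max_variant_missing <= 1 &&
              max_sample_missing >= 0 && max_sample_missing <= 1,
              "missingness limits must be in [0, 1]")
  vmiss <- colMeans(is.na(gm$dosages))
  gm <- subset_variants(gm, vmiss <= max_variant_missing, "filter_missingness_variants",
                        max_variant_missing = max_variant_missing)
  smiss <- rowMeans(is.na(gm$dosages))
  if (ncol(gm$dosages) == 0) smiss[] <- 0
  keep <- smiss <= max_sample_missing
  stop_if_not(any(keep), "all samples exceed the missingness limit")
  subset_samples(gm, keep, "filter_missingness_samples",
                 max_sample_missing = max_sample_missing)
}

#' Read a BED file as an interval set
#'
#' @param path BED file (0-based half-open intervals).
#' @return data.frame(chrom, start, end), 0-based half-open.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,  # back to 0-based
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Exclude variants inside intervals (e.g. transposable elements)
#'
#' Intervals are 0-based half-open (BED convention); a SNP at 1-based
#' position p is removed iff some interval on its chromosome satisfies
#' start < p <= end. Intervals on chromosomes absent from the data are
#' ignored with a warning.
#'
#' @param gm a `geno_matrix`.
#' @param intervals data.frame(chrom, start, end) as from [read_bed()].
#' @return Filtered `geno_matrix`.
#' @export
exclude_intervals <- function(gm, intervals) {
  if (nrow(intervals) == 0) return(subset_variants(gm, rep(TRUE, ncol(gm$dosages)),
                                                   "exclude_intervals"))
  stop_if_not(all(intervals$start < intervals$end), "intervals need start < end")
  unknown <- setdiff(unique(intervals$chrom), unique(gm$variants$chrom))
  if (length(unknown)) {
    warning(sprintf("ignoring intervals on unknown chromosomes: %s",
                    paste(unknown, collapse = ", ")))
    intervals <- intervals[!intervals$chrom %in% unknown, , drop = FALSE]
  }
  snp_gr <- GenomicRanges::GRanges(gm$variants$chrom,
                                   IRanges::IRanges(gm$variants$pos, width = 1L))
  te_gr <- GenomicRanges::GRanges(intervals$chrom,
                                  IRanges::IRanges(intervals$start + 1L, intervals$end))
  hit <- GenomicRanges::countOverlaps(snp_gr, te_gr) > 0
  subset_variants(gm, !hit, "exclude_intervals", n_intervals = nrow(intervals))
}

#' Sliding-window LD pruning
#'
#' Within each window of `window_bp` (advancing by `step_bp`), whenever a
#' retained pair of SNPs has squared Pearson correlation of dosages
#' (pairwise-complete) above `r2_max`, the later SNP (higher position, ties
#' broken by higher column index) is removed. The survivor set contains no
#' within-window pair with r-squared above the threshold, and re-running the
#' pruner on its own output changes nothing.
#'
#' @param gm a `geno_matrix`.
#' @param r2_max squared-correlation threshold.
#' @param window_bp window size in bp.
#' @param step_bp step size in bp; must not exceed `window_bp`.
#' @return Pruned `geno_matrix`.
#' @export
ld_prune <- function(gm, r2_max = 0.4, window_bp = 10000, step_bp = 5000) {
  stop_if_not(window_bp >= step_bp, "window_bp must be >= step_bp")
  keep <- rep(TRUE, ncol(gm$dosages))
  for (ch in unique(gm$variants$chrom)) {
    on_ch <- which(gm$variants$chrom == ch)
    pos <- gm$variants$pos[on_ch]
    if (length(on_ch) < 2) next
    starts <- seq(min(pos), max(pos), by = step_bp)
    for (ws in starts) {
      in_win <- on_ch[pos >= ws & pos < ws + window_bp & keep[on_ch]]
      if (length(in_win) < 2) next
      # position order; column order already breaks position ties
      sub <- gm$dosages[, in_win, drop = FALSE]
      r2 <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))^2
      w <- length(in_win)
      alive <- rep(TRUE, w)
      for (i in seq_len(w - 1L)) {
        if (!alive[i]) next
        for (j in (i + 1L):w) {
          if (alive[j] && !is.na(r2[i, j]) && r2[i, j] > r2_max) alive[j] <- FALSE
        }
      }
      keep[in_win[!alive]] <- FALSE
    }
  }
  subset_variants(gm, keep, "ld_prune", r2_max = r2_max,
                  window_bp = window_bp, step_bp = step_bp)
}

#' Per-population alternate-allele frequencies
#'
#' Frequency = alternate gene copies / called gene copies; missing genotypes
#' count in neither. A population with zero called copies at a locus gets a
#' missing frequency there.
#'
#' @param gm a `geno_matrix`.
#' @param grouping factor/character of population labels per individual;
#'   defaults to the sample-to-site map.
#' @return list(freq = populations x SNPs matrix, copies = called gene copies
#'   per population x SNP, pops = population labels), class `allele_freq_table`.
#' @export
allele_freqs_by_pop <- function(gm, grouping = gm$samples$site) {
  grouping <- as.character(grouping)
  stop_if_not(length(grouping) == nrow(gm$dosages), "grouping length mismatch")
  pops <- unique(grouping)
  L <- ncol(gm$dosages)
  freq <- matrix(NA_real_, length(pops), L, dimnames = list(pops, colnames(gm$dosages)))
  copies <- matrix(0L, length(pops), L, dimnames = dimnames(freq))
  for (k in seq_along(pops)) {
    d <- gm$dosages[grouping == pops[k], , drop = FALSE]
    called <- colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    copies[k, ] <- 2L * called
    freq[k, ] <- ifelse(called > 0, alt / (2 * called), NA_real_)
  }
  structure(list(freq = freq, copies = copies, pops = pops),
            class = "allele_freq_table")
}
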