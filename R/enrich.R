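# Candidate SNP -> gene mapping and GO-term over-representation.

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 file (1-based closed coordinates).
#' @param feature_type feature to keep (default "gene").
#' @return data.frame(gene_id, chrom, start, end).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  id <- gr$ID %||% gr$Name
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Map SNPs to nearby genes
#'
#' distance = 0 for a SNP inside \[start, end\], otherwise the gap to the
#' nearer gene end; every gene within `max_dist` (same chromosome) is
#' reported.
#'
#' @param snp_positions data.frame(snp, chrom, pos) with 1-based positions
#'   (e.g. `gm$variants` renamed), or a `geno_matrix`.
#' @param genes data.frame(gene_id, chrom, start, end) as from
#'   [read_gff_genes()], or a GFF3 path.
#' @param max_dist maximum SNP-gene distance in bp (default 1000).
#' @return data.frame(snp, gene_id, distance), one row per mapped pair.
#' @export
map_snps_to_genes <- function(snp_positions, genes, max_dist = 1000L) {
  if (inherits(snp_positions, "geno_matrix")) {
    snp_positions <- data.frame(snp = snp_positions$variants$id,
                                chrom = snp_positions$variants$chrom,
                                pos = snp_positions$variants$pos)
  }
  if (is.character(genes)) genes <- read_gff_genes(genes)
  out <- list()
  for (ch in unique(snp_positions$chrom)) {
    s <- snp_positions[snp_positions$chrom == ch, , drop = FALSE]
    gn <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(gn) == 0 || nrow(s) == 0) next
    # distance matrix: 0 inside the gene, else gap to the nearer end
    d_lo <- outer(gn$start, s$pos, `-`)      # genes x snps: start - pos
    d_hi <- outer(s$pos, gn$end, `-`)        # snps x genes: pos - end
    dist <- pmax(d_lo, t(d_hi), 0)
    hit <- which(dist <= max_dist, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[ch]] <- data.frame(snp = s$snp[hit[, 2]],
                              gene_id = gn$gene_id[hit[, 1]],
                              distance = dist[hit])
    }
  }
  if (!length(out)) return(data.frame(snp = character(0), gene_id = character(0),
                                      distance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$snp, snp_positions$snp), res$distance), , drop = FALSE]
}

#' Read a gene-to-GO-term mapping TSV
#'
#' @param path TSV with columns gene_id and go_id.
#' @return data.frame(gene_id, go_id).
#' @export
read_gene2go <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("gene_id", "go_id") %in% names(df)),
              "gene2go table needs gene_id and go_id columns")
  df[, c("gene_id", "go_id")]
}

#' GO-term over-representation by one-sided Fisher's exact test
#'
#' For each GO term, a 2x2 table (candidate / non-candidate x has-term /
#' lacks-term over the background gene universe) is tested for
#' over-representation (one-sided). Raw p-values are flagged at `alpha`
#' (default 0.01); BH q-values are reported alongside.
#'
#' @param candidate_genes character vector, a subset of `background_genes`.
#' @param background_genes character vector (the gene universe).
#' @param go_map data.frame(gene_id, go_id).
#' @param alpha flagging threshold on the raw p-value.
#' @return data.frame(go_id, n_candidate, n_background, p, q, flag), ordered
#'   by p.
#' @export
go_fisher <- function(candidate_genes, background_genes, go_map, alpha = 0.01) {
  background_genes <- unique(background_genes)
  candidate_genes <- unique(candidate_genes)
  stop_if_not(length(background_genes) > 0, "background gene set is empty")
  stop_if_not(all(candidate_genes %in% background_genes),
              "candidates must be a subset of the background")
  go_map <- go_map[go_map$gene_id %in% background_genes, , drop = FALSE]
  terms <- unique(go_map$go_id)
  n_bg <- length(background_genes)
  n_cand <- length(candidate_genes)
  res <- lapply(terms, function(tm) {
    with_term <- unique(go_map$gene_id[go_map$go_id == tm])
    a <- sum(candidate_genes %in% with_term)
    tab <- matrix(c(a, length(with_term) - a,
                    n_cand - a, n_bg - length(with_term) - (n_cand - a)),
                  nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(go_id = tm, n_candidate = a, n_background = length(with_term), p = p)
  })
  res <- do.call(rbind, res)
  res$q <- bh_qvalues(res$p)
  res$flag <- res$p < alpha
  res[order(res$p, res$go_id), , drop = FALSE]
}
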