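# Candidate-gene annotation: interval intersection of +/- flank windows
# around associated SNPs with a user-supplied gene table.

#' Read a gene annotation table
#'
#' Accepts GFF3 (rows of type `gene` are kept; 1-based inclusive
#' coordinates pass through) or BED (0-based half-open, converted on read).
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"gff3"`, `"bed"` or `"auto"`.
#' @return Data frame `gene_id`, `symbol`, `chr`, `start_bp`, `end_bp`,
#'   `strand` (1-based inclusive).
#' @export
read_genes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    gene_id <- if ("ID" %in% names(df)) df$ID else df$gene_id
    symbol <- if ("Name" %in% names(df)) df$Name else NA_character_
  } else {
    gene_id <- if ("name" %in% names(df)) df$name else
      sprintf("gene%04d", seq_len(nrow(df)))
    symbol <- NA_character_
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    chr = as.character(df$seqnames),
                    start_bp = df$start, end_bp = df$end,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  out
}

#' Candidate genes within a flanking window of SNP hits
#'
#' A gene is a candidate for a SNP when its `[start, end]` interval
#' intersects `[pos - flank, pos + flank]` on the same chromosome (strand
#' ignored). `distance_bp` is 0 when the SNP lies inside the gene, else the
#' gap to the nearest gene edge. Duplicate (snp, gene) pairs are collapsed.
#'
#' @param hits Data frame with `snp_id`, `chr`, `pos_bp` (e.g. labeled scan
#'   fits filtered to suggestive SNPs).
#' @param genes Gene table from [read_genes()] or of the same shape.
#' @param flank Window half-width in bp (default 100,000).
#' @return Data frame `snp_id`, `gene_id`, `symbol`, `distance_bp`.
#' @export
window_genes <- function(hits, genes, flank = 1e5) {
  stopifnot(all(c("snp_id", "chr", "pos_bp") %in% names(hits)),
            all(c("gene_id", "chr", "start_bp", "end_bp") %in% names(genes)))
  hits <- hits[!duplicated(hits$snp_id), , drop = FALSE]
  known <- as.character(hits$chr) %in% as.character(genes$chr)
  if (any(!known)) {
    warning(sprintf("%d SNP(s) on chromosomes absent from the gene table skipped",
                    sum(!known)))
    hits <- hits[known, , drop = FALSE]
  }
  if (nrow(hits) == 0 || nrow(genes) == 0) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      symbol = character(0), distance_bp = integer(0)))
  }
  snp_gr <- GenomicRanges::GRanges(
    as.character(hits$chr),
    IRanges::IRanges(hits$pos_bp - flank, hits$pos_bp + flank))
  gene_gr <- GenomicRanges::GRanges(
    as.character(genes$chr),
    IRanges::IRanges(genes$start_bp, genes$end_bp))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  pos <- hits$pos_bp[qi]
  dist <- pmax(genes$start_bp[si] - pos, pos - genes$end_bp[si], 0)
  out <- data.frame(snp_id = hits$snp_id[qi],
                    gene_id = genes$gene_id[si],
                    symbol = if ("symbol" %in% names(genes))
                      genes$symbol[si] else NA_character_,
                    distance_bp = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("snp_id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
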