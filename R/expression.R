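# Gene expression from genomic alignments (RPKM), readthrough splice
# expression proxies, splicing efficiency, and the conditioned
# with-vs-without readthrough expression comparison.

#' Reads per kilobase of exon per million total reads
#'
#' @param exon_reads reads aligned to the gene's exons.
#' @param exon_kb kilobases of merged exonic sequence.
#' @param total_reads library size.
#' @return numeric RPKM.
#' @export
compute_rpkm <- function(exon_reads, exon_kb, total_reads) {
  if (any(exon_kb <= 0)) stop("zero exon length")
  if (any(total_reads <= 0)) stop("zero library size")
  exon_reads / (exon_kb * total_reads / 1e6)
}

#' Count exonic reads per gene and compute RPKM
#'
#' Counts reads whose genomic interval overlaps the merged exons of each
#' gene (a read overlapping two genes counts toward both, or fractionally
#' when `fractional = TRUE`), then normalises by merged exonic kilobases
#' and library size.
#'
#' @param alignments data.frame of genomic read alignments with columns
#'   read_id, sample_id, chrom, start, end.
#' @param txs the [transcript_set()].
#' @param fractional split multi-gene reads equally instead of double
#'   counting (default FALSE).
#' @return data.table: gene_id, sample_id, exon_reads, exon_kb,
#'   total_reads, rpkm.
#' @export
expression_matrix <- function(alignments, txs, fractional = FALSE) {
  alignments <- data.table::as.data.table(alignments)
  ex <- merge(txs$exons, txs$tx[, .(accession, gene_id, chrom)],
              by = "accession")
  merged <- ex[, {
    ir <- IRanges::reduce(IRanges::IRanges(start, end))
    .(start = IRanges::start(ir), end = IRanges::end(ir))
  }, by = .(gene_id, chrom)]
  exon_kb <- merged[, .(exon_kb = sum(end - start + 1L) / 1000), by = gene_id]
  lib <- alignments[, .(total_reads = .N), by = sample_id]
  gr_reads <- GenomicRanges::GRanges(alignments$chrom,
                                     IRanges::IRanges(alignments$start,
                                                      alignments$end))
  gr_ex <- GenomicRanges::GRanges(merged$chrom,
                                  IRanges::IRanges(merged$start, merged$end))
  ov <- GenomicRanges::findOverlaps(gr_reads, gr_ex)
  hits <- data.table::data.table(
    ridx = S4Vectors::queryHits(ov),
    gene_id = merged$gene_id[S4Vectors::subjectHits(ov)])
  hits <- unique(hits)  # one count per (read, gene)
  hits[, sample_id := alignments$sample_id[ridx]]
  if (fractional) {
    hits[, w := 1 / .N, by = ridx]
  } else {
    hits[, w := 1]
  }
  counts <- hits[, .(exon_reads = sum(w)), by = .(gene_id, sample_id)]
  grid <- data.table::CJ(gene_id = exon_kb$gene_id, sample_id = lib$sample_id)
  res <- merge(grid, counts, by = c("gene_id", "sample_id"), all.x = TRUE)
  res[is.na(exon_reads), exon_reads := 0]
  res <- merge(res, exon_kb, by = "gene_id")
  res <- merge(res, lib, by = "sample_id")
  res[, rpkm := compute_rpkm(exon_reads, exon_kb, total_reads)]
  res[]
}

#' Readthrough splicing efficiency
#'
#' Splice expression of the readthrough junction divided by the 5' gene's
#' expression. Reported on its natural scale; the spread across events
#' typically spans orders of magnitude, so plots and summaries use log10.
#'
#' @param tic_splice_expression junction-supporting reads per million (or
#'   any expression proxy for the readthrough splice).
#' @param gene5_expression 5' gene expression on the same scale.
#' @return numeric ratio; NA where the 5' gene expression is zero.
#' @export
splicing_efficiency <- function(tic_splice_expression, gene5_expression) {
  ifelse(gene5_expression > 0,
         tic_splice_expression / gene5_expression, NA_real_)
}

#' Expression of genes with vs without an observed readthrough
#'
#' For each sample, compares the expression of 5' (and 3') genes that have
#' an observed readthrough event against those that do not, restricted to
#' genes that (a) have at least one observed intragenic splice in that
#' sample (i.e. are detectably expressed) and (b) have a potential
#' readthrough partner exon within `max_distance` downstream (5' role) or
#' upstream (3' role) — so both groups could in principle have shown an
#' event.
#'
#' @param events event table from [call_events()].
#' @param expr expression table from [expression_matrix()].
#' @param tic_targets the readthrough target set (defines which genes have
#'   a potential partner).
#' @param intragenic_observed data.frame with gene_id, sample_id rows for
#'   genes with at least one observed intragenic splice per sample.
#' @param max_distance partner window (default 200000; already encoded in
#'   the target set, retained for documentation).
#' @return data.table: sample_id, role ("5p"/"3p"), gene_id, rpkm,
#'   with_tic.
#' @export
tic_conditioned_expression_report <- function(events, expr, tic_targets,
                                              intragenic_observed,
                                              max_distance = 200000L) {
  intragenic_observed <- data.table::as.data.table(intragenic_observed)
  pot5 <- unique(unlist(tic_targets$donor_genes))
  pot3 <- unique(unlist(tic_targets$acceptor_genes))
  out <- list()
  for (smp in unique(expr$sample_id)) {
    seen <- intragenic_observed[sample_id == smp]$gene_id
    ev5 <- unique(events[vapply(events$samples, function(s) smp %in% s, TRUE)]$gene5)
    ev3 <- unique(events[vapply(events$samples, function(s) smp %in% s, TRUE)]$gene3)
    e <- expr[sample_id == smp]
    g5 <- e[gene_id %in% intersect(seen, pot5)]
    g3 <- e[gene_id %in% intersect(seen, pot3)]
    if (nrow(g5)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        sample_id = smp, role = "5p", gene_id = g5$gene_id,
        rpkm = g5$rpkm, with_tic = g5$gene_id %in% ev5)
    }
    if (nrow(g3)) {
      out[[length(out) + 1L]] <- data.table::data.table(
        sample_id = smp, role = "3p", gene_id = g3$gene_id,
        rpkm = g3$rpkm, with_tic = g3$gene_id %in% ev3)
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(sample_id = character(), role = character(),
                                  gene_id = character(), rpkm = numeric(),
                                  with_tic = logical()))
  }
  data.table::rbindlist(out)
}
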