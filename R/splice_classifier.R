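# Classification of split/spliced alignment records against the gene model:
# readthrough vs distant-fusion taxonomy (long-range, scrambled, inversion,
# translocation) and detection of intervening-exon readthroughs (TICIEs).
# Records are consumed from a 10-column TSV (or equivalent data.frame), so
# no external spliced aligner is required.

#' Load split-alignment records
#'
#' Reads the canonical 10-column tab-delimited format: read_id, sample_id,
#' chrom_a, strand_a, start_a, end_a, chrom_b, strand_b, start_b, end_b.
#' Segment A precedes segment B in read order; the splice donor is the
#' transcription-direction end of segment A and the acceptor the start of
#' segment B.
#'
#' @param path TSV file with a header line.
#' @return data.table of records.
#' @export
load_split_records <- function(path) {
  rec <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c(1:4, 7, 8)))
  need <- c("read_id", "sample_id", "chrom_a", "strand_a", "start_a",
            "end_a", "chrom_b", "strand_b", "start_b", "end_b")
  if (!all(need %in% names(rec))) {
    stop("split-record file must have columns: ", paste(need, collapse = ", "))
  }
  rec
}

# splice-site coordinates implied by a record
.record_sites <- function(records) {
  records <- data.table::as.data.table(records)
  records[, donor_pos := ifelse(strand_a == "+", end_a, start_a)]
  records[, acceptor_pos := ifelse(strand_b == "+", start_b, end_b)]
  records[]
}

#' Classify split-alignment records into fusion categories
#'
#' Applies the fixed decision order so that every record receives exactly
#' one label: different chromosomes -> translocation; opposite strands of
#' one chromosome -> inversion; acceptor upstream of donor in transcription
#' orientation -> scrambled; donor-acceptor distance above `max_local` ->
#' long_range; different genes -> readthrough; otherwise intragenic.
#' Segments that cannot be assigned to a gene keep category from geometry
#' with NA gene columns.
#'
#' @param records split-alignment records (see [load_split_records()]).
#' @param txs the [transcript_set()], or NULL to classify on geometry alone
#'   (gene columns NA; local same-strand records with unknown genes fall in
#'   the intragenic bucket).
#' @param sites optional site catalogs from [catalog_splice_sites()]; when
#'   given, known-site flags and exon labels are attached.
#' @param max_local readthrough distance bound in bp (default 200000).
#' @return data.table: the records plus donor_pos, acceptor_pos, category,
#'   donor_gene, acceptor_gene, distance, and (with `sites`) donor_known,
#'   acceptor_known, donor_label, acceptor_label.
#' @export
classify_split <- function(records, txs, sites = NULL, max_local = 200000L) {
  rec <- .record_sites(records)
  n <- nrow(rec)
  dgene <- agene <- rep(NA_character_, n)
  if (!is.null(txs) && n > 0L) {
    extents <- .gene_extents(txs)
    assign_all <- function(chrom, strand, pos) {
      out <- rep(NA_character_, length(pos))
      gr_pt <- GenomicRanges::GRanges(paste0(chrom, strand),
                                      IRanges::IRanges(pos, pos))
      gr_gx <- GenomicRanges::GRanges(paste0(extents$chrom, extents$strand),
                                      IRanges::IRanges(extents$start,
                                                       extents$end))
      ov <- GenomicRanges::findOverlaps(gr_pt, gr_gx, select = "first")
      out[!is.na(ov)] <- extents$gene_id[ov[!is.na(ov)]]
      out
    }
    dgene <- assign_all(rec$chrom_a, rec$strand_a, rec$donor_pos)
    agene <- assign_all(rec$chrom_b, rec$strand_b, rec$acceptor_pos)
  }
  distance <- abs(rec$acceptor_pos - rec$donor_pos)
  upstream <- ifelse(rec$strand_a == "+",
                     rec$acceptor_pos < rec$donor_pos,
                     rec$acceptor_pos > rec$donor_pos)
  category <- rep("intragenic", n)
  category[!is.na(dgene) & !is.na(agene) & dgene != agene] <- "readthrough"
  category[distance > max_local] <- "long_range"
  category[upstream] <- "scrambled"
  category[rec$strand_a != rec$strand_b] <- "inversion"
  category[rec$chrom_a != rec$chrom_b] <- "translocation"
  distance[category == "translocation"] <- NA_integer_
  rec[, `:=`(category = category, donor_gene = dgene, acceptor_gene = agene,
             distance = distance)]
  if (!is.null(sites)) {
    dk <- site_key(rec$chrom_a, rec$strand_a, rec$donor_pos, "donor")
    ak <- site_key(rec$chrom_b, rec$strand_b, rec$acceptor_pos, "acceptor")
    dcat <- sites$donors
    acat <- sites$acceptors
    dkk <- site_key(dcat$chrom, dcat$strand, dcat$pos, "donor")
    akk <- site_key(acat$chrom, acat$strand, acat$pos, "acceptor")
    rec[, donor_known := dk %in% dkk]
    rec[, acceptor_known := ak %in% akk]
    lab1 <- function(cat, key, keys) {
      i <- match(key, keys)
      if (is.na(i)) return(NA_character_)
      lb <- cat$labels[[i]][order(accession)]
      exon_label(lb$exon_index[1L], lb$exon_count[1L])
    }
    rec[, donor_label := vapply(dk, lab1, "", cat = dcat, keys = dkk)]
    rec[, acceptor_label := vapply(ak, lab1, "", cat = acat, keys = akk)]
  }
  rec[]
}

#' Aggregate classified records into fusion calls
#'
#' Groups records by category and donor/acceptor splice-site coordinates,
#' counting supporting reads and samples.
#'
#' @param classified output of [classify_split()].
#' @return data.table of calls with n_reads and samples.
#' @export
aggregate_fusion_calls <- function(classified) {
  classified[, .(
    donor_gene = donor_gene[1L], acceptor_gene = acceptor_gene[1L],
    distance = distance[1L], n_reads = .N,
    samples = list(sort(unique(sample_id)))),
    by = .(category, chrom_a, strand_a, donor_pos,
           chrom_b, strand_b, acceptor_pos)]
}

#' Multi-read filter for distant-fusion calls
#'
#' Distant-fusion categories (long_range, scrambled, inversion,
#' translocation) are retained only with at least `min_reads` supporting
#' reads; readthrough and intragenic calls are untouched, reflecting the
#' asymmetric evidence policy: a local readthrough splice is plausible on a
#' single read, a distant fusion is not.
#'
#' @param calls output of [aggregate_fusion_calls()].
#' @param min_reads threshold (default 2).
#' @return the filtered calls.
#' @export
filter_multiread <- function(calls, min_reads = 2L) {
  distant <- c("long_range", "scrambled", "inversion", "translocation")
  calls[!(category %in% distant) | n_reads >= min_reads]
}

# gene-homology part of the homology filter (40 matches / 50 columns)
.gene_homology_fails <- function(tx_seqs5, tx_seqs3, window_matches = 40L,
                                 window_size = 50L) {
  for (s5 in tx_seqs5) {
    for (s3 in tx_seqs3) {
      al <- .local_alignment(s5, s3)
      if (.max_window_matches(al$p, al$s, window_size) >= window_matches) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Detect readthroughs with intervening exons (TICIEs)
#'
#' Pairs, within each sample, an upstream splice (known donor to novel
#' acceptor) with a downstream splice (novel donor to known acceptor) whose
#' two novel sites delimit a putative intervening exon of at most
#' `exon_max` bp on the same strand. Both flanking splices must span at
#' most `max_local` bp, the known sites must belong to two different
#' coding genes, and the gene pair must pass the gene-homology rule. The
#' intervening interval is classified by genomic overlap: the 5' gene's
#' last exon, the 3' gene's first exon, any other exon of either gene
#' (internal_novel), or none (intergenic).
#'
#' @param records split-alignment records.
#' @param sites site catalogs from [catalog_splice_sites()].
#' @param txs the [transcript_set()].
#' @param genome genome (for the homology rule's transcript sequences).
#' @param exon_max maximum intervening-exon length in bp (default 300).
#' @param max_local flanking-splice distance bound (default 200000).
#' @param homology apply the gene-homology rule (default TRUE).
#' @return data.table of candidates: gene5, gene3, exon_start, exon_end,
#'   exon_length, location_class, sample_id, n_reads, same_read.
#' @export
detect_ticie <- function(records, sites, txs, genome, exon_max = 300L,
                         max_local = 200000L, homology = TRUE) {
  cls <- classify_split(records, txs, sites = sites, max_local = .Machine$integer.max)
  empty <- data.table::data.table(
    gene5 = character(), gene3 = character(), chrom = character(),
    strand = character(), exon_start = integer(), exon_end = integer(),
    exon_length = integer(), location_class = character(),
    sample_id = character(), n_reads = integer(), same_read = logical())
  # local same-strand splices only
  loc <- cls[chrom_a == chrom_b & strand_a == strand_b &
             abs(acceptor_pos - donor_pos) <= max_local]
  up <- loc[donor_known == TRUE & acceptor_known == FALSE]
  dn <- loc[donor_known == FALSE & acceptor_known == TRUE]
  if (nrow(up) == 0L || nrow(dn) == 0L) return(empty)
  # collapse per distinct splice: pairing depends only on the junction
  up <- up[, .(reads = list(unique(read_id))),
           by = .(sample_id, chrom_a, strand_a, donor_pos, acceptor_pos,
                  donor_gene)]
  dn <- dn[, .(reads = list(unique(read_id))),
           by = .(sample_id, chrom_a, strand_a, donor_pos, acceptor_pos,
                  acceptor_gene)]
  seq_cache <- .make_seq_cache(txs, genome)
  exg <- merge(txs$exons, txs$tx[, .(accession, gene_id, chrom, strand,
                                     coding, n_exons)], by = "accession")
  out <- list()
  for (i in seq_len(nrow(up))) {
    u <- up[i]
    cand <- dn[sample_id == u$sample_id & chrom_a == u$chrom_a &
               strand_a == u$strand_a]
    if (nrow(cand) == 0L) next
    for (j in seq_len(nrow(cand))) {
      d <- cand[j]
      if (u$strand_a == "+") {
        es <- u$acceptor_pos; ee <- d$donor_pos
      } else {
        es <- d$donor_pos; ee <- u$acceptor_pos
      }
      if (ee < es) next
      elen <- ee - es + 1L
      if (elen > exon_max) next
      g5 <- u$donor_gene; g3 <- d$acceptor_gene
      if (is.na(g5) || is.na(g3) || g5 == g3) next
      if (!any(txs$tx[gene_id == g5]$coding) ||
          !any(txs$tx[gene_id == g3]$coding)) next
      if (homology) {
        s5 <- vapply(txs$tx[gene_id == g5]$accession, seq_cache, "")
        s3 <- vapply(txs$tx[gene_id == g3]$accession, seq_cache, "")
        if (.gene_homology_fails(s5, s3)) next
      }
      loc_class <- .ticie_location(exg, g5, g3, u$chrom_a, es, ee)
      out[[length(out) + 1L]] <- data.table::data.table(
        gene5 = g5, gene3 = g3, chrom = u$chrom_a, strand = u$strand_a,
        exon_start = es, exon_end = ee, exon_length = elen,
        location_class = loc_class, sample_id = u$sample_id,
        reads = list(unique(c(u$reads[[1L]], d$reads[[1L]]))),
        same_read = length(intersect(u$reads[[1L]], d$reads[[1L]])) > 0L)
    }
  }
  if (length(out) == 0L) return(empty)
  all <- data.table::rbindlist(out)
  all[, .(n_reads = length(unique(unlist(reads))),
          same_read = any(same_read)),
      by = .(gene5, gene3, chrom, strand, exon_start, exon_end,
             exon_length, location_class, sample_id)]
}

# classify an intervening interval by overlap with the 5' gene's last exon,
# the 3' gene's first exon, any other exon, or nothing
.ticie_location <- function(exg, g5, g3, chrom, es, ee) {
  ov <- function(s, e) any(s <= ee & e >= es)
  e5 <- exg[gene_id == g5 & exg$chrom == chrom]
  e3 <- exg[gene_id == g3 & exg$chrom == chrom]
  last5 <- e5[exon_rank == n_exons]
  first3 <- e3[exon_rank == 1L]
  if (nrow(last5) > 0L && ov(last5$start, last5$end)) {
    return("overlaps_5p_last_exon")
  }
  if (nrow(first3) > 0L && ov(first3$start, first3$end)) {
    return("overlaps_3p_first_exon")
  }
  oth <- rbind(e5, e3)
  if (nrow(oth) > 0L && ov(oth$start, oth$end)) return("internal_novel")
  "intergenic"
}
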