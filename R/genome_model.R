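#' Load a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a named character vector of
#' chromosome sequences. Sequences are uppercased and any character outside
#' the A/C/G/T/N alphabet is mapped to N. Chromosome names are taken from
#' the first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase chromosome sequences.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  nms <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in FASTA")
  names(seqs) <- nms
  seqs
}

#' Construct a transcript set
#'
#' Assembles the package's gene/transcript model from per-transcript exon
#' tables. Coordinates are 1-based inclusive genomic positions; exons are
#' listed in transcription order (ascending genomic start on the plus
#' strand, descending on the minus strand). The optional CDS is given in
#' transcript coordinates and runs through the last base of the stop codon.
#'
#' @param exons data.frame with columns accession, exon_rank, start, end.
#' @param tx data.frame with columns accession, gene_id, chrom, strand,
#'   and optionally coding (logical), cds_start, cds_end (transcript
#'   coordinates, 1-based inclusive).
#' @param genome optional genome (from [load_genome()]) used to validate
#'   that exons lie within their chromosome.
#' @return an object of class `transcript_set` with elements `tx` and
#'   `exons` (data.tables).
#' @export
transcript_set <- function(exons, tx, genome = NULL) {
  exons <- data.table::as.data.table(exons)
  tx <- data.table::as.data.table(tx)
  stopifnot(all(c("accession", "exon_rank", "start", "end") %in% names(exons)),
            all(c("accession", "gene_id", "chrom", "strand") %in% names(tx)))
  if (!"coding" %in% names(tx)) tx[, coding := grepl("^NM_", accession)]
  if (!"cds_start" %in% names(tx)) tx[, cds_start := NA_integer_]
  if (!"cds_end" %in% names(tx)) tx[, cds_end := NA_integer_]
  if (anyDuplicated(tx$accession)) stop("duplicate transcript accession")
  data.table::setkey(exons, accession, exon_rank)
  tx[, n_exons := exons[.(tx$accession), .N, by = .EACHI]$N]

  # per-transcript structural validation
  for (i in seq_len(nrow(tx))) {
    acc <- tx$accession[i]
    ex <- exons[.(acc)]
    if (nrow(ex) == 0L) stop("transcript without exons: ", acc)
    if (any(ex$end < ex$start)) stop("malformed exon in transcript ", acc)
    if (!is.null(genome)) {
      if (!tx$chrom[i] %in% names(genome)) {
        stop("transcript ", acc, " on unknown chromosome ", tx$chrom[i])
      }
      clen <- nchar(genome[[tx$chrom[i]]])
      if (any(ex$start < 1L) || any(ex$end > clen)) {
        stop("exon outside chromosome bounds in transcript ", acc)
      }
    }
    if (nrow(ex) > 1L) {
      ord <- order(ex$start)
      if (any(ex$start[ord][-1] - ex$end[ord][-nrow(ex)] < 2L)) {
        stop("overlapping or abutting exons in transcript ", acc)
      }
      if (tx$strand[i] == "+") {
        if (is.unsorted(ex$start, strictly = TRUE)) {
          stop("exon_rank not in transcription order for + transcript ", acc)
        }
      } else {
        if (is.unsorted(rev(ex$start), strictly = TRUE)) {
          stop("exon_rank not in transcription order for - transcript ", acc)
        }
      }
    }
    if (!is.na(tx$cds_start[i])) {
      txlen <- sum(ex$end - ex$start + 1L)
      if (tx$cds_start[i] < 1L || tx$cds_end[i] > txlen ||
          tx$cds_end[i] - tx$cds_start[i] + 1L < 3L) {
        stop("CDS outside transcript or shorter than one codon: ", acc)
      }
    }
  }
  structure(list(tx = tx[], exons = exons[]), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d genes, %d exons\n",
              nrow(x$tx), length(unique(x$tx$gene_id)), nrow(x$exons)))
  invisible(x)
}

#' Load transcript annotation
#'
#' Reads transcript models from GTF, GFF3 or BED12. The dialect is detected
#' from the file extension and can be overridden. GTF/GFF3 exon features
#' must carry `gene_id` and `transcript_id` attributes; CDS features, when
#' present, are mapped into transcript coordinates. BED12 blocks encode the
#' exons of one transcript per line (the BED name doubles as gene_id unless
#' a `geneid:` prefix tag is present in the name, written as
#' `accession|gene_id`); the thick interval encodes the CDS.
#'
#' A transcript is flagged coding when its accession starts with `NM_`
#' (RefSeq mRNA convention) or when it has an annotated CDS.
#'
#' @param path annotation file.
#' @param genome genome from [load_genome()] for bounds validation.
#' @param format one of "auto", "gtf", "gff3", "bed".
#' @return a [transcript_set()].
#' @export
load_transcripts <- function(path, genome = NULL,
                             format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed",
      stop("cannot auto-detect annotation dialect from extension: ", ext))
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    return(.transcripts_from_bed(gr, genome))
  }
  gr <- rtracklayer::import(path, format = format)
  .transcripts_from_gff(gr, genome)
}

.transcripts_from_gff <- function(gr, genome) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon features")
  exd <- data.table::data.table(
    accession = as.character(S4Vectors::mcols(ex)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex))
  if (anyNA(exd$accession)) stop("exon feature without transcript_id")
  # transcription order
  exd <- exd[order(accession, ifelse(strand == "+", 1L, -1L) * start)]
  exd[, exon_rank := seq_len(.N), by = accession]
  txd <- exd[, .(gene_id = gene_id[1L], chrom = chrom[1L],
                 strand = strand[1L], nchrom = length(unique(chrom))),
             by = accession]
  if (any(txd$nchrom > 1L)) {
    stop("transcript spans two chromosomes: ",
         paste(txd$accession[txd$nchrom > 1L], collapse = ", "))
  }
  txd[, nchrom := NULL]

  # CDS features -> transcript coordinates
  cds <- gr[type == "CDS"]
  txd[, `:=`(cds_start = NA_integer_, cds_end = NA_integer_)]
  if (length(cds) > 0L) {
    cdd <- data.table::data.table(
      accession = as.character(S4Vectors::mcols(cds)$transcript_id),
      start = GenomicRanges::start(cds),
      end = GenomicRanges::end(cds))
    for (acc in unique(cdd$accession)) {
      g5 <- min(cdd[accession == acc]$start)
      g3 <- max(cdd[accession == acc]$end)
      strand <- txd[accession == acc]$strand
      tc1 <- genomic_to_tx(exd[accession == acc], strand,
                           if (strand == "+") g5 else g3)
      tc2 <- genomic_to_tx(exd[accession == acc], strand,
                           if (strand == "+") g3 else g5)
      txd[accession == acc, `:=`(cds_start = tc1, cds_end = tc2)]
    }
  }
  txd[, coding := grepl("^NM_", accession) | !is.na(cds_start)]
  transcript_set(exd[, .(accession, exon_rank, start, end)],
                 txd, genome = genome)
}

.transcripts_from_bed <- function(gr, genome) {
  md <- S4Vectors::mcols(gr)
  nm <- as.character(md$name)
  parts <- strsplit(nm, "|", fixed = TRUE)
  acc <- vapply(parts, `[`, "", 1L)
  gid <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L], "")
  blocks <- md$blocks
  exl <- lapply(seq_along(gr), function(i) {
    b <- IRanges::shift(blocks[[i]], GenomicRanges::start(gr)[i] - 1L)
    data.table::data.table(start = IRanges::start(b), end = IRanges::end(b))
  })
  exd <- data.table::rbindlist(exl, idcol = "row")
  exd[, accession := acc[row]]
  strand <- as.character(GenomicRanges::strand(gr))
  exd[, strand := strand[row]]
  exd <- exd[order(accession, ifelse(strand == "+", 1L, -1L) * start)]
  exd[, exon_rank := seq_len(.N), by = accession]
  txd <- data.table::data.table(
    accession = acc, gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    cds_start = NA_integer_, cds_end = NA_integer_)
  thick <- md$thick
  if (!is.null(thick)) {
    for (i in seq_along(gr)) {
      th <- thick[i]
      if (IRanges::width(th) <= 1L) next  # BED convention: no CDS
      exi <- exd[accession == acc[i], .(accession, exon_rank, start, end)]
      if (strand[i] == "+") {
        txd$cds_start[i] <- genomic_to_tx(exi, strand[i], IRanges::start(th))
        txd$cds_end[i] <- genomic_to_tx(exi, strand[i], IRanges::end(th))
      } else {
        txd$cds_start[i] <- genomic_to_tx(exi, strand[i], IRanges::end(th))
        txd$cds_end[i] <- genomic_to_tx(exi, strand[i], IRanges::start(th))
      }
    }
  }
  txd[, coding := grepl("^NM_", accession) | !is.na(cds_start)]
  transcript_set(exd[, .(accession, exon_rank, start, end)],
                 txd, genome = genome)
}

# Map a genomic position to a 1-based transcript coordinate given the
# transcript's exons (data.table with exon_rank/start/end in transcription
# order) and strand. Position must be exonic.
genomic_to_tx <- function(exons, strand, gpos) {
  exons <- exons[order(exon_rank)]
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (gpos >= s && gpos <= e) {
      return(off + if (strand == "+") gpos - s + 1L else e - gpos + 1L)
    }
    off <- off + (e - s + 1L)
  }
  stop("genomic position ", gpos, " is not exonic in this transcript")
}

# Inverse of genomic_to_tx.
tx_to_genomic <- function(exons, strand, tpos) {
  exons <- exons[order(exon_rank)]
  off <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i] + 1L
    if (tpos <= off + w) {
      d <- tpos - off
      return(if (strand == "+") exons$start[i] + d - 1L
             else exons$end[i] - d + 1L)
    }
    off <- off + w
  }
  stop("transcript position ", tpos, " beyond transcript length")
}

#' Spliced transcript sequence
#'
#' @param txs a [transcript_set()].
#' @param genome genome from [load_genome()].
#' @param accession transcript accession.
#' @return the mRNA sequence (transcription orientation).
#' @export
transcript_sequence <- function(txs, genome, accession) {
  i <- match(accession, txs$tx$accession)
  if (is.na(i)) stop("unknown transcript: ", accession)
  .acc <- accession
  ex <- txs$exons[.(.acc)][order(exon_rank)]
  strand <- txs$tx$strand[i]
  chrom <- txs$tx$chrom[i]
  pieces <- vapply(seq_len(nrow(ex)), function(j) {
    genome_seq(genome, chrom, ex$start[j], ex$end[j], strand)
  }, "")
  paste(pieces, collapse = "")
}

#' Exon label in "e<index>/<count>" notation
#'
#' The conventional shorthand for exon position: `e4/5` is the fourth exon
#' of a five-exon transcript.
#'
#' @param exon_index 1-based exon index (transcription order).
#' @param exon_count number of exons in the transcript.
#' @return character vector of labels.
#' @export
exon_label <- function(exon_index, exon_count) {
  if (any(exon_index < 1L | exon_index > exon_count)) {
    stop("exon_index out of range")
  }
  sprintf("e%d/%d", as.integer(exon_index), as.integer(exon_count))
}

#' Catalogue donor and acceptor splice sites
#'
#' Enumerates the internal exon boundaries of every multi-exon transcript:
#' one donor at the transcription-direction end of each non-terminal exon,
#' one acceptor at the start of each non-initial exon. Sites shared between
#' alternative transcripts are deduplicated by (chrom, strand, position,
#' kind) with their exon labels and gene ids merged. Terminal transcript
#' boundaries are not splice sites; single-exon transcripts contribute
#' nothing.
#'
#' Donor position is the genomic coordinate of the last exonic base before
#' the intron; acceptor position is the first exonic base after it (both
#' 1-based).
#'
#' @param txs a [transcript_set()].
#' @return list with data.tables `donors` and `acceptors`, each with
#'   columns chrom, strand, pos, kind, labels (list of data.tables with
#'   accession/exon_index/exon_count), gene_ids (list of character).
#' @export
catalog_splice_sites <- function(txs) {
  recs <- list()
  for (i in seq_len(nrow(txs$tx))) {
    n <- txs$tx$n_exons[i]
    if (n < 2L) next
    acc <- txs$tx$accession[i]
    strand <- txs$tx$strand[i]
    chrom <- txs$tx$chrom[i]
    gid <- txs$tx$gene_id[i]
    ex <- txs$exons[.(acc)][order(exon_rank)]
    don_pos <- if (strand == "+") ex$end[-n] else ex$start[-n]
    acc_pos <- if (strand == "+") ex$start[-1L] else ex$end[-1L]
    recs[[length(recs) + 1L]] <- data.table::data.table(
      chrom = chrom, strand = strand,
      pos = c(don_pos, acc_pos),
      kind = rep(c("donor", "acceptor"), each = n - 1L),
      accession = acc,
      exon_index = c(seq_len(n - 1L), seq_len(n - 1L) + 1L),
      exon_count = n, gene_id = gid)
  }
  if (length(recs) == 0L) {
    empty <- data.table::data.table(
      chrom = character(), strand = character(), pos = integer(),
      kind = character(), labels = list(), gene_ids = list())
    return(list(donors = empty, acceptors = data.table::copy(empty)))
  }
  all <- data.table::rbindlist(recs)
  agg <- all[, .(
    labels = list(data.table::data.table(
      accession = accession, exon_index = exon_index,
      exon_count = exon_count)),
    gene_ids = list(sort(unique(gene_id)))),
    by = .(chrom, strand, pos, kind)]
  list(donors = agg[kind == "donor"][order(chrom, strand, pos)],
       acceptors = agg[kind == "acceptor"][order(chrom, strand, pos)])
}
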