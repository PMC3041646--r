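# Assembly of chimeric (readthrough) transcripts, coding-region prediction,
# frame and termination (NMD) classification, intervening-exon frame
# effects, and protein-domain preservation.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# translate starting at `from` (1-based, in frame) until the first stop;
# returns the amino-acid string (stop excluded) and the stop codon's first
# base position (NA when translation runs off the end without a stop)
.translate_to_stop <- function(seq, from) {
  n <- nchar(seq)
  starts <- seq.int(from, n - 2L, by = 3L)
  if (from > n - 2L) return(list(protein = "", stop_start = NA_integer_))
  codons <- substring(seq, starts, starts + 2L)
  stop_i <- which(codons %in% STOP_CODONS)
  gc <- Biostrings::GENETIC_CODE
  if (length(stop_i) == 0L) {
    aa <- gc[codons]
    aa[is.na(aa)] <- "X"
    return(list(protein = paste(aa, collapse = ""), stop_start = NA_integer_))
  }
  k <- stop_i[1L]
  aa <- if (k == 1L) character() else {
    a <- gc[codons[seq_len(k - 1L)]]
    a[is.na(a)] <- "X"
    a
  }
  list(protein = paste(aa, collapse = ""), stop_start = starts[k])
}

# all ATG-initiated ORFs (start..stop, complete) in the three frames;
# returns data.table(start, stop_start, codons)
.find_orfs <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) {
    return(data.table::data.table(start = integer(), stop_start = integer(),
                                  codons = integer()))
  }
  out <- list()
  atg <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1L]])
  atg <- atg[atg > 0L]
  for (s in atg) {
    tr <- .translate_to_stop(seq, s)
    if (is.na(tr$stop_start)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      start = s, stop_start = tr$stop_start,
      codons = (tr$stop_start - s) / 3L)
  }
  if (length(out) == 0L) {
    return(data.table::data.table(start = integer(), stop_start = integer(),
                                  codons = integer()))
  }
  unique(data.table::rbindlist(out))
}

#' Assemble a chimeric transcript
#'
#' Concatenates exons 1..donor_exon_index of the 5' transcript, an optional
#' intervening exon, and exons acceptor_exon_index..n of the 3' transcript,
#' extracting each segment's sequence from the genome in transcription
#' orientation.
#'
#' @param txs the [transcript_set()].
#' @param genome genome from [load_genome()].
#' @param tx5,tx3 accessions of the 5' and 3' transcripts.
#' @param donor_exon_index last 5' exon retained (1-based).
#' @param acceptor_exon_index first 3' exon retained (1-based).
#' @param intervening optional list(chrom, start, end, strand) for an
#'   intervening exon.
#' @return object of class `chimeric_transcript`: segments (data.table
#'   with source tags 5p/intervening/3p), sequence, junction_positions
#'   (transcript coordinate of the last base before each splice),
#'   last_exon_start, and bookkeeping fields used by [predict_cds()].
#' @export
assemble_chimera <- function(txs, genome, tx5, donor_exon_index,
                             tx3, acceptor_exon_index, intervening = NULL) {
  i5 <- match(tx5, txs$tx$accession)
  i3 <- match(tx3, txs$tx$accession)
  if (is.na(i5) || is.na(i3)) stop("unknown transcript accession")
  n5 <- txs$tx$n_exons[i5]; n3 <- txs$tx$n_exons[i3]
  if (donor_exon_index < 1L || donor_exon_index > n5) {
    stop("donor exon index out of range for ", tx5)
  }
  if (acceptor_exon_index < 1L || acceptor_exon_index > n3) {
    stop("acceptor exon index out of range for ", tx3)
  }
  ex5 <- txs$exons[.(tx5)][order(exon_rank)][seq_len(donor_exon_index)]
  ex3 <- txs$exons[.(tx3)][order(exon_rank)][seq.int(acceptor_exon_index, n3)]
  seg <- data.table::rbindlist(list(
    data.table::data.table(chrom = txs$tx$chrom[i5], strand = txs$tx$strand[i5],
                           start = ex5$start, end = ex5$end, source = "5p"),
    if (!is.null(intervening)) data.table::data.table(
      chrom = intervening$chrom, strand = intervening$strand,
      start = intervening$start, end = intervening$end,
      source = "intervening"),
    data.table::data.table(chrom = txs$tx$chrom[i3], strand = txs$tx$strand[i3],
                           start = ex3$start, end = ex3$end, source = "3p")))
  pieces <- vapply(seq_len(nrow(seg)), function(j) {
    genome_seq(genome, seg$chrom[j], seg$start[j], seg$end[j], seg$strand[j])
  }, "")
  lens <- nchar(pieces)
  cum <- cumsum(lens)
  structure(list(
    segments = seg,
    sequence = paste(pieces, collapse = ""),
    junction_positions = cum[-length(cum)],
    last_exon_start = cum[length(cum) - 1L] + 1L,
    prefix5_len = sum(lens[seg$source == "5p"]),
    intervening_len = sum(lens[seg$source == "intervening"]),
    suffix3_start = sum(lens[seg$source != "3p"]) + 1L,
    tx5 = tx5, tx3 = tx3,
    donor_exon_index = donor_exon_index,
    acceptor_exon_index = acceptor_exon_index,
    tx3_suffix_from = sum((txs$exons[.(tx3)][order(exon_rank)]$end -
                           txs$exons[.(tx3)][order(exon_rank)]$start +
                           1L)[seq_len(acceptor_exon_index - 1L)]) + 1L),
    class = "chimeric_transcript")
}

#' @export
print.chimeric_transcript <- function(x, ...) {
  cat(sprintf("chimeric_transcript %s(e1..%d) + %s(e%d..) : %d nt, %d segments\n",
              x$tx5, x$donor_exon_index, x$tx3, x$acceptor_exon_index,
              nchar(x$sequence), nrow(x$segments)))
  invisible(x)
}

#' Predict the coding region of a chimeric transcript
#'
#' When the 5' transcript's original start codon is retained in the chimera
#' (the breakpoint lies at or after the CDS start), translation proceeds
#' from it; otherwise the start is predicted from the longest ATG-initiated
#' open reading frame of at least `min_orf_codons` codons (ties broken
#' 5'-most). Classification: `full_cds` when the stop codon coincides with
#' the 3' transcript's original stop mapped into the chimera; `shift_3p`
#' when translation starts from the original 5' start but terminates
#' elsewhere; `new_tss` when the breakpoint precedes the original start.
#' Termination is `PTC` (premature, hence a nonsense-mediated-decay
#' substrate) when the stop codon begins before the start of the last
#' exon, else `TLE`.
#'
#' @param chimera a [assemble_chimera()] object.
#' @param txs the [transcript_set()] carrying the original CDS annotations
#'   (transcript coordinates, through the stop codon's last base).
#' @param min_orf_codons minimum reported ORF length for new-TSS
#'   prediction (default 30).
#' @return object of class `cds_call`: start_class, frame_class,
#'   termination_class, cds_start, stop_start, protein, noncoding flag,
#'   nmd_subject flag.
#' @export
predict_cds <- function(chimera, txs, min_orf_codons = 30L) {
  i5 <- match(chimera$tx5, txs$tx$accession)
  i3 <- match(chimera$tx3, txs$tx$accession)
  cds5_start <- txs$tx$cds_start[i5]
  cds3_end <- txs$tx$cds_end[i3]
  seq <- chimera$sequence
  # original 3' stop codon mapped into chimera coordinates (first stop base)
  mapped_stop3 <- NA_integer_
  if (!is.na(cds3_end) && cds3_end - 2L >= chimera$tx3_suffix_from) {
    mapped_stop3 <- (cds3_end - 2L) - chimera$tx3_suffix_from +
      chimera$suffix3_start
  }

  if (!is.na(cds5_start) && cds5_start <= chimera$prefix5_len) {
    start_class <- "original_tss"
    if (substring(seq, cds5_start, cds5_start + 2L) != "ATG") {
      stop("no start codon at the retained 5' CDS start")
    }
    cds_start <- cds5_start
  } else {
    start_class <- "new_tss"
    orfs <- .find_orfs(seq)
    orfs <- orfs[codons >= min_orf_codons]
    if (nrow(orfs) == 0L) {
      return(structure(list(start_class = start_class, frame_class = "new_tss",
                            termination_class = NA_character_,
                            cds_start = NA_integer_, stop_start = NA_integer_,
                            mapped_stop3 = mapped_stop3, protein = "",
                            noncoding = TRUE, nmd_subject = FALSE),
                       class = "cds_call"))
    }
    data.table::setorder(orfs, -codons, start)
    cds_start <- orfs$start[1L]
  }
  tr <- .translate_to_stop(seq, cds_start)
  stop_start <- tr$stop_start
  frame_class <- if (start_class == "new_tss") {
    "new_tss"
  } else if (!is.na(stop_start) && !is.na(mapped_stop3) &&
             stop_start == mapped_stop3) {
    "full_cds"
  } else {
    "shift_3p"
  }
  termination_class <- if (is.na(stop_start)) {
    "TLE"  # ran off the transcript end: terminates in (or past) the last exon
  } else if (stop_start < chimera$last_exon_start) "PTC" else "TLE"
  structure(list(start_class = start_class, frame_class = frame_class,
                 termination_class = termination_class,
                 cds_start = cds_start, stop_start = stop_start,
                 mapped_stop3 = mapped_stop3, protein = tr$protein,
                 noncoding = nchar(tr$protein) == 0L,
                 nmd_subject = termination_class == "PTC"),
            class = "cds_call")
}

#' @export
print.cds_call <- function(x, ...) {
  cat(sprintf("cds_call: %s / %s / %s, %d aa%s\n", x$start_class,
              x$frame_class, x$termination_class %||% "NA",
              nchar(x$protein), if (x$nmd_subject) " (NMD substrate)" else ""))
  invisible(x)
}

# does the call preserve the 3' gene's reading frame (stop at the mapped
# original stop)?
.frame_preserved <- function(call) {
  !is.na(call$stop_start) && !is.na(call$mapped_stop3) &&
    call$stop_start == call$mapped_stop3
}

#' Effect of an intervening exon on the chimera's coding potential
#'
#' Compares the coding calls of the same gene pair with and without the
#' intervening exon: `out_of_frame` (the exon breaks a previously
#' preserved 3' frame), `into_frame` (it restores it),
#' `stop_to_different_stop` (both premature, different stop codons
#' relative to the 3' gene), or `no_effect` (including the case where the
#' predicted start lies after the intervening exon, so the exon is not
#' translated differently).
#'
#' @param call_with [predict_cds()] call for the chimera with the exon.
#' @param call_without call for the chimera without it.
#' @param chimera_with,chimera_without the corresponding chimeras.
#' @return one of the four category strings.
#' @export
intervening_exon_frame_effect <- function(call_with, call_without,
                                          chimera_with, chimera_without) {
  ivl_end <- chimera_with$prefix5_len + chimera_with$intervening_len
  if (call_with$start_class == "new_tss" && !is.na(call_with$cds_start) &&
      call_with$cds_start > ivl_end &&
      identical(call_with$start_class, call_without$start_class)) {
    return("no_effect")
  }
  fw <- .frame_preserved(call_with)
  fo <- .frame_preserved(call_without)
  if (fo && !fw) return("out_of_frame")
  if (!fo && fw) return("into_frame")
  if (!fo && !fw) {
    # compare stop positions relative to the 3' segment
    sw <- call_with$stop_start - chimera_with$suffix3_start
    so <- call_without$stop_start - chimera_without$suffix3_start
    if (!is.na(sw) && !is.na(so) && sw != so &&
        call_with$termination_class == "PTC") {
      return("stop_to_different_stop")
    }
  }
  "no_effect"
}

# longest common prefix / suffix lengths of two strings
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- charToRaw(substring(a, 1L, n)); rb <- charToRaw(substring(b, 1L, n))
  d <- which(ra != rb)
  if (length(d) == 0L) n else d[1L] - 1L
}
.lcs <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ra <- rev(charToRaw(substring(a, nchar(a) - n + 1L, nchar(a))))
  rb <- rev(charToRaw(substring(b, nchar(b) - n + 1L, nchar(b))))
  d <- which(ra != rb)
  if (length(d) == 0L) n else d[1L] - 1L
}

#' Compare preserved protein domains between a chimera and its parents
#'
#' A 5' domain is preserved when its amino-acid interval lies entirely
#' within the longest common prefix of the chimeric and original 5'
#' proteins; a 3' domain when its interval lies within the longest common
#' suffix of the chimeric and original 3' proteins. Chimeras with a
#' premature termination codon preserve no 3' domains. Status per side:
#' `ND` (no original domains), `Null` (none preserved), `Subset` (some),
#' `Cover` (all).
#'
#' @param domains5,domains3 data.frames with columns domain, aa_start,
#'   aa_end (1-based amino-acid intervals on the original proteins); may
#'   have zero rows.
#' @param protein5,protein3 original protein sequences.
#' @param call the chimera's [predict_cds()] call.
#' @return list with elements `side5` and `side3`, each a list(status,
#'   preserved, original).
#' @export
compare_domains <- function(domains5, domains3, protein5, protein3, call) {
  domains5 <- data.table::as.data.table(domains5)
  domains3 <- data.table::as.data.table(domains3)
  chk <- function(d, prot, side) {
    if (nrow(d) > 0L &&
        (any(d$aa_start < 1L) || any(d$aa_end > nchar(prot)))) {
      stop("domain interval outside original ", side, " protein")
    }
  }
  chk(domains5, protein5, "5'")
  chk(domains3, protein3, "3'")
  p <- .lcp(call$protein, protein5)
  s <- if (call$termination_class %in% "PTC") 0L else .lcs(call$protein, protein3)
  keep5 <- if (nrow(domains5)) domains5$domain[domains5$aa_end <= p] else character()
  keep3 <- if (nrow(domains3)) {
    domains3$domain[domains3$aa_start > nchar(protein3) - s]
  } else character()
  status <- function(orig, kept) {
    if (length(orig) == 0L) "ND"
    else if (length(kept) == 0L) "Null"
    else if (setequal(kept, orig)) "Cover"
    else "Subset"
  }
  list(side5 = list(status = status(domains5$domain, keep5),
                    preserved = keep5, original = domains5$domain),
       side3 = list(status = status(domains3$domain, keep3),
                    preserved = keep3, original = domains3$domain))
}

#' Load a protein-domain table
#'
#' TSV with columns protein_id, domain, aa_start, aa_end (a score column
#' is tolerated and ignored). Domain intervals are consumed as given; no
#' HMM scanning is performed.
#'
#' @param path TSV file.
#' @return data.table.
#' @export
load_domain_table <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("protein_id", "domain", "aa_start", "aa_end")
  if (!all(need %in% names(d))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  d
}
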