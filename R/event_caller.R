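# Event calling on junction alignments: intragenic-equivalence filter,
# per-junction clustering, match-consistency filter, homology filters,
# shifted-junction FDR, isoform grouping and event reports.

#' Remove alignments to junctions joining two isoforms of one gene
#'
#' A candidate readthrough junction whose donor and acceptor gene-id sets
#' intersect merely spans a splice combination across two transcripts of
#' the same gene, and is removed.
#'
#' @param alignments alignment table from [align_reads()].
#' @param targets the junction-target table the index was built from.
#' @return the surviving alignments.
#' @export
filter_intragenic_equivalents <- function(alignments, targets) {
  if (nrow(alignments) == 0L) return(alignments)
  m <- match(alignments$junction_id, targets$junction_id)
  shared <- vapply(m, function(i) {
    length(intersect(targets$donor_genes[[i]], targets$acceptor_genes[[i]])) > 0L
  }, TRUE)
  alignments[!shared]
}

#' Cluster junction alignments by junction
#'
#' @param alignments alignment table.
#' @param targets junction-target table (for target sequence and junction
#'   position).
#' @return named list of clusters; each cluster is a list with junction_id,
#'   target_seq, junction_at and the alignment sub-table.
#' @export
build_clusters <- function(alignments, targets) {
  if (nrow(alignments) == 0L) return(list())
  m <- match(unique(alignments$junction_id), targets$junction_id)
  ids <- unique(alignments$junction_id)
  cl <- lapply(seq_along(ids), function(i) {
    list(junction_id = ids[i],
         target_seq = targets$seq[m[i]],
         junction_at = targets$junction_at[m[i]],
         alignments = alignments[junction_id == ids[i]])
  })
  names(cl) <- ids
  cl
}

# per-target-position coverage and match counts for a cluster
.cluster_profile <- function(cluster) {
  a <- cluster$alignments
  tlen <- nchar(cluster$target_seq)
  cov <- integer(tlen)
  mat <- integer(tlen)
  for (i in seq_len(nrow(a))) {
    L <- a$left_overhang[i] + a$right_overhang[i]
    span <- seq.int(a$target_offset[i], a$target_offset[i] + L - 1L)
    cov[span] <- cov[span] + 1L
    ok <- setdiff(span, a$mismatch_positions[[i]])
    mat[ok] <- mat[ok] + 1L
  }
  list(coverage = cov, matches = mat)
}

#' Match-consistency filter for a junction cluster
#'
#' Accepts a cluster only when every one of the `window` positions
#' immediately left and right of the junction has at least one covering
#' read that matches the target there (a "consistent match"), and no
#' covered position anywhere in the cluster span is mismatched by every
#' read covering it (a "consistent mismatch"). For a singleton cluster
#' this reduces to one read matching all `window` bases on both sides.
#'
#' @param cluster one element of [build_clusters()].
#' @param window number of junction-flanking positions that must be
#'   consistently matched on each side (default 11).
#' @return list with `pass` (logical) and `reason` (NA, "side_coverage"
#'   or "consistent_mismatch").
#' @export
consistency_filter <- function(cluster, window = 11L) {
  stopifnot(nrow(cluster$alignments) > 0L)
  prof <- .cluster_profile(cluster)
  jat <- cluster$junction_at
  tlen <- nchar(cluster$target_seq)
  left <- seq.int(jat - window + 1L, jat)
  right <- seq.int(jat + 1L, jat + window)
  if (any(left < 1L) || any(right > tlen)) {
    return(list(pass = FALSE, reason = "side_coverage"))
  }
  covered <- which(prof$coverage > 0L)
  if (any(prof$matches[covered] == 0L)) {
    return(list(pass = FALSE, reason = "consistent_mismatch"))
  }
  sides <- c(left, right)
  if (any(prof$coverage[sides] == 0L) || any(prof$matches[sides] == 0L)) {
    return(list(pass = FALSE, reason = "side_coverage"))
  }
  list(pass = TRUE, reason = NA_character_)
}

# local alignment of two sequences with the package's homology scoring;
# returns aligned pattern/subject character vectors (with "-" gaps)
.local_alignment <- function(pattern, subject, match = 1, mismatch = -1,
                             gap_open = 2, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(p = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]],
       s = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]])
}

# max number of matches in any window of `size` alignment columns
.max_window_matches <- function(p, s, size = 50L) {
  m <- as.integer(p == s & p != "-")
  n <- length(m)
  if (n == 0L) return(0L)
  w <- min(size, n)
  cs <- cumsum(m)
  max(cs[w:n] - c(0L, cs)[seq.int(1L, n - w + 1L)])
}

#' Homology filter for a junction cluster
#'
#' Two rejection rules against false positives from homologous (often
#' paralogous) genes: (1) junction homology — the junction fragment (the
#' longest observed left overhang concatenated with the longest observed
#' right overhang) locally aligns over 90\% or more of its length to any
#' transcript of either component gene; (2) gene homology — any transcript
#' of the 5' gene locally aligns to any transcript of the 3' gene with at
#' least 40 matching columns inside a 50-column window. Local alignment
#' scoring: match +1, mismatch -1, gap open -2, gap extend -1.
#'
#' @param cluster one element of [build_clusters()].
#' @param tx_seqs5 named character vector of 5'-gene transcript sequences.
#' @param tx_seqs3 named character vector of 3'-gene transcript sequences.
#' @param fraction junction-homology coverage threshold (default 0.90).
#' @param window_matches,window_size gene-homology rule (default 40 within
#'   50).
#' @return list with `pass` and `reason` (NA, "junction_homology" or
#'   "gene_homology").
#' @export
homology_filter <- function(cluster, tx_seqs5, tx_seqs3, fraction = 0.90,
                            window_matches = 40L, window_size = 50L) {
  if (length(tx_seqs5) == 0L || length(tx_seqs3) == 0L) {
    stop("missing transcript sequences for homology filter")
  }
  a <- cluster$alignments
  jat <- cluster$junction_at
  maxL <- max(a$left_overhang)
  maxR <- max(a$right_overhang)
  frag <- substring(cluster$target_seq, jat - maxL + 1L, jat + maxR)
  flen <- nchar(frag)
  for (txseq in c(tx_seqs5, tx_seqs3)) {
    al <- .local_alignment(frag, txseq)
    aligned_cols <- sum(al$p != "-" & al$s != "-")
    if (aligned_cols / flen >= fraction) {
      return(list(pass = FALSE, reason = "junction_homology"))
    }
  }
  for (s5 in tx_seqs5) {
    for (s3 in tx_seqs3) {
      al <- .local_alignment(s5, s3)
      if (.max_window_matches(al$p, al$s, window_size) >= window_matches) {
        return(list(pass = FALSE, reason = "gene_homology"))
      }
    }
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Shifted-junction false discovery rate
#'
#' FDR of the event caller estimated as the number of candidates surviving
#' the identical pipeline run against shifted control junctions, divided by
#' the number of accepted real events.
#'
#' @param n_control surviving control-arm candidate count.
#' @param n_real accepted event count.
#' @return list with n_control, n_real, fdr (fraction, NA when n_real is
#'   0) and percent (percentage rounded to one decimal).
#' @export
estimate_fdr <- function(n_control, n_real) {
  stopifnot(n_control >= 0L, n_real >= 0L)
  fdr <- if (n_real > 0L) n_control / n_real else NA_real_
  structure(list(n_control = as.integer(n_control),
                 n_real = as.integer(n_real),
                 fdr = fdr,
                 percent = round(100 * fdr, 1L)),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf("FDR: %d/%d = %s%%\n", x$n_control, x$n_real,
              ifelse(is.na(x$percent), "NA", format(x$percent, nsmall = 1))))
  invisible(x)
}

#' Call readthrough events from surviving clusters
#'
#' One event per junction: gene pair, representative donor/acceptor exon
#' labels (lexicographically first transcript), splice and intergenic
#' distances, read and sample support, the (n-1)->+2 pattern flag (the
#' donor is the penultimate exon of the 5' gene and the acceptor the
#' second exon of the 3' gene for some label), and an isoform group shared
#' by events joining the same gene pair, with its shared splice site
#' annotated.
#'
#' @param clusters surviving clusters from [build_clusters()].
#' @param targets junction-target table.
#' @return data.table of events.
#' @export
call_events <- function(clusters, targets) {
  if (length(clusters) == 0L) return(.empty_events())
  rows <- lapply(clusters, function(cl) {
    i <- match(cl$junction_id, targets$junction_id)
    dl <- targets$donor_labels[[i]]
    al <- targets$acceptor_labels[[i]]
    dl <- dl[order(accession)]
    al <- al[order(accession)]
    data.table::data.table(
      junction_id = cl$junction_id,
      gene5 = targets$donor_genes[[i]][1L],
      gene3 = targets$acceptor_genes[[i]][1L],
      donor_label = exon_label(dl$exon_index[1L], dl$exon_count[1L]),
      acceptor_label = exon_label(al$exon_index[1L], al$exon_count[1L]),
      chrom = targets$chrom[i], strand = targets$strand[i],
      donor_pos = targets$donor_pos[i], acceptor_pos = targets$acceptor_pos[i],
      splice_distance = targets$splice_distance[i],
      intergenic_distance = targets$intergenic_distance[i],
      n_reads = nrow(cl$alignments),
      samples = list(sort(unique(cl$alignments$sample_id))),
      pattern_flag = any(dl$exon_index == dl$exon_count - 1L) &&
        any(al$exon_index == 2L))
  })
  ev <- data.table::rbindlist(rows)
  data.table::setorder(ev, gene5, gene3, donor_pos, acceptor_pos)
  ev[, isoform_group := .GRP, by = .(gene5, gene3)]
  ev[, shared_site := {
    if (.N == 1L) NA_character_
    else if (data.table::uniqueN(acceptor_pos) == 1L) "acceptor"
    else if (data.table::uniqueN(donor_pos) == 1L) "donor"
    else "none"
  }, by = isoform_group]
  ev[]
}

.empty_events <- function() {
  data.table::data.table(
    junction_id = character(), gene5 = character(), gene3 = character(),
    donor_label = character(), acceptor_label = character(),
    chrom = character(), strand = character(), donor_pos = integer(),
    acceptor_pos = integer(), splice_distance = integer(),
    intergenic_distance = integer(), n_reads = integer(), samples = list(),
    pattern_flag = logical(), isoform_group = integer(),
    shared_site = character())
}

#' Run the full readthrough-detection arm
#'
#' Orchestrates the targeted-alignment pipeline over one target set:
#' alignment, intragenic-equivalence filter, intragenic-placement
#' preference, overhang support, clustering, consistency filter and
#' homology filter, in that order, logging stage attrition.
#'
#' @param reads read table (read_id, sample_id, sequence).
#' @param targets readthrough (or control) junction targets.
#' @param intragenic_index index over intragenic targets, used both as the
#'   competing alignment universe and for the placement preference; NULL to
#'   skip the preference step.
#' @param txs,genome gene model and genome, for homology-filter transcript
#'   sequences.
#' @param overhang_min candidate-stage overhang threshold (default 8).
#' @param window consistency window (default 11).
#' @param max_mismatches aligner threshold (default 1).
#' @param homology_fraction,homology_matches,homology_window homology-rule
#'   parameters (defaults 0.90, 40, 50).
#' @param k seed length for the target index.
#' @return list with `events`, `clusters`, `attrition` (named integer
#'   vector of per-stage survivor counts) and `alignments`.
#' @export
detect_tic_events <- function(reads, targets, intragenic_index, txs, genome,
                              overhang_min = 8L, window = 11L,
                              max_mismatches = 1L, homology_fraction = 0.90,
                              homology_matches = 40L, homology_window = 50L,
                              k = 12L) {
  attrition <- c()
  idx <- build_index(targets, k = k)
  res <- align_reads(reads, idx, max_mismatches = max_mismatches)
  aln <- res$alignments
  attrition["aligned"] <- nrow(aln)
  aln <- filter_intragenic_equivalents(aln, targets)
  attrition["post_equivalence"] <- nrow(aln)
  if (!is.null(intragenic_index) && nrow(aln) > 0L) {
    aln <- prefer_intragenic(aln, reads, intragenic_index, max_mismatches)
  }
  attrition["post_intragenic_preference"] <- nrow(aln)
  if (nrow(aln) > 0L) aln <- aln[supports_junction(aln, overhang_min)]
  attrition["post_overhang"] <- nrow(aln)
  clusters <- build_clusters(aln, targets)
  attrition["clusters"] <- length(clusters)
  clusters <- Filter(function(cl) consistency_filter(cl, window)$pass, clusters)
  attrition["post_consistency"] <- length(clusters)
  seq_cache <- .make_seq_cache(txs, genome)
  gene_tx_seqs <- function(gid) {
    accs <- txs$tx[gene_id == gid]$accession
    if (length(accs) == 0L) stop("no transcript sequence for gene ", gid)
    vapply(accs, seq_cache, "")
  }
  clusters <- Filter(function(cl) {
    i <- match(cl$junction_id, targets$junction_id)
    homology_filter(cl,
                    gene_tx_seqs(targets$donor_genes[[i]][1L]),
                    gene_tx_seqs(targets$acceptor_genes[[i]][1L]),
                    fraction = homology_fraction,
                    window_matches = homology_matches,
                    window_size = homology_window)$pass
  }, clusters)
  attrition["post_homology"] <- length(clusters)
  events <- call_events(clusters, targets)
  attrition["events"] <- nrow(events)
  list(events = events, clusters = clusters, attrition = attrition,
       alignments = aln)
}

#' Control arm of the FDR estimate
#'
#' Runs the identical pipeline against shifted control junctions and
#' returns the surviving candidate count (the FDR numerator).
#'
#' @param reads read table.
#' @param control_targets output of [build_control_targets()].
#' @inheritParams detect_tic_events
#' @param ... passed through to [detect_tic_events()].
#' @return integer candidate count.
#' @export
run_control_arm <- function(reads, control_targets, intragenic_index,
                            txs, genome, ...) {
  if (nrow(control_targets) == 0L) return(0L)
  res <- detect_tic_events(reads, control_targets, intragenic_index,
                           txs, genome, ...)
  nrow(res$events)
}
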