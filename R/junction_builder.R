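# Junction-target construction: artificial exon-exon junction sequences used
# as alignment targets. Three kinds are built: "intragenic" (all exon pairs
# within a transcript), "tic" (candidate readthrough donor-acceptor pairs
# within a distance window) and "control" (shifted junctions used as a null
# for FDR estimation).

# Flank of a splice site along the spliced transcript, crossing exon
# boundaries when the terminal exon is shorter than the requested flank.
# For a donor, the flank is the transcript sequence ending at the donor
# base; for an acceptor, the sequence starting at the acceptor base. The
# representative transcript is the one yielding the longest flank, ties
# broken by lexicographic accession.
.site_flank <- function(site_labels, txs, seq_cache, kind, flank) {
  best <- NULL
  for (j in seq_len(nrow(site_labels))) {
    acc <- site_labels$accession[j]
    idx <- site_labels$exon_index[j]
    ex <- txs$exons[.(acc)][order(exon_rank)]
    lens <- ex$end - ex$start + 1L
    if (kind == "donor") {
      avail <- sum(lens[seq_len(idx)])
    } else {
      avail <- sum(lens) - sum(lens[seq_len(idx - 1L)])
    }
    got <- min(flank, avail)
    cand <- list(accession = acc, idx = idx, got = got, avail = avail)
    if (is.null(best) || got > best$got ||
        (got == best$got && acc < best$accession)) {
      best <- cand
    }
  }
  txseq <- seq_cache(best$accession)
  ex <- txs$exons[.(best$accession)][order(exon_rank)]
  lens <- ex$end - ex$start + 1L
  if (kind == "donor") {
    endpos <- sum(lens[seq_len(best$idx)])
    s <- substring(txseq, endpos - best$got + 1L, endpos)
  } else {
    startpos <- sum(lens[seq_len(best$idx - 1L)]) + 1L
    s <- substring(txseq, startpos, startpos + best$got - 1L)
  }
  list(seq = s, truncated = best$got < flank, accession = best$accession)
}

.make_seq_cache <- function(txs, genome) {
  env <- new.env(parent = emptyenv())
  function(acc) {
    if (is.null(env[[acc]])) env[[acc]] <- transcript_sequence(txs, genome, acc)
    env[[acc]]
  }
}

.gene_extents <- function(txs) {
  ex <- merge(txs$exons, txs$tx[, .(accession, gene_id, chrom, strand)],
              by = "accession")
  ex[, .(start = min(start), end = max(end)),
     by = .(gene_id, chrom, strand)]
}

.empty_targets <- function() {
  data.table::data.table(
    junction_id = character(), kind = character(), chrom = character(),
    strand = character(), donor_pos = integer(), acceptor_pos = integer(),
    left_seq = character(), right_seq = character(), seq = character(),
    junction_at = integer(), splice_distance = integer(),
    intergenic_distance = integer(), donor_genes = list(),
    acceptor_genes = list(), donor_labels = list(), acceptor_labels = list(),
    truncated = logical(), source_junction_id = character())
}

#' Build candidate readthrough (TIC) junction targets
#'
#' Pairs every catalogued donor with every catalogued acceptor on the same
#' chromosome and strand that lies strictly downstream in transcription
#' orientation, within `max_distance`, and shares no transcript accession
#' with the donor. Each qualifying pair yields one artificial junction
#' sequence: `flank` nt of spliced transcript upstream of the donor
#' concatenated with `flank` nt downstream of the acceptor (160 nt total at
#' the default flank of 80, shorter when a terminal exon runs out of
#' transcript, in which case the target is flagged truncated).
#'
#' @param sites site catalogs from [catalog_splice_sites()].
#' @param txs the [transcript_set()].
#' @param genome genome from [load_genome()].
#' @param max_distance maximum donor-acceptor distance in bp (default
#'   200000).
#' @param flank flank length in nt on each side (default 80).
#' @param strict_adjacency if TRUE, drop pairs whose donor and acceptor
#'   genes have another annotated gene entirely between them (default
#'   FALSE: gene-skipping pairs are generated).
#' @return data.table of junction targets.
#' @export
build_tic_targets <- function(sites, txs, genome, max_distance = 200000L,
                              flank = 80L, strict_adjacency = FALSE) {
  donors <- sites$donors
  acceptors <- sites$acceptors
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) return(.empty_targets())
  seq_cache <- .make_seq_cache(txs, genome)
  extents <- .gene_extents(txs)
  out <- vector("list", 0L)
  for (ch in unique(donors$chrom)) {
    for (st in c("+", "-")) {
      dn <- donors[chrom == ch & strand == st]
      ac <- acceptors[chrom == ch & strand == st]
      if (nrow(dn) == 0L || nrow(ac) == 0L) next
      for (i in seq_len(nrow(dn))) {
        dp <- dn$pos[i]
        if (st == "+") {
          hit <- which(ac$pos > dp & ac$pos - dp <= max_distance)
        } else {
          hit <- which(ac$pos < dp & dp - ac$pos <= max_distance)
        }
        if (length(hit) == 0L) next
        dacc <- dn$labels[[i]]$accession
        for (j in hit) {
          if (length(intersect(dacc, ac$labels[[j]]$accession)) > 0L) next
          if (strict_adjacency &&
              .gene_between(extents, ch, st, dp, ac$pos[j],
                            dn$gene_ids[[i]], ac$gene_ids[[j]])) next
          lf <- .site_flank(dn$labels[[i]], txs, seq_cache, "donor", flank)
          rf <- .site_flank(ac$labels[[j]], txs, seq_cache, "acceptor", flank)
          igd <- .intergenic_distance(extents, st,
                                      dn$gene_ids[[i]][1L],
                                      ac$gene_ids[[j]][1L])
          out[[length(out) + 1L]] <- data.table::data.table(
            junction_id = sprintf("tic|%s:%s:%d-%d", ch, st, dp, ac$pos[j]),
            kind = "tic", chrom = ch, strand = st,
            donor_pos = dp, acceptor_pos = ac$pos[j],
            left_seq = lf$seq, right_seq = rf$seq,
            seq = paste0(lf$seq, rf$seq), junction_at = nchar(lf$seq),
            splice_distance = abs(ac$pos[j] - dp),
            intergenic_distance = igd,
            donor_genes = list(dn$gene_ids[[i]]),
            acceptor_genes = list(ac$gene_ids[[j]]),
            donor_labels = list(dn$labels[[i]]),
            acceptor_labels = list(ac$labels[[j]]),
            truncated = lf$truncated || rf$truncated,
            source_junction_id = NA_character_)
        }
      }
    }
  }
  if (length(out) == 0L) return(.empty_targets())
  data.table::rbindlist(out)
}

# any gene extent strictly inside the (donor, acceptor) genomic interval?
.gene_between <- function(extents, ch, st, dp, ap, dgenes, agenes) {
  lo <- min(dp, ap); hi <- max(dp, ap)
  cand <- extents[chrom == ch & strand == st &
                  start > lo & end < hi &
                  !gene_id %in% c(dgenes, agenes)]
  nrow(cand) > 0L
}

# gap between the 5' gene's extent and the 3' gene's extent in
# transcription orientation; NA when either gene is unknown, negative when
# the extents overlap.
.intergenic_distance <- function(extents, st, g5, g3) {
  e5 <- extents[gene_id == g5]
  e3 <- extents[gene_id == g3]
  if (nrow(e5) == 0L || nrow(e3) == 0L) return(NA_integer_)
  if (st == "+") as.integer(e3$start[1L] - e5$end[1L] - 1L)
  else as.integer(e5$start[1L] - e3$end[1L] - 1L)
}

#' Build intragenic junction targets
#'
#' Builds one target per ordered exon pair (i, j), i < j in transcription
#' order, within each multi-exon transcript, regardless of distance, then
#' deduplicates across isoforms by junction coordinates. These targets give
#' reads arising from ordinary (including exon-skipping) splicing somewhere
#' to align, so that they are not forced onto readthrough targets.
#'
#' @inheritParams build_tic_targets
#' @return data.table of junction targets (kind "intragenic").
#' @export
build_intragenic_targets <- function(txs, genome, flank = 80L) {
  seq_cache <- .make_seq_cache(txs, genome)
  out <- vector("list", 0L)
  for (t in seq_len(nrow(txs$tx))) {
    n <- txs$tx$n_exons[t]
    if (n < 2L) next
    acc <- txs$tx$accession[t]
    st <- txs$tx$strand[t]
    ch <- txs$tx$chrom[t]
    gid <- txs$tx$gene_id[t]
    ex <- txs$exons[.(acc)][order(exon_rank)]
    lens <- ex$end - ex$start + 1L
    txseq <- seq_cache(acc)
    cum <- cumsum(lens)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        dp <- if (st == "+") ex$end[i] else ex$start[i]
        ap <- if (st == "+") ex$start[j] else ex$end[j]
        lgot <- min(flank, cum[i])
        ls <- substring(txseq, cum[i] - lgot + 1L, cum[i])
        rstart <- cum[j] - lens[j] + 1L
        rgot <- min(flank, cum[n] - rstart + 1L)
        rs <- substring(txseq, rstart, rstart + rgot - 1L)
        out[[length(out) + 1L]] <- data.table::data.table(
          junction_id = sprintf("intra|%s:%s:%d-%d", ch, st, dp, ap),
          kind = "intragenic", chrom = ch, strand = st,
          donor_pos = dp, acceptor_pos = ap,
          left_seq = ls, right_seq = rs, seq = paste0(ls, rs),
          junction_at = nchar(ls),
          splice_distance = abs(ap - dp),
          intergenic_distance = NA_integer_,
          donor_genes = list(gid), acceptor_genes = list(gid),
          donor_labels = list(data.table::data.table(
            accession = acc, exon_index = i, exon_count = n)),
          acceptor_labels = list(data.table::data.table(
            accession = acc, exon_index = j, exon_count = n)),
          truncated = lgot + rgot < 2L * flank,
          source_junction_id = NA_character_)
      }
    }
  }
  if (length(out) == 0L) return(.empty_targets())
  all <- data.table::rbindlist(out)
  # deduplicate across isoforms: keep the variant with the longest target
  all[, .len := nchar(seq)]
  data.table::setorder(all, junction_id, -.len)
  all <- all[!duplicated(junction_id)]
  all[, .len := NULL]
  all[]
}

#' Build shifted control junction targets
#'
#' For every input target, deletes the five bases at distances 6..10 from
#' the junction on each side (positions -10..-6 into the left flank and
#' +6..+10 into the right flank), preserving the five junction-proximal
#' bases and rejoining them to the shifted distal sequence. A read that
#' matches a genuine junction with an overhang of at least 6 nt cannot
#' match its control without multiple mismatches, so the control set
#' behaves as a null for FDR estimation. Targets with under 10 nt on
#' either side are skipped with a warning.
#'
#' @param targets data.table of targets from the builders above.
#' @return data.table of control targets (each 10 nt shorter than its
#'   source).
#' @export
build_control_targets <- function(targets) {
  ok <- nchar(targets$left_seq) >= 10L & nchar(targets$right_seq) >= 10L
  if (any(!ok)) {
    warning(sum(!ok), " target(s) with flank < 10 nt skipped")
  }
  src <- targets[ok]
  if (nrow(src) == 0L) return(.empty_targets())
  ctl <- data.table::copy(src)
  nl <- nchar(src$left_seq)
  ctl[, left_seq := paste0(substring(src$left_seq, 1L, nl - 10L),
                           substring(src$left_seq, nl - 4L, nl))]
  ctl[, right_seq := paste0(substring(src$right_seq, 1L, 5L),
                            substring(src$right_seq, 11L))]
  ctl[, seq := paste0(left_seq, right_seq)]
  ctl[, junction_at := nchar(left_seq)]
  ctl[, source_junction_id := src$junction_id]
  ctl[, junction_id := paste0("ctl|", src$junction_id)]
  ctl[, kind := "control"]
  ctl[]
}

#' Export junction targets as FASTA
#'
#' @param targets data.table of targets.
#' @param path output FASTA path.
#' @export
targets_to_fasta <- function(targets, path) {
  ss <- Biostrings::DNAStringSet(targets$seq)
  names(ss) <- sprintf("%s %s dist=%s", targets$junction_id, targets$kind,
                       targets$splice_distance)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
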