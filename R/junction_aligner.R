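# Short-read alignment to junction targets: exact k-mer seeding followed by
# ungapped full-length extension. A read supports a junction only when it
# has a unique, <=1-mismatch, indel-free, full-length alignment crossing the
# junction. This deliberately simple engine reproduces the acceptance
# contract of a seeded genomic aligner restricted to substitution-only
# alignments.

#' Load short reads from FASTQ or FASTA
#'
#' @param path reads file; format detected from extension (fq/fastq vs
#'   fa/fasta) unless given.
#' @param sample_id sample identifier attached to every read; defaults to
#'   the file name without extension.
#' @param format "auto", "fastq" or "fasta".
#' @return data.table with columns read_id, sample_id, sequence.
#' @export
load_reads <- function(path, sample_id = NULL,
                       format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  ss <- Biostrings::readBStringSet(path, format = format)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  data.table::data.table(
    read_id = sub("\\s.*$", "", names(ss)),
    sample_id = sample_id,
    sequence = toupper(as.character(ss)))
}

#' Build a k-mer index over junction targets
#'
#' Targets sharing identical junction coordinates (chrom, strand, donor
#' position, acceptor position) are collapsed before indexing, so that
#' duplicate targets arising from alternative isoforms cannot destroy
#' alignment uniqueness. Every k-mer of every collapsed target is posted.
#'
#' @param targets data.table of junction targets.
#' @param k seed length (default 12; less than 8 is refused as too
#'   unspecific).
#' @return a `junction_index` object.
#' @export
build_index <- function(targets, k = 12L) {
  if (k < 8L) stop("seed length k < 8 is too unspecific")
  if (nrow(targets) == 0L) stop("no targets to index")
  tg <- data.table::copy(targets)
  tg[, .jkey := paste(chrom, strand, donor_pos, acceptor_pos, sep = ":")]
  tg <- tg[!duplicated(.jkey)]
  tg[, .jkey := NULL]
  tg[, target_idx := seq_len(.N)]
  lens <- nchar(tg$seq)
  noff <- pmax(lens - k + 1L, 0L)
  tidx <- rep.int(tg$target_idx, noff)
  toff <- unlist(lapply(noff, seq_len), use.names = FALSE)
  postings <- data.table::data.table(
    kmer = substring(tg$seq[tidx], toff, toff + k - 1L),
    target_idx = tidx, toff = toff)
  data.table::setkey(postings, kmer)
  structure(list(targets = tg, postings = postings, k = as.integer(k)),
            class = "junction_index")
}

#' @export
print.junction_index <- function(x, ...) {
  cat(sprintf("junction_index: %d targets, k=%d, %d postings\n",
              nrow(x$targets), x$k, nrow(x$postings)))
  invisible(x)
}

# Enumerate unique candidate placements (read_idx, target_idx, start) from
# exact k-mer seeds. start is the 1-based read start on the target and may
# fall outside the target (flagged by the caller).
#
# Seeding uses the pigeonhole principle: max_mismatches + 1 disjoint
# k-windows of the read (when it is long enough to hold them) — any
# ungapped placement within the mismatch budget leaves at least one window
# exact, so the candidate set over that budget is identical to trying
# every k-mer. Shorter reads fall back to all k-mer positions.
.seed_candidates <- function(sequences, index, max_mismatches = 1L) {
  k <- index$k
  L <- nchar(sequences)
  usable <- which(L >= k)
  if (length(usable) == 0L) {
    return(data.table::data.table(read_idx = integer(),
                                  target_idx = integer(), start = integer()))
  }
  nwin <- max_mismatches + 1L
  seed_offsets <- function(len) {
    if (len >= nwin * k) {
      # nwin disjoint windows spread across the read
      as.integer(round(seq(1L, len - k + 1L, length.out = nwin)))
    } else {
      seq_len(len - k + 1L)
    }
  }
  offs <- lapply(L[usable], seed_offsets)
  noff <- lengths(offs)
  ridx <- rep.int(usable, noff)
  roff <- unlist(offs, use.names = FALSE)
  q <- data.table::data.table(
    kmer = substring(sequences[ridx], roff, roff + k - 1L),
    read_idx = ridx, roff = roff)
  hits <- index$postings[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) {
    return(data.table::data.table(read_idx = integer(),
                                  target_idx = integer(), start = integer()))
  }
  hits[, start := toff - roff + 1L]
  unique(hits[, .(read_idx, target_idx, start)])
}

#' Align short reads to a junction index
#'
#' Seed-and-extend alignment: exact k-mer seeds (pigeonhole windows, see
#' `.seed_candidates`) propose candidate ungapped full-length placements,
#' finding every placement within the mismatch budget; placements with at most
#' `max_mismatches` substitutions (N never matches) are kept; a read is
#' accepted only if exactly one junction attains the minimum mismatch count
#' among placements that cross the junction (at least one read base on each
#' side). Everything else is rejected with a reason: `no_hit` (no seed
#' candidate), `multi_mapped` (tied junctions at the minimum),
#' `too_many_mismatches`, `no_junction_overlap` (good placement not
#' crossing the junction), or `clipped` (placements only beyond the target
#' ends).
#'
#' @param reads data.table with read_id, sample_id, sequence.
#' @param index a [build_index()] object.
#' @param max_mismatches maximum substitutions accepted (default 1).
#' @return list with `alignments` (data.table: read_id, sample_id,
#'   junction_id, target_idx, target_offset, mismatches,
#'   mismatch_positions, left_overhang, right_overhang) and `rejects`
#'   (data.table: read_id, reason).
#' @export
align_reads <- function(reads, index, max_mismatches = 1L) {
  reads <- data.table::as.data.table(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (!"sample_id" %in% names(reads)) reads[, sample_id := "sample1"]
  n <- nrow(reads)
  reject <- function(idx, why) data.table::data.table(
    read_id = reads$read_id[idx], reason = why)
  if (n == 0L) {
    return(list(alignments = .empty_alignments(), rejects = reject(integer(), character())))
  }
  L <- nchar(reads$sequence)
  if (index$k > floor(min(L) / 2)) {
    warning("seed length exceeds half the shortest read; ",
            "1-mismatch placements may be missed")
  }
  cand <- .seed_candidates(reads$sequence, index, max_mismatches)
  tlen <- nchar(index$targets$seq)
  jat <- index$targets$junction_at
  status <- rep("no_hit", n)
  status[unique(cand$read_idx)] <- "pending"

  aln <- .empty_alignments()
  if (nrow(cand) > 0L) {
    cand[, Lr := L[read_idx]]
    cand[, inb := start >= 1L & start + Lr - 1L <= tlen[target_idx]]
    # note rejection evidence for reads with only out-of-bounds candidates
    clipped_reads <- setdiff(unique(cand$read_idx), unique(cand[inb == TRUE]$read_idx))
    status[clipped_reads] <- "clipped"
    cand <- cand[inb == TRUE]
  }
  if (nrow(cand) > 0L) {
    cand[, mm := .mismatch_counts(reads$sequence, index$targets$seq,
                                  read_idx, target_idx, start,
                                  as.integer(max_mismatches))]
    cand[, lov := jat[target_idx] - start + 1L]
    cand[, rov := Lr - lov]
    cand[, ok := mm <= max_mismatches & lov >= 1L & rov >= 1L]
    bad <- cand[, .(any_ok = any(ok),
                    any_mm_ok = any(mm <= max_mismatches)), by = read_idx]
    status[bad[any_ok == FALSE & any_mm_ok == TRUE]$read_idx] <- "no_junction_overlap"
    status[bad[any_ok == FALSE & any_mm_ok == FALSE]$read_idx] <- "too_many_mismatches"

    acc <- cand[ok == TRUE]
    if (nrow(acc) > 0L) {
      acc[, minmm := min(mm), by = read_idx]
      acc <- acc[mm == minmm]
      nj <- acc[, .(njunc = data.table::uniqueN(target_idx)), by = read_idx]
      multi <- nj[njunc > 1L]$read_idx
      status[multi] <- "multi_mapped"
      uni <- acc[!read_idx %in% multi]
      if (nrow(uni) > 0L) {
        data.table::setorder(uni, read_idx, start)
        uni <- uni[!duplicated(read_idx)]
        status[uni$read_idx] <- "accepted"
        mp <- lapply(seq_len(nrow(uni)), function(i) {
          if (uni$mm[i] == 0L) return(integer())
          r <- charToRaw(reads$sequence[uni$read_idx[i]])
          t <- charToRaw(substring(index$targets$seq[uni$target_idx[i]],
                                   uni$start[i], uni$start[i] + uni$Lr[i] - 1L))
          which(r != t | r == charToRaw("N")) + uni$start[i] - 1L
        })
        aln <- data.table::data.table(
          read_id = reads$read_id[uni$read_idx],
          sample_id = reads$sample_id[uni$read_idx],
          junction_id = index$targets$junction_id[uni$target_idx],
          target_idx = uni$target_idx,
          target_offset = uni$start,
          mismatches = uni$mm,
          mismatch_positions = mp,
          left_overhang = uni$lov,
          right_overhang = uni$rov)
      }
    }
  }
  rejects <- data.table::data.table(
    read_id = reads$read_id[status != "accepted"],
    reason = status[status != "accepted"])
  list(alignments = aln, rejects = rejects)
}

.empty_alignments <- function() {
  data.table::data.table(
    read_id = character(), sample_id = character(), junction_id = character(),
    target_idx = integer(), target_offset = integer(), mismatches = integer(),
    mismatch_positions = list(), left_overhang = integer(),
    right_overhang = integer())
}

#' Align a single read
#'
#' @param read either a single sequence string or a one-row data.frame with
#'   read_id/sample_id/sequence.
#' @inheritParams align_reads
#' @return a one-row alignment data.table, or a character rejection reason.
#' @export
align_read <- function(read, index, max_mismatches = 1L) {
  if (is.character(read) && length(read) == 1L) {
    read <- data.table::data.table(read_id = "read1", sample_id = "sample1",
                                   sequence = toupper(read))
  }
  res <- align_reads(read, index, max_mismatches)
  if (nrow(res$alignments) == 1L) res$alignments else res$rejects$reason[1L]
}

#' Does an alignment support its junction at a given overhang?
#'
#' TRUE when the read extends past the junction by at least `overhang_min`
#' nt on its shorter side. The working thresholds are 8 nt for readthrough
#' and control targets at the candidate stage and 11 nt for intragenic
#' splice reporting.
#'
#' @param alignments alignment data.table from [align_reads()].
#' @param overhang_min minimum overhang in nt.
#' @return logical vector.
#' @export
supports_junction <- function(alignments, overhang_min) {
  pmin(alignments$left_overhang, alignments$right_overhang) >= overhang_min
}

#' Best full-length placement mismatch count per read
#'
#' Minimum mismatch count over all in-bounds ungapped placements of each
#' read on the indexed targets (junction crossing and uniqueness are not
#' required). Used to test whether an intragenic target can explain a read
#' at least as well as a readthrough target.
#'
#' @inheritParams align_reads
#' @return integer vector aligned with `reads` rows; NA when no placement
#'   with at most `max_mismatches` exists.
#' @export
best_placement_mismatches <- function(reads, index, max_mismatches = 1L) {
  reads <- data.table::as.data.table(reads)
  out <- rep(NA_integer_, nrow(reads))
  if (nrow(reads) == 0L) return(out)
  cand <- .seed_candidates(reads$sequence, index, max_mismatches)
  if (nrow(cand) == 0L) return(out)
  L <- nchar(reads$sequence)
  tlen <- nchar(index$targets$seq)
  cand <- cand[start >= 1L & start + L[read_idx] - 1L <= tlen[target_idx]]
  if (nrow(cand) == 0L) return(out)
  cand[, mm := .mismatch_counts(reads$sequence, index$targets$seq,
                                read_idx, target_idx, start,
                                as.integer(max_mismatches))]
  best <- cand[mm <= max_mismatches, .(mm = min(mm)), by = read_idx]
  out[best$read_idx] <- best$mm
  out
}

#' Drop readthrough alignments explainable by intragenic splicing
#'
#' A readthrough (TIC) alignment is discarded when any intragenic junction
#' target admits a full-length placement of the same read with a mismatch
#' count less than or equal to the readthrough alignment's. Ties are
#' dropped (conservative).
#'
#' @param tic_alignments alignment table from aligning against readthrough
#'   targets.
#' @param reads the read table those alignments came from.
#' @param intragenic_index a [build_index()] over intragenic targets.
#' @param max_mismatches as in [align_reads()].
#' @return the surviving subset of `tic_alignments`.
#' @export
prefer_intragenic <- function(tic_alignments, reads, intragenic_index,
                              max_mismatches = 1L) {
  if (nrow(tic_alignments) == 0L) return(tic_alignments)
  reads <- data.table::as.data.table(reads)
  sub <- reads[match(tic_alignments$read_id, reads$read_id)]
  intra_mm <- best_placement_mismatches(sub, intragenic_index, max_mismatches)
  keep <- is.na(intra_mm) | intra_mm > tic_alignments$mismatches
  tic_alignments[keep]
}
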