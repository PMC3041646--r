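# Fixture builders and independent brute-force oracles used across tests.

library(data.table)

# a hand-built two-gene plus-strand genome with fully known coordinates:
# geneA: 3 exons of 30 nt, introns 20 nt; geneB 5 kb downstream, 3 exons.
hand_genome <- function(seed = 42L, gap = 5000L) {
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  lead <- 300L
  mk_locus <- function() {
    ex <- replicate(3L, rand(30L))
    ino <- replicate(2L, {
      s <- rand(20L)
      paste0("GT", substring(s, 3L, 18L), "AG")
    })
    paste0(ex[1L], ino[1L], ex[2L], ino[2L], ex[3L])
  }
  locusA <- mk_locus()
  locusB <- mk_locus()
  genome <- c(chr1 = paste0(rand(lead), locusA, rand(gap), locusB, rand(300L)))
  startA <- lead + 1L
  startB <- lead + nchar(locusA) + gap + 1L
  exon_at <- function(s) data.table(
    start = c(s, s + 50L, s + 100L), end = c(s + 29L, s + 79L, s + 129L))
  exA <- exon_at(startA)
  exB <- exon_at(startB)
  exons <- rbind(cbind(accession = "NM_A", exon_rank = 1:3, exA),
                 cbind(accession = "NM_B", exon_rank = 1:3, exB))
  tx <- data.table(accession = c("NM_A", "NM_B"),
                   gene_id = c("GA", "GB"), chrom = "chr1", strand = "+",
                   coding = TRUE, cds_start = NA_integer_,
                   cds_end = NA_integer_)
  list(genome = genome,
       txs = transcript_set(exons, tx, genome = genome),
       exA = exA, exB = exB)
}

# brute-force splice-site enumeration: every internal exon boundary of
# every multi-exon transcript, deduplicated by (chrom, strand, pos, kind)
bf_splice_sites <- function(txs) {
  rows <- list()
  for (i in seq_len(nrow(txs$tx))) {
    acc <- txs$tx$accession[i]
    ex <- txs$exons[txs$exons$accession == acc, ][order(exon_rank)]
    n <- nrow(ex)
    if (n < 2L) next
    st <- txs$tx$strand[i]
    for (e in seq_len(n - 1L)) {
      rows[[length(rows) + 1L]] <- data.table(
        chrom = txs$tx$chrom[i], strand = st,
        pos = if (st == "+") ex$end[e] else ex$start[e], kind = "donor")
      rows[[length(rows) + 1L]] <- data.table(
        chrom = txs$tx$chrom[i], strand = st,
        pos = if (st == "+") ex$start[e + 1L] else ex$end[e + 1L],
        kind = "acceptor")
    }
  }
  unique(rbindlist(rows))
}

# brute-force readthrough pair enumeration over the site catalogs
bf_tic_pairs <- function(sites, max_distance = 200000L) {
  out <- 0L
  d <- sites$donors; a <- sites$acceptors
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(a))) {
      if (d$chrom[i] != a$chrom[j] || d$strand[i] != a$strand[j]) next
      down <- if (d$strand[i] == "+") a$pos[j] > d$pos[i] else a$pos[j] < d$pos[i]
      if (!down) next
      if (abs(a$pos[j] - d$pos[i]) > max_distance) next
      if (length(intersect(d$labels[[i]]$accession,
                           a$labels[[j]]$accession)) > 0L) next
      out <- out + 1L
    }
  }
  out
}

# brute-force all-offsets ungapped aligner implementing the same acceptance
# contract (min-mismatch, unique junction, junction crossing) by direct
# scanning; independent of the k-mer seeded engine
bf_align_read <- function(seq, targets, max_mm = 1L) {
  L <- nchar(seq)
  rr <- charToRaw(seq)
  rawN <- charToRaw("N")
  hits <- list()
  any_cand <- FALSE
  any_inb_ok <- FALSE
  any_inb <- FALSE
  for (t in seq_len(nrow(targets))) {
    tl <- nchar(targets$seq[t])
    if (tl < L) next
    rt <- charToRaw(targets$seq[t])
    for (off in seq_len(tl - L + 1L)) {
      any_inb <- TRUE
      win <- rt[off:(off + L - 1L)]
      mm <- sum(win != rr | rr == rawN)
      if (mm > max_mm) next
      any_inb_ok <- TRUE
      lov <- targets$junction_at[t] - off + 1L
      rov <- L - lov
      if (lov < 1L || rov < 1L) next
      hits[[length(hits) + 1L]] <- data.table(
        junction_id = targets$junction_id[t], off = off, mm = mm,
        lov = lov, rov = rov)
    }
  }
  if (length(hits) == 0L) {
    if (any_inb_ok) return(list(status = "no_junction_overlap"))
    if (any_inb) return(list(status = "too_many_mismatches"))
    return(list(status = "no_hit"))
  }
  h <- rbindlist(hits)
  h <- h[mm == min(mm)]
  if (uniqueN(h$junction_id) > 1L) return(list(status = "multi_mapped"))
  h <- h[order(off)][1L]
  list(status = "accepted", junction_id = h$junction_id, mm = h$mm,
       off = h$off, lov = h$lov, rov = h$rov)
}

# naive codon-by-codon translator (independent of the package's table
# lookup): translates from `from` until a stop codon, using a hard-coded
# standard-code switch over first base families
naive_translate <- function(seq, from) {
  aa <- character()
  p <- from
  code <- as.list(Biostrings::GENETIC_CODE)
  repeat {
    if (p + 2L > nchar(seq)) return(list(protein = paste(aa, collapse = ""),
                                         stop_start = NA_integer_))
    cod <- substr(seq, p, p + 2L)
    a <- code[[cod]]
    if (is.null(a)) a <- "X"
    if (a == "*") return(list(protein = paste(aa, collapse = ""),
                              stop_start = p))
    aa <- c(aa, a)
    p <- p + 3L
  }
}

# random DNA helper
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# substitute k positions of a sequence with different bases
mutate_seq <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1L]]
  at <- sample.int(length(ch), k)
  ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                              1L), "")
  paste(ch, collapse = "")
}

# faster brute-force scan for large oracle runs: per target, precompute the
# matrix of all length-L windows once, then compare each read against all
# offsets with one vectorised operation; acceptance semantics identical to
# bf_align_read
bf_scan_statuses <- function(reads, targets, max_mm = 1L) {
  L <- nchar(reads[1L])
  stopifnot(all(nchar(reads) == L))
  rawN <- charToRaw("N")
  win <- lapply(seq_len(nrow(targets)), function(t) {
    rt <- charToRaw(targets$seq[t])
    noff <- length(rt) - L + 1L
    if (noff < 1L) return(NULL)
    matrix(rt[outer(seq_len(L) - 1L, seq_len(noff), "+")], nrow = L)
  })
  lov_of <- lapply(seq_len(nrow(targets)), function(t) {
    noff <- nchar(targets$seq[t]) - L + 1L
    targets$junction_at[t] - seq_len(noff) + 1L
  })
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rr <- charToRaw(reads[i])
    best <- NULL
    any_inb_ok <- FALSE
    for (t in seq_len(nrow(targets))) {
      if (is.null(win[[t]])) next
      mm <- colSums(win[[t]] != rr | rr == rawN)
      ok <- which(mm <= max_mm)
      if (length(ok) == 0L) next
      any_inb_ok <- TRUE
      lov <- lov_of[[t]][ok]
      rov <- L - lov
      cross <- lov >= 1L & rov <= L - 1L & rov >= 1L
      ok <- ok[cross]
      if (length(ok) == 0L) next
      cand <- data.table(junction_id = targets$junction_id[t],
                         off = ok, mm = mm[ok],
                         lov = lov_of[[t]][ok])
      best <- if (is.null(best)) cand else rbind(best, cand)
    }
    if (is.null(best)) {
      out[[i]] <- list(status = if (any_inb_ok) "no_junction_overlap"
                       else "rejected_no_placement")
      next
    }
    best <- best[mm == min(mm)]
    if (uniqueN(best$junction_id) > 1L) {
      out[[i]] <- list(status = "multi_mapped")
      next
    }
    best <- best[order(off)][1L]
    out[[i]] <- list(status = "accepted", junction_id = best$junction_id,
                     mm = best$mm, off = best$off, lov = best$lov,
                     rov = L - best$lov)
  }
  out
}
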