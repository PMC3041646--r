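# Seeded simulator: toy genomes and annotations, planted readthrough /
# intervening-exon / distant-fusion events, log-normal expression, reads
# with substitution errors, split-alignment records, and a machine-readable
# truth manifest. Every pipeline stage is testable against planted truth
# without any external data.

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Collects every tunable of the simulator; the seed fixes all downstream
#' randomness. Defaults encode the study conditions the package is
#' validated under: read lengths 33/50/75 nt, 1\% substitution error,
#' exponential intergenic spacing, 54\% weight on the penultimate-donor to
#' second-acceptor splice pattern and an 11\% multiple-isoform fraction
#' among readthrough gene pairs.
#'
#' @param seed integer seed.
#' @param n_chroms number of chromosomes.
#' @param n_genes number of genes (spread round-robin over chromosomes).
#' @param exons_per_gene integer range c(min, max).
#' @param exon_len,intron_len integer ranges in bp.
#' @param intergenic_mean mean of the exponential intergenic gap (bp).
#' @param read_length read length in nt (33, 50 or 75).
#' @param error_rate per-base substitution probability.
#' @param depth total number of reads to simulate.
#' @param sample_id sample identifier attached to the reads.
#' @param n_tic,n_ticie,n_fusion_per_category,n_decoy planted event counts
#'   (n_fusion_per_category covers long_range, scrambled, inversion and
#'   translocation).
#' @param pattern_weight probability that a planted readthrough uses the
#'   (n-1) donor and +2 acceptor (default 0.54).
#' @param isoform_fraction fraction of readthrough gene pairs given a
#'   second splice isoform (default 0.11).
#' @param tic_efficiency readthrough splice intensity as a fraction of the
#'   5' gene's intensity (recycled over events).
#' @param ticie_exon_len intervening-exon length range (bp, max 300 by
#'   the exon-length threshold).
#' @param paralog_identity sequence identity of decoy paralog pairs.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters.
#' @param anchor_min minimum read anchor on each side of a splice for a
#'   split record to be emitted (spliced-aligner detectability emulation).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, n_genes = 20L,
                       exons_per_gene = c(3L, 5L), exon_len = c(90L, 250L),
                       intron_len = c(200L, 1500L), intergenic_mean = 10000,
                       read_length = 50L, error_rate = 0.01,
                       depth = 20000L, sample_id = "S1",
                       n_tic = 5L, n_ticie = 0L, n_fusion_per_category = 0L,
                       n_decoy = 0L, pattern_weight = 0.54,
                       isoform_fraction = 0.11, tic_efficiency = 0.1,
                       ticie_exon_len = c(80L, 300L),
                       paralog_identity = 0.92,
                       expr_meanlog = 3, expr_sdlog = 0.8,
                       anchor_min = 14L) {
  stopifnot(read_length %in% c(33L, 50L, 75L),
            error_rate >= 0, error_rate < 1,
            all(exons_per_gene >= 1L), all(exon_len > 0L),
            all(intron_len > 0L), intergenic_mean > 0)
  structure(as.list(environment()), class = "sim_config")
}

# build one gene: transcript sequence with an enforced CDS (ATG start, no
# internal in-frame stop, stop codon in the last exon), plus intron
# sequences with canonical GT..AG motifs, all in transcription orientation
.make_gene <- function(cfg) {
  n_ex <- sample(seq.int(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L]), 1L)
  exlen <- sample(seq.int(cfg$exon_len[1L], cfg$exon_len[2L]), n_ex,
                  replace = TRUE)
  inlen <- if (n_ex > 1L) {
    sample(seq.int(cfg$intron_len[1L], cfg$intron_len[2L]), n_ex - 1L,
           replace = TRUE)
  } else integer()
  txlen <- sum(exlen)
  txseq <- .rand_dna(txlen)
  # CDS: start early in exon 1, stop inside the last exon
  cds_start <- 10L
  last_start <- txlen - exlen[n_ex] + 1L
  cds_end <- txlen - 6L
  cds_end <- cds_start + 2L +
    3L * ((cds_end - cds_start - 2L) %/% 3L)  # in-frame stop-end
  stopifnot(cds_end - 2L >= last_start + 1L)  # stop codon in last exon
  ch <- strsplit(txseq, "")[[1L]]
  ch[cds_start:(cds_start + 2L)] <- c("A", "T", "G")
  # scrub in-frame stops strictly inside the CDS
  for (p in seq.int(cds_start + 3L, cds_end - 3L, by = 3L)) {
    if (paste(ch[p:(p + 2L)], collapse = "") %in% STOP_CODONS) {
      ch[p] <- "C"
    }
  }
  ch[(cds_end - 2L):cds_end] <- c("T", "A", "A")
  txseq <- paste(ch, collapse = "")
  introns <- vapply(inlen, function(l) {
    s <- .rand_dna(l)
    paste0("GT", substring(s, 3L, l - 2L), "AG")
  }, "")
  list(n_ex = n_ex, exlen = exlen, inlen = inlen, txseq = txseq,
       introns = introns, cds_start = cds_start, cds_end = cds_end)
}

#' Generate a toy genome and annotation
#'
#' Places `n_genes` genes round-robin over `n_chroms` chromosomes with
#' exponential intergenic gaps, random strands, uniform exon/intron
#' lengths, canonical GT..AG motifs at every annotated intron and a valid
#' CDS (ATG start, clean in-frame interior, stop codon in the last exon)
#' in every transcript. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `tic_sim`: genome (named character), txs
#'   ([transcript_set()]), gene_table (placement bookkeeping), config.
#' @export
generate_genome <- function(config) {
  .with_seed(config$seed, {
    chrom_of <- rep(seq_len(config$n_chroms), length.out = config$n_genes)
    strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    chrom_parts <- rep(list(character()), config$n_chroms)
    chrom_pos <- rep(0L, config$n_chroms)
    exon_rows <- list()
    tx_rows <- list()
    gene_rows <- list()
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("G%03d", g)
      acc <- sprintf("NM_%03d", g)
      ci <- chrom_of[g]
      st <- strands[g]
      gene <- .make_gene(config)
      gap <- as.integer(round(stats::rexp(1L, 1 / config$intergenic_mean))) + 200L
      # locus in transcription orientation
      ends <- cumsum(gene$exlen)
      starts <- ends - gene$exlen + 1L
      exon_seqs <- substring(gene$txseq, starts, ends)
      locus <- character(2L * gene$n_ex - 1L)
      locus[seq.int(1L, by = 2L, length.out = gene$n_ex)] <- exon_seqs
      if (gene$n_ex > 1L) {
        locus[seq.int(2L, by = 2L, length.out = gene$n_ex - 1L)] <- gene$introns
      }
      locus <- paste(locus, collapse = "")
      glen <- nchar(locus)
      gstart <- chrom_pos[ci] + gap + 1L
      chrom_parts[[ci]] <- c(chrom_parts[[ci]], .rand_dna(gap),
                             if (st == "+") locus else revcomp(locus))
      chrom_pos[ci] <- gstart + glen - 1L
      # genomic exon coordinates (transcription order)
      piece_len <- integer(2L * gene$n_ex - 1L)
      piece_len[seq.int(1L, by = 2L, length.out = gene$n_ex)] <- gene$exlen
      if (gene$n_ex > 1L) {
        piece_len[seq.int(2L, by = 2L, length.out = gene$n_ex - 1L)] <- gene$inlen
      }
      off <- cumsum(c(0L, piece_len[-length(piece_len)]))
      ex_off <- off[seq.int(1L, by = 2L, length.out = gene$n_ex)]
      if (st == "+") {
        ex_start <- gstart + ex_off
        ex_end <- ex_start + gene$exlen - 1L
      } else {
        gend <- gstart + glen - 1L
        ex_end <- gend - ex_off
        ex_start <- ex_end - gene$exlen + 1L
      }
      exon_rows[[g]] <- data.table::data.table(
        accession = acc, exon_rank = seq_len(gene$n_ex),
        start = ex_start, end = ex_end)
      tx_rows[[g]] <- data.table::data.table(
        accession = acc, gene_id = gid,
        chrom = sprintf("chr%d", ci), strand = st, coding = TRUE,
        cds_start = gene$cds_start, cds_end = gene$cds_end)
      gene_rows[[g]] <- data.table::data.table(
        gene_id = gid, accession = acc, chrom = sprintf("chr%d", ci),
        strand = st, start = gstart, end = gstart + glen - 1L,
        n_exons = gene$n_ex, order_on_chrom = sum(chrom_of[seq_len(g)] == ci))
    }
    genome <- vapply(seq_len(config$n_chroms), function(ci) {
      paste(c(chrom_parts[[ci]],
              .rand_dna(as.integer(config$intergenic_mean))), collapse = "")
    }, "")
    names(genome) <- sprintf("chr%d", seq_len(config$n_chroms))
    txs <- transcript_set(data.table::rbindlist(exon_rows),
                          data.table::rbindlist(tx_rows), genome = genome)
    structure(list(genome = genome, txs = txs,
                   gene_table = data.table::rbindlist(gene_rows),
                   config = config,
                   events = NULL, chimeras = NULL, expression = NULL),
              class = "tic_sim")
  })
}

#' @export
print.tic_sim <- function(x, ...) {
  cat(sprintf("tic_sim: %d chromosome(s) (%s bp), %d genes, %d planted event(s)\n",
              length(x$genome),
              paste(nchar(x$genome), collapse = "+"),
              nrow(x$gene_table),
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

# same-strand (gene5, gene3) pairs with the 3' gene downstream within
# max_dist of the 5' gene, ordered by intergenic distance
.candidate_pairs <- function(gene_table, max_dist = 200000L) {
  gt <- gene_table
  ij <- data.table::CJ(i = seq_len(nrow(gt)), j = seq_len(nrow(gt)))
  ij <- ij[i != j]
  ok <- gt$chrom[ij$i] == gt$chrom[ij$j] & gt$strand[ij$i] == gt$strand[ij$j]
  ij <- ij[ok]
  plus <- gt$strand[ij$i] == "+"
  d <- ifelse(plus, gt$start[ij$j] - gt$end[ij$i],
              gt$start[ij$i] - gt$end[ij$j])
  keep <- d > 0L & d <= max_dist
  p <- data.table::data.table(g5 = gt$gene_id[ij$i][keep],
                              g3 = gt$gene_id[ij$j][keep],
                              dist = as.integer(d[keep]))
  p[order(dist)]
}

.take_disjoint <- function(pairs, n, used) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    if (length(out) == n) break
    if (pairs$g5[i] %in% used || pairs$g3[i] %in% used) next
    out[[length(out) + 1L]] <- pairs[i]
    used <- c(used, pairs$g5[i], pairs$g3[i])
  }
  if (length(out) < n) stop("not enough qualifying gene pairs to plant events")
  list(pairs = data.table::rbindlist(out), used = used)
}

#' Plant events into a simulated genome
#'
#' Chooses disjoint gene pairs and plants readthrough (TIC) events
#' (splice-site choice weighted by `pattern_weight`, a second isoform for
#' an `isoform_fraction` share of pairs), intervening-exon events
#' (TICIEs, exon placed in the intergenic gap), one distant fusion per
#' category (long_range, scrambled, inversion, translocation) and decoy
#' paralog pairs: the decoy 3' gene's exons are rewritten as a
#' `paralog_identity` copy of the 5' gene's transcript, and junction reads
#' are emitted for the decoy exactly as for a real readthrough, so the
#' homology filter has to reject it. The truth manifest records every
#' planted junction.
#'
#' @param sim a [generate_genome()] object.
#' @return the sim with `events` (truth manifest) and `chimeras`
#'   (assembled chimeric transcripts) filled in; the genome is modified
#'   for decoys.
#' @export
plant_events <- function(sim) {
  cfg <- sim$config
  .with_seed(cfg$seed + 1L, {
    gt <- sim$gene_table
    txs <- sim$txs
    used <- character()
    events <- list()
    chimeras <- list()
    add_event <- function(kind, g5, g3, d_idx, a_idx, eff, decoy = FALSE,
                          intervening = NULL, category = NA_character_) {
      acc5 <- gt[gene_id == g5]$accession
      acc3 <- gt[gene_id == g3]$accession
      n5 <- gt[gene_id == g5]$n_exons
      n3 <- gt[gene_id == g3]$n_exons
      ch <- assemble_chimera(txs, sim$genome, acc5, d_idx, acc3, a_idx,
                             intervening = intervening)
      ex5 <- txs$exons[.(acc5)][order(exon_rank)]
      ex3 <- txs$exons[.(acc3)][order(exon_rank)]
      st5 <- txs$tx[accession == acc5]$strand
      st3 <- txs$tx[accession == acc3]$strand
      id <- sprintf("%s|%s-%s|%d-%d%s", kind, g5, g3, d_idx, a_idx,
                    if (!is.null(intervening)) "|ie" else "")
      events[[length(events) + 1L]] <<- data.table::data.table(
        event_id = id, kind = kind, gene5 = g5, gene3 = g3,
        tx5 = acc5, tx3 = acc3,
        donor_exon = d_idx, acceptor_exon = a_idx,
        donor_label = exon_label(d_idx, n5),
        acceptor_label = exon_label(a_idx, n3),
        chrom5 = txs$tx[accession == acc5]$chrom,
        chrom3 = txs$tx[accession == acc3]$chrom,
        strand5 = st5, strand3 = st3,
        donor_pos = if (st5 == "+") ex5$end[d_idx] else ex5$start[d_idx],
        acceptor_pos = if (st3 == "+") ex3$start[a_idx] else ex3$end[a_idx],
        efficiency = eff, decoy = decoy,
        pattern = d_idx == n5 - 1L && a_idx == 2L,
        ie_start = if (is.null(intervening)) NA_integer_ else intervening$start,
        ie_end = if (is.null(intervening)) NA_integer_ else intervening$end,
        category = category)
      chimeras[[id]] <<- ch
    }
    pick_sites <- function(n5, n3) {
      if (n5 >= 2L && stats::runif(1L) < cfg$pattern_weight) {
        c(n5 - 1L, 2L)
      } else {
        d <- sample(seq_len(max(n5 - 1L, 1L)), 1L)
        a <- sample(seq.int(2L, n3), 1L)
        c(d, a)
      }
    }

    eff <- rep_len(cfg$tic_efficiency, cfg$n_tic)
    if (cfg$n_tic > 0L) {
      got <- .take_disjoint(.candidate_pairs(gt), cfg$n_tic, used)
      used <- got$used
      for (i in seq_len(cfg$n_tic)) {
        g5 <- got$pairs$g5[i]; g3 <- got$pairs$g3[i]
        n5 <- gt[gene_id == g5]$n_exons
        n3 <- gt[gene_id == g3]$n_exons
        da <- pick_sites(n5, n3)
        add_event("tic", g5, g3, da[1L], da[2L], eff[i])
        if (stats::runif(1L) < cfg$isoform_fraction && n5 >= 3L) {
          alt <- if (da[1L] > 1L) da[1L] - 1L else da[1L] + 1L
          if (alt >= 1L && alt <= n5 - 1L) {
            add_event("tic", g5, g3, alt, da[2L], eff[i] / 2)
          }
        }
      }
    }

    if (cfg$n_ticie > 0L) {
      pairs <- .candidate_pairs(gt)
      pairs <- pairs[dist >= max(cfg$ticie_exon_len) + 60L]
      got <- .take_disjoint(pairs, cfg$n_ticie, used)
      used <- got$used
      for (i in seq_len(cfg$n_ticie)) {
        g5 <- got$pairs$g5[i]; g3 <- got$pairs$g3[i]
        a <- gt[gene_id == g5]; b <- gt[gene_id == g3]
        n5 <- a$n_exons; n3 <- b$n_exons
        elen <- sample(seq.int(cfg$ticie_exon_len[1L],
                               cfg$ticie_exon_len[2L]), 1L)
        if (a$strand == "+") {
          lo <- a$end + 30L
          es <- lo + sample.int(max(b$start - elen - 30L - lo, 1L), 1L) - 1L
          ivl <- list(chrom = a$chrom, start = es, end = es + elen - 1L,
                      strand = "+")
        } else {
          hi <- a$start - 30L
          ee <- hi - sample.int(max(hi - (b$end + elen + 30L), 1L), 1L) + 1L
          ivl <- list(chrom = a$chrom, start = ee - elen + 1L, end = ee,
                      strand = "-")
        }
        add_event("ticie", g5, g3, n5 - 1L, 2L, cfg$tic_efficiency,
                  intervening = ivl)
      }
    }

    if (cfg$n_fusion_per_category > 0L) {
      cats <- rep(c("long_range", "scrambled", "inversion", "translocation"),
                  each = cfg$n_fusion_per_category)
      for (cat in cats) {
        pick <- switch(cat,
          long_range = {
            p <- .candidate_pairs(gt, max_dist = .Machine$integer.max)
            p <- p[dist > 200000L][!(g5 %in% used) & !(g3 %in% used)]
            if (nrow(p) == 0L) stop("no gene pair available for long_range")
            p[.N]  # farthest apart
          },
          scrambled = {
            p <- .candidate_pairs(gt)[!(g5 %in% used) & !(g3 %in% used)]
            if (nrow(p) == 0L) stop("no gene pair available for scrambled")
            data.table::data.table(g5 = p$g3[1L], g3 = p$g5[1L],
                                   dist = p$dist[1L])  # swap: acceptor upstream
          },
          inversion = {
            cand <- data.table::CJ(i = seq_len(nrow(gt)), j = seq_len(nrow(gt)))
            cand <- cand[i != j]
            ok <- which(gt$chrom[cand$i] == gt$chrom[cand$j] &
                        gt$strand[cand$i] != gt$strand[cand$j] &
                        !(gt$gene_id[cand$i] %in% used) &
                        !(gt$gene_id[cand$j] %in% used))
            if (length(ok) == 0L) stop("no gene pair available for inversion")
            data.table::data.table(g5 = gt$gene_id[cand$i[ok[1L]]],
                                   g3 = gt$gene_id[cand$j[ok[1L]]],
                                   dist = NA_integer_)
          },
          translocation = {
            cand <- data.table::CJ(i = seq_len(nrow(gt)), j = seq_len(nrow(gt)))
            cand <- cand[i != j]
            ok <- which(gt$chrom[cand$i] != gt$chrom[cand$j] &
                        !(gt$gene_id[cand$i] %in% used) &
                        !(gt$gene_id[cand$j] %in% used))
            if (length(ok) == 0L) stop("no gene pair available for translocation")
            data.table::data.table(g5 = gt$gene_id[cand$i[ok[1L]]],
                                   g3 = gt$gene_id[cand$j[ok[1L]]],
                                   dist = NA_integer_)
          })
        g5 <- pick$g5[1L]; g3 <- pick$g3[1L]
        used <- c(used, g5, g3)
        n5 <- gt[gene_id == g5]$n_exons
        n3 <- gt[gene_id == g3]$n_exons
        add_event("fusion", g5, g3, max(n5 - 1L, 1L), min(2L, n3),
                  cfg$tic_efficiency, category = cat)
      }
    }

    if (cfg$n_decoy > 0L) {
      got <- .take_disjoint(.candidate_pairs(gt), cfg$n_decoy, used)
      used <- got$used
      for (i in seq_len(cfg$n_decoy)) {
        g5 <- got$pairs$g5[i]; g3 <- got$pairs$g3[i]
        acc5 <- gt[gene_id == g5]$accession
        acc3 <- gt[gene_id == g3]$accession
        # rewrite the 3' gene's exons as a high-identity copy of the 5'
        # transcript, making the pair paralogous
        src <- transcript_sequence(txs, sim$genome, acc5)
        ex3 <- txs$exons[.(acc3)][order(exon_rank)]
        st3 <- txs$tx[accession == acc3]$strand
        ch3 <- txs$tx[accession == acc3]$chrom
        need <- sum(ex3$end - ex3$start + 1L)
        tpl <- substring(paste(rep(src, ceiling(need / nchar(src))),
                               collapse = ""), 1L, need)
        chv <- strsplit(tpl, "")[[1L]]
        nmut <- round((1 - cfg$paralog_identity) * need)
        at <- sample.int(need, nmut)
        chv[at] <- vapply(chv[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, "")
        tpl <- paste(chv, collapse = "")
        off <- 0L
        gseq <- strsplit(sim$genome[[ch3]], "")[[1L]]
        for (e in seq_len(nrow(ex3))) {
          w <- ex3$end[e] - ex3$start[e] + 1L
          piece <- substring(tpl, off + 1L, off + w)
          if (st3 == "-") piece <- revcomp(piece)
          gseq[ex3$start[e]:ex3$end[e]] <- strsplit(piece, "")[[1L]]
          off <- off + w
        }
        sim$genome[[ch3]] <- paste(gseq, collapse = "")
        n5 <- gt[gene_id == g5]$n_exons
        n3 <- gt[gene_id == g3]$n_exons
        add_event("tic", g5, g3, max(n5 - 1L, 1L), min(2L, n3),
                  cfg$tic_efficiency, decoy = TRUE)
      }
      # re-assemble all chimeras against the mutated genome
      ev <- data.table::rbindlist(events)
      for (r in seq_len(nrow(ev))) {
        ivl <- if (is.na(ev$ie_start[r])) NULL else {
          list(chrom = ev$chrom5[r], start = ev$ie_start[r],
               end = ev$ie_end[r], strand = ev$strand5[r])
        }
        chimeras[[ev$event_id[r]]] <- assemble_chimera(
          txs, sim$genome, ev$tx5[r], ev$donor_exon[r], ev$tx3[r],
          ev$acceptor_exon[r], intervening = ivl)
      }
    }

    sim$events <- data.table::rbindlist(events)
    sim$chimeras <- chimeras
    sim
  })
}

#' Assign log-normal expression to genes and planted chimeras
#'
#' Gene intensities are drawn log-normal; each planted chimera's intensity
#' is its efficiency times its 5' gene's intensity (readthrough as
#' transcriptional leakage from the upstream gene).
#'
#' @param sim a [plant_events()] object.
#' @return the sim with an `expression` table (source_id, gene_id or NA,
#'   intensity).
#' @export
assign_expression <- function(sim) {
  cfg <- sim$config
  .with_seed(cfg$seed + 2L, {
    g <- data.table::data.table(
      source_id = sim$gene_table$accession,
      gene_id = sim$gene_table$gene_id,
      intensity = stats::rlnorm(nrow(sim$gene_table),
                                cfg$expr_meanlog, cfg$expr_sdlog))
    ev <- sim$events
    if (!is.null(ev) && nrow(ev) > 0L) {
      ch <- data.table::data.table(
        source_id = ev$event_id, gene_id = NA_character_,
        intensity = ev$efficiency *
          g$intensity[match(ev$gene5, g$gene_id)])
    } else {
      ch <- g[0L]
    }
    sim$expression <- rbind(g, ch)
    sim
  })
}

# segment map (chrom, strand, start, end in transcription order) and
# junction annotations for every read source (transcripts and chimeras)
.source_maps <- function(sim) {
  maps <- list()
  for (i in seq_len(nrow(sim$txs$tx))) {
    acc <- sim$txs$tx$accession[i]
    ex <- sim$txs$exons[.(acc)][order(exon_rank)]
    maps[[acc]] <- list(
      seg = data.table::data.table(
        chrom = sim$txs$tx$chrom[i], strand = sim$txs$tx$strand[i],
        start = ex$start, end = ex$end),
      seq = transcript_sequence(sim$txs, sim$genome, acc),
      fusion_junction = NA_integer_)
  }
  if (!is.null(sim$events) && nrow(sim$events) > 0L) {
    for (r in seq_len(nrow(sim$events))) {
      id <- sim$events$event_id[r]
      ch <- sim$chimeras[[id]]
      # fusion junction: after the 5p block (readthrough/fusion), and for
      # TICIEs both flanks of the intervening exon are "fusion" splices
      n5seg <- sum(ch$segments$source == "5p")
      maps[[id]] <- list(
        seg = ch$segments[, .(chrom, strand, start, end)],
        seq = ch$sequence,
        fusion_junction = n5seg)
    }
  }
  maps
}

#' Simulate reads and split-alignment records
#'
#' Samples reads uniformly along each source (transcripts and planted
#' chimeras) with per-source counts proportional to intensity times the
#' number of start positions, applies i.i.d. substitution errors, and
#' emits: the read table; a provenance table mapping every read to its
#' source and start; and split-alignment records for every read spanning a
#' splice junction with at least `anchor_min` nt on both sides (the
#' detectability threshold of a split-read aligner on short reads).
#'
#' @param sim a sim that has been through [plant_events()] and
#'   [assign_expression()].
#' @return list with `reads`, `provenance`, `split_records`.
#' @export
simulate_reads <- function(sim) {
  cfg <- sim$config
  if (is.null(sim$expression)) stop("run assign_expression() first")
  .with_seed(cfg$seed + 3L, {
    L <- cfg$read_length
    maps <- .source_maps(sim)
    src <- sim$expression[source_id %in% names(maps)]
    slen <- vapply(maps[src$source_id], function(m) nchar(m$seq), 0L)
    npos <- pmax(slen - L + 1L, 0L)
    w <- src$intensity * npos
    if (sum(w) <= 0) stop("no source long enough to emit reads")
    counts <- stats::rmultinom(1L, cfg$depth, w / sum(w))[, 1L]
    reads <- vector("list", length(counts))
    prov <- vector("list", length(counts))
    recs <- list()
    rid0 <- 0L
    bases <- c("A", "C", "G", "T")
    for (s in seq_along(counts)) {
      n <- counts[s]
      if (n == 0L) next
      id <- src$source_id[s]
      m <- maps[[id]]
      starts <- sample.int(npos[s], n, replace = TRUE)
      seqs <- substring(m$seq, starts, starts + L - 1L)
      # substitution errors: per-read error counts, then vectorised
      # single-base substitutions (repeated positions within a read merge)
      nerr <- stats::rbinom(n, L, cfg$error_rate)
      tot <- sum(nerr)
      if (tot > 0L) {
        ridx <- rep.int(seq_len(n), nerr)
        at <- sample.int(L, tot, replace = TRUE)
        old <- substring(seqs[ridx], at, at)
        new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "",
                      USE.NAMES = FALSE)
        for (e in seq_len(tot)) {
          substr(seqs[ridx[e]], at[e], at[e]) <- new[e]
        }
      }
      ids <- sprintf("r%07d", rid0 + seq_len(n))
      rid0 <- rid0 + n
      reads[[s]] <- data.table::data.table(
        read_id = ids, sample_id = cfg$sample_id, sequence = seqs)
      seg <- m$seg
      lens <- seg$end - seg$start + 1L
      cum <- cumsum(lens)
      cum0 <- c(0L, cum[-length(cum)])  # transcript offset before segment k
      junc <- cum[-length(cum)]
      spans_fusion <- rep(FALSE, n)
      for (j in seq_along(junc)) {
        # reads crossing junction j with >= anchor_min nt on both sides
        sel <- which(starts <= junc[j] - cfg$anchor_min + 1L &
                     starts >= junc[j] + cfg$anchor_min - L + 1L)
        if (!is.na(m$fusion_junction) && j == m$fusion_junction) {
          spans_fusion[sel] <- TRUE
        }
        if (length(sel) == 0L) next
        t1 <- pmax(starts[sel], cum0[j] + 1L)
        t2 <- pmin(starts[sel] + L - 1L, cum[j + 1L])
        if (seg$strand[j] == "+") {
          a1 <- seg$start[j] + (t1 - cum0[j]) - 1L
          a2 <- seg$start[j] + (junc[j] - cum0[j]) - 1L
        } else {
          a1 <- seg$end[j] - (junc[j] - cum0[j]) + 1L
          a2 <- seg$end[j] - (t1 - cum0[j]) + 1L
        }
        if (seg$strand[j + 1L] == "+") {
          b1 <- seg$start[j + 1L]
          b2 <- seg$start[j + 1L] + (t2 - cum[j] ) - 1L
        } else {
          b1 <- seg$end[j + 1L] - (t2 - cum[j]) + 1L
          b2 <- seg$end[j + 1L]
        }
        recs[[length(recs) + 1L]] <- data.table::data.table(
          read_id = ids[sel], sample_id = cfg$sample_id,
          chrom_a = seg$chrom[j], strand_a = seg$strand[j],
          start_a = pmin(a1, a2), end_a = pmax(a1, a2),
          chrom_b = seg$chrom[j + 1L], strand_b = seg$strand[j + 1L],
          start_b = pmin(b1, b2), end_b = pmax(b1, b2))
      }
      prov[[s]] <- data.table::data.table(
        read_id = ids, source_id = id, start = starts,
        spans_fusion = spans_fusion)
    }
    list(reads = data.table::rbindlist(reads),
         provenance = data.table::rbindlist(prov),
         split_records = if (length(recs)) data.table::rbindlist(recs) else
           data.table::data.table(
             read_id = character(), sample_id = character(),
             chrom_a = character(), strand_a = character(),
             start_a = integer(), end_a = integer(),
             chrom_b = character(), strand_b = character(),
             start_b = integer(), end_b = integer()))
  })
}

#' Expected junction-spanning read counts for planted events
#'
#' For a planted chimera with intensity share w among all sources, a run
#' of `depth` reads places depth*w reads uniformly over its start
#' positions, of which (L-1) cross the fusion junction, giving lambda =
#' depth * w * (L-1) / (len - L + 1) expected junction reads.
#'
#' @param sim sim after [assign_expression()].
#' @param depth total read count (defaults to the config depth).
#' @return data.table event_id, lambda.
#' @export
expected_junction_reads <- function(sim, depth = NULL) {
  cfg <- sim$config
  depth <- depth %||% cfg$depth
  L <- cfg$read_length
  maps <- .source_maps(sim)
  src <- sim$expression[source_id %in% names(maps)]
  slen <- vapply(maps[src$source_id], function(m) nchar(m$seq), 0L)
  npos <- pmax(slen - L + 1L, 0L)
  w <- src$intensity * npos
  w <- w / sum(w)
  ev <- sim$events
  i <- match(ev$event_id, src$source_id)
  data.table::data.table(
    event_id = ev$event_id,
    lambda = depth * w[i] * (L - 1L) / npos[i])
}

#' Write simulation outputs to files
#'
#' Emits genome FASTA, annotation GTF, reads FASTQ (constant quality),
#' split-record TSV and a JSON truth manifest.
#'
#' @param sim the sim object.
#' @param readsim output of [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, readsim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
  write_gtf(sim$txs, file.path(dir, "annotation.gtf"))
  fq <- file.path(dir, "reads.fastq")
  con <- file(fq, "w")
  writeLines(paste0("@", readsim$reads$read_id, "\n", readsim$reads$sequence,
                    "\n+\n",
                    strrep("I", nchar(readsim$reads$sequence))), con)
  close(con)
  data.table::fwrite(readsim$split_records,
                     file.path(dir, "split_records.tsv"), sep = "\t")
  truth <- list(events = sim$events, expression = sim$expression,
                provenance = readsim$provenance)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Write a transcript set as GTF
#'
#' Emits exon and CDS features with gene_id/transcript_id attributes; CDS
#' genomic intervals are derived from the transcript-coordinate CDS and
#' include the stop codon.
#'
#' @param txs a [transcript_set()].
#' @param path output path.
#' @export
write_gtf <- function(txs, path) {
  lines <- character()
  for (i in seq_len(nrow(txs$tx))) {
    acc <- txs$tx$accession[i]
    ex <- txs$exons[.(acc)][order(exon_rank)]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     txs$tx$gene_id[i], acc)
    lines <- c(lines, sprintf("%s\tticfinder\texon\t%d\t%d\t.\t%s\t.\t%s",
                              txs$tx$chrom[i], ex$start, ex$end,
                              txs$tx$strand[i], attrs))
    if (!is.na(txs$tx$cds_start[i])) {
      st <- txs$tx$strand[i]
      # CDS genomic blocks: intersect the CDS transcript interval with exons
      lens <- ex$end - ex$start + 1L
      cum <- cumsum(lens)
      cum0 <- c(0L, cum[-length(cum)])
      for (k in seq_len(nrow(ex))) {
        lo <- max(txs$tx$cds_start[i], cum0[k] + 1L)
        hi <- min(txs$tx$cds_end[i], cum[k])
        if (lo > hi) next
        g1 <- tx_to_genomic(ex, st, lo)
        g2 <- tx_to_genomic(ex, st, hi)
        lines <- c(lines, sprintf("%s\tticfinder\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                                  txs$tx$chrom[i], min(g1, g2), max(g1, g2),
                                  st, 0L, attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
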