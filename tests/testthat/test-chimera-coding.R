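# Builds two fully controlled genes on a synthetic genome so that CDS
# frames at the junction are known by construction, then checks coding
# calls against a naive translation oracle.

# A gene whose exon lengths are chosen so the CDS prefix retained by a
# donor at exon `d` has a known length. All coding, plus strand.
build_coding_gene <- function(acc, gid, exlen, cds_start, cds_end,
                              offset, seed) {
  set.seed(seed)
  txlen <- sum(exlen)
  ch <- strsplit(rand_dna(txlen), "")[[1L]]
  ch[cds_start:(cds_start + 2L)] <- c("A", "T", "G")
  for (p in seq.int(cds_start + 3L, cds_end - 3L, by = 3L)) {
    if (paste(ch[p:(p + 2L)], collapse = "") %in% ticfinder:::STOP_CODONS) {
      ch[p] <- "C"
    }
  }
  ch[(cds_end - 2L):cds_end] <- c("T", "A", "A")
  txseq <- paste(ch, collapse = "")
  ends <- cumsum(exlen)
  starts <- ends - exlen + 1L
  pieces <- substring(txseq, starts, ends)
  introns <- vapply(seq_len(length(exlen) - 1L), function(i) {
    paste0("GT", rand_dna(46L), "AG")
  }, "")
  locus <- pieces[1L]
  for (i in seq_along(introns)) locus <- paste0(locus, introns[i],
                                                pieces[i + 1L])
  gstart <- offset + 1L
  piece_len <- integer(2L * length(exlen) - 1L)
  piece_len[seq(1L, by = 2L, length.out = length(exlen))] <- exlen
  piece_len[seq(2L, by = 2L, length.out = length(introns))] <- 50L
  off <- cumsum(c(0L, piece_len[-length(piece_len)]))
  ex_off <- off[seq(1L, by = 2L, length.out = length(exlen))]
  list(locus = locus,
       exons = data.table(accession = acc, exon_rank = seq_along(exlen),
                          start = gstart + ex_off,
                          end = gstart + ex_off + exlen - 1L),
       tx = data.table(accession = acc, gene_id = gid, chrom = "chr1",
                       strand = "+", coding = TRUE,
                       cds_start = cds_start, cds_end = cds_end),
       txseq = txseq)
}

# two genes: gene A 3 exons (120, 90, 120), CDS 10..324 (stop in exon 3);
# gene B 3 exons (100, 110, 120), CDS 12..326
coding_fixture <- function(seed = 8L) {
  set.seed(seed)
  lead <- 50L
  gA <- build_coding_gene("NM_A", "GA", c(120L, 90L, 120L), 10L, 324L,
                          lead, seed)
  gapA_end <- lead + nchar(gA$locus)
  gB <- build_coding_gene("NM_B", "GB", c(100L, 110L, 120L), 12L, 326L,
                          gapA_end + 400L, seed + 1L)
  genome <- c(chr1 = paste0(rand_dna(lead), gA$locus, rand_dna(400L),
                            gB$locus, rand_dna(100L)))
  txs <- transcript_set(rbind(gA$exons, gB$exons), rbind(gA$tx, gB$tx),
                        genome = genome)
  list(genome = genome, txs = txs, gA = gA, gB = gB)
}

test_that("chimera assembly concatenates the expected segments and sequence", {
  fx <- coding_fixture()
  ch <- assemble_chimera(fx$txs, fx$genome, "NM_A", 2L, "NM_B", 2L)
  expect_equal(nrow(ch$segments), 2L + 2L)
  expect_identical(ch$segments$source, c("5p", "5p", "3p", "3p"))
  # string oracle: direct substring concatenation from the genome
  exA <- fx$txs$exons[accession == "NM_A"][order(exon_rank)]
  exB <- fx$txs$exons[accession == "NM_B"][order(exon_rank)]
  want <- paste0(
    substring(fx$genome, exA$start[1L], exA$end[1L]),
    substring(fx$genome, exA$start[2L], exA$end[2L]),
    substring(fx$genome, exB$start[2L], exB$end[2L]),
    substring(fx$genome, exB$start[3L], exB$end[3L]))
  expect_identical(ch$sequence, want)
  expect_equal(ch$junction_positions, cumsum(c(120L, 90L, 110L)))
  expect_equal(ch$last_exon_start, 120L + 90L + 110L + 1L)

  ivl <- list(chrom = "chr1", start = exA$end[3L] + 50L,
              end = exA$end[3L] + 169L, strand = "+")
  ch2 <- assemble_chimera(fx$txs, fx$genome, "NM_A", 2L, "NM_B", 2L,
                          intervening = ivl)
  expect_equal(nrow(ch2$segments), 5L)
  expect_identical(ch2$segments$source[3L], "intervening")
  expect_error(assemble_chimera(fx$txs, fx$genome, "NM_A", 9L, "NM_B", 2L),
               "out of range")
})

test_that("coding calls distinguish full CDS, 3' shift and new TSS", {
  fx <- coding_fixture()
  # donor exon 2 of A: retained coding prefix = 210 - 9 = 201 nt (0 mod 3);
  # acceptor exon 2 of B: discarded 3' prefix = 100 nt, CDS offset 11 in
  # the retained suffix -> combined frame offset known by construction
  ch <- assemble_chimera(fx$txs, fx$genome, "NM_A", 2L, "NM_B", 2L)
  call <- predict_cds(ch, fx$txs)
  # oracle: naive translation from the original start
  o <- naive_translate(ch$sequence, 10L)
  expect_identical(call$protein, o$protein)
  expect_identical(call$start_class, "original_tss")
  expect_equal(call$stop_start, o$stop_start)
  # frame test matches mod-3 arithmetic: 5' coding prefix (210 - 10 + 1 =
  # 201) + 3' offset to CDS; full CDS iff the 3' CDS is reached in frame
  in_frame <- !is.na(call$mapped_stop3) && !is.na(o$stop_start) &&
    o$stop_start == call$mapped_stop3
  expect_identical(call$frame_class == "full_cds", in_frame)
  # full_cds implies termination in the last exon
  if (call$frame_class == "full_cds") {
    expect_identical(call$termination_class, "TLE")
  }

  # breakpoint before the 5' CDS start: acceptor keeps whole of gene B ->
  # new TSS predicted from the longest ORF; gene B's own CDS (104 codons)
  # is the longest ORF and preserves its frame
  chB <- assemble_chimera(fx$txs, fx$genome, "NM_A", 2L, "NM_B", 1L)
  # make the 5' CDS start NOT included: donor exon before the CDS start
  # needs cds_start > prefix; instead simulate by lifting the CDS start
  txs2 <- fx$txs
  txs2$tx <- copy(fx$txs$tx)
  txs2$tx[accession == "NM_A", cds_start := 250L]  # starts in exon 3
  txs2$tx[accession == "NM_A", cds_end := 324L]
  ch3 <- assemble_chimera(txs2, fx$genome, "NM_A", 2L, "NM_B", 2L)
  call3 <- predict_cds(ch3, txs2, min_orf_codons = 20L)
  expect_identical(call3$start_class, "new_tss")
  expect_identical(call3$frame_class, "new_tss")
})

test_that("premature stops in shifted chimeras are flagged as NMD substrates", {
  fx <- coding_fixture()
  found <- FALSE
  for (a_idx in c(2L, 3L)) for (d_idx in c(1L, 2L)) {
    ch <- assemble_chimera(fx$txs, fx$genome, "NM_A", d_idx, "NM_B", a_idx)
    call <- predict_cds(ch, fx$txs)
    o <- naive_translate(ch$sequence, 10L)
    expect_identical(call$protein, o$protein)
    if (call$frame_class == "shift_3p" &&
        !is.na(o$stop_start) && o$stop_start < ch$last_exon_start) {
      expect_identical(call$termination_class, "PTC")
      expect_true(call$nmd_subject)
      found <- TRUE
    }
  }
  expect_true(found)  # the fixture exercises at least one shifted PTC case
})

test_that("translation matches the naive oracle over random chimeras", {
  sim <- generate_genome(sim_config(seed = 91L, n_genes = 20L))
  set.seed(14L)
  accs <- sim$txs$tx$accession
  n_ok <- 0L
  for (i in 1:150) {
    t5 <- sample(accs, 1L); t3 <- sample(setdiff(accs, t5), 1L)
    n5 <- sim$txs$tx[accession == t5]$n_exons
    n3 <- sim$txs$tx[accession == t3]$n_exons
    d <- sample.int(n5, 1L); a <- sample.int(n3, 1L)
    ch <- assemble_chimera(sim$txs, sim$genome, t5, d, t3, a)
    call <- predict_cds(ch, sim$txs)
    if (call$start_class == "original_tss") {
      o <- naive_translate(ch$sequence, sim$txs$tx[accession == t5]$cds_start)
      expect_identical(call$protein, o$protein)
      # frame arithmetic: full CDS iff translation reaches the mapped
      # original 3' stop
      expect_identical(call$frame_class == "full_cds",
                       !is.na(o$stop_start) && !is.na(call$mapped_stop3) &&
                         o$stop_start == call$mapped_stop3)
      # full CDS implies termination in the last exon on these gene models
      if (call$frame_class == "full_cds") {
        expect_identical(call$termination_class, "TLE")
      }
      n_ok <- n_ok + 1L
    }
  }
  expect_gt(n_ok, 100L)
})

test_that("intervening exons shift, restore or leave the frame unchanged", {
  fx <- coding_fixture()
  base <- assemble_chimera(fx$txs, fx$genome, "NM_A", 2L, "NM_B", 2L)
  base_call <- predict_cds(base, fx$txs)
  exA <- fx$txs$exons[accession == "NM_A"][order(exon_rank)]
  mk_ivl <- function(len, seed = 30L) {
    # an intervening exon with no in-frame stop in any frame: use a run
    # free of T so no stop codon can occur
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G"), len, TRUE), collapse = "")
    start <- exA$end[3L] + 60L
    g <- fx$genome
    substr(g[["chr1"]], start, start + len - 1L) <- s
    list(genome = g, ivl = list(chrom = "chr1", start = start,
                                end = start + len - 1L, strand = "+"))
  }
  # length divisible by 3: frame class unchanged
  m <- mk_ivl(120L)
  with120 <- assemble_chimera(fx$txs, m$genome, "NM_A", 2L, "NM_B", 2L,
                              intervening = m$ivl)
  call120 <- predict_cds(with120, fx$txs)
  expect_identical(call120$frame_class, base_call$frame_class)
  expect_identical(
    intervening_exon_frame_effect(call120, base_call, with120, base),
    "no_effect")

  # length 100 (not divisible by 3) flips the 3' frame
  m100 <- mk_ivl(100L)
  with100 <- assemble_chimera(fx$txs, m100$genome, "NM_A", 2L, "NM_B", 2L,
                              intervening = m100$ivl)
  call100 <- predict_cds(with100, fx$txs)
  eff <- intervening_exon_frame_effect(call100, base_call, with100, base)
  if (base_call$frame_class == "full_cds") {
    expect_identical(eff, "out_of_frame")
  } else {
    expect_true(eff %in% c("into_frame", "stop_to_different_stop",
                           "no_effect"))
  }
  # oracle check for both variants
  expect_identical(call100$protein,
                   naive_translate(with100$sequence, 10L)$protein)
})

test_that("domain preservation uses exact prefix/suffix containment", {
  p5 <- "MAAAKKKWWWFFFLLL"     # 16 aa
  p3 <- "MGGGHHHYYYQQQPPP"     # 16 aa
  d5 <- data.table(domain = c("D5a", "D5b"), aa_start = c(2L, 10L),
                   aa_end = c(5L, 14L))
  d3 <- data.table(domain = "D3", aa_start = 9L, aa_end = 15L)
  # chimera preserving 8 aa of the 5' prefix and 10 aa of the 3' suffix
  call <- list(protein = paste0(substr(p5, 1L, 8L), substr(p3, 7L, 16L)),
               termination_class = "TLE")
  dc <- compare_domains(d5, d3, p5, p3, call)
  expect_identical(dc$side5$status, "Subset")   # D5a kept, D5b lost
  expect_identical(dc$side5$preserved, "D5a")
  expect_identical(dc$side3$status, "Cover")    # D3 within the kept suffix

  # full preservation on both sides
  call2 <- list(protein = paste0(p5, substr(p3, 2L, 16L)),
                termination_class = "TLE")
  dc2 <- compare_domains(d5, d3, p5, p3, call2)
  expect_identical(dc2$side5$status, "Cover")
  expect_identical(dc2$side3$status, "Cover")

  # a PTC chimera preserves no 3' domains even with matching sequence
  call3 <- list(protein = paste0(substr(p5, 1L, 8L), substr(p3, 7L, 16L)),
                termination_class = "PTC")
  dc3 <- compare_domains(d5, d3, p5, p3, call3)
  expect_identical(dc3$side3$status, "Null")

  # no original domains -> ND
  dc4 <- compare_domains(d5[0L], d3, p5, p3, call)
  expect_identical(dc4$side5$status, "ND")
  expect_error(compare_domains(data.table(domain = "X", aa_start = 1L,
                                          aa_end = 20L), d3, p5, p3, call),
               "outside")
})

test_that("5' domain status never degrades as the breakpoint moves 3'", {
  p5 <- strrep("ACDEFGHIKLMNPQRS", 4L)  # 64 aa
  p3 <- strrep("TVWYACDEFGHIKLMN", 4L)
  d5 <- data.table(domain = c("d1", "d2"), aa_start = c(5L, 30L),
                   aa_end = c(20L, 50L))
  d3 <- data.table(domain = character(), aa_start = integer(),
                   aa_end = integer())
  rank <- c(Null = 0L, Subset = 1L, Cover = 2L)
  prev <- -1L
  for (keep in c(10L, 25L, 45L, 55L, 64L)) {
    call <- list(protein = paste0(substr(p5, 1L, keep), substr(p3, 1L, 30L)),
                 termination_class = "TLE")
    st <- compare_domains(d5, d3, p5, p3, call)$side5$status
    expect_gte(rank[[st]], prev)
    prev <- rank[[st]]
  }
})
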