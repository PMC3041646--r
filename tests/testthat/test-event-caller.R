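mk_cluster <- function(target_seq, junction_at, offsets, mm_pos = NULL,
                       ids = NULL) {
  n <- length(offsets)
  L <- 33L
  if (is.null(mm_pos)) mm_pos <- replicate(n, integer(), simplify = FALSE)
  if (is.null(ids)) ids <- sprintf("r%d", seq_len(n))
  aln <- data.table(
    read_id = ids, sample_id = "s", junction_id = "j1", target_idx = 1L,
    target_offset = offsets,
    mismatches = lengths(mm_pos),
    mismatch_positions = mm_pos,
    left_overhang = junction_at - offsets + 1L,
    right_overhang = L - (junction_at - offsets + 1L))
  list(junction_id = "j1", target_seq = target_seq, junction_at = junction_at,
       alignments = aln)
}

test_that("same-gene isoform junctions are filtered out", {
  tg <- data.table(junction_id = c("j1", "j2"),
                   donor_genes = list("gA", "gA"),
                   acceptor_genes = list("gA", "gB"))
  aln <- data.table(read_id = c("r1", "r2"), junction_id = c("j1", "j2"))
  kept <- filter_intragenic_equivalents(aln, tg)
  expect_identical(kept$junction_id, "j2")
})

test_that("consistency filter implements union coverage plus mismatch veto", {
  seq <- rand_dna(160L)
  # single clean read, overhangs (15, 18): all 11 positions matched -> PASS
  cl <- mk_cluster(seq, 80L, offsets = 66L)
  expect_true(consistency_filter(cl)$pass)

  # single read with overhangs (9, 24): left side coverage < 11 -> FAIL
  cl2 <- mk_cluster(seq, 80L, offsets = 72L)
  r <- consistency_filter(cl2)
  expect_false(r$pass)
  expect_identical(r$reason, "side_coverage")

  # one read mismatching at +3 rescued by a second read matching there
  pos_p3 <- 83L
  cl3 <- mk_cluster(seq, 80L, offsets = c(66L, 64L),
                    mm_pos = list(pos_p3, integer()))
  expect_true(consistency_filter(cl3)$pass)

  # a single read with one mismatch at -4: every covering read mismatches
  # that position -> FAIL even though 11 consistent matches exist elsewhere
  cl4 <- mk_cluster(seq, 80L, offsets = 66L, mm_pos = list(77L))
  r4 <- consistency_filter(cl4)
  expect_false(r4$pass)
  expect_identical(r4$reason, "consistent_mismatch")
})

test_that("homology filter rejects junction fragments matching a parent gene", {
  set.seed(3L)
  txA <- rand_dna(1000L)
  txB <- rand_dna(1000L)
  # fragment lifted verbatim from the 5' transcript
  frag_src <- substring(txA, 301L, 360L)
  target <- paste0(substring(frag_src, 1L, 30L), substring(frag_src, 31L, 60L))
  cl <- mk_cluster(target, 30L, offsets = 7L)
  cl$alignments$left_overhang <- 24L
  cl$alignments$right_overhang <- 9L
  r <- homology_filter(cl, c(NM_A = txA), c(NM_B = txB))
  expect_false(r$pass)
  expect_identical(r$reason, "junction_homology")

  # unrelated random genes pass both rules
  targ2 <- paste0(substring(txA, 101L, 130L), substring(txB, 501L, 530L))
  cl2 <- mk_cluster(targ2, 30L, offsets = 10L)
  cl2$alignments$left_overhang <- 21L
  cl2$alignments$right_overhang <- 12L
  expect_true(homology_filter(cl2, c(NM_A = txA), c(NM_B = txB))$pass)

  # identical 60-nt segment shared by the two genes: 50 matches in a
  # 50-column window -> gene homology
  txB2 <- paste0(substring(txB, 1L, 400L), substring(txA, 201L, 260L),
                 substring(txB, 461L, 1000L))
  r2 <- homology_filter(cl2, c(NM_A = txA), c(NM_B = txB2))
  expect_false(r2$pass)
  expect_identical(r2$reason, "gene_homology")

  # 92%-identity paralogs are rejected
  txP <- mutate_seq(txA, 80L, seed = 4L)
  r3 <- homology_filter(cl2, c(NM_A = txA), c(NM_P = txP))
  expect_false(r3$pass)
  expect_identical(r3$reason, "gene_homology")

  expect_error(homology_filter(cl2, character(), c(NM_B = txB)), "missing")
})

test_that("homology and consistency filters commute", {
  sim <- generate_genome(sim_config(seed = 21L, n_genes = 12L, n_tic = 3L,
                                    depth = 6000L, error_rate = 0.005))
  sim <- assign_expression(plant_events(sim))
  rs <- simulate_reads(sim)
  sites <- catalog_splice_sites(sim$txs)
  tt <- build_tic_targets(sites, sim$txs, sim$genome)
  aln <- align_reads(rs$reads, build_index(tt))$alignments
  aln <- aln[supports_junction(aln, 8L)]
  clusters <- build_clusters(aln, tt)
  sc <- ticfinder:::.make_seq_cache(sim$txs, sim$genome)
  gseqs <- function(gid) {
    vapply(sim$txs$tx[gene_id == gid]$accession, sc, "")
  }
  hom_pass <- function(cl) {
    i <- match(cl$junction_id, tt$junction_id)
    homology_filter(cl, gseqs(tt$donor_genes[[i]][1L]),
                    gseqs(tt$acceptor_genes[[i]][1L]))$pass
  }
  con_pass <- function(cl) consistency_filter(cl)$pass
  ab <- Filter(hom_pass, Filter(con_pass, clusters))
  ba <- Filter(con_pass, Filter(hom_pass, clusters))
  expect_identical(names(ab), names(ba))
})

test_that("FDR estimates render as percentages to one decimal", {
  f <- estimate_fdr(5L, 339L)
  expect_equal(f$percent, 1.5)
  expect_equal(f$fdr, 5 / 339)
  expect_equal(estimate_fdr(0L, 100L)$percent, 0)
  expect_equal(estimate_fdr(3L, 200L)$percent, 1.5)
  expect_true(is.na(estimate_fdr(2L, 0L)$fdr))
  expect_error(estimate_fdr(-1L, 10L))
})

test_that("events carry pattern flags, isoform groups and shared sites", {
  lab <- function(acc, i, n) data.table(accession = acc, exon_index = i,
                                        exon_count = n)
  tg <- data.table(
    junction_id = c("j1", "j2", "j3"), kind = "tic", chrom = "chr1",
    strand = "+", donor_pos = c(100L, 200L, 900L),
    acceptor_pos = c(500L, 500L, 1500L),
    left_seq = "", right_seq = "", seq = strrep("A", 160L),
    junction_at = 80L, splice_distance = c(400L, 300L, 600L),
    intergenic_distance = 100L,
    donor_genes = list("gA", "gA", "gC"),
    acceptor_genes = list("gB", "gB", "gD"),
    donor_labels = list(lab("NM_A", 4L, 5L), lab("NM_A", 3L, 5L),
                        lab("NM_C", 1L, 3L)),
    acceptor_labels = list(lab("NM_B", 2L, 4L), lab("NM_B", 2L, 4L),
                           lab("NM_D", 3L, 3L)),
    truncated = FALSE, source_junction_id = NA_character_)
  clusters <- lapply(c("j1", "j2", "j3"), function(j) {
    list(junction_id = j, target_seq = strrep("A", 160L), junction_at = 80L,
         alignments = data.table(read_id = paste0(j, "_r1"), sample_id = "s",
                                 junction_id = j, target_idx = 1L,
                                 target_offset = 60L, mismatches = 0L,
                                 mismatch_positions = list(integer()),
                                 left_overhang = 21L, right_overhang = 12L))
  })
  ev <- call_events(clusters, tg)
  expect_equal(nrow(ev), 3L)
  j1 <- ev[junction_id == "j1"]
  expect_identical(j1$donor_label, "e4/5")
  expect_identical(j1$acceptor_label, "e2/4")
  expect_true(j1$pattern_flag)     # (n-1) donor and +2 acceptor
  expect_false(ev[junction_id == "j2"]$pattern_flag)
  # j1 and j2 join the same gene pair sharing the acceptor
  expect_equal(ev[junction_id == "j1"]$isoform_group,
               ev[junction_id == "j2"]$isoform_group)
  expect_identical(ev[junction_id == "j1"]$shared_site, "acceptor")
  expect_true(is.na(ev[junction_id == "j3"]$shared_site))
})

test_that("planted readthroughs are recovered and decoy paralogs rejected", {
  cfg <- sim_config(seed = 33L, n_genes = 24L, n_tic = 4L, n_decoy = 1L,
                    depth = 1000L, tic_efficiency = 0.25)
  sim <- assign_expression(plant_events(generate_genome(cfg)))
  # depth chosen so every event expects >= 5 clean junction reads with
  # both overhangs past the 11-nt consistency window
  lam_unit <- expected_junction_reads(sim, depth = 1L)
  L <- cfg$read_length
  usable <- ((L - 22L + 1L) / (L - 1L)) * (1 - cfg$error_rate)^L
  real <- sim$events[decoy == FALSE]
  sim$config$depth <- as.integer(ceiling(
    5 / (min(lam_unit[event_id %in% real$event_id]$lambda) * usable)))
  lam <- expected_junction_reads(sim)
  rs <- simulate_reads(sim)
  res <- run_targeted(sim$genome, sim$txs, rs$reads)
  ev <- res$events
  # every planted (non-decoy) event is called at this coverage
  covered <- merge(real, lam, by = "event_id")
  for (i in seq_len(nrow(covered))) {
    hit <- ev[gene5 == covered$gene5[i] & gene3 == covered$gene3[i] &
              donor_pos == covered$donor_pos[i] &
              acceptor_pos == covered$acceptor_pos[i]]
    expect_equal(nrow(hit), 1L)
  }
  # no event joins genes never planted together
  planted_pairs <- unique(paste(sim$events$gene5, sim$events$gene3))
  expect_true(all(paste(ev$gene5, ev$gene3) %in% planted_pairs))
  # the decoy pair is rejected by the homology filter
  dec <- sim$events[decoy == TRUE]
  expect_equal(nrow(ev[gene5 == dec$gene5 & gene3 == dec$gene3]), 0L)
  # every reported event keeps a supporting alignment with min overhang >= 8
  expect_true(all(ev$n_reads >= 1L))
  aln <- res$alignments
  expect_true(all(pmin(aln$left_overhang, aln$right_overhang) >= 8L))
})

test_that("control arm is silent on clean planted-signal reads", {
  cfg <- sim_config(seed = 57L, n_genes = 14L, n_tic = 2L, depth = 10000L,
                    error_rate = 0, tic_efficiency = 0.3)
  sim <- assign_expression(plant_events(generate_genome(cfg)))
  rs <- simulate_reads(sim)
  sites <- catalog_splice_sites(sim$txs)
  tt <- build_tic_targets(sites, sim$txs, sim$genome)
  it <- build_intragenic_targets(sim$txs, sim$genome)
  ctl <- build_control_targets(tt)
  n_ctl <- run_control_arm(rs$reads, ctl, build_index(it), sim$txs, sim$genome)
  expect_equal(n_ctl, 0L)
  # monotonicity: control arm never exceeds the real arm on planted signal
  real <- detect_tic_events(rs$reads, tt, build_index(it), sim$txs, sim$genome)
  expect_lte(n_ctl, nrow(real$events))
})
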