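# Pipeline orchestration: configuration block, the targeted-alignment run
# (events + FDR), the split-record classifier run, and the coding-potential
# run, each returning a classed result with print methods and TSV writers.

#' Pipeline configuration
#'
#' All detection thresholds in one place. The defaults are the package's
#' working values: 200 kb readthrough window, 80 nt junction flanks, 8 nt
#' candidate overhang (11 nt for intragenic splice reporting), 11 bp
#' consistency window, 90\% junction-homology coverage, 40 matches in a
#' 50-column window for gene homology, 300 bp intervening-exon maximum,
#' 2-read minimum for distant fusions and 14 nt split-record anchors.
#'
#' @param max_distance,flank,overhang_tic,overhang_intragenic
#'   ,consistency_window,homology_fraction,homology_matches,homology_window
#'   ,exon_max,min_fusion_reads,anchor_min,k,max_mismatches thresholds; see
#'   description.
#' @param seed integer seed for any randomised step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(max_distance = 200000L, flank = 80L,
                            overhang_tic = 8L, overhang_intragenic = 11L,
                            consistency_window = 11L,
                            homology_fraction = 0.90, homology_matches = 40L,
                            homology_window = 50L, exon_max = 300L,
                            min_fusion_reads = 2L, anchor_min = 14L,
                            k = 12L, max_mismatches = 1L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, TRUE)))
  structure(cfg, class = "pipeline_config")
}

#' Run the targeted-alignment readthrough pipeline
#'
#' Builds intragenic, readthrough and shifted-control junction targets from
#' the gene model, aligns the reads against the readthrough and intragenic
#' sets, applies the filter cascade, and estimates the FDR from the control
#' arm.
#'
#' @param genome genome from [load_genome()] or a sim.
#' @param txs [transcript_set()].
#' @param reads read table (read_id, sample_id, sequence).
#' @param config a [pipeline_config()].
#' @return object of class `tic_result`: events, fdr, attrition (real
#'   arm), control_attrition, targets.
#' @export
run_targeted <- function(genome, txs, reads, config = pipeline_config()) {
  sites <- catalog_splice_sites(txs)
  tic_targets <- build_tic_targets(sites, txs, genome,
                                   max_distance = config$max_distance,
                                   flank = config$flank)
  intra_targets <- build_intragenic_targets(txs, genome, flank = config$flank)
  ctl_targets <- build_control_targets(tic_targets)
  intra_index <- if (nrow(intra_targets) > 0L) build_index(intra_targets,
                                                           k = config$k) else NULL
  real <- detect_tic_events(reads, tic_targets, intra_index, txs, genome,
                            overhang_min = config$overhang_tic,
                            window = config$consistency_window,
                            max_mismatches = config$max_mismatches,
                            homology_fraction = config$homology_fraction,
                            homology_matches = config$homology_matches,
                            homology_window = config$homology_window,
                            k = config$k)
  ctl <- detect_tic_events(reads, ctl_targets, intra_index, txs, genome,
                           overhang_min = config$overhang_tic,
                           window = config$consistency_window,
                           max_mismatches = config$max_mismatches,
                           homology_fraction = config$homology_fraction,
                           homology_matches = config$homology_matches,
                           homology_window = config$homology_window,
                           k = config$k)
  fdr <- estimate_fdr(nrow(ctl$events), nrow(real$events))
  structure(list(events = real$events, fdr = fdr,
                 attrition = real$attrition,
                 control_attrition = ctl$attrition,
                 alignments = real$alignments,
                 targets = tic_targets, config = config),
            class = "tic_result")
}

#' @export
print.tic_result <- function(x, ...) {
  cat(sprintf("tic_result: %d readthrough event(s)\n", nrow(x$events)))
  if (nrow(x$events) > 0L) {
    cat(sprintf("  %s-%s %s-%s (%d read(s))\n",
                x$events$gene5, x$events$donor_label,
                x$events$gene3, x$events$acceptor_label,
                x$events$n_reads), sep = "")
  }
  cat(sprintf("stage attrition: %s\n",
              paste(names(x$attrition), x$attrition, sep = "=",
                    collapse = ", ")))
  print(x$fdr)
  invisible(x)
}

#' @export
#' @method summary tic_result
summary.tic_result <- function(object, ...) {
  ev <- object$events
  cat(sprintf("readthrough events: %d over %d gene pair(s)\n",
              nrow(ev), data.table::uniqueN(ev[, .(gene5, gene3)])))
  if (nrow(ev)) {
    cat(sprintf("(n-1)->+2 pattern: %d/%d (%.0f%%)\n",
                sum(ev$pattern_flag), nrow(ev),
                100 * mean(ev$pattern_flag)))
    multi <- ev[, .N, by = isoform_group][N > 1L]
    cat(sprintf("gene pairs with multiple isoforms: %d\n", nrow(multi)))
    cat(sprintf("median splice distance: %.0f bp\n",
                stats::median(ev$splice_distance)))
  }
  print(object$fdr)
  invisible(object)
}

#' Run the split-record classifier
#'
#' Classifies split-alignment records into the six fusion categories,
#' aggregates per junction, applies the multi-read filter to the distant
#' categories, and detects intervening-exon readthroughs.
#'
#' @param records split-alignment records (or a TSV path).
#' @param txs [transcript_set()].
#' @param genome genome (needed for the TICIE homology rule).
#' @param config a [pipeline_config()].
#' @return object of class `fusion_result`: classified, calls,
#'   filtered_calls, ticie.
#' @export
run_classifier <- function(records, txs, genome, config = pipeline_config()) {
  if (is.character(records)) records <- load_split_records(records)
  sites <- catalog_splice_sites(txs)
  classified <- classify_split(records, txs, sites = sites,
                               max_local = config$max_distance)
  calls <- aggregate_fusion_calls(classified)
  filtered <- filter_multiread(calls, min_reads = config$min_fusion_reads)
  ticie <- detect_ticie(records, sites, txs, genome,
                        exon_max = config$exon_max,
                        max_local = config$max_distance)
  structure(list(classified = classified, calls = calls,
                 filtered_calls = filtered, ticie = ticie, config = config),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  tab <- table(x$classified$category)
  cat("fusion_result — records by category:\n")
  print(tab)
  cat(sprintf("calls after multi-read filter: %d; TICIE candidates: %d\n",
              nrow(x$filtered_calls), nrow(x$ticie)))
  invisible(x)
}

#' Run the coding-potential analysis over readthrough events
#'
#' Assembles the chimeric transcript for each event, predicts its coding
#' region, frame and termination class, and (when domain tables are given)
#' the preserved-domain status of both sides.
#'
#' @param events event table from [call_events()] / [run_targeted()]; must
#'   carry gene5/gene3 plus donor/acceptor labels resolvable in `txs`.
#' @param txs,genome gene model and genome.
#' @param domains optional domain table (see [load_domain_table()]).
#' @param min_orf_codons passed to [predict_cds()].
#' @return data.table with one row per event: start/frame/termination
#'   classes, protein length, and domain statuses when available.
#' @export
run_coding <- function(events, txs, genome, domains = NULL,
                       min_orf_codons = 30L) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i]
    tx5 <- txs$tx[gene_id == ev$gene5]$accession[1L]
    tx3 <- txs$tx[gene_id == ev$gene3]$accession[1L]
    if (is.na(tx5) || is.na(tx3)) {
      stop("event references unknown gene: ", ev$gene5, "/", ev$gene3)
    }
    d_idx <- as.integer(sub("^e(\\d+)/.*$", "\\1", ev$donor_label))
    a_idx <- as.integer(sub("^e(\\d+)/.*$", "\\1", ev$acceptor_label))
    chim <- assemble_chimera(txs, genome, tx5, d_idx, tx3, a_idx)
    call <- predict_cds(chim, txs, min_orf_codons = min_orf_codons)
    row <- data.table::data.table(
      gene5 = ev$gene5, gene3 = ev$gene3,
      donor_label = ev$donor_label, acceptor_label = ev$acceptor_label,
      start_class = call$start_class, frame_class = call$frame_class,
      termination_class = call$termination_class,
      nmd_subject = call$nmd_subject,
      protein_aa = nchar(call$protein))
    if (!is.null(domains)) {
      p5 <- .original_protein(txs, genome, tx5)
      p3 <- .original_protein(txs, genome, tx3)
      d5 <- domains[domains$protein_id == tx5, ]
      d3 <- domains[domains$protein_id == tx3, ]
      dc <- compare_domains(d5[, c("domain", "aa_start", "aa_end")],
                            d3[, c("domain", "aa_start", "aa_end")],
                            p5, p3, call)
      row[, `:=`(domains5 = dc$side5$status, domains3 = dc$side3$status)]
    }
    out[[length(out) + 1L]] <- row
  }
  data.table::rbindlist(out, fill = TRUE)
}

# translate a transcript's annotated CDS (stop codon excluded)
.original_protein <- function(txs, genome, acc) {
  i <- match(acc, txs$tx$accession)
  if (is.na(txs$tx$cds_start[i])) stop("transcript has no CDS: ", acc)
  s <- transcript_sequence(txs, genome, acc)
  .translate_to_stop(s, txs$tx$cds_start[i])$protein
}

#' Write an event report TSV
#'
#' Fixed column order; list columns are collapsed with commas.
#'
#' @param events event table.
#' @param path output TSV.
#' @export
write_event_report <- function(events, path) {
  ev <- data.table::copy(events)
  ev[, samples := vapply(samples, paste, "", collapse = ",")]
  data.table::fwrite(ev, path, sep = "\t")
  invisible(path)
}
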