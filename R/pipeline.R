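#' Run the full piRNA analysis on a study
#'
#' Chains every stage of the pipeline: tag collapsing, genome mapping,
#' sequential ncRNA and miRNA subtraction, the 24-33 nt / unique-locus
#' candidate call, per-comparison expression records and DEpiRNA
#' screening, complementarity-based target prediction with the free-energy
#' gate, term enrichment, and regulatory-network construction.
#'
#' @param x a `pirna_sim` object from [simulate_study()], or a list with
#'   elements `manifest` (data.frame replicate/group/file), `genome`,
#'   `annotations`, `mirna`, `transcripts`, `gene2term`, `terms` (paths or
#'   parsed objects).
#' @param comparisons list of [comparison_spec()]; defaults to
#'   consecutive-group comparisons in manifest group order.
#' @param params a [scoring_params()].
#' @param nn a [nn_params()].
#' @param categories pathway-category configuration for the network.
#' @param min_overlap_frac interval-overlap fraction for subtraction.
#' @param length_range candidate length window.
#' @param max_mismatches mapper mismatch allowance.
#' @return object of class `pirna_study`: list with `tags`, `hits`,
#'   `ledger`, `candidates`, `lib_sizes`, `records` (per comparison),
#'   `de` (per comparison), `target_hits`, `gated`, `enrichment` (per
#'   comparison), `network`, `hubs`.
#' @export
analyze_study <- function(x, comparisons = NULL,
                          params = scoring_params(), nn = nn_params(),
                          categories = default_pathway_categories(),
                          min_overlap_frac = 0.5,
                          length_range = c(24L, 33L),
                          max_mismatches = 0L) {
  if (inherits(x, "pirna_sim")) {
    inp <- list(manifest = x$reads$manifest, genome = x$genome,
                annotations = x$loci, mirna = x$paths$mirna,
                transcripts = x$transcripts,
                gene2term = x$gene2term, terms = x$terms)
  } else inp <- x

  tags <- collapse_reads(inp$manifest)
  groups <- attr(tags, "groups")
  lib_sizes <- colSums(tag_count_matrix(tags))

  hits <- map_tags(tags, inp$genome, max_mismatches = max_mismatches)
  s1 <- subtract_ncrna(tags, hits, inp$annotations,
                       min_overlap_frac = min_overlap_frac)
  s2 <- subtract_mirna(s1$tags, s1$hits, mirna_seqs = inp$mirna)
  ledger <- rbind(s1$ledger, s2$ledger)
  candidates <- call_pirnas(s2$tags, s2$hits, length_range = length_range)

  glab <- unique(unname(groups))
  if (is.null(comparisons)) {
    comparisons <- lapply(seq_len(length(glab) - 1L), function(k)
      comparison_spec(numerator = glab[k + 1L], denominator = glab[k]))
  }
  names(comparisons) <- vapply(comparisons, `[[`, "", "name")

  records <- lapply(comparisons, function(sp)
    expression_records(candidates, lib_sizes, sp))
  de <- lapply(records, call_depirnas)

  de_ids <- unique(unlist(lapply(de, function(d)
    c(d$up$pirna_id, d$down$pirna_id))))
  pir_seq <- setNames(candidates$sequence, candidates$pirna_id)
  target_hits <- if (length(de_ids)) {
    predict_targets(pir_seq[de_ids], inp$transcripts, params, nn)
  } else {
    scan_targets(strrep("A", 24), inp$transcripts, params, nn)[0, ]
  }
  gated <- gate_targets(target_hits, params$energy_gate)

  map <- term_map(inp$gene2term, inp$terms)
  tx_names <- if (methods::is(inp$transcripts, "DNAStringSet"))
    names(inp$transcripts)
  else if (is.character(inp$transcripts) && length(inp$transcripts) == 1L &&
           file.exists(inp$transcripts))
    names(Biostrings::readDNAStringSet(inp$transcripts))
  else names(inp$transcripts)

  enrichment <- lapply(names(de), function(cmp) {
    ids <- c(de[[cmp]]$up$pirna_id, de[[cmp]]$down$pirna_id)
    tg <- unique(gated$hits$transcript_id[gated$hits$pirna_id %in% ids])
    if (!length(tg)) return(NULL)
    enrich_terms(tg, tx_names, map)
  })
  names(enrichment) <- names(de)

  network <- build_network(de, gated$hits, map, categories)
  hubs <- hub_stats(network)

  structure(list(tags = tags, hits = hits, ledger = ledger,
                 candidates = candidates, lib_sizes = lib_sizes,
                 groups = groups, records = records, de = de,
                 target_hits = target_hits, gated = gated,
                 enrichment = enrichment, network = network, hubs = hubs),
            class = "pirna_study")
}

#' @export
print.pirna_study <- function(x, ...) {
  cat(sprintf("piRNA study analysis: %d tags -> %d candidate piRNAs\n",
              nrow(x$tags), nrow(x$candidates)))
  for (cmp in names(x$de)) {
    s <- x$de[[cmp]]$summary
    cat(sprintf("  %s: %d up, %d down\n", cmp, s$n_up, s$n_down))
  }
  cat(sprintf("  %d gated target relations; network: %d nodes, %d edges\n",
              nrow(x$gated$hits), igraph::vcount(x$network),
              igraph::ecount(x$network)))
  invisible(x)
}

#' Write the analysis tables of a study to disk
#'
#' Writes the candidate catalog, removal ledger, per-comparison expression
#' records and DE summaries, gated target table, enrichment tables, and
#' the network (SIF + GraphML) under `outdir`.
#'
#' @param study a `pirna_study` from [analyze_study()].
#' @param outdir output directory.
#' @return named vector of written paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(candidates = file.path(outdir, "candidates.tsv"),
             ledger = file.path(outdir, "removal_ledger.tsv"),
             targets = file.path(outdir, "gated_targets.tsv"))
  write_tsv(study$candidates, paths["candidates"])
  write_tsv(study$ledger, paths["ledger"])
  write_tsv(study$gated$hits, paths["targets"])
  for (cmp in names(study$records)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", cmp)
    f <- file.path(outdir, sprintf("expression_%s.tsv", slug))
    write_tsv(study$records[[cmp]], f)
    paths[paste0("expression_", slug)] <- f
    g <- file.path(outdir, sprintf("de_summary_%s.tsv", slug))
    write_tsv(study$de[[cmp]]$summary, g)
    paths[paste0("de_summary_", slug)] <- g
    if (!is.null(study$enrichment[[cmp]])) {
      h <- file.path(outdir, sprintf("enrichment_%s.tsv", slug))
      write_tsv(study$enrichment[[cmp]], h)
      paths[paste0("enrichment_", slug)] <- h
    }
  }
  net <- export_network(study$network, file.path(outdir, "network"))
  paths <- c(paths, net)
  invisible(paths)
}
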