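#' Configuration for a synthetic piRNA study
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults reproduce the design the downstream analysis assumes: three
#' developmental groups (`Am4`, `Am5`, `Am6`) with three biological
#' replicates each, 24-33 nt piRNA loci with a cytosine-dominant first
#' base, contaminating rRNA/tRNA/snRNA/snoRNA/scRNA fragments and miRNAs,
#' negative-binomial replicate counts, and 10% of piRNA loci carrying a
#' planted |log2 fold change| of 2 between consecutive groups.
#'
#' @param seed integer seed controlling every random draw downstream.
#' @param genome_length genome size in bp (single chromosome `chr1`).
#' @param n_pirna_loci number of piRNA-producing loci.
#' @param pirna_length_range inclusive piRNA length bounds, within 18-40 nt.
#' @param first_base_weights named probabilities over A/C/G/T for the piRNA
#'   5' base; must sum to 1. The default is C-dominant.
#' @param ping_pong_10A if `TRUE`, piRNA position 10 is adenine with
#'   probability 0.7 (secondary piRNA ping-pong signature); off by default
#'   since the emulated libraries show a primary-like 1C bias.
#' @param n_ncrna_loci named integer vector: loci per contaminating ncRNA
#'   class (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `scRNA`).
#' @param ncrna_length_range length bounds for ncRNA loci (bp).
#' @param n_mirna number of miRNA loci.
#' @param mirna_length_range length bounds for mature miRNAs (nt).
#' @param n_transcripts number of target transcripts (separate FASTA, not
#'   genomic).
#' @param transcript_length_range transcript length bounds (nt).
#' @param n_replicates biological replicates per group.
#' @param groups ordered group labels; consecutive pairs define the
#'   comparisons (e.g. `"Am4 vs Am5"`).
#' @param mean_depth expected reads per replicate library.
#' @param nb_dispersion negative-binomial dispersion of replicate counts
#'   (variance = mu + dispersion * mu^2).
#' @param de_fraction fraction of piRNA loci with a planted expression
#'   effect.
#' @param planted_log2fc_range magnitude bounds for planted log2 fold
#'   changes; the default plants exactly |log2FC| = 2 (sign random).
#' @param target_site_rate expected planted target sites per DE piRNA
#'   (Poisson; the first DE piRNA gets three times the rate and acts as the
#'   designed hub).
#' @param site_edits number of core-region mismatches engineered into each
#'   planted target site (0 = exact reverse complement).
#' @param contamination named fractions of each library drawn from ncRNA
#'   fragments and miRNAs.
#' @param seq_error_rate per-base substitution rate applied to reads
#'   (0 = reads are exact locus copies).
#' @param abundance_sdlog log-normal sd of baseline locus abundances.
#' @param enriched_term_frac named fractions: probability that a targeted /
#'   background transcript carries the designed enriched pathway term.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_pirna_loci = 50, mean_depth = 1000)
#' cfg$groups
sim_config <- function(seed = 1L,
                       genome_length = 200000L,
                       n_pirna_loci = 500L,
                       pirna_length_range = c(24L, 33L),
                       first_base_weights = c(A = 0.15, C = 0.55, G = 0.15, T = 0.15),
                       ping_pong_10A = FALSE,
                       n_ncrna_loci = c(rRNA = 15L, tRNA = 15L, snRNA = 10L,
                                        snoRNA = 10L, scRNA = 5L),
                       ncrna_length_range = c(70L, 150L),
                       n_mirna = 40L,
                       mirna_length_range = c(21L, 22L),
                       n_transcripts = 150L,
                       transcript_length_range = c(300L, 1200L),
                       n_replicates = 3L,
                       groups = c("Am4", "Am5", "Am6"),
                       mean_depth = 100000L,
                       nb_dispersion = 0.1,
                       de_fraction = 0.1,
                       planted_log2fc_range = c(2, 2),
                       target_site_rate = 3,
                       site_edits = 0L,
                       contamination = c(ncrna = 0.10, mirna = 0.05),
                       seq_error_rate = 0,
                       abundance_sdlog = 1,
                       enriched_term_frac = c(target = 0.8, background = 0.1)) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_pirna_loci = as.integer(n_pirna_loci),
              pirna_length_range = as.integer(pirna_length_range),
              first_base_weights = first_base_weights,
              ping_pong_10A = isTRUE(ping_pong_10A),
              n_ncrna_loci = n_ncrna_loci,
              ncrna_length_range = as.integer(ncrna_length_range),
              n_mirna = as.integer(n_mirna),
              mirna_length_range = as.integer(mirna_length_range),
              n_transcripts = as.integer(n_transcripts),
              transcript_length_range = as.integer(transcript_length_range),
              n_replicates = as.integer(n_replicates), groups = groups,
              mean_depth = as.integer(mean_depth),
              nb_dispersion = nb_dispersion, de_fraction = de_fraction,
              planted_log2fc_range = planted_log2fc_range,
              target_site_rate = target_site_rate,
              site_edits = as.integer(site_edits),
              contamination = contamination,
              seq_error_rate = seq_error_rate,
              abundance_sdlog = abundance_sdlog,
              enriched_term_frac = enriched_term_frac)

  stopifnot(length(cfg$pirna_length_range) == 2L)
  if (abs(sum(cfg$first_base_weights) - 1) > 1e-8)
    stop("first_base_weights must sum to 1", call. = FALSE)
  if (!all(names(cfg$first_base_weights) %in% DNA_BASES))
    stop("first_base_weights must be named with A/C/G/T", call. = FALSE)
  if (cfg$pirna_length_range[1] < 18L || cfg$pirna_length_range[2] > 40L ||
      cfg$pirna_length_range[1] > cfg$pirna_length_range[2])
    stop("pirna_length_range must satisfy 18 <= low <= high <= 40", call. = FALSE)
  if (length(cfg$groups) < 2L)
    stop("need at least two group labels", call. = FALSE)
  if (anyDuplicated(cfg$groups))
    stop("group labels must be unique", call. = FALSE)
  if (cfg$nb_dispersion <= 0)
    stop("nb_dispersion must be positive", call. = FALSE)
  counts <- c(cfg$genome_length, cfg$n_pirna_loci, cfg$n_ncrna_loci,
              cfg$n_mirna, cfg$n_transcripts, cfg$n_replicates,
              cfg$mean_depth)
  if (any(counts < 0))
    stop("counts and depths must be non-negative", call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  if (sum(cfg$contamination) >= 1)
    stop("contamination fractions must sum to < 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic piRNA study configuration\n")
  cat(sprintf("  seed %d | genome %s bp | %d piRNA loci (%d-%d nt)\n",
              x$seed, format(x$genome_length, big.mark = ","),
              x$n_pirna_loci, x$pirna_length_range[1], x$pirna_length_range[2]))
  cat(sprintf("  groups: %s x %d replicates, %s reads/replicate\n",
              paste(x$groups, collapse = "/"), x$n_replicates,
              format(x$mean_depth, big.mark = ",")))
  cat(sprintf("  DE: %.0f%% of loci, planted |log2FC| in [%g, %g], NB dispersion %g\n",
              100 * x$de_fraction, x$planted_log2fc_range[1],
              x$planted_log2fc_range[2], x$nb_dispersion))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Draw one random sequence per requested length (vectorized over loci).
random_dna_set <- function(lengths) {
  vapply(lengths, random_dna, character(1))
}

#' Generate the synthetic genome and locus annotations
#'
#' Builds a random-composition single-chromosome genome and embeds
#' non-overlapping piRNA, ncRNA (rRNA/tRNA/snRNA/snoRNA/scRNA), and miRNA
#' loci with recorded strands. piRNA locus sequences draw their 5' base
#' from `first_base_weights` and their lengths uniformly from
#' `pirna_length_range`. All coordinates are 0-based half-open internally
#' (converted to 1-based closed GFF3 on export).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named [Biostrings::DNAStringSet]) and `loci`
#'   (a [GenomicRanges::GRanges] with metadata columns `locus_id`, `class`,
#'   `sequence`; `class` is `piRNA_locus`, one of the ncRNA classes, or
#'   `miRNA`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  classes <- c(rep("piRNA_locus", config$n_pirna_loci),
               rep(names(config$n_ncrna_loci), config$n_ncrna_loci),
               rep("miRNA", config$n_mirna))
  n <- length(classes)
  lens <- integer(n)
  pir <- classes == "piRNA_locus"
  mir <- classes == "miRNA"
  ncr <- !pir & !mir
  lens[pir] <- sample(config$pirna_length_range[1]:config$pirna_length_range[2],
                      sum(pir), replace = TRUE)
  lens[ncr] <- sample(config$ncrna_length_range[1]:config$ncrna_length_range[2],
                      sum(ncr), replace = TRUE)
  lens[mir] <- sample(config$mirna_length_range[1]:config$mirna_length_range[2],
                      sum(mir), replace = TRUE)

  slack <- config$genome_length - sum(lens)
  if (slack < 0)
    stop(sprintf("loci do not fit: need %d bp but genome_length is %d (short by %d bp)",
                 sum(lens), config$genome_length, -slack), call. = FALSE)

  ord <- sample.int(n)           # interleave classes along the genome
  classes <- classes[ord]; lens <- lens[ord]
  pir <- classes == "piRNA_locus"; mir <- classes == "miRNA"

  offsets <- floor(sort(runif(n)) * slack)        # non-decreasing slack usage
  starts <- offsets + cumsum(c(0L, lens[-n]))     # 0-based, non-overlapping
  strands <- sample(c("+", "-"), n, replace = TRUE)

  seqs <- character(n)
  seqs[!pir] <- random_dna_set(lens[!pir])
  first <- sample(names(config$first_base_weights), sum(pir), replace = TRUE,
                  prob = config$first_base_weights)
  rest <- random_dna_set(lens[pir] - 1L)
  pseq <- paste0(first, rest)
  if (config$ping_pong_10A) {
    hit <- runif(sum(pir)) < 0.7
    if (any(hit)) {
      tmp <- pseq[hit]
      substr(tmp, 10, 10) <- "A"
      pseq[hit] <- tmp
    }
  }
  seqs[pir] <- pseq

  genome <- strsplit(random_dna(config$genome_length), "")[[1]]
  embed <- ifelse(strands == "+", seqs, rc(seqs))
  for (i in seq_len(n)) {
    genome[(starts[i] + 1L):(starts[i] + lens[i])] <-
      strsplit(embed[i], "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(genome) <- "chr1"

  ids <- sprintf("%s_%04d", sub("piRNA_locus", "piL", classes),
                 stats::ave(seq_len(n), classes, FUN = seq_along))
  loci <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(start = starts + 1L, width = lens),
                                 strand = strands,
                                 locus_id = ids, class = classes, sequence = seqs)
  GenomeInfoDb::seqlengths(loci) <- config$genome_length
  list(genome = genome, loci = loci)
}

#' Assign baseline abundances and planted expression effects
#'
#' Draws log-normal baseline abundances for every piRNA locus and plants
#' expression effects on a `de_fraction` of them: each affected locus is
#' assigned to one consecutive-group comparison and its mean abundance is
#' shifted by `2^log2fc` from the comparison's second group onward (a
#' sustained developmental shift), so the other comparison stays null.
#'
#' @param config a [sim_config()].
#' @param loci the `loci` GRanges from [simulate_genome()].
#' @return the truth table: a data.frame with one row per piRNA locus
#'   (identifier, interval, sequence, per-group true mean abundance, true
#'   log2 fold change per comparison, DE flag and affected comparison).
#' @export
assign_effects <- function(config, loci) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  p <- loci[loci$class == "piRNA_locus"]
  n <- length(p)
  G <- length(config$groups)
  base <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  means <- matrix(base, n, G, dimnames = list(NULL, config$groups))

  n_de <- floor(n * config$de_fraction)
  de_idx <- sort(sample.int(n, n_de))
  comp_names <- paste(config$groups[-G], "vs", config$groups[-1])
  comp_of <- integer(n)
  lfc <- numeric(n)
  if (n_de > 0) {
    comp_of[de_idx] <- sample(seq_len(G - 1L), n_de, replace = TRUE)
    mag <- runif(n_de, config$planted_log2fc_range[1], config$planted_log2fc_range[2])
    lfc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    for (k in seq_along(de_idx)) {
      i <- de_idx[k]
      shift_groups <- (comp_of[i] + 1L):G
      means[i, shift_groups] <- means[i, shift_groups] * 2^lfc[i]
    }
  }

  truth <- data.frame(pirna_id = pirna_id(p$sequence),
                      locus_id = p$locus_id,
                      chrom = as.character(GenomeInfoDb::seqnames(p)),
                      start = GenomicRanges::start(p) - 1L,
                      end = GenomicRanges::end(p),
                      strand = as.character(GenomicRanges::strand(p)),
                      sequence = p$sequence,
                      length = nchar(p$sequence),
                      de = comp_of > 0L,
                      de_comparison = ifelse(comp_of > 0L, comp_names[pmax(comp_of, 1L)], ""),
                      stringsAsFactors = FALSE)
  for (g in config$groups) truth[[paste0("mean_", g)]] <- means[, g]
  for (k in seq_len(G - 1L)) {
    truth[[paste0("log2fc_", gsub(" ", "_", comp_names[k]))]] <-
      log2(means[, k + 1L] / means[, k])
  }
  truth
}

#' Generate grouped replicate FASTQ libraries and the true count matrix
#'
#' Per-replicate piRNA counts are negative-binomial
#' (`variance = mu + nb_dispersion * mu^2`) around group means scaled so a
#' library's expected size is `mean_depth`; reads are exact locus copies
#' unless `seq_error_rate > 0`. Contaminating reads are emitted from the
#' annotated ncRNA loci (as a small catalog of stereotyped degradation
#' fragments, 20-35 nt) and from miRNA loci (full mature sequences), at the
#' configured library fractions. Quality strings are constant Phred+33 `I`.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [assign_effects()].
#' @param loci the `loci` GRanges from [simulate_genome()].
#' @param outdir directory for the FASTQ files (created if needed).
#' @return list with `files` (named per replicate), `manifest` (data.frame
#'   replicate/group/file), `counts` (true piRNA-locus count matrix, loci x
#'   replicates, before contamination), and `lib_sizes` (total reads per
#'   replicate).
#' @export
generate_reads <- function(config, truth, loci, outdir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  reps <- as.vector(t(outer(config$groups, seq_len(config$n_replicates),
                            function(g, r) paste0(g, "_r", r))))
  rep_group <- rep(config$groups, each = config$n_replicates)
  n_loci <- nrow(truth)
  size <- 1 / config$nb_dispersion
  frac_pirna <- 1 - sum(config$contamination)

  # contaminant sources, fixed across replicates
  ncl <- loci[loci$class %in% c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")]
  frag_catalog <- character(0)
  frag_weight <- numeric(0)
  if (length(ncl) > 0) {
    for (i in seq_along(ncl)) {
      sq <- ncl$sequence[i]
      nfrag <- 8L
      maxlen <- nchar(sq)
      fl <- pmin(sample(20:35, nfrag, replace = TRUE), maxlen)
      fs <- vapply(fl, function(l) sample.int(maxlen - l + 1L, 1L), integer(1))
      frag_catalog <- c(frag_catalog, substring(sq, fs, fs + fl - 1L))
      frag_weight <- c(frag_weight, rlnorm(nfrag, 0, 1))
    }
  }
  mil <- loci[loci$class == "miRNA"]
  mir_weight <- if (length(mil)) rlnorm(length(mil), 0, 1) else numeric(0)

  counts <- matrix(0L, n_loci, length(reps),
                   dimnames = list(truth$pirna_id, reps))
  files <- character(length(reps)); names(files) <- reps
  lib_sizes <- integer(length(reps)); names(lib_sizes) <- reps

  for (j in seq_along(reps)) {
    g <- rep_group[j]
    mu_rel <- truth[[paste0("mean_", g)]]
    scale <- if (sum(mu_rel) > 0 && config$mean_depth > 0)
      config$mean_depth * frac_pirna / sum(mu_rel) else 0
    cj <- as.integer(rnbinom(n_loci, mu = mu_rel * scale, size = size))
    counts[, j] <- cj

    reads <- rep(truth$sequence, cj)
    if (length(frag_catalog) && config$mean_depth > 0) {
      n_nc <- round(config$mean_depth * config$contamination[["ncrna"]])
      pick <- sample.int(length(frag_catalog), n_nc, replace = TRUE,
                         prob = frag_weight)
      reads <- c(reads, frag_catalog[pick])
    }
    if (length(mil) && config$mean_depth > 0) {
      n_mi <- round(config$mean_depth * config$contamination[["mirna"]])
      pick <- sample.int(length(mil), n_mi, replace = TRUE, prob = mir_weight)
      reads <- c(reads, mil$sequence[pick])
    }
    if (config$seq_error_rate > 0 && length(reads)) {
      reads <- mutate_reads(reads, config$seq_error_rate)
    }
    f <- file.path(outdir, sprintf("reads_%s.fastq", reps[j]))
    write_fastq(reads, f, prefix = reps[j])
    files[j] <- f
    lib_sizes[j] <- length(reads)
  }

  manifest <- data.frame(replicate = reps, group = rep_group,
                         file = unname(files), stringsAsFactors = FALSE)
  list(files = files, manifest = manifest, counts = counts,
       lib_sizes = lib_sizes)
}

# uniform substitution errors, vectorized over the base pool
mutate_reads <- function(reads, rate) {
  chars <- strsplit(reads, "")
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    repl <- vapply(flat[hit],
                   function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    flat[hit] <- repl
  }
  vapply(split(flat, rep(seq_along(lens), lens)), paste, character(1),
         collapse = "")
}

#' Generate target transcripts, planted binding sites and a gene-term map
#'
#' Every DE-flagged piRNA receives `Poisson(target_site_rate)` planted
#' binding sites (the first DE piRNA gets three times the rate, acting as a
#' designed hub), each embedded in a distinct random transcript as the
#' reverse complement of the piRNA with `site_edits` engineered core
#' mismatches. The gene-term map assigns each transcript one GO-style term
#' and pathway terms; the designed enriched pathway term is carried by
#' `enriched_term_frac["target"]` of targeted transcripts versus
#' `enriched_term_frac["background"]` of the rest.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [assign_effects()] (needs `sequence`, `de`).
#' @return list with `transcripts` (named DNAStringSet), `sites`
#'   (data.frame: pirna_id, transcript_id, start, end, edits, energy_class),
#'   `gene2term` (data.frame gene/term), and `terms` (data.frame
#'   term/label/namespace).
#' @export
generate_transcripts_and_sites <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)

  tx_len <- sample(config$transcript_length_range[1]:config$transcript_length_range[2],
                   config$n_transcripts, replace = TRUE)
  tx_ids <- sprintf("gene_%04d", seq_len(config$n_transcripts))
  tx <- random_dna_set(tx_len)
  names(tx) <- tx_ids

  de_rows <- which(truth$de)
  sites <- list()
  used <- setNames(vector("list", config$n_transcripts), tx_ids)
  for (k in seq_along(de_rows)) {
    i <- de_rows[k]
    rate <- config$target_site_rate * if (k == 1L) 3 else 1
    n_sites <- rpois(1L, rate)
    if (n_sites < 1L) next
    n_sites <- min(n_sites, config$n_transcripts)
    which_tx <- sample.int(config$n_transcripts, n_sites)
    pir_seq <- truth$sequence[i]
    site_seq <- rc(pir_seq)
    L <- nchar(site_seq)
    if (config$site_edits > 0) {
      # engineered mismatches at core positions (piRNA positions 2-13);
      # piRNA position p pairs site position L - p (0-based)
      core_pos <- sample(2:13, config$site_edits)
      for (p in core_pos) {
        j <- L - p + 1L                       # 1-based site index
        old <- substr(site_seq, j, j)
        pir_base <- substr(pir_seq, p, p)
        bad <- setdiff(DNA_BASES, c(old, switch(pir_base, G = "T", T = "G", character(0))))
        substr(site_seq, j, j) <- sample(bad, 1L)
      }
    }
    for (t in which_tx) {
      if (L > tx_len[t])
        stop(sprintf("planted site (%d nt) longer than transcript %s (%d nt)",
                     L, tx_ids[t], tx_len[t]), call. = FALSE)
      # place without overlapping previously planted sites in this transcript
      pos <- NA_integer_
      for (attempt in seq_len(50L)) {
        cand <- sample.int(tx_len[t] - L + 1L, 1L) - 1L   # 0-based start
        ivs <- used[[t]]
        if (is.null(ivs) || !any(cand < ivs[, 2] & cand + L > ivs[, 1])) {
          pos <- cand; break
        }
      }
      if (is.na(pos)) next
      used[[t]] <- rbind(used[[t]], c(pos, pos + L))
      substr(tx[t], pos + 1L, pos + L) <- site_seq
      sites[[length(sites) + 1L]] <- data.frame(
        pirna_id = truth$pirna_id[i], transcript_id = tx_ids[t],
        start = pos, end = pos + L, edits = config$site_edits,
        energy_class = if (config$site_edits == 0 && L >= 20) "strong" else "weak",
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(pirna_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0), edits = integer(0),
               energy_class = character(0), stringsAsFactors = FALSE)

  # term universe: GO-style terms plus pathway terms named after the
  # developmental / immune / energy-metabolism pathways of interest
  go_terms <- data.frame(term = sprintf("GO:%07d", 1:15),
                         label = sprintf("biological feature %02d", 1:15),
                         namespace = rep(c("BP", "MF", "CC"), 5),
                         stringsAsFactors = FALSE)
  pw_labels <- c("Wnt signaling pathway", "Hippo signaling pathway",
                 "Notch signaling pathway", "mTOR signaling pathway",
                 "Jak/STAT signaling pathway", "endocytosis",
                 "ubiquitin-mediated proteolysis", "sulfur metabolism",
                 "nitrogen metabolism", "oxidative phosphorylation")
  pw_terms <- data.frame(term = sprintf("PW%04d", seq_along(pw_labels)),
                         label = pw_labels, namespace = "pathway",
                         stringsAsFactors = FALSE)
  terms <- rbind(go_terms, pw_terms)

  targeted <- tx_ids %in% sites$transcript_id
  enr_term <- pw_terms$term[1]                      # designed enriched term
  other_pw <- pw_terms$term[-1]
  g2t <- list()
  p_enr <- ifelse(targeted, config$enriched_term_frac[["target"]],
                  config$enriched_term_frac[["background"]])
  has_enr <- runif(config$n_transcripts) < p_enr
  for (t in seq_len(config$n_transcripts)) {
    tms <- sample(go_terms$term, 1L)
    tms <- c(tms, sample(other_pw, 1L))
    if (has_enr[t]) tms <- c(tms, enr_term)
    g2t[[t]] <- data.frame(gene = tx_ids[t], term = tms,
                           stringsAsFactors = FALSE)
  }
  gene2term <- do.call(rbind, g2t)

  list(transcripts = Biostrings::DNAStringSet(tx), sites = sites,
       gene2term = gene2term, terms = terms, enriched_term = enr_term)
}

#' Generate and write a complete synthetic piRNA study
#'
#' Orchestrates [simulate_genome()], [assign_effects()],
#' [generate_reads()] and [generate_transcripts_and_sites()] under one
#' seed, writes every artifact to `outdir` (genome FASTA, GFF3 annotations,
#' per-replicate FASTQ, miRNA and transcript FASTA, truth/count/term
#' tables as TSV, a read manifest, and a YAML echo of the configuration),
#' and returns all pieces in memory.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return an object of class `pirna_sim`: list with `config`, `genome`,
#'   `loci`, `truth`, `reads` (see [generate_reads()]), `transcripts`,
#'   `sites`, `gene2term`, `terms`, `enriched_term`, and `paths`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_study(sim_config(seed = 7, n_pirna_loci = 40,
#'                                  mean_depth = 2000), tempfile("sim"))
#' head(sim$truth$sequence)
#' }
simulate_study <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  gen <- simulate_genome(config)
  truth <- assign_effects(config, gen$loci)
  reads <- generate_reads(config, truth, gen$loci, file.path(outdir, "reads"))
  tx <- generate_transcripts_and_sites(config, truth)

  paths <- list(genome = file.path(outdir, "genome.fa"),
                annotations = file.path(outdir, "annotations.gff3"),
                mirna = file.path(outdir, "mirna.fa"),
                transcripts = file.path(outdir, "transcripts.fa"),
                truth = file.path(outdir, "truth_pirna.tsv"),
                sites = file.path(outdir, "truth_sites.tsv"),
                counts = file.path(outdir, "counts_true.tsv"),
                gene2term = file.path(outdir, "gene2term.tsv"),
                terms = file.path(outdir, "terms.tsv"),
                manifest = file.path(outdir, "manifest.tsv"),
                config = file.path(outdir, "config.yaml"))

  Biostrings::writeXStringSet(gen$genome, paths$genome)
  gr <- gen$loci
  gr$type <- gr$class
  gr$ID <- gr$locus_id
  rtracklayer::export(gr, paths$annotations, format = "gff3")
  mil <- gen$loci[gen$loci$class == "miRNA"]
  mi <- Biostrings::DNAStringSet(mil$sequence)
  names(mi) <- mil$locus_id
  Biostrings::writeXStringSet(mi, paths$mirna)
  Biostrings::writeXStringSet(tx$transcripts, paths$transcripts)
  write_tsv(truth, paths$truth)
  write_tsv(tx$sites, paths$sites)
  write_tsv(data.frame(pirna_id = rownames(reads$counts), reads$counts,
                       check.names = FALSE), paths$counts)
  write_tsv(tx$gene2term, paths$gene2term)
  write_tsv(tx$terms, paths$terms)
  manifest_rel <- reads$manifest
  # keep the written manifest portable (and byte-identical across output
  # directories): paths relative to the study directory
  manifest_rel$file <- file.path("reads", basename(manifest_rel$file))
  write_tsv(manifest_rel, paths$manifest)
  cfg_plain <- unclass(config)
  cfg_plain <- lapply(cfg_plain, function(x) if (is.numeric(x)) unname(x) else x)
  yaml::write_yaml(cfg_plain, paths$config)

  structure(list(config = config, genome = gen$genome, loci = gen$loci,
                 truth = truth, reads = reads,
                 transcripts = tx$transcripts, sites = tx$sites,
                 gene2term = tx$gene2term, terms = tx$terms,
                 enriched_term = tx$enriched_term, paths = paths),
            class = "pirna_sim")
}

#' @export
print.pirna_sim <- function(x, ...) {
  cat(sprintf("Synthetic piRNA study: %d piRNA loci, %d DE, %d replicates x %d groups\n",
              nrow(x$truth), sum(x$truth$de), x$config$n_replicates,
              length(x$config$groups)))
  cat(sprintf("  %d planted target sites in %d transcripts; files under %s\n",
              nrow(x$sites), length(x$transcripts),
              dirname(x$paths$genome)))
  invisible(x)
}
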