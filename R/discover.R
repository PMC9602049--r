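NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")
KNOWN_FEATURE_CLASSES <- c(NCRNA_CLASSES, "miRNA", "piRNA_locus", "mRNA")

#' Collapse replicate FASTQ files into unique sequence tags
#'
#' Reads every replicate library and collapses identical read sequences
#' into one tag with exact per-replicate occurrence counts ("clean tags").
#' The output is sorted by sequence, so input record order is irrelevant.
#'
#' @param files FASTQ paths named by replicate, or a manifest data.frame
#'   with columns `replicate`, `group`, `file`.
#' @return data.frame with columns `sequence`, `length`, and one count
#'   column per replicate; attributes `replicates` and (when a manifest is
#'   given) `groups` (named character: replicate -> group label).
#' @export
collapse_reads <- function(files) {
  if (is.data.frame(files)) {
    manifest <- files
    stopifnot(all(c("replicate", "file") %in% names(manifest)))
    paths <- setNames(manifest$file, manifest$replicate)
    groups <- if ("group" %in% names(manifest))
      setNames(manifest$group, manifest$replicate) else NULL
  } else {
    paths <- files
    if (is.null(names(paths))) names(paths) <- basename(paths)
    groups <- NULL
  }
  if (anyDuplicated(names(paths)))
    stop("replicate labels must be unique", call. = FALSE)

  per_rep <- lapply(names(paths), function(r) {
    seqs <- read_fastq_sequences(paths[[r]])
    if (!length(seqs))
      return(data.table::data.table(sequence = character(0), N = integer(0),
                                    replicate = character(0)))
    dt <- data.table::data.table(sequence = seqs)[, .N, by = "sequence"]
    dt$replicate <- r
    dt
  })
  all <- data.table::rbindlist(per_rep)
  if (nrow(all) == 0L) {
    tags <- data.frame(sequence = character(0), length = integer(0))
    for (r in names(paths)) tags[[r]] <- integer(0)
  } else {
    wide <- data.table::dcast(all, sequence ~ replicate, value.var = "N",
                              fill = 0L)
    missing_rep <- setdiff(names(paths), names(wide))
    for (r in missing_rep) wide[[r]] <- 0L
    data.table::setcolorder(wide, c("sequence", names(paths)))
    data.table::setorder(wide, sequence)
    tags <- as.data.frame(wide)
    tags <- data.frame(sequence = tags$sequence,
                       length = nchar(tags$sequence),
                       tags[names(paths)], check.names = FALSE,
                       stringsAsFactors = FALSE)
  }
  attr(tags, "replicates") <- names(paths)
  if (!is.null(groups)) attr(tags, "groups") <- groups
  tags
}

tag_count_matrix <- function(tags) {
  reps <- attr(tags, "replicates")
  as.matrix(tags[, reps, drop = FALSE])
}

#' Map tags to a reference genome
#'
#' Exact-match, index-based mapping of every tag to both strands of the
#' genome (suitable for desk-scale references). With
#' `max_mismatches > 0` a slower scan reports all hits at each tag's best
#' mismatch stratum. Every hit is verified by direct sequence comparison
#' (reverse complement on the minus strand).
#'
#' @param tags tag table from [collapse_reads()] (needs a `sequence`
#'   column).
#' @param genome a named [Biostrings::DNAStringSet] or FASTA path.
#' @param max_mismatches maximum mismatches allowed (default 0).
#' @return data.frame of alignment hits: `sequence`, `chrom`, `start`
#'   (0-based), `end` (half-open), `strand`, `mismatches`.
#' @export
map_tags <- function(tags, genome, max_mismatches = 0L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- unique(tags$sequence)
  if (!length(seqs))
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))

  hits <- if (max_mismatches == 0L) {
    map_exact(seqs, genome)
  } else {
    map_mismatch(seqs, genome, max_mismatches)
  }
  # best mismatch stratum per tag
  if (nrow(hits) && max(hits$mismatches) > 0L) {
    best <- tapply(hits$mismatches, hits$sequence, min)
    hits <- hits[hits$mismatches == best[hits$sequence], , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits[order(hits$sequence, hits$chrom, hits$start, hits$strand), ,
       drop = FALSE]
}

map_exact <- function(seqs, genome) {
  lens <- nchar(seqs)
  w <- min(lens)
  fwd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(seqs, 1L, w)))
  rcs <- rc(seqs)
  rev <- Biostrings::PDict(Biostrings::DNAStringSet(substr(rcs, 1L, w)))
  out <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    chrom_str <- as.character(subj)
    for (str in c("+", "-")) {
      pd <- if (str == "+") fwd else rev
      full <- if (str == "+") seqs else rcs
      m <- Biostrings::matchPDict(pd, subj)
      starts <- Biostrings::startIndex(m)
      for (i in seq_along(seqs)) {
        ss <- starts[[i]]
        if (is.null(ss) || !length(ss)) next
        ok <- ss + lens[i] - 1L <= nchar(chrom_str) &
          substring(chrom_str, ss, ss + lens[i] - 1L) == full[i]
        ss <- ss[ok]
        if (!length(ss)) next
        out[[length(out) + 1L]] <- data.frame(
          sequence = seqs[i], chrom = chrom, start = ss - 1L,
          end = ss - 1L + lens[i], strand = str, mismatches = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0))
}

map_mismatch <- function(seqs, genome, max_mismatches) {
  out <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (i in seq_along(seqs)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") seqs[i] else rc(seqs[i])
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatches)
        if (!length(m)) next
        mm <- Biostrings::neditAt(Biostrings::DNAString(pat), subj,
                                  at = Biostrings::start(m))
        out[[length(out) + 1L]] <- data.frame(
          sequence = seqs[i], chrom = chrom,
          start = Biostrings::start(m) - 1L, end = Biostrings::end(m),
          strand = str, mismatches = as.integer(mm),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0))
}

#' Ingest externally produced alignments (BAM)
#'
#' Accepts a coordinate-style alignment file, re-verifies every record
#' against the genome by direct sequence comparison, and returns hits in
#' the same shape as [map_tags()]. Gapped alignments are skipped.
#'
#' @param bam path to a BAM file (requires the Rsamtools package).
#' @param genome named [Biostrings::DNAStringSet] or FASTA path.
#' @return hit data.frame as in [map_tags()].
#' @export
ingest_alignments <- function(bam, genome) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("ingest_alignments() requires the Rsamtools package", call. = FALSE)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("seq", "rname", "pos", "strand", "cigar")))[[1]]
  keep <- !is.na(b$pos) & grepl("^[0-9]+M$", b$cigar)
  rn <- as.character(b$rname)[keep]
  unknown <- setdiff(unique(rn), names(genome))
  if (length(unknown))
    stop(sprintf("reference mismatch: chromosome(s) %s not in genome FASTA",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  seqs <- as.character(b$seq)[keep]
  pos <- b$pos[keep]
  strand <- as.character(b$strand)[keep]
  # BAM stores the read in reference orientation; recover the tag sequence
  tag_seq <- ifelse(strand == "-", rc(seqs), seqs)
  lens <- nchar(seqs)
  ref <- vapply(seq_along(seqs), function(i)
    substring(as.character(genome[[rn[i]]]), pos[i], pos[i] + lens[i] - 1L),
    character(1))
  mism <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)), seqs, ref)
  data.frame(sequence = tag_seq, chrom = rn, start = pos - 1L,
             end = pos - 1L + lens, strand = strand,
             mismatches = as.integer(mism), stringsAsFactors = FALSE)
}

as_annotation_granges <- function(annotations) {
  if (is.character(annotations))
    annotations <- rtracklayer::import(annotations)
  stopifnot(methods::is(annotations, "GRanges"))
  cls <- annotations$class %||% as.character(annotations$type)
  annotations$class <- cls
  annotations
}

#' Subtract tags overlapping annotated ncRNA features
#'
#' Removes a tag when any of its alignment hits overlaps a feature of a
#' listed contaminant class by at least `min_overlap_frac` of the tag
#' length, on either strand. A removal ledger records which class claimed
#' each tag (ties broken by `classes` order on maximal overlap).
#'
#' @param tags tag table ([collapse_reads()]).
#' @param hits alignment hits ([map_tags()]).
#' @param annotations a GRanges (or GFF3/BED path) whose `class` (or
#'   `type`) column names the feature class.
#' @param classes contaminant classes to subtract.
#' @param min_overlap_frac minimum overlap as a fraction of tag length.
#' @return list with `tags`, `hits` (both filtered) and `ledger`
#'   (data.frame `sequence`, `class`, `stage`).
#' @export
subtract_ncrna <- function(tags, hits, annotations,
                           classes = NCRNA_CLASSES,
                           min_overlap_frac = 0.5) {
  bad <- setdiff(classes, KNOWN_FEATURE_CLASSES)
  if (length(bad))
    stop(sprintf("unknown feature class in filter list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  annotations <- as_annotation_granges(annotations)
  feats <- annotations[annotations$class %in% classes]

  removed <- character(0)
  led_class <- character(0)
  if (length(feats) && nrow(hits)) {
    hgr <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$start + 1L, hits$end),
                                  strand = "*")
    ov <- GenomicRanges::findOverlaps(hgr, feats, ignore.strand = TRUE)
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(GenomicRanges::pintersect(hgr[qh], feats[sh],
                                                          ignore.strand = TRUE))
      taglen <- hits$end[qh] - hits$start[qh]
      keep_ov <- w >= min_overlap_frac * taglen
      if (any(keep_ov)) {
        df <- data.frame(sequence = hits$sequence[qh[keep_ov]],
                         class = feats$class[sh[keep_ov]],
                         overlap = w[keep_ov], stringsAsFactors = FALSE)
        # per tag: class of maximal overlap, ties by classes order
        df$class_rank <- match(df$class, classes)
        df <- df[order(df$sequence, -df$overlap, df$class_rank), ]
        df <- df[!duplicated(df$sequence), ]
        removed <- df$sequence
        led_class <- df$class
      }
    }
  }
  keep <- !(tags$sequence %in% removed)
  list(tags = tags[keep, , drop = FALSE] |> preserve_tag_attrs(tags),
       hits = hits[!(hits$sequence %in% removed), , drop = FALSE],
       ledger = data.frame(sequence = removed, class = led_class,
                           stage = rep("ncRNA", length(removed)),
                           stringsAsFactors = FALSE))
}

preserve_tag_attrs <- function(x, template) {
  attr(x, "replicates") <- attr(template, "replicates")
  attr(x, "groups") <- attr(template, "groups")
  rownames(x) <- NULL
  x
}

#' Subtract known miRNA tags
#'
#' Removes tags that exactly match a known miRNA sequence (T/U
#' normalized), and/or tags whose hits overlap annotated miRNA loci by the
#' same interval rule as [subtract_ncrna()].
#'
#' @param tags tag table.
#' @param hits alignment hits (needed only when `mirna_loci` is given).
#' @param mirna_seqs known miRNA sequences (character,
#'   [Biostrings::DNAStringSet], or FASTA path), or `NULL`.
#' @param mirna_loci GRanges of miRNA loci (or `NULL`).
#' @param min_overlap_frac overlap fraction for the locus rule.
#' @return list with `tags`, `hits`, `ledger` (stage `"miRNA"`).
#' @export
subtract_mirna <- function(tags, hits = NULL, mirna_seqs = NULL,
                           mirna_loci = NULL, min_overlap_frac = 0.5) {
  if (is.null(mirna_seqs) && is.null(mirna_loci))
    stop("provide miRNA sequences and/or miRNA loci", call. = FALSE)
  removed <- character(0)
  if (!is.null(mirna_seqs)) {
    if (is.character(mirna_seqs) && length(mirna_seqs) == 1L &&
        file.exists(mirna_seqs))
      mirna_seqs <- Biostrings::readDNAStringSet(mirna_seqs)
    mirna_seqs <- chartr("U", "T", toupper(as.character(mirna_seqs)))
    removed <- tags$sequence[tags$sequence %in% mirna_seqs]
  }
  if (!is.null(mirna_loci) && !is.null(hits) && nrow(hits)) {
    mirna_loci <- as_annotation_granges(mirna_loci)
    mirna_loci$class <- "miRNA"
    sub <- subtract_ncrna(tags, hits, mirna_loci, classes = "miRNA",
                          min_overlap_frac = min_overlap_frac)
    removed <- union(removed, sub$ledger$sequence)
  }
  keep <- !(tags$sequence %in% removed)
  list(tags = preserve_tag_attrs(tags[keep, , drop = FALSE], tags),
       hits = if (is.null(hits)) NULL else
         hits[!(hits$sequence %in% removed), , drop = FALSE],
       ledger = data.frame(sequence = removed,
                           class = rep("miRNA", length(removed)),
                           stage = rep("miRNA", length(removed)),
                           stringsAsFactors = FALSE))
}

#' Call candidate piRNAs from subtracted tags
#'
#' Retains tags whose length lies in `length_range` (inclusive on both
#' ends) and whose best-stratum alignment occurs at exactly one genomic
#' position across both strands. Candidates are sorted by descending
#' pooled count, then sequence; identifiers derive from the tag sequence
#' via [pirna_id()].
#'
#' @param tags subtracted tag table.
#' @param hits alignment hits for those tags.
#' @param length_range inclusive length window (default 24-33 nt).
#' @return data.frame of candidates: `pirna_id`, `sequence`, `length`,
#'   `first_base` (T reported as U), locus columns (`chrom`, `start`,
#'   `end`, `strand`), and per-replicate counts. Attributes `replicates` /
#'   `groups` carried over from `tags`.
#' @export
call_pirnas <- function(tags, hits, length_range = c(24L, 33L)) {
  nhit <- table(hits$sequence)
  uniq <- names(nhit)[nhit == 1L]
  keep <- tags$length >= length_range[1] & tags$length <= length_range[2] &
    tags$sequence %in% uniq
  cand <- tags[keep, , drop = FALSE]
  h <- hits[match(cand$sequence, hits$sequence), , drop = FALSE]
  reps <- attr(tags, "replicates")
  pooled <- rowSums(as.matrix(cand[, reps, drop = FALSE]))
  out <- data.frame(pirna_id = pirna_id(cand$sequence),
                    sequence = cand$sequence,
                    length = cand$length,
                    first_base = chartr("T", "U", substr(cand$sequence, 1L, 1L)),
                    chrom = h$chrom, start = h$start, end = h$end,
                    strand = h$strand,
                    cand[, reps, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-pooled, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  attr(out, "groups") <- attr(tags, "groups")
  out
}

group_pooled_counts <- function(candidates, groups = NULL) {
  reps <- attr(candidates, "replicates")
  groups <- groups %||% attr(candidates, "groups")
  if (is.null(groups))
    stop("no replicate->group mapping available", call. = FALSE)
  cm <- as.matrix(candidates[, reps, drop = FALSE])
  glab <- unique(unname(groups[reps]))
  pooled <- sapply(glab, function(g)
    rowSums(cm[, reps[groups[reps] == g], drop = FALSE]))
  if (is.null(dim(pooled))) pooled <- matrix(pooled, nrow = nrow(cm),
                                             dimnames = list(NULL, glab))
  pooled
}

#' First-base composition of a group's piRNAs
#'
#' Fractions of A/C/G/U at the 5' position among distinct candidate
#' sequences present in a group (pooled group count >= `min_count`);
#' optionally weighted by read count.
#'
#' @param candidates catalog from [call_pirnas()].
#' @param group group label.
#' @param groups optional replicate -> group mapping (defaults to the
#'   catalog attribute).
#' @param weighted if `TRUE`, weight each candidate by its pooled group
#'   count instead of counting sequences once.
#' @param min_count presence threshold on the pooled group count.
#' @return named numeric over `A`, `C`, `G`, `U`; sums to 1.
#' @export
first_base_bias <- function(candidates, group, groups = NULL,
                            weighted = FALSE, min_count = 1L) {
  pooled <- group_pooled_counts(candidates, groups)
  if (!group %in% colnames(pooled))
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  present <- pooled[, group] >= min_count
  if (!any(present))
    stop(sprintf("group '%s' has no present candidates", group),
         call. = FALSE)
  fb <- candidates$first_base[present]
  w <- if (weighted) pooled[present, group] else rep(1, sum(present))
  tot <- tapply(w, factor(fb, levels = c("A", "C", "G", "U")), sum,
                default = 0)
  setNames(as.numeric(tot) / sum(tot), c("A", "C", "G", "U"))
}

#' Partition candidates into shared and group-unique sets
#'
#' Presence in a group means pooled group count >= `min_count`. Every
#' detected candidate falls in exactly one intersection cell (Venn-style),
#' so the partition is exhaustive and disjoint.
#'
#' @inheritParams first_base_bias
#' @param min_count presence threshold.
#' @return list with `cells` (named integer: cell key like `"Am4&Am5"` ->
#'   size), `shared` (ids present in all groups), `unique_per_group`
#'   (list), and `membership` (logical presence matrix).
#' @export
group_set_partition <- function(candidates, groups = NULL, min_count = 1L) {
  pooled <- group_pooled_counts(candidates, groups)
  if (ncol(pooled) < 2L) stop("need at least two groups", call. = FALSE)
  pres <- pooled >= min_count
  rownames(pres) <- candidates$pirna_id
  key <- apply(pres, 1L, function(x)
    if (any(x)) paste(colnames(pres)[x], collapse = "&") else "none")
  glab <- colnames(pres)
  all_key <- paste(glab, collapse = "&")
  cells <- table(key)
  list(cells = setNames(as.integer(cells), names(cells)),
       shared = candidates$pirna_id[key == all_key],
       unique_per_group = setNames(
         lapply(glab, function(g) candidates$pirna_id[key == g]), glab),
       membership = pres)
}

#' Length histogram of a group's piRNAs
#'
#' @inheritParams first_base_bias
#' @param length_range histogram support (keys), default 24-33.
#' @return named integer vector over `length_range`; sums to the number of
#'   present candidates.
#' @export
length_distribution <- function(candidates, group, groups = NULL,
                                min_count = 1L, length_range = c(24L, 33L)) {
  pooled <- group_pooled_counts(candidates, groups)
  if (!group %in% colnames(pooled))
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  present <- pooled[, group] >= min_count
  lv <- length_range[1]:length_range[2]
  tab <- table(factor(candidates$length[present], levels = lv))
  setNames(as.integer(tab), lv)
}
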