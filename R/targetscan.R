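#' Complementarity scoring parameters
#'
#' Penalty constants for the plant-miRNA-style target scoring scheme:
#' mismatches cost 1, G:U wobbles 0.5, gaps 1, all doubled inside the core
#' region (piRNA positions 2-13 from the 5' end); alignments with total
#' penalty above `max_score` are discarded. `energy_gate` is the duplex
#' free-energy threshold applied downstream (strict less-than).
#'
#' @param mismatch_penalty,gu_penalty,gap_penalty non-negative penalties.
#' @param core_region inclusive 1-based piRNA position window whose
#'   penalties are doubled.
#' @param max_score maximum total penalty for a reported site.
#' @param energy_gate free-energy threshold in kcal/mol (strict `<`).
#' @param max_gaps maximum gaps per duplex (band width of the scan).
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(mismatch_penalty = 1.0, gu_penalty = 0.5,
                           gap_penalty = 1.0, core_region = c(2L, 13L),
                           max_score = 4.0, energy_gate = -15.0,
                           max_gaps = 2L) {
  stopifnot(mismatch_penalty >= 0, gu_penalty >= 0, gap_penalty >= 0,
            length(core_region) == 2L, core_region[1] >= 1L,
            core_region[1] <= core_region[2], max_gaps >= 0L)
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty, gap_penalty = gap_penalty,
                 core_region = as.integer(core_region),
                 max_score = max_score, energy_gate = energy_gate,
                 max_gaps = as.integer(max_gaps)),
            class = "scoring_params")
}

# Canonical Watson-Crick stack free energies (kcal/mol, 37 C), keyed as
# "XY/WZ": XY read 5'->3' on the piRNA strand, WZ the bases paired under
# them (3'->5' on the target), X pairing W and Y pairing Z.
WC_STACK_SEED <- c("AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
                   "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
                   "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26,
                   "GC/CG" = -3.42)

#' Nearest-neighbor duplex energy parameters
#'
#' A simplified, versioned nearest-neighbor table for RNA/RNA duplexes at
#' 37 C: the 16 Watson-Crick dinucleotide stacks carry standard values,
#' stacks involving one G:U wobble are set to -1.3 kcal/mol and stacks of
#' two wobbles to -0.5 kcal/mol; a fixed duplex-initiation term and a
#' fixed penalty per internal unpaired position (mismatch or gap) replace
#' full loop thermodynamics.
#'
#' @param initiation duplex initiation free energy (kcal/mol).
#' @param defect_penalty free-energy penalty per internal mismatch/gap
#'   position (kcal/mol).
#' @param gu_single,gu_double stack values for one / two wobble pairs.
#' @return object of class `nn_params` with elements `stack` (named
#'   numeric over all 36 ordered stacks), `initiation`, `defect_penalty`,
#'   `version`.
#' @export
nn_params <- function(initiation = 4.09, defect_penalty = 2.0,
                      gu_single = -1.3, gu_double = -0.5) {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  is_gu <- function(p) p %in% c("GU", "UG")
  keys <- character(0); vals <- numeric(0)
  for (p1 in pairs) for (p2 in pairs) {
    x <- substr(p1, 1, 1); w <- substr(p1, 2, 2)
    y <- substr(p2, 1, 1); z <- substr(p2, 2, 2)
    key <- paste0(x, y, "/", w, z)
    ngu <- is_gu(p1) + is_gu(p2)
    v <- if (ngu == 0L) {
      if (!is.na(WC_STACK_SEED[key])) unname(WC_STACK_SEED[key]) else {
        # read off the symmetric partner (other-strand orientation)
        sym <- paste0(z, w, "/", y, x)
        unname(WC_STACK_SEED[sym])
      }
    } else if (ngu == 1L) gu_single else gu_double
    keys <- c(keys, key); vals <- c(vals, v)
  }
  stopifnot(!anyNA(vals))
  structure(list(stack = setNames(vals, keys), initiation = initiation,
                 defect_penalty = defect_penalty,
                 version = "beepiR-nn-1.0"),
            class = "nn_params")
}

validate_nt <- function(x, what) {
  bad <- grepl("[^ACGTU]", toupper(x))
  if (any(bad))
    stop(sprintf("non-nucleotide characters in %s", what), call. = FALSE)
  chartr("U", "T", toupper(x))
}

#' Scan transcripts for piRNA binding sites
#'
#' Banded antisense alignment of one piRNA against every window of every
#' transcript (at most `max_gaps` gaps per duplex), emitting sites whose
#' total complementarity penalty is at most `params$max_score`.
#' Overlapping qualifying sites are collapsed to the best one (lowest
#' score, ties to the leftmost start). By default both orientations of
#' each transcript are scanned and recorded, so scanning a reverse
#' complement reproduces the same hits at mirrored coordinates.
#'
#' @param pirna one piRNA sequence (>= 18 nt; U and T interchangeable).
#' @param transcripts named character vector, [Biostrings::DNAStringSet],
#'   or FASTA path.
#' @param params a [scoring_params()].
#' @param nn a [nn_params()] used to attach duplex free energies.
#' @param orientations scan `"both"` orientations (default) or `"sense"`
#'   only.
#' @param id identifier recorded in the output (defaults to [pirna_id()]
#'   of the sequence).
#' @return data.frame of duplex hits: `pirna_id`, `transcript_id`,
#'   `start`/`end` (0-based half-open on the input transcript),
#'   `orientation`, `score`, `gaps`, `pairing` (`|` match, `:` G:U, `.`
#'   mismatch, `-` gap), `aln_pirna` (5'->3'), `aln_target` (3'->5'), and
#'   `delta_g` (kcal/mol).
#' @export
scan_targets <- function(pirna, transcripts, params = scoring_params(),
                         nn = nn_params(),
                         orientations = c("both", "sense"),
                         id = NULL) {
  orientations <- match.arg(orientations)
  p <- validate_nt(pirna, "piRNA")
  if (nchar(p) < 18L) stop("piRNA must be >= 18 nt", call. = FALSE)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts) && is.null(names(transcripts)))
    transcripts <- Biostrings::readDNAStringSet(transcripts)
  nms <- names(transcripts)             # as.character/toupper drop names
  tx <- toupper(as.character(transcripts))
  names(tx) <- nms
  if (!length(tx)) stop("transcripts must be non-empty", call. = FALSE)
  if (is.null(names(tx))) names(tx) <- paste0("tx", seq_along(tx))
  tx <- vapply(tx, validate_nt, character(1), what = "transcript")
  pid <- id %||% pirna_id(p)

  ors <- if (orientations == "both") c("sense", "rc") else "sense"
  out <- list()
  for (tid in names(tx)) {
    n <- nchar(tx[[tid]])
    for (orient in ors) {
      subj <- if (orient == "sense") tx[[tid]] else rc(tx[[tid]])
      d <- scan_anchors_cpp(p, subj, params$mismatch_penalty,
                            params$gu_penalty, params$gap_penalty,
                            params$core_region[1], params$core_region[2],
                            params$max_score, params$max_gaps)
      if (!nrow(d)) next
      d <- collapse_overlaps(d)
      if (orient == "rc") {
        s <- n - d$end
        d$end <- n - d$start
        d$start <- s
      }
      d <- data.frame(pirna_id = pid, transcript_id = tid,
                      d[, c("start", "end")], orientation = orient,
                      d[, c("score", "gaps", "pairing", "aln_pirna",
                            "aln_target")],
                      stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- d
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(pirna_id = character(0), transcript_id = character(0),
               start = integer(0), end = integer(0),
               orientation = character(0), score = numeric(0),
               gaps = integer(0), pairing = character(0),
               aln_pirna = character(0), aln_target = character(0),
               stringsAsFactors = FALSE)
  hits$delta_g <- if (nrow(hits))
    vapply(seq_len(nrow(hits)), function(i)
      duplex_energy(hits$pairing[i], hits$aln_pirna[i], hits$aln_target[i],
                    nn), numeric(1))
  else numeric(0)
  rownames(hits) <- NULL
  hits[order(hits$transcript_id, hits$start, hits$orientation), ,
       drop = FALSE] -> hits
  rownames(hits) <- NULL
  hits
}

# keep the best site among overlapping qualifying sites (lowest score,
# ties to the leftmost start); deterministic greedy sweep
collapse_overlaps <- function(d) {
  d <- d[order(d$score, d$start, d$end), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(d))) {
    if (!length(kept) ||
        !any(d$start[i] < d$end[kept] & d$end[i] > d$start[kept]))
      kept <- c(kept, i)
  }
  d[sort(kept), , drop = FALSE]
}

#' Scan a set of piRNAs against transcripts
#'
#' Convenience wrapper around [scan_targets()] for a named set of piRNA
#' sequences.
#'
#' @param pirnas named character vector of piRNA sequences (names used as
#'   identifiers).
#' @inheritParams scan_targets
#' @return row-bound hit data.frame (see [scan_targets()]).
#' @export
predict_targets <- function(pirnas, transcripts, params = scoring_params(),
                            nn = nn_params(),
                            orientations = c("both", "sense")) {
  orientations <- match.arg(orientations)
  stopifnot(!is.null(names(pirnas)))
  res <- lapply(names(pirnas), function(pid)
    scan_targets(pirnas[[pid]], transcripts, params, nn, orientations,
                 id = pid))
  do.call(rbind, res)
}

#' Nearest-neighbor duplex free energy
#'
#' Sums stacking free energies over consecutive paired positions of an
#' aligned piRNA/target duplex, adds the duplex initiation term, and
#' penalizes every internal unpaired position (mismatch `.` or gap `-`
#' lying between the outermost paired positions); terminal unpaired
#' overhangs are free. Pairing and sequences must agree position by
#' position.
#'
#' @param pairing pairing string (`|` Watson-Crick, `:` G:U, `.` mismatch,
#'   `-` gap).
#' @param aln_pirna aligned piRNA string, 5'->3', `-` for gaps.
#' @param aln_target aligned target string, 3'->5' under the piRNA.
#' @param nn a [nn_params()].
#' @return free energy estimate in kcal/mol (more negative = more stable).
#' @export
#' @examples
#' nn <- nn_params()
#' duplex_energy("||||", "GCGC", "CGCG", nn)
duplex_energy <- function(pairing, aln_pirna, aln_target, nn = nn_params()) {
  stopifnot(inherits(nn, "nn_params"))
  n <- nchar(pairing)
  if (nchar(aln_pirna) != n || nchar(aln_target) != n)
    stop("pairing string and aligned sequences have different lengths",
         call. = FALSE)
  pr <- strsplit(pairing, "")[[1]]
  s1 <- strsplit(dna_to_rna(toupper(aln_pirna)), "")[[1]]
  s2 <- strsplit(dna_to_rna(toupper(aln_target)), "")[[1]]
  paired <- pr %in% c("|", ":")
  # consistency: paired positions must hold complementary (or wobble) bases
  for (i in which(paired)) {
    ok <- paste0(s1[i], s2[i]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
    if (!ok)
      stop(sprintf("pairing string inconsistent with sequences at position %d",
                   i), call. = FALSE)
  }
  e <- nn$initiation
  if (any(paired)) {
    idx <- which(paired)
    for (k in which(diff(idx) == 1L)) {
      i <- idx[k]
      key <- paste0(s1[i], s1[i + 1], "/", s2[i], s2[i + 1])
      e <- e + nn$stack[[key]]
    }
    internal <- seq(min(idx), max(idx))
    e <- e + nn$defect_penalty * sum(!paired[internal])
  }
  unname(e)
}

#' Gate duplex hits on binding free energy
#'
#' Retains hits whose free energy is strictly below `energy_gate`
#' (default -15 kcal/mol) and tabulates distinct target genes per piRNA.
#'
#' @param hits duplex hit data.frame (needs `delta_g`, `pirna_id`,
#'   `transcript_id`).
#' @param energy_gate threshold in kcal/mol (strict `<`).
#' @return list with `hits` (retained rows) and `targets` (data.frame
#'   `pirna_id`, `n_targets`, sorted by `n_targets` descending then id).
#' @export
gate_targets <- function(hits, energy_gate = -15.0) {
  keep <- hits$delta_g < energy_gate
  retained <- hits[keep, , drop = FALSE]
  rownames(retained) <- NULL
  if (nrow(retained)) {
    uniq <- unique(retained[, c("pirna_id", "transcript_id")])
    tab <- table(uniq$pirna_id)
    targets <- data.frame(pirna_id = names(tab),
                          n_targets = as.integer(tab),
                          stringsAsFactors = FALSE)
    targets <- targets[order(-targets$n_targets, targets$pirna_id), ,
                       drop = FALSE]
    rownames(targets) <- NULL
  } else {
    targets <- data.frame(pirna_id = character(0), n_targets = integer(0),
                          stringsAsFactors = FALSE)
  }
  list(hits = retained, targets = targets)
}
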