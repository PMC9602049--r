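write_tmp_fastq <- function(seqs, name) {
  f <- file.path(tempdir(), name)
  write_fastq(seqs, f)
  f
}

test_that("collapse_reads counts exact per-replicate occurrences", {
  f1 <- write_tmp_fastq(c("ACGT", "ACGT", "ACGT", "GGGG", "GGGG"), "r1.fastq")
  f2 <- write_tmp_fastq(c("ACGT"), "r2.fastq")
  tags <- collapse_reads(c(rep1 = f1, rep2 = f2))
  expect_identical(nrow(tags), 2L)
  expect_identical(tags$rep1[tags$sequence == "ACGT"], 3L)
  expect_identical(tags$rep1[tags$sequence == "GGGG"], 2L)
  expect_identical(tags$rep2[tags$sequence == "ACGT"], 1L)
  expect_identical(tags$rep2[tags$sequence == "GGGG"], 0L)
  expect_identical(sum(tag_count_matrix(tags)), 6L)

  fe <- write_tmp_fastq(character(0), "empty.fastq")
  empty <- collapse_reads(c(only = fe))
  expect_identical(nrow(empty), 0L)
})

test_that("malformed FASTQ reports a line number", {
  f <- file.path(tempdir(), "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), f)
  expect_error(collapse_reads(c(r = f)), "line")
  writeLines(c("@r1", "ACGT", "x", "IIII"), f)
  expect_error(collapse_reads(c(r = f)), "line 3")
  expect_error(collapse_reads(c(a = "x.fq", a = "y.fq")), "unique")
})

test_that("map_tags finds unique, reverse-complement and multi-locus hits", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("T", 100), "ACGTACGTACGTACGTACGTACGA", strrep("T", 76))))
  tag_fwd <- "ACGTACGTACGTACGTACGTACGA"
  tags <- data.frame(sequence = tag_fwd)
  h <- map_tags(tags, genome)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 100L)
  expect_identical(h$end, 124L)
  expect_identical(h$strand, "+")

  h2 <- map_tags(data.frame(sequence = revcomp(tag_fwd)), genome)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$strand, "-")
  expect_identical(h2$start, 100L)

  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "CCCCC", "ACGTACGTACGTACGTACGTACGA", strrep("G", 30),
    "ACGTACGTACGTACGTACGTACGA", "CCCCC")))
  h3 <- map_tags(data.frame(sequence = tag_fwd), genome2)
  expect_identical(nrow(h3), 2L)
})

test_that("every reported hit is verified by direct comparison", {
  sim <- small_sim()
  st <- small_study()
  gstr <- as.character(sim$genome[[1]])
  h <- st$hits[sample(nrow(st$hits), min(25, nrow(st$hits))), ]
  for (i in seq_len(nrow(h))) {
    sub <- substring(gstr, h$start[i] + 1, h$end[i])
    expected <- if (h$strand[i] == "+") h$sequence[i] else revcomp(h$sequence[i])
    expect_identical(sub, expected)
  }
})

test_that("ncRNA subtraction follows the overlap-fraction rule", {
  # annotation: tRNA at [100, 200)
  annot <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                                  strand = "+", class = "tRNA")
  tags <- data.frame(sequence = c("AAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
                                  "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"),
                     length = c(30L, 30L), r1 = c(1L, 1L))
  attr(tags, "replicates") <- "r1"
  # tag 1 fully inside; tag 2 overlaps by 10/30 only
  hits <- data.frame(sequence = tags$sequence,
                     chrom = "chr1", start = c(120L, 190L),
                     end = c(150L, 220L), strand = "+",
                     mismatches = 0L, stringsAsFactors = FALSE)
  res <- subtract_ncrna(tags, hits, annot)
  expect_identical(res$ledger$sequence, tags$sequence[1])
  expect_identical(res$ledger$class, "tRNA")
  expect_identical(res$tags$sequence, tags$sequence[2])

  # exactly half the tag overlapping is removed (>= rule)
  hits$start <- c(120L, 185L); hits$end <- c(150L, 215L)
  res2 <- subtract_ncrna(tags, hits, annot)
  expect_identical(sort(res2$ledger$sequence), sort(tags$sequence))

  # no annotations: everything retained
  res3 <- subtract_ncrna(tags, hits, annot[0])
  expect_identical(nrow(res3$tags), 2L)
  expect_error(subtract_ncrna(tags, hits, annot, classes = "lncRNA"),
               "unknown feature class")
})

test_that("miRNA subtraction removes exact matches only", {
  tags <- data.frame(sequence = c("ACGTACGTACGTACGTACGTA",
                                  "ACGTACGTACGTACGTACGTT"),
                     length = 21L, r1 = c(2L, 3L))
  attr(tags, "replicates") <- "r1"
  res <- subtract_mirna(tags, mirna_seqs = "ACGTACGTACGTACGTACGTA")
  expect_identical(res$tags$sequence, "ACGTACGTACGTACGTACGTT")
  expect_identical(res$ledger$stage, "miRNA")

  res2 <- subtract_mirna(tags, mirna_seqs = character(0))
  expect_identical(nrow(res2$tags), 2L)
  expect_error(subtract_mirna(tags), "provide")
})

test_that("candidate call enforces the inclusive length window and uniqueness", {
  seqs <- c(random_seq(23), random_seq(24), random_seq(33), random_seq(34),
            random_seq(28))
  tags <- data.frame(sequence = seqs, length = nchar(seqs),
                     r1 = rep(1L, 5))
  attr(tags, "replicates") <- "r1"
  attr(tags, "groups") <- c(r1 = "Am4")
  hits <- data.frame(sequence = c(seqs, seqs[5]),   # last tag maps twice
                     chrom = "chr1",
                     start = c(0L, 100L, 200L, 300L, 400L, 500L),
                     end = c(0L, 100L, 200L, 300L, 400L, 500L) +
                       nchar(c(seqs, seqs[5])),
                     strand = "+", mismatches = 0L,
                     stringsAsFactors = FALSE)
  cand <- call_pirnas(tags, hits)
  expect_setequal(cand$sequence, seqs[2:3])
  expect_true(all(cand$length >= 24 & cand$length <= 33))
  expect_identical(cand$pirna_id, pirna_id(cand$sequence))
})

test_that("first-base fractions are over A/C/G/U and sum to one", {
  counts <- matrix(c(1L, 1L, 1L, 0L, 2L, 5L), ncol = 2,
                   dimnames = list(NULL, c("a1", "b1")))
  cand <- fake_candidates(c("CAAAAAAAAAAAAAAAAAAAAAAA",
                            "CTTTTTTTTTTTTTTTTTTTTTTT",
                            "GAAAAAAAAAAAAAAAAAAAAAAA"),
                          counts, c(a1 = "A", b1 = "B"))
  fb <- first_base_bias(cand, "A")
  expect_equal(sum(fb), 1, tolerance = 1e-12)
  expect_equal(unname(fb["C"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(fb["G"]), 1 / 3, tolerance = 1e-12)
  # group B: only candidates 2 and 3 present
  fbB <- first_base_bias(cand, "B")
  expect_equal(unname(fbB["C"]), 1 / 2, tolerance = 1e-12)
  counts0 <- matrix(c(1L, 0L), ncol = 2,
                    dimnames = list(NULL, c("a1", "b1")))
  cand0 <- fake_candidates("CAAAAAAAAAAAAAAAAAAAAAAA", counts0,
                           c(a1 = "A", b1 = "B"))
  expect_error(first_base_bias(cand0, "B"), "no present candidates")

  all_c <- fake_candidates(c("CAAAAAAAAAAAAAAAAAAAAAAA",
                             "CTTTTTTTTTTTTTTTTTTTTTTT"),
                           matrix(1L, 2, 1, dimnames = list(NULL, "a1")),
                           c(a1 = "A"))
  expect_equal(unname(first_base_bias(all_c, "A")["C"]), 1)
})

test_that("group set partition is exhaustive and disjoint", {
  counts <- matrix(c(1L, 1L, 1L,   # a in all three groups
                     1L, 0L, 0L,   # b only group 1
                     0L, 1L, 0L),  # c only group 2
                   nrow = 3, byrow = TRUE,
                   dimnames = list(NULL, c("g1", "g2", "g3")))
  cand <- fake_candidates(c("AAAAAAAAAAAAAAAAAAAAAAAAA",
                            "CCCCCCCCCCCCCCCCCCCCCCCCC",
                            "GGGGGGGGGGGGGGGGGGGGGGGGG"),
                          counts, c(g1 = "G1", g2 = "G2", g3 = "G3"))
  part <- group_set_partition(cand)
  expect_identical(length(part$shared), 1L)
  expect_identical(length(part$unique_per_group$G1), 1L)
  expect_identical(length(part$unique_per_group$G2), 1L)
  expect_identical(length(part$unique_per_group$G3), 0L)
  expect_identical(sum(part$cells), nrow(cand))

  one <- fake_candidates("AAAAAAAAAAAAAAAAAAAAAAAAA",
                         matrix(c(1L, 1L), 1, 2,
                                dimnames = list(NULL, c("g1", "g2"))),
                         c(g1 = "G1", g2 = "G2"))
  p1 <- group_set_partition(one)
  expect_identical(length(p1$shared), 1L)
  expect_true(all(lengths(p1$unique_per_group) == 0L))
})

test_that("length histogram is supported on 24-33 and counts present candidates", {
  counts <- matrix(1L, 3, 1, dimnames = list(NULL, "r1"))
  cand <- fake_candidates(c(strrep("A", 24), strrep("C", 24), strrep("G", 30)),
                          counts, c(r1 = "Am4"))
  ld <- length_distribution(cand, "Am4")
  expect_identical(names(ld), as.character(24:33))
  expect_identical(unname(ld[c("24", "30")]), c(2L, 1L))
  expect_identical(sum(ld), 3L)
})

test_that("generator length distribution is near-uniform on 24-33", {
  gen <- simulate_genome(sim_config(seed = 31, n_pirna_loci = 1000,
                                    genome_length = 250000))
  lens <- nchar(gen$loci$sequence[gen$loci$class == "piRNA_locus"])
  tab <- table(factor(lens, levels = 24:33))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("input record order does not change any output", {
  sim <- small_sim()
  st <- small_study()
  # permute the records of one replicate and rerun the discovery chain
  f <- sim$reads$files[[1]]
  reads <- read_fastq_sequences(f)
  perm <- file.path(tempdir(), "permuted.fastq")
  set.seed(4)
  write_fastq(sample(reads), perm)
  manifest <- sim$reads$manifest
  manifest$file[1] <- perm
  tags2 <- collapse_reads(manifest)
  hits2 <- map_tags(tags2, sim$genome)
  s1 <- subtract_ncrna(tags2, hits2, sim$loci)
  s2 <- subtract_mirna(s1$tags, s1$hits, mirna_seqs = sim$paths$mirna)
  cand2 <- call_pirnas(s2$tags, s2$hits)
  expect_identical(cand2, st$candidates)
})

test_that("discovery recovers planted loci and rejects contaminants", {
  sim <- small_sim()
  st <- small_study()
  expect_gte(mean(sim$truth$sequence %in% st$candidates$sequence), 0.95)
  contaminant <- sim$loci$sequence[sim$loci$class != "piRNA_locus"]
  expect_identical(sum(st$candidates$sequence %in% contaminant), 0L)
  # conservation at every subtraction stage
  expect_identical(nrow(st$tags),
                   nrow(st$candidates) +
                     (nrow(st$tags) - nrow(st$candidates)))
  led <- st$ledger
  surv_after_sub <- nrow(st$tags) - nrow(led)
  kept_tags <- st$tags$sequence[!(st$tags$sequence %in% led$sequence)]
  expect_identical(length(kept_tags), surv_after_sub)
})
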