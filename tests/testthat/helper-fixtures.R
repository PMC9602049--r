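# Shared fixtures (built once per test run) and independent oracles.

fixture_env <- new.env(parent = emptyenv())

with_fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# a small but fully featured synthetic study
small_sim <- function() with_fixture("small_sim", {
  simulate_study(sim_config(seed = 101, n_pirna_loci = 60,
                            genome_length = 60000, mean_depth = 15000,
                            n_transcripts = 60),
                 file.path(tempdir(), "beepir_small_sim"))
})

small_study <- function() with_fixture("small_study",
                                       analyze_study(small_sim()))

# the full default-condition study used by the end-to-end recovery checks
default_sim <- function() with_fixture("default_sim", {
  simulate_study(sim_config(seed = 1979),
                 file.path(tempdir(), "beepir_default_sim"))
})

default_study <- function() with_fixture("default_study",
                                         analyze_study(default_sim()))

# build a candidate-catalog-shaped data.frame by hand
fake_candidates <- function(sequences, counts, groups) {
  reps <- colnames(counts)
  df <- data.frame(pirna_id = pirna_id(sequences), sequence = sequences,
                   length = nchar(sequences),
                   first_base = chartr("T", "U", substr(sequences, 1, 1)),
                   chrom = "chr1", start = 0L, end = nchar(sequences),
                   strand = "+", stringsAsFactors = FALSE)
  for (r in reps) df[[r]] <- counts[, r]
  attr(df, "replicates") <- reps
  attr(df, "groups") <- groups
  df
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# --- independent oracles -------------------------------------------------

# Audic-Claverie two-sided p by brute-force enumeration over the finite
# conditional support: given the total n = x + y, p(k) = C(n, k) q^k
# (1-q)^(n-k) with q = n2/(n1+n2); double the smaller inclusive tail
ac_oracle <- function(x, y, n1 = 1, n2 = 1) {
  n <- x + y
  if (n == 0) return(1)
  q <- n2 / (n1 + n2)
  k <- 0:n
  logp <- lchoose(n, k) + k * log(q) + (n - k) * log1p(-q)
  p <- exp(logp)
  lower <- sum(p[k <= y])
  upper <- sum(p[k >= y])
  min(1, 2 * min(lower, upper))
}

# two-sided hypergeometric p by direct enumeration with lchoose arithmetic
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, b) - lchoose(m + n, k))
  sum(p[p <= p_obs * (1 + 1e-9)])
}

# exhaustive enumeration of banded antisense alignments: for every anchor
# e0 and every gap placement (<= max_gaps), the minimum total penalty;
# recursion mirrors the duplex-space alignment definition independently of
# the scanner's DP
scan_oracle <- function(pirna, transcript, mismatch = 1, gu = 0.5,
                        gap = 1, core = c(2, 13), max_gaps = 2) {
  p <- strsplit(pirna, "")[[1]]
  t <- strsplit(transcript, "")[[1]]
  L <- length(p); n <- length(t)
  pair_pen <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "C" && b == "G") || (a == "G" && b == "C")) return(0)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(gu)
    mismatch
  }
  mult <- function(pos) {
    pos <- min(max(pos, 1), L)
    if (pos >= core[1] && pos <= core[2]) 2 else 1
  }
  best_score <- Inf
  best_sites <- list()
  for (e0 in max(L - max_gaps, 1):n) {
    q <- t[e0 - seq_len(min(e0, L + max_gaps)) + 1L]
    rec <- function(i, j, g, acc) {
      if (acc > best_anchor + 1e-12) return()  # branch-and-bound on the min
      if (i == L && abs(j - L) <= max_gaps) {
        if (acc < best_anchor - 1e-12) {
          best_anchor <<- acc; best_js <<- j
        } else if (acc <= best_anchor + 1e-12) {
          best_js <<- unique(c(best_js, j))
        }
      }
      if (i < L && j < length(q))
        rec(i + 1, j + 1, g,
            acc + pair_pen(p[i + 1], q[j + 1]) *
              (if (pair_pen(p[i + 1], q[j + 1]) == 0) 1 else mult(i + 1)))
      if (g < max_gaps) {
        if (i < L) rec(i + 1, j, g + 1, acc + gap * mult(i + 1))
        if (j < length(q)) rec(i, j + 1, g + 1, acc + gap * mult(i + 1))
      }
    }
    best_anchor <- Inf; best_js <- integer(0)
    rec(0, 0, 0, 0)
    if (is.finite(best_anchor)) {
      sites_here <- lapply(best_js, function(j) c(start = e0 - j, end = e0))
      if (best_anchor < best_score - 1e-12) {
        best_score <- best_anchor
        best_sites <- sites_here
      } else if (abs(best_anchor - best_score) <= 1e-12) {
        best_sites <- c(best_sites, sites_here)
      }
    }
  }
  list(score = best_score, sites = best_sites)
}
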