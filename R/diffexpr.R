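#' Tags-per-million normalization
#'
#' `TPM = T * 1e6 / N`, where `T` is a tag's count and `N` the library's
#' total clean small-RNA tags (not the catalog-restricted total).
#'
#' @param counts numeric vector or matrix of tag counts (columns =
#'   libraries).
#' @param lib_sizes total clean tags per library (scalar, or one value per
#'   column of `counts`).
#' @return TPM values with the shape of `counts`.
#' @export
#' @examples
#' tpm_normalize(5, 1e6)            # 5
#' tpm_normalize(325249, 32524933)  # ~9999.97
tpm_normalize <- function(counts, lib_sizes) {
  if (any(lib_sizes <= 0))
    stop("library sizes must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.matrix(counts)) {
    stopifnot(length(lib_sizes) %in% c(1L, ncol(counts)))
    sweep(counts, 2L, lib_sizes, function(t, n) t * 1e6 / n)
  } else {
    counts * 1e6 / lib_sizes
  }
}

#' Log2 fold change between two TPM values
#'
#' Both TPMs are floored at `floor` before taking the ratio, so zero
#' expression yields a finite extreme value rather than +/-Inf. Swapping
#' the arguments negates the result exactly.
#'
#' @param tpm_num numerator TPM (second/later group in a comparison).
#' @param tpm_den denominator TPM.
#' @param floor positive floor applied to both TPMs (default 0.01).
#' @return `log2(max(tpm_num, floor) / max(tpm_den, floor))`, vectorized.
#' @export
#' @examples
#' fold_change(20, 5)          # 2
#' fold_change(100, 0)         # log2(1e4) ~ 13.29
fold_change <- function(tpm_num, tpm_den, floor = 0.01) {
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  log2(pmax(tpm_num, floor) / pmax(tpm_den, floor))
}

#' Audic-Claverie test for pooled digital counts
#'
#' Exact conditional test comparing a tag's pooled counts `x` and `y`
#' between two libraries of sizes `n1` and `n2`. Conditional on the total
#' `x + y`, the null law of `y` is binomial with success probability
#' `n2 / (n1 + n2)`; the two-sided p-value doubles the smaller inclusive
#' tail and caps at 1. This conditional formulation is exactly symmetric
#' under swapping the two libraries, so reversing a comparison preserves
#' every p-value. Both counts zero returns p = 1 with a `"warning"`
#' attribute.
#'
#' @param x,y non-negative counts (vectorized).
#' @param n1,n2 library sizes (totals behind `x` and `y`).
#' @return two-sided p-values in `[0, 1]`.
#' @export
#' @examples
#' ac_test(0, 10)   # 2 * P(Y >= 10 | total 10) = 2^-9
#' ac_test(5, 5)    # 1 at the symmetric center
ac_test <- function(x, y, n1 = 1, n2 = 1) {
  stopifnot(all(x >= 0), all(y >= 0), n1 > 0, n2 > 0)
  p0 <- n2 / (n1 + n2)
  n <- x + y
  lower <- stats::pbinom(y, n, p0)
  upper <- 1 - stats::pbinom(y - 1, n, p0)   # P(Y >= y)
  p <- pmin(1, 2 * pmin(lower, upper))
  zero <- x == 0 & y == 0
  if (any(zero)) {
    p[zero] <- 1
    attr(p, "warning") <- "both groups all-zero for some tags; p set to 1"
  }
  p
}

#' Specification of one group-vs-group comparison
#'
#' @param numerator group whose TPM forms the fold-change numerator (the
#'   later developmental stage, e.g. `"Am5"` in `"Am4 vs Am5"`).
#' @param denominator baseline group.
#' @param test `"pooled-count"` (Audic-Claverie on replicate-pooled
#'   counts, the default) or `"welch-t"` (Welch t-test on replicate TPMs).
#' @param zero_tpm_floor TPM floor for fold changes.
#' @param name comparison label; defaults to
#'   `"<denominator> vs <numerator>"`.
#' @return object of class `comparison_spec`.
#' @export
comparison_spec <- function(numerator, denominator,
                            test = c("pooled-count", "welch-t"),
                            zero_tpm_floor = 0.01,
                            name = paste(denominator, "vs", numerator)) {
  test <- match.arg(test)
  if (identical(numerator, denominator))
    stop("numerator and denominator groups must differ", call. = FALSE)
  if (zero_tpm_floor <= 0) stop("zero_tpm_floor must be > 0", call. = FALSE)
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, test = test,
                 zero_tpm_floor = zero_tpm_floor),
            class = "comparison_spec")
}

#' Reverse a comparison (swap numerator and denominator)
#' @param spec a [comparison_spec()].
#' @return the reversed `comparison_spec`.
#' @export
reverse_comparison <- function(spec) {
  comparison_spec(spec$denominator, spec$numerator, spec$test,
                  spec$zero_tpm_floor)
}

#' Per-piRNA expression records for one comparison
#'
#' Computes per-replicate and pooled-group TPMs, the log2 fold change on
#' pooled TPMs (numerator over denominator, floored), and a p-value from
#' the configured test.
#'
#' @param candidates candidate catalog from [call_pirnas()] (or any
#'   data.frame with `pirna_id` plus per-replicate count columns and
#'   `replicates` / `groups` attributes).
#' @param lib_sizes named total clean tags per replicate.
#' @param spec a [comparison_spec()].
#' @param groups optional replicate -> group mapping override.
#' @return data.frame: `pirna_id`, `comparison`, `tpm_<den>`, `tpm_<num>`
#'   (pooled), `count_<den>`, `count_<num>` (pooled), `log2fc`, `p_value`,
#'   `direction` (`up`/`down`/`ns` at p <= 0.05, |log2FC| >= 1).
#' @export
expression_records <- function(candidates, lib_sizes, spec, groups = NULL) {
  stopifnot(inherits(spec, "comparison_spec"))
  reps <- attr(candidates, "replicates")
  groups <- groups %||% attr(candidates, "groups")
  stopifnot(!is.null(reps), !is.null(groups),
            all(reps %in% names(lib_sizes)))
  for (g in c(spec$numerator, spec$denominator))
    if (!g %in% groups) stop(sprintf("unknown group '%s'", g), call. = FALSE)

  cm <- as.matrix(candidates[, reps, drop = FALSE])
  reps_num <- reps[groups[reps] == spec$numerator]
  reps_den <- reps[groups[reps] == spec$denominator]
  x_den <- rowSums(cm[, reps_den, drop = FALSE])
  y_num <- rowSums(cm[, reps_num, drop = FALSE])
  n_den <- sum(lib_sizes[reps_den])
  n_num <- sum(lib_sizes[reps_num])
  tpm_den <- tpm_normalize(x_den, n_den)
  tpm_num <- tpm_normalize(y_num, n_num)
  lfc <- fold_change(tpm_num, tpm_den, spec$zero_tpm_floor)

  p <- if (spec$test == "pooled-count") {
    as.numeric(ac_test(x_den, y_num, n_den, n_num))
  } else {
    tpm_rep <- tpm_normalize(cm, lib_sizes[reps])
    vapply(seq_len(nrow(cm)), function(i) {
      a <- tpm_rep[i, reps_num]; b <- tpm_rep[i, reps_den]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      t.test(a, b)$p.value
    }, numeric(1))
  }

  out <- data.frame(pirna_id = candidates$pirna_id,
                    comparison = spec$name,
                    stringsAsFactors = FALSE)
  out[[paste0("count_", spec$denominator)]] <- x_den
  out[[paste0("count_", spec$numerator)]] <- y_num
  out[[paste0("tpm_", spec$denominator)]] <- tpm_den
  out[[paste0("tpm_", spec$numerator)]] <- tpm_num
  out$log2fc <- lfc
  out$p_value <- p
  out$direction <- ifelse(p <= 0.05 & lfc >= 1, "up",
                          ifelse(p <= 0.05 & lfc <= -1, "down", "ns"))
  attr(out, "spec") <- spec
  out
}

#' Call differentially expressed piRNAs
#'
#' Screens expression records at `p <= p_max` and `|log2FC| >= lfc_min`
#' (both boundaries inclusive); ranks each list by |log2FC| descending,
#' ties by ascending p, then identifier. Optionally applies
#' Benjamini-Hochberg adjustment before thresholding (off by default,
#' matching the raw-p screening criterion).
#'
#' @param records data.frame from [expression_records()].
#' @param p_max p-value threshold (inclusive; default 0.05).
#' @param lfc_min |log2 fold change| threshold (inclusive; default 1).
#' @param adjust apply BH adjustment to p-values first.
#' @return list with `up`, `down` (ranked data.frames) and `summary`
#'   (data.frame `comparison`, `n_up`, `n_down`).
#' @export
call_depirnas <- function(records, p_max = 0.05, lfc_min = 1,
                          adjust = FALSE) {
  p <- if (adjust) p.adjust(records$p_value, "BH") else records$p_value
  sig <- p <= p_max & abs(records$log2fc) >= lfc_min
  rank_de <- function(df) {
    df <- df[order(-abs(df$log2fc), df$p_value, df$pirna_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  up <- rank_de(records[sig & records$log2fc > 0, , drop = FALSE])
  down <- rank_de(records[sig & records$log2fc < 0, , drop = FALSE])
  list(up = up, down = down,
       summary = data.frame(comparison = records$comparison[1] %||% NA_character_,
                            n_up = nrow(up), n_down = nrow(down)))
}

#' Relative expression via the 2^-ddCt method
#'
#' Converts RT-qPCR cycle thresholds for a target and a reference gene in
#' a test versus control condition into relative expression:
#' `2^-((ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl))`.
#'
#' @param ct_target_test,ct_ref_test Ct values in the test condition.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control condition.
#' @return relative expression (1 = no change), vectorized.
#' @export
#' @examples
#' ddct_relative_expression(20, 18, 22, 18)  # ddCt = -2 -> 4
ddct_relative_expression <- function(ct_target_test, ct_ref_test,
                                     ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
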