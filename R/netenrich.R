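#' Gene-to-term annotation map
#'
#' Validates and bundles a gene -> term assignment with a term label
#' table. Every term referenced by a gene must exist in the label table.
#'
#' @param gene2term data.frame with columns `gene`, `term` (or a TSV
#'   path).
#' @param terms data.frame with columns `term`, `label`, `namespace`
#'   (GO `BP`/`MF`/`CC` or `pathway`), or a TSV path.
#' @return object of class `term_map` with elements `gene2term`, `terms`,
#'   and `by_gene` (named list gene -> term ids).
#' @export
term_map <- function(gene2term, terms) {
  if (is.character(gene2term)) gene2term <- read.delim(gene2term,
                                                       stringsAsFactors = FALSE)
  if (is.character(terms)) terms <- read.delim(terms,
                                               stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% names(gene2term)),
            all(c("term", "label") %in% names(terms)))
  if (is.null(terms$namespace)) terms$namespace <- NA_character_
  orphan <- setdiff(gene2term$term, terms$term)
  if (length(orphan))
    stop(sprintf("terms referenced by genes but missing from label table: %s",
                 paste(utils::head(orphan, 5), collapse = ", ")),
         call. = FALSE)
  structure(list(gene2term = gene2term, terms = terms,
                 by_gene = split(gene2term$term, gene2term$gene)),
            class = "term_map")
}

# two-sided hypergeometric p: total probability of all tables (under fixed
# margins) no more likely than the observed one, matching Fisher's exact
# test; enumerated from dhyper over the full support
hypergeom_twosided <- function(a, b, c, d) {
  m <- a + c          # genes in term
  n <- b + d          # genes not in term
  k <- a + b          # targeted genes
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

#' Fisher's exact term enrichment
#'
#' For each annotation term, tests the 2x2 table of targeted /
#' non-targeted versus in-term / not-in-term genes with a two-sided
#' exact hypergeometric test. Significance is `p < alpha` (strict);
#' results are ordered by p-value then term id.
#'
#' @param targets character vector of target gene ids (must be a subset
#'   of `background`).
#' @param background character vector of background gene ids.
#' @param map a [term_map()].
#' @param alpha significance threshold (strict `<`; default 0.05).
#' @param adjust also report Benjamini-Hochberg q-values and use them for
#'   the significance flag.
#' @return data.frame: `term`, `label`, `namespace`, `n_target_in`,
#'   `n_target_out`, `n_bg_in`, `n_bg_out`, `odds_ratio`, `p_value`,
#'   optional `q_value`, `significant`.
#' @export
enrich_terms <- function(targets, background, map, alpha = 0.05,
                         adjust = FALSE) {
  stopifnot(inherits(map, "term_map"))
  if (!length(background)) stop("background set is empty", call. = FALSE)
  background <- unique(background)
  targets <- unique(targets)
  if (!all(targets %in% background))
    stop("targets must be a subset of the background", call. = FALSE)

  g2t <- map$gene2term[map$gene2term$gene %in% background, , drop = FALSE]
  term_ids <- sort(unique(g2t$term))
  is_target <- background %in% targets
  nT <- sum(is_target)
  nB <- length(background)

  rows <- lapply(term_ids, function(tm) {
    in_term <- background %in% g2t$gene[g2t$term == tm]
    a <- sum(in_term & is_target)
    b <- nT - a
    cc <- sum(in_term) - a
    d <- nB - a - b - cc
    or <- (a * d) / (b * cc)
    data.frame(term = tm, n_target_in = a, n_target_out = b,
               n_bg_in = cc, n_bg_out = d, odds_ratio = or,
               p_value = hypergeom_twosided(a, b, cc, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- merge(res, map$terms[, c("term", "label", "namespace")],
               by = "term", all.x = TRUE, sort = FALSE)
  if (adjust) {
    res$q_value <- p.adjust(res$p_value, "BH")
    res$significant <- res$q_value < alpha
  } else {
    res$significant <- res$p_value < alpha
  }
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Default pathway-category configuration
#'
#' Named lists of pathway labels counted as development-, immune- and
#' energy-metabolism-associated in the regulatory-network analysis.
#' Entries may be term ids or term labels of the supplied [term_map()].
#'
#' @return named list of character vectors.
#' @export
default_pathway_categories <- function() {
  list(development = c("Wnt signaling pathway", "Hippo signaling pathway",
                       "Notch signaling pathway", "mTOR signaling pathway"),
       immune = c("endocytosis", "Jak/STAT signaling pathway",
                  "ubiquitin-mediated proteolysis"),
       energy_metabolism = c("sulfur metabolism", "nitrogen metabolism",
                             "oxidative phosphorylation"))
}

resolve_terms <- function(entries, map) {
  ids <- map$terms$term[match(entries, map$terms$term)]
  by_label <- map$terms$term[match(entries, map$terms$label)]
  ids[is.na(ids)] <- by_label[is.na(ids)]
  if (anyNA(ids))
    stop(sprintf("category names terms absent from the map: %s",
                 paste(entries[is.na(ids)], collapse = ", ")),
         call. = FALSE)
  ids
}

#' Build a piRNA-gene-pathway regulatory network
#'
#' Assembles a bipartite network between called DEpiRNAs and their
#' energy-gated target genes, restricted to genes annotated to at least
#' one pathway of the requested categories, plus pathway-category nodes.
#' Edges carry the duplex free energy, the comparison label and the
#' regulation direction.
#'
#' @param de_lists named list (by comparison label) of [call_depirnas()]
#'   results.
#' @param gated_hits energy-gated duplex hits ([gate_targets()]`$hits`).
#' @param map a [term_map()].
#' @param categories named list of pathway term ids/labels per category
#'   (default [default_pathway_categories()]).
#' @param which_categories categories to include (default all configured).
#' @return an [igraph::igraph] with vertex attributes `type` (`piRNA`,
#'   `gene`, `pathway_category`), and edge attributes `relation`,
#'   `delta_g`, `comparison`, `direction`.
#' @export
build_network <- function(de_lists, gated_hits, map,
                          categories = default_pathway_categories(),
                          which_categories = names(categories)) {
  stopifnot(inherits(map, "term_map"))
  unknown <- setdiff(which_categories, names(categories))
  if (length(unknown))
    stop(sprintf("unknown category: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cat_terms <- lapply(categories[which_categories], resolve_terms, map = map)

  de_tab <- do.call(rbind, lapply(names(de_lists), function(cmp) {
    dl <- de_lists[[cmp]]
    rbind(
      if (nrow(dl$up)) data.frame(pirna_id = dl$up$pirna_id,
                                  comparison = cmp, direction = "up",
                                  stringsAsFactors = FALSE),
      if (nrow(dl$down)) data.frame(pirna_id = dl$down$pirna_id,
                                    comparison = cmp, direction = "down",
                                    stringsAsFactors = FALSE))
  }))
  if (is.null(de_tab))
    de_tab <- data.frame(pirna_id = character(0), comparison = character(0),
                         direction = character(0))

  # gene passes if annotated to >= 1 configured pathway in any requested
  # category
  gene_cats <- function(g) {
    tms <- map$by_gene[[g]] %||% character(0)
    names(cat_terms)[vapply(cat_terms, function(ct) any(tms %in% ct),
                            logical(1))]
  }

  edges <- list()
  gene_cat_edges <- list()
  hk <- gated_hits[gated_hits$pirna_id %in% de_tab$pirna_id, , drop = FALSE]
  if (nrow(hk)) {
    uniq <- unique(hk[, c("pirna_id", "transcript_id")])
    for (i in seq_len(nrow(uniq))) {
      g <- uniq$transcript_id[i]
      cats <- gene_cats(g)
      if (!length(cats)) next
      rows <- hk[hk$pirna_id == uniq$pirna_id[i] &
                   hk$transcript_id == g, , drop = FALSE]
      best <- rows[which.min(rows$delta_g), , drop = FALSE]
      de_rows <- de_tab[de_tab$pirna_id == uniq$pirna_id[i], , drop = FALSE]
      edges[[length(edges) + 1L]] <- data.frame(
        from = uniq$pirna_id[i], to = g, relation = "targets",
        delta_g = best$delta_g,
        comparison = paste(unique(de_rows$comparison), collapse = ";"),
        direction = paste(unique(de_rows$direction), collapse = ";"),
        stringsAsFactors = FALSE)
      for (cat in cats)
        gene_cat_edges[[paste(g, cat)]] <- data.frame(
          from = g, to = cat, relation = "member_of", delta_g = NA_real_,
          comparison = NA_character_, direction = NA_character_,
          stringsAsFactors = FALSE)
    }
  }
  edf <- do.call(rbind, c(edges, unname(gene_cat_edges)))
  if (is.null(edf)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  g <- igraph::graph_from_data_frame(edf, directed = FALSE)
  vt <- ifelse(igraph::V(g)$name %in% de_tab$pirna_id, "piRNA",
               ifelse(igraph::V(g)$name %in% names(cat_terms),
                      "pathway_category", "gene"))
  igraph::V(g)$type <- vt
  g
}

#' Per-piRNA degree ranking (network hubs)
#'
#' Degrees count distinct gene neighbors of each piRNA node; ranking is
#' by degree descending, ties broken by ascending identifier.
#'
#' @param network network from [build_network()].
#' @return data.frame `pirna_id`, `degree`, ranked.
#' @export
hub_stats <- function(network) {
  if (igraph::vcount(network) == 0)
    return(data.frame(pirna_id = character(0), degree = integer(0)))
  vt <- igraph::V(network)$type
  pir <- igraph::V(network)$name[vt == "piRNA"]
  deg <- vapply(pir, function(p) {
    nb <- igraph::neighbors(network, p)
    sum(nb$type == "gene")
  }, numeric(1))
  out <- data.frame(pirna_id = pir, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$pirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a regulatory network to SIF and GraphML
#'
#' SIF lines are `source<TAB>relation<TAB>target` (tab-delimited, so node
#' ids may contain spaces); GraphML carries the node `type` and the edge
#' `relation`, `delta_g`, `comparison` and `direction` attributes and
#' round-trips through [igraph::read_graph()].
#'
#' @param network network from [build_network()].
#' @param path_prefix output path without extension; writes
#'   `<prefix>.sif` and/or `<prefix>.graphml`.
#' @param formats subset of `c("sif", "graphml")`.
#' @return named character vector of written paths, invisibly.
#' @export
export_network <- function(network, path_prefix,
                           formats = c("sif", "graphml")) {
  formats <- match.arg(formats, several.ok = TRUE)
  out <- character(0)
  if ("sif" %in% formats) {
    f <- paste0(path_prefix, ".sif")
    if (igraph::ecount(network) > 0) {
      ed <- igraph::as_data_frame(network, what = "edges")
      writeLines(paste(ed$from, ed$relation, ed$to, sep = "\t"), f)
    } else {
      writeLines(character(0), f)
    }
    out["sif"] <- f
  }
  if ("graphml" %in% formats) {
    f <- paste0(path_prefix, ".graphml")
    igraph::write_graph(network, f, format = "graphml")
    out["graphml"] <- f
  }
  invisible(out)
}

#' Read a SIF file back as an edge table
#'
#' @param path SIF file written by [export_network()].
#' @return data.frame `from`, `relation`, `to`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(from = character(0), relation = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1L),
             relation = vapply(parts, `[`, "", 2L),
             to = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
}
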