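toy_map <- function() {
  genes <- sprintf("g%03d", 1:100)
  g2t <- rbind(data.frame(gene = genes[1:10], term = "T1"),
               data.frame(gene = genes, term = "T2"),
               data.frame(gene = genes[1:40], term = "T3"))
  terms <- data.frame(term = c("T1", "T2", "T3"),
                      label = c("focused term", "universal term", "broad term"),
                      namespace = c("BP", "BP", "pathway"))
  term_map(g2t, terms)
}

test_that("term_map validates that every referenced term has a label", {
  expect_error(term_map(data.frame(gene = "g1", term = "TX"),
                        data.frame(term = "T1", label = "a")),
               "missing from label table")
  m <- toy_map()
  expect_identical(sort(m$by_gene[["g001"]]), c("T1", "T2", "T3"))
})

test_that("enrichment p-values match hypergeometric enumeration", {
  m <- toy_map()
  genes <- sprintf("g%03d", 1:100)
  # a term covering the whole background is never enriched
  res <- enrich_terms(genes[1:20], genes, m)
  expect_equal(res$p_value[res$term == "T2"], 1, tolerance = 1e-12)
  # targets == background: every term has p = 1
  res2 <- enrich_terms(genes, genes, m)
  expect_true(all(res2$p_value == 1))

  # the spec's 2x2 example: a=5, b=5, c=5, d=85
  targets <- c(genes[1:5], genes[41:45])      # 5 in T3-complement trick below
  # build the table for term T1 directly: 10 genes in T1
  res3 <- enrich_terms(c(genes[1:5], genes[51:55]), genes, m)
  row <- res3[res3$term == "T1", ]
  expect_identical(c(row$n_target_in, row$n_target_out, row$n_bg_in,
                     row$n_bg_out), c(5L, 5L, 5L, 85L))
  expect_equal(row$p_value, fisher_oracle(5, 5, 5, 85), tolerance = 1e-12)
  # independent cross-check against stats::fisher.test
  ft <- fisher.test(matrix(c(5, 5, 5, 85), 2))$p.value
  expect_equal(row$p_value, ft, tolerance = 1e-6)

  expect_error(enrich_terms("g1", character(0), m), "empty")
  expect_error(enrich_terms("zz", genes, m), "subset")
})

test_that("enrichment matches the enumeration oracle on random tables", {
  set.seed(99)
  for (i in 1:40) {
    nbg <- sample(20:200, 1)
    genes <- sprintf("x%03d", seq_len(nbg))
    in_term <- sample(genes, sample(3:nbg, 1))
    g2t <- rbind(data.frame(gene = in_term, term = "TT"),
                 data.frame(gene = genes, term = "ALL"))
    m <- term_map(g2t, data.frame(term = c("TT", "ALL"),
                                  label = c("t", "a"),
                                  namespace = "BP"))
    targets <- sample(genes, sample(2:(nbg - 1), 1))
    res <- enrich_terms(targets, genes, m)
    a <- sum(targets %in% in_term); b <- length(targets) - a
    cc <- length(in_term) - a; d <- nbg - a - b - cc
    expect_equal(res$p_value[res$term == "TT"], fisher_oracle(a, b, cc, d),
                 tolerance = 1e-12, label = sprintf("table %d", i))
    expect_equal(res$p_value[res$term == "TT"],
                 fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-6, label = sprintf("fisher %d", i))
  }
})

test_that("the designed enriched term is detected in synthetic data", {
  sim <- small_sim()
  m <- term_map(sim$gene2term, sim$terms)
  targets <- unique(sim$sites$transcript_id)
  res <- enrich_terms(targets, names(sim$transcripts), m)
  row <- res[res$term == sim$enriched_term, ]
  expect_lt(row$p_value, 0.05)
  expect_true(row$significant)
  expect_identical(res$term[1], sim$enriched_term)  # strongest signal first
})

toy_network_inputs <- function() {
  de_lists <- list("A vs B" = list(
    up = data.frame(pirna_id = "pir1"),
    down = data.frame(pirna_id = character(0))))
  hits <- data.frame(pirna_id = "pir1",
                     transcript_id = c("g1", "g2", "g3"),
                     delta_g = c(-20, -18, -16))
  g2t <- data.frame(gene = c("g1", "g2", "g3"),
                    term = c("PW1", "PW2", "PW2"))
  terms <- data.frame(term = c("PW1", "PW2"),
                      label = c("Wnt signaling pathway", "other pathway"),
                      namespace = "pathway")
  list(de = de_lists, hits = hits, map = term_map(g2t, terms))
}

test_that("network keeps only category-annotated genes", {
  inp <- toy_network_inputs()
  net <- build_network(inp$de, inp$hits, inp$map,
                       categories = list(development = "Wnt signaling pathway"))
  expect_identical(as.integer(igraph::vcount(net)), 3L)   # piRNA, gene, category
  expect_identical(as.integer(igraph::ecount(net)), 2L)   # pir1-g1, g1-development
  vt <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  expect_identical(unname(vt[c("pir1", "g1", "development")]),
                   c("piRNA", "gene", "pathway_category"))

  empty <- build_network(inp$de, inp$hits, inp$map,
                         categories = list(development = character(0)))
  expect_identical(as.integer(igraph::ecount(empty)), 0L)
  expect_error(build_network(inp$de, inp$hits, inp$map,
                             categories = list(development = "nope")),
               "absent from the map")
  expect_error(build_network(inp$de, inp$hits, inp$map,
                             which_categories = "bogus"),
               "unknown category")
})

test_that("hub ranking is by degree then identifier", {
  inp <- toy_network_inputs()
  inp$de[["A vs B"]]$up <- data.frame(pirna_id = c("pir1", "pir2"))
  inp$hits <- rbind(inp$hits,
                    data.frame(pirna_id = "pir2", transcript_id = "g2",
                               delta_g = -19))
  net <- build_network(inp$de, inp$hits, inp$map,
                       categories = list(x = c("Wnt signaling pathway",
                                               "other pathway")))
  hubs <- hub_stats(net)
  expect_identical(hubs$pirna_id, c("pir1", "pir2"))
  expect_identical(hubs$degree, c(3L, 1L))

  # ties resolved by ascending id
  inp2 <- toy_network_inputs()
  inp2$de[["A vs B"]]$up <- data.frame(pirna_id = c("pirB", "pirA"))
  inp2$hits <- data.frame(pirna_id = c("pirB", "pirA"),
                          transcript_id = "g1", delta_g = -20)
  net2 <- build_network(inp2$de, inp2$hits, inp2$map,
                        categories = list(x = "Wnt signaling pathway"))
  expect_identical(hub_stats(net2)$pirna_id, c("pirA", "pirB"))

  expect_identical(nrow(hub_stats(igraph::make_empty_graph(directed = FALSE))),
                   0L)
})

test_that("network edges equal gated hits passing the category filter", {
  st <- small_study()
  sim <- small_sim()
  m <- term_map(sim$gene2term, sim$terms)
  cats <- default_pathway_categories()
  cat_ids <- unique(unlist(lapply(cats, beepiR:::resolve_terms, map = m)))
  de_ids <- unique(unlist(lapply(st$de, function(d)
    c(d$up$pirna_id, d$down$pirna_id))))
  gh <- unique(st$gated$hits[st$gated$hits$pirna_id %in% de_ids,
                             c("pirna_id", "transcript_id")])
  pass <- vapply(gh$transcript_id, function(g)
    any((m$by_gene[[g]] %||% character(0)) %in% cat_ids), logical(1))
  n_target_edges <- sum(pass)
  ed <- igraph::as_data_frame(st$network, what = "edges")
  expect_identical(sum(ed$relation == "targets"), n_target_edges)
})

test_that("the designed hub piRNA attains maximal network degree", {
  st <- small_study()
  sim <- small_sim()
  truth_counts <- table(sim$sites$pirna_id)
  designed_hub <- names(which.max(truth_counts))
  hubs <- hub_stats(st$network)
  expect_gt(nrow(hubs), 0)
  expect_identical(hubs$pirna_id[1], designed_hub)
})

test_that("SIF and GraphML exports round-trip", {
  inp <- toy_network_inputs()
  net <- build_network(inp$de, inp$hits, inp$map,
                       categories = list(development = "Wnt signaling pathway"))
  pre <- file.path(tempdir(), "net_export")
  paths <- export_network(net, pre)
  sif <- read_sif(paths[["sif"]])
  expect_identical(nrow(sif), 2L)
  expect_true(all(c("targets", "member_of") %in% sif$relation))

  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  ed0 <- igraph::as_data_frame(net, "edges")
  ed1 <- igraph::as_data_frame(back, "edges")
  expect_setequal(paste(ed0$from, ed0$to), paste(ed1$from, ed1$to))
  expect_setequal(igraph::V(back)$type, igraph::V(net)$type)

  # node ids containing whitespace survive both formats
  g <- igraph::make_graph(~ "node one" - "node two")
  igraph::E(g)$relation <- "targets"
  p2 <- export_network(g, file.path(tempdir(), "ws_net"))
  s2 <- read_sif(p2[["sif"]])
  expect_identical(s2$from, "node one")
  expect_identical(s2$to, "node two")
  b2 <- igraph::read_graph(p2[["graphml"]], format = "graphml")
  expect_setequal(igraph::V(b2)$name, c("node one", "node two"))

  # a single-edge network produces a single SIF line
  one <- igraph::make_graph(~ a - b)
  igraph::E(one)$relation <- "targets"
  p3 <- export_network(one, file.path(tempdir(), "one_net"),
                       formats = "sif")
  expect_identical(length(readLines(p3[["sif"]])), 1L)
})
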