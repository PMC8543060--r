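test_that("TSV edge lists parse into validated graphs", {
  path <- tiny_graph_file(c(
    "# a comment",
    "g1\tgene\tassociation\tP1\tprocess\tliterature",
    "g2\tgene\tassociation\tP1\tprocess\tfactual_database",
    "g1\tgene\tinteraction\tg2\tgene\tliterature"))
  kg <- read_knowledge_graph(path)
  expect_equal(nrow(kg$vertices), 3L)
  expect_equal(nrow(kg$edges), 3L)
  expect_setequal(kg$vertices$kind, c("gene", "gene", "process"))

  # empty file -> empty graph
  empty <- read_knowledge_graph(tiny_graph_file("# only a header"))
  expect_equal(nrow(empty$vertices), 0L)
  expect_equal(nrow(empty$edges), 0L)

  # duplicate identical records collapse; oracle = unique line count
  lines <- c("g1\tgene\tassociation\tP1\tprocess",
             "g1\tgene\tassociation\tP1\tprocess",
             "g2\tgene\tassociation\tP1\tprocess")
  dup <- read_knowledge_graph(tiny_graph_file(lines))
  expect_equal(nrow(dup$edges), length(unique(lines)))
  expect_equal(attr(dup, "load_summary")$duplicates, 1L)
})

test_that("malformed, self-loop and unknown-kind records are handled", {
  expect_error(
    read_knowledge_graph(tiny_graph_file(c(
      "g1\tgene\tassociation\tP1\tprocess",
      "g2\tgene\tbroken"))),
    "line 2")
  # self-loops rejected with a load-summary count
  suppressMessages(
    kg <- read_knowledge_graph(tiny_graph_file(c(
      "g1\tgene\tassociation\tg1\tgene",
      "g1\tgene\tassociation\tP1\tprocess"))))
  expect_equal(attr(kg, "load_summary")$self_loops, 1L)
  expect_equal(nrow(kg$edges), 1L)
  # unknown kind coerced to 'other' with a warning
  expect_warning(
    kg2 <- read_knowledge_graph(tiny_graph_file(
      "x\tgadget\tassociation\tP1\tprocess")),
    "other")
  expect_equal(kg2$vertices$kind[kg2$vertices$id == "x"], "other")
})

test_that("loading is order-independent", {
  lines <- c("g1\tgene\tassociation\tP1\tprocess\tliterature",
             "g2\tgene\tregulation\tP1\tprocess\tfactual_database",
             "g1\tgene\tinteraction\tg2\tgene\tliterature",
             "g3\tgene\tassociation\tP2\tprocess\tliterature")
  kg1 <- read_knowledge_graph(tiny_graph_file(lines))
  kg2 <- read_knowledge_graph(tiny_graph_file(rev(lines)))
  expect_identical(kg1$vertices, kg2$vertices)
  expect_identical(kg1$edges, kg2$edges)
})

test_that("degree counts distinct neighbours, not edge records", {
  kg <- knowledge_graph(
    data.frame(id = c("a", "b", "c"), kind = "gene", name = c("a", "b", "c")),
    data.frame(source = c("a", "a"), target = c("b", "b"),
               relation = c("interaction", "regulation"),
               provenance = "literature"))
  expect_equal(degree_of(kg, "a"), 1L)  # two parallel edges, one neighbour
  expect_equal(degree_of(kg, "c"), 0L)  # isolated vertex
  expect_error(degree_of(kg, "zz"), "unknown vertex")
})

test_that("degree matches a brute-force scan and the handshake identity", {
  for (s in 1:5) {
    spec <- fixture_spec(n_genes = 30, n_processes = 10,
                         gene_gene_edge_prob = 0.1, rng_seed = s)
    kg <- make_knowledge_graph(spec)
    degs <- vapply(kg$vertices$id, function(v) degree_of(kg, v), integer(1))
    expect_equal(degs,
                 vapply(kg$vertices$id, function(v) oracle_degree(kg, v),
                        integer(1)))
    # sum of distinct-neighbour degrees = 2 x number of adjacent pairs
    pairs <- unique(kg$edges[, c("source", "target")])
    expect_equal(sum(degs), 2L * nrow(pairs))
  }
})

test_that("graph construction rejects contract violations", {
  v <- data.frame(id = c("a", "b"), kind = "gene", name = c("a", "b"))
  e <- function(...) data.frame(..., stringsAsFactors = FALSE)
  expect_error(knowledge_graph(v, e(source = "a", target = "a",
                                    relation = "x", provenance = "literature")),
               "self-loop")
  expect_error(knowledge_graph(v, e(source = "a", target = "zz",
                                    relation = "x", provenance = "literature")),
               "endpoint")
  expect_error(knowledge_graph(v, e(source = "a", target = "b",
                                    relation = "", provenance = "literature")),
               "relation")
  expect_error(knowledge_graph(rbind(v, v), e(source = "a", target = "b",
                                              relation = "x",
                                              provenance = "literature")),
               "duplicate")
})

test_that("knowledge graphs round-trip through the TSV writer", {
  for (s in 1:3) {
    kg <- make_knowledge_graph(fixture_spec(n_genes = 25, n_processes = 8,
                                            rng_seed = s))
    path <- tempfile(fileext = ".tsv")
    write_knowledge_graph(kg, path)
    back <- read_knowledge_graph(path)
    expect_identical(back$edges, kg$edges)
    expect_setequal(back$vertices$id, kg$vertices$id)
  }
})
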