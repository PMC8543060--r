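test_that("cross-talk centrality is the link fraction", {
  expect_equal(ctc(0, 292), 0)
  expect_equal(ctc(10, 10), 1)
  expect_equal(ctc(3, 10), 0.3)
  expect_error(ctc(5, 4), "Ni")
  expect_error(ctc(1, 0), "M")
})

test_that("hypergeometric tail is inclusive and matches enumeration", {
  expect_equal(hypergeom_pvalue(0, 7, 3, 10), 1)       # P(X >= 0) = 1
  expect_equal(hypergeom_pvalue(2, 5, 4, 10), 186 / 252)
  expect_equal(hypergeom_pvalue(5, 5, 12, 12), 1)      # K = N_U: certain
  expect_error(hypergeom_pvalue(5, 4, 10, 12), "Ni")
  expect_error(hypergeom_pvalue(1, 13, 4, 12), "N_U")
  # spot-check the enumeration oracle agreement at a few sizes
  for (cfg in list(c(3, 6, 4, 9), c(1, 2, 5, 8), c(4, 6, 6, 11)))
    expect_equal(hypergeom_pvalue(cfg[1], cfg[2], cfg[3], cfg[4]),
                 oracle_hyper(cfg[1], cfg[2], cfg[3], cfg[4]))
})

test_that("Benjamini-Yekutieli follows the step-up definition", {
  expect_equal(benjamini_yekutieli(0.03), 0.03)     # c(1) = 1
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.9)),
               c(0.055, 0.055, 1))                  # c(3) = 11/6
  expect_identical(benjamini_yekutieli(numeric(0)), numeric(0))
  expect_error(benjamini_yekutieli(c(0.5, 0)), "0, 1")
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "0, 1")
  # monotone: larger p never gets a smaller q
  withr::with_seed(13, {
    p <- stats::runif(50)
    q <- benjamini_yekutieli(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= 0))
    expect_true(all(q >= p))
  })
})

test_that("the annotation universe counts annotated genes and per-process K", {
  kg <- knowledge_graph(
    data.frame(id = c("g1", "g2", "g3", "P1", "P2"),
               kind = c("gene", "gene", "gene", "process", "process"),
               name = c("g1", "g2", "g3", "P1", "P2")),
    data.frame(source = c("g1", "g2", "g1", "g2"),
               target = c("P1", "P1", "P2", "g3"),
               relation = c("association", "association", "association",
                            "interaction"),
               provenance = "literature"))
  u <- annotation_universe(kg)
  expect_equal(u$universe_size, 2L)  # g3 has no process annotation
  expect_equal(u$annotation_counts, c(P1 = 2L, P2 = 1L))
})

test_that("prioritization ranks by CTC with q-value and id tie-breaks", {
  # two extreme candidates: saturated one first, unconnected one last
  kg <- knowledge_graph(
    data.frame(id = c("g1", "g2", "S", "Pfull", "Pnone"),
               kind = c("gene", "gene", "process", "process", "process"),
               name = c("g1", "g2", "S", "Pfull", "Pnone")),
    data.frame(source = c("g1", "g2", "g1", "g2", "g1"),
               target = c("S", "S", "Pfull", "Pfull", "Pnone"),
               relation = "association", provenance = "literature"))
  net <- reconstruct(kg, "S")
  sc <- prioritize(kg, net, candidates = c("Pnone", "Pfull"))
  expect_equal(sc$process_id, c("Pfull", "Pnone"))
  expect_equal(sc$rank, 1:2)
  expect_equal(sc$ctc, c(1, 0.5))
  # Pnone is annotated (to g1) but its link to the 2-member net is partial
  expect_true(all(sc$p_value <= sc$q_value))

  # ranks are a permutation and invariant to candidate order
  spec <- fixture_spec(n_genes = 40, n_processes = 15, rng_seed = 2)
  kgf <- make_knowledge_graph(spec)
  netf <- reconstruct(kgf, fixture_process_ids(spec)[1])
  cands <- fixture_process_ids(spec)[-1]
  s1 <- prioritize(kgf, netf, cands)
  s2 <- prioritize(kgf, netf, rev(cands))
  expect_setequal(s1$rank, seq_len(nrow(s1)))
  expect_identical(s1, s2)
  # equal ctc -> lower q first; equal q -> id lexicographic
  expect_true(all(diff(s1$ctc) <= 0))
  ties <- split(seq_len(nrow(s1)), s1$ctc)
  for (ix in ties)
    if (length(ix) > 1) expect_true(all(diff(s1$q_value[ix]) >= 0))
})

test_that("CTC values equal the brute-force adjacency oracle on random graphs", {
  for (s in 1:20) {
    spec <- withr::with_seed(1000 + s,
      fixture_spec(n_genes = sample(10:50, 1), n_processes = sample(5:30, 1),
                   background_link_prob = 0.1, rng_seed = s))
    kg <- make_knowledge_graph(spec)
    net <- reconstruct(kg, fixture_process_ids(spec)[1])
    sc <- prioritize(kg, net)
    for (i in seq_len(nrow(sc))) {
      ni <- oracle_links(kg, net$members, sc$process_id[i])
      expect_identical(sc$Ni[i], ni)
      expect_equal(sc$ctc[i], ni / net$M)
    }
  }
})

test_that("unannotated candidates are not scored", {
  kg <- knowledge_graph(
    data.frame(id = c("g1", "S", "Plonely"),
               kind = c("gene", "process", "process"),
               name = c("g1", "S", "Plonely")),
    data.frame(source = "g1", target = "S",
               relation = "association", provenance = "literature"))
  net <- reconstruct(kg, "S")
  sc <- prioritize(kg, net)
  expect_false("Plonely" %in% sc$process_id)  # K = 0: cannot be drawn
  expect_error(prioritize(kg, net, candidates = character(0)), "candidate")
})

test_that("significance filtering preserves order and matches a linear scan", {
  spec <- fixture_spec(n_genes = 40, n_processes = 20, rng_seed = 3)
  kg <- make_knowledge_graph(spec)
  net <- reconstruct(kg, fixture_process_ids(spec)[1])
  sc <- prioritize(kg, net)
  # alpha = 1 keeps everything below the q = 1 ceiling
  expect_equal(nrow(significant(sc, alpha = 1)), sum(sc$q_value < 1))
  all1 <- sc; all1$q_value <- 1
  expect_equal(nrow(significant(all1)), 0L)
  for (alpha in c(0.01, 0.05, 0.5)) {
    sig <- significant(sc, alpha)
    expect_identical(sig$process_id, sc$process_id[sc$q_value < alpha])
  }
})

test_that("rankings round-trip through the TSV writer", {
  spec <- fixture_spec(n_genes = 30, n_processes = 10, rng_seed = 8)
  kg <- make_knowledge_graph(spec)
  net <- reconstruct(kg, fixture_process_ids(spec)[1])
  sc <- prioritize(kg, net)
  path <- tempfile(fileext = ".tsv")
  write_ranking(sc, path)
  back <- read_ranking(path)
  expect_equal(back$process_id, sc$process_id)
  expect_equal(back$q_value, sc$q_value, tolerance = 1e-12)
})
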