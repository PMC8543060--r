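#' Specification for a synthetic knowledge-graph fixture
#'
#' Describes a reproducible random knowledge graph: `n_genes` gene vertices,
#' `n_processes` process vertices of which the first `n_seeds` are designated
#' seed processes. Each gene links to each seed with probability
#' `seed_process_fraction`; planted candidate processes link to the first
#' seed's members at their `planted_ctc` target fraction, the remaining
#' (decoy) processes link to every gene at `background_link_prob`; gene-gene
#' interaction edges appear with probability `gene_gene_edge_prob`. The toy
#' ontology is a complete `is_a` tree of the given depth and branching with a
#' fraction of acyclicity-preserving `part_of` cross-links. One integer seed
#' drives a single pseudo-random stream for the whole fixture.
#'
#' @param n_genes number of network-eligible gene vertices (>= 1).
#' @param n_background_genes annotated genes outside every seed network.
#'   Knowledge bases are genome-scale: the reconstructed network is a small
#'   part of the annotated universe, and the over-representation test is
#'   only calibrated in that regime. Background genes (ids `B...`) receive
#'   decoy-process annotations but never link to a seed.
#' @param n_processes number of process vertices (>= 1), seeds included.
#' @param n_seeds number of designated seed processes.
#' @param seed_process_fraction probability a gene links to each seed.
#' @param planted_ctc named numeric: candidate process id -> target link
#'   fraction over the first seed's members.
#' @param background_link_prob decoy-process link probability per gene.
#' @param gene_gene_edge_prob gene-gene edge probability per pair.
#' @param ontology_depth,ontology_branching shape of the toy ontology tree.
#' @param part_of_fraction fraction of non-root terms receiving an extra
#'   `part_of` link to a shallower term.
#' @param rng_seed integer seed; identical seeds give identical fixtures.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 100L, n_background_genes = 200L,
                         n_processes = 31L, n_seeds = 1L,
                         seed_process_fraction = 0.9, planted_ctc = NULL,
                         background_link_prob = 0.05,
                         gene_gene_edge_prob = 0.02,
                         ontology_depth = 3L, ontology_branching = 3L,
                         part_of_fraction = 0.15, rng_seed = 1L) {
  probs <- c(seed_process_fraction, background_link_prob,
             gene_gene_edge_prob, part_of_fraction, planted_ctc)
  stopifnot(n_genes >= 1L, n_background_genes >= 0L, n_processes >= 1L,
            n_seeds >= 1L, n_seeds <= n_processes,
            all(probs >= 0), all(probs <= 1),
            ontology_depth >= 1L, ontology_branching >= 1L)
  structure(list(n_genes = as.integer(n_genes),
                 n_background_genes = as.integer(n_background_genes),
                 n_processes = as.integer(n_processes),
                 n_seeds = as.integer(n_seeds),
                 seed_process_fraction = seed_process_fraction,
                 planted_ctc = planted_ctc,
                 background_link_prob = background_link_prob,
                 gene_gene_edge_prob = gene_gene_edge_prob,
                 ontology_depth = as.integer(ontology_depth),
                 ontology_branching = as.integer(ontology_branching),
                 part_of_fraction = part_of_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

fixture_gene_ids <- function(n) sprintf("G%04d", seq_len(n))
fixture_term_ids <- function(i) sprintf("GO:%07d", i)

#' Process ids used by a fixture's knowledge graph
#'
#' The fixture's process vertices reuse the toy ontology's term ids
#' (skipping the root), so the clustering stage can resolve them; the first
#' `n_seeds` are the seed processes.
#'
#' @param spec a [fixture_spec].
#' @return Character vector of length `n_processes`.
#' @export
fixture_process_ids <- function(spec) fixture_term_ids(seq_len(spec$n_processes) + 1L)

#' Generate a synthetic knowledge graph with planted signal
#'
#' @param spec a [fixture_spec].
#' @return A [knowledge_graph]; reproducible from `spec$rng_seed`.
#' @export
make_knowledge_graph <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  procs <- fixture_process_ids(spec)
  seeds <- procs[seq_len(spec$n_seeds)]
  cand <- setdiff(procs, seeds)
  if (!is.null(spec$planted_ctc)) {
    bad <- setdiff(names(spec$planted_ctc), procs)
    if (length(bad))
      stop("infeasible spec: planted fraction for unknown process ",
           paste(bad, collapse = ", "))
  }
  planted <- names(spec$planted_ctc)
  genes <- fixture_gene_ids(spec$n_genes)
  bg <- if (spec$n_background_genes > 0L)
    sprintf("B%04d", seq_len(spec$n_background_genes)) else character()

  withr::with_seed(spec$rng_seed, {
    src <- character(); tgt <- character(); rel <- character()
    add <- function(s, t, r) {
      src <<- c(src, s); tgt <<- c(tgt, t); rel <<- c(rel, rep_len(r, length(s)))
    }
    seed1_members <- NULL
    for (sd in seeds) {
      hit <- runif(spec$n_genes) < spec$seed_process_fraction
      if (!any(hit)) hit[1L] <- TRUE      # a seed network needs >= 1 member
      add(genes[hit], rep(sd, sum(hit)), "association")
      if (is.null(seed1_members)) seed1_members <- genes[hit]
    }
    for (p in planted) {
      hit <- runif(length(seed1_members)) < spec$planted_ctc[[p]]
      if (any(hit)) add(seed1_members[hit], rep(p, sum(hit)), "association")
    }
    all_genes <- c(genes, bg)
    for (p in setdiff(cand, planted)) {
      hit <- runif(length(all_genes)) < spec$background_link_prob
      if (any(hit)) add(all_genes[hit], rep(p, sum(hit)), "association")
    }
    if (spec$n_genes > 1L && spec$gene_gene_edge_prob > 0) {
      pr <- utils::combn(genes, 2L)
      hit <- runif(ncol(pr)) < spec$gene_gene_edge_prob
      if (any(hit)) add(pr[1L, hit], pr[2L, hit], "interaction")
    }
    prov <- PROVENANCE_LEVELS[1L + (runif(length(src)) < 0.5)]

    vdf <- data.frame(
      id = c(all_genes, procs),
      kind = c(rep("gene", length(all_genes)), rep("process", length(procs))),
      name = c(all_genes, procs), stringsAsFactors = FALSE)
    edf <- data.frame(source = src, target = tgt, relation = rel,
                      provenance = prov, stringsAsFactors = FALSE)
    knowledge_graph(vdf, edf)
  })
}

#' Generate a toy ontology DAG
#'
#' A complete `is_a` tree of `ontology_depth` levels below the root with
#' `ontology_branching` children per node (term ids assigned breadth-first
#' from `GO:0000001`), plus random `part_of` cross-links from a fraction of
#' non-root terms to a uniformly chosen strictly shallower term. Every extra
#' edge points to a shallower level, so the construction is acyclic by
#' design.
#'
#' @param spec a [fixture_spec].
#' @return An [ontology_dag]; reproducible from `spec$rng_seed`.
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  b <- spec$ontology_branching
  d <- spec$ontology_depth
  n_terms <- sum(b ^ (0:d))
  ids <- fixture_term_ids(seq_len(n_terms))
  level <- rep(0:d, times = b ^ (0:d))
  # BFS numbering: parent of node i (> 1) is node floor((i - 2)/b) + 1
  parent_idx <- function(i) (i - 2L) %/% b + 1L

  withr::with_seed(spec$rng_seed + 1L, {
    child <- ids[2:n_terms]
    parent <- ids[parent_idx(2:n_terms)]
    type <- rep("is_a", n_terms - 1L)
    extra <- which(level >= 1L & runif(n_terms) < spec$part_of_fraction)
    for (i in extra) {
      shallower <- which(level < level[i])
      pick <- shallower[sample.int(length(shallower), 1L)]
      if (pick == parent_idx(i)) next   # already the is_a parent
      child <- c(child, ids[i]); parent <- c(parent, ids[pick])
      type <- c(type, "part_of")
    }
    ontology_dag(
      data.frame(id = ids, name = paste0("synthetic process ", seq_len(n_terms)),
                 namespace = "biological_process", stringsAsFactors = FALSE),
      data.frame(child = child, parent = parent, type = type,
                 stringsAsFactors = FALSE))
  })
}

#' Three-condition comparison fixture with known ground truth
#'
#' Emulates a multi-condition study design: each condition's seed process is
#' annotated to its own exclusive genes plus a block of genes shared by all
#' conditions. Planted "common" processes link (at `planted_fraction`) to the
#' genes of every condition; each planted "specific" process links only to
#' one condition's exclusive genes; decoy processes link to all genes at
#' `background_link_prob`. A pool of background genes annotated to a
#' catch-all process widens the sampling universe, as in a genome-scale
#' knowledge base where most annotated genes lie outside any one network.
#'
#' @param n_conditions number of seed networks (>= 2).
#' @param n_exclusive exclusive genes per condition.
#' @param n_shared genes shared by all conditions.
#' @param n_background annotated background genes outside every network.
#' @param n_common planted processes common to all conditions.
#' @param n_specific planted condition-specific processes per condition.
#' @param n_decoys unplanted decoy processes.
#' @param planted_fraction link fraction for planted processes.
#' @param background_link_prob decoy link probability per gene.
#' @param rng_seed integer seed.
#' @return List with `kg` (the [knowledge_graph]) and `truth` (named list:
#'   `seeds`, `common`, `specific` — a per-condition list —, `decoys`,
#'   `conditions`).
#' @export
make_comparison_fixture <- function(n_conditions = 3L, n_exclusive = 40L,
                                    n_shared = 20L, n_background = 200L,
                                    n_common = 2L, n_specific = 1L,
                                    n_decoys = 30L, planted_fraction = 0.8,
                                    background_link_prob = 0.05,
                                    rng_seed = 1L) {
  stopifnot(n_conditions >= 2L, n_exclusive >= 1L, n_common >= 1L,
            n_specific >= 1L)
  conds <- paste0("condition_", seq_len(n_conditions))
  n_cond_genes <- n_conditions * n_exclusive + n_shared
  genes <- fixture_gene_ids(n_cond_genes + n_background)
  excl <- lapply(seq_len(n_conditions), function(c)
    genes[(c - 1L) * n_exclusive + seq_len(n_exclusive)])
  names(excl) <- conds
  shared <- if (n_shared > 0L)
    genes[n_conditions * n_exclusive + seq_len(n_shared)] else character()
  background <- genes[seq_len(n_background) + n_cond_genes]

  i <- 1L
  nxt <- function(n) {
    out <- fixture_term_ids(seq_len(n) + i)
    i <<- i + n
    out
  }
  seeds <- setNames(nxt(n_conditions), conds)
  common <- nxt(n_common)
  specific <- setNames(lapply(seq_len(n_conditions), function(c) nxt(n_specific)),
                       conds)
  decoys <- nxt(n_decoys)
  catchall <- nxt(1L)

  withr::with_seed(rng_seed, {
    src <- character(); tgt <- character()
    add <- function(s, t) { src <<- c(src, s); tgt <<- c(tgt, t) }
    for (cn in conds) {
      mem <- c(excl[[cn]], shared)
      add(mem, rep(seeds[[cn]], length(mem)))
    }
    all_cond_genes <- c(unlist(excl), shared)
    for (p in common) {
      hit <- runif(length(all_cond_genes)) < planted_fraction
      add(all_cond_genes[hit], rep(p, sum(hit)))
    }
    for (cn in conds) for (p in specific[[cn]]) {
      hit <- runif(n_exclusive) < planted_fraction
      add(excl[[cn]][hit], rep(p, sum(hit)))
    }
    for (p in decoys) {
      hit <- runif(length(genes)) < background_link_prob
      add(genes[hit], rep(p, sum(hit)))
    }
    if (n_background > 0L) add(background, rep(catchall, n_background))

    procs <- c(unname(seeds), common, unlist(specific), decoys, catchall)
    vdf <- data.frame(
      id = c(genes, procs),
      kind = c(rep("gene", length(genes)), rep("process", length(procs))),
      name = c(genes, procs), stringsAsFactors = FALSE)
    edf <- data.frame(source = src, target = tgt,
                      relation = "association", provenance = "literature",
                      stringsAsFactors = FALSE)
    list(kg = knowledge_graph(vdf, edf),
         truth = list(seeds = seeds, common = common, specific = specific,
                      decoys = decoys, conditions = conds))
  })
}
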