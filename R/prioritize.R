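#' Cross-talk centrality of a candidate vertex
#'
#' `CTC = N_i / M`: the fraction of an associative gene network's `M` member
#' vertices directly linked to candidate `i`. Ranges from 0 (the candidate is
#' not related to any network vertex) to 1 (linked to all of them).
#'
#' @param Ni number of distinct network members adjacent to the candidate.
#' @param M network size (number of member vertices), `M >= 1`.
#' @return Numeric in \[0, 1\].
#' @export
ctc <- function(Ni, M) {
  stopifnot(length(Ni) == length(M) || length(M) == 1L)
  if (any(M < 1)) stop("M must be >= 1")
  if (any(Ni < 0) || any(Ni > M)) stop("Ni must satisfy 0 <= Ni <= M")
  Ni / M
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' Probability of observing `Ni` or more links by chance: `P(X >= Ni)` with
#' `X ~ Hypergeometric(N_U, K, M)` — `M` members drawn without replacement
#' from a universe of `N_U` annotated genes of which `K` are annotated to the
#' candidate process. The tail is inclusive.
#'
#' @param Ni observed link count.
#' @param M network size (number of draws).
#' @param K genes annotated to the candidate in the whole knowledge graph.
#' @param N_U universe size (annotated gene/protein vertices).
#' @return `P(X >= Ni)` in (0, 1].
#' @export
hypergeom_pvalue <- function(Ni, M, K, N_U) {
  if (any(M > N_U) || any(K > N_U)) stop("M and K must not exceed N_U")
  if (any(Ni > pmin(M, K)) || any(Ni < 0)) stop("Ni must satisfy 0 <= Ni <= min(M, K)")
  stats::phyper(Ni - 1, K, N_U - K, M, lower.tail = FALSE)
}

#' Benjamini-Yekutieli adjusted q-values
#'
#' Step-up false-discovery-rate adjustment valid under arbitrary dependence:
#' `q_(i) = min_(j >= i) ( p_(j) * m * c(m) / j )` capped at 1, with
#' `c(m)` the harmonic sum `1 + 1/2 + ... + 1/m`. Returned in the input's
#' original order. Delegates to [stats::p.adjust()] with `method = "BY"`.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as the input.
#' @export
benjamini_yekutieli <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues <= 0) || any(pvalues > 1) || anyNA(pvalues))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BY")
}

#' Annotation universe of a knowledge graph
#'
#' The sampling frame for the over-representation test: `universe_size` is the
#' number of distinct gene/protein vertices carrying at least one link to a
#' process vertex, and `annotation_counts` maps each process to `K`, the
#' number of distinct gene/protein vertices linked to it anywhere in the
#' graph.
#'
#' @param kg a [knowledge_graph].
#' @return List with `universe_size` and named integer `annotation_counts`.
#' @export
annotation_universe <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  kind <- setNames(kg$vertices$kind, kg$vertices$id)
  e <- kg$edges
  # gene/protein -- process incidences, both edge orientations
  gp <- rbind(
    e[kind[e$source] %in% c("gene", "protein") & kind[e$target] == "process",
      c("source", "target")],
    setNames(e[kind[e$target] %in% c("gene", "protein") & kind[e$source] == "process",
               c("target", "source")], c("source", "target")))
  gp <- unique(gp)
  procs <- kg$vertices$id[kg$vertices$kind == "process"]
  counts <- table(factor(gp$target, levels = procs))
  list(universe_size = length(unique(gp$source)),
       annotation_counts = setNames(as.integer(counts), procs))
}

#' Score and rank candidate biological processes against a network
#'
#' For each candidate process the link count `N_i`, cross-talk centrality
#' `CTC = N_i/M`, upper-tail hypergeometric p-value and Benjamini-Yekutieli
#' q-value (adjusted across all scored candidates of this run) are computed.
#' Candidates are ranked by CTC descending, ties broken by q-value ascending,
#' then id. Candidates with no gene annotation anywhere in the graph
#' (`K = 0`) cannot be drawn into a network and are not scored.
#'
#' @param kg the [knowledge_graph].
#' @param net the reconstructed [gene_network].
#' @param candidates character vector of process ids to score; default all
#'   process vertices of the graph.
#' @param universe optional list (`universe_size`, `annotation_counts`)
#'   overriding [annotation_universe()]; allows a custom sampling frame.
#' @return data.frame with columns `process_id`, `process_name`, `Ni`, `M`,
#'   `ctc`, `p_value`, `q_value`, `rank`, ordered by rank.
#' @export
prioritize <- function(kg, net, candidates = NULL, universe = NULL) {
  stopifnot(inherits(kg, "knowledge_graph"), inherits(net, "gene_network"))
  kind <- setNames(kg$vertices$kind, kg$vertices$id)
  if (is.null(candidates))
    candidates <- kg$vertices$id[kg$vertices$kind == "process"]
  if (length(candidates) == 0L) stop("no candidate processes to score")
  unknown <- setdiff(candidates, kg$vertices$id)
  if (length(unknown))
    stop("unknown candidate(s): ", paste(head(unknown, 5L), collapse = ", "))
  if (any(kind[candidates] != "process"))
    stop("candidates must be process vertices")
  if (is.null(universe)) universe <- annotation_universe(kg)
  N_U <- universe$universe_size
  K <- universe$annotation_counts

  adj <- adjacency_sets(kg)
  Ni <- vapply(candidates, function(p)
    length(intersect(adj[[p]], net$members)), integer(1))

  scored <- candidates[K[candidates] > 0L]
  if (length(scored) == 0L) stop("no candidate with gene annotations to score")
  Ni <- Ni[scored]
  Kv <- K[scored]
  if (net$M > N_U)
    stop("network size M exceeds the annotation universe; check the universe spec")

  p <- hypergeom_pvalue(Ni, net$M, Kv, N_U)
  q <- benjamini_yekutieli(p)
  name <- setNames(kg$vertices$name, kg$vertices$id)
  out <- data.frame(
    process_id = scored,
    process_name = unname(name[scored]),
    Ni = as.integer(Ni),
    M = net$M,
    ctc = as.numeric(Ni) / net$M,
    p_value = unname(p),
    q_value = unname(q),
    stringsAsFactors = FALSE)
  ord <- order(-out$ctc, out$q_value, out$process_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter a ranking to the significant processes
#'
#' @param scores data.frame from [prioritize()].
#' @param alpha significance threshold on the q-value; default 0.05.
#' @return The rows with `q_value < alpha`, ranking order preserved.
#' @export
significant <- function(scores, alpha = 0.05) {
  stopifnot(is.data.frame(scores), alpha > 0, alpha <= 1)
  out <- scores[scores$q_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a ranking table
#'
#' Plain TSV with columns `process_id`, `process_name`, `Ni`, `M`, `ctc`,
#' `p_value`, `q_value`, `rank` — the machine-readable twin of a published
#' process-ranking table.
#'
#' @param scores data.frame from [prioritize()].
#' @param path file path.
#' @export
write_ranking <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = c(
                      process_id = "character", process_name = "character"))
}
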