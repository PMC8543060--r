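#' Reconstruct the associative gene network of a seed biological process
#'
#' Network members are all gene/protein vertices of the knowledge graph
#' directly adjacent to the seed process through any relation type (after the
#' optional provenance filter); internal edges are all retained knowledge-graph
#' edges with both endpoints among members. Only direct neighbours of the seed
#' are taken: no multi-hop expansion.
#'
#' @param kg a [knowledge_graph].
#' @param seed id of the seed vertex; must exist with kind `process`.
#' @param provenance `"both"` (default), `"literature"` or
#'   `"factual_database"`: which edge provenance to use.
#' @return A [gene_network].
#' @export
reconstruct <- function(kg, seed, provenance = "both") {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (!seed %in% kg$vertices$id)
    stop("seed process not found in graph: ", seed)
  kind <- setNames(kg$vertices$kind, kg$vertices$id)
  if (kind[[seed]] != "process")
    stop("seed vertex is not a process: ", seed, " (kind ", kind[[seed]], ")")
  kg <- filter_provenance(kg, provenance)

  nb <- unique(igraph::neighbors(kg$graph, seed)$name)
  members <- sort(nb[kind[nb] %in% c("gene", "protein")])
  if (length(members) == 0L)
    stop("empty network: no gene/protein vertex adjacent to seed ", seed,
         " under provenance filter '", provenance, "'")

  keep_e <- kg$edges$source %in% members & kg$edges$target %in% members
  gene_network(seed,
               kg$vertices[kg$vertices$id %in% members, , drop = FALSE],
               kg$edges[keep_e, , drop = FALSE])
}

#' Number of network members linked to a candidate process
#'
#' `N_i`: the number of distinct members of the reconstructed network adjacent
#' to the candidate vertex in the knowledge graph. Ranges from 0 (candidate
#' unrelated to the network) to `M` (linked to every member).
#'
#' @param kg the [knowledge_graph] the network was reconstructed from.
#' @param net a [gene_network].
#' @param candidate process vertex id (the seed itself is allowed).
#' @return Integer in `[0, M]`.
#' @export
candidate_links <- function(kg, net, candidate) {
  stopifnot(inherits(kg, "knowledge_graph"), inherits(net, "gene_network"))
  if (!candidate %in% kg$vertices$id)
    stop("unknown candidate vertex: ", candidate)
  nb <- unique(igraph::neighbors(kg$graph, candidate)$name)
  length(intersect(nb, net$members))
}
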