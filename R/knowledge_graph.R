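#' @importFrom stats phyper p.adjust rbinom runif setNames
#' @importFrom utils head write.table
NULL

#' Vertex kinds recognised in a knowledge graph
#'
#' Molecular entities (genes, proteins, metabolites, microRNAs) and
#' higher-level factors (biological processes, traits, diseases) form the
#' vertex dictionary of a heterogeneous associative network. Records with a
#' kind outside this set are coerced to `"other"`.
#'
#' @export
VERTEX_KINDS <- c("gene", "protein", "metabolite", "microRNA", "process",
                  "trait", "disease", "other")

PROVENANCE_LEVELS <- c("literature", "factual_database")

#' Construct a typed knowledge graph
#'
#' A knowledge graph is a heterogeneous undirected multigraph: vertices are
#' typed molecular entities and higher-level factors, edges carry a relation
#' label (association, regulation, interaction, ...) and a provenance tag
#' (text-mined literature vs. factual database). Relation direction is kept
#' as a label only; all connectivity computations treat edges as undirected.
#'
#' @param vertices data.frame with columns `id`, `kind`, `name`.
#' @param edges data.frame with columns `source`, `target`, `relation`,
#'   `provenance`.
#' @return An object of class `knowledge_graph` with components `vertices`,
#'   `edges` (both canonically sorted) and `graph` (an [igraph][igraph::graph]
#'   undirected multigraph).
#' @export
knowledge_graph <- function(vertices, edges) {
  vertices <- as.data.frame(vertices, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind", "name") %in% names(vertices)))
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        relation = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "relation", "provenance") %in% names(edges)))

  if (any(!nzchar(vertices$id)) || anyNA(vertices$id))
    stop("vertex ids must be non-empty")
  if (anyDuplicated(vertices$id))
    stop("duplicate vertex ids: ",
         paste(unique(vertices$id[duplicated(vertices$id)]), collapse = ", "))
  bad_kind <- !vertices$kind %in% VERTEX_KINDS
  if (any(bad_kind)) {
    warning(sum(bad_kind), " vertex record(s) with unknown kind mapped to 'other'")
    vertices$kind[bad_kind] <- "other"
  }
  if (nrow(edges) > 0L) {
    if (any(!nzchar(edges$relation)) || anyNA(edges$relation))
      stop("edge relation labels must be non-empty")
    missing <- setdiff(c(edges$source, edges$target), vertices$id)
    if (length(missing))
      stop("edge endpoint(s) not in vertex set: ",
           paste(head(missing, 5L), collapse = ", "))
    if (any(edges$source == edges$target))
      stop("self-loops are not permitted in a knowledge graph")
    if (any(!edges$provenance %in% PROVENANCE_LEVELS))
      stop("provenance must be one of: ", paste(PROVENANCE_LEVELS, collapse = ", "))
  }

  # canonical order: vertices by id; edges by sorted endpoint pair, then labels.
  # Makes construction order-independent and serialisations reproducible.
  vertices <- vertices[order(vertices$id), c("id", "kind", "name"), drop = FALSE]
  if (nrow(edges) > 0L) {
    a <- pmin(edges$source, edges$target)
    b <- pmax(edges$source, edges$target)
    edges$source <- a
    edges$target <- b
    edges <- edges[order(a, b, edges$relation, edges$provenance),
                   c("source", "target", "relation", "provenance"), drop = FALSE]
    edges <- unique(edges)
  }
  rownames(vertices) <- NULL
  rownames(edges) <- NULL

  # display name goes into attribute `vname`: igraph reserves `name` for ids
  g <- igraph::graph_from_data_frame(
    d = edges,
    directed = FALSE,
    vertices = data.frame(id = vertices$id, kind = vertices$kind,
                          vname = vertices$name, stringsAsFactors = FALSE)
  )
  structure(
    list(vertices = vertices, edges = edges, graph = g),
    class = "knowledge_graph"
  )
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("Knowledge graph:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  tab <- table(x$vertices$kind)
  cat("  kinds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a knowledge graph from a tab-separated edge list
#'
#' Each record has five or six tab-separated fields: source id, source kind,
#' relation label, target id, target kind, and an optional provenance
#' (`literature` or `factual_database`; defaults to `literature`). Lines
#' starting with `#` and blank lines are skipped. Duplicate identical records
#' collapse to a single edge; self-loop records are dropped and counted in the
#' load summary attached as attribute `"load_summary"`.
#'
#' @param path path to the TSV edge list.
#' @param default_provenance provenance assumed when the sixth field is absent.
#' @return A [knowledge_graph] with attribute `load_summary`, a list with the
#'   counts of records read, duplicates collapsed and self-loops rejected.
#' @export
read_knowledge_graph <- function(path, default_provenance = "literature") {
  if (!file.exists(path)) stop("file not found: ", path)
  default_provenance <- match.arg(default_provenance, PROVENANCE_LEVELS)
  lines <- readLines(path, warn = FALSE)
  # `#vertex<TAB>id<TAB>kind` comment records declare edge-less vertices
  iso_lines <- grep("^#vertex\t", lines, value = TRUE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  iso <- if (length(iso_lines)) {
    f <- strsplit(iso_lines, "\t", fixed = TRUE)
    data.frame(id = vapply(f, `[[`, "", 2L),
               kind = vapply(f, function(x)
                 if (length(x) >= 3L) x[[3L]] else "other", ""),
               stringsAsFactors = FALSE)
  } else data.frame(id = character(), kind = character(),
                    stringsAsFactors = FALSE)

  if (length(lines) == 0L) {
    kg <- knowledge_graph(
      data.frame(id = iso$id, kind = iso$kind, name = iso$id,
                 stringsAsFactors = FALSE),
      data.frame(source = character(), target = character(),
                 relation = character(), provenance = character(),
                 stringsAsFactors = FALSE)
    )
    attr(kg, "load_summary") <- list(records = 0L, duplicates = 0L, self_loops = 0L)
    return(kg)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 5L)
  if (length(bad))
    stop("malformed record at line ", line_no[bad[1L]],
         ": expected >= 5 tab-separated fields, got ", nf[bad[1L]])

  rec <- data.frame(
    source_id   = vapply(fields, `[[`, "", 1L),
    source_kind = vapply(fields, `[[`, "", 2L),
    relation    = vapply(fields, `[[`, "", 3L),
    target_id   = vapply(fields, `[[`, "", 4L),
    target_kind = vapply(fields, `[[`, "", 5L),
    provenance  = vapply(fields, function(f)
      if (length(f) >= 6L && nzchar(f[[6L]])) f[[6L]] else default_provenance, ""),
    stringsAsFactors = FALSE
  )
  bad_rel <- which(!nzchar(rec$relation))
  if (length(bad_rel))
    stop("malformed record at line ", line_no[bad_rel[1L]],
         ": empty relation label")
  bad_prov <- which(!rec$provenance %in% PROVENANCE_LEVELS)
  if (length(bad_prov))
    stop("malformed record at line ", line_no[bad_prov[1L]],
         ": provenance must be one of ",
         paste(PROVENANCE_LEVELS, collapse = ", "))

  n_records <- nrow(rec)
  loops <- rec$source_id == rec$target_id
  n_loops <- sum(loops)
  if (n_loops > 0L) {
    message("rejected ", n_loops, " self-loop record(s) at line(s): ",
            paste(head(line_no[loops], 5L), collapse = ", "))
    rec <- rec[!loops, , drop = FALSE]
  }

  # first-seen kind wins when an id is re-declared with a different kind
  vid <- c(rec$source_id, rec$target_id)
  vkind <- c(rec$source_kind, rec$target_kind)
  first <- !duplicated(vid)
  vdf <- data.frame(id = vid[first], kind = vkind[first], name = vid[first],
                    stringsAsFactors = FALSE)
  new_iso <- !iso$id %in% vdf$id
  if (any(new_iso))
    vdf <- rbind(vdf, data.frame(id = iso$id[new_iso], kind = iso$kind[new_iso],
                                 name = iso$id[new_iso], stringsAsFactors = FALSE))
  conflict <- tapply(vkind, vid, function(k) length(unique(k)) > 1L)
  if (any(conflict))
    warning("vertex id(s) declared with conflicting kinds (first kind kept): ",
            paste(head(names(conflict)[conflict], 5L), collapse = ", "))

  edf <- data.frame(source = rec$source_id, target = rec$target_id,
                    relation = rec$relation, provenance = rec$provenance,
                    stringsAsFactors = FALSE)
  n_dup <- nrow(edf) - nrow(unique(edf))

  kg <- knowledge_graph(vdf, edf)
  attr(kg, "load_summary") <- list(records = n_records,
                                   duplicates = as.integer(n_dup),
                                   self_loops = as.integer(n_loops))
  kg
}

#' Write a knowledge graph as a TSV edge list
#'
#' Emits the same dialect [read_knowledge_graph()] consumes, so graphs
#' round-trip exactly (the writer uses the canonical edge order, making the
#' output byte-reproducible).
#'
#' @param kg a [knowledge_graph].
#' @param path output path.
#' @export
write_knowledge_graph <- function(kg, path) {
  stopifnot(inherits(kg, "knowledge_graph"))
  kind <- setNames(kg$vertices$kind, kg$vertices$id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# source_id\tsource_kind\trelation\ttarget_id\ttarget_kind\tprovenance", con)
  if (nrow(kg$edges) > 0L) {
    writeLines(paste(kg$edges$source, kind[kg$edges$source], kg$edges$relation,
                     kg$edges$target, kind[kg$edges$target], kg$edges$provenance,
                     sep = "\t"), con)
  }
  # isolated vertices carry no edge record; emit a degenerate comment so ids
  # with zero degree are not silently lost
  iso <- setdiff(kg$vertices$id, c(kg$edges$source, kg$edges$target))
  if (length(iso))
    writeLines(paste0("#vertex\t", iso, "\t", kind[iso]), con)
  invisible(path)
}

#' Restrict a knowledge graph to edges of a given provenance
#'
#' @param kg a [knowledge_graph].
#' @param provenance `"both"` (no filtering), `"literature"` or
#'   `"factual_database"`.
#' @return A [knowledge_graph] with the same vertex set and the retained edges.
#' @export
filter_provenance <- function(kg, provenance = c("both", PROVENANCE_LEVELS)) {
  stopifnot(inherits(kg, "knowledge_graph"))
  provenance <- match.arg(provenance)
  if (provenance == "both") return(kg)
  knowledge_graph(kg$vertices,
                  kg$edges[kg$edges$provenance == provenance, , drop = FALSE])
}

#' Distinct-neighbour degree of a vertex
#'
#' Number of distinct vertices adjacent to `vertex`. Parallel edges carrying
#' different relation labels between the same pair count once: connectivity is
#' defined over vertices, not edge records.
#'
#' @param graph a [knowledge_graph] or [gene_network].
#' @param vertex vertex id.
#' @return Integer count of distinct neighbours.
#' @export
degree_of <- function(graph, vertex) {
  g <- graph$graph
  if (!vertex %in% igraph::V(g)$name)
    stop("unknown vertex: ", vertex)
  length(unique(igraph::neighbors(g, vertex)$name))
}

adjacency_sets <- function(kg) {
  # named list: vertex id -> character vector of distinct neighbours
  el <- kg$edges[, c("source", "target")]
  both <- rbind(el, data.frame(source = el$target, target = el$source))
  both <- unique(both)
  split(both$target, factor(both$source, levels = kg$vertices$id))
}
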