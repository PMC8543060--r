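#' Construct an associative gene network
#'
#' The reconstructed per-seed subnetwork: the gene/protein vertices annotated
#' to the seed biological process (the members, `M` in total) and the edges of
#' the knowledge graph running among them. The seed itself is not a member.
#'
#' @param seed_process id of the seed biological-process vertex.
#' @param vertices data.frame (`id`, `kind`, `name`) of the member vertices.
#' @param edges data.frame (`source`, `target`, `relation`, `provenance`) of
#'   member-member edges.
#' @return An object of class `gene_network` with components `seed_process`,
#'   `members` (sorted ids), `M`, `vertices`, `edges`, `graph`.
#' @export
gene_network <- function(seed_process, vertices, edges) {
  stopifnot(is.character(seed_process), length(seed_process) == 1L,
            nzchar(seed_process))
  if (nrow(vertices) < 1L)
    stop("empty network: an associative gene network needs at least one member (M >= 1)")
  if (seed_process %in% vertices$id)
    stop("seed process must not be a network member")
  kg <- knowledge_graph(vertices, edges)  # reuses endpoint/self-loop validation
  structure(
    list(seed_process = seed_process,
         members = kg$vertices$id,
         M = nrow(kg$vertices),
         vertices = kg$vertices,
         edges = kg$edges,
         graph = kg$graph),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Associative gene network for seed process", x$seed_process, "\n")
  cat("  M =", x$M, "member vertices,", nrow(x$edges), "internal edges\n")
  invisible(x)
}

#' Write a reconstructed network to disk
#'
#' GraphML keeps `kind` and `name` vertex attributes, `relation` and
#' `provenance` edge attributes, and the seed process as a graph attribute.
#' The TSV dump uses one `V` record per member (`id`, `kind`, `name`) and one
#' `E` record per internal edge, with the seed in a `#seed_process` header
#' line. Both formats round-trip through [read_network()].
#'
#' @param net a [gene_network].
#' @param path output path.
#' @param format `"graphml"` or `"tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net$graph
    g <- igraph::set_graph_attr(g, "seed_process", net$seed_process)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("#seed_process\t", net$seed_process), con)
    writeLines(paste("V", net$vertices$id, net$vertices$kind,
                     net$vertices$name, sep = "\t"), con)
    if (nrow(net$edges) > 0L)
      writeLines(paste("E", net$edges$source, net$edges$target,
                       net$edges$relation, net$edges$provenance,
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path input path.
#' @param format `"graphml"` or `"tsv"`; inferred from the file extension when
#'   omitted.
#' @return A [gene_network].
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.graphml$|\\.xml$", path)) "graphml" else "tsv"
  format <- match.arg(format, c("graphml", "tsv"))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    seed <- igraph::graph_attr(g, "seed_process")
    v <- data.frame(id = igraph::V(g)$name,
                    kind = igraph::V(g)$kind,
                    name = if ("vname" %in% igraph::vertex_attr_names(g))
                      igraph::V(g)$vname else igraph::V(g)$name,
                    stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    e <- data.frame(source = el[, 1L], target = el[, 2L],
                    relation = if (igraph::ecount(g)) igraph::E(g)$relation else character(),
                    provenance = if (igraph::ecount(g)) igraph::E(g)$provenance else character(),
                    stringsAsFactors = FALSE)
    return(gene_network(seed, v, e))
  }
  lines <- readLines(path, warn = FALSE)
  seed_line <- grep("^#seed_process\t", lines, value = TRUE)
  if (length(seed_line) != 1L)
    stop("network TSV lacks the #seed_process header: ", path)
  seed <- sub("^#seed_process\t", "", seed_line)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[[`, "", 1L)
  vf <- fields[tag == "V"]
  ef <- fields[tag == "E"]
  v <- data.frame(id = vapply(vf, `[[`, "", 2L),
                  kind = vapply(vf, `[[`, "", 3L),
                  name = vapply(vf, `[[`, "", 4L),
                  stringsAsFactors = FALSE)
  e <- data.frame(source = vapply(ef, `[[`, "", 2L),
                  target = vapply(ef, `[[`, "", 3L),
                  relation = vapply(ef, `[[`, "", 4L),
                  provenance = vapply(ef, `[[`, "", 5L),
                  stringsAsFactors = FALSE)
  gene_network(seed, v, e)
}
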