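#' Pairwise Wang similarity matrix of a set of processes
#'
#' Symmetric matrix of Wang semantic similarities with unit diagonal.
#' Processes absent from the ontology (dictionary and ontology releases
#' drift) get similarity 0 to everything, with a warning.
#'
#' @param dag an [ontology_dag].
#' @param processes character vector of term ids (at least one).
#' @param weights per-relation contribution weights, see [svalues()].
#' @return A numeric matrix with `processes` as dimnames, class
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(dag, processes,
                              weights = DEFAULT_SEMANTIC_WEIGHTS) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (length(processes) == 0L) stop("empty process list")
  if (anyDuplicated(processes)) stop("duplicated process ids")
  known <- processes %in% dag$terms$id
  if (any(!known))
    warning(sum(!known), " process(es) absent from the ontology get ",
            "similarity 0: ", paste(head(processes[!known], 5L), collapse = ", "))
  sv <- setNames(vector("list", length(processes)), processes)
  sv[known] <- lapply(processes[known], svalues, dag = dag, weights = weights)

  n <- length(processes)
  m <- diag(1, n)
  dimnames(m) <- list(processes, processes)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (!known[i]) next
      for (j in seq((i + 1L), n)) {
        if (!known[j]) next
        m[i, j] <- m[j, i] <- wang_from_svalues(sv[[i]], sv[[j]])
      }
    }
  }
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Write a similarity matrix as TSV
#'
#' @param sim matrix from [similarity_matrix()].
#' @param path file path.
#' @export
write_similarity_matrix <- function(sim, path) {
  df <- data.frame(process_id = rownames(sim), unclass(sim),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_similarity <- function(sim) {
  sim <- unclass(as.matrix(sim))
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (is.null(rownames(sim))) stop("similarity matrix needs row/column ids")
  if (max(abs(sim - t(sim))) > 1e-12) stop("similarity matrix must be symmetric")
  if (any(sim < 0) || any(sim > 1)) stop("similarities must lie in [0, 1]")
  if (any(abs(diag(sim) - 1) > 1e-12)) stop("similarity diagonal must be 1")
  sim
}

#' Markov clustering of processes by semantic similarity
#'
#' Runs the Markov Cluster algorithm on the weighted similarity graph:
#' column-normalise the matrix (unit diagonal acts as the self-loop), then
#' alternate expansion (matrix power) and inflation (element-wise power
#' followed by column renormalisation) with pruning of small entries until
#' the iterate stabilises. Attractors (rows keeping mass on the diagonal)
#' define the clusters; overlapping attractor systems merge. A node left
#' without an attractor joins the cluster of its most similar neighbour, or
#' becomes a singleton if it has none. Deterministic for fixed input and
#' parameters.
#'
#' @param sim symmetric similarity matrix in \[0, 1\] with unit diagonal and
#'   row/column ids.
#' @param inflation inflation exponent, > 1; default 2.
#' @param expansion expansion power (integer >= 2); default 2.
#' @param self_loop weight put on the diagonal before normalisation; default 1.
#' @param sim_threshold off-diagonal similarities below this are zeroed before
#'   clustering; default 0 (no thresholding).
#' @param prune entries below this are zeroed after each inflation; default 1e-5.
#' @param tol convergence tolerance on the max absolute change; default 1e-8.
#' @param max_iter iteration cap; non-convergence yields a warning and the
#'   clustering of the last iterate.
#' @return List of class `cluster_assignment`: `mapping` (named integer,
#'   process id -> cluster label 1..n_clusters, no gaps), `n_clusters`,
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(sim, inflation = 2, expansion = 2L, self_loop = 1,
                        sim_threshold = 0, prune = 1e-5, tol = 1e-8,
                        max_iter = 200L) {
  sim <- validate_similarity(sim)
  stopifnot(inflation > 1, expansion >= 2L, self_loop > 0)
  ids <- rownames(sim)
  n <- length(ids)

  a <- sim
  if (sim_threshold > 0) a[a < sim_threshold] <- 0
  diag(a) <- self_loop
  colnorm <- function(m) {
    cs <- colSums(m)
    dead <- cs == 0
    if (any(dead)) {             # re-seed a starved column on its own node
      m[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    sweep(m, 2L, cs, "/")
  }
  m <- colnorm(a)

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mx <- m
    for (k in seq_len(expansion - 1L)) mx <- mx %*% m   # expansion
    mx <- mx ^ inflation                                # inflation
    mx[mx < prune] <- 0
    mx <- colnorm(mx)
    delta <- max(abs(mx - m))
    m <- mx
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering the last iterate")

  eps <- 1e-6
  attractors <- which(diag(m) > eps)
  labels <- integer(n)
  if (length(attractors)) {
    # attractor i claims every column j it keeps mass on; overlapping
    # attractor systems are merged via connected components
    edges <- do.call(rbind, lapply(attractors, function(i) {
      j <- which(m[i, ] > eps)
      cbind(i, j)
    }))
    g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2L),
                                     directed = FALSE)
    comp <- igraph::components(g)$membership
    covered <- as.integer(names(comp))
    labels[covered] <- comp
  }
  orphan <- which(labels == 0L)
  for (i in orphan) {
    s <- sim[i, ]
    s[i] <- 0
    s[labels[seq_len(n)] == 0L] <- 0   # only join already-clustered nodes
    if (max(s) > 0) labels[i] <- labels[which.max(s)]
  }
  still <- which(labels == 0L)
  if (length(still))
    labels[still] <- max(labels, 0L) + seq_along(still)

  # relabel 1..k in order of first appearance for determinism
  labels <- match(labels, unique(labels))
  structure(list(mapping = setNames(as.integer(labels), ids),
                 n_clusters = length(unique(labels)),
                 converged = converged, iterations = it),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("MCL clustering:", length(x$mapping), "processes in", x$n_clusters,
      "clusters (", if (x$converged) "converged" else "not converged",
      "after", x$iterations, "iterations )\n")
  invisible(x)
}

#' Write a cluster assignment as TSV
#'
#' @param assignment a `cluster_assignment` from [mcl_cluster()].
#' @param path file path.
#' @export
write_clusters <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- data.frame(process_id = names(assignment$mapping),
                   cluster_label = unname(assignment$mapping),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the similarity graph with cluster labels as GraphML
#'
#' One vertex per process (attribute `cluster`), one weighted edge per
#' non-zero off-diagonal similarity.
#'
#' @param sim matrix from [similarity_matrix()].
#' @param assignment matching `cluster_assignment`.
#' @param path file path.
#' @export
write_similarity_graph <- function(sim, assignment, path) {
  sim <- validate_similarity(sim)
  ids <- rownames(sim)
  stopifnot(identical(sort(ids), sort(names(assignment$mapping))))
  idx <- which(upper.tri(sim) & sim > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                   weight = sim[idx], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(id = ids,
                          cluster = unname(assignment$mapping[ids]),
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
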