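#' Compare significant-process sets across several networks
#'
#' Given prioritization rankings for two or more conditions (seed networks),
#' derives each condition's significant set (`q_value < alpha`), the common
#' core shared by all conditions, every pairwise intersection, and the
#' condition-specific remainders (significant in exactly one condition).
#' Processes are matched across conditions by term id.
#'
#' @param rankings named list (>= 2 conditions) of ranking data.frames from
#'   [prioritize()].
#' @param alpha significance threshold on the q-value; default 0.05.
#' @return Object of class `comparison_result`: `condition_names`,
#'   `per_condition_significant` (named list of id sets), `common_all`,
#'   `pairwise_common` (named list, names `"a|b"`), `specific` (named list).
#' @export
compare_networks <- function(rankings, alpha = 0.05) {
  if (!is.list(rankings) || length(rankings) < 2L)
    stop("need at least 2 conditions to compare")
  if (is.null(names(rankings)) || any(!nzchar(names(rankings))) ||
      anyDuplicated(names(rankings)))
    stop("rankings must be uniquely named by condition")
  conds <- names(rankings)
  sig <- lapply(rankings, function(r) sort(significant(r, alpha)$process_id))

  common_all <- Reduce(intersect, sig)
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  pairwise <- setNames(
    lapply(pairs, function(p) intersect(sig[[p[1L]]], sig[[p[2L]]])),
    vapply(pairs, paste, "", collapse = "|"))
  specific <- setNames(lapply(conds, function(cn) {
    others <- unique(unlist(sig[setdiff(conds, cn)]))
    setdiff(sig[[cn]], others)
  }), conds)

  structure(list(condition_names = conds,
                 per_condition_significant = sig,
                 common_all = common_all,
                 pairwise_common = pairwise,
                 specific = specific,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Comparison of", length(x$condition_names), "networks (alpha =",
      x$alpha, ")\n")
  for (cn in x$condition_names)
    cat("  ", cn, ": ", length(x$per_condition_significant[[cn]]),
        " significant, ", length(x$specific[[cn]]), " specific\n", sep = "")
  cat("  common to all:", length(x$common_all), "\n")
  invisible(x)
}

#' Write a comparison report as TSV
#'
#' One row per process significant in at least one condition: `process_id`,
#' a 0/1 significance column per condition, and a `category` column —
#' `common_all`, `specific:<condition>`, or `pairwise` (significant in more
#' than one but not all conditions).
#'
#' @param result a `comparison_result`.
#' @param path file path.
#' @export
report_comparison <- function(result, path) {
  stopifnot(inherits(result, "comparison_result"))
  sig <- result$per_condition_significant
  ids <- sort(unique(unlist(sig)))
  member <- vapply(sig, function(s) ids %in% s,
                   logical(length(ids)))
  member <- matrix(member, nrow = length(ids),
                   dimnames = list(NULL, names(sig)))
  n_in <- rowSums(member)
  category <- ifelse(ids %in% result$common_all, "common_all",
              ifelse(n_in == 1L,
                     paste0("specific:",
                            names(sig)[apply(member, 1L, which.max)]),
                     ifelse(n_in > 1L, "pairwise", "other")))
  df <- data.frame(process_id = ids, member + 0L, category,
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
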