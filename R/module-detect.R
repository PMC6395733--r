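# Module detection: significance networks over a ladder of p-value
# thresholds, maximal-clique enumeration, and assembly of the deduplicated,
# support-filtered module list.

#' Build a significance network at one threshold
#'
#' Undirected simple graph on the tested smCOGs, with an edge wherever a
#' pair is significant at `threshold` by *either* interaction kind (the
#' smaller of the pair's adjusted adjacency/colocalization p-values is
#' compared against the threshold).
#'
#' @param results Interaction table from [test_all_pairs()] (adjusted
#'   p-values required).
#' @param threshold Significance cutoff in (0, 1\].
#' @return An [igraph::igraph] graph; vertices are smCOG ids, edges carry
#'   the deciding adjusted p-value as attribute `p_adjusted`.
#' @export
build_network <- function(results, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort_bgc("threshold must be a single value in (0, 1]",
              "bgc_validation_error")
  }
  best <- results |>
    dplyr::group_by(.data$cog_a, .data$cog_b) |>
    dplyr::summarise(p_adjusted = min(.data$p_adjusted), .groups = "drop")
  edges <- best[best$p_adjusted <= threshold, ]
  nodes <- sort(unique(c(results$cog_a, results$cog_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("cog_a", "cog_b", "p_adjusted")],
    directed = FALSE, vertices = nodes
  )
  g$threshold <- threshold
  g
}

#' Enumerate maximal cliques of a significance network
#'
#' A maximal clique is a fully connected subgraph not contained in any
#' larger fully connected subgraph; each one whose size reaches `min_size`
#' is a putative module at this threshold. Enumeration is delegated to
#' igraph's Bron-Kerbosch-family implementation; output is sorted for
#' determinism (members sorted within each clique, cliques sorted
#' lexicographically).
#'
#' @param network Graph from [build_network()].
#' @param min_size Minimum clique size (default 3).
#' @return A list of character vectors of smCOG ids.
#' @export
maximal_cliques <- function(network, min_size = 3) {
  cliques <- igraph::max_cliques(network, min = min_size)
  cliques <- lapply(cliques, function(cl) sort(igraph::V(network)$name[cl]))
  keys <- vapply(cliques, paste, "", collapse = "\r")
  cliques[order(keys)]
}

#' Ladder of detection thresholds
#'
#' Every distinct adjusted p-value at or below `cap` is used in turn as the
#' significance threshold; modules are whatever emerges as a maximal
#' clique at any rung. `max_steps` optionally subsamples the ladder evenly
#' by rank (always keeping the smallest and largest rung) as a performance
#' knob; the default is the full ladder.
#'
#' @param results Interaction table from [test_all_pairs()].
#' @param cap Largest threshold considered (default 0.1).
#' @param max_steps Maximum number of rungs, or `Inf` for all.
#' @return Ascending numeric vector of thresholds (possibly empty).
#' @export
threshold_ladder <- function(results, cap = 0.1, max_steps = Inf) {
  ladder <- sort(unique(results$p_adjusted[results$p_adjusted <= cap]))
  if (is.finite(max_steps) && length(ladder) > max_steps) {
    idx <- unique(round(seq(1, length(ladder), length.out = max_steps)))
    ladder <- ladder[idx]
  }
  ladder
}

#' Detect putative modules
#'
#' Iterates over the threshold ladder, collecting all maximal cliques of
#' size `min_size` or more at each rung. A module's identity is its smCOG
#' set: the same set emitted at several thresholds is one module recorded
#' with the smallest (strictest) emitting threshold. A set emitted at one
#' rung may be a subset of a clique at a more lenient rung; both survive
#' as distinct (nested) modules. Modules contained in fewer than
#' `min_support` clusters — where a cluster contains a module when every
#' member smCOG occurs somewhere in it — are removed as likely false
#' positives.
#'
#' @param results Interaction table from [test_all_pairs()].
#' @param dataset The `bgc_dataset` the results were computed from (used
#'   for support counting).
#' @param cap Threshold-ladder cap (default 0.1).
#' @param min_size Minimum module size (default 3).
#' @param min_support Minimum number of supporting clusters (default 2).
#' @param max_steps Ladder subsampling knob, see [threshold_ladder()].
#' @return A tibble with one row per module: `module_id`, list-column
#'   `smcogs` (sorted members), `size`, `strictest_threshold`, list-column
#'   `supporting_clusters`, `n_bgc`; sorted by ascending strictest
#'   threshold, then descending size, then member key. Module ids are
#'   assigned in that order, so they are stable across reruns.
#' @export
detect_modules <- function(results, dataset, cap = 0.1, min_size = 3,
                           min_support = 2, max_steps = Inf) {
  ladder <- threshold_ladder(results, cap = cap, max_steps = max_steps)
  seen <- list()
  strictest <- numeric()
  for (thr in ladder) {
    g <- build_network(results, thr)
    for (cl in maximal_cliques(g, min_size = min_size)) {
      key <- paste(cl, collapse = "\r")
      if (is.null(seen[[key]])) {
        seen[[key]] <- cl
        strictest[[key]] <- thr
      }
    }
  }
  if (length(seen) == 0) {
    return(tibble::tibble(
      module_id = character(), smcogs = list(), size = integer(),
      strictest_threshold = double(), supporting_clusters = list(),
      n_bgc = integer()
    ))
  }
  membership <- dataset$genes |>
    dplyr::filter(!is_unassigned(.data$smcog_id)) |>
    dplyr::distinct(.data$cluster_id, .data$smcog_id)
  by_cog <- split(membership$cluster_id, membership$smcog_id)

  keys <- names(seen)
  support <- lapply(keys, function(k) {
    sort(Reduce(intersect, by_cog[seen[[k]]]))
  })
  modules <- tibble::tibble(
    smcogs = unname(seen[keys]),
    size = lengths(seen[keys]),
    strictest_threshold = unname(strictest[keys]),
    supporting_clusters = support,
    n_bgc = lengths(support),
    key = keys
  )
  modules <- modules[modules$n_bgc >= min_support, ]
  modules <- modules[order(modules$strictest_threshold, -modules$size,
                           modules$key), ]
  modules$key <- NULL
  modules$module_id <- sprintf("M%05d", seq_len(nrow(modules)))
  modules[, c("module_id", "smcogs", "size", "strictest_threshold",
              "supporting_clusters", "n_bgc")]
}

#' Export per-threshold edge lists
#'
#' Writes one TSV per ladder rung with the significant pairs at that
#' threshold (`cog_a`, `cog_b`, `p_adjusted`).
#'
#' @param results Interaction table from [test_all_pairs()].
#' @param dir Output directory (created if needed).
#' @param cap,max_steps Ladder parameters, see [threshold_ladder()].
#' @return Paths of the written files, invisibly.
#' @export
write_edge_lists <- function(results, dir, cap = 0.1, max_steps = Inf) {
  ladder <- threshold_ladder(results, cap = cap, max_steps = max_steps)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(ladder))
  for (i in seq_along(ladder)) {
    g <- build_network(results, ladder[i])
    edges <- igraph::as_data_frame(g, what = "edges")
    names(edges) <- c("cog_a", "cog_b", "p_adjusted")
    paths[i] <- file.path(dir, sprintf("edges_threshold_%03d.tsv", i))
    readr::write_tsv(tibble::as_tibble(edges), paths[i], progress = FALSE)
  }
  invisible(paths)
}
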