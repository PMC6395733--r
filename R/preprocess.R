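# Data conditioning: cluster trimming, smCOG size filtering, redundant
# cluster removal, and smCOG category annotation.

#' Trim low-probability genes from cluster extremes
#'
#' Predicted cluster boundaries are typically greedy, so clusters carry
#' flanking genes unlikely to be part of the biosynthetic unit. Trimming
#' removes genes from each end of a cluster, scanning strictly inward,
#' while their probability of carrying a biosynthesis-associated domain is
#' below `threshold`; the scan stops at the first gene meeting the
#' threshold, so interior low-probability genes always survive. Positions
#' are re-indexed densely afterwards.
#'
#' Clusters with any missing `domain_prob` are returned unchanged (the
#' probabilities are an optional input).
#'
#' @param dataset A `bgc_dataset`.
#' @param threshold Trimming threshold on `domain_prob` (default 0.1;
#'   raising it further has little effect in practice).
#' @return A list with `dataset` (trimmed, clusters that lost all genes
#'   dropped) and `report` (a [preprocess_report()]).
#' @export
trim_clusters <- function(dataset, threshold = 0.1) {
  genes <- dataset$genes
  keep <- rep(TRUE, nrow(genes))
  for (cid in unique(genes$cluster_id)) {
    idx <- which(genes$cluster_id == cid)
    idx <- idx[order(genes$position[idx])]
    p <- genes$domain_prob[idx]
    if (anyNA(p)) next
    lo <- 1L
    while (lo <= length(p) && p[lo] < threshold) lo <- lo + 1L
    hi <- length(p)
    while (hi >= lo && p[hi] < threshold) hi <- hi - 1L
    if (lo > 1L) keep[idx[seq_len(lo - 1L)]] <- FALSE
    if (hi < length(p)) keep[idx[seq(hi + 1L, length(p))]] <- FALSE
  }
  trimmed <- genes[keep, ]
  surviving <- unique(trimmed$cluster_id)
  dropped <- setdiff(unique(genes$cluster_id), surviving)
  trimmed <- reindex_positions(trimmed)
  out <- bgc_dataset(
    trimmed,
    dataset$clusters[dataset$clusters$cluster_id %in% surviving, ],
    provenance = dataset$provenance
  )
  report <- preprocess_report(
    genes_trimmed = sum(!keep),
    clusters_dropped_empty = length(dropped)
  )
  list(dataset = out, report = report)
}

reindex_positions <- function(genes) {
  genes |>
    dplyr::arrange(.data$cluster_id, .data$position) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::mutate(position = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
}

#' Remove under-populated smCOGs
#'
#' Orthogroups with fewer than `min_members` member genes across the whole
#' dataset carry too little signal to test and are removed; their genes are
#' relabelled [UNASSIGNED] but stay in place, so positional structure is
#' preserved. Clusters left without any assigned gene are dropped.
#'
#' @param dataset A `bgc_dataset`.
#' @param min_members Minimum member count for an smCOG to be kept
#'   (default 3; an smCOG with exactly `min_members` genes is retained).
#' @return A list with `dataset` and `report`.
#' @export
filter_smcogs <- function(dataset, min_members = 3) {
  genes <- dataset$genes
  assigned <- genes$smcog_id[!is_unassigned(genes$smcog_id)]
  counts <- table(assigned)
  small <- names(counts)[counts < min_members]
  hit <- genes$smcog_id %in% small
  genes$smcog_id[hit] <- UNASSIGNED

  has_assigned <- genes |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(any_cog = any(!is_unassigned(.data$smcog_id)),
                     .groups = "drop")
  empty <- has_assigned$cluster_id[!has_assigned$any_cog]
  genes <- genes[!genes$cluster_id %in% empty, ]

  out <- bgc_dataset(
    genes,
    dataset$clusters[!dataset$clusters$cluster_id %in% empty, ],
    provenance = dataset$provenance
  )
  report <- preprocess_report(
    smcogs_removed = length(small),
    genes_unassigned_after_filter = sum(hit),
    clusters_dropped_empty = length(empty)
  )
  list(dataset = out, report = report)
}

#' Remove clusters with redundant smCOG composition
#'
#' Clusters are grouped by their smCOG composition as a *multiset*
#' (unassigned genes excluded; copy numbers matter, so \{A,A,B\} and
#' \{A,B\} are distinct compositions). Within each group only the cluster
#' with the fewest total genes is kept; ties are broken by the
#' lexicographically smallest cluster id.
#'
#' @param dataset A `bgc_dataset` (apply [filter_smcogs()] first).
#' @return A list with `dataset` and `report`.
#' @export
dedupe_clusters <- function(dataset) {
  genes <- dataset$genes
  comp <- genes |>
    dplyr::filter(!is_unassigned(.data$smcog_id)) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(key = paste(sort(.data$smcog_id), collapse = "\r"),
                     .groups = "drop")
  sizes <- genes |>
    dplyr::count(.data$cluster_id, name = "n_genes")
  comp <- dplyr::left_join(comp, sizes, by = "cluster_id") |>
    dplyr::arrange(.data$key, .data$n_genes, .data$cluster_id)
  keep_ids <- comp$cluster_id[!duplicated(comp$key)]
  # clusters with no assigned genes at all have no composition key; keep them
  keep_ids <- c(keep_ids, setdiff(unique(genes$cluster_id), comp$cluster_id))

  dropped <- setdiff(unique(genes$cluster_id), keep_ids)
  out <- bgc_dataset(
    genes[genes$cluster_id %in% keep_ids, ],
    dataset$clusters[dataset$clusters$cluster_id %in% keep_ids, ],
    provenance = dataset$provenance
  )
  report <- preprocess_report(clusters_dropped_redundant = length(dropped))
  list(dataset = out, report = report)
}

#' Annotate an smCOG with a functional category
#'
#' Derives the smCOG-level category from its members' gene-level
#' categories. The rules, applied in order on the category shares:
#' \enumerate{
#'   \item if the most common category is "other" and the second most
#'     common exceeds 40\%, use the second (this takes precedence even
#'     when "other" itself exceeds 60\%);
#'   \item if the most common category exceeds 60\%, use it;
#'   \item if the top category is below 60\% but top and second together
#'     exceed 75\%, use the double category `"top/second"`;
#'   \item otherwise, `"mixed"`.
#' }
#' All comparisons are strict. Exact ties between shares are broken by the
#' fixed priority core > tailoring > transport > regulator > other.
#'
#' @param member_categories Character vector of gene-level categories
#'   (members of [GENE_CATEGORIES]); unassigned genes should be excluded
#'   before calling.
#' @return A single category string, possibly a double category or
#'   `"mixed"`.
#' @export
annotate_smcog_category <- function(member_categories) {
  if (length(member_categories) == 0) {
    abort_bgc("cannot annotate an smCOG with no members", "bgc_validation_error")
  }
  unknown <- setdiff(unique(member_categories), GENE_CATEGORIES)
  if (length(unknown) > 0) {
    abort_bgc(paste0("unknown gene category: ", paste(unknown, collapse = ", ")),
              "bgc_validation_error")
  }
  share <- table(factor(member_categories, levels = CATEGORY_PRIORITY))
  share <- as.numeric(share) / length(member_categories) * 100
  names(share) <- CATEGORY_PRIORITY
  ord <- order(-share, match(names(share), CATEGORY_PRIORITY))
  top <- names(share)[ord[1]]
  second <- names(share)[ord[2]]
  s_top <- share[[ord[1]]]
  s_second <- share[[ord[2]]]

  if (top == "other" && s_second > 40) return(second)
  if (s_top > 60) return(top)
  if (s_top + s_second > 75) return(paste(top, second, sep = "/"))
  "mixed"
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: end trimming ([trim_clusters()]), smCOG size
#' filtering ([filter_smcogs()]), and redundant-cluster removal
#' ([dedupe_clusters()]), accumulating one bookkeeping report.
#'
#' @param dataset A `bgc_dataset`.
#' @param trim_threshold Domain-probability threshold for end trimming.
#' @param min_members Minimum smCOG member count.
#' @return A list with the conditioned `dataset` and the combined `report`.
#' @export
preprocess_dataset <- function(dataset, trim_threshold = 0.1, min_members = 3) {
  s1 <- trim_clusters(dataset, threshold = trim_threshold)
  s2 <- filter_smcogs(s1$dataset, min_members = min_members)
  s3 <- dedupe_clusters(s2$dataset)
  list(
    dataset = s3$dataset,
    report = combine_reports(s1$report, s2$report, s3$report)
  )
}

#' Preprocessing bookkeeping report
#'
#' Counts of what each conditioning stage removed, mirroring the dataset
#' size changes; all counts are non-negative.
#'
#' @param genes_trimmed,smcogs_removed,genes_unassigned_after_filter,clusters_dropped_empty,clusters_dropped_redundant
#'   Non-negative counts.
#' @return A list of class `preprocess_report`.
#' @export
preprocess_report <- function(genes_trimmed = 0L, smcogs_removed = 0L,
                              genes_unassigned_after_filter = 0L,
                              clusters_dropped_empty = 0L,
                              clusters_dropped_redundant = 0L) {
  report <- list(
    genes_trimmed = as.integer(genes_trimmed),
    smcogs_removed = as.integer(smcogs_removed),
    genes_unassigned_after_filter = as.integer(genes_unassigned_after_filter),
    clusters_dropped_empty = as.integer(clusters_dropped_empty),
    clusters_dropped_redundant = as.integer(clusters_dropped_redundant)
  )
  if (any(unlist(report) < 0)) {
    abort_bgc("preprocess report counts must be non-negative",
              "bgc_validation_error")
  }
  structure(report, class = "preprocess_report")
}

combine_reports <- function(...) {
  reports <- list(...)
  out <- Reduce(function(a, b) Map(`+`, a, b), lapply(reports, unclass))
  do.call(preprocess_report, out)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %d\n", nm, x[[nm]]))
  invisible(x)
}
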