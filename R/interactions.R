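# Pairwise smCOG interaction counting. Two interaction kinds:
#   adjacency      — the two orthogroups sit at immediately neighbouring
#                    positions of the same cluster;
#   colocalization — they occur anywhere within the same cluster.
# For significance testing, the genes of one orthogroup ("fixed", COG A)
# stay in place and every remaining position is classified by its exposure
# to COG A; the other orthogroup ("moving", COG B) is the one treated as
# randomly placed.

#' Pairwise position-class profile
#'
#' The sufficient statistics of one ordered smCOG pair for one interaction
#' kind: per-class position capacities (how many available positions have a
#' given exposure to the fixed orthogroup), per-class occupancies (how many
#' moving-orthogroup genes actually sit in each class), totals, and the
#' observed interaction count.
#'
#' For adjacency the classes are positions adjacent to 0, 1 or 2 fixed-COG
#' genes and the interaction count is `B_b + 2 * B_c`; for colocalization
#' (computed on duplicate-collapsed clusters) the classes are positions
#' outside/inside fixed-COG-containing clusters and the count is `B_b`.
#' Positions occupied by fixed-COG genes are not available; positions
#' holding unassigned genes are.
#'
#' @param fixed_cog,moving_cog smCOG identifiers.
#' @param kind `"adjacency"` or `"colocalization"`.
#' @param capacities Named integer vector of per-class position counts
#'   (`N_a`, `N_b` and, for adjacency, `N_c`).
#' @param occupancies Named integer vector of per-class moving-gene counts
#'   (`B_a`, `B_b`(, `B_c`)).
#' @return A validated object of class `pair_profile`.
#' @export
pair_profile <- function(fixed_cog, moving_cog, kind, capacities, occupancies) {
  x <- structure(
    list(
      fixed_cog = fixed_cog, moving_cog = moving_cog, kind = kind,
      capacities = capacities, occupancies = occupancies,
      N_tot = sum(capacities), B_tot = sum(occupancies)
    ),
    class = "pair_profile"
  )
  validate_pair_profile(x)
  x$i_orig <- sum(interaction_weights(kind) * occupancies)
  x
}

# Interactions contributed by one moving gene in each class.
interaction_weights <- function(kind) {
  switch(kind,
    adjacency = c(0, 1, 2),
    colocalization = c(0, 1),
    abort_bgc(paste0("unknown interaction kind: ", kind), "bgc_validation_error")
  )
}

validate_pair_profile <- function(x) {
  k <- length(interaction_weights(x$kind))
  if (length(x$capacities) != k || length(x$occupancies) != k) {
    abort_bgc(sprintf("%s profile needs %d classes", x$kind, k),
              "bgc_validation_error")
  }
  if (any(x$occupancies > x$capacities)) {
    abort_bgc("class occupancy exceeds capacity", "bgc_validation_error")
  }
  if (any(x$capacities < 0) || any(x$occupancies < 0)) {
    abort_bgc("negative class count", "bgc_validation_error")
  }
  invisible(x)
}

#' @export
print.pair_profile <- function(x, ...) {
  cat(sprintf("<pair_profile> %s: %s (fixed) vs %s (moving)\n",
              x$kind, x$fixed_cog, x$moving_cog))
  cat(sprintf("  capacities: %s  (N_tot = %d)\n",
              paste(x$capacities, collapse = "/"), x$N_tot))
  cat(sprintf("  occupancies: %s  (B_tot = %d, i_orig = %d)\n",
              paste(x$occupancies, collapse = "/"), x$B_tot, x$i_orig))
  invisible(x)
}

check_pair <- function(dataset, cog_a, cog_b) {
  if (identical(cog_a, cog_b)) {
    abort_bgc("self-pairs are not supported", "bgc_validation_error")
  }
  if (any(is_unassigned(c(cog_a, cog_b)))) {
    abort_bgc("UNASSIGNED is not a testable smCOG", "bgc_validation_error")
  }
  present <- unique(dataset$genes$smcog_id)
  missing <- setdiff(c(cog_a, cog_b), present)
  if (length(missing) > 0) {
    abort_bgc(paste0("smCOG not present in dataset: ",
                     paste(missing, collapse = ", ")),
              "bgc_validation_error")
  }
}

# Number of fixed-COG genes adjacent to each position (left/right neighbour
# within the same cluster; linear topology, no wraparound). `genes` must be
# sorted by (cluster_id, position), which bgc_dataset() guarantees.
neighbour_exposure <- function(genes, cog) {
  n <- nrow(genes)
  left <- c(NA_character_, genes$smcog_id[-n])
  right <- c(genes$smcog_id[-1], NA_character_)
  same_left <- c(FALSE, genes$cluster_id[-1] == genes$cluster_id[-n])
  same_right <- c(genes$cluster_id[-n] == genes$cluster_id[-1], FALSE)
  (same_left & !is.na(left) & left == cog) +
    (same_right & !is.na(right) & right == cog)
}

# Per-fixed-cog state shared by all moving partners of that cog.
adjacency_state <- function(genes, cog) {
  exposure <- neighbour_exposure(genes, cog)
  available <- genes$smcog_id != cog
  cls <- exposure[available] + 1L
  capacities <- tabulate(cls, nbins = 3L)
  names(capacities) <- c("N_a", "N_b", "N_c")
  list(cls = cls, smcog = genes$smcog_id[available], capacities = capacities)
}

adjacency_profile_from_state <- function(state, cog_a, cog_b) {
  occ <- tabulate(state$cls[state$smcog == cog_b], nbins = 3L)
  names(occ) <- c("B_a", "B_b", "B_c")
  pair_profile(cog_a, cog_b, "adjacency", state$capacities, occ)
}

#' Count adjacency interactions for one ordered smCOG pair
#'
#' Fixes `cog_a` in place; every position not occupied by a `cog_a` gene
#' (including positions holding unassigned genes — they are not skipped) is
#' classified by how many of its immediate neighbours are `cog_a` genes.
#' Positions are pooled dataset-wide: the null model redistributes the
#' moving genes over all available positions in the whole collection.
#'
#' @param dataset A `bgc_dataset`.
#' @param cog_a Fixed smCOG.
#' @param cog_b Moving smCOG (must differ from `cog_a`).
#' @return A `pair_profile` of kind `"adjacency"`.
#' @export
count_adjacency <- function(dataset, cog_a, cog_b) {
  check_pair(dataset, cog_a, cog_b)
  adjacency_profile_from_state(adjacency_state(dataset$genes, cog_a),
                               cog_a, cog_b)
}

#' Collapse duplicated smCOG occurrences within clusters
#'
#' When an orthogroup occurs `k >= 2` times in one cluster, its occurrences
#' are replaced in place by empty (unassigned) positions and the `k` genes
#' are re-attached at the end of the cluster, preceded by one empty
#' separator position; duplicated orthogroups are appended in
#' first-occurrence order. The empty positions remain available to the
#' null model, which is what makes colocalization p-values computed on the
#' collapsed data conservative.
#'
#' The transform is applied once per dataset: the result is flagged in its
#' provenance and further calls return it unchanged, so the operation is
#' idempotent. It feeds colocalization counting only — adjacency always
#' uses the original clusters.
#'
#' @param dataset A `bgc_dataset`.
#' @return The collapsed `bgc_dataset`.
#' @export
collapse_duplicates <- function(dataset) {
  if (isTRUE(dataset$provenance$collapsed)) return(dataset)
  genes <- dplyr::arrange(dataset$genes, .data$cluster_id, .data$position)
  pieces <- lapply(split(genes, genes$cluster_id), collapse_one_cluster)
  out <- bgc_dataset(dplyr::bind_rows(pieces), dataset$clusters,
                     provenance = dataset$provenance)
  out$provenance$collapsed <- TRUE
  out
}

collapse_one_cluster <- function(cl) {
  assigned <- cl$smcog_id[!is_unassigned(cl$smcog_id)]
  counts <- table(assigned)
  dups <- names(counts)[counts >= 2]
  if (length(dups) == 0) return(cl)
  dups <- dups[order(match(dups, cl$smcog_id))]  # first-occurrence order

  body <- cl
  moved <- body$smcog_id %in% dups
  blocks <- body[moved, ]
  body$smcog_id[moved] <- UNASSIGNED
  body$gene_id[moved] <- sprintf("%s_emptied%02d", cl$cluster_id[1],
                                 seq_len(sum(moved)))
  body$category[moved] <- "other"
  body$domain_prob[moved] <- NA_real_

  tail_rows <- list()
  for (j in seq_along(dups)) {
    sep <- tibble::tibble(
      cluster_id = cl$cluster_id[1],
      gene_id = sprintf("%s_sep%02d", cl$cluster_id[1], j),
      position = NA_integer_, smcog_id = UNASSIGNED,
      category = "other", domain_prob = NA_real_
    )
    blk <- blocks[blocks$smcog_id == dups[j], ]
    tail_rows[[j]] <- dplyr::bind_rows(sep, blk)
  }
  out <- dplyr::bind_rows(body, dplyr::bind_rows(tail_rows))
  out$position <- seq_len(nrow(out)) - 1L
  out
}

#' Count colocalization interactions for one ordered smCOG pair
#'
#' Operates on duplicate-collapsed clusters (the collapse is applied
#' automatically if the dataset is not yet flagged as collapsed). Available
#' positions split into two classes: those inside clusters containing a
#' `cog_a` gene (excluding the `cog_a` positions themselves) and those in
#' all other clusters. The interaction count is the number of `cog_b`
#' genes co-resident with `cog_a`.
#'
#' @inheritParams count_adjacency
#' @return A `pair_profile` of kind `"colocalization"`.
#' @export
count_colocalization <- function(dataset, cog_a, cog_b) {
  check_pair(dataset, cog_a, cog_b)
  dataset <- collapse_duplicates(dataset)
  colocalization_profile_from_state(
    colocalization_state(dataset$genes, cog_a), cog_a, cog_b
  )
}

colocalization_state <- function(genes, cog) {
  a_clusters <- unique(genes$cluster_id[genes$smcog_id == cog])
  available <- genes$smcog_id != cog
  in_a <- genes$cluster_id %in% a_clusters
  cls <- in_a[available] + 1L
  capacities <- tabulate(cls, nbins = 2L)
  names(capacities) <- c("N_a", "N_b")
  list(cls = cls, smcog = genes$smcog_id[available], capacities = capacities)
}

colocalization_profile_from_state <- function(state, cog_a, cog_b) {
  occ <- tabulate(state$cls[state$smcog == cog_b], nbins = 2L)
  names(occ) <- c("B_a", "B_b")
  pair_profile(cog_a, cog_b, "colocalization", state$capacities, occ)
}

#' Enumerate smCOG pairs worth testing
#'
#' Only pairs that co-occur in at least one cluster can show either kind of
#' interaction, so all other pairs are never tested. Pairs are unordered
#' and listed once with `cog_a < cog_b`.
#'
#' @param dataset A `bgc_dataset`.
#' @return A tibble with columns `cog_a`, `cog_b`, sorted.
#' @export
enumerate_candidate_pairs <- function(dataset) {
  occ <- dataset$genes |>
    dplyr::filter(!is_unassigned(.data$smcog_id)) |>
    dplyr::distinct(.data$cluster_id, .data$smcog_id)
  pairs <- dplyr::inner_join(occ, occ, by = "cluster_id",
                             relationship = "many-to-many",
                             suffix = c("_1", "_2")) |>
    dplyr::filter(.data$smcog_id_1 < .data$smcog_id_2) |>
    dplyr::distinct(cog_a = .data$smcog_id_1, cog_b = .data$smcog_id_2) |>
    dplyr::arrange(.data$cog_a, .data$cog_b)
  pairs
}

#' Export pair profiles as a diagnostic table
#'
#' One row per ordered pair and interaction kind, flattening the class
#' capacities and occupancies.
#'
#' @param profiles A list of `pair_profile` objects.
#' @return A tibble.
#' @export
profile_table <- function(profiles) {
  purrr::map_dfr(profiles, function(p) {
    caps <- as.list(p$capacities)
    occs <- as.list(p$occupancies)
    tibble::tibble(
      fixed_cog = p$fixed_cog, moving_cog = p$moving_cog, kind = p$kind,
      N_a = caps$N_a, N_b = caps$N_b, N_c = caps$N_c %||% NA_integer_,
      B_a = occs$B_a, B_b = occs$B_b, B_c = occs$B_c %||% NA_integer_,
      N_tot = p$N_tot, B_tot = p$B_tot, i_orig = p$i_orig
    )
  })
}
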