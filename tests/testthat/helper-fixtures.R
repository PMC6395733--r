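# Shared fixtures and independent oracles. Everything here is deliberately
# naive (full enumeration, direct recounting) so that it cannot share a bug
# with the implementation under test.

# --- fixtures ---------------------------------------------------------------

# A dataset from a compact notation: list of character vectors of smCOG
# labels ("." = unassigned), one per cluster.
make_dataset <- function(layout, compound_class = NULL, curated = NULL,
                         domain_prob = NULL) {
  cids <- sprintf("c%02d", seq_along(layout))
  genes <- dplyr::bind_rows(lapply(seq_along(layout), function(i) {
    lab <- layout[[i]]
    tibble::tibble(
      cluster_id = cids[i],
      gene_id = sprintf("%s_g%d", cids[i], seq_along(lab)),
      position = seq_along(lab) - 1L,
      smcog_id = ifelse(lab == ".", UNASSIGNED, lab),
      category = "other",
      domain_prob = if (is.null(domain_prob)) NA_real_ else domain_prob[[i]]
    )
  }))
  clusters <- tibble::tibble(
    cluster_id = cids,
    compound_class = compound_class %||% rep("unknown", length(layout)),
    curated_flag = curated %||% rep(FALSE, length(layout)),
    organism = NA_character_
  )
  bgc_dataset(genes, clusters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

layout_of <- function(dataset) {
  lapply(split(dataset$genes, dataset$genes$cluster_id), function(g) {
    lab <- g$smcog_id[order(g$position)]
    ifelse(lab == UNASSIGNED, ".", lab)
  })
}

# Random small dataset: n_clusters clusters of the given lengths over a
# small smCOG alphabet, some positions unassigned.
random_dataset <- function(n_clusters = 5, len_range = c(4, 8), n_cogs = 4,
                           unassigned_rate = 0.25, allow_dups = TRUE) {
  cogs <- LETTERS[seq_len(n_cogs)]
  layout <- lapply(seq_len(n_clusters), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    lab <- if (allow_dups) {
      sample(cogs, len, replace = TRUE)
    } else {
      sample(c(cogs, sprintf("Z%d", seq_len(len)))[seq_len(len)])
    }
    lab[runif(len) < unassigned_rate] <- "."
    lab
  })
  make_dataset(layout)
}

# Random pair profile with a bounded placement space (for enumeration).
random_profile <- function(kind, max_lchoose = log(1e5)) {
  repeat {
    k <- if (kind == "adjacency") 3 else 2
    caps <- c(sample(0:12, 1), sample(0:6, k - 1, replace = TRUE))
    B_tot <- sample.int(max(1, sum(caps)), 1)
    if (B_tot > sum(caps)) next
    if (lchoose(sum(caps), B_tot) > max_lchoose) next
    occ <- as.vector(stats::rmultinom(1, B_tot, prob = (caps + 0.01)))
    if (any(occ > caps)) next
    names(caps) <- paste0("N_", letters[1:k])
    names(occ) <- paste0("B_", letters[1:k])
    prof <- pair_profile("A", "B", kind, caps, occ)
    if (prof$i_orig >= 1) return(prof)
  }
}

# --- oracle: exact tail by full placement enumeration -----------------------

# P(sum of class weights over drawn positions >= i_orig) by enumerating all
# C(N_tot, B_tot) unordered placements.
brute_force_tail <- function(capacities, B_tot, weights, i_orig) {
  labels <- rep(seq_along(capacities), capacities)
  if (B_tot == 0) return(if (i_orig <= 0) 1 else 0)
  sets <- utils::combn(length(labels), B_tot)
  counts <- apply(sets, 2, function(idx) sum(weights[labels[idx]]))
  sum(counts >= i_orig) / ncol(sets)
}

# --- oracle: direct interaction recounting ----------------------------------

# Adjacency interaction count between two label vectors, by scanning each
# cluster's neighbouring pairs.
recount_adjacency <- function(layout, a, b) {
  total <- 0
  for (lab in layout) {
    if (length(lab) < 2) next
    for (i in seq_len(length(lab) - 1)) {
      pair <- lab[c(i, i + 1)]
      if ((pair[1] == a && pair[2] == b) ||
          (pair[1] == b && pair[2] == a)) {
        total <- total + 1
      }
    }
  }
  total
}

recount_colocalization <- function(layout, a, b) {
  total <- 0
  for (lab in layout) {
    if (a %in% lab) total <- total + sum(lab == b)
  }
  total
}

# Monte-Carlo permutation estimate of P(i >= i_obs): keeps cog_a in place,
# redistributes cog_b's genes uniformly over the available positions, and
# recounts interactions by direct scanning.
permutation_tail <- function(dataset, cog_a, cog_b, kind, n_perm = 20000) {
  if (kind == "colocalization") dataset <- collapse_duplicates(dataset)
  genes <- dataset$genes[order(dataset$genes$cluster_id,
                               dataset$genes$position), ]
  lab <- genes$smcog_id
  cl <- genes$cluster_id
  avail <- which(lab != cog_a)
  B_tot <- sum(lab == cog_b)
  if (kind == "adjacency") {
    per_pos <- vapply(seq_along(lab), function(p) {
      nb <- c(p - 1, p + 1)
      nb <- nb[nb >= 1 & nb <= length(lab)]
      nb <- nb[cl[nb] == cl[p]]
      sum(lab[nb] == cog_a)
    }, 0)
  } else {
    a_clusters <- unique(cl[lab == cog_a])
    per_pos <- as.numeric(cl %in% a_clusters)
  }
  i_obs <- sum(per_pos[lab == cog_b])
  hits <- vapply(seq_len(n_perm), function(s) {
    sum(per_pos[sample(avail, B_tot)]) >= i_obs
  }, TRUE)
  list(i_obs = i_obs, p_hat = mean(hits),
       se = sqrt(mean(hits) * (1 - mean(hits)) / n_perm))
}

# --- oracle: Benjamini-Yekutieli reference step-up --------------------------

by_reference <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(adj))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- oracle: maximal cliques by exhaustive subset enumeration ---------------

# adj: symmetric logical matrix. Returns sorted member-name sets.
brute_force_cliques <- function(adj, min_size = 3) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1, 0:(n - 1))) > 0)
    if (length(members) < min_size) next
    sub <- adj[members, members, drop = FALSE]
    if (!all(sub[upper.tri(sub)])) next
    outside <- setdiff(seq_len(n), members)
    if (length(outside) > 0 &&
        any(colSums(adj[members, outside, drop = FALSE]) == length(members))) {
      next  # extendable, not maximal
    }
    out[[length(out) + 1]] <- sort(nodes[members])
  }
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

random_results_table <- function(n_nodes, p_edge, seed) {
  # a fake interaction table whose adjusted p-values induce a random graph
  set.seed(seed)
  pairs <- t(utils::combn(sprintf("n%02d", seq_len(n_nodes)), 2))
  tibble::tibble(
    cog_a = pairs[, 1], cog_b = pairs[, 2], kind = "colocalization",
    i_orig = 1L, p_fixed_a = 0.5, p_fixed_b = 0.5, p_conservative = 0.5,
    p_adjusted = ifelse(runif(nrow(pairs)) < p_edge, 0.01, 0.9)
  )
}
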