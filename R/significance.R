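# Exact tail probabilities for observed interaction counts under random
# placement of the moving orthogroup, conservative direction-pairing, and
# FDR control.
#
# Null model: the B_tot moving genes are dropped uniformly at random, as an
# unordered set, onto the N_tot available positions (those not occupied by
# the fixed orthogroup, pooled over all clusters). The chance of a given
# per-class occupancy (B_a, B_b, ...) is the multivariate hypergeometric
# mass prod_x C(N_x, B_x) / C(N_tot, B_tot); the p-value is the total mass
# of occupancies whose interaction count reaches the observed one.

# P(sum_x w_x * B_x >= i_orig) for capacities N, draw B_tot, class weights w.
# Exact integer arithmetic when the denominator is modest, log-gamma
# summation otherwise; both paths sum the upper-tail region directly so no
# catastrophic cancellation can occur.
hypergeom_tail <- function(capacities, B_tot, weights, i_orig) {
  if (i_orig <= 0) return(1)
  grid <- feasible_occupancies(capacities, B_tot)
  counts <- grid %*% weights
  tail <- grid[counts >= i_orig, , drop = FALSE]
  if (nrow(tail) == 0) return(0)

  ldenom <- lchoose(sum(capacities), B_tot)
  if (ldenom <= .EXACT_LCHOOSE_MAX) {
    num <- vapply(seq_len(nrow(tail)), function(r) {
      prod(vapply(seq_along(capacities),
                  function(x) choose_exact(capacities[x], tail[r, x]), 0))
    }, 0)
    sum(num) / choose_exact(sum(capacities), B_tot)
  } else {
    lnum <- rowSums(matrix(
      lchoose(rep(capacities, each = nrow(tail)), as.vector(tail)),
      nrow = nrow(tail)
    ))
    min(1, exp(logsumexp(lnum) - ldenom))
  }
}

# All (B_1..B_k) with sum = B_tot and B_x <= N_x, one row per occupancy.
feasible_occupancies <- function(capacities, B_tot) {
  k <- length(capacities)
  if (k == 2) {
    b2 <- 0:min(capacities[2], B_tot)
    grid <- matrix(b2, ncol = 1)
  } else {
    b2 <- 0:min(capacities[2], B_tot)
    b3 <- 0:min(capacities[3], B_tot)
    grid <- cbind(rep(b2, times = length(b3)), rep(b3, each = length(b2)))
  }
  first <- B_tot - rowSums(grid)
  ok <- first >= 0 & first <= capacities[1]
  out <- cbind(first, grid)[ok, , drop = FALSE]
  colnames(out) <- paste0("B_", seq_len(k))
  out
}

#' Adjacency interaction p-value
#'
#' Probability of observing at least the recorded number of adjacency
#' interactions if the moving orthogroup's genes were placed uniformly at
#' random over all available positions, keeping the fixed orthogroup in
#' place. Sums the multivariate hypergeometric mass over all occupancy
#' triples `(B_a, B_b, B_c)` with `B_b + 2 B_c >= i_orig`; an observed
#' count of zero gives p = 1 exactly. Arithmetic is exact-integer for
#' small search spaces and log-gamma based otherwise.
#'
#' @param profile A `pair_profile` of kind `"adjacency"` from
#'   [count_adjacency()].
#' @return A single p-value in (0, 1\].
#' @export
adjacency_pvalue <- function(profile) {
  stopifnot(inherits(profile, "pair_profile"))
  if (profile$kind != "adjacency") {
    abort_bgc("profile is not an adjacency profile", "bgc_validation_error")
  }
  validate_pair_profile(profile)
  hypergeom_tail(profile$capacities, profile$B_tot,
                 interaction_weights("adjacency"), profile$i_orig)
}

#' Colocalization interaction p-value
#'
#' Upper tail of the two-class hypergeometric: the probability that at
#' least `i_orig` of the moving orthogroup's genes land inside clusters
#' containing the fixed orthogroup, when placed uniformly over all
#' available positions of the duplicate-collapsed dataset. The empty
#' positions introduced by [collapse_duplicates()] count as available,
#' which makes the estimate conservative.
#'
#' @param profile A `pair_profile` of kind `"colocalization"` from
#'   [count_colocalization()].
#' @return A single p-value in (0, 1\].
#' @export
colocalization_pvalue <- function(profile) {
  stopifnot(inherits(profile, "pair_profile"))
  if (profile$kind != "colocalization") {
    abort_bgc("profile is not a colocalization profile", "bgc_validation_error")
  }
  validate_pair_profile(profile)
  hypergeom_tail(profile$capacities, profile$B_tot,
                 interaction_weights("colocalization"), profile$i_orig)
}

#' Conservative pairing of directional p-values
#'
#' Each pair yields two p-values, depending on which orthogroup is held
#' fixed; the larger of the two is used downstream, the most conservative
#' choice.
#'
#' @param p_fixed_a,p_fixed_b Directional p-values in (0, 1\].
#' @return `max(p_fixed_a, p_fixed_b)`.
#' @export
conservative_pvalue <- function(p_fixed_a, p_fixed_b) {
  check_pvalues(c(p_fixed_a, p_fixed_b))
  pmax(p_fixed_a, p_fixed_b)
}

check_pvalues <- function(p) {
  if (length(p) == 0) {
    abort_bgc("empty p-value vector", "bgc_validation_error")
  }
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort_bgc("p-values must lie in (0, 1]", "bgc_validation_error")
  }
  invisible(p)
}

#' Benjamini-Yekutieli FDR correction
#'
#' Adjusts p-values for multiple testing with the Benjamini-Yekutieli
#' step-up procedure, which controls the false discovery rate under
#' arbitrary dependency — appropriate here because the pairwise interaction
#' tests share genes and clusters and are far from independent.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values in the original order, each at least its
#'   input value.
#' @export
correct_fdr <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BY")
}

#' Test all candidate smCOG pairs
#'
#' Runs the full significance stage: for every pair of orthogroups sharing
#' at least one cluster, builds both directional profiles for each
#' interaction kind with at least one observed interaction, computes both
#' directional p-values, takes the conservative maximum, and applies the
#' Benjamini-Yekutieli correction jointly across all (pair x kind) tests
#' as a single family.
#'
#' @param dataset A preprocessed `bgc_dataset`.
#' @return A tibble with one row per tested (pair, kind): `cog_a`, `cog_b`
#'   (sorted so `cog_a < cog_b`), `kind`, `i_orig` (count with `cog_a`
#'   fixed), `p_fixed_a`, `p_fixed_b`, `p_conservative`, `p_adjusted`;
#'   deterministically sorted by pair then kind.
#' @export
test_all_pairs <- function(dataset) {
  pairs <- enumerate_candidate_pairs(dataset)
  empty <- tibble::tibble(
    cog_a = character(), cog_b = character(), kind = character(),
    i_orig = integer(), p_fixed_a = double(), p_fixed_b = double(),
    p_conservative = double(), p_adjusted = double()
  )
  if (nrow(pairs) == 0) return(empty)
  collapsed <- collapse_duplicates(dataset)

  # The per-fixed-cog position classification is shared by every partner of
  # that cog, so it is computed once per cog rather than once per pair.
  cogs <- unique(c(pairs$cog_a, pairs$cog_b))
  adj_state <- lapply(stats::setNames(cogs, cogs),
                      function(f) adjacency_state(dataset$genes, f))
  col_state <- lapply(stats::setNames(cogs, cogs),
                      function(f) colocalization_state(collapsed$genes, f))

  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    a <- pairs$cog_a[i]
    b <- pairs$cog_b[i]
    out <- list()

    adj_a <- adjacency_profile_from_state(adj_state[[a]], a, b)
    if (adj_a$i_orig >= 1) {
      adj_b <- adjacency_profile_from_state(adj_state[[b]], b, a)
      out$adjacency <- tibble::tibble(
        cog_a = a, cog_b = b, kind = "adjacency", i_orig = adj_a$i_orig,
        p_fixed_a = adjacency_pvalue(adj_a),
        p_fixed_b = adjacency_pvalue(adj_b)
      )
    }
    col_a <- colocalization_profile_from_state(col_state[[a]], a, b)
    col_b <- colocalization_profile_from_state(col_state[[b]], b, a)
    if (col_a$i_orig >= 1 || col_b$i_orig >= 1) {
      out$colocalization <- tibble::tibble(
        cog_a = a, cog_b = b, kind = "colocalization", i_orig = col_a$i_orig,
        p_fixed_a = colocalization_pvalue(col_a),
        p_fixed_b = colocalization_pvalue(col_b)
      )
    }
    dplyr::bind_rows(out)
  })
  results <- dplyr::bind_rows(rows)
  if (nrow(results) == 0) return(empty)
  results$p_conservative <- conservative_pvalue(results$p_fixed_a,
                                                results$p_fixed_b)
  results$p_adjusted <- correct_fdr(results$p_conservative)
  dplyr::arrange(results, .data$cog_a, .data$cog_b, .data$kind)
}
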