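# Module prioritisation: per-module metrics, compound-class Shannon
# entropy, the MIB (Module Interest Benchmarking) weighted-rank score, and
# the top-quartile enrichment test.

#' Shannon entropy of compound-class counts
#'
#' Measures how diverse the predicted compound classes of a module's
#' supporting clusters are: `SE = -sum f_i ln(f_i)` over classes with
#' positive frequency, where `f_i` is the fraction of supporting clusters
#' of class `i`. Zero when all supporting clusters share one class,
#' `ln(k)` at the uniform distribution over `k` classes. High entropy
#' marks modules re-used across many chemistries — likely well-defined
#' functional units — and down-ranks lineage-specific artefacts.
#'
#' @param class_counts Named numeric vector of non-negative counts, at
#'   least one positive.
#' @return Entropy in nats (natural log), `>= 0`.
#' @export
shannon_entropy <- function(class_counts) {
  if (length(class_counts) == 0 || any(class_counts < 0) ||
      sum(class_counts) == 0) {
    abort_bgc("class counts must be non-negative with a positive total",
              "bgc_validation_error")
  }
  f <- class_counts[class_counts > 0] / sum(class_counts)
  -sum(f * log(f))
}

#' Compute prioritisation metrics for detected modules
#'
#' Attaches to each module: the number of supporting clusters present in
#' the curated database (`n_curated`), the number of distinct compound
#' classes among supporting clusters and their Shannon entropy, and the
#' percentage of member smCOGs in each functional category. A double
#' category such as `"tailoring/core"` contributes 0.5 to each of its two
#' named categories, so the percentages always sum to 100.
#'
#' @param modules Module tibble from [detect_modules()].
#' @param dataset The `bgc_dataset` the modules were detected in.
#' @param smcogs Optional precomputed [smcog_table()] (with smCOG-level
#'   categories); derived from `dataset` when omitted.
#' @return `modules` with columns `n_curated`, `n_classes`,
#'   `shannon_entropy`, and `pct_<category>` appended.
#' @export
compute_module_metrics <- function(modules, dataset, smcogs = NULL) {
  if (is.null(smcogs)) smcogs <- smcog_table(dataset)
  # recomputing on an already-annotated table replaces the old metrics
  stale <- c("n_curated", "n_classes", "shannon_entropy", "mib_score",
             paste0("pct_", MODULE_CATEGORIES))
  modules <- modules[, setdiff(names(modules), stale)]
  if (is.null(modules$supporting_clusters)) {
    abort_bgc(paste0("modules table lacks supporting_clusters ",
                     "(is the module JSON sidecar missing?)"),
              "bgc_validation_error")
  }
  cluster_class <- stats::setNames(dataset$clusters$compound_class,
                                   dataset$clusters$cluster_id)
  cluster_curated <- stats::setNames(dataset$clusters$curated_flag,
                                     dataset$clusters$cluster_id)
  cog_category <- stats::setNames(smcogs$category, smcogs$smcog_id)

  per_module <- purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    support <- modules$supporting_clusters[[i]]
    classes <- table(cluster_class[support])
    cats <- cog_category[modules$smcogs[[i]]]
    if (anyNA(cats)) {
      abort_bgc(
        paste0("module ", modules$module_id[i],
               " has member smCOG(s) without a category"),
        "bgc_validation_error"
      )
    }
    pct <- category_percentages(cats)
    tibble::tibble(
      n_curated = sum(cluster_curated[support]),
      n_classes = length(classes),
      shannon_entropy = shannon_entropy(as.numeric(classes)),
      !!!stats::setNames(as.list(pct), paste0("pct_", names(pct)))
    )
  })
  dplyr::bind_cols(modules, per_module)
}

# Percentage of members per category; "x/y" double categories split 0.5/0.5.
category_percentages <- function(categories) {
  tally <- stats::setNames(numeric(length(MODULE_CATEGORIES)),
                           MODULE_CATEGORIES)
  for (cat in categories) {
    parts <- strsplit(cat, "/", fixed = TRUE)[[1]]
    unknown <- setdiff(parts, MODULE_CATEGORIES)
    if (length(unknown) > 0) {
      abort_bgc(paste0("unknown smCOG category: ", cat),
                "bgc_validation_error")
    }
    tally[parts] <- tally[parts] + 1 / length(parts)
  }
  tally / length(categories) * 100
}

#' MIB score weights
#'
#' One non-negative weight per prioritisation metric. The defaults weight
#' module size 2 (longer modules are more specific), Shannon entropy 15,
#' supporting-cluster count 10, strictest p-value threshold 5, tailoring
#' percentage 10, and everything else 0.
#'
#' @param size,entropy,n_bgc,threshold,pct_tailoring,n_curated,n_classes,pct_core,pct_regulator,pct_transport,pct_other,pct_mixed
#'   Non-negative weights.
#' @return A named numeric vector of class `mib_weights`.
#' @export
mib_weights <- function(size = 2, entropy = 15, n_bgc = 10, threshold = 5,
                        pct_tailoring = 10, n_curated = 0, n_classes = 0,
                        pct_core = 0, pct_regulator = 0, pct_transport = 0,
                        pct_other = 0, pct_mixed = 0) {
  w <- c(size = size, entropy = entropy, n_bgc = n_bgc, threshold = threshold,
         pct_tailoring = pct_tailoring, n_curated = n_curated,
         n_classes = n_classes, pct_core = pct_core,
         pct_regulator = pct_regulator, pct_transport = pct_transport,
         pct_other = pct_other, pct_mixed = pct_mixed)
  if (any(!is.finite(w)) || any(w < 0)) {
    abort_bgc("MIB weights must be non-negative", "bgc_validation_error")
  }
  structure(w, class = "mib_weights")
}

# metric name -> (column, higher-is-better)
MIB_METRIC_COLUMNS <- list(
  size = list(column = "size", ascending = FALSE),
  entropy = list(column = "shannon_entropy", ascending = FALSE),
  n_bgc = list(column = "n_bgc", ascending = FALSE),
  threshold = list(column = "strictest_threshold", ascending = TRUE),
  pct_tailoring = list(column = "pct_tailoring", ascending = FALSE),
  n_curated = list(column = "n_curated", ascending = FALSE),
  n_classes = list(column = "n_classes", ascending = FALSE),
  pct_core = list(column = "pct_core", ascending = FALSE),
  pct_regulator = list(column = "pct_regulator", ascending = FALSE),
  pct_transport = list(column = "pct_transport", ascending = FALSE),
  pct_other = list(column = "pct_other", ascending = FALSE),
  pct_mixed = list(column = "pct_mixed", ascending = FALSE)
)

#' MIB weighted-rank interest score
#'
#' For each metric, modules are ranked with the "better" end receiving the
#' higher rank (larger size, entropy, support, and category percentages
#' are better; a *smaller* strictest threshold is better; ties get
#' average fractional ranks). The score is the weighted sum of ranks,
#' linearly rescaled so the least interesting module scores 1 and the most
#' interesting 100. Because only ranks enter, the score is invariant to
#' monotone transformations of any metric. If all modules tie on every
#' weighted metric (including the single-module case) every score is 100.
#'
#' @param metrics Module table from [compute_module_metrics()].
#' @param weights A [mib_weights()] vector.
#' @return Numeric scores in \[1, 100\], one per module.
#' @export
mib_score <- function(metrics, weights = mib_weights()) {
  if (!inherits(weights, "mib_weights")) weights <- do.call(mib_weights, as.list(weights))
  n <- nrow(metrics)
  if (n == 0) return(numeric())
  total <- numeric(n)
  for (metric in names(MIB_METRIC_COLUMNS)) {
    w <- weights[[metric]]
    if (w == 0) next
    spec <- MIB_METRIC_COLUMNS[[metric]]
    x <- metrics[[spec$column]]
    if (is.null(x)) {
      abort_bgc(paste0("metrics table lacks column ", spec$column),
                "bgc_validation_error")
    }
    if (spec$ascending) x <- -x
    total <- total + w * rank(x, ties.method = "average")
  }
  lo <- min(total)
  hi <- max(total)
  if (hi == lo) return(rep(100, n))
  1 + (total - lo) / (hi - lo) * 99
}

#' Top-quantile enrichment of a module selection
#'
#' Tests whether a selected set of modules is over-represented in the top
#' scoring fraction, e.g. whether experimentally validated modules
#' concentrate in the top quartile of MIB scores. The top set holds the
#' `floor(quantile * n)` highest scores (ties broken by original order,
#' deterministically); the returned value is the one-sided Fisher exact
#' p-value for the selected-by-top 2x2 table.
#'
#' @param selected Logical mask or integer indices into `all_scores`
#'   marking the selected modules; must be non-empty.
#' @param all_scores Numeric scores of all modules.
#' @param quantile Top fraction considered (default 0.25).
#' @return One-sided (enrichment) Fisher exact p-value.
#' @export
quartile_enrichment <- function(selected, all_scores, quantile = 0.25) {
  n <- length(all_scores)
  if (is.logical(selected)) {
    if (length(selected) != n) {
      abort_bgc("logical selection mask must match all_scores in length",
                "bgc_validation_error")
    }
    selected <- which(selected)
  }
  selected <- as.integer(selected)
  if (length(selected) == 0) {
    abort_bgc("empty selection", "bgc_validation_error")
  }
  if (any(selected < 1 | selected > n) || anyDuplicated(selected) > 0) {
    abort_bgc("selection indices must be unique and within all_scores",
              "bgc_validation_error")
  }
  if (quantile <= 0 || quantile >= 1) {
    abort_bgc("quantile must lie strictly between 0 and 1",
              "bgc_validation_error")
  }
  n_top <- floor(quantile * n)
  top <- order(-all_scores, seq_len(n))[seq_len(n_top)]
  k <- sum(selected %in% top)
  tab <- matrix(c(k, length(selected) - k,
                  n_top - k, n - length(selected) - n_top + k),
                nrow = 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}
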