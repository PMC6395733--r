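# Synthetic cluster collections with planted modules: a controlled stand-in
# for real BGC collections, so detection can be benchmarked end-to-end with
# a known ground truth.

#' Specification for a synthetic cluster collection
#'
#' Describes a collection of gene clusters with a random background of
#' orthogroups and, optionally, planted modules: fixed smCOG sets inserted
#' together (contiguously or scattered) into a controlled fraction of
#' clusters. Background smCOGs are drawn uniformly with replacement, so
#' duplicated occurrences within a cluster arise naturally and exercise
#' the duplicate-collapse transform.
#'
#' @param n_clusters Number of clusters (default 100).
#' @param cluster_length_range Integer (min, max) genes per cluster,
#'   minimum at least 3 (default `c(5, 15)`).
#' @param n_background_cogs Number of background orthogroups (default 30).
#' @param background_rate Probability that a background position carries an
#'   smCOG rather than staying unassigned (default 0.7).
#' @param planted_modules List of planted modules, each a list with
#'   `smcogs` (character set of size 3-6), `fraction` (fraction of clusters
#'   carrying the module, in (0, 1\]) and `contiguous` (insert as a block
#'   or scattered; default `TRUE`).
#' @param n_classes Number of compound-class labels (default 6).
#' @param curated_fraction Fraction of clusters flagged as present in the
#'   curated database (default 0.05).
#' @param correlate_classes If `TRUE`, clusters carrying a planted module
#'   share one compound class with probability 0.9, emulating the
#'   lineage-driven class bias that Shannon entropy is meant to down-rank
#'   (default `FALSE`).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 100, cluster_length_range = c(5, 15),
                           n_background_cogs = 30, background_rate = 0.7,
                           planted_modules = list(), n_classes = 6,
                           curated_fraction = 0.05,
                           correlate_classes = FALSE, seed = 1) {
  if (cluster_length_range[1] < 3 || cluster_length_range[2] <
      cluster_length_range[1]) {
    abort_bgc("cluster lengths must be >= 3 with min <= max",
              "bgc_validation_error")
  }
  if (background_rate <= 0 || background_rate > 1) {
    abort_bgc("background_rate must lie in (0, 1]", "bgc_validation_error")
  }
  for (m in planted_modules) {
    size <- length(m$smcogs)
    if (size < 3 || size > 6) {
      abort_bgc("planted modules must have 3-6 smCOGs", "bgc_validation_error")
    }
    if (size > cluster_length_range[1]) {
      abort_bgc("planted module size exceeds the minimum cluster length",
                "bgc_validation_error")
    }
    if (is.null(m$fraction) || m$fraction <= 0 || m$fraction > 1) {
      abort_bgc("planted-module fraction must lie in (0, 1]",
                "bgc_validation_error")
    }
  }
  structure(
    list(
      n_clusters = as.integer(n_clusters),
      cluster_length_range = as.integer(cluster_length_range),
      n_background_cogs = as.integer(n_background_cogs),
      background_rate = background_rate,
      planted_modules = lapply(planted_modules, function(m) {
        list(smcogs = sort(as.character(m$smcogs)), fraction = m$fraction,
             contiguous = isTRUE(m$contiguous %||% TRUE))
      }),
      n_classes = as.integer(n_classes),
      curated_fraction = curated_fraction,
      correlate_classes = isTRUE(correlate_classes),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cluster collection
#'
#' Builds the dataset a [synthetic_spec()] describes: background positions
#' carry uniformly drawn smCOGs (or stay unassigned), then each planted
#' module overwrites a random block (contiguous) or random positions
#' (scattered) of its share of clusters, with member order shuffled per
#' insertion. Each background smCOG has a "home" functional category; its
#' member genes inherit it with probability 0.8, so smCOG-level category
#' annotation sees realistic majorities. Deterministic under the spec's
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `bgc_dataset`; the spec is recorded in its provenance.
#' @export
generate_clusters <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    cids <- sprintf("SYN%04d", seq_len(spec$n_clusters))
    lens <- sample(seq(spec$cluster_length_range[1],
                       spec$cluster_length_range[2]),
                   spec$n_clusters, replace = TRUE)
    bg_cogs <- sprintf("BG%03d", seq_len(spec$n_background_cogs))
    home <- sample(GENE_CATEGORIES, spec$n_background_cogs, replace = TRUE,
                   prob = c(0.25, 0.15, 0.3, 0.15, 0.15))
    names(home) <- bg_cogs
    planted_cogs <- unique(unlist(lapply(spec$planted_modules, `[[`, "smcogs")))
    if (length(planted_cogs) > 0) {
      home[planted_cogs] <- sample(GENE_CATEGORIES, length(planted_cogs),
                                   replace = TRUE,
                                   prob = c(0.25, 0.15, 0.3, 0.15, 0.15))
    }

    smcog <- vector("list", spec$n_clusters)
    for (i in seq_len(spec$n_clusters)) {
      lab <- rep(UNASSIGNED, lens[i])
      hit <- stats::runif(lens[i]) < spec$background_rate
      lab[hit] <- sample(bg_cogs, sum(hit), replace = TRUE)
      smcog[[i]] <- lab
    }

    carries <- matrix(FALSE, spec$n_clusters,
                      max(1L, length(spec$planted_modules)))
    for (j in seq_along(spec$planted_modules)) {
      m <- spec$planted_modules[[j]]
      size <- length(m$smcogs)
      n_target <- max(1L, round(m$fraction * spec$n_clusters))
      targets <- sample(which(lens >= size), n_target)
      carries[targets, j] <- TRUE
      for (i in targets) {
        members <- sample(m$smcogs)
        if (m$contiguous) {
          start <- sample(seq_len(lens[i] - size + 1L), 1)
          pos <- start:(start + size - 1L)
        } else {
          pos <- sort(sample(seq_len(lens[i]), size))
        }
        smcog[[i]][pos] <- members
      }
    }

    genes <- tibble::tibble(
      cluster_id = rep(cids, lens),
      position = unlist(lapply(lens, function(l) seq_len(l) - 1L)),
      smcog_id = unlist(smcog)
    )
    genes$gene_id <- sprintf("%s_g%02d", genes$cluster_id, genes$position + 1L)
    assigned <- !is_unassigned(genes$smcog_id)
    genes$category <- "other"
    h <- home[genes$smcog_id[assigned]]
    keep_home <- stats::runif(sum(assigned)) < 0.8
    alt <- vapply(h, function(cat) sample(setdiff(GENE_CATEGORIES, cat), 1), "")
    genes$category[assigned] <- ifelse(keep_home, h, alt)
    genes$domain_prob <- NA_real_

    classes <- sprintf("class%02d", seq_len(spec$n_classes))
    compound <- sample(classes, spec$n_clusters, replace = TRUE)
    if (spec$correlate_classes && length(spec$planted_modules) > 0) {
      for (j in seq_along(spec$planted_modules)) {
        cls <- classes[(j - 1L) %% spec$n_classes + 1L]
        hit <- carries[, j] & stats::runif(spec$n_clusters) < 0.9
        compound[hit] <- cls
      }
    }
    clusters <- tibble::tibble(
      cluster_id = cids,
      compound_class = compound,
      curated_flag = stats::runif(spec$n_clusters) < spec$curated_fraction,
      organism = NA_character_
    )
    bgc_dataset(genes, clusters,
                provenance = list(generator = "synthetic", spec = unclass(spec)))
  })
}

#' Score recovery of planted modules
#'
#' Compares detected modules against the planted ground truth. Each
#' planted set is classified as recovered `exact` (some detected set
#' equals it), `superset` (some detected set strictly contains it),
#' `subset` (some detected set of size >= 3 is strictly contained in it),
#' or `missed` — in that priority order, so categories are mutually
#' exclusive. Detected modules sharing no smCOG with any planted set are
#' counted as spurious.
#'
#' @param detected Module tibble from [detect_modules()].
#' @param spec The [synthetic_spec()] used to generate the data.
#' @return A list with tibble `planted` (columns `module`, `outcome`) and
#'   `n_spurious`.
#' @export
score_recovery <- function(detected, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  det <- detected$smcogs %||% list()
  planted <- lapply(spec$planted_modules, `[[`, "smcogs")
  outcome <- vapply(planted, function(p) {
    if (any(vapply(det, function(d) setequal(d, p), TRUE))) return("exact")
    if (any(vapply(det, function(d) all(p %in% d) && length(d) > length(p),
                   TRUE))) {
      return("superset")
    }
    if (any(vapply(det, function(d) all(d %in% p) && length(d) < length(p),
                   TRUE))) {
      return("subset")
    }
    "missed"
  }, "")
  all_planted <- unique(unlist(planted))
  spurious <- vapply(det, function(d) length(intersect(d, all_planted)) == 0,
                     TRUE)
  list(
    planted = tibble::tibble(
      module = vapply(planted, paste, "", collapse = ","),
      outcome = outcome
    ),
    n_spurious = sum(spurious)
  )
}
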