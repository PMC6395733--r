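# Domain model: clusters of ordered genes with orthogroup (smCOG) labels,
# plus readers/writers for the standard cluster-table formats.

GENE_COLUMNS <- c("cluster_id", "gene_id", "position", "smcog_id", "category")

#' Construct a BGC dataset
#'
#' The central container of the package: a set of gene clusters, each an
#' ordered list of genes, where every gene carries an orthogroup (smCOG)
#' label or the [UNASSIGNED] sentinel. Gene order is the genomic order;
#' positions are dense 0-based indices within each cluster, and genomic
#' coordinates are not retained — only order matters to the method.
#'
#' @param genes Data frame with columns `cluster_id`, `gene_id`, `position`
#'   (0-based, consecutive within each cluster), `smcog_id`, `category`
#'   (one of [GENE_CATEGORIES]), and optionally `domain_prob` (probability
#'   in \[0,1\] that the gene carries a biosynthesis-associated domain).
#' @param clusters Data frame with one row per cluster: `cluster_id`,
#'   `compound_class` (predicted chemical class of the end product),
#'   `curated_flag` (present in a curated database), optional `organism`.
#'   If `NULL`, a skeleton table is derived from `genes` with unknown
#'   compound classes.
#' @param provenance Free-form metadata list.
#'
#' @return An object of class `bgc_dataset`: a list with tibbles `genes`
#'   and `clusters` plus `provenance`.
#' @seealso [read_cluster_table()], [preprocess_dataset()]
#' @export
bgc_dataset <- function(genes, clusters = NULL, provenance = list()) {
  genes <- tibble::as_tibble(genes)
  missing_cols <- setdiff(GENE_COLUMNS, names(genes))
  if (length(missing_cols) > 0) {
    abort_bgc(
      paste0("gene table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "bgc_format_error"
    )
  }
  if (!"domain_prob" %in% names(genes)) genes$domain_prob <- NA_real_
  genes$cluster_id <- as.character(genes$cluster_id)
  genes$gene_id <- as.character(genes$gene_id)
  genes$smcog_id <- as.character(genes$smcog_id)
  genes$category <- as.character(genes$category)
  genes$position <- as.integer(genes$position)
  genes$domain_prob <- as.double(genes$domain_prob)
  genes <- dplyr::arrange(genes, .data$cluster_id, .data$position)

  if (is.null(clusters)) {
    clusters <- tibble::tibble(
      cluster_id = unique(genes$cluster_id),
      compound_class = "unknown",
      curated_flag = FALSE,
      organism = NA_character_
    )
  }
  clusters <- tibble::as_tibble(clusters)
  if (!"cluster_id" %in% names(clusters)) {
    abort_bgc("cluster table is missing required column(s): cluster_id",
              "bgc_format_error")
  }
  if (!"compound_class" %in% names(clusters)) clusters$compound_class <- "unknown"
  if (!"curated_flag" %in% names(clusters)) clusters$curated_flag <- FALSE
  if (!"organism" %in% names(clusters)) clusters$organism <- NA_character_
  clusters$cluster_id <- as.character(clusters$cluster_id)
  clusters$compound_class <- as.character(clusters$compound_class)
  clusters$organism <- as.character(clusters$organism)
  clusters$curated_flag <- as.logical(clusters$curated_flag)
  clusters <- dplyr::arrange(clusters, .data$cluster_id)

  x <- structure(
    list(genes = genes, clusters = clusters, provenance = provenance),
    class = "bgc_dataset"
  )
  validate_bgc_dataset(x)
}

#' Validate a BGC dataset
#'
#' Checks the structural invariants: positions dense 0..len-1 per cluster
#' with no duplicates, `domain_prob` within \[0,1\] where present, known
#' gene categories, and a cluster-table row for every cluster seen in the
#' gene table.
#'
#' @param x A `bgc_dataset`.
#' @return `x`, invisibly unchanged, or an error of class
#'   `bgc_validation_error`.
#' @export
validate_bgc_dataset <- function(x) {
  genes <- x$genes
  dup <- duplicated(genes[, c("cluster_id", "position")])
  if (any(dup)) {
    bad <- genes[dup, ]
    abort_bgc(
      sprintf("duplicate (cluster_id, position): %s, %d",
              bad$cluster_id[1], bad$position[1]),
      "bgc_validation_error"
    )
  }
  by_cluster <- split(genes$position, genes$cluster_id)
  for (cid in names(by_cluster)) {
    pos <- sort(by_cluster[[cid]])
    if (!identical(pos, seq(0L, length(pos) - 1L))) {
      abort_bgc(
        sprintf("cluster '%s': positions are not consecutive 0..%d",
                cid, length(pos) - 1L),
        "bgc_validation_error"
      )
    }
  }
  dp <- genes$domain_prob
  if (any(!is.na(dp) & (dp < 0 | dp > 1))) {
    abort_bgc("domain_prob outside [0, 1]", "bgc_validation_error")
  }
  bad_cat <- setdiff(unique(genes$category[!is_unassigned(genes$smcog_id)]),
                     GENE_CATEGORIES)
  bad_cat <- bad_cat[!is.na(bad_cat)]
  if (length(bad_cat) > 0) {
    abort_bgc(paste0("unknown gene category: ", paste(bad_cat, collapse = ", ")),
              "bgc_validation_error")
  }
  if (any(is_unassigned(genes$gene_id))) {
    abort_bgc("UNASSIGNED is reserved and cannot be used as a gene_id",
              "bgc_validation_error")
  }
  orphan <- setdiff(unique(genes$cluster_id), x$clusters$cluster_id)
  if (length(orphan) > 0) {
    abort_bgc(paste0("genes reference cluster(s) absent from the cluster ",
                     "table: ", paste(orphan, collapse = ", ")),
              "bgc_validation_error")
  }
  invisible(x)
}

#' @export
print.bgc_dataset <- function(x, ...) {
  n_assigned <- sum(!is_unassigned(x$genes$smcog_id))
  cat(sprintf(
    "<bgc_dataset> %d clusters, %d genes (%d with smCOG, %d smCOGs)\n",
    nrow(x$clusters), nrow(x$genes), n_assigned,
    length(unique(x$genes$smcog_id[!is_unassigned(x$genes$smcog_id)]))
  ))
  invisible(x)
}

#' Summarise smCOG membership and categories
#'
#' One row per smCOG present in the dataset: member count and the
#' smCOG-level category derived from its members' gene-level categories via
#' [annotate_smcog_category()].
#'
#' @param dataset A `bgc_dataset`.
#' @return A tibble with columns `smcog_id`, `n_members`, `category`.
#' @export
smcog_table <- function(dataset) {
  assigned <- dataset$genes[!is_unassigned(dataset$genes$smcog_id), ]
  if (nrow(assigned) == 0) {
    return(tibble::tibble(smcog_id = character(), n_members = integer(),
                          category = character()))
  }
  assigned |>
    dplyr::group_by(.data$smcog_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      category = annotate_smcog_category(.data$category),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$smcog_id)
}

#' Read a cluster table
#'
#' Reads the package's standard flat representation of a BGC collection:
#' one row per gene with `cluster_id`, `gene_id`, `position`, `smcog_id`,
#' `category`, and optionally `domain_prob`, `compound_class`,
#' `curated_flag`, `organism` (the last three constant within a cluster).
#' JSON files may instead carry separate `genes` and `clusters` tables, as
#' written by [write_cluster_table()].
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default, tab-separated) or `"json"`.
#' @return A validated [bgc_dataset()].
#' @export
read_cluster_table <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_bgc(paste0("file not found: ", path), "bgc_io_error")
  }
  if (format == "tsv") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    from_flat_table(raw, provenance = list(source = path))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(obj)) {
      from_flat_table(tibble::as_tibble(obj), provenance = list(source = path))
    } else {
      bgc_dataset(
        genes = tibble::as_tibble(obj$genes),
        clusters = if (!is.null(obj$clusters)) tibble::as_tibble(obj$clusters),
        provenance = as.list(obj$provenance) %||% list(source = path)
      )
    }
  }
}

from_flat_table <- function(raw, provenance = list()) {
  missing_cols <- setdiff(GENE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_bgc(
      paste0("cluster table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "bgc_format_error"
    )
  }
  cluster_cols <- intersect(c("compound_class", "curated_flag", "organism"),
                            names(raw))
  clusters <- NULL
  if (length(cluster_cols) > 0) {
    clusters <- raw |>
      dplyr::distinct(dplyr::across(dplyr::all_of(c("cluster_id", cluster_cols))))
    if (anyDuplicated(clusters$cluster_id) > 0) {
      abort_bgc("cluster-level columns are not constant within a cluster",
                "bgc_validation_error")
    }
  }
  genes <- raw[, intersect(c(GENE_COLUMNS, "domain_prob"), names(raw))]
  bgc_dataset(genes, clusters, provenance = provenance)
}

#' Write a cluster table
#'
#' Inverse of [read_cluster_table()]. TSV output is the flat one-row-per-gene
#' form with the cluster-level columns repeated; JSON output keeps the two
#' tables separate and round-trips exactly.
#'
#' @param dataset A `bgc_dataset`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(dataset, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    flat <- dplyr::left_join(dataset$genes, dataset$clusters, by = "cluster_id")
    readr::write_tsv(flat, path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(genes = dataset$genes, clusters = dataset$clusters,
           provenance = dataset$provenance),
      path, dataframe = "columns", na = "null", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read clusters from a GenBank flat file
#'
#' Convenience reader: each GenBank record becomes one cluster whose genes
#' are the record's CDS features ordered by start coordinate (strand is
#' ignored — the method is purely positional). Orthogroup labels are not
#' part of GenBank files, so they must be supplied as a sidecar mapping;
#' genes absent from the mapping become [UNASSIGNED].
#'
#' @param path GenBank flat file (possibly multi-record).
#' @param smcog_map Optional data frame or 2/3-column TSV path mapping
#'   `gene_id` to `smcog_id` (and optionally `category`; defaults to
#'   `"other"`). Gene identifiers are taken from the CDS `/locus_tag`
#'   (falling back to `/gene`, then `/protein_id`).
#' @return A [bgc_dataset()]. Unparsable records are skipped with a warning;
#'   a file yielding no CDS features at all is an error.
#' @export
read_genbank_clusters <- function(path, smcog_map = NULL) {
  if (!file.exists(path)) {
    abort_bgc(paste0("file not found: ", path), "bgc_io_error")
  }
  if (is.character(smcog_map)) {
    smcog_map <- readr::read_tsv(smcog_map, show_col_types = FALSE,
                                 progress = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    abort_bgc("empty GenBank file", "bgc_format_error")
  }
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) {
    abort_bgc("no LOCUS records found in GenBank file", "bgc_format_error")
  }
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))

  gene_rows <- list()
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    parsed <- tryCatch(parse_genbank_record(rec),
                       error = function(e) NULL)
    if (is.null(parsed)) {
      warning(sprintf("skipping unparsable GenBank record starting at line %d",
                      rec_starts[r]), call. = FALSE)
      next
    }
    gene_rows[[length(gene_rows) + 1L]] <- parsed
  }
  genes <- dplyr::bind_rows(gene_rows)
  if (nrow(genes) == 0) {
    abort_bgc("GenBank file contains no CDS features", "bgc_format_error")
  }

  if (!is.null(smcog_map)) {
    names(smcog_map)[1:2] <- c("gene_id", "smcog_id")
    idx <- match(genes$gene_id, smcog_map$gene_id)
    genes$smcog_id <- ifelse(is.na(idx), UNASSIGNED, smcog_map$smcog_id[idx])
    if ("category" %in% names(smcog_map)) {
      genes$category <- ifelse(is.na(idx), "other", smcog_map$category[idx])
    }
  }
  bgc_dataset(genes, provenance = list(source = path, reader = "genbank"))
}

# Minimal GenBank feature-table parser for CDS features: locus name,
# location span and identifying qualifiers only. No installed R package
# reads local GenBank feature tables, hence the hand-written reader.
parse_genbank_record <- function(rec) {
  locus <- sub("^LOCUS\\s+(\\S+).*", "\\1", rec[1])
  feat_start <- grep("^FEATURES", rec)
  if (length(feat_start) == 0) stop("no FEATURES block")
  feat_end <- grep("^(ORIGIN|CONTIG|//)", rec)
  feat_end <- if (length(feat_end) > 0) min(feat_end) - 1L else length(rec)
  feats <- rec[(feat_start + 1L):feat_end]

  # Feature keys sit at column 6; qualifier/continuation lines at column 22.
  key_lines <- grep("^ {5}\\S", feats)
  cds <- list()
  for (i in seq_along(key_lines)) {
    start <- key_lines[i]
    end <- if (i < length(key_lines)) key_lines[i + 1] - 1L else length(feats)
    key <- sub("^\\s+(\\S+).*", "\\1", feats[start])
    if (key != "CDS") next
    block <- feats[start:end]
    loc <- sub("^\\s+CDS\\s+", "", block[1])
    coords <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(coords) == 0) stop("unparsable CDS location")
    qual <- function(name) {
      m <- grep(sprintf("^\\s+/%s=", name), block, value = TRUE)
      if (length(m) == 0) return(NA_character_)
      gsub('"', "", sub(sprintf("^\\s+/%s=", name), "", m[1]))
    }
    cds[[length(cds) + 1L]] <- tibble::tibble(
      start = min(coords),
      gene_id = qual("locus_tag") %||% NA_character_
    ) |>
      dplyr::mutate(gene_id = dplyr::coalesce(
        .data$gene_id, qual("gene"), qual("protein_id"),
        sprintf("%s_CDS%03d", locus, length(cds) + 1L)
      ))
  }
  if (length(cds) == 0) stop("record has no CDS features")
  cds <- dplyr::bind_rows(cds) |> dplyr::arrange(.data$start)
  tibble::tibble(
    cluster_id = locus,
    gene_id = cds$gene_id,
    position = seq_len(nrow(cds)) - 1L,
    smcog_id = UNASSIGNED,
    category = "other",
    domain_prob = NA_real_
  )
}

#' Write detected modules to disk
#'
#' Writes the module table as TSV (one row per module, smCOG members
#' serialized sorted and comma-joined, metric columns included when
#' present) and, alongside it, a JSON dump carrying the supporting cluster
#' IDs of each module. Output is deterministic and diffable.
#'
#' @param modules Module tibble from [detect_modules()] (optionally with
#'   metrics from [compute_module_metrics()] and a `mib_score` column).
#' @param path Output TSV path; the JSON dump goes to the same path with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  flat <- modules
  flat$smcogs <- vapply(modules$smcogs,
                        function(s) paste(sort(s), collapse = ","), "")
  flat$supporting_clusters <- NULL
  readr::write_tsv(flat, path, progress = FALSE)
  json_path <- paste0(sub("\\.tsv$", "", path), ".json")
  support <- purrr::map(
    seq_len(nrow(modules)),
    function(i) list(
      module_id = modules$module_id[i],
      smcogs = sort(modules$smcogs[[i]]),
      supporting_clusters = sort(modules$supporting_clusters[[i]])
    )
  )
  jsonlite::write_json(support, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a module table written by [write_modules()]
#'
#' @param path TSV path previously written by [write_modules()]; the JSON
#'   sidecar is read from the matching `.json` path when present.
#' @return A module tibble with list-columns `smcogs` and (if the sidecar
#'   exists) `supporting_clusters`.
#' @export
read_modules <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  flat$smcogs <- strsplit(flat$smcogs, ",", fixed = TRUE)
  json_path <- paste0(sub("\\.tsv$", "", path), ".json")
  if (file.exists(json_path)) {
    support <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    if (length(support) > 0) {
      idx <- match(flat$module_id, support$module_id)
      flat$supporting_clusters <- lapply(support$supporting_clusters[idx],
                                         as.character)
    }
  }
  flat
}
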