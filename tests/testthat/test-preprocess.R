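test_that("trimming removes low-probability genes from the extremes only", {
  d <- make_dataset(
    list(c("A", "B", "C", "D", "E", "F")),
    domain_prob = list(c(0.05, 0.02, 0.9, 0.05, 0.2, 0.01))
  )
  out <- trim_clusters(d)
  kept <- out$dataset$genes
  expect_equal(kept$smcog_id, c("C", "D", "E"))  # interior 0.05 survives
  expect_equal(kept$position, 0:2)               # re-indexed densely
  expect_equal(out$report$genes_trimmed, 3L)

  # all probabilities at/above threshold: identity
  d2 <- make_dataset(list(c("A", "B")), domain_prob = list(c(0.1, 0.9)))
  expect_equal(trim_clusters(d2)$dataset$genes$smcog_id, c("A", "B"))

  # all below: cluster dropped and counted
  d3 <- make_dataset(list(c("A", "B"), c("C", "D")),
                     domain_prob = list(c(0.01, 0.02), c(0.5, 0.5)))
  out3 <- trim_clusters(d3)
  expect_equal(nrow(out3$dataset$clusters), 1)
  expect_equal(out3$report$clusters_dropped_empty, 1L)

  # missing probabilities: no-op for that cluster
  d4 <- make_dataset(list(c("A", "B")))
  expect_equal(trim_clusters(d4)$dataset$genes$smcog_id, c("A", "B"))
})

test_that("trimming is idempotent", {
  set.seed(42)
  for (rep in 1:10) {
    probs <- round(runif(8), 2)
    d <- make_dataset(list(LETTERS[1:8]), domain_prob = list(probs))
    once <- trim_clusters(d)$dataset
    if (nrow(once$genes) == 0) next
    twice <- trim_clusters(once)$dataset
    expect_equal(twice$genes, once$genes)
  }
})

test_that("small smCOGs are removed but their positions are kept", {
  # A has 3 members (kept, at the default threshold), B has 2 (removed)
  d <- make_dataset(list(c("A", "B", "A"), c("B", "A", ".")))
  out <- filter_smcogs(d)
  g <- out$dataset$genes
  expect_equal(sum(g$smcog_id == "A"), 3)
  expect_false("B" %in% g$smcog_id)
  expect_equal(out$report$smcogs_removed, 1L)
  expect_equal(out$report$genes_unassigned_after_filter, 2L)
  # relabelled genes stay in place: positions unchanged
  expect_equal(g$position[g$cluster_id == "c01"], 0:2)
  expect_equal(g$smcog_id[g$cluster_id == "c01"],
               c("A", UNASSIGNED, "A"))
})

test_that("clusters left without assigned genes are dropped", {
  d <- make_dataset(list(c("A", "A", "A"), c("B", "B", ".")))
  out <- filter_smcogs(d)
  expect_equal(out$dataset$clusters$cluster_id, "c01")
  expect_equal(out$report$clusters_dropped_empty, 1L)
})

test_that("dedupe keeps the shortest cluster per multiset composition", {
  # {A,B,C} x2 with different lengths; {A,A,B} vs {A,B} distinct multisets
  d <- make_dataset(list(
    c("A", "B", "C", ".", "."),            # c01: {A,B,C}, 5 genes
    c("C", "A", "B", ".", ".", ".", "."),  # c02: {A,B,C}, 7 genes -> dropped
    c("A", "A", "B"),                      # c03: {A,A,B}
    c("A", "B", ".")                       # c04: {A,B}
  ))
  out <- dedupe_clusters(d)
  expect_equal(out$dataset$clusters$cluster_id, c("c01", "c03", "c04"))
  expect_equal(out$report$clusters_dropped_redundant, 1L)
})

test_that("dedupe breaks equal-length ties by smallest cluster id", {
  genes <- dplyr::bind_rows(
    tibble::tibble(cluster_id = "c2", gene_id = c("x1", "x2"), position = 0:1,
                   smcog_id = c("A", "B"), category = "other"),
    tibble::tibble(cluster_id = "c1", gene_id = c("y1", "y2"), position = 0:1,
                   smcog_id = c("B", "A"), category = "other")
  )
  out <- dedupe_clusters(bgc_dataset(genes))
  expect_equal(out$dataset$clusters$cluster_id, "c1")
})

test_that("dedupe emits exactly one cluster per composition key", {
  set.seed(7)
  for (rep in 1:5) {
    d <- random_dataset(n_clusters = 12, n_cogs = 3)
    out <- dedupe_clusters(d)$dataset
    keys <- unname(vapply(layout_of(d), function(lab) {
      paste(sort(lab[lab != "."]), collapse = ",")
    }, ""))
    keys_kept <- unname(vapply(layout_of(out), function(lab) {
      paste(sort(lab[lab != "."]), collapse = ",")
    }, ""))
    # clusters with no assigned genes carry no composition key and all stay
    expect_equal(sort(unique(keys[keys != ""])),
                 sort(keys_kept[keys_kept != ""]))
    expect_equal(sum(keys == ""), sum(keys_kept == ""))
  }
})

test_that("smCOG category annotation follows the 60/40/75 rules in order", {
  expect_equal(
    annotate_smcog_category(rep(c("tailoring", "other"), c(7, 3))),
    "tailoring"
  )  # 70% > 60%
  expect_equal(
    annotate_smcog_category(rep(c("other", "transport", "core"), c(10, 9, 1))),
    "transport"
  )  # top is "other"; second at 45% > 40% takes over
  expect_equal(
    annotate_smcog_category(rep(c("core", "tailoring", "other"), c(11, 5, 4))),
    "core/tailoring"
  )  # 55% < 60% but 80% > 75%: double category
  expect_equal(
    annotate_smcog_category(rep(c("core", "tailoring", "transport", "other"),
                                c(5, 5, 5, 5))),
    "mixed"
  )
  # "other" on top never wins while the runner-up clears 40%
  expect_equal(
    annotate_smcog_category(rep(c("other", "core"), c(13, 9))),
    "core"
  )
  # exact ties broken by fixed priority, then the rules proceed
  expect_equal(
    annotate_smcog_category(rep(c("tailoring", "core"), c(5, 5))),
    "core/tailoring"
  )
  expect_error(annotate_smcog_category(character(0)),
               class = "bgc_validation_error")
  expect_error(annotate_smcog_category(c("core", "sporulation")),
               class = "bgc_validation_error")
})

test_that("category annotation is total over random frequency vectors", {
  set.seed(11)
  single <- GENE_CATEGORIES
  doubles <- apply(expand.grid(single, single), 1, paste, collapse = "/")
  valid <- c(single, doubles, "mixed")
  for (rep in 1:50) {
    cats <- sample(GENE_CATEGORIES, sample(1:40, 1), replace = TRUE)
    expect_true(annotate_smcog_category(cats) %in% valid)
  }
})

test_that("the combined preprocess report is consistent with dataset sizes", {
  d <- make_dataset(
    list(c("A", "B", "A"), c("B", "A", "C"), c("A", "B", ".")),
    domain_prob = list(c(0.5, 0.5, 0.05), c(0.9, 0.9, 0.9), c(0.3, 0.3, 0.3))
  )
  out <- preprocess_dataset(d)
  expect_s3_class(out$report, "preprocess_report")
  n_before <- nrow(d$genes)
  n_after <- nrow(out$dataset$genes)
  dropped_gene_rows <- n_before - n_after
  expect_gte(dropped_gene_rows, out$report$genes_trimmed)
  expect_true(all(unlist(out$report) >= 0))
})
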