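test_that("adjacency counting classifies positions by neighbouring fixed genes", {
  # [A, B, ., A]: both open positions have exactly one A neighbour
  d <- make_dataset(list(c("A", "B", ".", "A")))
  p <- count_adjacency(d, "A", "B")
  expect_equal(unname(p$capacities), c(0, 2, 0))
  expect_equal(unname(p$occupancies), c(0, 1, 0))
  expect_equal(p$N_tot, 2)
  expect_equal(p$B_tot, 1)
  expect_equal(p$i_orig, 1)

  # middle position of [A, ., A] is flanked by two A genes: class c
  d2 <- make_dataset(list(c("A", ".", "A"), c("B", ".", ".")))
  p2 <- count_adjacency(d2, "A", "B")
  expect_equal(unname(p2$capacities), c(3, 0, 1))
  expect_equal(p2$i_orig, 0)

  # A and B never share a cluster: all B genes in class a
  d3 <- make_dataset(list(c("A", "."), c("B", "B")))
  p3 <- count_adjacency(d3, "A", "B")
  expect_equal(p3$i_orig, 0)
  expect_equal(unname(p3$occupancies), c(2, 0, 0))

  expect_error(count_adjacency(d, "A", "A"), class = "bgc_validation_error")
  expect_error(count_adjacency(d, "A", UNASSIGNED),
               class = "bgc_validation_error")
})

test_that("adjacency i_orig equals direct recounting on random datasets", {
  set.seed(101)
  for (rep in 1:20) {
    d <- random_dataset(n_clusters = 4, n_cogs = 3)
    layout <- layout_of(d)
    cogs <- setdiff(unique(d$genes$smcog_id), UNASSIGNED)
    if (length(cogs) < 2) next
    pair <- sample(cogs, 2)
    p <- count_adjacency(d, pair[1], pair[2])
    expect_equal(p$i_orig, recount_adjacency(layout, pair[1], pair[2]))
    # symmetric under role swap: each adjacent pair counts once either way
    q <- count_adjacency(d, pair[2], pair[1])
    expect_equal(q$i_orig, p$i_orig)
  }
})

test_that("profile invariants hold on random datasets", {
  set.seed(202)
  for (rep in 1:15) {
    d <- random_dataset()
    cogs <- setdiff(unique(d$genes$smcog_id), UNASSIGNED)
    if (length(cogs) < 2) next
    pair <- sample(cogs, 2)
    for (p in list(count_adjacency(d, pair[1], pair[2]),
                   count_colocalization(d, pair[1], pair[2]))) {
      expect_equal(sum(p$capacities), p$N_tot)
      expect_equal(sum(p$occupancies), p$B_tot)
      expect_true(all(p$occupancies <= p$capacities))
      w <- bgcmodules:::interaction_weights(p$kind)
      expect_lte(p$i_orig, sum(w * pmin(p$capacities, p$B_tot)))
    }
  }
})

test_that("duplicate collapse empties in place and appends blocks in order", {
  d <- make_dataset(list(c("A", "B", "A", "C")))
  out <- collapse_duplicates(d)
  expect_equal(layout_of(out)$c01, c(".", "B", ".", "C", ".", "A", "A"))

  d2 <- make_dataset(list(c("A", "A", "A")))
  expect_equal(layout_of(collapse_duplicates(d2))$c01,
               c(".", ".", ".", ".", "A", "A", "A"))

  # no duplicates: identity
  d3 <- make_dataset(list(c("A", "B", "."), c("C", "A", ".")))
  expect_equal(layout_of(collapse_duplicates(d3)), layout_of(d3))

  # two duplicated cogs append in first-occurrence order
  d4 <- make_dataset(list(c("B", "A", "B", "A", "C")))
  expect_equal(layout_of(collapse_duplicates(d4))$c01,
               c(".", ".", ".", ".", "C", ".", "B", "B", ".", "A", "A"))

  # length grows by one separator per duplicated cog
  expect_equal(length(layout_of(out)$c01), 4 + 2 + 1)
})

test_that("duplicate collapse is idempotent and preserves gene multisets", {
  set.seed(303)
  for (rep in 1:10) {
    d <- random_dataset(allow_dups = TRUE)
    once <- collapse_duplicates(d)
    twice <- collapse_duplicates(once)
    expect_identical(twice$genes, once$genes)
    tab_before <- table(d$genes$smcog_id[d$genes$smcog_id != UNASSIGNED])
    tab_after <- table(once$genes$smcog_id[once$genes$smcog_id != UNASSIGNED])
    expect_equal(tab_before, tab_after)
  }
})

test_that("colocalization counts moving genes co-resident with the fixed cog", {
  d <- make_dataset(list(c("A", ".", "B"), c(".", ".", ".")))
  p <- count_colocalization(d, "A", "B")
  expect_equal(unname(p$capacities), c(3, 2))
  expect_equal(p$N_tot, 5)
  expect_equal(p$B_tot, 1)
  expect_equal(p$i_orig, 1)

  # duplicated moving cog: both copies count after collapse
  d2 <- make_dataset(list(c("A", "B", "B")))
  p2 <- count_colocalization(d2, "A", "B")
  expect_equal(p2$i_orig, 2)
  expect_equal(unname(p2$capacities), c(0, 5))  # collapsed length 6 minus A

  # never co-resident
  d3 <- make_dataset(list(c("A", "."), c("B", ".")))
  expect_equal(count_colocalization(d3, "A", "B")$i_orig, 0)
})

test_that("colocalization i_orig matches direct recounting (no duplicates)", {
  set.seed(404)
  for (rep in 1:15) {
    d <- random_dataset(allow_dups = FALSE)
    cogs <- setdiff(unique(d$genes$smcog_id), UNASSIGNED)
    if (length(cogs) < 2) next
    pair <- sample(cogs, 2)
    p <- count_colocalization(d, pair[1], pair[2])
    expect_equal(p$i_orig,
                 recount_colocalization(layout_of(d), pair[1], pair[2]))
    # without duplicated cogs the count is symmetric in the two roles
    expect_equal(count_colocalization(d, pair[2], pair[1])$i_orig, p$i_orig)
  }
})

test_that("candidate pairs are exactly the co-resident unordered pairs", {
  d <- make_dataset(list(c("A", "B", "."), c("C", ".", "."), c("B", "A", ".")))
  pairs <- enumerate_candidate_pairs(d)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$cog_a, "A")
  expect_equal(pairs$cog_b, "B")

  d2 <- make_dataset(list(c("A", "."), c("B", "."), c("C", ".")))
  expect_equal(nrow(enumerate_candidate_pairs(d2)), 0)

  d3 <- make_dataset(list(c("A", "B", "C")))
  pairs3 <- enumerate_candidate_pairs(d3)
  expect_equal(nrow(pairs3), 3)
  expect_true(all(pairs3$cog_a < pairs3$cog_b))
})
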