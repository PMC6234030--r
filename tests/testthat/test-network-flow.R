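test_that("class aggregation sums member cells and normalizes to 100%", {
  g <- generate_glomerulus(small_config(seed = 19))
  contacts <- expand_contacts(g$dataset)
  inc <- filter_included_bodies(cell_contact_totals(contacts), min_total = 10)
  mat <- build_contact_matrix(contacts, inc, g$dataset$cells)

  agg <- aggregate_by_class(mat, g$dataset$cells, level = "major")
  labels <- major_class(class_of_body(as.integer(rownames(mat)),
                                      g$dataset$cells))
  ref <- oracle_class_agg(mat, labels)
  expect_identical(agg$class_matrix[rownames(ref), colnames(ref), drop = FALSE], ref)
  expect_equal(sum(agg$flows$percent_of_total), 100)
  expect_identical(sum(agg$class_matrix), sum(mat))

  # single-class matrix: one flow at 100%
  one <- matrix(c(0L, 2L, 3L, 0L), 2, 2,
                dimnames = list(c("101", "102"), c("101", "102")))
  cells1 <- cell_table(101:102, c("a", "b"), "LN")
  agg1 <- aggregate_by_class(one, cells1)
  expect_identical(nrow(agg1$flows), 1L)
  expect_identical(agg1$flows$percent_of_total, 100)

  # subtype level gives a finer partition that sums to the same total
  agg_sub <- aggregate_by_class(mat, g$dataset$cells, level = "subtype")
  expect_identical(sum(agg_sub$class_matrix), sum(mat))
  expect_gte(nrow(agg_sub$flows), nrow(agg$flows))
})

test_that("aggregation commutes with totalling and scaling", {
  set.seed(3)
  m <- random_count_matrix(12, p_zero = 0.3)
  ids <- as.integer(rownames(m))
  cells <- cell_table(ids, paste0("c", ids),
                      sample(c("PN", "LN", "ORN_ipsi"), 12, replace = TRUE))
  agg <- aggregate_by_class(m, cells)
  expect_identical(sum(agg$class_matrix), sum(m))
  m3 <- m * 3L
  agg3 <- aggregate_by_class(m3, cells)
  expect_equal(agg3$flows$percent_of_total, agg$flows$percent_of_total)

  cells$cell_class[1] <- NA
  expect_error(aggregate_by_class(m, cells), as.character(ids[1]))
})

test_that("aggregate class ratios come from the matrix margins", {
  m <- matrix(0L, 2, 2, dimnames = list(c("101", "102"), c("101", "102")))
  m["101", "102"] <- 6L  # ORN -> PN
  m["102", "101"] <- 2L  # PN -> ORN
  cells <- cell_table(101:102, c("orn", "pn"), c("ORN_ipsi", "PN"))
  r <- class_pre_post_ratio(m, cells)
  expect_identical(r$ratio[r$group == "ORN_ipsi"], 6 / 2)
  expect_identical(r$ratio[r$group == "PN"], 2 / 6)
})

test_that("ratio classification applies ordered closed/open thresholds", {
  st <- data.frame(
    body_id = 1:8,
    pre_post_ratio = c(3.9, 1.0, 0.06, 2.5, 0.6, 2.49, 0.61, NA)
  )
  cls <- classify_by_ratio(st)
  expect_identical(
    cls$predicted_class,
    c("ORN", "LN", "PN", "ORN", "PN", "LN", "LN", "unclassifiable")
  )
  # determinism and boundary confidence notes
  expect_identical(cls, classify_by_ratio(st))
  expect_true(cls$near_boundary[cls$body_id == 4])   # at 2.5
  expect_true(cls$near_boundary[cls$body_id == 6])   # within 20% of 2.5
  expect_false(cls$near_boundary[cls$body_id == 2])  # 1.0 sits mid-band
})

test_that("ratio classifier recovers generator truth on synthetic data", {
  g <- generate_glomerulus(synth_config(seed = 42, total_tbars = 4000))
  d <- g$dataset
  contacts <- expand_contacts(d)
  inc <- filter_included_bodies(cell_contact_totals(contacts))
  st <- per_cell_stats(d, contacts)
  cls <- classify_by_ratio(st)
  truth <- major_class(unname(g$truth$classes[as.character(st$body_id)]))
  sel <- !is.na(truth) & truth %in% c("ORN", "PN", "LN") &
    st$body_id %in% inc
  expect_gte(mean(cls$predicted_class[sel] == truth[sel]), 0.85)
})

test_that("network export writes GraphML/DOT and edge lists round-trip", {
  m <- matrix(c(0L, 0L, 7L, 0L), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(m, f, "graphml", classes = c(A = "PN", B = "LN"))
  g <- igraph::read_graph(f, format = "graphml")
  expect_identical(igraph::ecount(g), 1)
  expect_identical(igraph::V(g)$class, c("PN", "LN"))
  e <- igraph::as_data_frame(g)
  expect_identical(e$weight, 7)
  expect_identical(e$from, "A")

  fdot <- withr::local_tempfile(fileext = ".dot")
  export_network(m, fdot, "dot")
  expect_true(any(grepl("->", readLines(fdot))))

  set.seed(4)
  big <- random_count_matrix(8, p_zero = 0.4)
  fel <- withr::local_tempfile(fileext = ".csv")
  export_network(big, fel, "edgelist")
  back <- read_matrix(fel, layout = "edgelist")
  expect_identical(sum(back), sum(big))

  expect_error(export_network(m, f, "pajek"))
})

test_that("the synthetic class network has a recurrent loop per major class", {
  g <- generate_glomerulus(small_config(seed = 29))
  contacts <- expand_contacts(g$dataset)
  inc <- filter_included_bodies(cell_contact_totals(contacts), min_total = 10)
  mat <- build_contact_matrix(contacts, inc, g$dataset$cells)
  cm <- aggregate_by_class(mat, g$dataset$cells)$class_matrix
  for (cl in c("ORN", "LN", "PN")) {
    expect_gt(cm[cl, cl], 0L)
  }
})
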