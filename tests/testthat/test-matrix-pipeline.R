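test_that("polyadic synapses expand to one directed contact per PSD", {
  d <- tiny_dataset()
  contacts <- expand_contacts(d)
  expect_identical(nrow(contacts), nrow(d$psds))
  # T-bar 1 on body 1 drives PSDs on 2, 3, 2
  c1 <- contacts[contacts$tbar_id == 1, ]
  expect_identical(c1$pre_body, rep(1L, 3))
  expect_identical(sort(c1$post_body), c(2L, 2L, 3L))
  expect_false(any(contacts$is_autapse))

  # an autapse is flagged and retained
  d$psds <- rbind(d$psds,
                  data.frame(psd_id = 7L, tbar_id = 3L, post_body = 2L,
                             x = 1, y = 1, z = 1))
  contacts <- expand_contacts(d)
  expect_identical(sum(contacts$is_autapse), 1L)
  expect_identical(contacts$pre_body[contacts$is_autapse],
                   contacts$post_body[contacts$is_autapse])
})

test_that("contact totals conserve and match a brute-force recount", {
  g <- generate_glomerulus(small_config(seed = 13))
  contacts <- expand_contacts(g$dataset)
  tot <- cell_contact_totals(contacts)
  expect_identical(sum(tot$pre_contacts), nrow(contacts))
  expect_identical(sum(tot$post_contacts), nrow(contacts))
  ref <- oracle_totals(contacts)
  expect_equal(tot, ref, ignore_attr = TRUE)
})

test_that("the inclusion filter cuts strictly above 50 contacts", {
  tot <- data.frame(body_id = 1:4,
                    pre_contacts = c(50L, 26L, 60L, 0L),
                    post_contacts = c(0L, 25L, 0L, 50L),
                    total = c(50L, 51L, 60L, 50L))
  expect_identical(filter_included_bodies(tot), c(2L, 3L))
  # "either" mode requires one direction alone to reach the threshold
  expect_identical(filter_included_bodies(tot, count_mode = "either"), 3L)
  expect_identical(filter_included_bodies(tot, min_total = 1),
                   1:4)
})

test_that("the contact matrix conserves contacts and counts autapses on the diagonal", {
  g <- generate_glomerulus(small_config(seed = 17))
  contacts <- expand_contacts(g$dataset)
  tot <- cell_contact_totals(contacts)
  inc <- filter_included_bodies(tot, min_total = 20)
  mat <- build_contact_matrix(contacts, inc, g$dataset$cells)

  both_in <- contacts$pre_body %in% inc & contacts$post_body %in% inc
  expect_identical(sum(mat), sum(both_in))
  # conservation: matrix total + contacts touching excluded bodies = all PSDs
  expect_identical(sum(mat) + sum(!both_in), nrow(g$dataset$psds))

  ref <- oracle_matrix(contacts, inc)
  expect_identical(mat[rownames(ref), colnames(ref), drop = FALSE], ref)

  auta <- contacts[contacts$is_autapse & contacts$pre_body %in% inc, ]
  for (b in as.character(unique(auta$pre_body))) {
    expect_identical(mat[b, b], sum(auta$pre_body == as.integer(b)))
  }
  expect_error(build_contact_matrix(contacts, integer()), "no included")
})

test_that("matrix rows follow the PN, LN, ORN display convention", {
  g <- generate_glomerulus(small_config(seed = 1))
  contacts <- expand_contacts(g$dataset)
  inc <- filter_included_bodies(cell_contact_totals(contacts), min_total = 20)
  mat <- build_contact_matrix(contacts, inc, g$dataset$cells)
  cls <- class_of_body(as.integer(rownames(mat)), g$dataset$cells)
  seen <- unique(cls)
  want <- c("PN", "LN", "ORN_ipsi", "ORN_contra", "other", "orphan")
  expect_identical(seen, want[want %in% seen])
})

test_that("per-cell statistics follow their definitions on a constructed cell", {
  # 10 T-bars with 3 PSDs each driven by body 1; body 1 receives 5 PSDs
  cells <- cell_table(1:2, c("a", "b"), c("PN", "LN"),
                      volume_um3 = c(5, NA))
  tbars <- data.frame(tbar_id = 1:11, pre_body = c(rep(1L, 10), 2L),
                      x = 0, y = 0, z = 0)
  psds <- data.frame(
    psd_id = 1:35,
    tbar_id = c(rep(1:10, each = 3), rep(11L, 5)),
    post_body = c(rep(2L, 30), rep(1L, 5)),
    x = 0, y = 0, z = 0
  )
  d <- glomerulus_dataset(cells, tbars, psds, 100)
  st <- per_cell_stats(d)
  r1 <- st[st$body_id == 1, ]
  expect_identical(r1$n_tbars, 10L)
  expect_identical(r1$psds_per_tbar, 3.0)
  expect_identical(r1$pre_post_ratio, 6.0)
  expect_identical(r1$tbar_density, 2.0)
  # undefined ratios and densities are flagged missing, not infinite
  r2 <- st[st$body_id == 2, ]
  expect_true(is.na(r2$tbar_density))
  expect_identical(r2$pre_post_ratio, 5 / 30)
  d0 <- glomerulus_dataset(cells, tbars[1:10, ], psds[1:30, ], 100)
  st0 <- per_cell_stats(d0)
  expect_true(is.na(st0$pre_post_ratio[st0$body_id == 1]))
  expect_true(is.na(st0$psds_per_tbar[st0$body_id == 2]))
})

test_that("T-bars without PSDs are dropped from counts and density", {
  d <- tiny_dataset()
  d$tbars <- rbind(d$tbars,
                   data.frame(tbar_id = 9L, pre_body = 3L,
                              x = 0, y = 0, z = 0))
  st <- per_cell_stats(d)
  expect_identical(st$n_tbars[st$body_id == 3], 0L)
  expect_identical(synapse_density(d), 3 / 100)
})

test_that("strength distributions match a brute-force histogram", {
  set.seed(99)
  for (trial in 1:20) {
    m <- random_count_matrix(10)
    dist <- strength_distribution(m)
    ref <- oracle_strengths(m)
    expect_identical(stats::setNames(dist$n_pairs, dist$strength), ref)
    expect_identical(sum(dist$n_pairs), sum(m > 0))
    # cumulative tail equals direct count
    for (k in c(1, 3, 11)) {
      expect_identical(strength_tail(dist, k), sum(m >= k))
    }
  }
  all_ones <- matrix(1L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_identical(strength_tail(strength_distribution(all_ones), 3), 0L)
})

test_that("synapse density is a simple volumetric ratio", {
  cells <- cell_table(1L, "a", "PN")
  tbars <- data.frame(tbar_id = 1:2, pre_body = 1L, x = 0, y = 0, z = 0)
  psds <- data.frame(psd_id = 1:2, tbar_id = 1:2, post_body = 1L,
                     x = 0, y = 0, z = 0)
  d <- glomerulus_dataset(cells, tbars, psds, 4)
  expect_identical(synapse_density(d), 0.5)
  d_half <- glomerulus_dataset(cells, tbars, psds, 2)
  expect_identical(synapse_density(d_half), 2 * synapse_density(d))
  d_none <- glomerulus_dataset(cells, tbars, psds[0, ], 4)
  expect_identical(synapse_density(d_none), 0)
})

test_that("permuting synapse order leaves every output unchanged", {
  g <- generate_glomerulus(small_config(seed = 23))
  d <- g$dataset
  d2 <- d
  set.seed(1)
  d2$psds <- d2$psds[sample(nrow(d2$psds)), ]
  d2$tbars <- d2$tbars[sample(nrow(d2$tbars)), ]

  c1 <- expand_contacts(d)
  c2 <- expand_contacts(d2)
  t1 <- cell_contact_totals(c1)
  t2 <- cell_contact_totals(c2)
  expect_identical(t1, t2)
  i1 <- filter_included_bodies(t1)
  expect_identical(build_contact_matrix(c1, i1, d$cells),
                   build_contact_matrix(c2, i1, d2$cells))
  s1 <- per_cell_stats(d, c1)
  s2 <- per_cell_stats(d2, c2)
  expect_identical(s1, s2)
})
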