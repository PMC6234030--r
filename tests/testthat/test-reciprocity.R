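test_that("pair tables read both directions off the matrix, diagonal excluded", {
  m <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- 5L
  m["C", "C"] <- 4L  # autapses never form a pair
  p <- pair_table(m)
  expect_identical(nrow(p), 1L)
  expect_identical(p$forward, 5L)
  expect_identical(p$backward, 0L)
  expect_true(is.na(p$ratio))

  m["B", "A"] <- 5L
  p <- pair_table(m)
  expect_identical(p$ratio, 1.0)
})

test_that("reciprocity flags respect thresholds and band boundaries", {
  m <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m["A", "B"] <- 12L

  m["B", "A"] <- 2L  # 12 vs 2: not reciprocal at min_each = 3
  ra <- reciprocity_analysis(pair_table(m))
  expect_false(ra$pairs$reciprocal)
  expect_identical(ra$summary$n_reciprocal, 0L)

  m["B", "A"] <- 3L  # 12 vs 3: ratio exactly 4, on the closed band edge
  within <- reciprocity_analysis(pair_table(m))
  expect_true(within$pairs$reciprocal)
  expect_identical(within$pairs$ratio, 4.0)
  expect_true(within$pairs$strong)
  outside <- reciprocity_analysis(pair_table(m), band_mode = "outside")
  expect_true(outside$pairs$strong)  # >= 4:1 in one direction

  m["B", "A"] <- 4L  # ratio 3: inside the band, not a 4:1 imbalance
  expect_true(reciprocity_analysis(pair_table(m))$pairs$strong)
  expect_false(reciprocity_analysis(pair_table(m),
                                    band_mode = "outside")$pairs$strong)

  expect_error(reciprocity_analysis(pair_table(m), band = c(4, 0.25)),
               "band")
})

test_that("pair analysis matches an exhaustive double-loop reference", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(3:12, 1)
    m <- random_count_matrix(n, max_count = 8, p_zero = 0.4)
    ra <- reciprocity_analysis(pair_table(m))
    ref <- oracle_pairs(m)
    if (is.null(ref)) {
      expect_identical(nrow(ra$pairs), 0L)
      next
    }
    got <- ra$pairs[order(ra$pairs$body_a, ra$pairs$body_b), ]
    ref <- ref[order(ref$body_a, ref$body_b), ]
    expect_equal(got, ref, ignore_attr = TRUE)
    expect_identical(ra$summary$n_universe, sum(ref$in_universe))
    expect_identical(ra$summary$n_reciprocal, sum(ref$reciprocal))
    expect_identical(ra$summary$n_strong, sum(ref$strong))
  }
})

test_that("n_strong <= n_reciprocal <= n_universe for any band and threshold", {
  set.seed(21)
  for (trial in 1:25) {
    m <- random_count_matrix(8, max_count = 15, p_zero = 0.3)
    min_each <- sample(1:5, 1)
    lo <- stats::runif(1, 0.05, 1)
    hi <- lo * stats::runif(1, 1, 10)
    for (mode in c("within", "outside")) {
      ra <- reciprocity_analysis(pair_table(m), min_each = min_each,
                                 band = c(lo, hi), band_mode = mode)
      s <- ra$summary
      expect_lte(s$n_strong, s$n_reciprocal)
      expect_lte(s$n_reciprocal, s$n_universe)
    }
  }
})

test_that("relabelling bodies permutes but preserves the pair multiset", {
  set.seed(5)
  m <- random_count_matrix(7, p_zero = 0.4)
  perm <- sample(nrow(m))
  m2 <- m[perm, perm]
  key <- function(p) sort(paste(pmin(p$forward, p$backward),
                                pmax(p$forward, p$backward)))
  expect_identical(key(pair_table(m)), key(pair_table(m2)))
})

test_that("the ratio matrix reflects inversely about the diagonal", {
  m <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m["A", "B"] <- 8L
  m["B", "A"] <- 2L
  ra <- reciprocity_analysis(pair_table(m), min_each = 2)
  rm <- reciprocity_matrix(ra)
  expect_identical(rm["A", "B"], 4.0)
  expect_identical(rm["B", "A"], 0.25)

  set.seed(31)
  m <- random_count_matrix(9, p_zero = 0.3)
  ra <- reciprocity_analysis(pair_table(m))
  rm <- reciprocity_matrix(ra, bodies = rownames(m))
  filled <- which(!is.na(rm), arr.ind = TRUE)
  for (k in seq_len(nrow(filled))) {
    i <- filled[k, 1]; j <- filled[k, 2]
    expect_equal(rm[i, j], 1 / rm[j, i])
    expect_true(m[i, j] >= 3 && m[j, i] >= 3)  # only reciprocal pairs filled
    expect_equal(rm[i, j], m[i, j] / m[j, i])
  }
  # and every reciprocal pair is filled
  rec <- ra$pairs[ra$pairs$reciprocal, ]
  for (k in seq_len(nrow(rec))) {
    expect_false(is.na(rm[rec$body_a[k], rec$body_b[k]]))
  }
})

test_that("class-pair reciprocity summarizes percentages and direction", {
  # two mPN1 cells and two LN1 cells with known cross-class structure:
  # p1->l1 9/3 (reciprocal, PN-dominant), p2->l2 6/2 (one-way: 2 < 3),
  # p1->l2 4/4 (reciprocal, tie counts as forward-dominant), l1->p2 5/0
  labs <- c("p1", "p2", "l1", "l2")
  m <- matrix(0L, 4, 4, dimnames = list(labs, labs))
  m["p1", "l1"] <- 9L; m["l1", "p1"] <- 3L
  m["p2", "l2"] <- 6L; m["l2", "p2"] <- 2L
  m["p1", "l2"] <- 4L; m["l2", "p1"] <- 4L
  m["l1", "p2"] <- 5L
  classes <- c(p1 = "mPN1", p2 = "mPN1", l1 = "LN1", l2 = "LN1")
  ra <- reciprocity_analysis(pair_table(m))
  cp <- class_pair_reciprocity(ra, classes)
  row <- cp[cp$class_a == "LN1" & cp$class_b == "mPN1", ]
  expect_identical(row$n_pairs, 4L)
  expect_identical(row$n_reciprocal, 2L)
  expect_identical(row$pct_reciprocal, 50)
  expect_identical(row$dominant_pre, "mPN1")
  expect_identical(row$pct_dominant, 100)
  expect_equal(row$mean_ratio, mean(c(9 / 3, 4 / 4)))

  # unlabelled bodies are an error; absent classes yield no row
  expect_error(class_pair_reciprocity(ra, classes[-1]), "p1")
  expect_false("ORN" %in% c(cp$class_a, cp$class_b))
})
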