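test_that("the utilization index is one minus found over expected", {
  # pooled 80% of indexed elements present (64 of 80 units) -> index 20%
  nec <- necropsies_of(
    necropsy_row("C1", 2000, c(humerus = 0, femur = 0,
                               scapula = 0, radius_ulna = 0)),    # 8/16
    necropsy_row("C2", 2000, c(humerus = 0, femur = 0,
                               scapula = 0, radius_ulna = 0)),    # 8/16
    necropsy_row("C3", 2000), necropsy_row("C4", 2000),
    necropsy_row("C5", 2000)
  )
  expect_equal(utilization_index(nec), 0.2)
  expect_equal(utilization_index(necropsies_of(necropsy_row("C1", 2000))), 0)
  all_gone <- necropsy_row("C1", 2000,
                           stats::setNames(rep(0, 8), default_index_elements()))
  expect_equal(utilization_index(necropsies_of(all_gone)), 1)
})

test_that("found counts beyond a complete skeleton are rejected", {
  expect_error(necropsies_of(necropsy_row("C1", 2000, c(humerus = 3))),
               "exceeds the expected")
  expect_error(utilization_index(necropsies_of(necropsy_row("C1", 2000)),
                                 elements = "tusk"), "unknown element")
})

test_that("presence/absence elements map presence to the full pair", {
  nec <- necropsies_of(necropsy_row("C1", 2000, c(metacarpus = 1)))
  expect_equal(nec$metacarpus, 2L)
  nec0 <- necropsies_of(necropsy_row("C2", 2000, c(metatarsus = 0)))
  expect_equal(utilization_index(nec0, elements = "metatarsus"), 1)
})

test_that("per-element removal proportions match hand computation", {
  rows <- lapply(1:10, function(i) {
    necropsy_row(sprintf("C%02d", i), 2000,
                 c(humerus = if (i <= 2) 1 else 2))
  })
  nec <- necropsies_of(do.call(rbind, rows))
  expect_equal(element_removal_proportion(nec, "humerus"), 2 / 20)  # 18 of 20
  expect_equal(element_removal_proportion(nec, "femur"), 0)
})

test_that("moving averages are centered with truncated edges", {
  expect_equal(moving_average(c(1, 2, 3, 4), 3), c(1.5, 2, 3, 3.5))
  expect_equal(moving_average(rep(7, 6), 5), rep(7, 6))
  expect_equal(moving_average(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_error(moving_average(1:4, 2), "odd")
  set.seed(808)
  x <- stats::runif(30)
  for (w in c(3, 5, 7)) {
    sm <- moving_average(x, w)
    expect_length(sm, length(x))
    half <- (w - 1) / 2
    for (i in seq_along(x)) {
      win <- x[max(1, i - half):min(length(x), i + half)]
      expect_gte(sm[i], min(win))
      expect_lte(sm[i], max(win))
    }
  }
})

test_that("yearly pooling equals the expected-count-weighted mean of per-carcass indices", {
  set.seed(909)
  nec <- simulate_necropsies(30, 1997:2001, 0.25, seed = 3)
  ys <- yearly_series(nec)
  for (r in seq_len(nrow(ys))) {
    sub <- nec[nec$year == ys$year[r], , drop = FALSE]
    per_carcass <- vapply(seq_len(nrow(sub)), function(i) {
      utilization_index(sub[i, , drop = FALSE])
    }, 0)
    # equal expected counts per carcass: pooled == plain mean
    expect_equal(ys$proportion_removed[r], mean(per_carcass))
  }
  expect_equal(ys$smoothed, moving_average(ys$proportion_removed, 3))
})

test_that("a constant removal probability is recovered within binomial bounds", {
  # count-based elements only: yearly missing totals are exactly binomial
  counted <- setdiff(default_index_elements(), c("metacarpus", "metatarsus"))
  nec <- simulate_necropsies(100, 1997:2016, 0.2, seed = 21,
                             elements = counted)
  ys <- yearly_series(nec, elements = counted)
  expect_equal(nrow(ys), 20)
  n_units <- 100 * 12
  lo <- stats::qbinom(0.005, n_units, 0.2) / n_units
  hi <- stats::qbinom(0.995, n_units, 0.2) / n_units
  expect_true(all(ys$proportion_removed >= lo & ys$proportion_removed <= hi))
  # pooled proportion over the full default index concentrates tightly
  nec_full <- simulate_necropsies(100, 1997:2016, 0.2, seed = 21)
  expect_lt(abs(utilization_index(nec_full) - 0.2), 0.01)
})

test_that("deterministic two-year inputs give the exact series", {
  rows <- c(
    lapply(1:10, function(i) {
      found <- if (i <= 8) c() else stats::setNames(rep(0, 8),
                                                    default_index_elements())
      necropsy_row(sprintf("A%02d", i), 1997, found)
    }),
    lapply(1:10, function(i) {
      necropsy_row(sprintf("B%02d", i), 1998,
                   c(humerus = 0, femur = 0, scapula = 0, radius_ulna = 0,
                     mandible = if (i <= 8) 2 else 0))
    })
  )
  nec <- necropsies_of(do.call(rbind, rows))
  ys <- yearly_series(nec)
  expect_equal(ys$proportion_removed[1], 0.2)  # 2 of 10 carcasses fully stripped
  expect_equal(ys$proportion_removed[2], (8 * 8 + 2 * 10) / 160)
})

test_that("period splits recover known removal proportions and detect the shift", {
  nec_e <- simulate_necropsies(100, 1997:2006, 0.15, seed = 31)
  nec_l <- simulate_necropsies(100, 2007:2016, 0.20, seed = 32)
  nec_l$carcass_id <- paste0("L", nec_l$carcass_id)
  nec <- necropsy_records(rbind(as.data.frame(nec_e), as.data.frame(nec_l)))
  sp <- period_split_comparison(nec, cut_year = 2006)
  expect_lt(abs(sp$early - 0.15), 0.02)
  expect_lt(abs(sp$late - 0.20), 0.02)
  expect_lt(sp$test$p.value, 0.05)

  # identical periods: equal proportions, p near 1
  same <- necropsies_of(
    necropsy_row("E1", 2000, c(humerus = 0)),
    necropsy_row("L1", 2010, c(humerus = 0))
  )
  sp2 <- period_split_comparison(same, cut_year = 2006)
  expect_equal(sp2$early, sp2$late)
  expect_equal(sp2$test$p.value, 1)

  # one carcass per period, all-present vs all-missing
  stripped <- necropsy_row("L1", 2010,
                           stats::setNames(rep(0, 8), default_index_elements()))
  sp3 <- period_split_comparison(
    necropsies_of(necropsy_row("E1", 2000), stripped), cut_year = 2006)
  expect_equal(sp3$early, 0)
  expect_equal(sp3$late, 1)
})
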