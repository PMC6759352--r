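test_that("all percents match a brute-force enumeration on random small samples", {
  set.seed(101)
  dent <- wolf_dentition()
  for (rep in 1:25) {
    n_skulls <- sample(1:5, 1)
    rows <- lapply(seq_len(n_skulls), function(s) {
      m <- sample(1:10, 1)
      skull_df(sprintf("S%02d", s),
               sample(c("intact", "broken", "missing"), m, replace = TRUE),
               codes = sample(dent$tooth_code, m))
    })
    rec <- records_of(do.call(rbind, rows))

    # naive per-tooth and per-individual counts by explicit loops
    brk <- obs <- 0
    brk_nc <- obs_nc <- 0
    skull_has_break <- logical(n_skulls)
    for (i in seq_len(nrow(rec))) {
      is_canine <- parse_tooth_code(rec$tooth_code[i])$tooth_class == "canine"
      if (rec$status[i] != "missing") {
        obs <- obs + 1
        if (!is_canine) obs_nc <- obs_nc + 1
      }
      if (rec$status[i] == "broken") {
        brk <- brk + 1
        if (!is_canine) brk_nc <- brk_nc + 1
        skull_has_break[match(rec$skull_id[i], sort(unique(rec$skull_id)))] <- TRUE
      }
    }
    if (obs > 0) {
      expect_equal(percent_teeth_broken(rec),
                   naive_pct(brk, obs, 1))
    }
    if (obs_nc > 0) {
      expect_equal(percent_teeth_broken(rec, include_canines = FALSE),
                   naive_pct(brk_nc, obs_nc, 1))
    }
    expect_equal(percent_individuals_with_fracture(rec),
                 naive_pct(sum(skull_has_break), n_skulls, 1))
  }
})

test_that("canine exclusion removes exactly the canine counts", {
  set.seed(202)
  for (rep in 1:10) {
    spec <- hazard_spec(40, c(`2` = 0.3, `5` = 0.4, `8` = 0.3),
                        hazards = 0.05, seed = rep)
    rec <- simulate_population(spec)
    with_c <- fracture_counts(rec, include_canines = TRUE)
    no_c <- fracture_counts(rec, include_canines = FALSE)
    canines <- rec[rec$tooth_class == "canine", ]
    expect_equal(with_c[["n_broken"]] - no_c[["n_broken"]],
                 sum(canines$status == "broken"))
    expect_equal(with_c[["n_observed"]] - no_c[["n_observed"]],
                 sum(canines$status != "missing"))
  }
})

test_that("per-tooth frequency never exceeds per-individual frequency on equal dentitions", {
  set.seed(303)
  for (rep in 1:10) {
    spec <- hazard_spec(60, c(`3` = 0.5, `7` = 0.5), hazards = 0.04,
                        teeth_per_skull = 30, seed = 100 + rep)
    rec <- simulate_population(spec)
    expect_lte(percent_teeth_broken(rec, decimals = 6),
               percent_individuals_with_fracture(rec, decimals = 6))
  }
})

test_that("tooth-class breakdown matches hand counts and conserves the partition", {
  # 3 skulls with enumerated per-class counts
  rec <- records_of(
    skull_df("A", c("broken", "intact", "intact", "broken", "intact"),
             codes = c("U_L_I1", "U_L_C1", "U_L_P1", "U_L_P4", "U_L_M1")),
    skull_df("B", c("intact", "broken", "missing"),
             codes = c("U_R_I1", "U_R_C1", "U_R_P4")),
    skull_df("C", c("intact", "intact"), codes = c("L_L_M1", "L_L_M2"))
  )
  by_cls <- fracture_by_tooth_class(rec)
  expect_equal(by_cls$n_observed[by_cls$tooth_class == "incisor"], 2)
  expect_equal(by_cls$n_broken[by_cls$tooth_class == "incisor"], 1)
  expect_equal(by_cls$percent[by_cls$tooth_class == "incisor"], 50)
  expect_equal(by_cls$n_observed[by_cls$tooth_class == "carnassial"], 2)
  expect_equal(by_cls$n_broken[by_cls$tooth_class == "carnassial"], 1)
  expect_equal(by_cls$n_broken[by_cls$tooth_class == "canine"], 1)
  expect_equal(by_cls$percent[by_cls$tooth_class == "canine"], 50)
  # observed counts sum to the sample's observed-teeth total
  expect_equal(sum(by_cls$n_observed), fracture_counts(rec)[["n_observed"]])

  # only broken canines: canine 100%, every other observed class 0%
  rec2 <- records_of(skull_df("D", c("broken", "broken", "intact"),
                              codes = c("U_L_C1", "U_R_C1", "U_L_P1")))
  b2 <- fracture_by_tooth_class(rec2)
  expect_equal(b2$percent[b2$tooth_class == "canine"], 100)
  expect_equal(b2$percent[b2$tooth_class == "premolar"], 0)
  expect_true(all(is.na(b2$percent[b2$n_observed == 0])))
})

test_that("elevated canine hazard yields the highest canine class frequency", {
  h <- stats::setNames(c(0.01, 0.05, 0.01, 0.01, 0.01), tooth_classes())
  rec <- simulate_population(hazard_spec(2000, c(`2` = 0.25, `4` = 0.25,
                                                 `6` = 0.25, `9` = 0.25),
                                         hazards = h, seed = 7))
  by_cls <- fracture_by_tooth_class(rec, decimals = 4)
  canine_pct <- by_cls$percent[by_cls$tooth_class == "canine"]
  expect_true(all(canine_pct > by_cls$percent[by_cls$tooth_class != "canine"]))
})

test_that("wear distributions count skulls with known wear only", {
  rec <- generate_fixture(marginal_spec("IR", 64, 640,
                                        wear_counts = c(slight = 1, moderate = 30,
                                                        heavy = 33)))
  wd <- wear_distribution(rec)
  expect_equal(sum(wd$n), 64)
  expect_equal(wd$percent[wd$wear_stage == "slight"], 2)    # 1/64
  rec2 <- generate_fixture(marginal_spec("YNPL", 83, 830,
                                         wear_counts = c(slight = 24, moderate = 30,
                                                         heavy = 29)))
  expect_equal(wear_distribution(rec2)$percent[1], 29)      # 24/83
  rec3 <- records_of(skull_df("A", "intact", wear = "heavy"),
                     skull_df("B", "intact", wear = "heavy"))
  wd3 <- wear_distribution(rec3)
  expect_equal(wd3$percent, c(0, 0, 100))
  rec4 <- records_of(skull_df("A", "intact"))
  expect_error(wear_distribution(rec4), "wear stage")
})

test_that("stratification is disjoint and exhaustive with unknown kept apart", {
  rec <- records_of(skull_df("A", "intact", age = 2),
                    skull_df("B", "intact", age = 5),
                    skull_df("C", "intact", age = 9))
  st <- stratify(rec, "age_class")
  expect_equal(names(st), c("1-3", "4-6", "7+"))
  expect_true(all(vapply(st, nrow, 0L) == 1))

  rec2 <- records_of(skull_df("A", "intact"), skull_df("B", "intact"))
  expect_equal(names(stratify(rec2, "age_class")), "unknown")

  rec3 <- simulate_population(hazard_spec(100, c(`2` = 0.4, `5` = 0.3, `8` = 0.3),
                                          hazards = 0.03, seed = 5))
  for (by in c("age_class", "wear_stage", "tooth_class")) {
    st3 <- stratify(rec3, by)
    expect_equal(sum(vapply(st3, nrow, 0L)), nrow(rec3))  # exhaustive
    ids <- unlist(lapply(st3, function(x) paste(x$skull_id, x$tooth_code)))
    expect_false(anyDuplicated(ids) > 0)                  # disjoint
  }
})

test_that("sample summaries delegate consistently and handle the all-intact case", {
  rec <- generate_fixture(marginal_spec("SCAND", 94, 3778,
                                        pct_individuals = "33", pct_teeth = "1.7"))
  s <- summarize_sample(rec)
  expect_equal(s$n_skulls, 94)
  expect_equal(s$n_teeth, 3778)
  expect_equal(s$pct_teeth_broken, 1.7)
  expect_equal(s$pct_individuals_broken, percent_individuals_with_fracture(rec))
  expect_equal(sum(s$by_tooth_class$n_observed), s$n_teeth)

  one <- records_of(skull_df("A", rep("intact", 42)))
  s1 <- summarize_sample(one)
  expect_equal(s1$pct_individuals_broken, 0)
  expect_equal(s1$pct_teeth_broken, 0)
  expect_equal(s1$pct_teeth_broken_no_canines, 0)
})

test_that("zero-fracture and canine-only samples give zero headline percents", {
  rec <- generate_fixture(marginal_spec("Z", 10, 100))
  expect_equal(percent_individuals_with_fracture(rec), 0)
  expect_equal(percent_teeth_broken(rec), 0)
  # every skull has exactly one broken canine; excluded -> 0
  canine_only <- records_of(
    skull_df("A", c("broken", "intact"), codes = c("U_L_C1", "U_L_P1")),
    skull_df("B", c("broken", "intact"), codes = c("U_L_C1", "U_L_P1"))
  )
  expect_equal(percent_individuals_with_fracture(canine_only,
                                                 include_canines = FALSE), 0)
  expect_equal(percent_individuals_with_fracture(canine_only), 100)
})

test_that("cross-sample means are unweighted and rounded half-up", {
  expect_equal(mean_of_sample_percentages(c(71.9, 33, 47.1, 37.7, 64)), 51)
  expect_equal(mean_of_sample_percentages(42.3), 42)
  expect_equal(mean_of_sample_percentages(c(0, 100)), 50)
  expect_error(mean_of_sample_percentages(numeric(0)), "empty")
})

test_that("half-up rounding follows the printed-value convention", {
  expect_equal(round_half_up(71.875, 1), 71.9)
  expect_equal(round_half_up(63.855, 0), 64)
  expect_equal(round_half_up(1.5625, 0), 2)
  expect_equal(round_half_up(2.5, 0), 3)       # ties up, not to even
  expect_equal(round_half_up(100 * 46 / 64, 1), 71.9)
  set.seed(9)
  k <- sample(0:500, 200, replace = TRUE)
  n <- sample(1:5000, 200, replace = TRUE)
  k <- pmin(k, n)
  for (d in 0:2) {
    expect_equal(round_half_up(100 * k / n, d), naive_pct(k, n, d))
  }
})
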