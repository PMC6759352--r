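#' Invert a printed percentage into an integer count
#'
#' Published sample summaries print percentages at a fixed number of
#' decimals; given the denominator, the underlying integer count can be
#' recovered by exhaustive inversion of the rounding. Returns the
#' smallest integer `k` in `[0, n]` whose half-up rounding of
#' `100 k / n` at `decimals` places equals the printed value, with an
#' attribute flagging whether `k` is unique.
#'
#' @param printed_pct Printed percentage (numeric, 0--100).
#' @param n Denominator (positive integer).
#' @param decimals Decimals at which the percentage was printed.
#' @return Integer count with attribute `"unique"` (logical).
#' @export
#' @examples
#' solve_count_from_percent(71.9, 64, 1)    # 46, unique
#' solve_count_from_percent(8.6, 1866, 1)   # 160, non-unique (161 also fits)
solve_count_from_percent <- function(printed_pct, n, decimals) {
  stopifnot(length(printed_pct) == 1, length(n) == 1, n > 0,
            printed_pct >= 0, printed_pct <= 100)
  k <- 0:n
  hits <- k[round_half_up(100 * k / n, decimals) == printed_pct]
  if (length(hits) == 0) {
    stop("no count in [0, ", n, "] rounds to ", printed_pct, " at ",
         decimals, " decimal(s)", call. = FALSE)
  }
  structure(as.integer(hits[1]), unique = length(hits) == 1L)
}

# Number of digits after the decimal point in a printed value.
printed_decimals <- function(s) {
  s <- as.character(s)
  ifelse(grepl(".", s, fixed = TRUE),
         nchar(sub(".*\\.", "", s)), 0L)
}

#' Marginal specification for a deterministic fixture
#'
#' Describes one skull sample by its printed aggregates: skull and tooth
#' counts plus the printed per-individual and per-tooth fracture
#' percentages (given as the printed strings so that their decimal
#' precision is known — `"33"` is a 0-decimal value, `"71.9"` a 1-decimal
#' value). Broken counts may instead be given directly when the source
#' prints the fraction itself (e.g. 66/671). Optional per-skull ages and
#' wear-stage counts constrain the age and wear structure exactly.
#'
#' @param sample_label Sample name.
#' @param n_skulls Number of skulls.
#' @param n_teeth Total observed teeth across the sample.
#' @param pct_individuals Printed percent of individuals with >=1 broken
#'   tooth (string or number), or `NULL`.
#' @param pct_teeth Printed percent of teeth broken (string or number),
#'   or `NULL`.
#' @param n_individuals_broken,n_teeth_broken Direct counts, overriding
#'   the percent inversion.
#' @param ages Optional ages in years: scalar or length-`n_skulls` vector.
#' @param wear_counts Optional named counts, e.g.
#'   `c(slight = 1, moderate = 30, heavy = 33)`; must sum to at most
#'   `n_skulls` (remaining skulls get no recorded stage).
#' @param seed Integer seed stored with the spec (fixture construction is
#'   fully deterministic; the seed is part of the spec identity).
#' @return List of class `"marginal_spec"` with solved integer counts and
#'   ambiguity flags.
#' @export
marginal_spec <- function(sample_label, n_skulls, n_teeth,
                          pct_individuals = NULL, pct_teeth = NULL,
                          n_individuals_broken = NULL, n_teeth_broken = NULL,
                          ages = NULL, wear_counts = NULL, seed = 1L) {
  stopifnot(n_skulls >= 1, n_teeth >= 1, n_teeth <= 42 * n_skulls)
  solve_one <- function(pct, n) {
    if (is.null(pct)) return(NULL)
    solve_count_from_percent(as.numeric(as.character(pct)), n,
                             printed_decimals(pct))
  }
  if (is.null(n_individuals_broken)) {
    n_individuals_broken <- solve_one(pct_individuals, n_skulls)
  }
  if (is.null(n_teeth_broken)) {
    n_teeth_broken <- solve_one(pct_teeth, n_teeth)
  }
  if (is.null(n_teeth_broken)) n_teeth_broken <- 0L
  if (is.null(n_individuals_broken)) {
    n_individuals_broken <- min(n_teeth_broken, n_skulls)
  }
  if (n_teeth_broken < n_individuals_broken) {
    stop("infeasible: fewer broken teeth than broken individuals", call. = FALSE)
  }
  if (!is.null(ages)) {
    ages <- rep_len(as.numeric(ages), n_skulls)
    stopifnot(all(is.na(ages) | ages >= 0))
  }
  if (!is.null(wear_counts)) {
    stopifnot(all(names(wear_counts) %in% WEAR_STAGES),
              sum(wear_counts) <= n_skulls, all(wear_counts >= 0))
  }
  structure(list(
    sample_label = sample_label,
    n_skulls = as.integer(n_skulls),
    n_teeth = as.integer(n_teeth),
    n_individuals_broken = as.integer(n_individuals_broken),
    n_teeth_broken = as.integer(n_teeth_broken),
    pct_individuals = pct_individuals,
    pct_teeth = pct_teeth,
    ages = ages,
    wear_counts = wear_counts,
    seed = as.integer(seed)
  ), class = "marginal_spec")
}

#' Generate a deterministic fixture from printed marginals
#'
#' Builds an exact integer dataset reproducing a sample's printed
#' aggregates: `n_skulls` skulls whose observed teeth are spread as
#' evenly as possible to total `n_teeth` (extra teeth go to the first
#' skulls), exactly `n_individuals_broken` skulls carrying at least one
#' broken tooth and exactly `n_teeth_broken` broken teeth. Broken teeth
#' are placed deterministically: one at the first observed position of
#' each broken skull, then round-robin through subsequent canonical
#' positions. Identical specs always yield byte-identical tables.
#'
#' @param spec A [marginal_spec()].
#' @return A [dental_records] table.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "marginal_spec"))
  n <- spec$n_skulls
  base <- spec$n_teeth %/% n
  m <- rep(base, n) + c(rep(1L, spec$n_teeth %% n), rep(0L, n - spec$n_teeth %% n))
  if (any(m < 1)) stop("infeasible: a skull with zero observed teeth", call. = FALSE)
  k_ind <- spec$n_individuals_broken
  capacity <- sum(m[seq_len(k_ind)])
  if (spec$n_teeth_broken > capacity) {
    stop("infeasible: broken teeth exceed capacity of broken skulls", call. = FALSE)
  }
  broken <- matrix(FALSE, nrow = n, ncol = 42)
  if (k_ind > 0) broken[cbind(seq_len(k_ind), 1L)] <- TRUE
  extra <- spec$n_teeth_broken - k_ind
  p <- 2L
  while (extra > 0) {
    for (s in seq_len(k_ind)) {
      if (extra > 0 && p <= m[s] && !broken[s, p]) {
        broken[s, p] <- TRUE
        extra <- extra - 1L
      }
    }
    p <- p + 1L
    if (p > 42L) stop("infeasible broken-tooth placement", call. = FALSE)
  }
  wear <- rep(NA_character_, n)
  if (!is.null(spec$wear_counts)) {
    wear_vec <- rep(names(spec$wear_counts), times = spec$wear_counts)
    wear[seq_along(wear_vec)] <- wear_vec
  }
  ages <- if (is.null(spec$ages)) rep(NA_real_, n) else spec$ages
  codes <- wolf_dentition()$tooth_code
  skull_ids <- sprintf("%s_%03d", spec$sample_label, seq_len(n))
  rows <- lapply(seq_len(n), function(s) {
    data.frame(
      skull_id = skull_ids[s],
      sample_label = spec$sample_label,
      death_year = NA_integer_,
      age_years = ages[s],
      wear_stage = wear[s],
      tooth_code = codes[seq_len(m[s])],
      status = ifelse(broken[s, seq_len(m[s])], "broken", "intact"),
      stringsAsFactors = FALSE
    )
  })
  dental_records(do.call(rbind, rows))
}

#' Printed marginals of the five published wolf skull samples
#'
#' The published sample summary (skull counts, observed tooth counts and
#' fracture percentages with and without canines) for the Isle Royale,
#' Scandinavia, historic North American and the two chronological
#' Yellowstone samples. Percentages are kept as printed strings so that
#' their decimal precision is preserved (`"33"` and `"64"` were printed
#' at 0 decimals, the rest at 1). The canine-excluded column is carried
#' for reporting but cannot be inverted exactly without the per-sample
#' observed-canine counts, which were not published.
#'
#' @return data.frame with columns `sample_label`, `n_skulls`, `n_teeth`,
#'   `pct_individuals`, `pct_teeth`, `pct_teeth_no_canines` (character
#'   percents).
#' @export
wolf_sample_marginals <- function() {
  data.frame(
    sample_label = c("IRNP", "SCAND", "NA_OTHER", "YNP_96_06", "YNP_07_16"),
    n_skulls = c(64L, 94L, 223L, 77L, 83L),
    n_teeth = c(1866L, 3778L, 8619L, 2991L, 3237L),
    pct_individuals = c("71.9", "33", "47.1", "37.7", "64"),
    pct_teeth = c("8.6", "1.7", "3.4", "1.8", "4.6"),
    pct_teeth_no_canines = c("7.4", "1.5", "3.1", "1.3", "3.9"),
    stringsAsFactors = FALSE
  )
}

#' Deterministic fixtures for all five published samples
#'
#' @param seed Seed recorded in each spec (construction is deterministic).
#' @return Named list of [dental_records] tables, one per row of
#'   [wolf_sample_marginals()].
#' @export
wolf_sample_fixtures <- function(seed = 1L) {
  tab <- wolf_sample_marginals()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    generate_fixture(marginal_spec(
      sample_label = tab$sample_label[i],
      n_skulls = tab$n_skulls[i],
      n_teeth = tab$n_teeth[i],
      pct_individuals = tab$pct_individuals[i],
      pct_teeth = tab$pct_teeth[i],
      seed = seed
    ))
  })
  names(out) <- tab$sample_label
  out
}

#' Hazard specification for the age-structured fracture simulator
#'
#' Parameters of a stochastic cross-sectional population in which each
#' tooth of a wolf aged `a` years has been broken in life with
#' probability `1 - (1 - h)^floor(a)` — a constant annual per-tooth
#' fracture hazard `h` per tooth class — and whole-dentition wear
#' accumulates linearly with age plus standard-normal noise, thresholded
#' into the slight/moderate/heavy stages.
#'
#' @param n_skulls Number of skulls to simulate.
#' @param age_probs Named numeric vector: ages in years -> sampling
#'   probability (the cross-sectional age-at-death distribution).
#' @param hazards Annual fracture hazard per tooth class: scalar or named
#'   vector over [tooth_classes()]; values in \[0, 1\].
#' @param teeth_per_skull Observed teeth per skull (<= 42; the first
#'   positions in canonical order).
#' @param wear_rate Mean wear-score increase per year of age.
#' @param wear_thresholds Two increasing cut points on the wear score
#'   separating slight/moderate and moderate/heavy.
#' @param wear_sd Standard deviation of the wear-score noise.
#' @param sample_label Label for the simulated sample.
#' @param seed Integer seed; simulation is reproducible given the spec.
#' @return List of class `"hazard_spec"`.
#' @export
hazard_spec <- function(n_skulls, age_probs, hazards, teeth_per_skull = 42,
                        wear_rate = 1, wear_thresholds = c(3, 7), wear_sd = 1,
                        sample_label = "SIM", seed = 1L) {
  stopifnot(n_skulls >= 1, length(age_probs) >= 1,
            !is.null(names(age_probs)), all(age_probs >= 0),
            sum(age_probs) > 0, teeth_per_skull >= 1, teeth_per_skull <= 42,
            length(wear_thresholds) == 2, diff(wear_thresholds) > 0,
            wear_sd >= 0, wear_rate >= 0)
  cls <- tooth_classes()
  if (length(hazards) == 1 && is.null(names(hazards))) {
    hazards <- stats::setNames(rep(as.numeric(hazards), 5), cls)
  }
  stopifnot(setequal(names(hazards), cls),
            all(hazards >= 0 & hazards <= 1))
  structure(list(
    n_skulls = as.integer(n_skulls),
    age_probs = age_probs / sum(age_probs),
    hazards = hazards[cls],
    teeth_per_skull = as.integer(teeth_per_skull),
    wear_rate = wear_rate,
    wear_thresholds = wear_thresholds,
    wear_sd = wear_sd,
    sample_label = sample_label,
    seed = as.integer(seed)
  ), class = "hazard_spec")
}

#' Simulate a cross-sectional skull sample under the hazard model
#'
#' @param spec A [hazard_spec()].
#' @return A [dental_records] table with known ages and wear stages.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "hazard_spec"))
  set.seed(spec$seed)
  n <- spec$n_skulls
  ages <- sample(as.numeric(names(spec$age_probs)), n, replace = TRUE,
                 prob = spec$age_probs)
  score <- spec$wear_rate * ages + stats::rnorm(n, 0, spec$wear_sd)
  wear <- as.character(cut(score,
                           c(-Inf, spec$wear_thresholds, Inf),
                           labels = WEAR_STAGES))
  dent <- wolf_dentition()[seq_len(spec$teeth_per_skull), ]
  m <- spec$teeth_per_skull
  skull_idx <- rep(seq_len(n), each = m)
  h <- spec$hazards[dent$tooth_class[rep(seq_len(m), times = n)]]
  p_break <- 1 - (1 - h)^floor(ages[skull_idx])
  status <- ifelse(stats::rbinom(n * m, 1, p_break) == 1, "broken", "intact")
  dental_records(data.frame(
    skull_id = sprintf("%s_%04d", spec$sample_label, skull_idx),
    sample_label = spec$sample_label,
    death_year = NA_integer_,
    age_years = ages[skull_idx],
    wear_stage = wear[skull_idx],
    tooth_code = rep(dent$tooth_code, times = n),
    status = status,
    stringsAsFactors = FALSE
  ))
}

#' Maximum-likelihood annual fracture hazard for a tooth class
#'
#' Estimates the constant annual per-tooth fracture hazard `h` under
#' `P(broken | age a) = 1 - (1 - h)^floor(a)` from a cross-sectional
#' sample, using the observed teeth of the given class in skulls of known
#' age (>= 1 year). The log-likelihood is maximized by one-dimensional
#' search on \[0, 1\]; the all-intact and all-broken boundary cases
#' return 0 and 1 exactly.
#'
#' @param records A [dental_records] table.
#' @param tooth_class One of [tooth_classes()].
#' @return Estimated hazard in \[0, 1\].
#' @export
estimate_tooth_hazard <- function(records, tooth_class) {
  stopifnot(tooth_class %in% tooth_classes())
  sub <- records[records$tooth_class == tooth_class &
                   records$status != "missing" &
                   !is.na(records$age_years) &
                   floor(records$age_years) >= 1, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no observed ", tooth_class, " teeth with known age >= 1", call. = FALSE)
  }
  a <- floor(sub$age_years)
  y <- as.integer(sub$status == "broken")
  if (sum(y) == 0) return(0)
  if (all(y == 1)) return(1)
  nll <- function(h) {
    q <- (1 - h)^a
    -sum(y * log(1 - q) + (1 - y) * a * log(1 - h))
  }
  stats::optimise(nll, c(1e-12, 1 - 1e-12), tol = 1e-10)$minimum
}

#' Simulate kill-site necropsies with known removal probabilities
#'
#' Each indexed element of each carcass is removed unit-by-unit with its
#' element's removal probability (independent Bernoulli draws per
#' expected unit). Elements recorded as presence/absence in the field
#' (metacarpus, metatarsus) are removed whole with the same probability,
#' so their expected removal proportion also equals `p`. Non-index
#' elements are left fully present.
#'
#' @param n_per_year Carcasses per year.
#' @param years Integer vector of years.
#' @param removal_prob Scalar or named per-element removal probability
#'   over the index elements.
#' @param seed Integer seed.
#' @param elements Index element set.
#' @param season Season label recorded on every carcass.
#' @return A [necropsy_records] table.
#' @export
simulate_necropsies <- function(n_per_year, years, removal_prob, seed = 1L,
                                elements = default_index_elements(),
                                season = "winter") {
  set.seed(seed)
  el <- skeletal_elements()
  if (length(removal_prob) == 1 && is.null(names(removal_prob))) {
    removal_prob <- stats::setNames(rep(removal_prob, length(elements)), elements)
  }
  stopifnot(setequal(names(removal_prob), elements),
            all(removal_prob >= 0 & removal_prob <= 1))
  total <- n_per_year * length(years)
  df <- data.frame(
    carcass_id = sprintf("C%05d", seq_len(total)),
    year = rep(as.integer(years), each = n_per_year),
    season = season,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(el))) {
    nm <- el$element[i]
    if (nm %in% elements) {
      df[[nm]] <- if (el$presence_only[i]) {
        el$expected[i] * stats::rbinom(total, 1, 1 - removal_prob[[nm]])
      } else {
        el$expected[i] - stats::rbinom(total, el$expected[i], removal_prob[[nm]])
      }
    } else {
      df[[nm]] <- el$expected[i]
    }
  }
  necropsy_records(df)
}
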