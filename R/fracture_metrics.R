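#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' all printed percentages in this package; base [round()] rounds ties to
#' even. A tiny binary-representation guard is applied so that values such
#' as `100 * 46 / 64` round at their decimal meaning.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.5625 * 100 / 100, 0)  # 2
#' round_half_up(71.875, 1)              # 71.9
round_half_up <- function(x, digits = 0) {
  scaled <- round(x * 10^digits, 9)  # strip float noise before the tie rule
  floor(scaled + 0.5) / 10^digits
}

# Broken / observed tooth counts over the considered positions.
#' Fracture counts for a sample
#'
#' @param records A [dental_records] table.
#' @param include_canines Count canine positions? Canine teeth break in
#'   combat and prey capture as well as in feeding, so bone-consumption
#'   comparisons are usually run both with and without them.
#' @return Named integer vector `c(n_broken, n_observed)` (observed =
#'   intact + broken in life; missing teeth excluded).
#' @export
fracture_counts <- function(records, include_canines = TRUE) {
  rec <- if (include_canines) records else
    records[records$tooth_class != "canine", , drop = FALSE]
  c(n_broken = sum(rec$status == "broken"),
    n_observed = sum(rec$status != "missing"))
}

#' Percent of individuals with at least one broken tooth
#'
#' @inheritParams fracture_counts
#' @param decimals Decimal places for half-up rounding (default 1,
#'   matching sample-summary output).
#' @return Percentage in \[0, 100\].
#' @export
percent_individuals_with_fracture <- function(records, include_canines = TRUE,
                                              decimals = 1) {
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  sk <- skull_table(records, include_canines = include_canines)
  round_half_up(100 * sum(sk$n_broken >= 1) / nrow(sk), decimals)
}

#' Percent of observed teeth broken in life
#'
#' @inheritParams percent_individuals_with_fracture
#' @return Percentage in \[0, 100\].
#' @export
percent_teeth_broken <- function(records, include_canines = TRUE, decimals = 1) {
  cnt <- fracture_counts(records, include_canines = include_canines)
  if (cnt[["n_observed"]] == 0) {
    stop("no observed teeth among the considered positions", call. = FALSE)
  }
  round_half_up(100 * cnt[["n_broken"]] / cnt[["n_observed"]], decimals)
}

#' Fracture frequency by tooth class
#'
#' Partitions all observed teeth into the five functional classes and
#' reports per-class broken counts and percentages. Classes with no
#' observed teeth get an `NA` percent.
#'
#' @inheritParams percent_individuals_with_fracture
#' @return data.frame with columns `tooth_class`, `n_broken`,
#'   `n_observed`, `percent`.
#' @export
fracture_by_tooth_class <- function(records, decimals = 1) {
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  classes <- tooth_classes()
  obs <- records$status != "missing"
  brk <- records$status == "broken"
  n_obs <- vapply(classes, function(cl) sum(obs & records$tooth_class == cl), 0L)
  n_brk <- vapply(classes, function(cl) sum(brk & records$tooth_class == cl), 0L)
  pct <- ifelse(n_obs > 0, round_half_up(100 * n_brk / n_obs, decimals), NA_real_)
  data.frame(tooth_class = classes, n_broken = as.integer(n_brk),
             n_observed = as.integer(n_obs), percent = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wear-stage distribution of a sample
#'
#' Counts skulls per whole-dentition wear stage; percentages are over
#' skulls with a recorded stage only.
#'
#' @inheritParams percent_individuals_with_fracture
#' @param decimals Decimal places (default 0, matching in-text style).
#' @return data.frame with columns `wear_stage`, `n`, `percent`.
#' @export
wear_distribution <- function(records, decimals = 0) {
  sk <- skull_table(records)
  sk <- sk[!is.na(sk$wear_stage), , drop = FALSE]
  if (nrow(sk) == 0) stop("no skull has a recorded wear stage", call. = FALSE)
  n <- vapply(WEAR_STAGES, function(w) sum(sk$wear_stage == w), 0L)
  data.frame(wear_stage = WEAR_STAGES, n = as.integer(n),
             percent = round_half_up(100 * n / nrow(sk), decimals),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify records by age class, wear stage or tooth class
#'
#' Splits a record table into a disjoint, exhaustive partition. For
#' `age_class` and `wear_stage` the split is by skull; skulls with an
#' unknown key are kept in a separate `"unknown"` stratum. For
#' `tooth_class` the split is by tooth row.
#'
#' @inheritParams percent_individuals_with_fracture
#' @param by One of `"age_class"`, `"wear_stage"`, `"tooth_class"`.
#' @return Named list of [dental_records] subsets (empty strata dropped).
#' @export
stratify <- function(records, by = c("age_class", "wear_stage", "tooth_class")) {
  by <- match.arg(by)
  key <- switch(by,
    age_class = as.character(assign_age_class(records$age_years)),
    wear_stage = ifelse(is.na(records$wear_stage), "unknown", records$wear_stage),
    tooth_class = records$tooth_class
  )
  levels <- switch(by,
    age_class = AGE_CLASSES,
    wear_stage = c(WEAR_STAGES, "unknown"),
    tooth_class = tooth_classes()
  )
  out <- lapply(levels, function(lv) {
    sub <- records[key == lv, , drop = FALSE]
    rownames(sub) <- NULL
    class(sub) <- c("dental_records", "data.frame")
    sub
  })
  names(out) <- levels
  out[vapply(out, nrow, 0L) > 0]
}

#' Summarize one skull sample
#'
#' Aggregates every descriptive statistic for a sample: per-individual
#' and per-tooth fracture percentages (with and without canines), the
#' tooth-class breakdown, the wear-stage distribution, and nested
#' summaries per adult age class.
#'
#' @inheritParams percent_individuals_with_fracture
#' @param decimals Decimal places for the headline percentages (default 1).
#' @return An object of class `"sample_summary"`: a list with elements
#'   `sample_label`, `n_skulls`, `n_teeth`, `pct_individuals_broken`,
#'   `pct_individuals_broken_no_canines`, `pct_teeth_broken`,
#'   `pct_teeth_broken_no_canines`, `by_tooth_class`, `wear_distribution`
#'   (`NULL` when no skull has a recorded stage) and `by_age_class`.
#' @export
summarize_sample <- function(records, decimals = 1) {
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  sk <- skull_table(records)
  by_age <- lapply(stratify(records, "age_class"), function(sub) {
    cnt <- fracture_counts(sub)
    cnt_nc <- fracture_counts(sub, include_canines = FALSE)
    list(
      n_skulls = length(unique(sub$skull_id)),
      n_teeth = cnt[["n_observed"]],
      n_broken = cnt[["n_broken"]],
      pct_teeth_broken = if (cnt[["n_observed"]] > 0)
        percent_teeth_broken(sub, decimals = decimals) else NA_real_,
      pct_teeth_broken_no_canines = if (cnt_nc[["n_observed"]] > 0)
        percent_teeth_broken(sub, include_canines = FALSE,
                             decimals = decimals) else NA_real_
    )
  })
  structure(list(
    sample_label = unique(records$sample_label)[1],
    n_skulls = nrow(sk),
    n_teeth = unname(fracture_counts(records)[["n_observed"]]),
    pct_individuals_broken =
      percent_individuals_with_fracture(records, decimals = decimals),
    pct_individuals_broken_no_canines =
      percent_individuals_with_fracture(records, include_canines = FALSE,
                                        decimals = decimals),
    pct_teeth_broken = percent_teeth_broken(records, decimals = decimals),
    pct_teeth_broken_no_canines =
      percent_teeth_broken(records, include_canines = FALSE,
                           decimals = decimals),
    by_tooth_class = fracture_by_tooth_class(records, decimals = decimals),
    wear_distribution = if (all(is.na(sk$wear_stage))) NULL else
      wear_distribution(records),
    by_age_class = by_age
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Sample:", x$sample_label, "\n")
  cat(sprintf("  %d skulls, %d observed teeth\n", x$n_skulls, x$n_teeth))
  cat(sprintf("  %% individuals with >=1 broken tooth: %s\n",
              format(x$pct_individuals_broken)))
  cat(sprintf("  %% teeth broken: %s (canines excluded: %s)\n",
              format(x$pct_teeth_broken),
              format(x$pct_teeth_broken_no_canines)))
  invisible(x)
}

#' Mean of per-sample percentages
#'
#' Unweighted arithmetic mean of sample-level percentages (each sample
#' counts once regardless of size), rounded half-up.
#'
#' @param values Numeric vector of percentages.
#' @param decimals Decimal places (default 0).
#' @return Percentage.
#' @export
#' @examples
#' mean_of_sample_percentages(c(71.9, 33, 47.1, 37.7, 64))  # 51
mean_of_sample_percentages <- function(values, decimals = 0) {
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  round_half_up(mean(values), decimals)
}
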