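#' Skeletal elements recorded at kill-site necropsies
#'
#' Field necropsies of wolf-killed ungulates record counts of mandibles,
#' scapulae, humeri, radii+ulnae, femora, tibiae and vertebrae, and
#' presence/absence of metacarpi, metatarsi, skull and pelvis. The
#' utilization index is computed over the eight paired mandible and limb
#' elements (16 expected per complete carcass); skull and pelvis are
#' always excluded (they were almost always present), and vertebrae are
#' recorded but outside the default index.
#'
#' @return data.frame with columns `element`, `expected` (per-carcass
#'   count in a complete skeleton), `in_index` (in the default index set)
#'   and `presence_only` (recorded as presence/absence in the field).
#' @export
skeletal_elements <- function() {
  data.frame(
    element = c("mandible", "scapula", "humerus", "radius_ulna", "metacarpus",
                "femur", "tibia", "metatarsus", "vertebrae", "skull", "pelvis"),
    expected = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 49L, 1L, 1L),
    in_index = c(rep(TRUE, 8), FALSE, FALSE, FALSE),
    presence_only = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                      FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default index element set
#'
#' @return Character vector: the eight paired mandible and limb elements.
#' @export
default_index_elements <- function() {
  el <- skeletal_elements()
  el$element[el$in_index]
}

NECROPSY_HEADER <- c("carcass_id", "year", "season", skeletal_elements()$element)
SEASONS <- c("winter", "other", "unknown")

#' Build and validate a necropsy record table
#'
#' One row per carcass with found-counts per skeletal element.
#' Presence/absence elements (metacarpus, metatarsus) accept 0/1 on input,
#' with presence mapped to the full paired count of 2.
#'
#' @param df data.frame with columns `carcass_id`, `year`, `season`
#'   (`winter`/`other`/`unknown`) and one integer column per element of
#'   [skeletal_elements()].
#' @return Validated data.frame with class `"necropsy_records"`.
#' @export
necropsy_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(NECROPSY_HEADER, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$carcass_id <- as.character(df$carcass_id)
  df$year <- as.integer(df$year)
  df$season <- as.character(df$season)
  if (anyNA(df$year)) stop("every carcass needs a year", call. = FALSE)
  if (any(!df$season %in% SEASONS)) {
    stop("season must be one of ", paste(SEASONS, collapse = "/"), call. = FALSE)
  }
  if (anyDuplicated(df$carcass_id)) {
    stop("duplicate carcass_id '", df$carcass_id[duplicated(df$carcass_id)][1],
         "'", call. = FALSE)
  }
  el <- skeletal_elements()
  for (i in seq_len(nrow(el))) {
    nm <- el$element[i]
    x <- as.integer(df[[nm]])
    if (anyNA(x) || any(x < 0)) {
      stop("column '", nm, "' must hold non-negative integer counts", call. = FALSE)
    }
    if (el$presence_only[i] && el$expected[i] == 2L) {
      x[x == 1L] <- 2L  # presence recorded as 0/1 in the field
    }
    if (any(x > el$expected[i])) {
      stop("column '", nm, "' exceeds the expected per-carcass count of ",
           el$expected[i], call. = FALSE)
    }
    df[[nm]] <- x
  }
  df <- df[order(df$year, df$carcass_id), NECROPSY_HEADER]
  rownames(df) <- NULL
  class(df) <- c("necropsy_records", "data.frame")
  df
}

#' Read a necropsy table from delimited text
#'
#' @param path Comma-separated file with header
#'   `carcass_id,year,season,mandible,...,pelvis`.
#' @return A [necropsy_records] table.
#' @export
read_necropsy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, NECROPSY_HEADER)) {
    stop("unexpected header in ", path, call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = ",", quote = "")
  bad <- which(nf != length(NECROPSY_HEADER))
  if (length(bad)) {
    stop("malformed row ", bad[1], " in ", path, call. = FALSE)
  }
  necropsy_records(utils::read.csv(path, quote = "", stringsAsFactors = FALSE))
}

#' Write a necropsy table to delimited text
#'
#' @param records A [necropsy_records] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_necropsy_table <- function(records, path) {
  records <- necropsy_records(records)
  utils::write.table(records, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

index_totals <- function(records, elements) {
  el <- skeletal_elements()
  unknown <- setdiff(elements, el$element)
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(elements) == 0) stop("empty index element set", call. = FALSE)
  expected <- sum(el$expected[match(elements, el$element)]) * nrow(records)
  found <- sum(vapply(elements, function(nm) sum(records[[nm]]), 0))
  c(found = found, expected = expected)
}

#' Skeletal utilization index
#'
#' One minus the ratio of indexed skeletal elements found at kill sites
#' to the number expected if skeletons were complete, pooled over the
#' supplied carcasses: if 80% of the indexed skeleton remains, the
#' utilization index is 0.2 (20%). Higher values indicate fuller carcass
#' consumption or removal.
#'
#' @param records A [necropsy_records] table (one or more carcasses).
#' @param elements Index element set (default the eight paired
#'   mandible/limb elements).
#' @return Proportion in \[0, 1\].
#' @export
utilization_index <- function(records, elements = default_index_elements()) {
  tot <- index_totals(records, elements)
  1 - tot[["found"]] / tot[["expected"]]
}

#' Removal proportion for a single element
#'
#' @param records A [necropsy_records] table.
#' @param element One element name from [skeletal_elements()].
#' @return Proportion of that element missing (presumed removed) across
#'   all carcasses.
#' @export
element_removal_proportion <- function(records, element) {
  if (nrow(records) == 0) stop("no carcasses", call. = FALSE)
  utilization_index(records, elements = element)
}

#' Centered simple moving average
#'
#' Window must be odd; at the series edges the window truncates to the
#' available points, so the output has the same length as the input and
#' every smoothed value lies within the local min/max of its window.
#'
#' @param x Numeric vector (ordered series).
#' @param window Odd positive integer window width.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' moving_average(c(1, 2, 3, 4), 3)  # 1.5 2.0 3.0 3.5
moving_average <- function(x, window) {
  if (length(window) != 1 || window < 1 || window != round(window)) {
    stop("window must be a positive integer", call. = FALSE)
  }
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, 0)
}

#' Yearly skeletal-utilization series
#'
#' Pools found/expected counts per calendar year and smooths the series
#' with a centered simple moving average (default 3-year window). Years
#' with no carcasses are omitted.
#'
#' @inheritParams utilization_index
#' @param window Odd moving-average window in years (default 3).
#' @return data.frame with columns `year`, `n_carcasses`,
#'   `proportion_removed` and `smoothed`.
#' @export
yearly_series <- function(records, elements = default_index_elements(),
                          window = 3) {
  if (nrow(records) == 0) stop("no carcasses", call. = FALSE)
  years <- sort(unique(records$year))
  prop <- vapply(years, function(y) {
    utilization_index(records[records$year == y, , drop = FALSE], elements)
  }, 0)
  n <- vapply(years, function(y) sum(records$year == y), 0L)
  data.frame(year = years, n_carcasses = n, proportion_removed = prop,
             smoothed = moving_average(prop, window), stringsAsFactors = FALSE)
}

#' Compare element removal between two chronological periods
#'
#' Splits carcasses at `cut_year` (years `<= cut_year` are "early"),
#' pools missing/expected element counts per period and compares the two
#' removal proportions with a pooled two-proportion z-test; the
#' statistical unit is the indexed skeletal element.
#'
#' @inheritParams utilization_index
#' @param cut_year Last year of the early period.
#' @return List of class `"period_split"` with `early`, `late`
#'   (proportions), `counts` (missing/expected per period) and `test`
#'   (an `"htest"`).
#' @export
period_split_comparison <- function(records, cut_year,
                                    elements = default_index_elements()) {
  early <- records[records$year <= cut_year, , drop = FALSE]
  late <- records[records$year > cut_year, , drop = FALSE]
  if (nrow(early) == 0 || nrow(late) == 0) {
    stop("both periods must contain carcasses", call. = FALSE)
  }
  te <- index_totals(early, elements)
  tl <- index_totals(late, elements)
  miss_e <- te[["expected"]] - te[["found"]]
  miss_l <- tl[["expected"]] - tl[["found"]]
  structure(list(
    cut_year = cut_year,
    early = miss_e / te[["expected"]],
    late = miss_l / tl[["expected"]],
    counts = data.frame(period = c("early", "late"),
                        n_missing = c(miss_e, miss_l),
                        n_expected = c(te[["expected"]], tl[["expected"]])),
    test = two_proportion_test(miss_e, te[["expected"]],
                               miss_l, tl[["expected"]])
  ), class = "period_split")
}

#' @export
print.period_split <- function(x, ...) {
  cat(sprintf("Element removal <=%d: %.3f;  >%d: %.3f  (p %s)\n",
              x$cut_year, x$early, x$cut_year, x$late,
              format_p(x$test$p.value)))
  invisible(x)
}
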