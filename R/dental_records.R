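#' @title Per-tooth skull records
#' @description
#' Dental data are held in a plain data.frame, one row per tooth per skull,
#' with class `"dental_records"`. Columns:
#'
#' * `skull_id` — skull identifier (character).
#' * `sample_label` — population/sample the skull belongs to.
#' * `death_year` — integer year of death, `NA` when unknown.
#' * `age_years` — estimated age at death in years, `NA` when unknown.
#' * `wear_stage` — whole-dentition wear score, `"slight"`, `"moderate"`
#'   or `"heavy"`, `NA` when unrecorded.
#' * `tooth_code` — canonical position code (see [wolf_dentition()]).
#' * `status` — `"intact"`, `"broken"` (broken in life: fracture plus
#'   subsequent wear on the break surface) or `"missing"`. Missing teeth
#'   are never counted as broken and are excluded from both numerator and
#'   denominator of fracture frequencies; teeth damaged post mortem must
#'   be encoded as missing by the data preparer.
#' * `tooth_class` — derived from `tooth_code`.
#'
#' Skull-level fields (`sample_label`, `death_year`, `age_years`,
#' `wear_stage`) must be constant within a skull, and no tooth position may
#' appear twice for the same skull.
#' @name dental_records
NULL

WEAR_STAGES <- c("slight", "moderate", "heavy")
TOOTH_STATUSES <- c("intact", "broken", "missing")
DENTAL_HEADER <- c("skull_id", "sample_label", "death_year", "age_years",
                   "wear_stage", "tooth_code", "status")

#' Build and validate a dental record table
#'
#' @param df data.frame with the columns documented in [dental_records].
#'   `tooth_class` is (re)derived from `tooth_code`.
#' @return The validated data.frame with class `"dental_records"`, rows
#'   ordered by `skull_id` then canonical tooth order.
#' @export
dental_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(DENTAL_HEADER, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$skull_id <- as.character(df$skull_id)
  df$sample_label <- as.character(df$sample_label)
  df$death_year <- as.integer(df$death_year)
  df$age_years <- as.numeric(df$age_years)
  df$wear_stage <- as.character(df$wear_stage)
  df$tooth_code <- as.character(df$tooth_code)
  df$status <- as.character(df$status)

  bad_status <- !df$status %in% TOOTH_STATUSES
  if (any(bad_status)) {
    stop("invalid status at row ", which(bad_status)[1], ": '",
         df$status[which(bad_status)[1]], "'", call. = FALSE)
  }
  bad_wear <- !is.na(df$wear_stage) & !df$wear_stage %in% WEAR_STAGES
  if (any(bad_wear)) {
    stop("invalid wear_stage at row ", which(bad_wear)[1], ": '",
         df$wear_stage[which(bad_wear)[1]], "'", call. = FALSE)
  }
  bad_age <- !is.na(df$age_years) & df$age_years < 0
  if (any(bad_age)) {
    stop("negative age_years at row ", which(bad_age)[1], call. = FALSE)
  }

  pos <- parse_tooth_code(df$tooth_code)
  df$tooth_class <- pos$tooth_class

  dup <- duplicated(df[, c("skull_id", "tooth_code")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicate tooth position ", df$tooth_code[i], " for skull '",
         df$skull_id[i], "'", call. = FALSE)
  }
  for (field in c("sample_label", "death_year", "age_years", "wear_stage")) {
    n_vals <- tapply(df[[field]], df$skull_id, function(x) length(unique(x)))
    if (any(n_vals > 1)) {
      stop("skull '", names(n_vals)[which(n_vals > 1)[1]],
           "' has inconsistent ", field, call. = FALSE)
    }
  }
  per_skull <- table(df$skull_id)
  if (any(per_skull > 42)) {
    stop("skull '", names(per_skull)[which(per_skull > 42)[1]],
         "' has more than 42 tooth records", call. = FALSE)
  }

  ord <- order(df$skull_id, match(df$tooth_code, wolf_dentition()$tooth_code))
  df <- df[ord, c(DENTAL_HEADER, "tooth_class")]
  rownames(df) <- NULL
  class(df) <- c("dental_records", "data.frame")
  df
}

#' Read a dental record table from delimited text
#'
#' Expects a UTF-8 comma-separated file with header
#' `skull_id,sample_label,death_year,age_years,wear_stage,tooth_code,status`.
#' Empty `death_year`, `age_years` and `wear_stage` fields denote unknown
#' values. Malformed rows, unknown tooth codes, duplicate positions within
#' a skull and negative ages are rejected with the offending row named.
#'
#' @param path Path to the file.
#' @return A [dental_records] table.
#' @export
read_dental_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, DENTAL_HEADER)) {
    stop("unexpected header in ", path, "; expected '",
         paste(DENTAL_HEADER, collapse = ","), "'", call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = ",", quote = "", blank.lines.skip = FALSE)
  bad <- which(nf != length(DENTAL_HEADER))
  if (length(bad)) {
    stop("malformed row ", bad[1], " in ", path, ": expected ",
         length(DENTAL_HEADER), " fields, found ", nf[bad[1]], call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", quote = "",
                         blank.lines.skip = FALSE)
  raw$death_year <- suppress_blank_as_na(raw$death_year, "death_year", as.integer)
  raw$age_years <- suppress_blank_as_na(raw$age_years, "age_years", as.numeric)
  raw$wear_stage[raw$wear_stage == ""] <- NA_character_
  dental_records(raw)
}

suppress_blank_as_na <- function(x, field, coerce) {
  x[x == ""] <- NA
  out <- suppressWarnings(coerce(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop("malformed ", field, " at data row ", which(bad)[1], ": '",
         x[which(bad)[1]], "'", call. = FALSE)
  }
  out
}

#' Write a dental record table to delimited text
#'
#' Output is deterministic: rows are sorted by `skull_id` then canonical
#' tooth order, unknown values are written as empty fields, and
#' [read_dental_table()] inverts the result exactly.
#'
#' @param records A [dental_records] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dental_table <- function(records, path) {
  records <- dental_records(records)
  out <- records[, DENTAL_HEADER]
  for (col in names(out)) {
    x <- as.character(out[[col]])
    x[is.na(x)] <- ""
    out[[col]] <- x
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

AGE_CLASSES <- c("1-3", "4-6", "7+", "unknown")

#' Assign adult age classes
#'
#' Ages are floored to whole years and binned into the three adult
#' classes used for age-controlled comparisons: 1--3 years, 4--6 years
#' and seven or more years. Unknown ages map to `"unknown"`. Ages below
#' one year (pups, outside the cross-sectional adult samples) are flagged
#' with a warning and mapped to `"unknown"` rather than rejected.
#'
#' @param age_years Numeric vector of ages in years (`NA` = unknown).
#' @return Factor with levels `"1-3"`, `"4-6"`, `"7+"`, `"unknown"`.
#' @export
#' @examples
#' assign_age_class(c(3.9, 7, NA))  # "1-3", "7+", "unknown"
assign_age_class <- function(age_years) {
  stopifnot(is.numeric(age_years) || all(is.na(age_years)))
  age_years <- as.numeric(age_years)
  if (any(!is.na(age_years) & age_years < 0)) {
    stop("age_years must be non-negative", call. = FALSE)
  }
  a <- floor(age_years)
  out <- rep("unknown", length(a))
  pup <- !is.na(a) & a < 1
  if (any(pup)) {
    warning(sum(pup), " age(s) below 1 year assigned to 'unknown'",
            call. = FALSE)
  }
  out[!is.na(a) & a >= 1 & a <= 3] <- "1-3"
  out[!is.na(a) & a >= 4 & a <= 6] <- "4-6"
  out[!is.na(a) & a >= 7] <- "7+"
  factor(out, levels = AGE_CLASSES)
}

# One row per skull: skull-level fields plus observed/broken tooth counts.
skull_table <- function(records, include_canines = TRUE) {
  rec <- if (include_canines) records else
    records[records$tooth_class != "canine", , drop = FALSE]
  ids <- unique(records$skull_id)
  first <- records[!duplicated(records$skull_id), ]
  first <- first[match(ids, first$skull_id), ]
  observed <- rec$status != "missing"
  broken <- rec$status == "broken"
  data.frame(
    skull_id = ids,
    sample_label = first$sample_label,
    death_year = first$death_year,
    age_years = first$age_years,
    wear_stage = first$wear_stage,
    n_observed = as.integer(tapply0(observed, rec$skull_id, ids)),
    n_broken = as.integer(tapply0(broken, rec$skull_id, ids)),
    stringsAsFactors = FALSE
  )
}

# Sum of x by group, zero-filled over the full id set.
tapply0 <- function(x, group, ids) {
  s <- tapply(x, group, sum)
  out <- s[match(ids, names(s))]
  out[is.na(out)] <- 0
  unname(out)
}
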