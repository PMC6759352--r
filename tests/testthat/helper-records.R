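# Builders for small in-code fixtures.

skull_df <- function(id, statuses, label = "S", age = NA_real_,
                     wear = NA_character_, year = NA_integer_, codes = NULL) {
  if (is.null(codes)) {
    codes <- wolf_dentition()$tooth_code[seq_along(statuses)]
  }
  data.frame(skull_id = id, sample_label = label, death_year = year,
             age_years = age, wear_stage = wear, tooth_code = codes,
             status = statuses, stringsAsFactors = FALSE)
}

records_of <- function(...) dental_records(do.call(rbind, list(...)))

# Exact half-up rounding of 100 * k / n at d decimals via integer
# arithmetic: independent oracle for every percentage in the package.
naive_pct <- function(k, n, d) {
  (((200 * k * 10^d) + n) %/% (2 * n)) / 10^d
}

# One necropsy row with every element complete unless overridden.
necropsy_row <- function(id, year, found = c(), season = "winter") {
  el <- skeletal_elements()
  row <- as.list(stats::setNames(el$expected, el$element))
  for (nm in names(found)) row[[nm]] <- found[[nm]]
  cbind(data.frame(carcass_id = id, year = year, season = season,
                   stringsAsFactors = FALSE),
        as.data.frame(row))
}

necropsies_of <- function(...) necropsy_records(do.call(rbind, list(...)))
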