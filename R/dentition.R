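#' Canonical permanent dentition of the gray wolf
#'
#' The full permanent dentition of *Canis lupus* comprises 42 teeth
#' (dental formula I3/3 C1/1 P4/4 M2/3 per side). Each position carries a
#' canonical string code of the form `{U|L}_{L|R}_{I|C|P|M}{n}`, e.g.
#' `U_L_P4` for the upper left fourth premolar. Positions are grouped into
#' five functional classes: incisors, canines, premolars, carnassials
#' (upper P4 and lower M1 only) and post-carnassial molars (upper M1--M2,
#' lower M2--M3). The row order of the returned table is the canonical
#' tooth order used for deterministic output: upper jaw before lower,
#' left before right, mesial to distal within a quadrant.
#'
#' @return A data.frame with 42 rows and columns `tooth_code`, `jaw`
#'   (`"upper"`/`"lower"`), `side` (`"left"`/`"right"`), `tooth_type`
#'   (`I`, `C`, `P`, `M`), `tooth_index` (1-based within type) and
#'   `tooth_class` (one of [tooth_classes()]).
#' @seealso [parse_tooth_code()]
#' @export
#' @examples
#' nrow(wolf_dentition())          # 42
#' subset(wolf_dentition(), tooth_class == "carnassial")
wolf_dentition <- function() {
  quadrant <- function(jaw) {
    n_m <- if (jaw == "U") 2L else 3L
    data.frame(
      tooth_type  = c(rep("I", 3), "C", rep("P", 4), rep("M", n_m)),
      tooth_index = c(1:3, 1L, 1:4, seq_len(n_m)),
      stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, lapply(c("U", "L"), function(jaw) {
    do.call(rbind, lapply(c("L", "R"), function(side) {
      q <- quadrant(jaw)
      q$jaw_code <- jaw
      q$side_code <- side
      q
    }))
  }))
  rows$tooth_code <- sprintf("%s_%s_%s%d", rows$jaw_code, rows$side_code,
                             rows$tooth_type, rows$tooth_index)
  rows$jaw  <- ifelse(rows$jaw_code == "U", "upper", "lower")
  rows$side <- ifelse(rows$side_code == "L", "left", "right")
  rows$tooth_class <- tooth_class_of(rows$jaw, rows$tooth_type, rows$tooth_index)
  rows[, c("tooth_code", "jaw", "side", "tooth_type", "tooth_index", "tooth_class")]
}

#' The five functional tooth classes
#'
#' @return Character vector of the class labels, in anterior-to-posterior
#'   order: incisor, canine, premolar, carnassial, post-carnassial molar.
#' @export
tooth_classes <- function() {
  c("incisor", "canine", "premolar", "carnassial", "post_carnassial_molar")
}

# Class membership follows standard canid dental anatomy: the carnassial
# pair is upper P4 / lower m1; molars distal to the carnassial are the
# crushing (post-carnassial) teeth.
tooth_class_of <- function(jaw, tooth_type, tooth_index) {
  cls <- character(length(jaw))
  cls[tooth_type == "I"] <- "incisor"
  cls[tooth_type == "C"] <- "canine"
  cls[tooth_type == "P"] <- "premolar"
  cls[tooth_type == "M"] <- "post_carnassial_molar"
  cls[tooth_type == "P" & jaw == "upper" & tooth_index == 4] <- "carnassial"
  cls[tooth_type == "M" & jaw == "lower" & tooth_index == 1] <- "carnassial"
  cls
}

#' Parse canonical tooth position codes
#'
#' Resolves codes such as `"U_L_P4"` or `"L_R_M1"` against the canonical
#' 42-position dentition and returns the position attributes. Codes not in
#' the permanent wolf dentition (e.g. `"U_L_M3"`, which does not exist in
#' the upper jaw) are rejected.
#'
#' @param codes Character vector of tooth codes.
#' @return A data.frame with one row per input code and the columns of
#'   [wolf_dentition()].
#' @export
#' @examples
#' parse_tooth_code(c("U_L_P4", "L_R_M1"))$tooth_class  # both carnassial
parse_tooth_code <- function(codes) {
  stopifnot(is.character(codes))
  dent <- wolf_dentition()
  idx <- match(codes, dent$tooth_code)
  if (anyNA(idx)) {
    bad <- unique(codes[is.na(idx)])
    stop("unknown tooth code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dent[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
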