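#' Canonical treatment classes
#'
#' The eight treatment classes compared in the evidence network: combined
#' oral contraceptives, danazol, endometrial ablation/resection, the
#' levonorgestrel-releasing intrauterine system, placebo, progestogens given
#' for less than 2 weeks out of 4 per cycle (luteal-phase), progestogens
#' given for close to 3 weeks out of 4, and tranexamic acid.
#'
#' @return Character vector of the eight canonical class codes, in the fixed
#'   canonical (lexicographic) order used for deterministic table output.
#' @export
#' @examples
#' treatment_classes()
treatment_classes <- function() {
  sort(c("COC", "DANAZOL", "ABLATION", "LNG_IUS", "PLACEBO",
         "PROG_LT2WK", "PROG_3WK", "TXA"))
}

#' Normalise treatment class labels
#'
#' Class labels are case-insensitive on input and tolerant of separator
#' punctuation (\code{"lng-ius"}, \code{"LNG IUS"} and \code{"LNG_IUS"} are
#' equivalent). Unknown labels raise an error listing the admissible codes.
#'
#' @param x character vector of class labels.
#' @return Character vector of canonical class codes.
#' @export
canonical_class <- function(x) {
  canon <- toupper(trimws(as.character(x)))
  canon <- gsub("[^A-Z0-9]+", "_", canon)
  canon <- gsub("^_+|_+$", "", canon)
  # common label variants seen in source tables
  alias <- c(PROG_2WK = "PROG_LT2WK", PROG_LT_2WK = "PROG_LT2WK",
             PROG_2WKS = "PROG_LT2WK", PROG_3WKS = "PROG_3WK",
             LNGIUS = "LNG_IUS")
  hit <- canon %in% names(alias)
  canon[hit] <- alias[canon[hit]]
  valid <- treatment_classes()
  bad <- unique(canon[!canon %in% valid & !is.na(canon)])
  if (length(bad) > 0L) {
    stop("unknown treatment class label(s): ", paste(bad, collapse = ", "),
         "; admissible codes: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  canon
}

#' Admissible follow-up times
#'
#' Follow-up is recorded in exact integer months; the source trials used
#' 1, 2, 3, 6, 9, 12, 24 and 36 months.
#'
#' @return Integer vector of the standard follow-up menu.
#' @export
follow_up_menu <- function() c(1L, 2L, 3L, 6L, 9L, 12L, 24L, 36L)

# inverse logit, numerically safe for large |x|
invlogit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

# canonical unordered-pair label, lexicographic on class codes
pair_label <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = " & ")
}
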