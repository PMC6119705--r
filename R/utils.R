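#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used in the package's
#' report tables (0.485 rounds to 0.49), as opposed to the IEEE
#' round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector, rounded.
#' @examples
#' round_half_up(c(0.485, 0.5425, 2.3175), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 0)
  m <- 10^digits
  out <- sign(x) * floor(abs(x) * m + 0.5) / m
  out[!is.finite(x)] <- x[!is.finite(x)]
  out
}

# shared enum normalisers ----------------------------------------------------

normalize_sex <- function(x) {
  raw <- trimws(as.character(x))
  up <- toupper(raw)
  out <- rep(NA_character_, length(up))
  out[up %in% c("F", "FEMALE")] <- "F"
  out[up %in% c("M", "MALE")] <- "M"
  out[up %in% c("", "NA", "U", "UNKNOWN") | is.na(raw)] <- "UNKNOWN"
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    stop("unknown sex token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

normalize_karyotype <- function(x) {
  raw <- trimws(as.character(x))
  up <- toupper(raw)
  out <- rep(NA_character_, length(up))
  out[up %in% c("I", "1", "N", "NORMAL")] <- "NORMAL"
  out[up %in% c("II", "III", "IV", "V", "2", "3", "4", "5",
                "T", "TRANSLOCATED")] <- "TRANSLOCATED"
  out[up %in% c("", "NA", "U", "UNKNOWN") | is.na(raw)] <- "UNKNOWN"
  if (anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    stop("unknown karyotype token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
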