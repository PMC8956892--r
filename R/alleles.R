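#' Parse STR allele designations
#'
#' Y-STR alleles are named by their repeat count, with micro-variant alleles
#' carrying a suffix counting extra bases beyond complete repeat units:
#' `"24"` is 24 full repeats, `"24.1"` is 24 repeats plus one base. Ordering
#' is lexicographic on (repeats, variant), so 22 < 22.1 < 23.
#'
#' Only a single micro-variant digit is accepted (`"24.15"` is malformed:
#' the suffix counts bases of an incomplete repeat, never two digits).
#'
#' @param x character vector of allele designations; `NA` passes through.
#' @return data.frame with integer columns `repeats` (1-99) and `variant`
#'   (0-9), one row per element of `x`.
#' @examples
#' parseAllele(c("15", "24.1"))
#' @export
parseAllele <- function(x) {
  x <- as.character(x)
  ok <- is.na(x) | grepl("^[0-9]{1,2}(\\.[0-9])?$", x)
  if (!all(ok))
    stop("malformed allele designation(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  rep_ <- ifelse(is.na(x), NA_integer_, as.integer(sub("\\..*$", "", x)))
  var_ <- ifelse(is.na(x) | !grepl("\\.", x), ifelse(is.na(x), NA_integer_, 0L),
                 suppressWarnings(as.integer(sub("^.*\\.", "", x))))
  bad <- !is.na(rep_) & (rep_ < 1L | rep_ > 99L)
  if (any(bad))
    stop("allele repeat count out of range [1, 99]: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  data.frame(repeats = rep_, variant = as.integer(var_))
}

#' Render allele (repeats, variant) pairs back to text
#'
#' Inverse of [parseAllele()]: `formatAllele(parseAllele(x))` reproduces `x`
#' exactly for every valid designation.
#'
#' @param repeats integer vector, or the data.frame returned by [parseAllele()].
#' @param variant integer vector of extra-base counts (0 = none).
#' @return character vector of designations.
#' @export
formatAllele <- function(repeats, variant = 0L) {
  if (is.data.frame(repeats)) {
    variant <- repeats$variant
    repeats <- repeats$repeats
  }
  ifelse(is.na(repeats), NA_character_,
         ifelse(variant > 0L, paste0(repeats, ".", variant), as.character(repeats)))
}

#' Numeric value of an allele for repeat-distance arithmetic
#'
#' Micro-variants map to repeats + variant/10, preserving the allele ordering
#' with a small explicit weight (so 24 < 24.1 < 25 and the squared distance
#' between 24 and 24.1 is 0.01).
#'
#' @param x character vector of allele designations.
#' @return numeric vector; `NA` where `x` is `NA`.
#' @export
alleleValue <- function(x) {
  p <- parseAllele(x)
  p$repeats + p$variant / 10
}

# sort allele designations by (repeats, variant)
sortAlleles <- function(x) {
  p <- parseAllele(x)
  x[order(p$repeats, p$variant, na.last = TRUE)]
}
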