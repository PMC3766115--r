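#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used everywhere a printed per-genome or
#' per-site ratio is produced. Base [round()] rounds half to even, which does
#' not reproduce mixed-format summary tables of the kind this package emits.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a per-genome ratio the way the summary tables print it
#'
#' Values of 10 or more are rendered as integers, values below 10 with one
#' decimal place, both with half-up rounding. Returns a numeric (39, 7.6, ...),
#' not a string, so downstream arithmetic still works.
#'
#' @param x numeric vector of ratios.
#' @return numeric vector formatted under the mixed integer/one-decimal rule.
#' @export
format_ratio <- function(x) {
  ifelse(is.na(x), NA_real_,
         ifelse(abs(x) >= 10, round_half_up(x, 0), round_half_up(x, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a functional role string for lookup
#'
#' Trims, collapses internal whitespace and lower-cases, so role matching is
#' exact-after-normalization rather than fuzzy.
#'
#' @param x character vector of role names.
#' @return normalized character vector.
#' @export
normalize_role <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

stop_record <- function(msg, record) {
  stop(sprintf("%s [record: %s]", msg, record), call. = FALSE)
}

# empty prototypes shared by readers/builders so column types stay stable
empty_genes <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             locus_tag = character(), functional_role = character(),
             stringsAsFactors = FALSE)
}

empty_sites <- function() {
  data.frame(site_id = character(), motif_id = character(),
             genome_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             score = numeric(), stringsAsFactors = FALSE)
}
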