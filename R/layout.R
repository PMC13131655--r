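#' Genome layout: chromosome lengths and assembly gaps
#'
#' A genome layout records the ordered chromosome lengths of an assembly and,
#' optionally, its assembly gaps (runs of Ns). It is the denominator object for
#' chromosome-end distances, gap distances, window clipping and interval
#' shuffling.
#'
#' @param chromosomes A data frame with columns `chrom` (character, unique) and
#'   `length` (positive integer bp), or a named numeric vector of lengths.
#' @param gaps Optional data frame of gap intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open); every gap must lie inside its
#'   chromosome.
#'
#' @return An object of class `genome_layout`: a list with tibbles
#'   `chromosomes` and `gaps`.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(chromosomes, gaps = NULL) {
  if (is.numeric(chromosomes)) {
    if (is.null(names(chromosomes))) {
      abort("chromosome length vector must be named")
    }
    chromosomes <- tibble(chrom = names(chromosomes),
                          length = unname(chromosomes))
  }
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns chrom, length")
  }
  if (anyDuplicated(chromosomes$chrom)) abort("duplicated chromosome names")
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be > 0")
  if (is.null(gaps)) {
    gaps <- tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    gaps <- as_tibble(gaps)[, c("chrom", "start", "end")]
    check_intervals(gaps)
    len <- chromosomes$length[match(gaps$chrom, chromosomes$chrom)]
    if (anyNA(len)) abort("gap on unknown chromosome")
    if (any(gaps$start < 0 | gaps$end > len)) {
      abort("gaps must lie within their chromosome")
    }
  }
  structure(list(chromosomes = chromosomes, gaps = gaps),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosomes, ",
      sum(x$chromosomes$length), " bp, ", nrow(x$gaps), " gaps\n", sep = "")
  invisible(x)
}

#' @rdname genome_layout
#' @param x Object to test.
#' @export
is_genome_layout <- function(x) inherits(x, "genome_layout")

layout_length <- function(layout, chrom) {
  layout$chromosomes$length[match(chrom, layout$chromosomes$chrom)]
}

#' Total genome size of a layout
#'
#' @param layout A [genome_layout()].
#' @param exclude_gaps Subtract total gap bp.
#' @return Numeric bp.
#' @export
genome_size <- function(layout, exclude_gaps = FALSE) {
  tot <- sum(layout$chromosomes$length)
  if (exclude_gaps && nrow(layout$gaps) > 0) {
    tot <- tot - sum(merge_within(layout$gaps, max_gap = 0) |>
                       dplyr::mutate(w = .data$end - .data$start) |>
                       dplyr::pull("w"))
  }
  tot
}

# validate an interval tibble: chrom/start/end present, 0 <= start < end
check_intervals <- function(x, allow_empty = TRUE) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort("interval table needs columns chrom, start, end")
  }
  if (nrow(x) == 0) {
    if (!allow_empty) abort("empty interval table")
    return(invisible(x))
  }
  if (any(is.na(x$chrom) | !nzchar(x$chrom))) abort("chrom must be non-empty")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(paste0("degenerate interval at row ", bad[1],
                 " (need 0 <= start < end)"))
  }
  invisible(x)
}
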