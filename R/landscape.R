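#' Neutral-rate configuration for dating repeat copies
#'
#' Converts per-copy CpG-corrected Kimura divergence (%) into absolute time
#' using a neutral substitution rate. The default rate, 3.2e-3
#' substitutions/site/MY, is the notothenioid neutral rate estimated from
#' 4-fold degenerate sites. Both dating conventions found in the literature
#' are supported: dividing by `2r` (divergence accumulates on the copy and
#' the consensus lineage) or by `r` alone.
#'
#' @param rate Neutral substitution rate in substitutions/site/MY (> 0).
#' @param divisor_mode `"2r"` (default) or `"r"`.
#' @return A `neutral_rate_config` list with `rate`, `divisor_mode`,
#'   `divisor`.
#' @export
neutral_rate_config <- function(rate = 3.2e-3, divisor_mode = c("2r", "r")) {
  divisor_mode <- match.arg(divisor_mode)
  if (!is.numeric(rate) || rate <= 0) abort("rate must be > 0")
  structure(list(rate = rate, divisor_mode = divisor_mode,
                 divisor = if (divisor_mode == "2r") 2 * rate else rate),
            class = "neutral_rate_config")
}

#' Translate Kimura divergence into age
#'
#' `age = (K / 100) / divisor`, monotone increasing in `K`.
#'
#' @param K Percent divergence (>= 0), vectorized.
#' @param cfg A [neutral_rate_config()].
#' @return Ages in MY.
#' @examples
#' divergence_to_age(6.4, neutral_rate_config(3.2e-3, "2r"))  # 10 MY
#' @export
divergence_to_age <- function(K, cfg = neutral_rate_config()) {
  if (any(K < 0)) abort("divergence must be >= 0")
  (K / 100) / cfg$divisor
}

#' Dated repeat landscape
#'
#' Bins repeat-derived bp by the age of each copy (from its divergence under
#' a neutral rate), per TE class and optionally per family. Every hit
#' contributes its full length to exactly one bin, so total bp is conserved.
#' Ages beyond `max_age` (when given) accumulate in an overflow bin
#' `[max_age, Inf)` rather than being dropped.
#'
#' @param repeats Repeat tibble (`chrom`, `start`, `end`, `class`,
#'   `divergence_pct`, optionally `family`).
#' @param cfg A [neutral_rate_config()].
#' @param bin_width Bin width in MY (> 0); 1 MY for class-level landscapes,
#'   0.5 MY for family-level ones.
#' @param by `"class"` or `"family"`.
#' @param max_age Optional overflow boundary in MY.
#' @return Tibble (`bin_low`, `bin_high`, group column, `bp`), bins
#'   contiguous and non-overlapping.
#' @export
dated_landscape <- function(repeats, cfg = neutral_rate_config(),
                            bin_width = 1, by = c("class", "family"),
                            max_age = NULL) {
  by <- match.arg(by)
  if (bin_width <= 0) abort("bin_width must be > 0")
  check_intervals(repeats)
  age <- divergence_to_age(repeats$divergence_pct, cfg)
  idx <- floor(age / bin_width)
  if (!is.null(max_age)) {
    over <- floor(max_age / bin_width)
    idx[idx >= over] <- over
  }
  d <- tibble(bin = idx, grp = repeats[[by]],
              bp = repeats$end - repeats$start) |>
    group_by(.data$bin, .data$grp) |>
    summarise(bp = sum(.data$bp), .groups = "drop")
  out <- tibble(bin_low = d$bin * bin_width, bin_high = (d$bin + 1) * bin_width,
                grp = d$grp, bp = d$bp)
  if (!is.null(max_age)) {
    out$bin_high[out$bin_low >= max_age] <- Inf
    out$bin_low[out$bin_low >= max_age] <- max_age
  }
  names(out)[names(out) == "grp"] <- by
  arrange(out, .data$bin_low, .data[[by]])
}

#' Genome coverage per repeat class and family
#'
#' Percent of the genome covered by each TE class (and family). With
#' `resolve = TRUE` overlapping hits are first flattened with
#' [resolve_overlaps_by_score()] so every base counts once, toward the
#' higher-scoring hit.
#'
#' @param repeats Repeat tibble with `score` when `resolve = TRUE`.
#' @param genome_bp Genome size (> 0) used as denominator.
#' @param resolve Resolve overlaps by score first (default `TRUE`).
#' @return Tibble (`level`, `name`, `bp`, `pct`); class rows sum to <= 100%.
#' @export
coverage_by_class <- function(repeats, genome_bp, resolve = TRUE) {
  if (genome_bp <= 0) abort("genome_bp must be > 0")
  check_intervals(repeats)
  hits <- if (resolve) resolve_overlaps_by_score(repeats) else repeats
  w <- hits$end - hits$start
  cls <- tibble(level = "class", name = hits$class, bp = w) |>
    group_by(.data$level, .data$name) |>
    summarise(bp = sum(.data$bp), .groups = "drop")
  out <- cls
  if ("family" %in% names(hits)) {
    fam <- tibble(level = "family", name = hits$family, bp = w) |>
      group_by(.data$level, .data$name) |>
      summarise(bp = sum(.data$bp), .groups = "drop")
    out <- bind_rows(cls, fam)
  }
  mutate(out, pct = 100 * .data$bp / genome_bp)
}
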