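#' Reciprocal overlap between paired intervals
#'
#' For each row pair (`a[i, ]`, `b[i, ]`) computes the overlap in bp and the
#' fraction of each interval covered by the other. This is the matching
#' primitive behind heterozygous transposon-insertion calling and
#' branch-insertion attribution, where two annotations are required to overlap
#' by at least 75% of their respective lengths.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`; 0-based half-open)
#'   with the same number of rows, compared row by row.
#' @return A tibble with columns `overlap_bp`, `frac_a`, `frac_b`. Pairs on
#'   different chromosomes get zero overlap.
#' @examples
#' reciprocal_overlap(
#'   tibble::tibble(chrom = "c", start = 0, end = 100),
#'   tibble::tibble(chrom = "c", start = 50, end = 150)
#' )
#' @export
reciprocal_overlap <- function(a, b) {
  check_intervals(a)
  check_intervals(b)
  if (nrow(a) != nrow(b)) abort("a and b must have the same number of rows")
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  tibble(
    overlap_bp = ov,
    frac_a = ov / (a$end - a$start),
    frac_b = ov / (b$end - b$start)
  )
}

#' Test a reciprocal-overlap threshold
#'
#' @param a,b Row-paired interval tibbles.
#' @param min_reciprocal Inclusive threshold; both fractions must reach it.
#' @return Logical vector.
#' @export
passes_reciprocal <- function(a, b, min_reciprocal = 0.75) {
  ro <- reciprocal_overlap(a, b)
  ro$frac_a >= min_reciprocal & ro$frac_b >= min_reciprocal
}

# All overlapping (query, subject) row-index pairs, per chromosome.
# Near-linear for bounded interval widths.
overlap_pairs <- function(query, subject) {
  out_q <- integer(0); out_s <- integer(0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    so <- si[order(subject$start[si])]
    ss <- subject$start[so]; se <- subject$end[so]
    wmax <- max(se - ss)
    for (i in qi) {
      qs <- query$start[i]; qe <- query$end[i]
      hi <- findInterval(qe - 1e-9, ss)          # subjects starting before qe
      lo <- findInterval(qs - wmax, ss) + 1L     # subjects that could reach qs
      if (hi < lo) next
      cand <- lo:hi
      keep <- cand[se[cand] > qs]
      if (length(keep)) {
        out_q <- c(out_q, rep.int(i, length(keep)))
        out_s <- c(out_s, so[keep])
      }
    }
  }
  tibble(query = out_q, subject = out_s)
}

#' Find reciprocal-overlap matches between two interval sets
#'
#' Returns every (query, subject) pair whose reciprocal overlap reaches
#' `min_reciprocal` on both sides, with overlap fractions attached.
#'
#' @param query,subject Interval tibbles.
#' @param min_reciprocal Inclusive threshold (default 0.75).
#' @return Tibble with `query`/`subject` row indices, `overlap_bp`,
#'   `frac_query`, `frac_subject`.
#' @export
reciprocal_matches <- function(query, subject, min_reciprocal = 0.75) {
  check_intervals(query)
  check_intervals(subject)
  pr <- overlap_pairs(query, subject)
  if (nrow(pr) == 0) {
    return(tibble(query = integer(), subject = integer(),
                  overlap_bp = numeric(), frac_query = numeric(),
                  frac_subject = numeric()))
  }
  qa <- query[pr$query, ]; sb <- subject[pr$subject, ]
  ov <- pmax(0, pmin(qa$end, sb$end) - pmax(qa$start, sb$start))
  fq <- ov / (qa$end - qa$start)
  fs <- ov / (sb$end - sb$start)
  keep <- fq >= min_reciprocal & fs >= min_reciprocal
  tibble(query = pr$query[keep], subject = pr$subject[keep],
         overlap_bp = ov[keep], frac_query = fq[keep], frac_subject = fs[keep])
}

#' Merge intervals separated by less than a gap
#'
#' Two intervals merge iff they are on the same chromosome, share the same
#' `group_key` value (when given), and the gap between them is strictly
#' smaller than `max_gap` ("closer than N bp"). Overlapping intervals always
#' merge. Used with `max_gap = 100` to re-join fragmented lifted insertions
#' of one ancestral event and with `max_gap = 5` to merge conserved elements.
#'
#' @param x Interval tibble.
#' @param max_gap Non-negative gap threshold in bp (strict inequality).
#' @param group_key Optional column name whose values must match for a merge.
#' @return Tibble of disjoint merged intervals per group with `n_merged`.
#' @examples
#' merge_within(tibble::tibble(chrom = "c", start = c(0, 109), end = c(10, 120)),
#'              max_gap = 100)
#' @export
merge_within <- function(x, max_gap, group_key = NULL) {
  check_intervals(x)
  if (max_gap < 0) abort("max_gap must be >= 0")
  if (nrow(x) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_merged = integer())
    if (!is.null(group_key)) out[[group_key]] <- character()
    return(out)
  }
  key <- if (is.null(group_key)) rep("", nrow(x)) else as.character(x[[group_key]])
  ord <- order(x$chrom, key, x$start, x$end)
  ch <- x$chrom[ord]; ky <- key[ord]; s <- x$start[ord]; e <- x$end[ord]
  cm <- e
  new_grp <- logical(length(s))
  new_grp[1] <- TRUE
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      same <- ch[i] == ch[i - 1] && ky[i] == ky[i - 1]
      if (same) cm[i] <- max(cm[i], cm[i - 1])
      # merge iff gap = s[i] - running_end < max_gap
      new_grp[i] <- !same || (s[i] - cm[i - 1]) >= max_gap
      if (new_grp[i]) cm[i] <- e[i]
    }
  }
  grp <- cumsum(new_grp)
  out <- tibble(chrom = ch, key = ky, start = s, end = e, grp = grp) |>
    group_by(.data$grp) |>
    summarise(chrom = first(.data$chrom), key = first(.data$key),
              start = min(.data$start), end = max(.data$end),
              n_merged = dplyr::n(), .groups = "drop") |>
    select(-"grp") |>
    arrange(.data$chrom, .data$key, .data$start)
  if (is.null(group_key)) out$key <- NULL else names(out)[names(out) == "key"] <- group_key
  out[, c("chrom", group_key, "start", "end", "n_merged")]
}

# union of intervals (disjoint, sorted); thin wrapper over merge_within(0)
# with touching intervals also coalesced (harmless for coverage sums).
interval_union <- function(x) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  ord <- order(x$chrom, x$start, x$end)
  ch <- x$chrom[ord]; s <- x$start[ord]; e <- x$end[ord]
  cm <- e
  new_grp <- logical(length(s)); new_grp[1] <- TRUE
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      same <- ch[i] == ch[i - 1]
      if (same) cm[i] <- max(cm[i], cm[i - 1])
      new_grp[i] <- !same || s[i] > cm[i - 1]
      if (new_grp[i]) cm[i] <- e[i]
    }
  }
  grp <- cumsum(new_grp)
  tibble(chrom = ch, start = s, end = e, grp = grp) |>
    group_by(.data$grp) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), .groups = "drop") |>
    select(-"grp") |>
    arrange(.data$chrom, .data$start)
}

#' Resolve overlapping scored hits, keeping the higher score per base
#'
#' Produces a disjoint annotation in which, at every base, the retained hit is
#' the one with the highest alignment score; lower-scoring hits are truncated
#' (possibly split into fragments) or dropped. Ties break by earlier start,
#' then input order. This mirrors the "higher score" overlap resolution used
#' to flatten repeat annotations before coverage summaries.
#'
#' @param hits Tibble with `chrom`, `start`, `end`, `score` plus any metadata
#'   columns, which are carried through.
#' @return Tibble of disjoint hits; a column `source_row` records the input
#'   row each output fragment came from.
#' @export
resolve_overlaps_by_score <- function(hits) {
  check_intervals(hits)
  if (!"score" %in% names(hits)) abort("hits need a numeric `score` column")
  if (nrow(hits) == 0) return(mutate(hits, source_row = integer()))
  prio <- order(-hits$score, hits$start, seq_len(nrow(hits)))
  pieces <- vector("list", length(prio))
  occ <- split(tibble(start = numeric(), end = numeric()), character(0))
  occupied <- list()  # per chrom: matrix-ish tibble of disjoint intervals
  for (k in seq_along(prio)) {
    i <- prio[k]
    ch <- hits$chrom[i]
    s <- hits$start[i]; e <- hits$end[i]
    oc <- occupied[[ch]]
    if (is.null(oc) || nrow(oc) == 0) {
      frag <- tibble(start = s, end = e)
    } else {
      # subtract occupied from [s, e)
      rel <- oc[oc$end > s & oc$start < e, , drop = FALSE]
      if (nrow(rel) == 0) {
        frag <- tibble(start = s, end = e)
      } else {
        rel <- rel[order(rel$start), , drop = FALSE]
        st <- pmax(s, c(s, rel$end))
        en <- pmin(e, c(rel$start, e))
        frag <- tibble(start = st, end = en)[en > st, , drop = FALSE]
      }
    }
    if (nrow(frag)) {
      pieces[[k]] <- mutate(frag, source_row = i)
      newoc <- bind_rows(oc %||% tibble(start = numeric(), end = numeric()),
                         frag)
      occupied[[ch]] <- interval_union(mutate(newoc, chrom = ch))[, c("start", "end")]
    }
  }
  frags <- bind_rows(pieces)
  if (is.null(frags) || nrow(frags) == 0) {
    return(mutate(hits[0, ], source_row = integer()))
  }
  out <- hits[frags$source_row, ]
  out$start <- frags$start
  out$end <- frags$end
  out$source_row <- frags$source_row
  arrange(out, .data$chrom, .data$start)
}

# cumulative-coverage lookup tables per chromosome for a union annotation
coverage_index <- function(annotation) {
  u <- interval_union(annotation)
  split(u, u$chrom) |>
    lapply(function(d) {
      list(s = d$start, e = d$end, cum = cumsum(d$end - d$start))
    })
}

# covered bp of [0, p) for one chromosome's index
covered_upto <- function(idx, p) {
  if (is.null(idx)) return(rep(0, length(p)))
  k <- findInterval(p, idx$s)
  out <- numeric(length(p))
  pos <- k > 0
  out[pos] <- idx$cum[k[pos]] - pmax(0, idx$e[k[pos]] - p[pos])
  out
}

#' Fraction of window bases covered by an annotation
#'
#' Coverage is of the union of the annotation (self-overlap counted once).
#' When a `layout` is supplied, windows are clipped at chromosome boundaries
#' and the clipped length is the denominator; a window entirely outside its
#' chromosome is an error.
#'
#' @param windows Interval tibble of query windows.
#' @param annotation Interval tibble (may self-overlap).
#' @param layout Optional [genome_layout()] for boundary clipping.
#' @return Numeric vector of fractions in `[0, 1]`, one per window.
#' @export
feature_fraction <- function(windows, annotation, layout = NULL) {
  check_intervals(windows)
  check_intervals(annotation)
  ws <- windows$start; we <- windows$end
  if (!is.null(layout)) {
    len <- layout_length(layout, windows$chrom)
    if (anyNA(len)) abort("window on chromosome absent from layout")
    if (any(ws >= len | we <= 0)) abort("window lies outside its chromosome")
    ws <- pmax(0, ws); we <- pmin(we, len)
  }
  idx <- coverage_index(annotation)
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    i <- windows$chrom == ch
    cov <- covered_upto(idx[[ch]], we[i]) - covered_upto(idx[[ch]], ws[i])
    out[i] <- cov / (we[i] - ws[i])
  }
  out
}

#' Distance to the nearest target interval
#'
#' Zero when `x` overlaps a target; otherwise the gap in bp to the closest
#' target on the same chromosome; `NA` when the chromosome carries no target
#' (never an error).
#'
#' @param x Interval tibble of queries.
#' @param targets Interval tibble of targets (e.g. assembly gaps).
#' @return Numeric vector of distances (bp), `NA` where undefined.
#' @export
distance_to_nearest <- function(x, targets) {
  check_intervals(x)
  check_intervals(targets)
  u <- interval_union(targets)
  us <- split(u, u$chrom)
  out <- rep(NA_real_, nrow(x))
  for (ch in unique(x$chrom)) {
    d <- us[[ch]]
    if (is.null(d) || nrow(d) == 0) next
    i <- which(x$chrom == ch)
    k <- findInterval(x$start[i], d$start)
    dist <- numeric(length(i))
    for (j in seq_along(i)) {
      kk <- k[j]
      qs <- x$start[i[j]]; qe <- x$end[i[j]]
      if (kk > 0 && d$end[kk] > qs) { dist[j] <- 0; next }
      if (kk < nrow(d) && d$start[kk + 1] < qe) { dist[j] <- 0; next }
      left <- if (kk > 0) qs - d$end[kk] else Inf
      right <- if (kk < nrow(d)) d$start[kk + 1] - qe else Inf
      dist[j] <- min(left, right)
    }
    out[i] <- dist
  }
  out
}

#' Distance to the nearest chromosome end
#'
#' @param x Interval tibble.
#' @param layout A [genome_layout()] providing chromosome lengths.
#' @return `pmin(start, length - end)` per interval.
#' @export
distance_to_chrom_end <- function(x, layout) {
  check_intervals(x)
  len <- layout_length(layout, x$chrom)
  if (anyNA(len)) abort("interval on chromosome absent from layout")
  if (any(x$end > len)) abort("interval extends beyond chromosome length")
  pmin(x$start, len - x$end)
}

#' Randomize interval placement, preserving lengths
#'
#' Places each input interval uniformly at random over the permitted positions
#' of the genome (optionally excluding assembly gaps, optionally restricted to
#' the interval's own chromosome), preserving its length exactly. This
#' produces the shuffled control set contrasted with observed structural
#' variants in the feature-association model.
#'
#' @param x Interval tibble.
#' @param layout A [genome_layout()].
#' @param seed Mandatory integer seed; a fixed seed reproduces the placement.
#' @param exclude_gaps Never intersect layout gaps (default `TRUE`).
#' @param preserve_chrom Keep each interval on its original chromosome.
#' @return Tibble with the same columns as `x` and new coordinates.
#' @export
shuffle_intervals <- function(x, layout, seed, exclude_gaps = TRUE,
                              preserve_chrom = FALSE) {
  check_intervals(x)
  spans <- permitted_spans(layout, exclude_gaps)
  sp_chrom <- spans$chrom
  sp_start <- spans$start
  sp_len <- spans$end - spans$start
  local_seed(seed, {
    w <- x$end - x$start
    new_chrom <- character(nrow(x)); new_start <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      elig <- which(sp_len >= w[i] &
                      (!preserve_chrom | sp_chrom == x$chrom[i]))
      if (length(elig) == 0) {
        abort(paste0("interval ", x$chrom[i], ":", x$start[i], "-", x$end[i],
                     " (", w[i], " bp) does not fit any permitted span"))
      }
      wt <- sp_len[elig] - w[i] + 1
      j <- elig[sample.int(length(elig), 1, prob = wt)]
      off <- floor(runif(1) * (sp_len[j] - w[i] + 1))  # uniform over starts
      new_chrom[i] <- sp_chrom[j]
      new_start[i] <- sp_start[j] + off
    }
    out <- x
    out$chrom <- new_chrom
    out$start <- new_start
    out$end <- new_start + w
    out
  })
}

# chromosome spans minus (optionally) gaps
permitted_spans <- function(layout, exclude_gaps = TRUE) {
  full <- tibble(chrom = layout$chromosomes$chrom, start = 0,
                 end = layout$chromosomes$length)
  if (!exclude_gaps || nrow(layout$gaps) == 0) return(full)
  g <- interval_union(layout$gaps)
  out <- list()
  for (i in seq_len(nrow(full))) {
    ch <- full$chrom[i]
    gg <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(gg) == 0) { out[[i]] <- full[i, ]; next }
    st <- c(0, gg$end); en <- c(gg$start, full$end[i])
    keep <- en > st
    out[[i]] <- tibble(chrom = ch, start = st[keep], end = en[keep])
  }
  bind_rows(out)
}
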