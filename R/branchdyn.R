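# Per-branch genome gain/loss rates and TE attribution of lifted insertions.

#' Net genome gain/loss rate per branch
#'
#' Sums the bp involved in insertion and deletion events on every branch of
#' a dated species tree, forms the net gain (insertions minus deletions),
#' and divides by the branch duration to get a rate in Mb/MY (1 Mb = 1e6
#' bp). Branches without events report zero bp.
#'
#' @param mutations Branch-mutation tibble (see [read_branch_mutations()]);
#'   every `branch_id` must exist in `tree`.
#' @param tree A [dated_tree()].
#' @return Tibble per branch: `branch_id`, `ins_bp`, `del_bp`, `net_bp`,
#'   `duration`, `net_rate_mb_my`.
#' @export
net_gain_rates <- function(mutations, tree) {
  br <- tree$branches
  unknown <- setdiff(unique(mutations$branch_id), br$branch_id)
  if (length(unknown)) {
    abort(paste0("unknown branch_id: ", paste(unknown, collapse = ", ")))
  }
  if (any(br$duration <= 0)) abort("branch durations must be > 0")
  sums <- mutations |>
    group_by(.data$branch_id) |>
    summarise(ins_bp = sum(.data$bp[.data$kind == "insertion"]),
              del_bp = sum(.data$bp[.data$kind == "deletion"]),
              .groups = "drop")
  br |>
    left_join(sums, by = "branch_id") |>
    mutate(ins_bp = dplyr::coalesce(.data$ins_bp, 0),
           del_bp = dplyr::coalesce(.data$del_bp, 0),
           net_bp = .data$ins_bp - .data$del_bp,
           net_rate_mb_my = .data$net_bp / 1e6 / .data$duration) |>
    select("branch_id", "ins_bp", "del_bp", "net_bp", "duration",
           "net_rate_mb_my")
}

#' Merge fragmented lifted insertions
#'
#' Lifted insertion intervals are often fragmented; fragments derived from
#' the same ancestral event (same `event_id`) and closer than `max_gap` bp
#' are merged back into single intervals, per branch. Fragments of
#' different events never merge. The merged record's bp is the merged
#' interval length.
#'
#' @param mutations Branch-mutation tibble; only insertion rows with lifted
#'   coordinates are used.
#' @param max_gap Strict gap threshold in bp (default 100).
#' @return Tibble `branch_id`, `event_id`, `chrom`, `start`, `end`, `bp`,
#'   `n_fragments`.
#' @export
merge_lifted_insertions <- function(mutations, max_gap = 100) {
  ins <- filter(mutations, .data$kind == "insertion", !is.na(.data$chrom))
  if (nrow(ins) == 0) {
    return(tibble(branch_id = character(), event_id = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  bp = numeric(), n_fragments = integer()))
  }
  ins <- mutate(ins, .grp = paste(.data$branch_id, .data$event_id, sep = "\r"))
  merged <- merge_within(ins[, c("chrom", "start", "end", ".grp")],
                         max_gap = max_gap, group_key = ".grp")
  parts <- stringr::str_split_fixed(merged$.grp, "\r", 2)
  tibble(branch_id = parts[, 1], event_id = parts[, 2],
         chrom = merged$chrom, start = merged$start, end = merged$end,
         bp = merged$end - merged$start, n_fragments = merged$n_merged) |>
    arrange(.data$branch_id, .data$chrom, .data$start)
}

#' Attribute merged insertions to annotated TEs
#'
#' An insertion is TE-attributable when it reciprocally overlaps a repeat
#' hit by at least `min_reciprocal` (inclusive) on both sides; the best
#' (highest-overlap) qualifying hit wins. Returns per-branch counts,
#' per-MY rates, and the class composition of attributed insertions.
#'
#' @param merged Output of [merge_lifted_insertions()].
#' @param repeats Repeat tibble on the same reference genome.
#' @param tree A [dated_tree()] supplying branch durations.
#' @param min_reciprocal Inclusive threshold (0.75).
#' @return List with `attributed` (one row per TE-attributed insertion,
#'   with `te_family`, `te_class`), `per_branch` (tibble `branch_id`,
#'   `n_insertions`, `n_te`, `duration`, `te_per_my`), and `composition`
#'   (tibble `branch_id`, `te_class`, `n`, `fraction`; fractions sum to 1
#'   per branch with attributed insertions).
#' @export
attribute_te_insertions <- function(merged, repeats, tree,
                                    min_reciprocal = 0.75) {
  mm <- reciprocal_matches(merged, repeats, min_reciprocal)
  best <- mm |>
    group_by(.data$query) |>
    arrange(desc(.data$overlap_bp), .data$subject, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  attributed <- merged[best$query, ]
  attributed$te_family <- repeats$family[best$subject]
  attributed$te_class <- repeats$class[best$subject]
  attributed$overlap_frac <- best$frac_query
  per_branch <- merged |>
    count(.data$branch_id, name = "n_insertions") |>
    left_join(count(attributed, .data$branch_id, name = "n_te"),
              by = "branch_id") |>
    mutate(n_te = dplyr::coalesce(.data$n_te, 0L)) |>
    inner_join(select(tree$branches, "branch_id", "duration"),
               by = "branch_id") |>
    mutate(te_per_my = .data$n_te / .data$duration)
  composition <- attributed |>
    count(.data$branch_id, .data$te_class, name = "n") |>
    group_by(.data$branch_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  list(attributed = attributed, per_branch = per_branch,
       composition = composition)
}

#' TE-insertion rate along a root-to-leaf path
#'
#' Piecewise-constant series of the per-MY TE insertion rate along the
#' branches from the root to a focal leaf, one step per branch spanning
#' `[parent_age, child_age)` in MYA. Optionally smoothed with a centred
#' moving average over steps (window recorded in the output).
#'
#' @param per_branch The `per_branch` tibble of [attribute_te_insertions()]
#'   (or any tibble with `branch_id`, `n_te`, `duration`, `te_per_my`).
#' @param tree A [dated_tree()].
#' @param focal_leaf Tip label of the focal species.
#' @param smooth_window Odd integer window for a moving average over steps;
#'   `NULL` (default) for no smoothing.
#' @return Tibble `branch_id`, `age_start` (older), `age_end`, `rate`
#'   (insertions/MY), `rate_smoothed` when requested; attribute
#'   `smooth_window`.
#' @export
rate_curve <- function(per_branch, tree, focal_leaf, smooth_window = NULL) {
  path <- root_to_leaf_branches(tree, focal_leaf)
  br <- tree$branches
  steps <- tibble(branch_id = path) |>
    inner_join(br, by = "branch_id") |>
    left_join(select(per_branch, "branch_id", "n_te", "te_per_my"),
              by = "branch_id") |>
    mutate(n_te = dplyr::coalesce(.data$n_te, 0L),
           rate = dplyr::coalesce(.data$te_per_my, 0)) |>
    select(branch_id = "branch_id", age_start = "parent_age",
           age_end = "child_age", "n_te", "rate")
  if (!is.null(smooth_window)) {
    k <- as.integer(smooth_window)
    if (k < 1 || k %% 2 == 0) abort("smooth_window must be a positive odd integer")
    steps$rate_smoothed <- stats::filter(steps$rate, rep(1 / k, k),
                                         sides = 2) |> as.numeric()
  }
  attr(steps, "smooth_window") <- smooth_window
  steps
}
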