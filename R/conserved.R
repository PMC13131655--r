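# Conserved-element post-processing: merging, ancestry classification from
# per-species alignment-depth tracks, genomic-feature assignment, and
# nearest-gene linkage of intergenic elements.

#' Merge conserved elements closer than a gap
#'
#' Thin wrapper over [merge_within()] with the conserved-element default of
#' a strict 5-bp gap.
#'
#' @param ces Interval tibble of conserved elements.
#' @param max_gap Strict gap threshold (default 5).
#' @return Merged disjoint elements.
#' @export
merge_ces <- function(ces, max_gap = 5) {
  merge_within(ces, max_gap = max_gap)
}

#' Per-species covered fraction of elements
#'
#' @param ces Interval tibble.
#' @param tracks Depth-track tibble (`species`, `chrom`, `start`, `end`).
#' @param species Species to evaluate (default: all in `tracks`).
#' @return Tibble `element` (row index), one column per species with the
#'   fraction of the element covered by that species' track.
#' @export
ce_coverage <- function(ces, tracks, species = unique(tracks$species)) {
  check_intervals(ces)
  out <- tibble(element = seq_len(nrow(ces)))
  for (sp in species) {
    tr <- filter(tracks, .data$species == sp)
    out[[sp]] <- feature_fraction(ces, tr[, c("chrom", "start", "end")])
  }
  out
}

#' Classify conserved-element ancestry from alignment depth
#'
#' An element is `ancestral` when covered over at least `min_cov` of its
#' length (inclusive) by *every* species; `clade_specific` when covered at
#' least `min_cov` by every member of the focal clade while at least one
#' non-clade species falls below the threshold; `other` otherwise.
#'
#' @param ces Interval tibble of (merged) conserved elements.
#' @param tracks Depth-track tibble; every species in `all_species` must
#'   appear (missing track is an error).
#' @param all_species Character vector of all aligned species.
#' @param focal_clade Subset of `all_species` forming the focal clade.
#' @param min_cov Inclusive coverage threshold (0.75).
#' @return `ces` with per-species fraction columns and an `ancestry` column.
#' @export
classify_ancestry <- function(ces, tracks, all_species, focal_clade,
                              min_cov = 0.75) {
  if (!all(focal_clade %in% all_species)) {
    abort("focal_clade must be a subset of all_species")
  }
  missing <- setdiff(all_species, unique(tracks$species))
  if (length(missing)) {
    abort(paste0("missing depth track for: ", paste(missing, collapse = ", ")))
  }
  cov <- ce_coverage(ces, tracks, all_species)
  covm <- as.matrix(cov[, all_species, drop = FALSE])
  outgroup <- setdiff(all_species, focal_clade)
  all_ok <- rowSums(covm >= min_cov) == length(all_species)
  clade_ok <- rowSums(covm[, focal_clade, drop = FALSE] >= min_cov) ==
    length(focal_clade)
  out_below <- rowSums(covm[, outgroup, drop = FALSE] < min_cov) > 0
  ancestry <- case_when(
    all_ok ~ "ancestral",
    clade_ok & out_below ~ "clade_specific",
    TRUE ~ "other"
  )
  bind_cols(ces, cov[, all_species, drop = FALSE]) |>
    mutate(ancestry = ancestry)
}

#' Assign conserved elements to genomic features
#'
#' Labels each element at its midpoint with priority
#' exon > promoter > TTS > intron > intergenic. The promoter window is
#' strand-aware (`promoter_up` bp upstream and `promoter_down` bp
#' downstream of the TSS); the transcription termination site (TTS) window
#' is `+- tts_window` bp around the transcript end.
#'
#' @param ces Interval tibble.
#' @param genes Gene-model tibble (`type` gene/exon rows with `strand`).
#' @param promoter_up,promoter_down Promoter window around the TSS (bp).
#' @param tts_window Half-window around the TTS (bp).
#' @return Character vector of feature labels, one per element.
#' @export
assign_feature <- function(ces, genes, promoter_up = 2000,
                           promoter_down = 200, tts_window = 200) {
  check_intervals(ces)
  mid <- floor((ces$start + ces$end) / 2)
  pts <- tibble(chrom = ces$chrom, start = mid, end = mid + 1)
  gene_rows <- filter(genes, .data$type == "gene")
  exon_rows <- filter(genes, .data$type == "exon")
  plus <- gene_rows$strand != "-"
  tss <- ifelse(plus, gene_rows$start, gene_rows$end)
  tts <- ifelse(plus, gene_rows$end, gene_rows$start)
  prom <- tibble(
    chrom = gene_rows$chrom,
    start = pmax(0, ifelse(plus, tss - promoter_up, tss - promoter_down)),
    end = ifelse(plus, tss + promoter_down, tss + promoter_up)
  )
  ttsw <- tibble(chrom = gene_rows$chrom,
                 start = pmax(0, tts - tts_window), end = tts + tts_window)
  in_exon <- feature_fraction(pts, exon_rows) > 0
  in_prom <- feature_fraction(pts, prom) > 0
  in_tts <- feature_fraction(pts, ttsw) > 0
  in_gene <- feature_fraction(pts, gene_rows) > 0
  case_when(
    in_exon ~ "exon",
    in_prom ~ "promoter",
    in_tts ~ "TTS",
    in_gene ~ "intron",
    TRUE ~ "intergenic"
  )
}

#' Link intergenic conserved elements to their nearest gene
#'
#' Distance is in bp from the element to the gene body (transcript bounds);
#' overlapping counts as 0. Equidistant genes are all reported. Elements on
#' a chromosome without genes are returned unlinked and flagged.
#'
#' @param cnes Interval tibble of (typically intergenic) elements.
#' @param genes Gene-model tibble (`type == "gene"` rows used).
#' @param max_distance Optional cap in bp; farther genes are not linked.
#' @return Tibble `cne` (row index), `gene_id`, `distance`, `linked`
#'   (FALSE rows have `NA` gene).
#' @export
link_cne_to_gene <- function(cnes, genes, max_distance = Inf) {
  check_intervals(cnes)
  g <- filter(genes, .data$type == "gene")
  out <- vector("list", nrow(cnes))
  for (i in seq_len(nrow(cnes))) {
    gg <- g[g$chrom == cnes$chrom[i], , drop = FALSE]
    if (nrow(gg) == 0) {
      out[[i]] <- tibble(cne = i, gene_id = NA_character_,
                         distance = NA_real_, linked = FALSE)
      next
    }
    d <- pmax(0, pmax(gg$start - cnes$end[i], cnes$start[i] - gg$end))
    dmin <- min(d)
    if (dmin > max_distance) {
      out[[i]] <- tibble(cne = i, gene_id = NA_character_,
                         distance = NA_real_, linked = FALSE)
    } else {
      hit <- which(d == dmin)
      out[[i]] <- tibble(cne = i, gene_id = gg$gene_id[hit],
                         distance = dmin, linked = TRUE)
    }
  }
  bind_rows(out)
}
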