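# Haplotype-comparison stage: hemizygosity, heterozygous TE insertions,
# insertion context, read-support concordance, and the SV/feature
# mixed-model association against shuffled controls.

#' Hemizygous fraction of the genome
#'
#' Fraction of the genome present on only one haplotype: heterozygous
#' deletions contribute the union of their reference intervals (overlapping
#' records counted once); heterozygous insertions represented as a 1-bp
#' anchor contribute their inserted length (insertions cannot overlap on the
#' reference). Records whose interval width equals their `length` are
#' treated as full intervals and unioned.
#'
#' @param svs SV tibble (see [read_sv_table()]); only het `INS`/`DEL` rows
#'   are used.
#' @param genome_bp Genome size in bp (> 0).
#' @return A single fraction.
#' @export
hemizygous_fraction <- function(svs, genome_bp) {
  if (genome_bp <= 0) abort("genome_bp must be > 0")
  h <- filter(svs, .data$sv_type %in% c("INS", "DEL"), .data$genotype == "het")
  if (nrow(h) == 0) return(0)
  full <- (h$end - h$start) == h$length
  u <- interval_union(h[full, c("chrom", "start", "end")])
  union_bp <- sum(u$end - u$start)
  anchor_bp <- sum(h$length[!full])
  (union_bp + anchor_bp) / genome_bp
}

#' Detect heterozygous TE insertions
#'
#' Matches heterozygous insertion/deletion SVs against the repeat annotation
#' of the haplotype that carries the sequence, requiring that both the indel
#' and the TE annotation overlap by at least `min_reciprocal` of their
#' respective lengths (inclusive). An indel matching several repeat hits
#' keeps the highest-overlap one.
#'
#' @param indel_svs SV tibble restricted (internally) to het `INS`/`DEL`
#'   records with full intervals on the carrier haplotype.
#' @param repeats Repeat tibble on the same haplotype.
#' @param min_reciprocal Inclusive reciprocal-overlap threshold (0.75).
#' @return Tibble of matched pairs: the SV columns plus `te_family`,
#'   `te_class`, `te_divergence_pct`, `frac_sv`, `frac_te`, and the index
#'   columns `sv_row`, `te_row`.
#' @export
detect_het_te_insertions <- function(indel_svs, repeats,
                                     min_reciprocal = 0.75) {
  sv <- mutate(indel_svs, sv_row = row_number()) |>
    filter(.data$sv_type %in% c("INS", "DEL"), .data$genotype == "het")
  if (nrow(sv) == 0) {
    return(mutate(sv, te_family = character(), te_class = character(),
                  te_divergence_pct = numeric(), frac_sv = numeric(),
                  frac_te = numeric(), te_row = integer()))
  }
  mm <- reciprocal_matches(sv, repeats, min_reciprocal)
  mm <- mm |>
    group_by(.data$query) |>
    arrange(desc(.data$overlap_bp), .data$subject, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  out <- sv[mm$query, ]
  out$te_family <- repeats$family[mm$subject]
  out$te_class <- repeats$class[mm$subject]
  out$te_divergence_pct <- repeats$divergence_pct[mm$subject]
  out$frac_sv <- mm$frac_query
  out$frac_te <- mm$frac_subject
  out$te_row <- mm$subject
  out
}

#' Genomic context of insertions
#'
#' Labels each insertion by its midpoint with priority
#' exon > intron > gene flank > intergenic. The flank is `flank_bp` on
#' either side of the gene body (2,500 bp by default).
#'
#' @param insertions Interval tibble.
#' @param genes Gene-model tibble (as from [read_gff3()]): rows of `type`
#'   `"gene"` and `"exon"`.
#' @param flank_bp Gene-flank width in bp.
#' @return List with `labels` (character vector, one per insertion) and
#'   `counts` (tibble `context`, `n`; conserves the number of insertions).
#' @export
insertion_context <- function(insertions, genes, flank_bp = 2500) {
  check_intervals(insertions)
  mid <- floor((insertions$start + insertions$end) / 2)
  pts <- tibble(chrom = insertions$chrom, start = mid, end = mid + 1)
  gene_rows <- filter(genes, .data$type == "gene")
  exon_rows <- filter(genes, .data$type == "exon")
  flanks <- mutate(gene_rows, start = pmax(0, .data$start - flank_bp),
                   end = .data$end + flank_bp)
  in_exon <- feature_fraction(pts, exon_rows) > 0
  in_gene <- feature_fraction(pts, gene_rows) > 0
  in_flank <- feature_fraction(pts, flanks) > 0
  labels <- case_when(
    in_exon ~ "exon",
    in_gene ~ "intron",
    in_flank ~ "flank",
    TRUE ~ "intergenic"
  )
  counts <- tibble(context = factor(labels, levels = c("exon", "intron",
                                                       "flank", "intergenic"))) |>
    count(.data$context, .drop = FALSE, name = "n") |>
    mutate(context = as.character(.data$context))
  list(labels = labels, counts = counts)
}

#' Compare assembly-based and read-based SV callsets
#'
#' Classifies each assembly SV (larger than `min_size`, strict) as
#' `het_supported` (matched by a read-based het call), `hom_alt` (matched by
#' a read-based call genotyped homozygous-alternate — a putative
#' mis-assembly), or `unsupported`. Matching requires the same SV type,
#' breakpoint distance `<= max_dist`, and a length ratio `>= min_len_ratio`;
#' matching is one-to-one, greedy by breakpoint distance.
#'
#' @param assembly_svs,read_svs SV tibbles.
#' @param max_dist Maximum breakpoint distance in bp (default 1,000).
#' @param min_size Strict size filter in bp applied to both callsets (50).
#' @param min_len_ratio Minimum `min(len)/max(len)` (default 0.7).
#' @return List with `classes` (assembly SVs + `support` label + matched
#'   read row) and `summary` (percentages by label).
#' @export
compare_sv_callsets <- function(assembly_svs, read_svs, max_dist = 1000,
                                min_size = 50, min_len_ratio = 0.7) {
  a <- filter(assembly_svs, .data$length > min_size) |>
    mutate(a_row = row_number())
  r <- filter(read_svs, .data$length > min_size) |>
    mutate(r_row = row_number())
  pairs <- inner_join(
    select(a, "a_row", "chrom", "sv_type", a_start = "start", a_end = "end",
           a_len = "length"),
    select(r, "r_row", "chrom", "sv_type", r_start = "start", r_end = "end",
           r_len = "length", "genotype"),
    by = c("chrom", "sv_type"), relationship = "many-to-many") |>
    mutate(dist = pmax(abs(.data$a_start - .data$r_start),
                       abs(.data$a_end - .data$r_end)),
           ratio = pmin(.data$a_len, .data$r_len) /
             pmax(.data$a_len, .data$r_len)) |>
    filter(.data$dist <= max_dist, .data$ratio >= min_len_ratio) |>
    arrange(.data$dist, .data$a_row, .data$r_row)
  used_a <- logical(nrow(a)); used_r <- logical(nrow(r))
  match_of <- rep(NA_integer_, nrow(a))
  for (k in seq_len(nrow(pairs))) {
    ia <- pairs$a_row[k]; ir <- pairs$r_row[k]
    if (!used_a[ia] && !used_r[ir]) {
      used_a[ia] <- TRUE; used_r[ir] <- TRUE
      match_of[ia] <- ir
    }
  }
  support <- case_when(
    is.na(match_of) ~ "unsupported",
    r$genotype[match_of] == "hom_alt" ~ "hom_alt",
    TRUE ~ "het_supported"
  )
  classes <- mutate(a, read_row = match_of, support = support)
  summary <- tibble(support = factor(support, levels = c("het_supported",
                                                         "hom_alt",
                                                         "unsupported"))) |>
    count(.data$support, .drop = FALSE, name = "n") |>
    mutate(support = as.character(.data$support),
           pct = if (nrow(a) > 0) 100 * .data$n / nrow(a) else 0)
  list(classes = classes, summary = summary)
}
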