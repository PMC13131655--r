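# Structural analytics of tandem antifreeze-glycoprotein (afgp) loci:
# functional/pseudogene validation, haplotype comparison with frame logic,
# alternating-orientation arrays and the repeated gene+TE duplication motif.

#' Validate afgp gene models
#'
#' A plain *afgp* gene is functional iff it has the exon-1 signal peptide,
#' an intact exon-2 reading frame (no internal stop or frameshift), and the
#' AARG terminal motif. A chimeric *afgp/tlp* gene is functional iff it has
#' exon-1, an intact frame, the XLF spacer motif, and retains its
#' *tlp*-derived exons. Every failed check contributes a reason code.
#'
#' @param genes Tibble with logical check columns `has_exon1`,
#'   `exon2_intact`, `has_terminal_motif`, `has_spacer_motif`,
#'   `tlp_exons_present`, a logical `is_chimeric`, and a `gene_id`. Flags
#'   can be derived from sequences with [afgp_checks_from_seq()].
#' @return `genes` with `status` (`"functional"`/`"pseudogene"`) and
#'   `reasons` (`;`-separated codes, `""` when functional).
#' @export
validate_gene <- function(genes) {
  if (nrow(genes) == 0) abort("empty gene model table")
  reasons <- purrr::pmap_chr(genes, function(...) {
    g <- list(...)
    r <- character(0)
    if (!isTRUE(g$has_exon1)) r <- c(r, "no signal peptide")
    if (!isTRUE(g$exon2_intact)) r <- c(r, "frameshift or premature stop in exon-2")
    if (isTRUE(g$is_chimeric)) {
      if (!isTRUE(g$has_spacer_motif)) r <- c(r, "missing spacer motif")
      if (!isTRUE(g$tlp_exons_present)) r <- c(r, "tlp exons deleted")
    } else {
      if (!isTRUE(g$has_terminal_motif)) r <- c(r, "missing terminal motif")
    }
    paste(r, collapse = ";")
  })
  mutate(genes, status = if_else(reasons == "", "functional", "pseudogene"),
         reasons = reasons)
}

# minimal standard-code translation, enough for motif checks
codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste0,
                  collapse = "")
  setNames(aa, codons)
}

translate_dna <- function(seq) {
  seq <- toupper(seq)
  n <- floor(nchar(seq) / 3)
  if (n == 0) return("")
  codons <- substring(seq, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  paste(codon_table()[codons], collapse = "")
}

#' Derive afgp check flags from exon sequences
#'
#' Translates exon-2 DNA and tests the reading frame (length divisible by 3,
#' no internal stop), the terminal motif (default `AARG`) at the C-terminus,
#' and the spacer motif (default `XLF`, `X` = any residue) anywhere in the
#' translation.
#'
#' @param exon1_seq Exon-1 DNA (or `NA` when the exon is absent).
#' @param exon2_seq Exon-2 DNA.
#' @param is_chimeric Logical.
#' @param tlp_exons_present Logical (chimeric genes only).
#' @param spacer_motif,terminal_motif Amino-acid motifs; `X` is a wildcard.
#' @return One-row tibble of check flags suitable for [validate_gene()].
#' @export
afgp_checks_from_seq <- function(exon1_seq, exon2_seq, is_chimeric = FALSE,
                                 tlp_exons_present = NA,
                                 spacer_motif = "XLF",
                                 terminal_motif = "AARG") {
  has_exon1 <- !is.na(exon1_seq) && nzchar(exon1_seq)
  frame_ok <- nchar(exon2_seq) %% 3 == 0
  aa <- if (frame_ok) translate_dna(exon2_seq) else ""
  body <- if (nchar(aa) > 1) substr(aa, 1, nchar(aa) - 1) else aa
  no_stop <- frame_ok && !grepl("\\*", body)
  rex <- function(m) gsub("X", ".", m, fixed = TRUE)
  tibble(
    has_exon1 = has_exon1,
    exon2_intact = frame_ok && no_stop,
    has_terminal_motif = grepl(paste0(rex(terminal_motif), "\\*?$"), aa),
    has_spacer_motif = grepl(rex(spacer_motif), aa),
    is_chimeric = is_chimeric,
    tlp_exons_present = tlp_exons_present
  )
}

#' Compare the afgp locus between two haplotypes
#'
#' Matches gene copies positionally: the ordered gene sequences between the
#' flanking anchor genes are split into runs of constant strand, runs are
#' paired in order, and genes within paired runs are matched by position.
#' Matched pairs report the exon-2 length difference and whether it
#' preserves the reading frame (`|delta| mod 3 == 0`); unmatched genes are
#' presence/absence candidates.
#'
#' @param hap1,hap2 Lists with `layout` (token tibble from
#'   [simulate_afgp_locus()] or equivalent: `token_type`, `name`,
#'   `gene_type`, `strand`, coordinates) and `genes` (tibble with
#'   `gene_id`, `exon2_len`).
#' @param anchors Length-2 character vector of flanking anchor gene names
#'   (error when absent from either haplotype).
#' @return List `matched` (tibble with `gene1`, `gene2`, `exon2_len1`,
#'   `exon2_len2`, `delta`, `frame_preserving`, `pseudogenizing`),
#'   `unmatched_hap1`, `unmatched_hap2` (character vectors).
#' @export
compare_haplotype_loci <- function(hap1, hap2, anchors = c("hsl", "tomm40")) {
  seq1 <- locus_gene_sequence(hap1$layout, anchors)
  seq2 <- locus_gene_sequence(hap2$layout, anchors)
  runs1 <- strand_runs(seq1)
  runs2 <- strand_runs(seq2)
  matched <- list(); un1 <- character(0); un2 <- character(0)
  nr <- max(length(runs1), length(runs2))
  for (k in seq_len(nr)) {
    r1 <- if (k <= length(runs1)) runs1[[k]] else NULL
    r2 <- if (k <= length(runs2)) runs2[[k]] else NULL
    if (is.null(r1)) { un2 <- c(un2, r2$name); next }
    if (is.null(r2)) { un1 <- c(un1, r1$name); next }
    m <- min(nrow(r1), nrow(r2))
    if (m > 0) {
      matched[[length(matched) + 1]] <- tibble(gene1 = r1$name[seq_len(m)],
                                               gene2 = r2$name[seq_len(m)])
    }
    if (nrow(r1) > m) un1 <- c(un1, r1$name[(m + 1):nrow(r1)])
    if (nrow(r2) > m) un2 <- c(un2, r2$name[(m + 1):nrow(r2)])
  }
  matched <- bind_rows(matched)
  g1 <- setNames(hap1$genes$exon2_len, hap1$genes$gene_id)
  g2 <- setNames(hap2$genes$exon2_len, hap2$genes$gene_id)
  matched <- matched |>
    mutate(exon2_len1 = unname(g1[.data$gene1]),
           exon2_len2 = unname(g2[.data$gene2]),
           delta = .data$exon2_len1 - .data$exon2_len2,
           frame_preserving = abs(.data$delta) %% 3 == 0,
           pseudogenizing = .data$delta != 0 & !.data$frame_preserving)
  list(matched = matched, unmatched_hap1 = un1, unmatched_hap2 = un2)
}

# ordered gene tokens between the two anchors (anchors excluded)
locus_gene_sequence <- function(layout, anchors) {
  g <- filter(layout, .data$token_type == "gene") |> arrange(.data$start)
  ia <- match(anchors, g$name)
  if (anyNA(ia)) {
    abort(paste0("anchor gene(s) absent: ",
                 paste(anchors[is.na(ia)], collapse = ", ")))
  }
  lo <- min(ia); hi <- max(ia)
  if (hi - lo < 2) return(g[0, ])
  g[(lo + 1):(hi - 1), ]
}

strand_runs <- function(genes) {
  if (nrow(genes) == 0) return(list())
  brk <- cumsum(c(TRUE, genes$strand[-1] == genes$strand[-nrow(genes)]))
  unname(split(genes, brk))
}

#' Detect alternating-orientation gene arrays
#'
#' Finds maximal runs of consecutive gene tokens whose strands strictly
#' alternate, reporting runs of at least `min_run` genes and the number of
#' pairs-of-pairs (`floor(length / 4)`) — the repeated two-gene-pair motif
#' of tandem locus expansion.
#'
#' @param layout Token tibble (`token_type`, `strand`, `start`, `end`,
#'   `chrom`, `name`).
#' @param min_run Minimum run length (default 4).
#' @return Tibble per run: `first_gene`, `last_gene`, `length`,
#'   `pairs_of_pairs`, `chrom`, `start`, `end`.
#' @export
detect_alternating_arrays <- function(layout, min_run = 4) {
  g <- filter(layout, .data$token_type == "gene") |> arrange(.data$start)
  if (nrow(g) == 0) abort("layout has no gene tokens")
  alt <- c(FALSE, g$strand[-1] != g$strand[-nrow(g)])
  run_id <- cumsum(!alt)
  runs <- tibble(i = seq_len(nrow(g)), run = run_id) |>
    group_by(.data$run) |>
    summarise(from = min(.data$i), to = max(.data$i), .groups = "drop") |>
    mutate(length = .data$to - .data$from + 1) |>
    filter(.data$length >= min_run)
  tibble(first_gene = g$name[runs$from], last_gene = g$name[runs$to],
         length = runs$length, pairs_of_pairs = floor(runs$length / 4),
         chrom = g$chrom[runs$from], start = g$start[runs$from],
         end = g$end[runs$to])
}

#' Token sequence of a locus layout
#'
#' Gene tokens carry the gene type and strand (`afgp+`); repeat tokens are
#' the family name.
#'
#' @param layout Token tibble.
#' @return Character vector of tokens, ordered by start.
#' @export
locus_tokens <- function(layout) {
  l <- arrange(layout, .data$start)
  ifelse(l$token_type == "gene", paste0(l$gene_type, l$strand), l$name)
}

#' Detect the tandem duplication motif of a locus
#'
#' Searches the token sequence for the repeated unit `U^k` (`k >= 2`,
#' unit length >= 2 tokens with >= 2 gene tokens) maximizing
#' `copies x unit length`; ties prefer more copies, then the earlier start.
#'
#' @param layout Token tibble (>= 4 tokens).
#' @return List with `found`, and when found `unit` (token vector),
#'   `copies`, `span` (tibble `chrom`, `start`, `end`), `first_token`,
#'   `score`.
#' @export
detect_duplication_motif <- function(layout) {
  l <- arrange(layout, .data$start)
  tok <- locus_tokens(l)
  n <- length(tok)
  if (n < 4) abort("token sequence must have >= 4 tokens")
  is_gene <- l$token_type == "gene"
  best <- list(found = FALSE, score = 0, copies = 0)
  for (L in 2:floor(n / 2)) {
    for (i in 1:(n - 2 * L + 1)) {
      unit <- tok[i:(i + L - 1)]
      if (sum(is_gene[i:(i + L - 1)]) < 2) next
      k <- 1
      while (i + (k + 1) * L - 1 <= n &&
             identical(tok[(i + k * L):(i + (k + 1) * L - 1)], unit)) {
        k <- k + 1
      }
      if (k < 2) next
      score <- k * L
      better <- score > best$score ||
        (score == best$score && k > best$copies) ||
        (score == best$score && k == best$copies && best$found &&
           i < best$first_token)
      if (better) {
        best <- list(found = TRUE, unit = unit, copies = k,
                     first_token = i, score = score,
                     span = tibble(chrom = l$chrom[i], start = l$start[i],
                                   end = l$end[i + k * L - 1]))
      }
    }
  }
  best
}
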