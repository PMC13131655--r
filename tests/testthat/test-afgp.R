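test_that("gene validation encodes every pseudogenization rule with reasons", {
  base <- tibble::tibble(
    gene_id = "g", is_chimeric = FALSE, has_exon1 = TRUE,
    exon2_intact = TRUE, has_terminal_motif = TRUE,
    has_spacer_motif = TRUE, tlp_exons_present = NA)
  expect_equal(validate_gene(base)$status, "functional")
  v <- validate_gene(dplyr::mutate(base, has_exon1 = FALSE))
  expect_equal(v$status, "pseudogene")
  expect_match(v$reasons, "no signal peptide")
  v <- validate_gene(dplyr::mutate(base, has_terminal_motif = FALSE))
  expect_match(v$reasons, "terminal motif")
  v <- validate_gene(dplyr::mutate(base, exon2_intact = FALSE))
  expect_match(v$reasons, "frameshift")
  chim <- dplyr::mutate(base, is_chimeric = TRUE, tlp_exons_present = TRUE)
  expect_equal(validate_gene(chim)$status, "functional")
  v <- validate_gene(dplyr::mutate(chim, tlp_exons_present = FALSE))
  expect_match(v$reasons, "tlp exons")
  v <- validate_gene(dplyr::mutate(chim, has_spacer_motif = FALSE))
  expect_match(v$reasons, "spacer")
  # multiple failures enumerate every failed check
  v <- validate_gene(dplyr::mutate(base, has_exon1 = FALSE,
                                   exon2_intact = FALSE))
  expect_equal(length(strsplit(v$reasons, ";")[[1]]), 2)
  expect_error(validate_gene(base[0, ]), "empty")
})

test_that("sequence-derived checks find frame breaks and motifs", {
  # Thr-Ala-Ala polyprotein ending in AARG, with an SLF spacer
  aa_to_dna <- function(aa) {
    map <- c(T = "ACT", A = "GCT", R = "CGT", G = "GGT", S = "TCT",
             L = "CTT", F = "TTT", K = "AAA")
    paste(map[strsplit(aa, "")[[1]]], collapse = "")
  }
  good <- aa_to_dna("TAATAASLFTAAAARG")
  fl <- afgp_checks_from_seq("ATGAAA", good)
  expect_true(fl$exon2_intact)
  expect_true(fl$has_terminal_motif)
  expect_true(fl$has_spacer_motif)
  # 1-bp deletion shifts the frame
  fs <- afgp_checks_from_seq("ATGAAA", substr(good, 1, nchar(good) - 1))
  expect_false(fs$exon2_intact)
  # premature stop
  st <- afgp_checks_from_seq("ATGAAA", paste0("TAA", good))
  expect_false(st$exon2_intact)
  # stripped terminus
  nt <- afgp_checks_from_seq("ATGAAA", aa_to_dna("TAATAASLFTAAK"))
  expect_false(nt$has_terminal_motif)
  expect_false(afgp_checks_from_seq(NA, good)$has_exon1)
})

test_that("haplotype comparison reports length variants with frame logic", {
  af1 <- simulate_afgp_locus(n_units = 3, seed = 5)
  af2 <- simulate_afgp_locus(n_units = 3, seed = 5)
  # identical loci: all matched, zero variants
  cmp <- compare_haplotype_loci(af1, af2)
  expect_equal(nrow(cmp$matched), nrow(af1$genes))
  expect_true(all(cmp$matched$delta == 0))
  expect_length(cmp$unmatched_hap1, 0)
  # a 1,224-bp exon-2 indel preserves the frame; a 1-bp one does not
  af2$genes$exon2_len[3] <- af2$genes$exon2_len[3] - 1224
  af2$genes$exon2_len[5] <- af2$genes$exon2_len[5] - 1
  cmp <- compare_haplotype_loci(af1, af2)
  m <- cmp$matched
  expect_true(m$frame_preserving[m$gene1 == af1$genes$gene_id[3]])
  expect_false(m$frame_preserving[m$gene1 == af1$genes$gene_id[5]])
  expect_true(m$pseudogenizing[m$gene1 == af1$genes$gene_id[5]])
  expect_error(compare_haplotype_loci(af1, af2, anchors = c("nope", "tomm40")),
               "anchor")
})

test_that("the frame flag follows the mod-3 rule for every delta in 1..3000", {
  af1 <- simulate_afgp_locus(n_units = 750, seed = 6)
  af2 <- simulate_afgp_locus(n_units = 750, seed = 6)
  n <- nrow(af1$genes)
  deltas <- rep_len(1:3000, n)
  af1$genes$exon2_len <- 9000
  af2$genes$exon2_len <- 9000 - deltas
  cmp <- compare_haplotype_loci(af1, af2)
  m <- cmp$matched
  d <- deltas[match(m$gene1, af1$genes$gene_id)]
  expect_equal(m$delta, d)
  expect_equal(m$frame_preserving, d %% 3 == 0)
  expect_equal(sum(!m$frame_preserving), sum(d %% 3 != 0))
})

test_that("alternating arrays match enumeration on all short strand strings", {
  mk_layout <- function(strands) {
    n <- length(strands)
    tibble::tibble(chrom = "c", start = (0:(n - 1)) * 100,
                   end = (0:(n - 1)) * 100 + 50, token_type = "gene",
                   name = paste0("g", 1:n), gene_type = "afgp",
                   strand = strands)
  }
  run <- detect_alternating_arrays(mk_layout(rep(c("+", "-"), 4)))
  expect_equal(run$length, 8)
  expect_equal(run$pairs_of_pairs, 2)
  expect_equal(nrow(detect_alternating_arrays(mk_layout(rep("+", 6)))), 0)
  set.seed(3)
  for (n in 4:10) {
    for (rep in 1:20) {
      s <- sample(c("+", "-"), n, replace = TRUE)
      got <- detect_alternating_arrays(mk_layout(s), min_run = 4)
      exp <- oracle_alternating(s, min_run = 4)
      expect_equal(nrow(got), length(exp))
      if (length(exp)) {
        expect_equal(got$length,
                     vapply(exp, function(r) r[2] - r[1] + 1L, 1L))
      }
    }
  }
})

test_that("the tandem-unit detector is exact for unit lengths 2-6, copies 2-5", {
  mk_tokens <- function(unit_types, unit_strands, k, tail_token = NULL) {
    types <- rep(unit_types, k)
    strands <- rep(unit_strands, k)
    if (!is.null(tail_token)) {
      types <- c(types, tail_token); strands <- c(strands, "+")
    }
    n <- length(types)
    tibble::tibble(chrom = "c", start = (0:(n - 1)) * 100,
                   end = (0:(n - 1)) * 100 + 50,
                   token_type = ifelse(types == "afgp", "gene", "repeat"),
                   name = ifelse(types == "afgp", paste0("g", 1:n), types),
                   gene_type = ifelse(types == "afgp", "afgp", NA),
                   strand = strands)
  }
  for (L in 2:6) {
    unit_types <- c("afgp", "afgp",
                    if (L > 2) paste0("te", seq_len(L - 2)))
    unit_strands <- c("+", "-", rep("+", L - 2))
    expected_unit <- ifelse(unit_types == "afgp",
                            paste0("afgp", unit_strands), unit_types)
    for (k in 2:5) {
      lay <- mk_tokens(unit_types, unit_strands, k)
      got <- detect_duplication_motif(lay)
      expect_true(got$found)
      expect_equal(got$copies, k)
      expect_equal(got$unit, expected_unit)
      # appending one non-matching token leaves the result unchanged
      got2 <- detect_duplication_motif(mk_tokens(unit_types, unit_strands, k,
                                                 tail_token = "teX"))
      expect_equal(got2$copies, k)
      expect_equal(got2$unit, expected_unit)
      # and agrees with the brute-force periodicity oracle
      tok <- locus_tokens(lay)
      orc <- oracle_tandem(tok, lay$token_type == "gene")
      expect_equal(got$copies * length(got$unit), orc$score)
    }
  }
  # no repetition -> empty result
  lay1 <- mk_tokens(c("afgp", "afgp", "te1", "te2"), c("+", "-", "+", "+"), 1)
  expect_false(detect_duplication_motif(lay1)$found)
})
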