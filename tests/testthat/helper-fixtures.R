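# Fixture builders shared across test files; everything is generated in
# code under fixed seeds.

rand_intervals <- function(n, n_chrom = 2, chrom_len = 1e4, max_w = 500,
                           seed = 1) {
  withr::with_seed(seed, {
    w <- sample.int(max_w, n, replace = TRUE)
    s <- vapply(w, function(wi) sample.int(chrom_len - wi, 1), 1L)
    tibble::tibble(chrom = sample(paste0("c", seq_len(n_chrom)), n,
                                  replace = TRUE),
                   start = s, end = s + w)
  })
}

rand_hits <- function(n, n_chrom = 1, chrom_len = 1e3, max_w = 120,
                      seed = 1) {
  x <- rand_intervals(n, n_chrom, chrom_len, max_w, seed)
  withr::with_seed(seed + 1, {
    x$score <- sample.int(20, n, replace = TRUE)  # few levels -> real ties
    x$family <- paste0("fam", seq_len(n))
    x$class <- sample(c("DNA", "LINE", "LTR"), n, replace = TRUE)
    x$divergence_pct <- runif(n, 0, 20)
  })
  x
}

tiny_layout <- function() {
  genome_layout(c(c1 = 1e4, c2 = 1e4),
                gaps = tibble::tibble(chrom = "c1", start = 4000, end = 4500))
}

five_taxon_tree <- function() {
  dated_tree(ape::read.tree(
    text = "((((Focal:3,Sister1:3):4,Sister2:7):4,Temperate:11):36,Outgroup:47);"))
}
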