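test_that("hemizygous fraction is a union, not a sum", {
  expect_equal(hemizygous_fraction(tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    sv_type = character(), length = numeric(), genotype = character()),
    1000), 0)
  one_del <- tibble::tibble(chrom = "c", start = 100, end = 110,
                            sv_type = "DEL", length = 10, genotype = "het")
  expect_equal(hemizygous_fraction(one_del, 1000), 0.01)
  # overlapping deletions count once (vs a bitmap union oracle)
  dels <- rand_intervals(60, n_chrom = 1, chrom_len = 5000, max_w = 300,
                         seed = 7)
  dels <- dplyr::mutate(dels, sv_type = "DEL", length = end - start,
                        genotype = "het")
  bitmap <- rep(FALSE, 5000)
  for (i in seq_len(nrow(dels))) {
    bitmap[seq(dels$start[i] + 1, dels$end[i])] <- TRUE
  }
  expect_equal(hemizygous_fraction(dels, 5000), mean(bitmap))
  # hom_alt and rearrangements are excluded
  dels$genotype <- "hom_alt"
  expect_equal(hemizygous_fraction(dels, 5000), 0)
})

test_that("het-TE detection applies the inclusive 75% rule and best-hit choice", {
  sv <- tibble::tibble(chrom = "c", start = c(100, 1000), end = c(600, 1500),
                       sv_type = "INS", length = 500, genotype = "het",
                       source = "assembly")
  reps <- tibble::tibble(chrom = "c", start = c(100, 1000, 1100),
                         end = c(600, 1300, 1500),
                         family = c("f1", "f2", "f3"), class = "LINE",
                         divergence_pct = 1, score = 10)
  got <- detect_het_te_insertions(sv, reps)
  # exact match accepted; 300/500 = 0.6 and 400/500 = 0.8 -> only f1 matches
  # sv2 vs f2: frac 0.6 -> fails; vs f3: 0.8/1.0 -> passes
  expect_equal(got$te_family, c("f1", "f3"))
  # an SV matching two hits keeps the highest-overlap one
  reps2 <- tibble::tibble(chrom = "c", start = c(100, 110), end = c(600, 610),
                          family = c("big", "shifted"), class = "DNA",
                          divergence_pct = 1, score = 10)
  got <- detect_het_te_insertions(sv[1, ], reps2)
  expect_equal(got$te_family, "big")
})

test_that("noiseless planted TEs are recovered with precision = recall = 1", {
  lay <- simulate_layout(n_chrom = 6, chrom_bp = 2e6, seed = 5)
  d <- simulate_diploid_sv_dataset(lay, 200, 200, 0,
                                   boundary_jitter_frac = 0, seed = 20)
  got <- detect_het_te_insertions(d$svs, d$repeats)
  truth_keys <- with(d$truth$het_te, paste(chrom, start, end))
  got_keys <- with(got, paste(chrom, start, end))
  expect_setequal(got_keys, truth_keys)            # recall = precision = 1
  expect_equal(nrow(got), nrow(d$truth$het_te))
})

test_that("insertion context labels partition with the stated priority", {
  genes <- tibble::tibble(
    chrom = "c", start = c(10000, 10000, 12000), end = c(15000, 11000, 13000),
    strand = "+", type = c("gene", "exon", "exon"),
    id = c("g1", "e1", "e2"), gene_id = "g1")
  ins <- tibble::tibble(chrom = "c",
                        start = c(10500, 11500, 9000, 50000),
                        end = c(10510, 11510, 9010, 50010))
  ctx <- insertion_context(ins, genes, flank_bp = 2500)
  expect_equal(ctx$labels, c("exon", "intron", "flank", "intergenic"))
  expect_equal(sum(ctx$counts$n), nrow(ins))
  # 2,400 bp upstream of the gene -> flank; 10 kb away -> intergenic
  ins2 <- tibble::tibble(chrom = "c", start = c(7600, 25000),
                         end = c(7610, 25010))
  expect_equal(insertion_context(ins2, genes)$labels,
               c("flank", "intergenic"))
})

test_that("read-support classification partitions assembly SVs", {
  a <- tibble::tibble(chrom = "c", start = c(100, 5000, 9000, 100),
                      end = c(400, 5300, 9300, 140),
                      sv_type = "DEL", length = c(300, 300, 300, 40),
                      genotype = "het", source = "assembly")
  r <- tibble::tibble(chrom = "c", start = c(150, 5100), end = c(450, 5400),
                      sv_type = "DEL", length = c(300, 290),
                      genotype = c("het", "hom_alt"), source = "reads")
  cmp <- compare_sv_callsets(a, r, max_dist = 1000)
  # the 40-bp SV is excluded from the denominator ("larger than 50 bp")
  expect_equal(nrow(cmp$classes), 3)
  expect_equal(sort(cmp$classes$support),
               sort(c("het_supported", "hom_alt", "unsupported")))
  expect_equal(sum(cmp$summary$pct), 100)
  # identical callsets -> 100% het supported
  cmp2 <- compare_sv_callsets(a[1:3, ],
                              dplyr::mutate(a[1:3, ], source = "reads"),
                              max_dist = 0)
  expect_true(all(cmp2$classes$support == "het_supported"))
})

test_that("association output satisfies the OR/CI invariants", {
  lay <- simulate_layout(n_chrom = 6, chrom_bp = 2e6, seed = 5)
  d <- simulate_diploid_sv_dataset(lay, 0, 0, 300,
                                   effect_log_odds = c(tandem = 0),
                                   seed = 21)
  sv <- dplyr::filter(d$svs, sv_type %in% c("INV", "DUP", "TRA"))
  fit <- sv_feature_association(sv, lay, d$features, seed = 31)
  td <- tidy(fit)
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$conf_low, exp(td$estimate - 1.96 * td$std_error))
  expect_true(all(td$conf_low <= td$odds_ratio &
                    td$odds_ratio <= td$conf_high))
  expect_equal(glance(fit)$n_cases, 300)
  expect_equal(glance(fit)$n_controls, 300)
  expect_s3_class(autoplot(fit), "ggplot")
  # fixed-effect fallback is flagged
  fit2 <- sv_feature_association(sv, lay, d$features, seed = 31,
                                 method = "glm")
  expect_equal(glance(fit2)$method, "glm")
})
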