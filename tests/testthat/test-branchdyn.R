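test_that("net gain rates reproduce the printed stem-branch arithmetic", {
  # 256 Mb net gain at 16.46 Mb/MY implies a ~15.553-MY branch; feeding the
  # derived duration back must return the printed rate
  dur <- 256 / 16.46
  phy <- ape::read.tree(text = sprintf("(A:%.15g,B:1);", dur))
  tr <- dated_tree(phy)
  mut <- tibble::tibble(branch_id = "A", kind = "insertion", bp = 256e6,
                        chrom = NA_character_, start = NA_real_,
                        end = NA_real_, event_id = "e")
  r <- net_gain_rates(mut, tr)
  expect_equal(r$net_rate_mb_my[r$branch_id == "A"], 16.46, tolerance = 1e-9)
  # ins = del -> zero rate
  mut2 <- dplyr::bind_rows(mut, dplyr::mutate(mut, kind = "deletion"))
  r2 <- net_gain_rates(mut2, tr)
  expect_equal(r2$net_bp[r2$branch_id == "A"], 0)
  expect_error(net_gain_rates(dplyr::mutate(mut, branch_id = "zz"), tr),
               "unknown branch")
})

test_that("per-branch sums equal an independent accumulation oracle", {
  tr <- five_taxon_tree()
  set.seed(52)
  ids <- tr$branches$branch_id
  mut <- tibble::tibble(
    branch_id = sample(ids, 400, replace = TRUE),
    kind = sample(c("insertion", "deletion"), 400, replace = TRUE),
    bp = sample.int(5000, 400, replace = TRUE),
    chrom = NA_character_, start = NA_real_, end = NA_real_,
    event_id = paste0("e", 1:400))
  r <- net_gain_rates(mut, tr)
  for (b in ids) {  # independent route: plain subscript sums
    expect_equal(r$ins_bp[r$branch_id == b],
                 sum(mut$bp[mut$branch_id == b & mut$kind == "insertion"]))
    expect_equal(r$del_bp[r$branch_id == b],
                 sum(mut$bp[mut$branch_id == b & mut$kind == "deletion"]))
  }
  expect_equal(r$net_rate_mb_my, r$net_bp / 1e6 / r$duration)
})

test_that("lifted-insertion merging respects event identity and gaps", {
  mut <- tibble::tibble(
    branch_id = "A", kind = "insertion", bp = c(40, 30, 30, 100),
    chrom = "c1", start = c(0, 90, 200, 400),
    end = c(40, 120, 230, 500),
    event_id = c("ev1", "ev1", "ev1", "ev2"))
  m <- merge_lifted_insertions(mut, max_gap = 100)  # gaps 50 and 80
  expect_equal(nrow(m), 2)
  expect_equal(m$n_fragments[m$event_id == "ev1"], 3)
  expect_equal(m$bp[m$event_id == "ev1"], 230)
  # same coordinates, different events: never merged
  mut2 <- dplyr::mutate(mut, event_id = paste0("x", 1:4))
  expect_equal(nrow(merge_lifted_insertions(mut2, 100)), 4)
})

test_that("TE attribution recovers the planted fraction and composition", {
  merged <- tibble::tibble(
    branch_id = "A", event_id = c("e1", "e2", "e3"), chrom = "c1",
    start = c(0, 1000, 2000), end = c(500, 1500, 2400),
    bp = c(500, 500, 400), n_fragments = 1L)
  reps <- tibble::tibble(chrom = "c1", start = c(0, 1100),
                         end = c(500, 1400),
                         family = c("L2", "hAT"), class = c("LINE", "DNA"),
                         divergence_pct = 1, score = 10)
  tr <- dated_tree(ape::read.tree(text = "(A:2,B:1);"))
  att <- attribute_te_insertions(merged, reps, tr)
  # e1 spans the LINE exactly; e2 overlaps 300/500 = 0.6 -> unattributed
  expect_equal(att$attributed$event_id, "e1")
  expect_equal(att$attributed$te_class, "LINE")
  pb <- att$per_branch
  expect_equal(pb$n_te[pb$branch_id == "A"], 1L)
  expect_equal(pb$te_per_my[pb$branch_id == "A"], 0.5)
  comp <- att$composition
  expect_equal(sum(comp$fraction[comp$branch_id == "A"]), 1)
})

test_that("planted per-branch rates are recovered within 3 Poisson SDs", {
  tr <- five_taxon_tree()
  lay <- simulate_layout(n_chrom = 8, chrom_bp = 4e6, seed = 3)
  n_rep <- 5
  tot <- 0; lambda <- 0
  for (k in seq_len(n_rep)) {
    bm <- simulate_branch_mutations(tr, lay, ins_rate = 2e4, del_rate = 0,
                                    event_bp = 1000, seed = 100 + k)
    r <- net_gain_rates(bm$mutations, tr)
    tot <- tot + sum(r$ins_bp)
    lambda <- lambda + sum(2e4 * tr$branches$duration / 1000)
  }
  expect_lt(abs(tot / 1000 - lambda), 3 * sqrt(lambda))
})

test_that("the rate curve integrates back to the total path count", {
  tr <- five_taxon_tree()
  lay <- simulate_layout(n_chrom = 8, chrom_bp = 4e6, seed = 3)
  bm <- simulate_branch_mutations(tr, lay, seed = 60)
  merged <- merge_lifted_insertions(bm$mutations)
  att <- attribute_te_insertions(merged, bm$repeats, tr)
  cu <- rate_curve(att$per_branch, tr, "Focal")
  path_ids <- cu$branch_id
  expect_equal(path_ids[1], "FocalSister1Sister2Temperate")
  expect_equal(tail(path_ids, 1), "Focal")
  expect_equal(sum(cu$rate * (cu$age_start - cu$age_end)), sum(cu$n_te))
  # hand-extracted path on the 5-taxon tree: ages step monotonically to 0
  expect_equal(cu$age_end[-nrow(cu)], cu$age_start[-1])
  expect_equal(cu$age_end[nrow(cu)], 0)
  expect_error(rate_curve(att$per_branch, tr, "NotALeaf"), "not in tree")
  # smoothing preserves the series and records its window
  cu2 <- rate_curve(att$per_branch, tr, "Focal", smooth_window = 3)
  expect_equal(attr(cu2, "smooth_window"), 3)
  expect_equal(cu2$rate, cu$rate)
})
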