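test_that("reciprocal overlap matches direct arithmetic and the 75% rule", {
  ro <- reciprocal_overlap(tibble::tibble(chrom = "c", start = 0, end = 100),
                           tibble::tibble(chrom = "c", start = 0, end = 100))
  expect_equal(ro$frac_a, 1)
  expect_equal(ro$frac_b, 1)
  ro <- reciprocal_overlap(tibble::tibble(chrom = "c", start = 0, end = 100),
                           tibble::tibble(chrom = "c", start = 50, end = 150))
  expect_equal(ro$frac_a, 0.5)
  expect_equal(ro$frac_b, 0.5)
  expect_false(passes_reciprocal(
    tibble::tibble(chrom = "c", start = 0, end = 100),
    tibble::tibble(chrom = "c", start = 50, end = 150)))
  # threshold is inclusive
  expect_true(passes_reciprocal(
    tibble::tibble(chrom = "c", start = 0, end = 100),
    tibble::tibble(chrom = "c", start = 25, end = 125), 0.75))
  # different chromosome -> zero
  ro <- reciprocal_overlap(tibble::tibble(chrom = "c1", start = 0, end = 10),
                           tibble::tibble(chrom = "c2", start = 0, end = 10))
  expect_equal(ro$overlap_bp, 0)
  expect_error(reciprocal_overlap(
    tibble::tibble(chrom = "c", start = 10, end = 10),
    tibble::tibble(chrom = "c", start = 0, end = 5)), "degenerate")
})

test_that("reciprocal overlap equals the per-base counting oracle", {
  a <- rand_intervals(300, seed = 11)
  b <- rand_intervals(300, seed = 12)
  got <- reciprocal_overlap(a, b)
  for (i in seq_len(50)) {  # spot-check a subset base-by-base
    exp <- oracle_reciprocal(a[i, ], b[i, ])
    expect_equal(c(got$frac_a[i], got$frac_b[i]), exp)
  }
})

test_that("strict-gap merging honours the boundary and the O(n^2) oracle", {
  x <- tibble::tibble(chrom = "c", start = c(0, 109), end = c(10, 120))
  m <- merge_within(x, max_gap = 100)  # gap 99 < 100 -> merge
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 120))
  x <- tibble::tibble(chrom = "c", start = c(0, 110), end = c(10, 120))
  m <- merge_within(x, max_gap = 100)  # gap 100 -> no merge
  expect_equal(nrow(m), 2)
  # group keys block merging
  x <- tibble::tibble(chrom = "c", start = c(0, 20), end = c(10, 30),
                      ev = c("a", "b"))
  expect_equal(nrow(merge_within(x, 100, group_key = "ev")), 2)
  # random instances against the naive pairwise oracle, both gap rules
  for (seed in 1:5) {
    x <- rand_intervals(80, n_chrom = 2, chrom_len = 3000, max_w = 100,
                        seed = seed)
    x$ev <- sample(c("e1", "e2"), nrow(x), replace = TRUE)
    for (gap in c(5, 100)) {
      got <- merge_within(x, gap, group_key = "ev")
      exp <- oracle_merge(x, gap, key = "ev")
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$chrom, exp$chrom)
      # idempotence
      again <- merge_within(got[, c("chrom", "start", "end", "ev")], gap,
                            group_key = "ev")
      expect_equal(again$start, got$start)
      expect_equal(again$end, got$end)
    }
  }
})

test_that("score-based overlap resolution keeps the per-base argmax", {
  h <- tibble::tibble(chrom = "c", start = c(0, 0), end = c(10, 10),
                      score = c(10, 5))
  r <- resolve_overlaps_by_score(h)
  expect_equal(nrow(r), 1)
  expect_equal(r$score, 10)
  # disjoint hits unchanged
  h <- tibble::tibble(chrom = "c", start = c(0, 20), end = c(10, 30),
                      score = c(1, 2))
  r <- resolve_overlaps_by_score(h)
  expect_equal(nrow(r), 2)
  # random overlapping sets against the bitmap oracle
  for (seed in 1:5) {
    h <- rand_hits(40, seed = seed)
    r <- resolve_overlaps_by_score(h)
    # disjoint output
    r2 <- dplyr::arrange(r, chrom, start)
    expect_true(all(r2$start[-1] >= r2$end[-nrow(r2)] |
                      r2$chrom[-1] != r2$chrom[-nrow(r2)]))
    expect_identical(resolved_to_bitmap(r, unique(h$chrom), 1e3),
                     oracle_resolve_bitmap(h, 1e3))
  }
  # invariant to input order up to the tie-break rule
  h <- rand_hits(40, seed = 9)
  perm <- withr::with_seed(1, sample.int(nrow(h)))
  r1 <- resolved_to_bitmap(resolve_overlaps_by_score(h), unique(h$chrom), 1e3)
  r2 <- resolved_to_bitmap(resolve_overlaps_by_score(h[perm, ]),
                           unique(h$chrom), 1e3)
  # map permuted source rows back to original indexing
  r2 <- lapply(r2, function(v) perm[v])
  # ties at equal score and start may legitimately differ; exclude them
  keep <- !(duplicated(h[, c("chrom", "start", "score")]) |
              duplicated(h[, c("chrom", "start", "score")], fromLast = TRUE))
  comparable <- function(v) ifelse(!is.na(v) & keep[v], v, NA)
  expect_identical(lapply(r1, comparable), lapply(r2, comparable))
})

test_that("feature fraction equals the bitmap union oracle and clips windows", {
  w <- tibble::tibble(chrom = "c1", start = 100, end = 200)
  ann <- tibble::tibble(chrom = "c1", start = c(0, 50), end = c(300, 400))
  expect_equal(feature_fraction(w, ann), 1)
  expect_equal(feature_fraction(w, ann[0, ]), 0)
  for (seed in 6:10) {
    wins <- rand_intervals(50, seed = seed)
    ann <- rand_intervals(60, seed = seed + 100)
    got <- feature_fraction(wins, ann)
    exp <- vapply(seq_len(nrow(wins)),
                  function(i) oracle_fraction(wins[i, ], ann), 1)
    expect_equal(got, exp)
  }
  # clipping at chromosome bounds uses the clipped denominator
  lay <- tiny_layout()
  w <- tibble::tibble(chrom = "c1", start = 9900, end = 10100)
  ann <- tibble::tibble(chrom = "c1", start = 9900, end = 10000)
  expect_equal(feature_fraction(w, ann, lay), 1)
  expect_error(
    feature_fraction(tibble::tibble(chrom = "c1", start = 10500, end = 10600),
                     ann, lay), "outside")
})

test_that("nearest distances match the exhaustive scan", {
  lay <- tiny_layout()
  x <- tibble::tibble(chrom = "c1", start = 10, end = 20)
  expect_equal(distance_to_chrom_end(x, lay), 10)
  expect_equal(
    distance_to_nearest(tibble::tibble(chrom = "c1", start = 4100, end = 4200),
                        lay$gaps), 0)
  expect_true(is.na(
    distance_to_nearest(tibble::tibble(chrom = "c2", start = 0, end = 10),
                        lay$gaps)))
  x <- rand_intervals(100, seed = 21)
  targets <- rand_intervals(30, seed = 22)
  got <- distance_to_nearest(x, targets)
  exp <- vapply(seq_len(nrow(x)),
                function(i) oracle_distance(x[i, ], targets), 1)
  expect_equal(got, exp)
})

test_that("shuffling preserves lengths, determinism, and gap exclusion", {
  lay <- tiny_layout()
  x <- rand_intervals(200, n_chrom = 2, chrom_len = 9000, max_w = 200,
                      seed = 31)
  s1 <- shuffle_intervals(x, lay, seed = 5)
  s2 <- shuffle_intervals(x, lay, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sort(s1$end - s1$start), sort(as.numeric(x$end - x$start)))
  # never intersects a gap
  hit <- reciprocal_matches(s1, lay$gaps, min_reciprocal = 0)
  ov <- pmax(0, pmin(s1$end, 4500) - pmax(s1$start, 4000))
  expect_true(all(ov[s1$chrom == "c1"] == 0))
  expect_error(
    shuffle_intervals(tibble::tibble(chrom = "c1", start = 0, end = 2e4),
                      lay, seed = 1), "does not fit")
})

test_that("1-bp shuffle placements are proportional to permitted length", {
  lay <- genome_layout(c(c1 = 6000, c2 = 2000))
  x <- tibble::tibble(chrom = rep("c1", 2000), start = 0, end = 1)
  s <- shuffle_intervals(x, lay, seed = 77)
  p1 <- 6000 / 8000
  n1 <- sum(s$chrom == "c1")
  sd3 <- 3 * sqrt(2000 * p1 * (1 - p1))
  expect_lt(abs(n1 - 2000 * p1), sd3)
})
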