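# Synthetic-data generators. Every generator is a deterministic function of
# (parameters, seed); each draws from its own child seed so adding one
# generator never perturbs another. The planted truth returned alongside the
# data is sufficient to regenerate and to score every downstream stage.

#' Default synthetic genome layout
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Length of each chromosome (bp).
#' @param n_gaps_per_chrom Assembly gaps planted per chromosome.
#' @param gap_bp Gap length.
#' @param seed Seed for gap placement.
#' @return A [genome_layout()].
#' @export
simulate_layout <- function(n_chrom = 20, chrom_bp = 5e6,
                            n_gaps_per_chrom = 2, gap_bp = 5000, seed = 1) {
  chroms <- tibble(chrom = sprintf("chr%02d", seq_len(n_chrom)),
                   length = chrom_bp)
  gaps <- local_seed(child_seed(seed, 1), {
    purrr::map(chroms$chrom, function(ch) {
      s <- sort(sample.int(chrom_bp - gap_bp, n_gaps_per_chrom))
      tibble(chrom = ch, start = s, end = s + gap_bp)
    }) |> bind_rows()
  })
  genome_layout(chroms, gaps)
}

# clustered background features: mixture of uniform placement and placement
# around per-chromosome hotspots, so 50-kb densities vary across the genome
place_clustered <- function(layout, n, len_range, hotspots_per_chrom = 4,
                            hotspot_sd = 3e5, p_hotspot = 0.7) {
  ch <- layout$chromosomes
  rows <- purrr::map(seq_len(nrow(ch)), function(i) {
    L <- ch$length[i]
    ni <- round(n / nrow(ch))
    centers <- runif(hotspots_per_chrom, 0, L)
    use_hot <- runif(ni) < p_hotspot
    pos <- ifelse(use_hot,
                  rnorm(ni, sample(centers, ni, replace = TRUE), hotspot_sd),
                  runif(ni, 0, L))
    w <- round(runif(ni, len_range[1], len_range[2]))
    s <- pmin(pmax(0, round(pos)), L - w - 1)
    tibble(chrom = ch$chrom[i], start = s, end = s + w)
  })
  bind_rows(rows)
}

#' Simulate a diploid SV dataset with planted heterozygous TE insertions
#'
#' Emulates the inputs of the haplotype-comparison stage on one reference
#' genome: a background annotation (TEs including LINEs, tandem repeats,
#' genes), `n_te_insertions` heterozygous indels each matched by a repeat
#' hit with reciprocal overlap exactly `1 - boundary_jitter_frac` (the
#' planted copy is shifted, not resized), `n_other_svs` heterozygous indels
#' guaranteed not to reciprocally match any repeat at 0.75, and
#' `n_rearrangements` rearrangement SVs (INV/DUP/TRA) whose midpoints are
#' exponentially tilted by planted per-feature log-odds on flank densities
#' standardized against the genomic background. Heterozygous indels are
#' reported as full intervals on the haplotype carrying the sequence, so
#' one repeat table serves the matching.
#'
#' @param layout A [genome_layout()] with >= 2 chromosomes.
#' @param n_te_insertions,n_other_svs,n_rearrangements Counts.
#' @param effect_log_odds Named numeric log-odds per background-SD of flank
#'   density, names among `te`, `tandem`, `line`, `gene`.
#' @param boundary_jitter_frac Fraction of the element length by which the
#'   planted indel is shifted against its repeat hit (0 = exact).
#' @param flank_bp Flank half-window used both here and by the association
#'   stage (identifiability of the planted log-odds).
#' @param te_len_range Planted TE length range (bp).
#' @param seed Mandatory seed.
#' @return List: `svs`, `repeats`, `genes`, `features` (named list of
#'   interval tibbles for the association stage), `truth`.
#' @export
simulate_diploid_sv_dataset <- function(layout, n_te_insertions = 500,
                                        n_other_svs = 500,
                                        n_rearrangements = 0,
                                        effect_log_odds = c(tandem = 0),
                                        boundary_jitter_frac = 0,
                                        flank_bp = 50000,
                                        te_len_range = c(500, 5000),
                                        seed) {
  if (nrow(layout$chromosomes) < 2) abort("layout needs >= 2 chromosomes")
  if (boundary_jitter_frac < 0 || boundary_jitter_frac >= 0.25) {
    abort("boundary_jitter_frac must be in [0, 0.25)")
  }
  genome_bp <- genome_size(layout)
  local_seed(child_seed(seed, 2), {
    # --- background annotation ------------------------------------------
    n_bg_te <- max(200, round(genome_bp / 5e4))
    bg_te <- place_clustered(layout, n_bg_te, c(500, 3000))
    bg_te$family <- sample(paste0("TE_fam", 1:20), nrow(bg_te), replace = TRUE)
    bg_te$class <- sample(c("DNA", "LINE", "LTR"), nrow(bg_te),
                          replace = TRUE, prob = c(0.4, 0.35, 0.25))
    bg_te$divergence_pct <- pmax(0, rnorm(nrow(bg_te), 10, 3))
    bg_te$score <- round(runif(nrow(bg_te), 100, 5000))
    tandem <- place_clustered(layout, round(genome_bp / 2e5), c(200, 2000),
                              hotspot_sd = 1.5e5, p_hotspot = 0.85)
    genes <- place_clustered(layout, round(genome_bp / 1e5), c(5000, 20000),
                             p_hotspot = 0.3)
    genes <- mutate(genes, strand = sample(c("+", "-"), dplyr::n(),
                                           replace = TRUE),
                    type = "gene", id = paste0("g", row_number()),
                    gene_id = .data$id)
    exons <- purrr::map(seq_len(nrow(genes)), function(i) {
      gl <- genes$end[i] - genes$start[i]
      e1 <- genes$start[i] + c(0, round(gl * 0.45))
      tibble(chrom = genes$chrom[i], start = e1,
             end = e1 + round(gl * 0.15), strand = genes$strand[i],
             type = "exon", id = paste0(genes$id[i], ".e", 1:2),
             gene_id = genes$id[i])
    }) |> bind_rows()
    gene_models <- bind_rows(genes, exons) |> arrange(.data$chrom, .data$start)

    # --- planted heterozygous TE insertions -----------------------------
    te_len <- round(runif(n_te_insertions, te_len_range[1], te_len_range[2]))
    te_iv <- shuffle_intervals(
      tibble(chrom = layout$chromosomes$chrom[1],
             start = 0, end = te_len),
      layout, seed = child_seed(seed, 3))
    shift <- round(boundary_jitter_frac * te_len) *
      sample(c(-1L, 1L), n_te_insertions, replace = TRUE)
    sv_te <- tibble(chrom = te_iv$chrom,
                    start = pmax(0, te_iv$start + shift),
                    end = pmax(0, te_iv$start + shift) + te_len,
                    sv_type = sample(c("INS", "DEL"), n_te_insertions,
                                     replace = TRUE),
                    length = te_len, genotype = "het", source = "assembly")
    te_hits <- tibble(chrom = te_iv$chrom, start = te_iv$start,
                      end = te_iv$end,
                      family = sample(paste0("TE_fam", 1:20), n_te_insertions,
                                      replace = TRUE),
                      class = sample(c("DNA", "LINE", "LTR"), n_te_insertions,
                                     replace = TRUE,
                                     prob = c(0.3, 0.45, 0.25)),
                      divergence_pct = pmax(0, rnorm(n_te_insertions, 1, 0.5)),
                      score = round(runif(n_te_insertions, 1000, 8000)))
    repeats <- bind_rows(te_hits, bg_te)

    # --- non-TE indels: never a reciprocal 0.75 match -------------------
    other <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
    need <- n_other_svs
    attempt <- 0
    while (need > 0 && attempt < 50) {
      len <- round(runif(need, 50, 2000))
      cand <- shuffle_intervals(tibble(chrom = layout$chromosomes$chrom[1],
                                       start = 0, end = len), layout,
                                seed = child_seed(seed, 100 + attempt))
      hit <- reciprocal_matches(cand, repeats, 0.7)  # margin below 0.75
      ok <- setdiff(seq_len(nrow(cand)), unique(hit$query))
      other <- bind_rows(other, cand[ok, ])
      need <- n_other_svs - nrow(other)
      attempt <- attempt + 1
    }
    other <- head(other, n_other_svs)
    sv_other <- mutate(other, sv_type = sample(c("INS", "DEL"), dplyr::n(),
                                               replace = TRUE),
                       length = .data$end - .data$start, genotype = "het",
                       source = "assembly")

    # --- rearrangements placed by exponential tilting -------------------
    features <- list(te = repeats[, c("chrom", "start", "end")],
                     tandem = tandem,
                     line = repeats[repeats$class == "LINE",
                                    c("chrom", "start", "end")],
                     gene = genes[, c("chrom", "start", "end")])
    sv_re <- NULL
    if (n_rearrangements > 0) {
      pool_n <- max(5L * n_rearrangements, 5000L)
      len <- round(exp(runif(pool_n, log(100), log(20000))))
      pool <- shuffle_intervals(tibble(chrom = layout$chromosomes$chrom[1],
                                       start = 0, end = len), layout,
                                seed = child_seed(seed, 4))
      Z <- assoc_predictors(pool, layout, features, flank_bp)
      eta <- rep(0, pool_n)
      for (nm in names(effect_log_odds)) {
        col <- paste0("frac_", nm)
        if (!col %in% names(Z)) abort(paste0("unknown effect feature: ", nm))
        z <- (Z[[col]] - mean(Z[[col]])) / sd(Z[[col]])
        eta <- eta + effect_log_odds[[nm]] * z
      }
      w <- exp(eta - max(eta))
      pick <- sample.int(pool_n, n_rearrangements, replace = TRUE, prob = w)
      sv_re <- pool[pick, ] |>
        mutate(sv_type = sample(c("INV", "DUP", "TRA"), n_rearrangements,
                                replace = TRUE),
               length = .data$end - .data$start, genotype = "het",
               source = "assembly")
    }

    svs <- bind_rows(sv_te, sv_other, sv_re)
    truth <- list(
      het_te = mutate(sv_te, te_row = seq_len(n_te_insertions)),
      te_hits = te_hits,
      other_indels = sv_other,
      rearrangements = sv_re,
      effect_log_odds = effect_log_odds,
      boundary_jitter_frac = boundary_jitter_frac,
      flank_bp = flank_bp, seed = seed
    )
    list(svs = svs, repeats = repeats, genes = gene_models,
         features = features, truth = truth)
  })
}

#' Simulate per-branch insertion/deletion tables on a dated tree
#'
#' Plants insertion events per branch at an expected `ins_rate x duration`
#' bp (Poisson event counts, fixed event length), fragments each event into
#' up to 3 pieces separated by gaps < 100 bp sharing one ancestral event
#' id, and gives a `te_fraction` of events an exactly spanning repeat hit.
#' Deletion bp is planted analogously without coordinates. Events occupy
#' disjoint genomic slots so no cross-event overlap can confuse matching.
#'
#' @param tree A [dated_tree()].
#' @param layout Reference-genome [genome_layout()] for lifted coordinates.
#' @param ins_rate,del_rate Rates in bp/MY (scalar or named per branch).
#' @param te_fraction Fraction of insertion events that are TE-derived.
#' @param event_bp Planted event length (bp).
#' @param seed Mandatory seed.
#' @return List: `mutations` (branch-mutation tibble), `repeats`, `truth`
#'   (per-branch planted totals).
#' @export
simulate_branch_mutations <- function(tree, layout, ins_rate = 2e4,
                                      del_rate = 5e3, te_fraction = 0.5,
                                      event_bp = 1000, seed) {
  br <- tree$branches
  rate_of <- function(r, id) {
    if (is.null(names(r))) rep(r, length(id)) else unname(r[id])
  }
  ins_r <- rate_of(ins_rate, br$branch_id)
  del_r <- rate_of(del_rate, br$branch_id)
  local_seed(child_seed(seed, 5), {
    n_ins <- rpois(nrow(br), ins_r * br$duration / event_bp)
    n_del <- rpois(nrow(br), del_r * br$duration / event_bp)
    total_events <- sum(n_ins)
    # disjoint slots over the gap-free genome
    slot_w <- event_bp + 300
    spans <- permitted_spans(layout)
    spans <- mutate(spans, n_slots = floor((.data$end - .data$start) / slot_w))
    slot_tbl <- purrr::map(seq_len(nrow(spans)), function(i) {
      if (spans$n_slots[i] == 0) return(NULL)
      tibble(chrom = spans$chrom[i],
             slot_start = spans$start[i] + slot_w * (seq_len(spans$n_slots[i]) - 1))
    }) |> bind_rows()
    if (total_events > nrow(slot_tbl)) {
      abort("genome too small for the requested event density")
    }
    slots <- slot_tbl[sample.int(nrow(slot_tbl), total_events), ]
    rows <- list(); reps <- list(); truth_rows <- list()
    ev <- 0
    for (b in seq_len(nrow(br))) {
      bid <- br$branch_id[b]
      te_n <- round(te_fraction * n_ins[b])
      for (j in seq_len(n_ins[b])) {
        ev <- ev + 1
        eid <- paste0("ev", ev)
        k <- sample(1:3, 1)
        cuts <- if (k > 1) sort(sample(seq_len(event_bp - 1), k - 1)) else integer(0)
        piece <- diff(c(0, cuts, event_bp))
        gaps <- if (k > 1) sample(10:90, k - 1, replace = TRUE) else integer(0)
        s0 <- slots$slot_start[ev]
        starts <- s0 + cumsum(c(0, head(piece, -1) + gaps))
        frag <- tibble(branch_id = bid, kind = "insertion", bp = piece,
                       chrom = slots$chrom[ev], start = starts,
                       end = starts + piece, event_id = eid)
        rows[[length(rows) + 1]] <- frag
        if (j <= te_n) {
          reps[[length(reps) + 1]] <- tibble(
            chrom = slots$chrom[ev], start = s0,
            end = max(frag$end),
            family = sample(paste0("TE_fam", 1:10), 1),
            class = sample(c("DNA", "LINE", "LTR"), 1),
            divergence_pct = pmax(0, rnorm(1, 5, 2)),
            score = round(runif(1, 500, 5000)))
        }
      }
      if (n_del[b] > 0) {
        rows[[length(rows) + 1]] <- tibble(
          branch_id = bid, kind = "deletion",
          bp = rep(event_bp, n_del[b]), chrom = NA_character_,
          start = NA_real_, end = NA_real_,
          event_id = paste0("del", b, "_", seq_len(n_del[b])))
      }
      truth_rows[[b]] <- tibble(branch_id = bid, n_ins_events = n_ins[b],
                                ins_bp = n_ins[b] * event_bp,
                                del_bp = n_del[b] * event_bp,
                                n_te = te_n,
                                duration = br$duration[b])
    }
    list(mutations = bind_rows(rows), repeats = bind_rows(reps),
         truth = bind_rows(truth_rows) |>
           mutate(planted_ins_rate = ins_r, planted_del_rate = del_r,
                  te_fraction = te_fraction, event_bp = event_bp,
                  seed = seed))
  })
}

#' Simulate per-species alignment-depth tracks for conserved elements
#'
#' Builds presence/absence tracks so that planted `ancestral` elements are
#' covered at least `min_cov` (inclusive) by every species, `clade_specific`
#' elements only by the focal clade, and `other` elements fall below the
#' threshold for at least one clade member. `margin = 0` places covered
#' fractions exactly at the boundary.
#'
#' @param ces Interval tibble of conserved elements.
#' @param ancestry Character vector of planted labels
#'   (`ancestral`/`clade_specific`/`other`), one per element.
#' @param all_species,focal_clade Species sets.
#' @param min_cov Threshold the tracks are built against (0.75).
#' @param margin Distance from the boundary (0 exercises it exactly).
#' @param seed Mandatory seed.
#' @return Depth-track tibble (`species`, `chrom`, `start`, `end`).
#' @export
simulate_depth_tracks <- function(ces, ancestry, all_species, focal_clade,
                                  min_cov = 0.75, margin = 0.05, seed) {
  check_intervals(ces)
  if (length(ancestry) != nrow(ces)) abort("one ancestry label per element")
  outgroup <- setdiff(all_species, focal_clade)
  local_seed(child_seed(seed, 6), {
    rows <- list()
    for (i in seq_len(nrow(ces))) {
      w <- ces$end[i] - ces$start[i]
      low_sp <- switch(ancestry[i],
        ancestral = character(0),
        clade_specific = outgroup,
        other = c(sample(focal_clade, 1),
                  sample(outgroup, rbinom(1, length(outgroup), 0.5))),
        abort(paste0("unknown ancestry label: ", ancestry[i])))
      for (sp in all_species) {
        if (sp %in% low_sp) {
          f <- runif(1, 0, max(0, min_cov - margin - 0.01))
          cov_len <- floor(f * w)
        } else {
          f <- min(1, min_cov + margin + runif(1, 0, 1 - min_cov - margin))
          cov_len <- min(w, ceiling(f * w))
        }
        if (cov_len < 1) next
        off <- sample.int(w - cov_len + 1, 1) - 1
        rows[[length(rows) + 1]] <- tibble(
          species = sp, chrom = ces$chrom[i],
          start = ces$start[i] + off, end = ces$start[i] + off + cov_len)
      }
    }
    bind_rows(rows)
  })
}

#' Simulate a repeat table with planted activity peaks
#'
#' Ages are drawn from a mixture of normal components (MY, truncated at 0)
#' and converted to divergences by inverting the dating formula:
#' `K = age x divisor x 100`.
#'
#' @param n Number of repeat copies.
#' @param age_components Tibble `mean_my`, `sd_my`, `weight`.
#' @param cfg A [neutral_rate_config()] (rate and divisor convention).
#' @param len_range Copy length range (bp).
#' @param seed Mandatory seed.
#' @return List: `repeats` tibble, `truth` (components + drawn ages).
#' @export
simulate_repeat_divergences <- function(n,
                                        age_components = tibble(
                                          mean_my = c(2, 9),
                                          sd_my = c(0.5, 0.8),
                                          weight = c(0.5, 0.5)),
                                        cfg = neutral_rate_config(),
                                        len_range = c(200, 4000), seed) {
  local_seed(child_seed(seed, 7), {
    comp <- sample.int(nrow(age_components), n, replace = TRUE,
                       prob = age_components$weight)
    age <- pmax(0, rnorm(n, age_components$mean_my[comp],
                         age_components$sd_my[comp]))
    len <- round(runif(n, len_range[1], len_range[2]))
    start <- cumsum(c(0, head(len, -1) + 100))
    repeats <- tibble(
      chrom = "chrSim", start = start, end = start + len,
      family = paste0("fam", comp),
      class = sample(c("DNA", "LINE", "LTR"), n, replace = TRUE),
      divergence_pct = age * cfg$divisor * 100,
      score = round(runif(n, 100, 5000)))
    list(repeats = repeats,
         truth = list(age_components = age_components, ages = age,
                      component = comp, cfg = cfg, seed = seed))
  })
}

#' Simulate a tandem antifreeze-locus layout
#'
#' Builds a token-level locus: an `hsl` anchor, `n_units` copies of the
#' duplication unit (two pairs of *afgp* genes with alternating orientation
#' `+ - + -` followed by the TE motif), two chimeric *afgp/tlp* genes, and a
#' `tomm40` anchor. Pseudogenization events are applied to chosen genes:
#' `drop_exon1`, `frameshift` (1-bp indel in exon-2), `strip_terminal`
#' (loses the AARG terminus), `delete_tlp` (chimeric gene loses its
#' *tlp*-derived exons).
#'
#' @param n_units Number of tandem duplication units (>= 1).
#' @param te_motif Character vector of repeat-family tokens in each unit.
#' @param pseudogene_events Tibble `gene` (gene id), `event` (one of the
#'   four codes), or `NULL`.
#' @param exon2_len Base exon-2 length (divisible by 3).
#' @param seed Mandatory seed (exon-2 length variation across copies).
#' @return List: `layout` (token tibble), `genes` (flag tibble for
#'   [validate_gene()]), `truth`.
#' @export
simulate_afgp_locus <- function(n_units = 3, te_motif = c("L2_IV", "DNA_hAT"),
                                pseudogene_events = NULL, exon2_len = 1500,
                                seed) {
  if (n_units < 1) abort("n_units must be >= 1")
  local_seed(child_seed(seed, 8), {
    gene_len <- 2000; te_len <- 600; spacer <- 150
    tokens <- list()
    pos <- 0
    add <- function(tokens, type, name, gene_type, strand, w, pos) {
      tokens[[length(tokens) + 1]] <- tibble(
        chrom = "chr16", start = pos, end = pos + w, token_type = type,
        name = name, gene_type = gene_type, strand = strand)
      tokens
    }
    tokens <- add(tokens, "gene", "hsl", "anchor", "+", gene_len, pos)
    pos <- gene_len + spacer
    gi <- 0
    strands <- c("+", "-", "+", "-")
    for (u in seq_len(n_units)) {
      for (s in strands) {
        gi <- gi + 1
        tokens <- add(tokens, "gene", paste0("afgp", gi), "afgp", s,
                      gene_len, pos)
        pos <- pos + gene_len + spacer
      }
      for (fam in te_motif) {
        tokens <- add(tokens, "repeat", fam, NA_character_, "+", te_len, pos)
        pos <- pos + te_len + spacer
      }
    }
    for (k in 1:2) {
      tokens <- add(tokens, "gene", paste0("afgp_tlp", k), "afgp_tlp",
                    c("+", "-")[k], gene_len * 2, pos)
      pos <- pos + gene_len * 2 + spacer
    }
    tokens <- add(tokens, "gene", "tomm40", "anchor", "-", gene_len, pos)
    layout <- bind_rows(tokens)
    gene_ids <- layout$name[layout$token_type == "gene" &
                              layout$gene_type != "anchor"]
    chimeric <- startsWith(gene_ids, "afgp_tlp")
    genes <- tibble(
      gene_id = gene_ids,
      is_chimeric = chimeric,
      has_exon1 = TRUE, exon2_intact = TRUE, has_terminal_motif = TRUE,
      has_spacer_motif = TRUE,
      tlp_exons_present = ifelse(chimeric, TRUE, NA),
      exon2_len = exon2_len + 3 * sample(0:100, length(gene_ids),
                                         replace = TRUE))
    if (!is.null(pseudogene_events)) {
      for (k in seq_len(nrow(pseudogene_events))) {
        g <- pseudogene_events$gene[k]
        i <- match(g, genes$gene_id)
        if (is.na(i)) abort(paste0("unknown gene in pseudogene_events: ", g))
        switch(pseudogene_events$event[k],
          drop_exon1 = { genes$has_exon1[i] <- FALSE },
          frameshift = { genes$exon2_intact[i] <- FALSE
                         genes$exon2_len[i] <- genes$exon2_len[i] - 1 },
          strip_terminal = { genes$has_terminal_motif[i] <- FALSE },
          delete_tlp = { genes$tlp_exons_present[i] <- FALSE },
          abort(paste0("unknown pseudogene event: ",
                       pseudogene_events$event[k])))
      }
    }
    list(layout = layout, genes = genes,
         truth = list(n_units = n_units, te_motif = te_motif,
                      pseudogene_events = pseudogene_events, seed = seed))
  })
}

#' Simulate gene trees with and without planted clade monophyly
#'
#' Each tree is monophyletic-with-sister with probability `p_monophyletic`:
#' `((clade), (sister, (outgroup)))`. Otherwise one clade member is swapped
#' with one outgroup member, breaking clade monophyly.
#'
#' @param n Number of trees.
#' @param clade_taxa,sister_taxon,outgroup_taxa Taxon names.
#' @param p_monophyletic Probability of a planted-monophyletic tree.
#' @param seed Mandatory seed.
#' @return List: `trees` (list of `phylo`), `truth` (tibble `gene`,
#'   `monophyletic`).
#' @export
simulate_gene_trees <- function(n, clade_taxa, sister_taxon, outgroup_taxa,
                                p_monophyletic = 0.5, seed) {
  if (length(clade_taxa) < 2 || length(outgroup_taxa) < 2) {
    abort("need >= 2 clade taxa and >= 2 outgroup taxa")
  }
  nest <- function(x) Reduce(function(a, b) paste0("(", a, ",", b, ")"), x)
  local_seed(child_seed(seed, 9), {
    mono <- runif(n) < p_monophyletic
    trees <- purrr::map(seq_len(n), function(i) {
      cl <- sample(clade_taxa)
      og <- sample(outgroup_taxa)
      if (!mono[i]) {  # swap one clade member with one outgroup member
        j <- sample(seq_along(cl), 1); k <- sample(seq_along(og), 1)
        tmp <- cl[j]; cl[j] <- og[k]; og[k] <- tmp
      }
      txt <- paste0("(", nest(cl), ",(", sister_taxon, ",", nest(og), "));")
      ape::read.tree(text = txt)
    })
    names(trees) <- paste0("gene", seq_len(n))
    list(trees = trees,
         truth = tibble(gene = names(trees), monophyletic = mono))
  })
}
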