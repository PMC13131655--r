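# End-to-end orchestration on a synthetic scenario: simulate every input,
# run each analysis stage in dependency order, and write diffable TSV
# artifacts plus a run manifest keyed by the configuration hash.

#' Default pipeline configuration
#'
#' All thresholds default to the study's values: reciprocal overlap 0.75,
#' merge gaps 100 bp (lifted insertions) and 5 bp (conserved elements),
#' coverage threshold 0.75, 50-kb association flanks, 2,500-bp context
#' flanks, 50-bp minimum SV size, neutral rate 3.2e-3/site/MY.
#'
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory.
#' @param ... Overrides for any config entry.
#' @return A named list (class `noto_config`).
#' @export
default_config <- function(seed, out_dir, ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    min_reciprocal = 0.75,
    merge_gap_insertions = 100,
    merge_gap_ces = 5,
    min_cov = 0.75,
    flank_bp = 50000,
    context_flank_bp = 2500,
    min_sv_size = 50,
    neutral_rate = 3.2e-3,
    divisor_mode = "2r",
    landscape_bin_my = 1,
    # synthetic scenario sizes (kept small for a fast smoke run)
    n_chrom = 4, chrom_bp = 2e6,
    n_te_insertions = 120, n_other_svs = 120, n_rearrangements = 150,
    n_ces = 60, n_gene_trees = 30, afgp_units = 3
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "noto_config")
}

# canonical text representation so the hash survives a JSON round-trip
config_hash <- function(cfg) {
  cfg <- cfg[sort(setdiff(names(cfg), "out_dir"))]
  vals <- vapply(cfg, function(v) {
    paste(format(v, digits = 15, scientific = FALSE), collapse = ",")
  }, "")
  rlang::hash(paste(names(cfg), vals, sep = "=", collapse = ";"))
}

#' Run the full synthetic pipeline
#'
#' Simulates a scenario from the config seed, then runs haplotype
#' variation, repeat landscape, branch dynamics, conserved elements, the
#' gene-tree filter and the afgp analytics, writing one TSV per stage plus
#' `config.json` and `manifest.json` (with the config hash). Re-running
#' with an identical config reproduces identical stage outputs.
#'
#' @param config A [default_config()] list.
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  layout <- stage("simulate", simulate_layout(
    n_chrom = cfg$n_chrom, chrom_bp = cfg$chrom_bp, seed = seed))
  dip <- stage("simulate", simulate_diploid_sv_dataset(
    layout, n_te_insertions = cfg$n_te_insertions,
    n_other_svs = cfg$n_other_svs, n_rearrangements = cfg$n_rearrangements,
    flank_bp = cfg$flank_bp, seed = seed))
  write_sv_table(dip$svs, file.path(cfg$out_dir, "svs.tsv"))
  write_repeat_table(dip$repeats, file.path(cfg$out_dir, "repeats.tsv"))
  write_gff3(dip$genes, file.path(cfg$out_dir, "genes.gff3"))

  hap <- stage("hapvar", {
    het <- detect_het_te_insertions(dip$svs, dip$repeats,
                                    cfg$min_reciprocal)
    ctx <- insertion_context(het, dip$genes, cfg$context_flank_bp)
    assoc <- sv_feature_association(
      filter(dip$svs, .data$sv_type %in% c("INV", "DUP", "TRA")),
      layout, dip$features, flank_bp = cfg$flank_bp,
      seed = child_seed(seed, 11))
    shift <- divergence_shift_test(
      het$te_divergence_pct,
      dip$repeats$divergence_pct[setdiff(seq_len(nrow(dip$repeats)),
                                         het$te_row)])
    list(het = het, context = ctx, assoc = assoc, shift = shift,
         hemi = hemizygous_fraction(dip$svs, genome_size(layout)))
  })
  readr::write_tsv(tidy(hap$assoc), file.path(cfg$out_dir, "association.tsv"),
                   progress = FALSE)
  readr::write_tsv(hap$het, file.path(cfg$out_dir, "het_te_insertions.tsv"),
                   progress = FALSE)

  cfg_rate <- neutral_rate_config(cfg$neutral_rate, cfg$divisor_mode)
  land <- stage("landscape", dated_landscape(
    dip$repeats, cfg_rate, bin_width = cfg$landscape_bin_my))
  readr::write_tsv(land, file.path(cfg$out_dir, "landscape.tsv"),
                   progress = FALSE)

  tree <- stage("simulate", dated_tree(ape::read.tree(text =
    "((((Focal:3,Sister1:3):4,Sister2:7):4,Temperate:11):36,Outgroup:47);")))
  bm <- stage("simulate", simulate_branch_mutations(
    tree, layout, seed = child_seed(seed, 12)))
  branch <- stage("branchdyn", {
    rates <- net_gain_rates(bm$mutations, tree)
    merged <- merge_lifted_insertions(bm$mutations,
                                      cfg$merge_gap_insertions)
    att <- attribute_te_insertions(merged, bm$repeats, tree,
                                   cfg$min_reciprocal)
    curve <- rate_curve(att$per_branch, tree, "Focal")
    list(rates = rates, att = att, curve = curve)
  })
  readr::write_tsv(branch$rates, file.path(cfg$out_dir, "branch_rates.tsv"),
                   progress = FALSE)
  readr::write_tsv(branch$curve, file.path(cfg$out_dir, "rate_curve.tsv"),
                   progress = FALSE)

  ces <- stage("simulate", local_seed(child_seed(seed, 16), {
    n <- cfg$n_ces
    w <- sample(c(100, 200, 400), n, replace = TRUE)
    s <- seq(0, by = 5000, length.out = n)
    ce <- tibble(chrom = layout$chromosomes$chrom[1], start = s, end = s + w)
    anc <- sample(c("ancestral", "clade_specific", "other"), n,
                  replace = TRUE)
    list(ce = ce, anc = anc)
  }))
  all_sp <- c("Focal", "Sister1", "Sister2", "Temperate", "Outgroup")
  clade <- c("Focal", "Sister1", "Sister2")
  tracks <- stage("simulate", simulate_depth_tracks(
    ces$ce, ces$anc, all_sp, clade, min_cov = cfg$min_cov,
    seed = child_seed(seed, 13)))
  ce_out <- stage("ces", {
    cls <- classify_ancestry(ces$ce, tracks, all_sp, clade, cfg$min_cov)
    cls$feature <- assign_feature(ces$ce, dip$genes)
    cls
  })
  readr::write_tsv(ce_out, file.path(cfg$out_dir, "conserved_elements.tsv"),
                   progress = FALSE)

  gt <- stage("simulate", simulate_gene_trees(
    cfg$n_gene_trees, clade_taxa = clade, sister_taxon = "Temperate",
    outgroup_taxa = c("Outgroup", "Outgroup2"),
    seed = child_seed(seed, 14)))
  keep <- stage("treefilter", monophyly_sister_filter(
    gt$trees, clade, "Temperate"))
  readr::write_tsv(keep, file.path(cfg$out_dir, "tree_filter.tsv"),
                   progress = FALSE)

  af <- stage("simulate", simulate_afgp_locus(
    n_units = cfg$afgp_units,
    pseudogene_events = tibble(gene = c("afgp1", "afgp_tlp2"),
                               event = c("drop_exon1", "delete_tlp")),
    seed = child_seed(seed, 15)))
  af_out <- stage("afgp", {
    status <- validate_gene(af$genes)
    arrays <- detect_alternating_arrays(af$layout)
    motif <- detect_duplication_motif(af$layout)
    list(status = status, arrays = arrays, motif = motif)
  })
  readr::write_tsv(select(af_out$status, -"tlp_exons_present"),
                   file.path(cfg$out_dir, "afgp_status.tsv"),
                   progress = FALSE)

  jsonlite::write_json(
    unclass(cfg), file.path(cfg$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(package = "notoscan",
         version = as.character(utils::packageVersion("notoscan")),
         seed = seed, config_hash = config_hash(cfg),
         hemizygous_fraction = hap$hemi,
         n_het_te = nrow(hap$het),
         shift_p = hap$shift$p_value,
         stages = c("simulate", "hapvar", "landscape", "branchdyn", "ces",
                    "treefilter", "afgp")),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(layout = layout, diploid = dip, hapvar = hap,
                 landscape = land, branch = branch, ces = ce_out,
                 tree_filter = keep, afgp = af_out))
}

#' Verify a pipeline output directory against its config
#'
#' Recomputes the config hash from `config.json` and compares it with the
#' hash recorded in `manifest.json`, detecting tampered configurations.
#'
#' @param out_dir Pipeline output directory.
#' @return `TRUE` when the hashes match, `FALSE` otherwise.
#' @export
verify_run <- function(out_dir) {
  cfg <- jsonlite::read_json(file.path(out_dir, "config.json"),
                             simplifyVector = TRUE)
  man <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                             simplifyVector = TRUE)
  identical(config_hash(cfg), man$config_hash)
}
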