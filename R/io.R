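# Readers/writers for the plain-text formats the pipeline touches. All
# coordinates are 0-based half-open internally; GFF3 (1-based inclusive) is
# converted at the boundary. Parsers reject malformed input with the line
# number rather than silently repairing it.

repeat_classes <- c("DNA", "LINE", "LTR", "SINE", "tandem", "simple", "other")
sv_types <- c("INS", "DEL", "INV", "DUP", "TRA")

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA", "."))
}

fail_row <- function(which, what) {
  # +1 for the header line of the package TSV dialects
  abort(paste0(what, " (line ", which + 1L, ")"))
}

#' Read genomic features
#'
#' Dispatcher over the supported feature formats: BED (columns 1-6 honoured),
#' GFF3 gene models (gene/mRNA/exon/CDS hierarchy, converted to 0-based
#' half-open), and the repeat-annotation table.
#'
#' @param path File path.
#' @param format One of `"bed"`, `"gff3"`, `"repeat_table"`.
#' @return A tibble; see [read_bed()], [read_gff3()], [read_repeat_table()].
#' @export
read_features <- function(path, format = c("bed", "gff3", "repeat_table")) {
  switch(match.arg(format),
         bed = read_bed(path),
         gff3 = read_gff3(path),
         repeat_table = read_repeat_table(path))
}

#' @rdname read_features
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  ncol <- lengths(parts)
  if (any(ncol < 3)) {
    abort(paste0("BED line with fewer than 3 columns (line ",
                 which(ncol < 3)[1], ")"))
  }
  m <- min(ncol, 6)
  get <- function(k, default = NA_character_) {
    vapply(parts, function(p) if (length(p) >= k) p[k] else default, "")
  }
  out <- tibble(
    chrom = get(1),
    start = suppressWarnings(as.numeric(get(2))),
    end = suppressWarnings(as.numeric(get(3))),
    name = if (m >= 4) get(4) else NA_character_,
    score = if (m >= 5) suppressWarnings(as.numeric(get(5))) else NA_real_,
    strand = if (m >= 6) get(6) else NA_character_
  )
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) abort(paste0("non-numeric BED coordinate (line ", bad[1], ")"))
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad)) abort(paste0("invalid BED interval (line ", bad[1], ")"))
  out
}

#' @param x Tibble to write.
#' @rdname read_features
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) {
    score <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
    strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name),
                         ifelse(is.na(score), "0", as.character(score)),
                         ifelse(is.na(strand), ".", strand)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a GFF3 file into a flat gene-model tibble
#'
#' Parses the gene/mRNA/exon/CDS hierarchy into one row per feature with its
#' owning `gene_id` resolved through Parent attributes. Coordinates are
#' converted from 1-based inclusive to 0-based half-open.
#'
#' @param path GFF3 file path.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `type`, `id`,
#'   `gene_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  parts <- stringr::str_split(lines[keep], "\t")
  bad <- which(lengths(parts) != 9)
  if (length(bad)) abort(paste0("GFF3 line without 9 columns (line ", lineno[bad[1]], ")"))
  f <- function(k) vapply(parts, `[[`, "", k)
  attr_get <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  attrs <- f(9)
  out <- tibble(
    chrom = f(1),
    type = f(3),
    start = suppressWarnings(as.numeric(f(4))) - 1,  # to 0-based half-open
    end = suppressWarnings(as.numeric(f(5))),
    strand = f(7),
    id = attr_get(attrs, "ID"),
    parent = attr_get(attrs, "Parent")
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 | out$start >= out$end)
  if (length(bad)) abort(paste0("invalid GFF3 coordinates (line ", lineno[bad[1]], ")"))
  # resolve gene_id: gene rows are their own gene; mRNA rows point at gene;
  # exon/CDS rows point at mRNA (or directly at gene)
  gene_of <- setNames(out$id[out$type == "gene"], out$id[out$type == "gene"])
  mrna <- out$type %in% c("mRNA", "transcript")
  gene_of[out$id[mrna]] <- ifelse(out$parent[mrna] %in% names(gene_of),
                                  gene_of[out$parent[mrna]], out$parent[mrna])
  out$gene_id <- dplyr::case_when(
    out$type == "gene" ~ out$id,
    TRUE ~ unname(gene_of[out$parent])
  )
  out$gene_id[is.na(out$gene_id)] <- out$parent[is.na(out$gene_id)]
  select(out, "chrom", "start", "end", "strand", "type", "id", "gene_id")
}

#' @rdname read_gff3
#' @param x Gene-model tibble as produced by [read_gff3()].
#' @param source Value for the GFF3 source column.
#' @export
write_gff3 <- function(x, path, source = "notoscan") {
  check_intervals(x)
  attrs <- paste0("ID=", x$id,
                  ifelse(is.na(x$gene_id) | x$type == "gene", "",
                         paste0(";Parent=", x$gene_id)))
  ln <- paste(x$chrom, source, x$type,
              format(x$start + 1, scientific = FALSE, trim = TRUE),
              format(x$end, scientific = FALSE, trim = TRUE),
              ".", ifelse(is.na(x$strand), ".", x$strand), ".", attrs,
              sep = "\t")
  writeLines(c("##gff-version 3", ln), path)
  invisible(path)
}

#' Read/write the repeat-annotation table
#'
#' Fixed TSV dialect with header
#' `chrom start end family class divergence_pct score`, carrying per-copy
#' CpG-corrected Kimura divergence (%) from the family consensus and the
#' alignment score used for overlap resolution.
#'
#' @param path File path.
#' @return Tibble of repeat hits.
#' @export
read_repeat_table <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), family = readr::col_character(),
    class = readr::col_character(), divergence_pct = readr::col_double(),
    score = readr::col_double()))
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad)) fail_row(bad[1], "invalid repeat interval")
  bad <- which(!out$class %in% repeat_classes)
  if (length(bad)) fail_row(bad[1], paste0("unknown repeat class '", out$class[bad[1]], "'"))
  bad <- which(is.na(out$divergence_pct) | out$divergence_pct < 0)
  if (length(bad)) fail_row(bad[1], "divergence_pct must be >= 0")
  out
}

#' @rdname read_repeat_table
#' @param x Repeat tibble.
#' @export
write_repeat_table <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "family", "class",
                         "divergence_pct", "score")], path, progress = FALSE)
  invisible(path)
}

#' Read/write the structural-variant table
#'
#' Fixed TSV dialect `chrom start end sv_type length genotype source`.
#' Deletions carry reference coordinates; insertions carry a 1-bp anchor and
#' the inserted-sequence length in `length`.
#'
#' @param path File path.
#' @return Tibble of SV records.
#' @export
read_sv_table <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), sv_type = readr::col_character(),
    length = readr::col_double(), genotype = readr::col_character(),
    source = readr::col_character()))
  bad <- which(!out$sv_type %in% sv_types)
  if (length(bad)) fail_row(bad[1], paste0("unknown sv_type '", out$sv_type[bad[1]], "'"))
  bad <- which(is.na(out$length) | out$length <= 0)
  if (length(bad)) fail_row(bad[1], "SV length must be > 0")
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad)) fail_row(bad[1], "invalid SV interval")
  bad <- which(!out$genotype %in% c("het", "hom_alt", "unknown"))
  if (length(bad)) fail_row(bad[1], "genotype must be het/hom_alt/unknown")
  bad <- which(!out$source %in% c("assembly", "reads"))
  if (length(bad)) fail_row(bad[1], "source must be assembly/reads")
  out
}

#' @rdname read_sv_table
#' @param x SV tibble.
#' @export
write_sv_table <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "sv_type", "length",
                         "genotype", "source")], path, progress = FALSE)
  invisible(path)
}

#' Read/write the per-branch mutation table
#'
#' Fixed TSV dialect `branch_id kind bp chrom start end event_id` holding
#' insertion/deletion events assigned to species-tree branches; insertion
#' rows carry coordinates lifted to the reference genome, deletion rows may
#' leave them empty (`.`). Fragments of one ancestral insertion share an
#' `event_id`.
#'
#' @param path File path.
#' @return Tibble of branch mutations.
#' @export
read_branch_mutations <- function(path) {
  out <- read_tsv_quiet(path, readr::cols(
    branch_id = readr::col_character(), kind = readr::col_character(),
    bp = readr::col_double(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    event_id = readr::col_character()))
  bad <- which(!out$kind %in% c("insertion", "deletion"))
  if (length(bad)) fail_row(bad[1], "kind must be insertion/deletion")
  bad <- which(is.na(out$bp) | out$bp <= 0)
  if (length(bad)) fail_row(bad[1], "bp must be > 0")
  has_coord <- !is.na(out$chrom)
  bad <- which(has_coord & !(out$start >= 0 & out$start < out$end))
  if (length(bad)) fail_row(bad[1], "invalid lifted interval")
  out
}

#' @rdname read_branch_mutations
#' @param x Branch-mutation tibble.
#' @export
write_branch_mutations <- function(x, path) {
  readr::write_tsv(x[, c("branch_id", "kind", "bp", "chrom", "start", "end",
                         "event_id")], path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read per-species alignment-depth tracks
#'
#' Each file is bedGraph-like (`chrom start end`, optional depth column);
#' intervals record where the species aligns to the reference genome
#' (presence/absence per base).
#'
#' @param paths Named character vector of file paths; names are species.
#' @return Tibble with `species`, `chrom`, `start`, `end`.
#' @export
read_depth_tracks <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be named by species")
  }
  purrr::imap(paths, function(p, sp) {
    b <- read_bed(p)
    tibble(species = sp, chrom = b$chrom, start = b$start, end = b$end)
  }) |> bind_rows()
}

#' @rdname read_depth_tracks
#' @param tracks Depth-track tibble (`species`, `chrom`, `start`, `end`).
#' @param dir Output directory; one `<species>.bedgraph` per species.
#' @export
write_depth_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in unique(tracks$species)) {
    d <- tracks[tracks$species == sp, ]
    write_bed(d[, c("chrom", "start", "end")],
              file.path(dir, paste0(sp, ".bedgraph")))
  }
  invisible(dir)
}
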