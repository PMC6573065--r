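# Configuration and orchestration: one reproducible run over the
# interactome and/or genomic stages, with a machine-readable manifest.

#' Pipeline configuration with the study defaults
#'
#' All tunable thresholds in one validated list. Defaults: stitch distance
#' 12500 bp, TSS exclusion window 1000 bp, top 5000 sites per factor,
#' summit window 200 bp, promoter half-width 1500 bp, RPKM activity
#' threshold 0.5, broad fraction 0.05, metaprofile bin 10 bp and flank
#' 12000 bp, interactor thresholds Mascot 50 / emPAI fold 5 / Mascot fold
#' 3 / treatment drop fold 2.
#'
#' @param ... Named overrides of the defaults; unknown keys are rejected.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(stitch = 12500, tss_window = 1000, top_n = 5000,
                   summit_window = 200, promoter_halfwidth = 1500,
                   rpkm_min = 0.5, broad_frac = 0.05, bin = 10, flank = 12000,
                   mascot_min = 50, empai_fold_min = 5, mascot_fold_min = 3,
                   treatment_drop_fold = 2)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("pipeline_config overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown pipeline_config key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    defaults[names(over)] <- over
  }
  for (nm in names(defaults)) {
    v <- defaults[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("pipeline_config key %s must be a single positive number", nm),
           call. = FALSE)
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' @noRd
as_filter_config <- function(config) {
  filter_config(mascot_min = config$mascot_min,
                empai_fold_min = config$empai_fold_min,
                mascot_fold_min = config$mascot_fold_min,
                treatment_drop_fold = config$treatment_drop_fold)
}

manifest_entry <- function(paths) {
  lapply(paths, function(p) list(path = p, md5 = unname(tools::md5sum(p))))
}

#' Run the genomic stage: enhancers, SEs, gene categories, overlaps, KD
#'
#' @param inputs Named list of file paths: required `ep300`, `h3k27ac`,
#'   `tss`, `med1_bedgraph`, `chrom_sizes`, `expression`; optional `de`,
#'   `h3k4me3`, `factors` (named character vector of narrowPeak paths for
#'   colocalization), `total_tags` (number, default 1e7).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and `manifest`.
#' @export
run_genomic_pipeline <- function(inputs, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("ep300", "h3k27ac", "tss", "med1_bedgraph", "chrom_sizes", "expression")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop(sprintf("missing genomic input(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  for (nm in need) {
    if (!file.exists(inputs[[nm]])) stop(sprintf("input file not found (%s): %s", nm, inputs[[nm]]), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  chrom_sizes <- read_chrom_sizes(inputs$chrom_sizes)
  total_tags <- if (!is.null(inputs$total_tags)) inputs$total_tags else 1e7
  ep300 <- read_peaks_bed(inputs$ep300, summit_mode = "column_offset")
  h3k27ac <- read_peaks_bed(inputs$h3k27ac)
  tss <- read_tss_table(inputs$tss)
  med1 <- read_signal_bedgraph(inputs$med1_bedgraph, chrom_sizes, total_tags)
  expression <- read_tabular(inputs$expression, "expression")

  enhancers <- define_enhancers(ep300, h3k27ac)
  kept <- exclude_tss_overlapping(enhancers, tss, window = config$tss_window)
  stitched <- stitch_enhancers(kept, max_gap = config$stitch)
  stitched$total_signal <- quantify_region_signal(stitched, med1)
  se_call <- call_se_cutoff(stitched)
  regions <- se_call$regions
  se_regions <- regions[regions$is_se, , drop = FALSE]
  typical_regions <- regions[!regions$is_se, , drop = FALSE]

  active_ids <- active_gene_set(expression, min_rpkm = config$rpkm_min)
  active_tss <- tss[tss$gene_id %in% active_ids, , drop = FALSE]
  se_nearest <- nearest_active_gene(se_regions, active_tss)
  typ_nearest <- nearest_active_gene(typical_regions, active_tss)
  se_gene_ids <- sort(unique(stats::na.omit(se_nearest$gene_id)))
  typical_gene_ids <- sort(unique(stats::na.omit(typ_nearest$gene_id)))

  results <- list(enhancers = enhancers, stitched = regions, se_call = se_call)
  counts <- list(n_enhancers = nrow(enhancers),
                 n_after_tss_exclusion = nrow(kept),
                 n_stitched = nrow(stitched),
                 n_se = se_call$n_se, n_typical = se_call$n_typical,
                 n_active_genes = length(active_ids),
                 n_se_genes = length(se_gene_ids),
                 n_typical_genes = length(typical_gene_ids))

  if (!is.null(inputs$h3k4me3)) {
    h3 <- read_peaks_bed(inputs$h3k4me3)
    widths <- promoter_domain_width(h3, tss)
    broad_ids <- intersect(broad_promoter_set(widths, top_frac = config$broad_frac),
                           active_ids)
    categories <- assign_gene_categories(active_ids, se_gene_ids,
                                         typical_gene_ids, broad_ids)
    se_gene_tab <- data.frame(se_id = se_regions$id,
                              total_signal = se_regions$total_signal,
                              gene_id = se_nearest$gene_id,
                              stringsAsFactors = FALSE)
    top100 <- top100_sets(se_gene_tab, broad_ids, widths)
    expr_summary <- category_expression_summary(categories, expression)
    results$categories <- categories
    results$top100 <- top100
    results$expression_summary <- expr_summary
    counts$n_broad_genes <- length(broad_ids)
    counts$n_se_broad <- sum(categories$category == "SE+Broad")
    counts$n_se_noBroad <- sum(categories$category == "SE-Broad")
    counts$n_broad_noSE <- sum(categories$category == "Broad-SE")
    counts$n_typical_category <- sum(categories$category == "Typical")
    write_tsv(categories, file.path(out_dir, "gene_categories.tsv"))
    for (nm in names(top100)) {
      writeLines(top100[[nm]], file.path(out_dir, paste0(nm, ".txt")))
    }
    write_tsv(expr_summary, file.path(out_dir, "expression_summary.tsv"))
    if (!is.null(inputs$de)) {
      de <- read_tabular(inputs$de, "de")
      kd <- kd_category_response(de, categories)
      results$kd_response <- kd
      write_tsv(kd, file.path(out_dir, "kd_response.tsv"))
    }
  }

  if (!is.null(inputs$factors)) {
    sets <- lapply(inputs$factors, function(p) {
      top_n_by_score(read_peaks_bed(p, summit_mode = "column_offset"),
                     n = config$top_n)
    })
    om <- suppressWarnings(
      summit_overlap_by_category(sets, tss, se_regions, typical_regions,
                                 window = config$summit_window,
                                 promoter_halfwidth = config$promoter_halfwidth))
    results$overlap <- om
    for (nm in names(om)) {
      utils::write.table(om[[nm]], file.path(out_dir, paste0("overlap_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
  }

  write_intervals_bed(data.frame(chrom = regions$chrom, start = regions$start,
                                 end = regions$end, name = regions$id,
                                 score = regions$total_signal,
                                 stringsAsFactors = FALSE),
                      file.path(out_dir, "stitched_regions.bed"))
  write_tsv(regions[, c("id", "chrom", "start", "end", "n_constituents",
                        "total_signal", "rank", "is_se")],
            file.path(out_dir, "se_rank.tsv"))
  write_tsv(se_call$curve, file.path(out_dir, "hockey_curve.tsv"))

  manifest <- list(stage = "genomic", parameters = unclass(config),
                   inputs = manifest_entry(Filter(is.character, inputs)),
                   counts = counts,
                   package_version = as.character(utils::packageVersion("mediascape")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest_genomic.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$counts <- counts
  results$manifest <- manifest
  invisible(results)
}

#' Run the interactome stage
#'
#' @param inputs Named list: required `apms`; optional `core_ids`,
#'   `cyto_ids`, `endogenous_ids` (plain-text id files, one per line).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, list with `calls`, `subtracted`, optional
#'   `endogenous`, `counts`, `manifest`.
#' @export
run_interactome_pipeline <- function(inputs, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs$apms)) stop("missing interactome input: apms", call. = FALSE)
  if (!file.exists(inputs$apms)) stop(sprintf("input file not found: %s", inputs$apms), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  read_ids <- function(p) if (!is.null(p)) readLines(p) else character()
  apms <- read_tabular(inputs$apms, "apms")
  calls <- call_interactors(apms, as_filter_config(config),
                            cyto_ids = read_ids(inputs$cyto_ids))
  sub <- subtract_core_subunits(calls, read_ids(inputs$core_ids))
  write_interactor_tables(calls, out_dir)
  counts <- list(n_proteins = nrow(apms), n_passing = sum(calls$passed),
                 n_core_matched = sub$n_core_matched,
                 n_interactors = sub$n_interactors)
  out <- list(calls = calls, subtracted = sub)
  if (!is.null(inputs$endogenous_ids)) {
    ov <- endogenous_overlap(sub$interactors$protein_id,
                             read_ids(inputs$endogenous_ids))
    counts$n_endogenous_overlap <- ov$count
    out$endogenous <- ov
  }
  manifest <- list(stage = "interactome", parameters = unclass(config),
                   inputs = manifest_entry(Filter(is.character, inputs)),
                   counts = counts,
                   package_version = as.character(utils::packageVersion("mediascape")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest_interactome.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$counts <- counts
  out$manifest <- manifest
  invisible(out)
}

#' Run all configured pipeline stages
#'
#' Executes the interactome stage when `inputs$apms` is given and the
#' genomic stage when `inputs$ep300` is given; either alone is fine.
#'
#' @param inputs Named list combining the inputs of
#'   [run_interactome_pipeline()] and [run_genomic_pipeline()].
#' @param out_dir Output directory (stage outputs and manifests).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(inputs, out_dir, config = pipeline_config()) {
  out <- list()
  if (!is.null(inputs$apms)) {
    out$interactome <- run_interactome_pipeline(inputs, out_dir, config)
  }
  if (!is.null(inputs$ep300)) {
    out$genomic <- run_genomic_pipeline(inputs, out_dir, config)
  }
  if (!length(out)) stop("no stage configured: provide apms and/or ep300 inputs", call. = FALSE)
  invisible(out)
}
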