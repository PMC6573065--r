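# Broad-H3K4me3 promoter classification, enhancer-to-gene assignment, and
# the SE+Broad / SE-Broad / Broad-SE / Typical gene partition.

#' Widest H3K4me3 domain covering each TSS
#'
#' A gene's promoter-domain width is the width of the widest H3K4me3 domain
#' whose interval contains the TSS base itself; 0 when no domain covers the
#' TSS.
#'
#' @param domains Interval data.frame of H3K4me3 domains.
#' @param tss TSS table.
#' @return Data.frame with `gene_id` and `h3k4me3_width` (bp).
#' @export
promoter_domain_width <- function(domains, tss) {
  assert_intervals(domains, "H3K4me3 domains")
  width <- numeric(nrow(tss))
  if (nrow(domains)) {
    dw <- domains$end - domains$start
    for (ch in unique(tss$chrom)) {
      ti <- which(tss$chrom == ch)
      di <- which(domains$chrom == ch)
      if (!length(di)) next
      for (k in ti) {
        cov <- di[domains$start[di] <= tss$pos[k] & tss$pos[k] < domains$end[di]]
        if (length(cov)) width[k] <- max(dw[cov])
      }
    }
  }
  data.frame(gene_id = tss$gene_id, h3k4me3_width = width,
             stringsAsFactors = FALSE)
}

#' Genes in the top fraction of promoter-domain widths
#'
#' Among genes with a nonzero domain width, computes the `(1 - top_frac)`
#' quantile of widths; a gene is broad when its width is at least that
#' threshold, so ties at the threshold are all included.
#'
#' @param assignments Output of [promoter_domain_width()].
#' @param top_frac Fraction of broadest domains to call broad (default 0.05).
#' @return Character vector of broad gene ids.
#' @export
broad_promoter_set <- function(assignments, top_frac = 0.05) {
  stopifnot(top_frac > 0, top_frac < 1)
  w <- assignments$h3k4me3_width
  pos <- w > 0
  if (!any(pos)) stop("no gene has a nonzero H3K4me3 domain width", call. = FALSE)
  thr <- stats::quantile(w[pos], 1 - top_frac, names = FALSE, type = 7)
  sort(assignments$gene_id[pos & w >= thr])
}

#' Active genes by mean RPKM
#'
#' A gene is active when its mean RPKM across replicates is strictly above
#' `min_rpkm`. Rows whose replicates are all missing are excluded with a
#' warning.
#'
#' @param expression Expression data.frame (see [read_tabular()] schema
#'   `expression`) with `gene_id` and `rpkm_*` replicate columns.
#' @param min_rpkm Activity threshold (default 0.5, strict inequality).
#' @return Character vector of active gene ids.
#' @export
active_gene_set <- function(expression, min_rpkm = 0.5) {
  if (!nrow(expression)) stop("empty expression table", call. = FALSE)
  reps <- grep("^rpkm_", names(expression), value = TRUE)
  if (!length(reps)) stop("expression table lacks rpkm_* columns", call. = FALSE)
  vals <- as.matrix(expression[, reps, drop = FALSE])
  all_na <- rowSums(!is.na(vals)) == 0L
  if (any(all_na)) {
    warning(sprintf("%d gene(s) with no replicate measurements excluded", sum(all_na)))
  }
  m <- rowMeans(vals, na.rm = TRUE)
  sort(expression$gene_id[!all_na & m > min_rpkm])
}

#' Mean RPKM per gene
#' @noRd
mean_rpkm <- function(expression) {
  reps <- grep("^rpkm_", names(expression), value = TRUE)
  stats::setNames(rowMeans(as.matrix(expression[, reps, drop = FALSE]), na.rm = TRUE),
                  expression$gene_id)
}

#' Nearest active gene per region
#'
#' Distance is 0 when the TSS lies within the region, otherwise the smaller
#' of the distances from the TSS to the two region edges (0-based; the last
#' base is `end - 1`). Ties go to the lexicographically smaller gene id;
#' genes on other chromosomes never match.
#'
#' @param regions Interval data.frame (an `id` column is carried through;
#'   row index used otherwise).
#' @param tss TSS table restricted to active genes.
#' @return Data.frame with `region_id`, `gene_id` (NA when no active gene
#'   shares the chromosome), and `distance` (bp).
#' @export
nearest_active_gene <- function(regions, tss) {
  assert_intervals(regions, "regions")
  rid <- if ("id" %in% names(regions)) regions$id else as.character(seq_len(nrow(regions)))
  gene <- rep(NA_character_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ci <- which(tss$chrom == regions$chrom[i])
    if (!length(ci)) next
    pos <- tss$pos[ci]
    inside <- pos >= regions$start[i] & pos < regions$end[i]
    d <- ifelse(inside, 0, pmin(abs(pos - regions$start[i]),
                                abs(pos - (regions$end[i] - 1))))
    best <- min(d)
    cand <- tss$gene_id[ci[d == best]]
    gene[i] <- sort(cand)[1L]
    dist[i] <- best
  }
  data.frame(region_id = rid, gene_id = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Partition active genes into SE/broad categories
#'
#' Categories: `SE+Broad` = SE genes with a broad promoter; `SE-Broad` = SE
#' genes without; `Broad-SE` = broad-promoter genes not nearest to an SE;
#' `Typical` = typical-enhancer genes with neither an SE nor a broad
#' promoter; all other active genes are `none`.
#'
#' @param active_ids Character vector of active gene ids.
#' @param se_gene_ids Genes that are the nearest active gene to at least one
#'   super enhancer (subset of `active_ids`).
#' @param typical_gene_ids Genes nearest to at least one typical enhancer
#'   (subset of `active_ids`).
#' @param broad_ids Broad-promoter genes (subset of `active_ids`).
#' @return Data.frame with `gene_id` and `category`, one row per active
#'   gene; categories are mutually exclusive and exhaustive over
#'   `active_ids`.
#' @export
assign_gene_categories <- function(active_ids, se_gene_ids, typical_gene_ids,
                                   broad_ids) {
  for (nm in c("se_gene_ids", "typical_gene_ids", "broad_ids")) {
    extra <- setdiff(get(nm), active_ids)
    if (length(extra)) {
      stop(sprintf("%s contains non-active gene(s), e.g. %s", nm, extra[1L]),
           call. = FALSE)
    }
  }
  category <- rep("none", length(active_ids))
  se <- active_ids %in% se_gene_ids
  br <- active_ids %in% broad_ids
  ty <- active_ids %in% typical_gene_ids
  category[ty & !se & !br] <- "Typical"
  category[br & !se] <- "Broad-SE"
  category[se & !br] <- "SE-Broad"
  category[se & br] <- "SE+Broad"
  data.frame(gene_id = active_ids, category = category,
             stringsAsFactors = FALSE)
}

#' Top-100 gene subsets per category
#'
#' Walks super enhancers in descending Med1 signal and collects each SE's
#' nearest gene (one gene per SE, duplicates kept at their highest-ranked
#' SE) into the broad-promoter or non-broad list until each holds `n` genes
#' or SEs are exhausted. The `Broad-SE` list holds the `n` widest-promoter
#' genes among broad genes not nearest to any SE.
#'
#' @param se_genes Data.frame with one row per SE: `se_id`, `total_signal`,
#'   `gene_id` (nearest active gene; NA rows are skipped).
#' @param broad_ids Broad-promoter gene ids.
#' @param widths Output of [promoter_domain_width()].
#' @param n Subset size (default 100).
#' @return List with character vectors `top100_se_broad`,
#'   `top100_se_noBroad`, `top100_broad_noSE`.
#' @export
top100_sets <- function(se_genes, broad_ids, widths, n = 100) {
  o <- order(-se_genes$total_signal, se_genes$se_id)
  se_broad <- character()
  se_nobroad <- character()
  seen <- character()
  for (i in o) {
    g <- se_genes$gene_id[i]
    if (is.na(g) || g %in% seen) next
    seen <- c(seen, g)
    if (g %in% broad_ids) {
      if (length(se_broad) < n) se_broad <- c(se_broad, g)
    } else {
      if (length(se_nobroad) < n) se_nobroad <- c(se_nobroad, g)
    }
    if (length(se_broad) >= n && length(se_nobroad) >= n) break
  }
  broad_no_se <- setdiff(broad_ids, se_genes$gene_id)
  w <- widths$h3k4me3_width[match(broad_no_se, widths$gene_id)]
  ow <- order(-w, broad_no_se)
  list(top100_se_broad = se_broad,
       top100_se_noBroad = se_nobroad,
       top100_broad_noSE = broad_no_se[utils::head(ow, n)])
}
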