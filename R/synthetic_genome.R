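# Seeded toy-genome generator with planted enhancers, SE clusters, broad
# promoters, category-dependent expression, and knockdown effects.
#
# Layout: each gene owns one tile on one of two chromosomes. SE-gene tiles
# (45 kb) carry a cluster of 3-4 high-Med1 constituent enhancers downstream
# of the TSS with inner gaps well below the stitch distance; typical-gene
# tiles (20 kb) carry one enhancer (sometimes split into two close
# constituents that stitch back together). Tile interiors keep >= 16 kb
# between features of neighbouring tiles so nothing stitches across genes.
# Typical constituent totals are drawn from a tight band and SE intensities
# ~10x higher, so the ranked Med1 curve has a single sharp elbow and the
# hockey-stick cutoff recovers the planted clusters deterministically.

#' Generate a toy genome fixture with planted ground truth
#'
#' Writes, into `out_dir`: `chrom.sizes`, `tss.tsv`, `ep300.narrowPeak`,
#' `h3k27ac.bed`, `h3k4me3.bed`, `med1.bedgraph`, `med1_peaks.narrowPeak`,
#' `tcf4_peaks.narrowPeak`, `expression.tsv`, `de.tsv`, `truth_genes.tsv`,
#' `truth_se.tsv`, and `params.json`. Identical seeds give byte-identical
#' files.
#'
#' Planted structure: `n_se_broad + n_se_noBroad` SE clusters (one per SE
#' gene), `n_typical` typical-enhancer genes, `n_broad_noSE` broad-promoter
#' genes without SEs; broad genes carry H3K4me3 domains wide enough to be
#' exactly the top-5% slice when `n_se_broad + n_broad_noSE` equals 5% of
#' the gene count (the defaults do). Decoy Ep300 peaks without H3K27ac and
#' promoter-proximal enhancer peaks exercise the definition and TSS-
#' exclusion filters. Expression is log-normal with category-ordered means
#' (SE+Broad > SE-Broad ~ Broad-SE > Typical) and the DE table uses
#' stratified planted down-fractions (see [gen_kd_table()]).
#'
#' @param out_dir Output directory.
#' @param seed Mandatory RNG seed.
#' @param n_se_broad,n_se_noBroad,n_broad_noSE,n_typical,n_active_other,n_inactive
#'   Planted gene-category counts (defaults 5/10/5/60/90/30).
#' @param se_intensity,typical_intensity Ranges (length-2) of per-bp Med1
#'   read density on SE / typical constituents.
#' @param coloc_prob Probability that a Tcf4 peak colocalizes (summit within
#'   the 200 bp window) with its Med1 peak (default 0.8).
#' @param down_probs Planted significant-and-down probabilities per category
#'   (passed to [gen_kd_table()]).
#' @param sig_frac Fraction of genes with significant DE calls.
#' @param rpkm_meanlog Named log-means for per-category expression.
#' @param total_tags Total mapped tags recorded for the Med1 track.
#' @param n_orphan_ep300 Decoy Ep300 peaks without H3K27ac support.
#' @param n_promoter_decoys Active genes that also get a promoter-proximal
#'   Ep300+H3K27ac peak (removed by the TSS-exclusion rule).
#' @return Invisibly, a list with `truth` (genes, se_clusters, enhancers),
#'   `paths`, and `params`.
#' @export
gen_genome_fixture <- function(out_dir, seed,
                               n_se_broad = 5, n_se_noBroad = 10,
                               n_broad_noSE = 5, n_typical = 60,
                               n_active_other = 90, n_inactive = 30,
                               se_intensity = c(8, 14),
                               typical_intensity = c(0.9, 1.3),
                               coloc_prob = 0.8,
                               down_probs = c("SE+Broad" = 0.65, "SE-Broad" = 0.40,
                                              "Broad-SE" = 0.20, "Typical" = 0.20),
                               sig_frac = 0.9,
                               rpkm_meanlog = c("SE+Broad" = log(50), "SE-Broad" = log(15),
                                                "Broad-SE" = log(15), "Typical" = log(6),
                                                "none" = log(2.5), "inactive" = log(0.08)),
                               total_tags = 1e6,
                               n_orphan_ep300 = 10, n_promoter_decoys = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  se_tile <- 45000
  typ_tile <- 20000
  pad <- 15000
  jitter_bp <- function(n) round(pmax(-60, pmin(60, stats::rnorm(n, 0, 20))))
  res <- with_seed(seed, {
    category <- sample(rep(c("SE+Broad", "SE-Broad", "Broad-SE", "Typical",
                             "none", "inactive"),
                           c(n_se_broad, n_se_noBroad, n_broad_noSE, n_typical,
                             n_active_other, n_inactive)))
    n_genes <- length(category)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    chrom <- rep(c("chr1", "chr2"), length.out = n_genes)
    is_se_gene <- category %in% c("SE+Broad", "SE-Broad")
    tile_w <- ifelse(is_se_gene, se_tile, typ_tile)
    tile_start <- numeric(n_genes)
    for (ch in c("chr1", "chr2")) {
      ci <- which(chrom == ch)
      tile_start[ci] <- pad + cumsum(c(0, utils::head(tile_w[ci], -1)))
    }
    chrom_sizes <- vapply(c("chr1", "chr2"), function(ch) {
      ci <- chrom == ch
      pad + sum(tile_w[ci]) + pad
    }, numeric(1))

    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tss <- tile_start + ifelse(is_se_gene, 13000, 8000)
    is_broad <- category %in% c("SE+Broad", "Broad-SE")
    h3_width <- ifelse(is_broad,
                       round(stats::runif(n_genes, 7000, 12000)),
                       round(stats::runif(n_genes, 400, 2500)))
    h3_left <- round(h3_width * stats::runif(n_genes, 0.3, 0.7))
    h3_start <- pmax(tile_start + 100, tss - h3_left)
    h3_end <- h3_start + h3_width

    enh <- list()   # one row per constituent enhancer
    se_rows <- list()
    for (i in seq_len(n_genes)) {
      if (is_se_gene[i]) {
        n_c <- sample(3:4, 1)
        wid <- round(stats::runif(n_c, 500, 900))
        gap <- round(stats::runif(n_c, 1000, 3000))   # gap[1] unused
        starts <- tss[i] + 2000 + cumsum(c(0, utils::head(wid, -1) + gap[-1]))
        inten <- stats::runif(n_c, se_intensity[1], se_intensity[2])
        enh[[length(enh) + 1L]] <- data.frame(
          chrom = chrom[i], start = starts, end = starts + wid,
          intensity = inten, role = "constituent_se", gene_id = gene_id[i],
          stringsAsFactors = FALSE)
        se_rows[[length(se_rows) + 1L]] <- data.frame(
          se_id = sprintf("se_%s", gene_id[i]), chrom = chrom[i],
          start = starts[1], end = starts[n_c] + wid[n_c],
          n_constituents = n_c, gene_id = gene_id[i], stringsAsFactors = FALSE)
      } else if (category[i] == "Typical" ||
                 (category[i] == "Broad-SE")) {
        split2 <- stats::runif(1) < 0.3
        if (split2) {
          wid <- round(stats::runif(2, 300, 450))
          gap <- round(stats::runif(1, 500, 1500))
          starts <- tss[i] + 2000 + c(0, wid[1] + gap)
        } else {
          wid <- round(stats::runif(1, 550, 800))
          starts <- tss[i] + 2000
        }
        inten <- rep(stats::runif(1, typical_intensity[1], typical_intensity[2]),
                     length(wid))
        enh[[length(enh) + 1L]] <- data.frame(
          chrom = chrom[i], start = starts, end = starts + wid,
          intensity = inten, role = "constituent_typical", gene_id = gene_id[i],
          stringsAsFactors = FALSE)
      }
    }
    enh <- do.call(rbind, enh)
    enh$id <- sprintf("cons_%04d", seq_len(nrow(enh)))
    se_clusters <- do.call(rbind, se_rows)

    active <- category != "inactive"
    # decoys: promoter-proximal Ep300+H3K27ac peaks (TSS-excluded downstream)
    dec_genes <- utils::head(which(active), n_promoter_decoys)
    promoter_decoys <- data.frame(
      chrom = chrom[dec_genes], start = tss[dec_genes] - 250,
      end = tss[dec_genes] + 250, role = "promoter_decoy",
      gene_id = gene_id[dec_genes], stringsAsFactors = FALSE)
    # decoys: Ep300 peaks without H3K27ac support (dropped at definition)
    orph_genes <- utils::head(which(!is_se_gene & category %in% c("none", "inactive")),
                              n_orphan_ep300)
    orphan_decoys <- data.frame(
      chrom = chrom[orph_genes], start = tile_start[orph_genes] + 16000,
      end = tile_start[orph_genes] + 16600, role = "orphan_decoy",
      gene_id = gene_id[orph_genes], stringsAsFactors = FALSE)

    # Med1 coverage: constituents + promoter signal of active genes
    prom_cov <- data.frame(chrom = chrom[active], start = tss[active] - 400,
                           end = tss[active] + 400,
                           value = round(stats::runif(sum(active), 1.5, 2.5), 3),
                           stringsAsFactors = FALSE)
    bg <- rbind(data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                           value = round(enh$intensity, 3), stringsAsFactors = FALSE),
                prom_cov)
    bg <- bg[order(bg$chrom, bg$start), , drop = FALSE]

    # Ep300 peaks: constituents + both decoy families
    ep_int <- rbind(enh[, c("chrom", "start", "end")],
                    promoter_decoys[, c("chrom", "start", "end")],
                    orphan_decoys[, c("chrom", "start", "end")])
    ep_role <- c(enh$role, promoter_decoys$role, orphan_decoys$role)
    ep_gene <- c(enh$gene_id, promoter_decoys$gene_id, orphan_decoys$gene_id)
    ep <- data.frame(chrom = ep_int$chrom, start = ep_int$start, end = ep_int$end,
                     name = sprintf("ep300_%04d", seq_len(nrow(ep_int))),
                     score = round(stats::runif(nrow(ep_int), 50, 500), 1),
                     role = ep_role, gene_id = ep_gene, stringsAsFactors = FALSE)
    ep$summit <- floor((ep$start + ep$end) / 2) + jitter_bp(nrow(ep))
    ep$summit <- pmax(ep$start, pmin(ep$end - 1, ep$summit))
    # H3K27ac: around every constituent and promoter decoy, not orphans
    k27_src <- ep[ep$role != "orphan_decoy", , drop = FALSE]
    k27 <- data.frame(chrom = k27_src$chrom, start = pmax(0, k27_src$start - 400),
                      end = k27_src$end + 400,
                      name = sprintf("k27_%04d", seq_len(nrow(k27_src))),
                      stringsAsFactors = FALSE)

    # factor peaks for colocalization: Med1 at constituents + active promoters
    med1_peaks <- rbind(
      data.frame(chrom = enh$chrom,
                 center = floor((enh$start + enh$end) / 2),
                 score = round((enh$end - enh$start) * enh$intensity, 1),
                 stringsAsFactors = FALSE),
      data.frame(chrom = chrom[active], center = tss[active],
                 score = round(stats::runif(sum(active), 30, 80), 1),
                 stringsAsFactors = FALSE))
    med1_peaks$summit <- med1_peaks$center + jitter_bp(nrow(med1_peaks))
    coloc <- stats::runif(nrow(med1_peaks)) < coloc_prob
    # non-colocalizing Tcf4 summits go to a feature-free zone near the owning
    # tile's end (> 1.2 kb from every planted summit)
    tcf4_summit <- ifelse(coloc, med1_peaks$summit + jitter_bp(nrow(med1_peaks)),
                          NA_real_)
    # map each med1 peak to its tile end per chromosome
    for (ch in c("chr1", "chr2")) {
      ci <- which(chrom == ch)
      bounds <- c(tile_start[ci][order(tile_start[ci])],
                  chrom_sizes[[ch]] - pad)
      pi <- which(med1_peaks$chrom == ch & !coloc)
      if (!length(pi)) next
      idx <- findInterval(med1_peaks$summit[pi], bounds)
      tile_end <- bounds[pmin(idx + 1L, length(bounds))]
      tcf4_summit[pi] <- tile_end - 2500 + round(stats::runif(length(pi), -1000, 1000))
    }
    tcf4 <- data.frame(chrom = med1_peaks$chrom,
                       start = tcf4_summit - 150, end = tcf4_summit + 150,
                       name = sprintf("tcf4_%04d", seq_len(nrow(med1_peaks))),
                       score = round(stats::rlnorm(nrow(med1_peaks), log(100), 0.5), 1),
                       summit = tcf4_summit, coloc = coloc,
                       stringsAsFactors = FALSE)
    med1_df <- data.frame(chrom = med1_peaks$chrom,
                          start = med1_peaks$center - 250,
                          end = med1_peaks$center + 250,
                          name = sprintf("med1_%04d", seq_len(nrow(med1_peaks))),
                          score = med1_peaks$score, summit = med1_peaks$summit,
                          stringsAsFactors = FALSE)

    expr_meanlog <- rpkm_meanlog[ifelse(active, category, "inactive")]
    rpkm <- matrix(stats::rlnorm(3L * n_genes, rep(expr_meanlog, each = 3), 0.25),
                   ncol = 3, byrow = TRUE)
    expression <- data.frame(gene_id = gene_id,
                             rpkm_rep1 = round(rpkm[, 1], 3),
                             rpkm_rep2 = round(rpkm[, 2], 3),
                             rpkm_rep3 = round(rpkm[, 3], 3),
                             stringsAsFactors = FALSE)

    genes <- data.frame(gene_id = gene_id, chrom = chrom, pos = tss,
                        strand = strand, category = category,
                        is_active = active, h3k4me3_width = h3_width,
                        tile_start = tile_start, tile_end = tile_start + tile_w,
                        stringsAsFactors = FALSE)
    h3 <- data.frame(chrom = chrom, start = h3_start, end = h3_end,
                     name = sprintf("k4me3_%s", gene_id), stringsAsFactors = FALSE)
    list(genes = genes, enh = enh, se_clusters = se_clusters, ep = ep,
         k27 = k27, h3 = h3, bg = bg, med1_df = med1_df, tcf4 = tcf4,
         expression = expression, chrom_sizes = chrom_sizes)
  })

  de <- gen_kd_table(
    categories = data.frame(gene_id = res$genes$gene_id[res$genes$is_active],
                            category = res$genes$category[res$genes$is_active],
                            stringsAsFactors = FALSE),
    down_probs = down_probs, sig_frac = sig_frac, seed = seed + 104729L)

  paths <- c(chrom_sizes = file.path(out_dir, "chrom.sizes"),
             tss = file.path(out_dir, "tss.tsv"),
             ep300 = file.path(out_dir, "ep300.narrowPeak"),
             h3k27ac = file.path(out_dir, "h3k27ac.bed"),
             h3k4me3 = file.path(out_dir, "h3k4me3.bed"),
             med1_bedgraph = file.path(out_dir, "med1.bedgraph"),
             med1_peaks = file.path(out_dir, "med1_peaks.narrowPeak"),
             tcf4_peaks = file.path(out_dir, "tcf4_peaks.narrowPeak"),
             expression = file.path(out_dir, "expression.tsv"),
             de = file.path(out_dir, "de.tsv"),
             truth_genes = file.path(out_dir, "truth_genes.tsv"),
             truth_se = file.path(out_dir, "truth_se.tsv"),
             truth_enhancers = file.path(out_dir, "truth_enhancers.tsv"),
             params = file.path(out_dir, "params.json"))
  writeLines(sprintf("%s\t%d", names(res$chrom_sizes), as.integer(res$chrom_sizes)),
             paths[["chrom_sizes"]])
  write_tsv(res$genes[, c("gene_id", "chrom", "pos", "strand")], paths[["tss"]])
  write_narrowpeak(res$ep[, c("chrom", "start", "end", "name", "score", "summit")],
                   paths[["ep300"]])
  write_intervals_bed(res$k27, paths[["h3k27ac"]])
  write_intervals_bed(res$h3, paths[["h3k4me3"]])
  writeLines(sprintf("%s\t%d\t%d\t%s", res$bg$chrom, as.integer(res$bg$start),
                     as.integer(res$bg$end), format(res$bg$value, trim = TRUE)),
             paths[["med1_bedgraph"]])
  write_narrowpeak(res$med1_df, paths[["med1_peaks"]])
  write_narrowpeak(res$tcf4[, c("chrom", "start", "end", "name", "score", "summit")],
                   paths[["tcf4_peaks"]])
  write_tsv(res$expression, paths[["expression"]])
  write_tsv(de, paths[["de"]])
  write_tsv(res$genes, paths[["truth_genes"]])
  write_tsv(res$se_clusters, paths[["truth_se"]])
  write_tsv(res$enh[, c("id", "chrom", "start", "end", "intensity", "role", "gene_id")],
            paths[["truth_enhancers"]])
  params <- list(seed = seed, n_se_broad = n_se_broad, n_se_noBroad = n_se_noBroad,
                 n_broad_noSE = n_broad_noSE, n_typical = n_typical,
                 n_active_other = n_active_other, n_inactive = n_inactive,
                 se_intensity = se_intensity, typical_intensity = typical_intensity,
                 coloc_prob = coloc_prob, down_probs = as.list(down_probs),
                 sig_frac = sig_frac, total_tags = total_tags)
  jsonlite::write_json(params, paths[["params"]], auto_unbox = TRUE, digits = NA)
  truth <- list(genes = res$genes, se_clusters = res$se_clusters,
                enhancers = res$enh, tcf4_coloc = res$tcf4$coloc,
                chrom_sizes = res$chrom_sizes, total_tags = total_tags)
  invisible(list(truth = truth, paths = paths, params = params))
}

# 10-column narrowPeak; column 10 is the summit offset from start
write_narrowpeak <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.\t%s\t-1\t-1\t%d",
                     df$chrom, as.integer(df$start), as.integer(df$end),
                     df$name, format(df$score, trim = TRUE),
                     format(df$score, trim = TRUE),
                     as.integer(df$summit - df$start)),
             path)
  invisible(path)
}
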