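# Strand-aware TSS metaprofiles and per-category expression / knockdown
# response summaries.

#' Strand-aware TSS metaprofile
#'
#' For every TSS the coverage on `[pos - flank, pos + flank)` is extracted
#' and, for minus-strand genes, reversed so that positive offsets always
#' point into the gene body. Windows clipped at a chromosome edge contribute
#' only their covered bases and each base position is renormalized by the
#' number of regions covering it. Bin densities are the per-bp mean signal
#' within each bin, scaled to 10 million mapped tags
#' (`density * 1e7 / total_tags`), so units are signal per bp per region.
#'
#' @param track A [signal_track()].
#' @param tss Non-empty TSS table.
#' @param bin Bin width in bp (default 10).
#' @param flank Flank on either side of the TSS in bp (default 12000;
#'   must be divisible by `bin`).
#' @return Data.frame with `offset` (bin center relative to the TSS,
#'   negative = upstream) and `density`; attribute `n_regions`.
#' @export
tss_metaprofile <- function(track, tss, bin = 10, flank = 12000) {
  stopifnot(inherits(track, "signal_track"), bin > 0, flank > 0)
  if (flank %% bin != 0) stop("flank must be divisible by bin", call. = FALSE)
  if (nrow(tss) == 0L) stop("empty TSS set", call. = FALSE)
  width <- 2L * as.integer(flank)
  sums <- numeric(width)
  cnts <- numeric(width)
  for (k in seq_len(nrow(tss))) {
    ch <- tss$chrom[k]
    cov <- track$coverage[[ch]]
    if (is.null(cov)) stop(sprintf("chromosome %s not in signal track", ch), call. = FALSE)
    pos <- tss$pos[k]
    minus <- tss$strand[k] == "-"
    # window [pos-flank, pos+flank) for + genes; shifted one base for - genes
    # so that after reversal the TSS base occupies the same profile index
    lo <- if (minus) pos - flank + 1 else pos - flank   # 0-based inclusive
    g0 <- max(lo, 0)
    g1 <- min(lo + width, length(cov))                  # 0-based exclusive
    if (g1 <= g0) next
    offs <- (g0 - lo + 1L):(g1 - lo)       # 1-based window indices
    w <- numeric(width)
    m <- logical(width)
    w[offs] <- cov[(g0 + 1L):g1]
    m[offs] <- TRUE
    if (minus) {
      w <- rev(w)
      m <- rev(m)
    }
    sums <- sums + w
    cnts <- cnts + m
  }
  perbp <- ifelse(cnts > 0, sums / cnts, 0)
  dens <- colMeans(matrix(perbp, nrow = bin)) * 1e7 / track$total_tags
  out <- data.frame(offset = -flank + (seq_len(width %/% bin) - 0.5) * bin,
                    density = dens)
  attr(out, "n_regions") <- nrow(tss)
  out
}

#' Expression distribution per gene category
#'
#' @param categories Data.frame with `gene_id` and `category` (see
#'   [assign_gene_categories()]).
#' @param expression Expression data.frame with `rpkm_*` replicate columns.
#'   Categorized genes missing from the table are dropped with a warning.
#' @return Data.frame with one row per category: `n`, `mean`, `median`,
#'   `q25`, `q75` of mean RPKM and `mean_log2` / `median_log2` of
#'   `log2(RPKM + 1)`. Empty categories yield `n = 0` and `NA` statistics.
#' @export
category_expression_summary <- function(categories, expression) {
  rpkm <- mean_rpkm(expression)
  cats <- unique(categories$category)
  missing <- setdiff(categories$gene_id, names(rpkm))
  if (length(missing)) {
    warning(sprintf("%d categorized gene(s) without expression dropped", length(missing)))
    categories <- categories[!categories$gene_id %in% missing, , drop = FALSE]
  }
  rows <- lapply(cats, function(cc) {
    v <- rpkm[categories$gene_id[categories$category == cc]]
    if (!length(v)) {
      return(data.frame(category = cc, n = 0L, mean = NA_real_, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_, mean_log2 = NA_real_,
                        median_log2 = NA_real_, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    data.frame(category = cc, n = length(v), mean = mean(v), median = stats::median(v),
               q25 = q[1L], q75 = q[2L], mean_log2 = mean(log2(v + 1)),
               median_log2 = stats::median(log2(v + 1)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Student t-test p-value matrix
#'
#' Two-sided unpaired t-tests between all pairs of groups; pooled-variance
#' Student test by default, Welch via `var_equal = FALSE`. When both groups
#' are constant the p-value is 1 for equal means and 0 otherwise.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student test (default TRUE).
#' @return Symmetric matrix of p-values with unit diagonal.
#' @export
pairwise_student_t <- function(groups, var_equal = TRUE) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2", call. = FALSE)
  nm <- names(groups)
  m <- matrix(1, length(nm), length(nm), dimnames = list(nm, nm))
  if (length(nm) < 2L) return(m)
  for (i in seq_along(nm)[-length(nm)]) {
    for (j in (i + 1L):length(nm)) {
      a <- groups[[i]]; b <- groups[[j]]
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(a, b, var.equal = var_equal)$p.value
      }
      m[i, j] <- p
      m[j, i] <- p
    }
  }
  m
}

#' Knockdown response per gene category
#'
#' Summarizes a differential-expression table per category. Mean log2 fold
#' change and its standard error are computed over the genes with a
#' significant call (the replicate-supported changes); the fraction
#' downregulated is the share of the category's DE-measured genes that are
#' both significant and negative.
#'
#' @param de DE data.frame (see [read_tabular()] schema `de`).
#' @param categories Data.frame with `gene_id` and `category`.
#' @return Data.frame per category: `n_measured`, `n_significant`,
#'   `mean_log2fc`, `sem_log2fc` (NA when no significant gene),
#'   `frac_down`. Categories with no DE-measured gene get `NA` markers.
#' @export
kd_category_response <- function(de, categories) {
  merged <- merge(categories, de, by = "gene_id")
  cats <- unique(categories$category)
  rows <- lapply(cats, function(cc) {
    sub <- merged[merged$category == cc, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(category = cc, n_measured = 0L, n_significant = 0L,
                        mean_log2fc = NA_real_, sem_log2fc = NA_real_,
                        frac_down = NA_real_, stringsAsFactors = FALSE))
    }
    sig <- sub[sub$significant, , drop = FALSE]
    data.frame(category = cc,
               n_measured = nrow(sub),
               n_significant = nrow(sig),
               mean_log2fc = if (nrow(sig)) mean(sig$log2fc) else NA_real_,
               sem_log2fc = if (nrow(sig) > 1L) stats::sd(sig$log2fc) / sqrt(nrow(sig)) else NA_real_,
               frac_down = sum(sig$log2fc < 0) / nrow(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
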