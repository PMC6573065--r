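# Summit colocalization between factors and site categorization.
#
# Binding-site overlap between two factors is summit-based: a site of factor
# A overlaps factor B when some B summit lies within a fixed window (default
# 200 bp) of the A summit on the same chromosome. Comparisons use the top-N
# most significant sites per factor.

#' Keep the top-n peaks by significance score
#'
#' @param peaks Peak data.frame with a `score` column.
#' @param n Number of peaks to retain (default 5000). Ties at rank n are
#'   broken by ascending (chrom, start, end). When fewer than `n` peaks are
#'   available all are retained with a warning.
#' @return Peak data.frame sorted by score descending, at most `n` rows.
#' @export
top_n_by_score <- function(peaks, n = 5000) {
  stopifnot(n > 0)
  if (nrow(peaks) < n) {
    warning(sprintf("only %d peaks available (requested top %d); keeping all",
                    nrow(peaks), n))
  }
  o <- order(-peaks$score, peaks$chrom, peaks$start, peaks$end)
  out <- peaks[utils::head(o, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-chromosome count of B summits within +/- window of each A summit;
# sorted-vector sweep via findInterval (O(n log n))
summits_hit <- function(a_chrom, a_summit, b_chrom, b_summit, window) {
  hit <- logical(length(a_summit))
  for (ch in unique(a_chrom)) {
    ai <- which(a_chrom == ch)
    bs <- sort(b_summit[b_chrom == ch])
    if (!length(bs)) next
    s <- a_summit[ai]
    cnt <- findInterval(s + window, bs) - findInterval(s - window - 1, bs)
    hit[ai] <- cnt > 0L
  }
  hit
}

#' Percentage of A peaks with a B summit within a window
#'
#' @param A,B Peak data.frames (typically [top_n_by_score()] output) with
#'   `chrom` and `summit` columns.
#' @param window Maximal summit distance in bp counted as overlap
#'   (default 200, inclusive: summits exactly `window` apart overlap).
#' @return Percentage in `[0, 100]`; each A peak is counted once.
#' @export
summit_overlap_percent <- function(A, B, window = 200) {
  stopifnot(window >= 0)
  if (nrow(A) == 0L) stop("empty query peak set", call. = FALSE)
  if (nrow(B) == 0L) return(0)
  100 * mean(summits_hit(A$chrom, A$summit, B$chrom, B$summit, window))
}

#' Pairwise summit-overlap percentage matrix
#'
#' @param peak_sets Named list of peak data.frames.
#' @param window Summit distance window in bp (default 200).
#' @return Square matrix; entry `[A, B]` is the percentage of A peaks with a
#'   B summit within the window. The diagonal is 100 for non-empty sets.
#' @export
summit_overlap_matrix <- function(peak_sets, window = 200) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  nm <- names(peak_sets)
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) for (b in nm) {
    m[a, b] <- summit_overlap_percent(peak_sets[[a]], peak_sets[[b]], window)
  }
  m
}

#' Categorize binding sites by summit position
#'
#' Assigns each peak exactly one category with priority
#' TSS > SE > typical enhancer > other, decided by its summit: a summit
#' within `promoter_halfwidth` of any TSS (inclusive) is `TSS`; otherwise a
#' summit inside a super-enhancer region is `SE`; otherwise inside a typical
#' enhancer region `typical_enhancer`; otherwise `other_nonTSS`.
#'
#' @param peaks Peak data.frame with `chrom` and `summit`.
#' @param tss TSS table.
#' @param se,typical Interval data.frames of super / typical enhancer
#'   regions (0-based half-open; summit containment is `start <= summit < end`).
#' @param promoter_halfwidth Promoter half-width in bp (default 1500 bp;
#'   1000 reproduces the narrower promoter definition).
#' @return Data.frame with `name` (peak name or row index) and `category`.
#' @export
categorize_sites <- function(peaks, tss, se, typical, promoter_halfwidth = 1500) {
  stopifnot(promoter_halfwidth >= 0)
  n <- nrow(peaks)
  cat_v <- rep("other_nonTSS", n)
  in_regions <- function(regions) {
    hit <- logical(n)
    if (is.null(regions) || nrow(regions) == 0L) return(hit)
    for (ch in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == ch)
      ri <- regions$chrom == ch
      hit[pi] <- points_in_regions(peaks$summit[pi], regions$start[ri], regions$end[ri])
    }
    hit
  }
  near_tss <- summits_hit(peaks$chrom, peaks$summit, tss$chrom, tss$pos,
                          promoter_halfwidth)
  cat_v[in_regions(typical)] <- "typical_enhancer"
  cat_v[in_regions(se)] <- "SE"
  cat_v[near_tss] <- "TSS"
  data.frame(name = if ("name" %in% names(peaks)) peaks$name else as.character(seq_len(n)),
             category = cat_v, stringsAsFactors = FALSE)
}

#' Per-category summit-overlap matrices
#'
#' Categorizes each factor's peaks with [categorize_sites()], then, for each
#' category, recomputes the pairwise overlap with the query (row) factor
#' restricted to peaks of that category and the subject (column) factor kept
#' as its full top-N set.
#'
#' @inheritParams summit_overlap_matrix
#' @inheritParams categorize_sites
#' @return Named list of matrices, one per category (`TSS`, `SE`,
#'   `typical_enhancer`, `other_nonTSS`), plus `all` for the unrestricted
#'   sets. Entries are `NA` when the query factor has no peaks in the
#'   category.
#' @export
summit_overlap_by_category <- function(peak_sets, tss, se, typical,
                                       window = 200, promoter_halfwidth = 1500) {
  cats <- c("TSS", "SE", "typical_enhancer", "other_nonTSS")
  assign_cat <- lapply(peak_sets, categorize_sites, tss = tss, se = se,
                       typical = typical, promoter_halfwidth = promoter_halfwidth)
  out <- list(all = summit_overlap_matrix(peak_sets, window))
  nm <- names(peak_sets)
  for (cc in cats) {
    m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
    for (a in nm) {
      sub <- peak_sets[[a]][assign_cat[[a]]$category == cc, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (b in nm) m[a, b] <- summit_overlap_percent(sub, peak_sets[[b]], window)
    }
    out[[cc]] <- m
  }
  out
}
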