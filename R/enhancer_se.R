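# Enhancer definition and super-enhancer calling.
#
# Enhancers are Ep300 peaks that overlap H3K27ac regions. Constituents within
# 1 kb of a TSS are discarded, the rest are stitched when their inner gap is
# at most 12.5 kb, stitched regions are ranked by total Med1 signal, and the
# hockey-stick tangent cutoff on the scaled ranked curve splits super
# enhancers from typical enhancers.

#' Define enhancers as Ep300 peaks overlapping H3K27ac
#'
#' Keeps every Ep300 peak with at least 1 bp overlap with any H3K27ac
#' region; the enhancer footprint is the Ep300 peak interval. Half-open
#' abutment ([100,200) vs [200,300)) is not overlap.
#'
#' @param ep300 Peak data.frame (see [read_peaks_bed()]).
#' @param h3k27ac Interval data.frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @return Data.frame with `chrom`, `start`, `end`, `id` (deterministic
#'   `enh_#####` by coordinate order), `source_ep300`, `source_h3k27ac`
#'   (comma-collapsed overlapping region names).
#' @export
define_enhancers <- function(ep300, h3k27ac) {
  assert_intervals(ep300, "Ep300 peaks")
  assert_intervals(h3k27ac, "H3K27ac regions")
  if (nrow(ep300) == 0L || nrow(h3k27ac) == 0L) return(empty_enhancers())
  hits <- GenomicRanges::findOverlaps(gr_from_intervals(ep300),
                                      gr_from_intervals(h3k27ac))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (!length(q)) return(empty_enhancers())
  h3_name <- if ("name" %in% names(h3k27ac)) h3k27ac$name else sprintf("h3k27ac_%05d", seq_len(nrow(h3k27ac)))
  ep_name <- if ("name" %in% names(ep300)) ep300$name else sprintf("ep300_%05d", seq_len(nrow(ep300)))
  keep <- sort(unique(q))
  src <- vapply(keep, function(i) paste(h3_name[s[q == i]], collapse = ","), "")
  out <- data.frame(chrom = ep300$chrom[keep], start = ep300$start[keep],
                    end = ep300$end[keep], source_ep300 = ep_name[keep],
                    source_h3k27ac = src, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  out <- cbind(id = sprintf("enh_%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_enhancers <- function() {
  data.frame(id = character(), chrom = character(), start = numeric(),
             end = numeric(), source_ep300 = character(),
             source_h3k27ac = character(), stringsAsFactors = FALSE)
}

#' Drop enhancers overlapping TSS-proximal windows
#'
#' Removes every enhancer overlapping the half-open exclusion window
#' `[pos - window, pos + window)` of any TSS, so promoter-proximal signal is
#' not counted toward stitched enhancers.
#'
#' @param enhancers Interval data.frame.
#' @param tss TSS table (see [read_tss_table()]).
#' @param window Half-width of the exclusion window in bp (default 1000).
#' @return The filtered enhancer data.frame.
#' @export
exclude_tss_overlapping <- function(enhancers, tss, window = 1000) {
  stopifnot(window > 0)
  assert_intervals(enhancers, "enhancers")
  if (nrow(enhancers) == 0L || nrow(tss) == 0L) return(enhancers)
  win <- data.frame(chrom = tss$chrom, start = pmax(0, tss$pos - window),
                    end = tss$pos + window)
  hits <- GenomicRanges::findOverlaps(gr_from_intervals(enhancers),
                                      gr_from_intervals(win))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop)) enhancers[-drop, , drop = FALSE] else enhancers
}

#' Stitch enhancers within a maximum gap
#'
#' Merges, per chromosome, the transitive closure of the relation "inner gap
#' (next start minus previous end) <= `max_gap`"; overlapping constituents
#' are merged as well. Each stitched region spans its constituents;
#' singletons pass through.
#'
#' @param enhancers Interval data.frame with an `id` column (constituent
#'   identifiers; generated when missing).
#' @param max_gap Maximal inner gap in bp (default 12500).
#' @return Data.frame with `chrom`, `start`, `end`, `id`
#'   (`stitched_####`), `n_constituents`, `constituent_ids`
#'   (comma-collapsed in coordinate order), sorted by (chrom, start).
#' @export
stitch_enhancers <- function(enhancers, max_gap = 12500) {
  stopifnot(max_gap >= 0)
  assert_intervals(enhancers, "enhancers")
  if (!"id" %in% names(enhancers)) {
    enhancers$id <- sprintf("enh_%05d", seq_len(nrow(enhancers)))
  }
  if (nrow(enhancers) == 0L) {
    return(data.frame(id = character(), chrom = character(), start = numeric(),
                      end = numeric(), n_constituents = integer(),
                      constituent_ids = character(), stringsAsFactors = FALSE))
  }
  gr <- gr_from_intervals(enhancers)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                   start = GenomicRanges::start(red) - 1,
                   end = GenomicRanges::end(red), stringsAsFactors = FALSE)
  df$n_constituents <- lengths(revmap)
  df$constituent_ids <- vapply(seq_along(revmap), function(i) {
    idx <- revmap[[i]]
    idx <- idx[order(enhancers$start[idx], enhancers$end[idx])]
    paste(enhancers$id[idx], collapse = ",")
  }, "")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df <- cbind(id = sprintf("stitched_%04d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Total ChIP signal over regions
#'
#' Sums per-base coverage over each region (units: read-bases). When a
#' background track is supplied the background sum is subtracted and the
#' result floored at 0.
#'
#' @param regions Interval data.frame.
#' @param chip A [signal_track()].
#' @param background Optional [signal_track()] on the same coordinates.
#' @return Numeric vector of total signal per region.
#' @export
quantify_region_signal <- function(regions, chip, background = NULL) {
  assert_intervals(regions, "regions")
  stopifnot(inherits(chip, "signal_track"))
  region_sum <- function(track, chrom, start, end) {
    cov <- track$coverage[[chrom]]
    if (is.null(cov) || end > length(cov)) {
      stop(sprintf("region %s:%d-%d outside signal track", chrom, start, end),
           call. = FALSE)
    }
    sum(cov[(start + 1L):end])
  }
  vapply(seq_len(nrow(regions)), function(i) {
    s <- region_sum(chip, regions$chrom[i], regions$start[i], regions$end[i])
    if (!is.null(background)) {
      b <- region_sum(background, regions$chrom[i], regions$start[i], regions$end[i])
      s <- max(0, s - b)
    }
    s
  }, numeric(1))
}

#' Hockey-stick cutoff: split stitched enhancers into super and typical
#'
#' Regions are sorted by signal ascending; rank is scaled to `[0,1]` via
#' `i/(n-1)` and signal via `(y - min) / (max - min)`. The cutoff index is
#' the first position where the discrete forward slope of the scaled curve
#' exceeds 1 (the tangent-slope-1 point of the hockey-stick plot); regions
#' with signal strictly above the signal at that index are super enhancers,
#' so ties at the cutoff signal stay typical. Labels are invariant to
#' positive rescaling of the signal.
#'
#' @param stitched Data.frame of stitched regions containing `signal_col`,
#'   or a bare numeric signal vector.
#' @param signal_col Name of the signal column (default `"total_signal"`).
#' @return List of class `se_call` with `regions` (input plus `rank` by
#'   descending signal and logical `is_se`, sorted descending),
#'   `cutoff_signal`, `n_se`, `n_typical`, and `curve` (scaled rank/signal
#'   coordinates, ascending).
#' @export
call_se_cutoff <- function(stitched, signal_col = "total_signal") {
  if (is.numeric(stitched)) {
    stitched <- data.frame(id = sprintf("region_%04d", seq_along(stitched)),
                           total_signal = stitched, stringsAsFactors = FALSE)
    signal_col <- "total_signal"
  }
  y_raw <- stitched[[signal_col]]
  if (is.null(y_raw)) stop(sprintf("no column '%s' in stitched regions", signal_col), call. = FALSE)
  n <- length(y_raw)
  if (n < 3L) stop("need at least 3 stitched regions to place a cutoff", call. = FALSE)
  if (any(!is.finite(y_raw)) || any(y_raw < 0)) stop("signals must be finite and >= 0", call. = FALSE)
  y <- sort(y_raw)
  if (y[n] == y[1L]) {
    warning("all signals equal; no super enhancers called")
    cutoff <- Inf
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    ys <- (y - y[1L]) / (y[n] - y[1L])
    slope <- diff(ys) / diff(x)
    cross <- which(slope > 1)
    cutoff <- if (length(cross)) y[cross[1L]] else Inf
  }
  is_se <- y_raw > cutoff
  out <- stitched
  out$total_signal <- y_raw
  out$is_se <- is_se
  out <- out[order(-out$total_signal), , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  structure(list(regions = out,
                 cutoff_signal = cutoff,
                 n_se = sum(is_se),
                 n_typical = sum(!is_se),
                 curve = data.frame(rank_scaled = (seq_len(n) - 1) / (n - 1),
                                    signal = y,
                                    signal_scaled = if (y[n] > y[1L]) (y - y[1L]) / (y[n] - y[1L]) else rep(0, n))),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf("se_call: %d regions -> %d super enhancers, %d typical (cutoff signal %.4g)\n",
              x$n_se + x$n_typical, x$n_se, x$n_typical, x$cutoff_signal))
  invisible(x)
}
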