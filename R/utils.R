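# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so generators are
#' reproducible without clobbering the session RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Validate a 0-based half-open interval table
#' @noRd
assert_intervals <- function(df, what = "interval table") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s lacks column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom)) {
    stop(sprintf("%s has empty chromosome names", what), call. = FALSE)
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s has malformed coordinates at row %d (need 0 <= start < end)",
                 what, bad[1L]), call. = FALSE)
  }
  invisible(df)
}

#' data.frame (0-based half-open) -> GRanges (1-based closed)
#' @noRd
gr_from_intervals <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Deterministic interval ordering: chrom, start, end, then name if present
#' @noRd
order_intervals <- function(df) {
  if ("name" %in% names(df)) {
    order(df$chrom, df$start, df$end, df$name)
  } else if ("id" %in% names(df)) {
    order(df$chrom, df$start, df$end, df$id)
  } else {
    order(df$chrom, df$start, df$end)
  }
}

#' Is a point summit inside any region of a sorted, disjoint region set?
#'
#' Regions are 0-based half-open. Vectorized over positions of one chromosome.
#' @noRd
points_in_regions <- function(pos, starts, ends) {
  if (!length(starts)) return(rep(FALSE, length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  idx <- findInterval(pos, starts)
  hit <- idx >= 1L
  hit[hit] <- pos[hit] < ends[idx[hit]]
  hit
}

#' Write a data.frame as plain TSV with a header, no quoting
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
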