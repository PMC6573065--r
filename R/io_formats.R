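# Readers/writers for the genomic and tabular formats the pipeline consumes.
# All genomic coordinates in this package are 0-based half-open (BED
# convention); a TSS is a single 0-based base.

#' Read peaks from a BED / narrowPeak file
#'
#' Parses a tab-separated BED-like file into a peak table. Columns beyond the
#' first three are optional: column 4 is the peak name (auto-generated when
#' absent), column 5 the significance score (0 when absent or "."), and, for
#' `summit_mode = "column_offset"`, column 10 carries the narrowPeak summit
#' offset relative to `start` (-1 meaning unknown, which falls back to the
#' interval midpoint).
#'
#' @param path Path to an existing BED/narrowPeak file. `track`/browser and
#'   `#` comment lines are skipped.
#' @param summit_mode How the summit is derived: `"midpoint"` sets
#'   `summit = floor((start+end)/2)`; `"column_offset"` uses narrowPeak
#'   column 10.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit` (all coordinates 0-based; `start` inclusive, `end`
#'   exclusive; `summit` an absolute 0-based position inside the interval).
#' @export
read_peaks_bed <- function(path, summit_mode = c("midpoint", "column_offset")) {
  summit_mode <- match.arg(summit_mode)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("line %d: fewer than 3 tab-separated columns", lineno[which(nf < 3L)[1L]]),
         call. = FALSE)
  }
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  chrom <- get_col(1L)
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end | !nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("line %d: malformed coordinates (need 0 <= start < end)", lineno[bad[1L]]),
         call. = FALSE)
  }
  name <- get_col(4L)
  auto <- is.na(name) | !nzchar(name) | name == "."
  name[auto] <- sprintf("peak_%05d", which(auto))
  score <- suppressWarnings(as.numeric(get_col(5L)))
  score[is.na(score)] <- 0
  if (any(score < 0)) {
    stop(sprintf("line %d: negative score", lineno[which(score < 0)[1L]]), call. = FALSE)
  }
  if (summit_mode == "midpoint") {
    summit <- floor((start + end) / 2)
  } else {
    if (any(nf < 10L)) {
      stop(sprintf("line %d: summit_mode 'column_offset' needs 10 narrowPeak columns",
                   lineno[which(nf < 10L)[1L]]), call. = FALSE)
    }
    off <- suppressWarnings(as.numeric(get_col(10L)))
    if (anyNA(off)) {
      stop(sprintf("line %d: non-numeric summit offset", lineno[which(is.na(off))[1L]]),
           call. = FALSE)
    }
    summit <- ifelse(off < 0, floor((start + end) / 2), start + off)
    oob <- which(summit < start | summit >= end)
    if (length(oob)) {
      stop(sprintf("line %d: summit offset outside the interval", lineno[oob[1L]]),
           call. = FALSE)
    }
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, summit = summit, stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), score = numeric(), summit = numeric(),
             stringsAsFactors = FALSE)
}

#' Write intervals or peaks as BED
#'
#' Emits tab-separated 0-based half-open BED, sorted by (chrom, start, end,
#' name) so output is deterministic regardless of input order. Peak tables
#' round-trip through [read_peaks_bed()] with identical coordinates and
#' scores.
#'
#' @param records Data.frame with at least `chrom`, `start`, `end`; optional
#'   `name` and `score` columns are written as BED columns 4-5.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_intervals_bed <- function(records, path) {
  assert_intervals(records, "BED output")
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(records)) {
    cols <- c(cols, "name")
    if ("score" %in% names(records)) cols <- c(cols, "score")
  }
  df <- records[order_intervals(records), cols, drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(df)) {
    utils::write.table(format(df, trim = TRUE, scientific = FALSE, digits = 15),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path Path to a `chrom.sizes` file (chrom, length).
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome in chrom.sizes", call. = FALSE)
  if (any(df$size <= 0)) stop("non-positive chromosome length", call. = FALSE)
  stats::setNames(df$size, df$chrom)
}

#' Construct a signal track
#'
#' A signal track holds dense per-base read coverage per chromosome plus the
#' total mapped tag count used for normalization (the `1e7 / total_tags`
#' scaling of metaprofiles).
#'
#' @param coverage Named list of non-negative numeric vectors, one per
#'   chromosome, length = chromosome size.
#' @param total_tags Total mapped read count, > 0.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(coverage, total_tags) {
  stopifnot(is.list(coverage), !is.null(names(coverage)))
  for (ch in names(coverage)) {
    v <- coverage[[ch]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("coverage for %s must be finite and >= 0", ch), call. = FALSE)
    }
  }
  if (!is.numeric(total_tags) || length(total_tags) != 1L || total_tags <= 0) {
    stop("total_tags must be a single positive number", call. = FALSE)
  }
  structure(list(coverage = coverage, total_tags = total_tags),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), %.0f bp, total_tags = %g\n",
              length(x$coverage), sum(lengths(x$coverage)), x$total_tags))
  invisible(x)
}

#' Read a bedGraph file into a dense signal track
#'
#' Expands bedGraph records to per-base coverage. Uncovered bases are 0.
#' Records must lie within the chromosome bounds and must not overlap.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @param chrom_sizes Named numeric vector of chromosome lengths (see
#'   [read_chrom_sizes()]).
#' @param total_tags Total mapped tags for normalization, > 0.
#' @return A [signal_track()] covering every chromosome in `chrom_sizes`.
#' @export
read_signal_bedgraph <- function(path, chrom_sizes, total_tags) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  cov <- lapply(chrom_sizes, function(L) numeric(L))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4L)) stop("bedGraph record with fewer than 4 columns", call. = FALSE)
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.numeric(vapply(fields, `[[`, "", 2L))
    end <- as.numeric(vapply(fields, `[[`, "", 3L))
    value <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (anyNA(start) || anyNA(end) || anyNA(value)) stop("non-numeric bedGraph field", call. = FALSE)
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown)) stop(sprintf("bedGraph chromosome not in chrom_sizes: %s", unknown[1L]), call. = FALSE)
    if (any(start < 0 | start >= end)) stop("malformed bedGraph interval", call. = FALSE)
    if (any(value < 0 | !is.finite(value))) stop("bedGraph value must be finite and >= 0", call. = FALSE)
    if (any(end > chrom_sizes[chrom])) stop("bedGraph interval beyond chromosome length", call. = FALSE)
    o <- order(chrom, start)
    chrom <- chrom[o]; start <- start[o]; end <- end[o]; value <- value[o]
    same <- chrom[-1L] == chrom[-length(chrom)]
    if (any(same & start[-1L] < end[-length(end)])) {
      stop("overlapping bedGraph records", call. = FALSE)
    }
    for (i in seq_along(chrom)) {
      cov[[chrom[i]]][(start[i] + 1L):end[i]] <- value[i]
    }
  }
  signal_track(cov, total_tags)
}

#' Read a TSS annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `pos` (0-based TSS
#'   coordinate), `strand` (`+` or `-`).
#' @return Validated data.frame of TSS records.
#' @export
read_tss_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "chrom", "pos", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("TSS table lacks column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$gene_id)) {
    stop(sprintf("duplicate gene_id in TSS table: %s", df$gene_id[anyDuplicated(df$gene_id)]), call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  }
  df$pos <- as.numeric(df$pos)
  if (anyNA(df$pos) || any(df$pos < 0)) stop("TSS pos must be a non-negative coordinate", call. = FALSE)
  df[need]
}

#' Read a typed tabular input (AP-MS, expression, or differential expression)
#'
#' Schemas:
#' * `apms`: `protein_id` plus `mascot_<role>` / `empai_<role>` numeric
#'   columns. Blank or missing numeric cells mean "not detected" and are read
#'   as 0.
#' * `expression`: `gene_id` plus `rpkm_rep*` replicate columns; missing
#'   cells stay `NA` (absent measurement).
#' * `de`: `gene_id`, `log2fc`, `p_adj`, `significant` (logical or 0/1).
#'
#' @param path TSV file with a header row.
#' @param schema One of `"apms"`, `"expression"`, `"de"`.
#' @return A validated data.frame.
#' @export
read_tabular <- function(path, schema = c("apms", "expression", "de")) {
  schema <- match.arg(schema)
  df <- read_tsv(path)
  if (schema == "apms") {
    if (!"protein_id" %in% names(df)) stop("apms table lacks protein_id", call. = FALSE)
    meas <- grep("^(mascot|empai)_", names(df), value = TRUE)
    if (!length(meas)) stop("apms table lacks mascot_*/empai_* columns", call. = FALSE)
    for (cn in meas) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      v[is.na(v)] <- 0
      if (any(v < 0)) stop(sprintf("negative value in %s", cn), call. = FALSE)
      df[[cn]] <- v
    }
  } else if (schema == "expression") {
    if (!"gene_id" %in% names(df)) stop("expression table lacks gene_id", call. = FALSE)
    reps <- grep("^rpkm_", names(df), value = TRUE)
    if (!length(reps)) stop("expression table lacks rpkm_* replicate columns", call. = FALSE)
    for (cn in reps) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  } else {
    need <- c("gene_id", "log2fc", "p_adj", "significant")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop(sprintf("de table lacks column(s): %s", paste(miss, collapse = ", ")), call. = FALSE)
    df$log2fc <- as.numeric(df$log2fc)
    df$p_adj <- as.numeric(df$p_adj)
    df$significant <- as.logical(df$significant) | (suppressWarnings(as.numeric(df$significant)) %in% 1)
    df$significant[is.na(df$significant)] <- FALSE
  }
  df
}
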