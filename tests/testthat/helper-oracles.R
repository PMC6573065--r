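# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (quadratic scans, union-find, closed forms)
# and share no code with the package internals.

# exhaustive evaluation of the interactor rule conjunction for one protein
oracle_protein_passes <- function(row, cfg, is_cyto = FALSE) {
  pairs <- list(c("untreated", "control_exp1"), c("benzonase", "control_exp1"),
                c("etbr", "control_exp1"), c("benzonase_rep2", "control_exp2"))
  ok_ratio <- function(s, cc, fold) {
    if (cc == 0) s > 0 else s / cc >= fold
  }
  for (p in pairs) {
    ms <- row[[paste0("mascot_", p[1])]]; mc <- row[[paste0("mascot_", p[2])]]
    es <- row[[paste0("empai_", p[1])]]; ec <- row[[paste0("empai_", p[2])]]
    if (ms < cfg$mascot_min) return(FALSE)
    if (!ok_ratio(es, ec, cfg$empai_fold_min)) return(FALSE)
    if (!ok_ratio(ms, mc, cfg$mascot_fold_min)) return(FALSE)
  }
  if (is_cyto) return(FALSE)
  for (r in c("untreated", "benzonase", "etbr", "benzonase_rep2")) {
    if (row[[paste0("empai_", r)]] == 0) return(FALSE)
  }
  u <- row$empai_untreated
  for (tr in c("empai_benzonase", "empai_etbr")) {
    v <- row[[tr]]
    if (u > 0 && (v == 0 || u / v >= cfg$treatment_drop_fold)) return(FALSE)
  }
  TRUE
}

# union-find transitive closure of the pairwise gap relation
oracle_stitch <- function(df, max_gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && df$chrom[i] == df$chrom[j]) {
      gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
      if (gap <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = df$chrom[idx[1]], start = min(df$start[idx]),
               end = max(df$end[idx]), n_constituents = length(idx),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# quadratic all-pairs summit scan
oracle_overlap_percent <- function(A, B, window) {
  hit <- vapply(seq_len(nrow(A)), function(i) {
    any(B$chrom == A$chrom[i] & abs(B$summit - A$summit[i]) <= window)
  }, logical(1))
  100 * mean(hit)
}

# sort-and-slice top fraction (distinct widths assumed)
oracle_broad <- function(gene_id, width, top_frac) {
  pos <- width > 0
  k <- ceiling(top_frac * sum(pos))
  o <- order(-width[pos])
  sort(gene_id[pos][o[seq_len(k)]])
}

# exhaustive nearest-gene scan
oracle_nearest <- function(region, tss) {
  best <- NA_character_; bd <- Inf
  for (k in seq_len(nrow(tss))) {
    if (tss$chrom[k] != region$chrom) next
    p <- tss$pos[k]
    d <- if (p >= region$start && p < region$end) 0 else
      min(abs(p - region$start), abs(p - (region$end - 1)))
    if (d < bd || (d == bd && tss$gene_id[k] < best)) { bd <- d; best <- tss$gene_id[k] }
  }
  list(gene_id = best, distance = if (is.finite(bd)) bd else NA_real_)
}

# textbook pooled-variance two-sample t-test
oracle_student_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# random AP-MS table for property tests
random_apms <- function(n, seed) {
  set.seed(seed)
  roles <- c("untreated", "benzonase", "etbr", "benzonase_rep2",
             "control_exp1", "control_exp2")
  df <- data.frame(protein_id = sprintf("R%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (r in roles) {
    e <- round(rlnorm(n, log(0.5), 1) * rbinom(n, 1, 0.8), 4)
    df[[paste0("empai_", r)]] <- e
    df[[paste0("mascot_", r)]] <- ifelse(e > 0, round(runif(n, 10, 400)), 0)
  }
  df[c("protein_id", grep("mascot|empai", names(df), value = TRUE))]
}

random_peaks <- function(n, seed, chroms = c("chr1", "chr2"), span = 1e5) {
  set.seed(seed)
  start <- sort(sample.int(span, n, replace = TRUE))
  w <- sample(50:500, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + w, name = sprintf("p%04d", seq_len(n)),
             score = round(runif(n, 0, 1000), 1),
             summit = start + floor(w / 2), stringsAsFactors = FALSE)
}
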