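test_that("AP-MS generator is byte-deterministic and honors empty counts", {
  d1 <- file.path(tempdir(), "apms_a"); d2 <- file.path(tempdir(), "apms_b")
  g1 <- gen_apms_dataset(d1, seed = 42)
  g2 <- gen_apms_dataset(d2, seed = 42)
  expect_identical(readLines(g1$paths[["apms"]]), readLines(g2$paths[["apms"]]))
  expect_identical(readLines(g1$paths[["truth"]]), readLines(g2$paths[["truth"]]))
  g3 <- gen_apms_dataset(file.path(tempdir(), "apms_c"), seed = 43)
  expect_false(identical(readLines(g1$paths[["apms"]]), readLines(g3$paths[["apms"]])))

  g0 <- gen_apms_dataset(file.path(tempdir(), "apms_0"), seed = 1,
                         n_true = 0, n_chromdep = 0, n_contaminant = 0,
                         n_core = 0, n_cyto = 0)
  expect_equal(nrow(g0$apms), 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted AP-MS classes are recovered exactly by the filter", {
  g <- gen_apms_dataset(file.path(tempdir(), "apms_rec"), seed = 7)
  apms <- read_tabular(g$paths[["apms"]], "apms")
  calls <- call_interactors(apms, cyto_ids = readLines(g$paths[["cyto"]]))
  planted <- g$truth$protein_id[g$truth$class %in% c("true_interactor", "core_subunit") &
                                  g$truth$subtype == "none"]
  called <- calls$protein_id[calls$passed]
  expect_setequal(called, planted)
  cd <- g$truth$protein_id[g$truth$class == "chromatin_dependent"]
  expect_true(all(grepl("treatment_drop", calls$reasons[match(cd, calls$protein_id)])))
  cy <- g$truth$protein_id[g$truth$subtype == "cytoplasmic"]
  expect_true(all(grepl("cyto", calls$reasons[match(cy, calls$protein_id)])))
})

test_that("KD table plants exact stratified down-fractions", {
  cats <- data.frame(gene_id = sprintf("g%04d", 1:800),
                     category = rep(c("SE+Broad", "Typical"), each = 400))
  de <- gen_kd_table(cats, down_probs = c("SE+Broad" = 0.65, "Typical" = 0.2),
                     sig_frac = 0.9, seed = 3)
  r <- kd_category_response(de, cats)
  expect_equal(r$frac_down[r$category == "SE+Broad"], 0.65)
  expect_equal(r$frac_down[r$category == "Typical"], 0.2)
  expect_equal(r$n_significant, c(360, 360))
  de2 <- gen_kd_table(cats, down_probs = c("SE+Broad" = 0.65, "Typical" = 0.2),
                      sig_frac = 0.9, seed = 3)
  expect_identical(de, de2)
})

test_that("genome fixture is deterministic and consistent with its truth", {
  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  g1 <- gen_genome_fixture(d1, seed = 11)
  g2 <- gen_genome_fixture(d2, seed = 11)
  for (nm in names(g1$paths)) {
    expect_identical(readLines(g1$paths[[nm]]), readLines(g2$paths[[nm]]),
                     info = nm)
  }
  truth <- g1$truth
  # every planted constituent appears in the Ep300 peak file
  ep <- read_peaks_bed(g1$paths[["ep300"]], "column_offset")
  key <- function(df) paste(df$chrom, df$start, df$end)
  expect_true(all(key(truth$enhancers) %in% key(ep)))
  # TSS table matches the truth genes
  tss <- read_tss_table(g1$paths[["tss"]])
  expect_equal(tss$gene_id, truth$genes$gene_id)
  expect_equal(tss$pos, truth$genes$pos)
  # coverage exists under every planted SE constituent
  tr <- read_signal_bedgraph(g1$paths[["med1_bedgraph"]],
                             read_chrom_sizes(g1$paths[["chrom_sizes"]]), 1e6)
  se_enh <- truth$enhancers[truth$enhancers$role == "constituent_se", ]
  sig <- quantify_region_signal(se_enh, tr)
  expect_true(all(sig > 0))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("forced colocalization probability of 1 gives 100% summit overlap", {
  g <- gen_genome_fixture(file.path(tempdir(), "gen_coloc"), seed = 5,
                          coloc_prob = 1)
  med1 <- read_peaks_bed(g$paths[["med1_peaks"]], "column_offset")
  tcf4 <- read_peaks_bed(g$paths[["tcf4_peaks"]], "column_offset")
  expect_equal(summit_overlap_percent(tcf4, med1, 200), 100)
})

test_that("planted SE clusters are recovered by the enhancer pipeline", {
  g <- gen_genome_fixture(file.path(tempdir(), "gen_se"), seed = 17)
  ep <- read_peaks_bed(g$paths[["ep300"]], "column_offset")
  k27 <- read_peaks_bed(g$paths[["h3k27ac"]])
  tss <- read_tss_table(g$paths[["tss"]])
  tr <- read_signal_bedgraph(g$paths[["med1_bedgraph"]],
                             read_chrom_sizes(g$paths[["chrom_sizes"]]), 1e6)
  enh <- exclude_tss_overlapping(define_enhancers(ep, k27), tss, 1000)
  st <- stitch_enhancers(enh, 12500)
  st$total_signal <- quantify_region_signal(st, tr)
  sc <- call_se_cutoff(st)
  called <- sc$regions[sc$regions$is_se, ]
  truth_se <- g$truth$se_clusters
  expect_equal(nrow(called), nrow(truth_se))
  hit <- vapply(seq_len(nrow(called)), function(i)
    any(truth_se$chrom == called$chrom[i] & truth_se$start < called$end[i] &
          truth_se$end > called$start[i]), logical(1))
  expect_true(all(hit))
})
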