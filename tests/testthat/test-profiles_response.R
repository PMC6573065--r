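test_that("metaprofile of uniform coverage is the closed-form constant", {
  tr <- signal_track(list(chr1 = rep(3.2, 60000)), total_tags = 4e6)
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    pos = c(25000, 31000), strand = c("+", "-"))
  mp <- tss_metaprofile(tr, tss, bin = 10, flank = 12000)
  expect_equal(nrow(mp), 2400)
  expect_equal(mp$density, rep(3.2 * 1e7 / 4e6, 2400))
  expect_equal(attr(mp, "n_regions"), 2)
})

test_that("metaprofile averages regions and scales linearly", {
  cov <- list(chr1 = c(rep(2, 5000), rep(4, 5000)))
  tr <- signal_track(cov, 1e7)
  tss <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    pos = c(2500, 7500), strand = "+")
  mp <- tss_metaprofile(tr, tss, bin = 10, flank = 1000)
  expect_equal(mp$density, rep(3, 200))   # mean of 2 and 4, tag factor 1
  tr2 <- signal_track(list(chr1 = cov$chr1 * 5), 1e7)
  mp5 <- tss_metaprofile(tr2, tss, bin = 10, flank = 1000)
  expect_equal(mp5$density, 5 * mp$density)
})

test_that("minus-strand windows are flipped into gene orientation", {
  cov <- numeric(6000)
  cov[1001:1500] <- 4          # bases 1000..1499, upstream of a - strand TSS at 2000
  tr <- signal_track(list(chr1 = cov), 1e7)
  tss <- data.frame(gene_id = "g", chrom = "chr1", pos = 2000, strand = "-")
  mp <- tss_metaprofile(tr, tss, bin = 10, flank = 1000)
  expect_equal(sum(mp$density[mp$offset < 0]), 0)
  expect_gt(sum(mp$density[mp$offset > 0]), 0)
})

test_that("mirroring the genome and flipping strands leaves the profile unchanged", {
  set.seed(61)
  L <- 20000
  cov <- round(runif(L, 0, 3), 3)
  tss <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(5000, 9000, 14000), strand = c("+", "-", "+"))
  tr <- signal_track(list(chr1 = cov), 2e6)
  mp <- tss_metaprofile(tr, tss, bin = 10, flank = 2000)
  # mirrored genome: base p -> L-1-p; strands flip
  trm <- signal_track(list(chr1 = rev(cov)), 2e6)
  tssm <- tss
  tssm$pos <- L - 1 - tss$pos
  tssm$strand <- ifelse(tss$strand == "+", "-", "+")
  mpm <- tss_metaprofile(trm, tssm, bin = 10, flank = 2000)
  expect_equal(mpm$density, mp$density)
})

test_that("windows clipped at chromosome edges renormalize per covered base", {
  tr <- signal_track(list(chr1 = rep(2, 3000)), 1e7)
  tss <- data.frame(gene_id = c("edge", "mid"), chrom = "chr1",
                    pos = c(100, 1500), strand = "+")
  mp <- tss_metaprofile(tr, tss, bin = 10, flank = 1000)
  # every covered base sees coverage 2 regardless of how many regions cover it
  expect_equal(unique(mp$density), 2)
})

test_that("category expression summaries report distribution stats", {
  cats <- data.frame(gene_id = c("g1", "g2", "g3"),
                     category = c("SE+Broad", "SE+Broad", "Typical"))
  ex <- data.frame(gene_id = c("g1", "g2", "g3"),
                   rpkm_rep1 = c(4, 8, 1), rpkm_rep2 = c(4, 8, 1))
  s <- category_expression_summary(cats, ex)
  row <- s[s$category == "Typical", ]
  expect_equal(row$mean, 1)
  expect_equal(row$median, 1)
  expect_equal(s$n[s$category == "SE+Broad"], 2)
  expect_equal(s$mean[s$category == "SE+Broad"], 6)

  cats2 <- rbind(cats, data.frame(gene_id = "gx", category = "Broad-SE"))
  expect_warning(s2 <- category_expression_summary(cats2, ex), "without expression")
  expect_equal(s2$n[s2$category == "Broad-SE"], 0)
  expect_true(is.na(s2$mean[s2$category == "Broad-SE"]))
})

test_that("pairwise Student t matches the closed form and handles degeneracy", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3, 4, 5), c = c(10, 11, 12))
  m <- pairwise_student_t(g)
  expect_equal(m["a", "b"], oracle_student_p(g$a, g$b), tolerance = 1e-10)
  expect_equal(m["a", "c"], oracle_student_p(g$a, g$c), tolerance = 1e-10)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(pairwise_student_t(list(x = 1:3, y = 1:3))["x", "y"], 1)
  expect_equal(pairwise_student_t(list(x = c(2, 2), y = c(2, 2)))["x", "y"], 1)
  expect_equal(pairwise_student_t(list(x = c(2, 2), y = c(3, 3)))["x", "y"], 0)
  expect_error(pairwise_student_t(list(x = 1, y = 1:3)), "n >= 2")
})

test_that("a planted 2-sigma shift is detected in >= 95% of simulations", {
  hits <- 0
  for (s in 1:200) {
    set.seed(4000 + s)
    a <- rnorm(100)
    b <- rnorm(100, mean = 2)
    if (pairwise_student_t(list(a = a, b = b))["a", "b"] < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("knockdown summaries follow the significant-and-down convention", {
  cats <- data.frame(gene_id = sprintf("g%d", 1:4), category = "SE+Broad")
  de_all <- data.frame(gene_id = cats$gene_id, log2fc = -1, p_adj = 0.01,
                       significant = TRUE)
  r <- kd_category_response(de_all, cats)
  expect_equal(r$frac_down, 1)
  expect_equal(r$mean_log2fc, -1)

  de_ns <- de_all; de_ns$significant <- FALSE
  r2 <- kd_category_response(de_ns, cats)
  expect_equal(r2$frac_down, 0)
  expect_true(is.na(r2$mean_log2fc))

  cats3 <- rbind(cats, data.frame(gene_id = "zz", category = "Typical"))
  r3 <- kd_category_response(de_all, cats3)
  expect_true(is.na(r3$frac_down[r3$category == "Typical"]))

  # order invariance
  r4 <- kd_category_response(de_all[sample.int(4), ], cats)
  expect_equal(r4, r)
})
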