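# helper to build one AP-MS row quickly
apms_row <- function(id = "P1", ...) {
  roles <- c("untreated", "benzonase", "etbr", "benzonase_rep2",
             "control_exp1", "control_exp2")
  row <- data.frame(protein_id = id, stringsAsFactors = FALSE)
  for (r in roles) {
    row[[paste0("mascot_", r)]] <- 0
    row[[paste0("empai_", r)]] <- 0
  }
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

test_that("inclusion rules enforce Mascot floor and fold enrichments", {
  cfg <- filter_config()
  base <- apms_row(mascot_untreated = 120, empai_untreated = 1,
                   mascot_control_exp1 = 10, empai_control_exp1 = 0.1)
  expect_true(passes_inclusion(base, "untreated", "control_exp1", cfg)$pass)

  low <- base; low$mascot_untreated <- 49
  r <- passes_inclusion(low, "untreated", "control_exp1", cfg)
  expect_false(r$pass)
  expect_true("mascot_min" %in% r$reasons)

  # absent from the control counts as infinite enrichment
  zc <- apms_row(mascot_untreated = 80, empai_untreated = 0.3)
  r <- passes_inclusion(zc, "untreated", "control_exp1", cfg)
  expect_true(r$pass)

  # 0.5 / 0.11 ~ 4.55 < 5
  nf <- apms_row(mascot_untreated = 300, empai_untreated = 0.5,
                 mascot_control_exp1 = 10, empai_control_exp1 = 0.11)
  r <- passes_inclusion(nf, "untreated", "control_exp1", cfg)
  expect_false(r$pass)
  expect_identical(r$reasons, "empai_fold")

  expect_error(passes_inclusion(base, "untreated", "nope", cfg), "unknown role")
})

test_that("chromatin independence uses the two-fold drop boundary", {
  cfg <- filter_config()
  expect_false(chromatin_independent(1.0, 0.5, cfg))   # exactly two-fold lower
  expect_true(chromatin_independent(1.0, 0.51, cfg))
  expect_true(chromatin_independent(0, 0.2, cfg))      # no drop definable
  expect_false(chromatin_independent(0.8, 0, cfg))     # complete loss
  expect_error(chromatin_independent(-1, 1, cfg))
})

test_that("call_interactors matches exhaustive rule evaluation on a planted fixture", {
  cfg <- filter_config()
  rows <- rbind(
    apms_row("good1", mascot_untreated = 200, mascot_benzonase = 180,
             mascot_etbr = 150, mascot_benzonase_rep2 = 120,
             empai_untreated = 1.2, empai_benzonase = 1.0, empai_etbr = 1.1,
             empai_benzonase_rep2 = 0.9),
    apms_row("good2", mascot_untreated = 60, mascot_benzonase = 70,
             mascot_etbr = 55, mascot_benzonase_rep2 = 52,
             empai_untreated = 0.2, empai_benzonase = 0.25, empai_etbr = 0.2,
             empai_benzonase_rep2 = 0.15),
    apms_row("low_mascot", mascot_untreated = 45, mascot_benzonase = 180,
             mascot_etbr = 150, mascot_benzonase_rep2 = 120,
             empai_untreated = 1, empai_benzonase = 1, empai_etbr = 1,
             empai_benzonase_rep2 = 1),
    apms_row("chromdep", mascot_untreated = 300, mascot_benzonase = 100,
             mascot_etbr = 100, mascot_benzonase_rep2 = 90,
             empai_untreated = 1.5, empai_benzonase = 0.4, empai_etbr = 0.5,
             empai_benzonase_rep2 = 0.4),
    apms_row("missing_one", mascot_untreated = 300, mascot_benzonase = 200,
             mascot_etbr = 150, empai_untreated = 1, empai_benzonase = 1,
             empai_etbr = 1, empai_benzonase_rep2 = 0),
    apms_row("contam", mascot_untreated = 200, mascot_benzonase = 200,
             mascot_etbr = 200, mascot_benzonase_rep2 = 200,
             mascot_control_exp1 = 150, mascot_control_exp2 = 150,
             empai_untreated = 1, empai_benzonase = 1, empai_etbr = 1,
             empai_benzonase_rep2 = 1, empai_control_exp1 = 0.8,
             empai_control_exp2 = 0.9)
  )
  calls <- call_interactors(rows, cfg)
  expected <- vapply(seq_len(nrow(rows)), function(i)
    oracle_protein_passes(rows[i, ], cfg), logical(1))
  expect_equal(calls$passed[match(rows$protein_id, calls$protein_id)], expected)
  expect_equal(sort(calls$protein_id[calls$passed]), c("good1", "good2"))
  expect_match(calls$reasons[calls$protein_id == "chromdep"], "treatment_drop")
  expect_match(calls$reasons[calls$protein_id == "missing_one"], "presence_all_four")
  # sorted by mean emPAI descending
  expect_equal(calls$mean_empai, sort(calls$mean_empai, decreasing = TRUE))
})

test_that("call_interactors equals the oracle on random tables and partitions proteins", {
  cfg <- filter_config()
  for (s in 1:8) {
    tab <- random_apms(20, seed = 100 + s)
    calls <- call_interactors(tab, cfg)
    oracle <- vapply(seq_len(nrow(tab)), function(i)
      oracle_protein_passes(tab[i, ], cfg), logical(1))
    expect_equal(calls$passed[match(tab$protein_id, calls$protein_id)], oracle)
    # partition: every failing call carries at least one reason, no passing call any
    expect_true(all(nzchar(calls$reasons[!calls$passed])))
    expect_true(all(!nzchar(calls$reasons[calls$passed])))
  }
})

test_that("raising any threshold never enlarges the passing set", {
  for (s in 1:100) {
    tab <- random_apms(25, seed = 2000 + s)
    base <- call_interactors(tab, filter_config())
    base_pass <- base$protein_id[base$passed]
    tweaks <- list(filter_config(mascot_min = 80),
                   filter_config(empai_fold_min = 8),
                   filter_config(mascot_fold_min = 5),
                   filter_config(treatment_drop_fold = 1.5))
    for (cfg in tweaks) {
      p <- call_interactors(tab, cfg)
      expect_true(all(p$protein_id[p$passed] %in% base_pass))
    }
  }
})

test_that("core subtraction and endogenous overlap do set arithmetic", {
  calls <- data.frame(protein_id = sprintf("P%02d", 1:10), passed = TRUE,
                      mean_empai = 10:1 / 10, edge_category = 1L, reasons = "")
  sub <- subtract_core_subunits(calls, c("P01", "P02", "P03", "PXX"))
  expect_equal(sub$n_core_matched, 3)
  expect_equal(sub$n_in, sub$n_interactors + sub$n_core_matched)
  expect_equal(nrow(subtract_core_subunits(calls, character())$interactors), 10)
  expect_equal(nrow(subtract_core_subunits(calls, calls$protein_id)$interactors), 0)

  expect_equal(endogenous_overlap(c("a", "b"), c("c", "d"))$count, 0)
  expect_equal(endogenous_overlap(c("a", "b", "c"), c("c", "b", "a"))$count, 3)
})

test_that("edge thickness categories follow the emPAI breakpoints", {
  expect_equal(edge_weight_category(c(1.6, 1.5, 0.76, 0.75, 0.26, 0.25, 0)),
               c(4L, 3L, 3L, 2L, 2L, 1L, 1L))
  expect_error(edge_weight_category(-0.1))
})
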