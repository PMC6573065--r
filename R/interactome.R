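# Chromatin-independent Mediator interactor calling from AP-MS tables.
#
# Four FLAG-Mediator purifications (untreated, Benzonase, EtBr, and an
# independent Benzonase replicate) are each compared against the control
# purification of their experiment. A protein is called an interactor when it
# passes the inclusion rules in every purification, does not drop two-fold or
# more in emPAI under either chromatin-disrupting treatment, and is present
# (emPAI > 0) in all four Mediator samples.

MED_ROLES <- c("untreated", "benzonase", "etbr", "benzonase_rep2")
CONTROL_OF <- c(untreated = "control_exp1", benzonase = "control_exp1",
                etbr = "control_exp1", benzonase_rep2 = "control_exp2")
ALL_ROLES <- c(MED_ROLES, "control_exp1", "control_exp2")

#' Thresholds for the interactor filter
#'
#' @param mascot_min Minimal Mascot score in a Mediator purification
#'   (default 50).
#' @param empai_fold_min Minimal emPAI fold enrichment over the paired
#'   control (default 5).
#' @param mascot_fold_min Minimal Mascot fold enrichment over the paired
#'   control (default 3).
#' @param treatment_drop_fold Treated emPAI this-fold lower than untreated
#'   (or more) disqualifies a protein as chromatin-dependent (default 2).
#' @param require_all_purifications Require emPAI > 0 in all four Mediator
#'   purifications (default TRUE).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mascot_min = 50, empai_fold_min = 5,
                          mascot_fold_min = 3, treatment_drop_fold = 2,
                          require_all_purifications = TRUE) {
  cfg <- list(mascot_min = mascot_min, empai_fold_min = empai_fold_min,
              mascot_fold_min = mascot_fold_min,
              treatment_drop_fold = treatment_drop_fold,
              require_all_purifications = isTRUE(require_all_purifications))
  for (nm in c("mascot_min", "empai_fold_min", "mascot_fold_min", "treatment_drop_fold")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop(sprintf("%s must be a single positive number", nm), call. = FALSE)
    }
  }
  structure(cfg, class = "filter_config")
}

# enrichment ratio rule with the zero-control convention: absence from the
# control counts as infinite enrichment, but a protein absent from the sample
# cannot be enriched
ratio_passes <- function(sample, control, fold) {
  (control == 0 & sample > 0) | (control > 0 & sample / control >= fold)
}

#' Inclusion rules for one Mediator purification against its control
#'
#' Rules: (1) Mascot >= `mascot_min` in the Mediator sample; (2) emPAI fold
#' enrichment over the control >= `empai_fold_min`; (3) Mascot fold
#' enrichment >= `mascot_fold_min`; (4) not annotated
#' cytoskeletal/cytoplasmic.
#'
#' @param row One AP-MS row: a list/one-row data.frame with
#'   `mascot_<role>`/`empai_<role>` entries.
#' @param sample_role,control_role Role names, e.g. `"untreated"` and
#'   `"control_exp1"`.
#' @param cfg A [filter_config()].
#' @param is_cyto Whether the protein is annotated cytoskeletal/cytoplasmic.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   failed rule identifiers among `mascot_min`, `empai_fold`,
#'   `mascot_fold`, `cyto`).
#' @export
passes_inclusion <- function(row, sample_role, control_role,
                             cfg = filter_config(), is_cyto = FALSE) {
  for (role in c(sample_role, control_role)) {
    if (is.null(row[[paste0("mascot_", role)]]) || is.null(row[[paste0("empai_", role)]])) {
      stop(sprintf("unknown role: %s", role), call. = FALSE)
    }
  }
  ms <- row[[paste0("mascot_", sample_role)]]
  mc <- row[[paste0("mascot_", control_role)]]
  es <- row[[paste0("empai_", sample_role)]]
  ec <- row[[paste0("empai_", control_role)]]
  reasons <- character()
  if (ms < cfg$mascot_min) reasons <- c(reasons, "mascot_min")
  if (!ratio_passes(es, ec, cfg$empai_fold_min)) reasons <- c(reasons, "empai_fold")
  if (!ratio_passes(ms, mc, cfg$mascot_fold_min)) reasons <- c(reasons, "mascot_fold")
  if (isTRUE(is_cyto)) reasons <- c(reasons, "cyto")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Chromatin-independence of an interaction under treatment
#'
#' An interaction is chromatin-independent when the treated emPAI is not
#' two-fold lower or more than the untreated emPAI (fold configurable).
#' An untreated value of 0 defines no drop (TRUE); a treated value of 0 with
#' a positive untreated value is a complete drop (FALSE).
#'
#' @param empai_untreated,empai_treated emPAI scores, >= 0. Vectorized.
#' @param cfg A [filter_config()]; `treatment_drop_fold` is used.
#' @return Logical vector.
#' @export
chromatin_independent <- function(empai_untreated, empai_treated,
                                  cfg = filter_config()) {
  if (any(empai_untreated < 0) || any(empai_treated < 0)) {
    stop("emPAI scores must be >= 0", call. = FALSE)
  }
  ifelse(empai_untreated == 0, TRUE,
         ifelse(empai_treated == 0, FALSE,
                empai_untreated / empai_treated < cfg$treatment_drop_fold))
}

#' Call Mediator interactors from an AP-MS table
#'
#' Applies [passes_inclusion()] for each of the four Mediator purifications
#' against its experiment's control (`untreated`/`benzonase`/`etbr` vs
#' `control_exp1`; `benzonase_rep2` vs `control_exp2`), the
#' [chromatin_independent()] rule for Benzonase and EtBr treatment, and the
#' presence-in-all-four rule (emPAI > 0 in every Mediator purification).
#'
#' @param apms AP-MS data.frame (see [read_tabular()] schema `apms`) with
#'   `mascot_<role>` / `empai_<role>` columns for roles `untreated`,
#'   `benzonase`, `etbr`, `benzonase_rep2`, `control_exp1`, `control_exp2`.
#' @param cfg A [filter_config()].
#' @param cyto_ids Protein ids annotated cytoskeletal/cytoplasmic (rule 4).
#'   An optional logical column `is_cyto` in `apms` is OR-ed in.
#' @return Data.frame sorted by `mean_empai` (mean emPAI over the four
#'   Mediator purifications) descending, with columns `protein_id`,
#'   `passed`, `mean_empai`, `edge_category`, `reasons`
#'   (";"-collapsed failed-rule identifiers, `""` when passed).
#' @export
call_interactors <- function(apms, cfg = filter_config(), cyto_ids = character()) {
  need <- c(paste0("mascot_", ALL_ROLES), paste0("empai_", ALL_ROLES))
  miss <- setdiff(need, names(apms))
  if (length(miss)) {
    stop(sprintf("apms table lacks role column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(apms)
  cyto <- apms$protein_id %in% cyto_ids
  if ("is_cyto" %in% names(apms)) cyto <- cyto | as.logical(apms$is_cyto)
  reasons <- character(n)
  passed <- logical(n)
  for (i in seq_len(n)) {
    row <- apms[i, ]
    rs <- character()
    for (role in MED_ROLES) {
      pi <- passes_inclusion(row, role, CONTROL_OF[[role]], cfg, is_cyto = FALSE)
      if (!pi$pass) rs <- c(rs, paste0(pi$reasons, ":", role))
    }
    if (cyto[i]) rs <- c(rs, "cyto")
    if (cfg$require_all_purifications &&
        any(vapply(MED_ROLES, function(r) row[[paste0("empai_", r)]] == 0, TRUE))) {
      rs <- c(rs, "presence_all_four")
    }
    if (!chromatin_independent(row$empai_untreated, row$empai_benzonase, cfg)) {
      rs <- c(rs, "treatment_drop:benzonase")
    }
    if (!chromatin_independent(row$empai_untreated, row$empai_etbr, cfg)) {
      rs <- c(rs, "treatment_drop:etbr")
    }
    reasons[i] <- paste(rs, collapse = ";")
    passed[i] <- length(rs) == 0L
  }
  mean_empai <- rowMeans(apms[, paste0("empai_", MED_ROLES)])
  out <- data.frame(protein_id = apms$protein_id, passed = passed,
                    mean_empai = mean_empai,
                    edge_category = edge_weight_category(mean_empai),
                    reasons = reasons, stringsAsFactors = FALSE)
  out[order(-out$mean_empai, out$protein_id), , drop = FALSE]
}

#' Remove core Mediator subunits from a passing call set
#'
#' @param calls Data.frame of passing interactor calls (see
#'   [call_interactors()]); rows with `passed == FALSE` are dropped first.
#' @param core_ids Character vector of core Mediator subunit protein ids.
#' @return List with `interactors` (calls not matching `core_ids`), `core`
#'   (matching calls), and counts `n_in`, `n_core_matched`, `n_interactors`
#'   satisfying `n_in == n_interactors + n_core_matched`.
#' @export
subtract_core_subunits <- function(calls, core_ids) {
  if ("passed" %in% names(calls)) calls <- calls[calls$passed, , drop = FALSE]
  is_core <- calls$protein_id %in% core_ids
  list(interactors = calls[!is_core, , drop = FALSE],
       core = calls[is_core, , drop = FALSE],
       n_in = nrow(calls),
       n_core_matched = sum(is_core),
       n_interactors = sum(!is_core))
}

#' Edge-thickness category from mean emPAI
#'
#' Categories for network rendering: 4 (thickest) for emPAI > 1.5, 3 for
#' 0.75 < emPAI <= 1.5, 2 for 0.25 < emPAI <= 0.75, 1 (thinnest) for
#' emPAI <= 0.25.
#'
#' @param mean_empai Non-negative numeric vector.
#' @return Integer vector in 1..4.
#' @export
edge_weight_category <- function(mean_empai) {
  if (any(mean_empai < 0)) stop("mean_empai must be >= 0", call. = FALSE)
  ifelse(mean_empai > 1.5, 4L,
         ifelse(mean_empai > 0.75, 3L,
                ifelse(mean_empai > 0.25, 2L, 1L)))
}

#' Overlap between the FLAG-interactor list and an endogenous IP list
#'
#' @param flag_interactors,endogenous_calls Character vectors of protein ids
#'   in the same namespace.
#' @return List with `count` and `ids` (the sorted intersection).
#' @export
endogenous_overlap <- function(flag_interactors, endogenous_calls) {
  ids <- sort(intersect(flag_interactors, endogenous_calls))
  list(count = length(ids), ids = ids)
}

#' Write interactor calls and a network edge table
#'
#' @param calls Output of [call_interactors()].
#' @param out_dir Directory for `interactors.tsv` and `edges.tsv` (edge list
#'   `MED-complex -> protein` with the emPAI weight category, passing
#'   proteins only).
#' @return Named character vector of written paths, invisibly.
#' @export
write_interactor_tables <- function(calls, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "interactors.tsv")
  write_tsv(calls, p1)
  pass <- calls[calls$passed, , drop = FALSE]
  edges <- data.frame(source = rep("MED-complex", nrow(pass)),
                      target = pass$protein_id,
                      weight_category = pass$edge_category,
                      stringsAsFactors = FALSE)
  p2 <- file.path(out_dir, "edges.tsv")
  write_tsv(edges, p2)
  invisible(c(interactors = p1, edges = p2))
}
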