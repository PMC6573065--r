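# Seeded AP-MS table generator with recorded ground truth.
#
# Emulates the purification design: four Mediator purifications (untreated,
# Benzonase, EtBr, independent Benzonase replicate) and one control per
# experiment. Protein classes:
#   true_interactor / core_subunit — present in all four Mediator samples,
#     absent from controls, treatment ratio ~ 1;
#   chromatin_dependent — specific for Mediator samples but drops >= drop_fold
#     in emPAI under both treatments;
#   contaminant — comparable abundance in controls (fails enrichment), some
#     stochastically absent from Mediator samples; a configurable number of
#     cytoplasmic-flagged proteins look like true interactors but are removed
#     by the annotation rule.

#' Generate a synthetic AP-MS dataset with planted truth
#'
#' Writes `apms.tsv` (schema `apms`), annotation id lists
#' (`core_subunits.txt`, `cyto_proteins.txt`, `endogenous_interactors.txt`),
#' `truth.tsv`, and `params.json` into `out_dir`. Identical seeds produce
#' byte-identical files. Effect sizes are chosen so that, at the defaults,
#' [call_interactors()] recovers exactly the planted
#' `true_interactor`/`core_subunit` set and every `chromatin_dependent`
#' protein fails with a `treatment_drop` reason.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Mandatory RNG seed.
#' @param n_true,n_chromdep,n_contaminant,n_core Class sizes (defaults
#'   50/10/40/26).
#' @param n_cyto Number of cytoplasmic-flagged proteins that would otherwise
#'   pass (default 5; planted as contaminants).
#' @param empai_meanlog,empai_sdlog Log-normal emPAI abundance parameters.
#' @param drop_fold Minimal treated-vs-untreated emPAI drop planted for
#'   chromatin-dependent proteins (default 3).
#' @param mascot_base,mascot_per_empai Mascot score model for detected
#'   proteins: `round(base + empai * per_empai * noise)`.
#' @param endogenous_frac Fraction of true interactors recovered in the
#'   emitted endogenous-IP list (default 0.6).
#' @return Invisibly, a list with `truth` (protein_id, class, subtype),
#'   `apms` (the table), `paths`, and `params`.
#' @export
gen_apms_dataset <- function(out_dir, seed,
                             n_true = 50, n_chromdep = 10, n_contaminant = 40,
                             n_core = 26, n_cyto = 5,
                             empai_meanlog = log(0.7), empai_sdlog = 0.5,
                             drop_fold = 3,
                             mascot_base = 60, mascot_per_empai = 250,
                             endogenous_frac = 0.6) {
  stopifnot(n_true >= 0, n_chromdep >= 0, n_contaminant >= 0, n_core >= 0,
            n_cyto >= 0, empai_sdlog > 0, drop_fold >= 2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_true + n_chromdep + n_contaminant + n_core + n_cyto
  res <- with_seed(seed, {
    class_v <- sample(rep(c("true_interactor", "chromatin_dependent",
                            "contaminant", "core_subunit", "contaminant_cyto"),
                          c(n_true, n_chromdep, n_contaminant, n_core, n_cyto)))
    ids <- sprintf("P%04d", seq_len(n))
    emp <- matrix(0, n, length(ALL_ROLES), dimnames = list(ids, ALL_ROLES))
    for (i in seq_len(n)) {
      a <- stats::rlnorm(1, empai_meanlog, empai_sdlog)
      cl <- class_v[i]
      if (cl %in% c("true_interactor", "core_subunit", "contaminant_cyto")) {
        # treated/untreated ratio bounded away from the 2-fold drop rule
        emp[i, "untreated"] <- a
        emp[i, c("benzonase", "etbr", "benzonase_rep2")] <- a * stats::runif(3, 0.8, 1.3)
      } else if (cl == "chromatin_dependent") {
        emp[i, "untreated"] <- a
        emp[i, c("benzonase", "etbr", "benzonase_rep2")] <-
          a / (drop_fold * stats::runif(3, 1.0, 1.5))
      } else { # contaminant: comparable in controls, ratio to control < 2x
        ctl <- a * stats::runif(2, 0.8, 1.2)
        med <- a * stats::runif(4, 0.4, 1.6)
        med[stats::runif(4) < 0.3] <- 0
        emp[i, c("control_exp1", "control_exp2")] <- ctl
        emp[i, MED_ROLES] <- med
      }
    }
    emp <- round(emp, 4)
    mas <- matrix(0, n, length(ALL_ROLES), dimnames = list(ids, ALL_ROLES))
    detected <- emp > 0
    base <- ifelse(class_v %in% c("contaminant"), 20, mascot_base)
    for (r in ALL_ROLES) {
      d <- detected[, r]
      mas[d, r] <- round(base[d] + emp[d, r] * mascot_per_empai * stats::runif(sum(d), 0.8, 1.2))
    }
    truth <- data.frame(protein_id = ids,
                        class = sub("_cyto$", "", class_v),
                        subtype = ifelse(class_v == "contaminant_cyto",
                                         "cytoplasmic", "none"),
                        stringsAsFactors = FALSE)
    endo <- sort(c(sample(ids[class_v == "true_interactor"],
                          round(endogenous_frac * n_true)),
                   ids[class_v == "core_subunit"]))
    list(emp = emp, mas = mas, truth = truth, endo = endo)
  })
  apms <- data.frame(protein_id = rownames(res$emp), stringsAsFactors = FALSE)
  for (r in ALL_ROLES) apms[[paste0("mascot_", r)]] <- res$mas[, r]
  for (r in ALL_ROLES) apms[[paste0("empai_", r)]] <- res$emp[, r]
  if (n == 0L) {
    apms <- data.frame(protein_id = character(), stringsAsFactors = FALSE)
    for (r in ALL_ROLES) apms[[paste0("mascot_", r)]] <- numeric()
    for (r in ALL_ROLES) apms[[paste0("empai_", r)]] <- numeric()
  }
  paths <- c(apms = file.path(out_dir, "apms.tsv"),
             core = file.path(out_dir, "core_subunits.txt"),
             cyto = file.path(out_dir, "cyto_proteins.txt"),
             endogenous = file.path(out_dir, "endogenous_interactors.txt"),
             truth = file.path(out_dir, "truth.tsv"),
             params = file.path(out_dir, "params.json"))
  write_tsv(apms, paths[["apms"]])
  writeLines(res$truth$protein_id[res$truth$class == "core_subunit"], paths[["core"]])
  writeLines(res$truth$protein_id[res$truth$subtype == "cytoplasmic"], paths[["cyto"]])
  writeLines(res$endo, paths[["endogenous"]])
  write_tsv(res$truth, paths[["truth"]])
  params <- list(seed = seed, n_true = n_true, n_chromdep = n_chromdep,
                 n_contaminant = n_contaminant, n_core = n_core,
                 n_cyto = n_cyto, empai_meanlog = empai_meanlog,
                 empai_sdlog = empai_sdlog, drop_fold = drop_fold,
                 mascot_base = mascot_base, mascot_per_empai = mascot_per_empai,
                 endogenous_frac = endogenous_frac)
  jsonlite::write_json(params, paths[["params"]], auto_unbox = TRUE, digits = NA)
  invisible(list(truth = res$truth, apms = apms,
                 endogenous_ids = res$endo, paths = paths, params = params))
}

#' Generate a knockdown DE table with planted per-category down-fractions
#'
#' Significance and down-regulation flags are planted by stratified
#' assignment: per category, `round(sig_frac * n)` genes are significant and
#' `round(p_down * n)` of them get a negative log2 fold change (membership
#' randomized, counts exact), so the realized down-fraction among measured
#' genes equals the planted probability up to rounding at any seed.
#'
#' @param categories Data.frame with `gene_id` and `category`.
#' @param down_probs Named numeric vector: planted probability that a gene
#'   of the category is significant-and-downregulated. Categories missing
#'   from the vector fall back to `default_down`.
#' @param sig_frac Fraction of genes per category with a significant call
#'   (default 0.9); must satisfy `down_probs <= sig_frac`.
#' @param default_down Fallback down-probability (default 0.15).
#' @param seed RNG seed.
#' @return DE data.frame (`gene_id`, `log2fc`, `p_adj`, `significant`).
#' @export
gen_kd_table <- function(categories,
                         down_probs = c("SE+Broad" = 0.65, "SE-Broad" = 0.40,
                                        "Broad-SE" = 0.20, "Typical" = 0.20),
                         sig_frac = 0.9, default_down = 0.15, seed) {
  stopifnot(sig_frac > 0, sig_frac <= 1, all(down_probs >= 0),
            all(down_probs <= sig_frac))
  with_seed(seed, {
    out <- lapply(unique(categories$category), function(cc) {
      g <- categories$gene_id[categories$category == cc]
      nn <- length(g)
      p <- if (cc %in% names(down_probs)) down_probs[[cc]] else default_down
      n_sig <- round(sig_frac * nn)
      n_down <- min(round(p * nn), n_sig)
      g <- sample(g)
      sig <- seq_len(nn) <= n_sig
      down <- seq_len(nn) <= n_down         # down genes are the first n_down of the significant block
      lfc <- numeric(nn)
      lfc[down] <- -stats::runif(sum(down), 0.3, 2.5)
      lfc[sig & !down] <- stats::runif(sum(sig & !down), 0.1, 1.5)
      lfc[!sig] <- stats::runif(sum(!sig), -0.3, 0.3)
      padj <- numeric(nn)
      padj[sig] <- stats::runif(sum(sig), 1e-6, 0.04)
      padj[!sig] <- stats::runif(sum(!sig), 0.06, 0.9)
      data.frame(gene_id = g, log2fc = round(lfc, 4), p_adj = signif(padj, 4),
                 significant = sig, stringsAsFactors = FALSE)
    })
    de <- do.call(rbind, out)
    de[order(de$gene_id), , drop = FALSE]
  })
}
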