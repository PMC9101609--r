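#' Default pipeline configuration
#'
#' Thresholds follow the conventional analysis settings: translation-group
#' significance at `p <= 1e-5`, protein fold-change filter 1.2 with
#' BH-adjusted `p <= 0.05` and at least 3 peptides per replicate, 50-nt NMD
#' boundary rule. Assay defaults plant a mutant cell state with reduced
#' respiration, higher glycolysis dependence and higher PFKFB3-inhibitor
#' sensitivity.
#'
#' @param seed Master seed.
#' @param n_genes,depth Simulation size (kept modest so the demo pipeline
#'   runs in seconds).
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, n_genes = 150L, depth = 3e5) {
  list(
    seed = as.integer(seed),
    thresholds = list(te_p = 1e-5, protein_fc = 1.2, protein_adj_p = 0.05,
                      peptide_min = 3L, nmd_rule_nt = 50L),
    round_mode = "half_even",
    sim = list(n_genes = as.integer(n_genes), depth = depth,
               frac_groupA = 0.35, te_shift_log2 = 1,
               frac_frameshift = 69 / 113, proteome_link_prob = 0.5),
    assays = list(
      respiration = list(WT = list(non_mito = 10, basal = 90, atp_linked = 60,
                                   maximal = 140),
                         MUT = list(non_mito = 10, basal = 63, atp_linked = 42,
                                    maximal = 98),
                         noise_sd = 2),
      ic50 = list(WT = 2.4, MUT = 1.7, hill = 1.5, noise_sd = 0.05),
      percent_change = list(sg_deprivation = list(WT = 0.37, MUT = 0.58),
                            galactose = list(WT = 0.63, MUT = 0.77),
                            glucose_uptake = 0.40,
                            n_reps = 3L, noise_sd = 0.05)
    )
  )
}

# internal: run one stage, aborting with its name on failure
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> junction quantification -> splice annotation ->
#' translation-efficiency classification -> proteome integration -> metabolic
#' assays, writing every stage's table under `outdir` and a machine-readable
#' `summary.json`. Deterministic given the seed: a rerun with the same
#' configuration reproduces every file byte for byte. Stages communicate
#' only through the files they declare.
#'
#' @param config A configuration list (see [pipeline_config()]) or the path
#'   to a JSON file holding one; partial configs are completed with the
#'   defaults.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- utils::modifyList(pipeline_config(), config)
  th <- config$thresholds
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  scfg <- .stage("config", do.call(sim_config, c(list(seed = config$seed),
                                                 config$sim)))
  ann <- .stage("simulate_annotation", {
    ann <- make_annotation(scfg)
    write_annotation(ann, file.path(outdir, "annotation"))
    ann
  })
  sim <- .stage("simulate_counts", {
    sim <- simulate_fraction_counts(scfg, ann)
    write_junction_counts(sim$matrix, file.path(outdir, "counts.tsv"))
    write_truth(sim$truth, file.path(outdir, "counts_truth.tsv"))
    sim
  })
  m <- .stage("junction_quant", {
    m <- load_junction_counts(file.path(outdir, "counts.tsv"))
    m <- normalize_counts(m)
    dje <- differential_junction_expression(m)
    write.table(dje, file.path(outdir, "junctions_diff.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    m
  })
  dje <- read.delim(file.path(outdir, "junctions_diff.tsv"),
                    stringsAsFactors = FALSE)
  frame_pred <- .stage("splice_annotation", {
    models <- read_annotation(file.path(outdir, "annotation", "transcripts.bed"),
                              file.path(outdir, "annotation", "genome.fa"))
    canonical <- models[grepl("\\.canonical$", names(models))]
    junctions <- read.delim(file.path(outdir, "annotation", "junctions.tsv"),
                            stringsAsFactors = FALSE)
    genome <- Biostrings::readDNAStringSet(
      file.path(outdir, "annotation", "genome.fa"))
    fp <- annotate_junctions(junctions, canonical, genome,
                             rule_nt = th$nmd_rule_nt)
    write.table(fp, file.path(outdir, "splice_annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    fp
  })
  te <- .stage("translation_efficiency", {
    te <- classify_groups(te_table(m), p_threshold = th$te_p)
    write.table(te, file.path(outdir, "te.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    te
  })
  gf <- group_fractions(te)
  prot <- .stage("proteome", {
    truth <- read.delim(file.path(outdir, "counts_truth.tsv"),
                        stringsAsFactors = FALSE)
    prot <- simulate_proteome(scfg, truth)
    write.table(prot$quant, file.path(outdir, "proteome.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    write_truth(prot$truth, file.path(outdir, "proteome_truth.tsv"))
    dp <- differential_abundance(prot$quant, fc_threshold = th$protein_fc,
                                 alpha = th$protein_adj_p,
                                 min_peptides = th$peptide_min)
    write.table(dp, file.path(outdir, "proteome_diff.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    dp
  })
  aberrant_genes <- unique(dje$gene_id[dje$pass])
  ov_splice <- .stage("overlaps", overlap_splice_protein(
    aberrant_genes, prot, round_mode = config$round_mode))
  strata <- stratify_fc_by_splice_category(prot, frame_pred)

  assays <- .stage("metabolic_assays", {
    acfg <- config$assays
    resp <- lapply(c(WT = "WT", MUT = "MUT"), function(g) {
      tr <- do.call(respiration_truth, as.list(acfg$respiration[[g]]))
      trace <- simulate_ocr_trace(tr, noise_sd = acfg$respiration$noise_sd,
                                  seed = config$seed + (g == "MUT"))
      rp <- respiration_params(trace)
      rp[c("non_mito", "basal", "atp_linked", "proton_leak", "maximal",
           "reserve")]
    })
    fits <- lapply(c(WT = "WT", MUT = "MUT"), function(g) {
      dr <- simulate_dose_response(acfg$ic50[[g]], hill = acfg$ic50$hill,
                                   noise_sd = acfg$ic50$noise_sd,
                                   seed = config$seed + 10L + (g == "MUT"))
      fit <- fit_4pl(dr)
      list(ic50 = fit$ic50, hill = fit$hill)
    })
    pc <- withr::with_seed(.stream_seed(config$seed, "pipeline"), {
      pcc <- acfg$percent_change
      gen <- function(mu) mu * (1 + rnorm(pcc$n_reps, 0, pcc$noise_sd))
      out <- list()
      for (cond in c("sg_deprivation", "galactose")) {
        out[[cond]] <- lapply(c(WT = "WT", MUT = "MUT"), function(g) {
          res <- percent_change(gen(1), gen(1 - pcc[[cond]][[g]]),
                                direction = "decrease")
          list(percent = res$percent, p = res$p)
        })
      }
      wt_upt <- glucose_uptake_per_cell(gen(1) * 1000, rep(100, pcc$n_reps))
      mut_upt <- glucose_uptake_per_cell(gen(1 + pcc$glucose_uptake) * 1000,
                                         rep(100, pcc$n_reps))
      res <- percent_change(wt_upt$per_cell, mut_upt$per_cell,
                            direction = "increase")
      out$glucose_uptake <- list(percent = res$percent, p = res$p)
      out
    })
    list(respiration = resp, ic50 = fits, percent_change = pc)
  })

  summary <- list(
    seed = config$seed,
    n_genes = scfg$n_genes,
    translation_groups = list(pctA = unname(gf["pctA"]),
                              pctB = unname(gf["pctB"]),
                              n_classified = sum(te$group != "unclassified")),
    differential_junctions = list(n_tested = nrow(dje),
                                  n_pass = sum(dje$pass)),
    frame_counts = as.list(table(frame_pred$frame)),
    nmd_counts = as.list(table(frame_pred$nmd)),
    proteome = list(n_proteins = nrow(prot),
                    n_under = sum(prot$call == "underrepresented"),
                    n_over = sum(prot$call == "overrepresented"),
                    n_unique_WT = sum(prot$call == "unique_WT"),
                    n_unique_MUT = sum(prot$call == "unique_MUT")),
    splice_protein_overlap = ov_splice,
    fc_by_splice_category = strata,
    assays = assays
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
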