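#' Simulate a label-free proteome quantification table with planted truth
#'
#' One protein per gene of the splicing truth table. Replicate intensities
#' are log-normal around a per-protein baseline; genes that are aberrantly
#' spliced with a predicted NMD-sensitive junction receive a planted
#' down-fold (`planted_fc`, default 1/1.5) with probability
#' `config$proteome_link_prob`, linking transcript decay to reduced protein
#' output. A small share of proteins is planted with a peptide count below 3
#' in at least one replicate (to exercise the quantification filter) and
#' another share is detected in only one condition (peptides >= 3 in all
#' replicates of that condition, 0 in the other).
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_fraction_counts()] (columns
#'   `gene_id`, `nmd`).
#' @param n_reps Replicates per condition (default 3).
#' @param planted_fc Planted MUT/WT fold change for linked proteins
#'   (default 1/1.5).
#' @param noise_sdlog Replicate log-intensity standard deviation (natural
#'   log; default 0.05, typical of well-behaved label-free replicates).
#' @param frac_lowpep Share of proteins planted to fail the peptide filter.
#' @param frac_unique Share of proteins detected in one condition only.
#' @return List with `quant` (wide table: `protein_id`, `gene_id`,
#'   `pep_<cond>_<rep>`, `int_<cond>_<rep>`) and `truth` (`protein_id`,
#'   `gene_id`, `planted_fc`, `planted_down`, `low_pep`, `unique`).
#' @export
simulate_proteome <- function(config, truth, n_reps = 3L, planted_fc = 1 / 1.5,
                              noise_sdlog = 0.05, frac_lowpep = 0.05,
                              frac_unique = 0.02) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(truth),
            all(c("gene_id", "nmd") %in% names(truth)))
  withr::with_seed(.stream_seed(config$seed, "proteome"), {
    n <- nrow(truth)
    nmd_active <- truth$nmd
    # decay only acts where the aberrant isoform is actually used
    if ("aberrant" %in% names(truth)) nmd_active <- nmd_active & truth$aberrant
    planted_down <- nmd_active & runif(n) < config$proteome_link_prob
    fc <- ifelse(planted_down, planted_fc, 1)
    base <- rlnorm(n, meanlog = log(1e6), sdlog = 1)
    wt_int <- base * matrix(exp(rnorm(n * n_reps, 0, noise_sdlog)), n)
    mut_int <- base * fc * matrix(exp(rnorm(n * n_reps, 0, noise_sdlog)), n)
    pep <- matrix(3L + stats::rpois(n * 2L * n_reps, 8), n)
    status <- sample(c("ok", "lowpep", "unique"), n, replace = TRUE,
                     prob = c(1 - frac_lowpep - frac_unique, frac_lowpep,
                              frac_unique))
    uniq <- rep(NA_character_, n)
    for (i in which(status == "lowpep")) {
      pep[i, sample.int(2L * n_reps, 1L)] <- sample(0:2, 1L)
    }
    for (i in which(status == "unique")) {
      side <- sample(c("WT", "MUT"), 1L)
      uniq[i] <- side
      if (side == "WT") {
        pep[i, n_reps + seq_len(n_reps)] <- 0L
        mut_int[i, ] <- NA_real_
      } else {
        pep[i, seq_len(n_reps)] <- 0L
        wt_int[i, ] <- NA_real_
      }
    }
    protein_id <- paste0("prot_", truth$gene_id)
    quant <- data.frame(protein_id = protein_id, gene_id = truth$gene_id,
                        stringsAsFactors = FALSE)
    for (r in seq_len(n_reps)) quant[[paste0("pep_WT_", r)]] <- pep[, r]
    for (r in seq_len(n_reps)) quant[[paste0("pep_MUT_", r)]] <- pep[, n_reps + r]
    for (r in seq_len(n_reps)) quant[[paste0("int_WT_", r)]] <- wt_int[, r]
    for (r in seq_len(n_reps)) quant[[paste0("int_MUT_", r)]] <- mut_int[, r]
    ptruth <- data.frame(protein_id = protein_id, gene_id = truth$gene_id,
                         planted_fc = fc, planted_down = planted_down,
                         low_pep = status == "lowpep", unique = uniq,
                         stringsAsFactors = FALSE)
    list(quant = quant, truth = ptruth)
  })
}
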