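#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults emulate the study conditions of an isogenic
#' mutant-vs-wild-type splicing-factor cell model profiled by polysome
#' fractionation: a third of aberrant junctions preferentially translated,
#' roughly 60% of cryptic inserts frameshifting, two sequenced replicates per
#' condition, and negative-binomial counts at a configurable library size.
#'
#' @param seed Integer master seed. Each generator derives its own fixed
#'   sub-stream from it, so identical configs give bit-identical outputs.
#' @param n_genes Number of simulated genes (one cryptic/canonical junction
#'   pair each).
#' @param frac_aberrant Proportion of genes whose cryptic junction usage is
#'   elevated in the mutant (the "aberrantly spliced" set).
#' @param frac_groupA Planted fraction of aberrant junctions receiving a
#'   positive translation-efficiency shift (more polysome-associated than the
#'   canonical partner); the remainder receive the opposite shift.
#' @param te_shift_log2 Magnitude (log2) of the planted polysome/monosome
#'   translation-efficiency shift.
#' @param depth Mean library size (reads) per sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param frac_frameshift Proportion of cryptic inserts whose length is not
#'   divisible by 3.
#' @param proteome_link_prob Probability that the gene of an NMD-sensitive
#'   junction receives a planted protein down-fold (<= 1/1.2).
#' @param wt_leak Leaky cryptic-site usage in wild-type cells, as a fraction
#'   of canonical usage. Nonzero so splice indices are defined in both
#'   genotypes.
#' @param mut_psi Cryptic-site usage in mutant cells for aberrant genes, as a
#'   fraction of canonical usage.
#' @param n_reps Replicates per genotype x fraction pool.
#' @param frac_inframe_ptc Proportion of in-frame inserts carrying a planted
#'   in-frame stop codon (a PTC without a frameshift).
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' cfg$frac_groupA
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       frac_aberrant = 1,
                       frac_groupA = 0.35,
                       te_shift_log2 = 1,
                       depth = 2e6,
                       nb_dispersion = 0.05,
                       frac_frameshift = 69 / 113,
                       proteome_link_prob = 0.5,
                       wt_leak = 0.05,
                       mut_psi = 0.30,
                       n_reps = 2L,
                       frac_inframe_ptc = 0.3) {
  .check_scalar_number(seed, "seed")
  .check_scalar_number(n_genes, "n_genes", lower = 1)
  .check_scalar_number(frac_aberrant, "frac_aberrant", 0, 1)
  .check_scalar_number(frac_groupA, "frac_groupA", 0, 1)
  .check_scalar_number(te_shift_log2, "te_shift_log2", lower = 0)
  .check_scalar_number(depth, "depth")
  if (depth <= 0) stop("'depth' must be > 0")
  .check_scalar_number(nb_dispersion, "nb_dispersion")
  if (nb_dispersion <= 0) stop("'nb_dispersion' must be > 0")
  .check_scalar_number(frac_frameshift, "frac_frameshift", 0, 1)
  .check_scalar_number(proteome_link_prob, "proteome_link_prob", 0, 1)
  .check_scalar_number(wt_leak, "wt_leak", 0, 1)
  .check_scalar_number(mut_psi, "mut_psi", 0, 1)
  .check_scalar_number(n_reps, "n_reps", lower = 1)
  .check_scalar_number(frac_inframe_ptc, "frac_inframe_ptc", 0, 1)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    frac_aberrant = frac_aberrant, frac_groupA = frac_groupA,
    te_shift_log2 = te_shift_log2, depth = depth,
    nb_dispersion = nb_dispersion, frac_frameshift = frac_frameshift,
    proteome_link_prob = proteome_link_prob, wt_leak = wt_leak,
    mut_psi = mut_psi, n_reps = as.integer(n_reps),
    frac_inframe_ptc = frac_inframe_ptc
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes, depth", format(x$depth, big.mark = ","),
      "| groupA", x$frac_groupA, "| TE shift", x$te_shift_log2,
      "log2 | frameshift", round(x$frac_frameshift, 3),
      "| seed", x$seed, "\n")
  invisible(x)
}
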