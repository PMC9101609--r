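#' Simulate polysome-fraction junction counts with planted truth
#'
#' Draws negative-binomial read counts for every junction in each
#' genotype x fraction-pool x replicate sample. Canonical-junction abundance
#' follows per-gene log-normal expression weights; cryptic (aberrant)
#' junction usage is leaky in wild type (`config$wt_leak` of canonical) and
#' elevated in the mutant for the planted aberrant genes
#' (`config$mut_psi`). Among mutant aberrant junctions, a planted fraction
#' `config$frac_groupA` receives a `+te_shift_log2` polysome/monosome
#' translation-efficiency shift (group A) and the remainder the opposite
#' shift (group B); the shift is split symmetrically between the two pools so
#' pool library sizes stay comparable. Expected counts are rescaled per
#' sample so every library has expected size `config$depth`; the rescaling
#' cancels in all within-sample ratios, leaving the planted shifts intact.
#'
#' @param config A [sim_config()].
#' @param annotation A `junction_annotation` from [make_annotation()] (run
#'   with the same config).
#' @return List with `matrix` (a [fraction_counts()] object) and `truth`
#'   (per-aberrant-junction planted truth: `junction_id`, `gene_id`,
#'   `aberrant`, `group` (`A`/`B`/`NA`), `insert_len`, `frame`, `nmd`).
#' @export
simulate_fraction_counts <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "junction_annotation"))
  if (config$depth <= 0) stop("library depth must be positive")
  withr::with_seed(.stream_seed(config$seed, "counts"), {
    genes <- annotation$genes
    n <- nrow(genes)
    w <- rlnorm(n, meanlog = 0, sdlog = 1)
    w <- w / sum(w)
    aberrant <- runif(n) < config$frac_aberrant
    group <- rep(NA_character_, n)
    if (config$te_shift_log2 > 0) {
      group[aberrant] <- ifelse(runif(sum(aberrant)) < config$frac_groupA, "A", "B")
    }
    samples <- expand.grid(replicate = seq_len(config$n_reps),
                           pool = c("monosome", "polysome"),
                           genotype = c("WT", "MUT"),
                           stringsAsFactors = FALSE)[, 3:1]
    samples$sample_id <- with(samples, paste(genotype, pool, replicate, sep = "."))
    half <- config$te_shift_log2 / 2
    mu_cols <- lapply(seq_len(nrow(samples)), function(s) {
      geno <- samples$genotype[s]; pool <- samples$pool[s]
      psi <- ifelse(geno == "MUT" & aberrant, config$mut_psi, config$wt_leak)
      shift <- rep(1, n)
      if (geno == "MUT") {
        sgn <- ifelse(is.na(group), 0, ifelse(group == "A", 1, -1))
        shift <- 2^(if (pool == "polysome") half * sgn else -half * sgn)
      }
      can_mu <- w
      ab_mu <- w * psi * shift
      mu <- c(can_mu, ab_mu)
      mu * config$depth / sum(mu)  # expected library size == depth
    })
    mu_mat <- do.call(cbind, mu_cols)
    size <- 1 / config$nb_dispersion
    counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = size),
                     nrow = nrow(mu_mat),
                     dimnames = list(c(paste0(genes$gene_id, "_can"),
                                       paste0(genes$gene_id, "_abr")),
                                     samples$sample_id))
    m <- fraction_counts(counts, samples[, c("sample_id", "genotype", "pool",
                                             "replicate")],
                         annotation$junctions)
    truth <- data.frame(
      junction_id = paste0(genes$gene_id, "_abr"),
      gene_id = genes$gene_id,
      aberrant = aberrant,
      group = group,
      insert_len = genes$insert_len,
      frame = genes$frame,
      nmd = genes$nmd,
      stringsAsFactors = FALSE
    )
    list(matrix = m, truth = truth)
  })
}

#' Write a planted-truth table
#'
#' @param truth Truth data.frame from a generator.
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
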