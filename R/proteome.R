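# internal: column names of a proteome quant table, by condition
.pep_cols <- function(q, cond) grep(paste0("^pep_", cond, "_"), names(q), value = TRUE)
.int_cols <- function(q, cond) grep(paste0("^int_", cond, "_"), names(q), value = TRUE)

.check_quant <- function(q) {
  stopifnot(is.data.frame(q), all(c("protein_id", "gene_id") %in% names(q)))
  for (cond in c("WT", "MUT")) {
    if (!length(.pep_cols(q, cond)) || !length(.int_cols(q, cond))) {
      stop("quant table needs pep_", cond, "_* and int_", cond, "_* columns")
    }
  }
  if (length(.pep_cols(q, "WT")) != length(.pep_cols(q, "MUT"))) {
    stop("replicate structure must be identical across conditions")
  }
  pep <- as.matrix(q[c(.pep_cols(q, "WT"), .pep_cols(q, "MUT"))])
  if (any(pep < 0, na.rm = TRUE)) stop("negative peptide counts")
  invisible(q)
}

#' Peptide-based quantification filter
#'
#' A protein is considered reliably quantified when every replicate of every
#' condition has at least `min_peptides` detected peptides.
#'
#' @param q Proteome quant table (see [simulate_proteome()] for the schema).
#' @param min_peptides Minimum peptides per replicate (default 3).
#' @return Logical vector, one element per protein.
#' @export
filter_quantified <- function(q, min_peptides = 3L) {
  .check_quant(q)
  pep <- as.matrix(q[c(.pep_cols(q, "WT"), .pep_cols(q, "MUT"))])
  rowSums(is.na(pep) | pep < min_peptides) == 0L
}

#' Proteins detected in only one condition
#'
#' A protein is condition-unique when it has at least `min_peptides` peptides
#' in every replicate of exactly one condition and zero peptides in every
#' replicate of the other.
#'
#' @inheritParams filter_quantified
#' @return List with character vectors `unique_WT` and `unique_MUT`.
#' @export
unique_proteins <- function(q, min_peptides = 3L) {
  .check_quant(q)
  pw <- as.matrix(q[.pep_cols(q, "WT")])
  pm <- as.matrix(q[.pep_cols(q, "MUT")])
  all_ge <- function(x) rowSums(is.na(x) | x < min_peptides) == 0L
  all_zero <- function(x) rowSums(is.na(x) | x != 0L) == 0L
  list(unique_WT = q$protein_id[all_ge(pw) & all_zero(pm)],
       unique_MUT = q$protein_id[all_zero(pw) & all_ge(pm)])
}

#' Differential protein abundance (label-free)
#'
#' Log2 fold change of mean intensities (MUT over WT) with a two-sample
#' Welch t-test on log2 intensities, Benjamini-Hochberg adjusted across the
#' quantified proteins. A protein is called `underrepresented` /
#' `overrepresented` when it passes the peptide filter, its absolute fold
#' change is at least `fc_threshold` and its (adjusted, by default) p-value
#' is at most `alpha`. Condition-unique proteins are called `unique_WT` /
#' `unique_MUT`; proteins failing the peptide filter are `unquantified`.
#'
#' @inheritParams filter_quantified
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 1.2).
#' @param alpha Significance threshold (default 0.05).
#' @param use_adjusted Test the BH-adjusted p (default) or the raw p.
#'   Published filters sometimes quote one in the methods and the other in a
#'   figure caption; both are supported.
#' @param min_peptides Peptide filter (default 3).
#' @return data.frame: `protein_id`, `gene_id`, `log2_fc`, `p`, `adj_p`,
#'   `call`. Zero intensities are lifted by half the smallest positive
#'   intensity before logging and flagged in the `zero_intensity` column.
#' @export
differential_abundance <- function(q, fc_threshold = 1.2, alpha = 0.05,
                                   use_adjusted = TRUE, min_peptides = 3L) {
  .check_quant(q)
  iw <- as.matrix(q[.int_cols(q, "WT")])
  im <- as.matrix(q[.int_cols(q, "MUT")])
  if (ncol(iw) < 2L || ncol(im) < 2L) stop("need >= 2 replicates per condition")
  zero_flag <- rowSums(iw == 0, na.rm = TRUE) + rowSums(im == 0, na.rm = TRUE) > 0
  if (any(zero_flag)) {
    offset <- min(c(iw[iw > 0], im[im > 0]), na.rm = TRUE) / 2
    iw[iw == 0] <- offset
    im[im == 0] <- offset
  }
  quantified <- filter_quantified(q, min_peptides)
  uniq <- unique_proteins(q, min_peptides)
  lw <- log2(iw)
  lm_ <- log2(im)
  # vectorized Welch t-test on log2 intensities
  mw <- rowMeans(lw)
  mm <- rowMeans(lm_)
  vw <- apply(lw, 1L, stats::var)
  vm <- apply(lm_, 1L, stats::var)
  nw <- ncol(lw)
  nm_ <- ncol(lm_)
  se2 <- vw / nw + vm / nm_
  tstat <- (mm - mw) / sqrt(se2)
  df <- se2^2 / ((vw / nw)^2 / (nw - 1) + (vm / nm_)^2 / (nm_ - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  log2_fc <- log2(rowMeans(im) / rowMeans(iw))
  adj_p <- rep(NA_real_, nrow(q))
  adj_p[quantified] <- stats::p.adjust(p[quantified], method = "BH")
  crit_p <- if (use_adjusted) adj_p else p
  call <- rep("unchanged", nrow(q))
  sig <- quantified & !is.na(crit_p) & crit_p <= alpha &
    abs(log2_fc) >= log2(fc_threshold)
  call[sig & log2_fc < 0] <- "underrepresented"
  call[sig & log2_fc > 0] <- "overrepresented"
  call[!quantified] <- "unquantified"
  call[q$protein_id %in% uniq$unique_WT] <- "unique_WT"
  call[q$protein_id %in% uniq$unique_MUT] <- "unique_MUT"
  out <- data.frame(protein_id = q$protein_id, gene_id = q$gene_id,
                    log2_fc = log2_fc, p = p, adj_p = adj_p, call = call,
                    zero_intensity = zero_flag, stringsAsFactors = FALSE)
  out$log2_fc[call %in% c("unique_WT", "unique_MUT")] <- NA_real_
  out$p[call %in% c("unique_WT", "unique_MUT", "unquantified")] <- NA_real_
  out$adj_p[call %in% c("unique_WT", "unique_MUT", "unquantified")] <- NA_real_
  rownames(out) <- NULL
  out
}

# internal: genes encoding dysregulated (under/over) proteins
.dysregulated_genes <- function(diff_proteins) {
  stopifnot(all(c("gene_id", "call") %in% names(diff_proteins)))
  list(under = unique(diff_proteins$gene_id[diff_proteins$call == "underrepresented"]),
       over = unique(diff_proteins$gene_id[diff_proteins$call == "overrepresented"]))
}

#' Overlap between aberrantly spliced genes and dysregulated proteins
#'
#' Counts how many aberrantly spliced genes encode differentially abundant
#' (under- or over-represented) proteins, and reports the share of the
#' aberrant set to one decimal place.
#'
#' @param aberrant_genes Character vector of aberrantly spliced gene ids.
#' @param diff_proteins Output of [differential_abundance()].
#' @param round_mode Passed to [percent_of()].
#' @return List: `n_aberrant`, `n_overlap`, `n_under`, `n_over`,
#'   `pct_overlap` (of the aberrant set), `pct_under`, `pct_over`.
#' @export
overlap_splice_protein <- function(aberrant_genes, diff_proteins,
                                   round_mode = c("half_even", "truncate")) {
  round_mode <- match.arg(round_mode)
  aberrant_genes <- unique(aberrant_genes)
  if (!length(aberrant_genes)) stop("empty aberrant gene set")
  dys <- .dysregulated_genes(diff_proteins)
  under <- intersect(aberrant_genes, dys$under)
  over <- intersect(aberrant_genes, dys$over)
  overlap <- union(under, over)
  list(n_aberrant = length(aberrant_genes),
       n_overlap = length(overlap),
       n_under = length(under), n_over = length(over),
       pct_overlap = percent_of(length(overlap), length(aberrant_genes), round_mode),
       pct_under = percent_of(length(under), length(aberrant_genes), round_mode),
       pct_over = percent_of(length(over), length(aberrant_genes), round_mode))
}

#' Overlap between differentially expressed genes and dysregulated proteins
#'
#' @param deg_genes Character vector of differentially expressed gene ids.
#' @param diff_proteins Output of [differential_abundance()].
#' @param round_mode Passed to [percent_of()].
#' @return List: `n_deg`, `n_overlap`, `n_under`, `n_over`, `pct_overlap`
#'   (of the differentially expressed set), `pct_under`, `pct_over`.
#' @export
overlap_expression_protein <- function(deg_genes, diff_proteins,
                                       round_mode = c("half_even", "truncate")) {
  round_mode <- match.arg(round_mode)
  deg_genes <- unique(deg_genes)
  if (!length(deg_genes)) stop("empty differentially-expressed gene set")
  dys <- .dysregulated_genes(diff_proteins)
  if (!length(dys$under) && !length(dys$over)) {
    stop("no dysregulated proteins in input")
  }
  under <- intersect(deg_genes, dys$under)
  over <- intersect(deg_genes, dys$over)
  overlap <- union(under, over)
  list(n_deg = length(deg_genes),
       n_overlap = length(overlap),
       n_under = length(under), n_over = length(over),
       pct_overlap = percent_of(length(overlap), length(deg_genes), round_mode),
       pct_under = percent_of(length(under), length(deg_genes), round_mode),
       pct_over = percent_of(length(over), length(deg_genes), round_mode))
}

#' Protein fold changes stratified by splice category
#'
#' Groups proteins into `canonical` (gene has no aberrant junction),
#' `NMD-sensitive` (gene has at least one NMD-sensitive aberrant junction)
#' and `NMD-insensitive` (aberrant junctions, none NMD-sensitive), and
#' summarizes the protein log2 fold-change distribution of each stratum.
#'
#' @param diff_proteins Output of [differential_abundance()].
#' @param frame_predictions Output of [annotate_junctions()] (columns
#'   `gene_id`, `nmd`).
#' @return data.frame: `category`, `n`, `median`, `q1`, `q3` (quartiles of
#'   `log2_fc`; `NA` for empty strata). Only proteins with a defined fold
#'   change contribute to the summaries.
#' @export
stratify_fc_by_splice_category <- function(diff_proteins, frame_predictions) {
  stopifnot(all(c("gene_id", "nmd") %in% names(frame_predictions)))
  nmd_genes <- unique(frame_predictions$gene_id[
    frame_predictions$nmd == "NMD-sensitive"])
  spliced <- unique(frame_predictions$gene_id)
  category <- ifelse(!(diff_proteins$gene_id %in% spliced), "canonical",
                     ifelse(diff_proteins$gene_id %in% nmd_genes,
                            "NMD-sensitive", "NMD-insensitive"))
  out <- lapply(c("canonical", "NMD-sensitive", "NMD-insensitive"), function(cat) {
    fc <- diff_proteins$log2_fc[category == cat]
    fc <- fc[!is.na(fc)]
    if (!length(fc)) {
      data.frame(category = cat, n = 0L, median = NA_real_, q1 = NA_real_,
                 q3 = NA_real_, stringsAsFactors = FALSE)
    } else {
      qs <- stats::quantile(fc, c(0.25, 0.75), names = FALSE)
      data.frame(category = cat, n = length(fc), median = stats::median(fc),
                 q1 = qs[1L], q3 = qs[2L], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
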