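#' Translation-efficiency log-ratio of an aberrant junction
#'
#' log2 of the ratio of aberrant splice indices between the polysome and
#' monosome pools within one genotype:
#' `log2[(aberrant/canonical)_polysome / (aberrant/canonical)_monosome]`.
#' A positive value means the aberrant isoform is relatively more
#' polysome-associated (more translated) than its canonical counterpart.
#' Replicates are averaged after normalization; a pseudocount is added to all
#' four normalized means so the ratio is finite with zero counts.
#'
#' @param m A normalized [fraction_counts()] object.
#' @param aberrant_id Aberrant junction id.
#' @param genotype Genotype to evaluate (default `"MUT"`).
#' @param pseudocount Added to each normalized mean (default 0.5).
#' @return The log2 translation-efficiency ratio (numeric scalar).
#' @export
te_log_ratio <- function(m, aberrant_id, genotype = "MUT", pseudocount = 0.5) {
  stopifnot(inherits(m, "fraction_counts"))
  if (is.null(m$size_factors)) m <- normalize_counts(m)
  j <- m$junctions[m$junctions$junction_id == aberrant_id, ]
  if (nrow(j) != 1L || j$kind != "aberrant") {
    stop("'", aberrant_id, "' is not an aberrant junction of this matrix")
  }
  for (pool in c("monosome", "polysome")) {
    if (!any(m$samples$genotype == genotype & m$samples$pool == pool)) {
      stop("pool absent for genotype ", genotype, ": ", pool)
    }
  }
  ab_p <- .mean_norm(m, aberrant_id, genotype, "polysome") + pseudocount
  can_p <- .mean_norm(m, j$partner, genotype, "polysome") + pseudocount
  ab_m <- .mean_norm(m, aberrant_id, genotype, "monosome") + pseudocount
  can_m <- .mean_norm(m, j$partner, genotype, "monosome") + pseudocount
  log2((ab_p / can_p) / (ab_m / can_m))
}

#' Significance of a junction's translation-efficiency shift
#'
#' Two-sided Fisher exact test on the 2x2 table (aberrant, canonical) x
#' (polysome, monosome) of pooled, half-even-rounded normalized counts for
#' one genotype.
#'
#' @inheritParams te_log_ratio
#' @return Two-sided p-value. An all-zero table yields `p = 1` with a
#'   warning.
#' @export
te_significance <- function(m, aberrant_id, genotype = "MUT") {
  stopifnot(inherits(m, "fraction_counts"))
  if (is.null(m$size_factors)) m <- normalize_counts(m)
  j <- m$junctions[m$junctions$junction_id == aberrant_id, ]
  if (nrow(j) != 1L || j$kind != "aberrant") {
    stop("'", aberrant_id, "' is not an aberrant junction of this matrix")
  }
  tab <- matrix(c(.pooled_norm(m, aberrant_id, genotype, "polysome"),
                  .pooled_norm(m, j$partner, genotype, "polysome"),
                  .pooled_norm(m, aberrant_id, genotype, "monosome"),
                  .pooled_norm(m, j$partner, genotype, "monosome")),
                nrow = 2L)
  if (sum(tab) == 0) {
    warning("empty contingency table for ", aberrant_id, "; p set to 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Per-junction translation-efficiency table
#'
#' Runs [te_log_ratio()] and [te_significance()] over every aberrant
#' junction.
#'
#' @inheritParams te_log_ratio
#' @return data.frame: `junction_id`, `gene_id`, `log2_te_ratio`, `p_value`.
#' @export
te_table <- function(m, genotype = "MUT", pseudocount = 0.5) {
  stopifnot(inherits(m, "fraction_counts"))
  if (is.null(m$size_factors)) m <- normalize_counts(m)
  ab <- m$junctions[m$junctions$kind == "aberrant", ]
  nm <- normalized_counts(m)
  poly <- m$samples$genotype == genotype & m$samples$pool == "polysome"
  mono <- m$samples$genotype == genotype & m$samples$pool == "monosome"
  if (!any(poly) || !any(mono)) {
    stop("both monosome and polysome pools are required for genotype ", genotype)
  }
  rows <- lapply(seq_len(nrow(ab)), function(i) {
    aid <- ab$junction_id[i]; cid <- ab$partner[i]
    lfc <- log2(((mean(nm[aid, poly]) + pseudocount) /
                   (mean(nm[cid, poly]) + pseudocount)) /
                  ((mean(nm[aid, mono]) + pseudocount) /
                     (mean(nm[cid, mono]) + pseudocount)))
    tab <- matrix(round(c(sum(nm[aid, poly]), sum(nm[cid, poly]),
                          sum(nm[aid, mono]), sum(nm[cid, mono]))), nrow = 2L)
    p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
    data.frame(junction_id = aid, gene_id = ab$gene_id[i],
               log2_te_ratio = lfc, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify junctions into translation groups A and B
#'
#' Group A: significantly more translated aberrant isoform
#' (`p <= p_threshold` and positive log2 TE ratio); group B: significantly
#' less translated (negative ratio); everything else `unclassified`. A
#' significant junction with a ratio of exactly zero is left unclassified and
#' flagged with a warning.
#'
#' @param te data.frame from [te_table()].
#' @param p_threshold Significance threshold (default `1e-5`).
#' @return The input with a `group` column (`A`, `B`, `unclassified`).
#' @export
classify_groups <- function(te, p_threshold = 1e-5) {
  stopifnot(all(c("junction_id", "log2_te_ratio", "p_value") %in% names(te)))
  sig <- te$p_value <= p_threshold
  group <- rep("unclassified", nrow(te))
  group[sig & te$log2_te_ratio > 0] <- "A"
  group[sig & te$log2_te_ratio < 0] <- "B"
  zero_sig <- sig & te$log2_te_ratio == 0
  if (any(zero_sig)) {
    warning(sum(zero_sig), " significant junction(s) with a log2 TE ratio of ",
            "exactly 0 left unclassified")
  }
  te$group <- group
  te
}

#' Group percentages over classified junctions
#'
#' @param labeled Output of [classify_groups()].
#' @return Named numeric: `pctA`, `pctB`, percentages over classified
#'   junctions only (`pctA + pctB == 100` exactly).
#' @export
group_fractions <- function(labeled) {
  stopifnot("group" %in% names(labeled))
  nA <- sum(labeled$group == "A")
  nB <- sum(labeled$group == "B")
  if (nA + nB == 0L) stop("no classified junctions")
  pctA <- 100 * nA / (nA + nB)
  c(pctA = pctA, pctB = 100 - pctA)
}
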