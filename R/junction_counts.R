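#' Construct a fraction count matrix
#'
#' Junction-by-sample read counts from a polysome-profiling experiment, with
#' sample metadata (genotype, fraction pool, replicate) and the junction
#' pairing table (each aberrant junction linked to its canonical partner).
#'
#' @param counts Integer matrix, junctions x samples; rownames are junction
#'   ids, colnames are sample ids.
#' @param samples data.frame with columns `sample_id`, `genotype` (`WT` /
#'   `MUT`), `pool` (`monosome` / `polysome` / `whole` or a fraction number),
#'   `replicate`.
#' @param junctions data.frame with columns `junction_id`, `gene_id`, `kind`
#'   (`canonical` / `aberrant`), `partner` (canonical partner id for aberrant
#'   rows).
#' @param size_factors Optional positive numeric per sample (set by
#'   [normalize_counts()]).
#' @return An object of class `fraction_counts`.
#' @export
fraction_counts <- function(counts, samples, junctions, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    bad <- which(rowSums(counts < 0) > 0)
    stop("negative counts in rows: ",
         paste(rownames(counts)[bad], collapse = ", "))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate junction ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  stopifnot(identical(sort(rownames(counts)), sort(junctions$junction_id)),
            identical(colnames(counts), samples$sample_id))
  need <- c("sample_id", "genotype", "pool", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample metadata incomplete; need columns: ", paste(need, collapse = ", "))
  }
  ab <- junctions[junctions$kind == "aberrant", ]
  missing_partner <- ab$junction_id[!(ab$partner %in% junctions$junction_id) |
                                      is.na(ab$partner)]
  if (length(missing_partner)) {
    stop("aberrant junctions without a canonical partner: ",
         paste(missing_partner, collapse = ", "))
  }
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts) || any(size_factors <= 0)) {
      stop("size_factors must be positive, one per sample")
    }
  }
  structure(list(counts = counts, samples = samples, junctions = junctions,
                 size_factors = size_factors),
            class = "fraction_counts")
}

#' @export
print.fraction_counts <- function(x, ...) {
  cat("fraction_counts:", nrow(x$counts), "junctions x", ncol(x$counts),
      "samples |", sum(x$junctions$kind == "aberrant"), "aberrant junctions |",
      if (is.null(x$size_factors)) "unnormalized" else "normalized", "\n")
  invisible(x)
}

#' Write / load a junction count table (TSV)
#'
#' One row per junction. Leading columns `junction_id`, `gene_id`, `kind`,
#' `partner`; remaining columns are counts, named
#' `<genotype>.<pool>.<replicate>` (e.g. `MUT.polysome.1`).
#'
#' @param m A [fraction_counts()] object.
#' @param path TSV path.
#' @return `write_junction_counts`: the path, invisibly.
#' @export
write_junction_counts <- function(m, path) {
  stopifnot(inherits(m, "fraction_counts"))
  df <- cbind(m$junctions[match(rownames(m$counts), m$junctions$junction_id),
                          c("junction_id", "gene_id", "kind", "partner")],
              as.data.frame(m$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_junction_counts
#' @param strict Fail on malformed rows (default) instead of dropping them.
#' @return `load_junction_counts`: a validated [fraction_counts()] object.
#' @export
load_junction_counts <- function(path, strict = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                   check.names = FALSE)
  meta_cols <- c("junction_id", "gene_id", "kind", "partner")
  if (!all(meta_cols %in% names(df))) {
    stop("count TSV must start with columns: ", paste(meta_cols, collapse = ", "))
  }
  count_cols <- setdiff(names(df), meta_cols)
  if (!length(count_cols)) stop("no sample columns found")
  cmat <- suppressWarnings(
    vapply(df[count_cols], function(x) as.numeric(x), numeric(nrow(df))))
  cmat <- matrix(cmat, nrow = nrow(df),
                 dimnames = list(df$junction_id, count_cols))
  bad_rows <- which(rowSums(is.na(cmat)) > 0 |
                      rowSums(cmat < 0, na.rm = TRUE) > 0 |
                      rowSums(cmat != floor(cmat), na.rm = TRUE) > 0)
  if (length(bad_rows)) {
    msg <- paste0("malformed counts at line(s) ",
                  paste(bad_rows + 1L, collapse = ", "), " (junction ",
                  paste(df$junction_id[bad_rows], collapse = ", "), ")")
    if (strict) stop(msg) else warning(msg)
    df <- df[-bad_rows, , drop = FALSE]
    cmat <- cmat[-bad_rows, , drop = FALSE]
  }
  parts <- strsplit(count_cols, ".", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("sample columns must be named <genotype>.<pool>.<replicate>; got: ",
         paste(count_cols[lengths(parts) != 3L], collapse = ", "))
  }
  samples <- data.frame(sample_id = count_cols,
                        genotype = vapply(parts, `[`, "", 1L),
                        pool = vapply(parts, `[`, "", 2L),
                        replicate = as.integer(vapply(parts, `[`, "", 3L)),
                        stringsAsFactors = FALSE)
  junctions <- df[, meta_cols]
  fraction_counts(cmat, samples, junctions)
}

#' Normalize a count matrix (counts per million)
#'
#' Sets per-sample size factors. The default (and only built-in) method is
#' counts-per-million: size factor = column total / 1e6, normalized value =
#' count / size factor. Zeros are preserved by construction.
#'
#' @param m A [fraction_counts()] object.
#' @param method Normalization method; `"cpm"`.
#' @return The object with `size_factors` set.
#' @export
normalize_counts <- function(m, method = c("cpm")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "fraction_counts"))
  totals <- colSums(m$counts)
  if (any(totals == 0)) {
    stop("all-zero sample column(s): ",
         paste(colnames(m$counts)[totals == 0], collapse = ", "))
  }
  m$size_factors <- totals / 1e6
  m
}

#' Normalized count matrix
#'
#' @param m A normalized [fraction_counts()] object.
#' @return Matrix of counts divided by their sample size factors.
#' @export
normalized_counts <- function(m) {
  stopifnot(inherits(m, "fraction_counts"))
  if (is.null(m$size_factors)) stop("call normalize_counts() first")
  sweep(m$counts, 2L, m$size_factors, "/")
}

# internal: mean normalized count of one junction over the samples of one
# genotype/pool cell (replicates averaged after normalization)
.mean_norm <- function(m, junction_id, genotype, pool) {
  sel <- m$samples$genotype == genotype & m$samples$pool == pool
  if (!any(sel)) stop("no samples for genotype=", genotype, ", pool=", pool)
  nm <- normalized_counts(m)
  mean(nm[junction_id, sel])
}

# internal: pooled (summed then half-even rounded) normalized count
.pooled_norm <- function(m, junction_id, genotype, pool = NULL) {
  sel <- m$samples$genotype == genotype
  if (!is.null(pool)) sel <- sel & m$samples$pool == pool
  if (!any(sel)) stop("no samples for genotype=", genotype,
                      if (!is.null(pool)) paste0(", pool=", pool))
  nm <- normalized_counts(m)
  round(sum(nm[junction_id, sel]))
}

#' Aberrant splice index
#'
#' Ratio of normalized aberrant-junction to normalized canonical-junction
#' abundance for one gene in one genotype and fraction pool, replicates
#' averaged after normalization. The index is undefined (flagged, value `NA`)
#' when the canonical normalized count is zero.
#'
#' @param m A normalized [fraction_counts()] object.
#' @param aberrant_id Aberrant junction id (its canonical partner is looked
#'   up in the pairing table).
#' @param genotype,pool Sample stratum.
#' @return data.frame: `junction_id`, `genotype`, `pool`, `index`,
#'   `undefined`.
#' @export
splice_index <- function(m, aberrant_id, genotype, pool) {
  stopifnot(inherits(m, "fraction_counts"))
  j <- m$junctions[m$junctions$junction_id == aberrant_id, ]
  if (nrow(j) != 1L || j$kind != "aberrant") {
    stop("'", aberrant_id, "' is not an aberrant junction of this matrix")
  }
  ab <- .mean_norm(m, aberrant_id, genotype, pool)
  can <- .mean_norm(m, j$partner, genotype, pool)
  undefined <- can == 0
  data.frame(junction_id = aberrant_id, genotype = genotype, pool = pool,
             index = if (undefined) NA_real_ else ab / can,
             undefined = undefined, stringsAsFactors = FALSE)
}

#' Differential junction expression between genotypes
#'
#' For each aberrant junction, tests the 2x2 table (aberrant, canonical) x
#' (MUT, WT) of pooled, half-even-rounded normalized counts with Fisher's
#' exact test, controlling for gene expression through the canonical partner.
#' P-values are Benjamini-Hochberg adjusted across junctions. The reported
#' log2 fold change is the normalized aberrant-junction fold change (MUT over
#' WT, mean over samples, pseudocount added).
#'
#' @param m A [fraction_counts()] object (normalized automatically if not).
#' @param alpha Adjusted-p threshold for the `pass` flag (default 0.05).
#' @param pseudocount Added to normalized means for the fold change.
#' @return data.frame: `junction_id`, `gene_id`, `log2_fc`, `p`, `adj_p`,
#'   `pass`. Replicates are pooled for the exact test (recorded in the
#'   `pooled` attribute).
#' @export
differential_junction_expression <- function(m, alpha = 0.05, pseudocount = 0.5) {
  stopifnot(inherits(m, "fraction_counts"))
  for (g in c("WT", "MUT")) {
    if (!any(m$samples$genotype == g)) stop("genotype absent from matrix: ", g)
  }
  if (is.null(m$size_factors)) m <- normalize_counts(m)
  ab <- m$junctions[m$junctions$kind == "aberrant", ]
  nm <- normalized_counts(m)
  mut <- m$samples$genotype == "MUT"
  wt <- m$samples$genotype == "WT"
  res <- lapply(seq_len(nrow(ab)), function(i) {
    aid <- ab$junction_id[i]; cid <- ab$partner[i]
    tab <- matrix(round(c(sum(nm[aid, mut]), sum(nm[cid, mut]),
                          sum(nm[aid, wt]), sum(nm[cid, wt]))), nrow = 2L)
    p <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
    lfc <- log2((mean(nm[aid, mut]) + pseudocount) /
                  (mean(nm[aid, wt]) + pseudocount))
    data.frame(junction_id = aid, gene_id = ab$gene_id[i],
               log2_fc = lfc, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$pass <- out$adj_p <= alpha & abs(out$log2_fc) > 0
  attr(out, "pooled") <- TRUE
  rownames(out) <- NULL
  out
}
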