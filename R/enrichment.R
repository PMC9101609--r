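#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: name, description, member genes.
#' Duplicate genes within a set are removed with a warning.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line(s) with fewer than 3 fields: ", paste(short, collapse = ", "))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[`, "", 1L)
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning("duplicated genes removed from set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets <- lapply(sets, unique)
  }
  sets
}

#' Gene-set over-representation (hypergeometric) test
#'
#' One-sided hypergeometric over-representation test of a gene list against
#' each set, within a stated universe; Benjamini-Hochberg adjustment across
#' sets and `-log10 p` for plotting.
#'
#' @param gene_list Character vector of hit genes (e.g. group-A genes).
#' @param universe Character vector of all testable genes; must contain
#'   `gene_list`.
#' @param gene_sets Named list of character vectors, or a GMT path.
#' @return data.frame: `set`, `set_size` (within universe), `overlap`, `p`,
#'   `adj_p`, `minus_log10_p`.
#' @export
enrich_genesets <- function(gene_list, universe, gene_sets) {
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- read_gmt(gene_sets)
  }
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) {
    stop("gene_list contains genes outside the universe: ",
         paste(head(setdiff(gene_list, universe), 5L), collapse = ", "))
  }
  n_list <- length(gene_list)
  n_univ <- length(universe)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    k <- length(intersect(gene_list, set))
    # P(X >= k), X ~ Hypergeom(set in universe, rest, draws = list size)
    p <- stats::phyper(k - 1L, length(set), n_univ - length(set), n_list,
                       lower.tail = FALSE)
    data.frame(set = s, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$minus_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  out
}
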