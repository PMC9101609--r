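#' Transcript model
#'
#' A minimal container for a spliced transcript: ordered exons in genomic
#' coordinates (0-based half-open, ascending), strand, CDS boundaries in
#' transcript coordinates, and the spliced sequence.
#'
#' @param transcript_id Identifier.
#' @param exons data.frame with integer columns `start`, `end` (0-based
#'   half-open genomic intervals, ascending, non-overlapping).
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end CDS interval in transcript coordinates (0-based
#'   half-open); `cds_start` is the first nucleotide of the start codon.
#' @param sequence Spliced transcript sequence (uppercase DNA).
#' @param check_cds_frame Require `cds_end - cds_start` divisible by 3
#'   (default). Derived aberrant isoforms with frameshifting inserts set this
#'   to `FALSE`: their annotated CDS span (start codon to where the canonical
#'   stop ends) is deliberately out of frame.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, exons, strand, cds_start, cds_end,
                             sequence, check_cds_frame = TRUE) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (any(exons$end <= exons$start)) stop("exon with end <= start")
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("exons must be ordered and non-overlapping in genomic coordinates")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  tx_len <- sum(exons$end - exons$start)
  if (nchar(sequence) != tx_len) {
    stop("sequence length (", nchar(sequence), ") does not match exon total (",
         tx_len, ")")
  }
  if (cds_start < 0L || cds_end > tx_len || cds_end <= cds_start) {
    stop("CDS [", cds_start, ",", cds_end, ") outside transcript [0,", tx_len, ")")
  }
  if (check_cds_frame && (cds_end - cds_start) %% 3L != 0L) {
    stop("CDS length not divisible by 3")
  }
  if (grepl("[^ACGT]", sequence)) stop("sequence must be uppercase ACGT DNA")
  structure(list(transcript_id = transcript_id, exons = exons, strand = strand,
                 cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
                 sequence = sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "|", nrow(x$exons), "exons |",
      nchar(x$sequence), "nt | CDS [", x$cds_start, ",", x$cds_end, ") |",
      x$strand, "\n")
  invisible(x)
}

#' Length of the intronic insert created by a cryptic 3' splice site
#'
#' The aberrant junction uses an acceptor upstream of the canonical acceptor
#' within the same intron, so the mature mRNA retains the intron's last
#' stretch. The insert length is the strand-aware distance between the
#' cryptic and canonical 3' splice sites.
#'
#' @param aberrant,canonical Single junction records (one-row data.frames or
#'   lists with `chrom`, `start`, `end`, `strand`): 0-based half-open intron
#'   intervals, BED convention.
#' @return Insert length in nucleotides (positive integer).
#' @export
insert_length <- function(aberrant, canonical) {
  for (f in c("chrom", "start", "end", "strand")) {
    if (is.null(aberrant[[f]]) || is.null(canonical[[f]])) {
      stop("junction records need fields chrom/start/end/strand; missing ", f)
    }
  }
  if (aberrant$chrom != canonical$chrom || aberrant$strand != canonical$strand) {
    stop("aberrant and canonical junctions must share chrom and strand")
  }
  d <- if (aberrant$strand == "+") {
    if (aberrant$start != canonical$start) {
      stop("junctions must share the 5' donor (start on + strand)")
    }
    canonical$end - aberrant$end
  } else {
    if (aberrant$end != canonical$end) {
      stop("junctions must share the 5' donor (end on - strand)")
    }
    aberrant$start - canonical$start
  }
  intron_len <- canonical$end - canonical$start
  if (d <= 0L || d >= intron_len) {
    stop("cryptic 3'ss must lie inside the intron, upstream of the canonical ",
         "acceptor (got insert length ", d, " for an intron of ", intron_len, " nt)")
  }
  as.integer(d)
}

#' Classify an insert length by reading frame
#'
#' @param insert_len Insert length(s) in nucleotides (non-negative).
#' @return `"in-frame"` if `insert_len %% 3 == 0`, else `"out-of-frame"`.
#' @examples
#' classify_frame(c(12, 13, 0))
#' @export
classify_frame <- function(insert_len) {
  if (any(is.na(insert_len)) || any(insert_len < 0)) {
    stop("insert lengths must be non-negative")
  }
  ifelse(insert_len %% 3 == 0, "in-frame", "out-of-frame")
}

#' Reconstruct an aberrant isoform from a canonical model and junction pair
#'
#' Replaces the canonical intron's 3' end with the cryptic acceptor, pulling
#' the last `insert_length` intronic nucleotides into the mature transcript.
#' The CDS start is inherited; the CDS end is shifted by the insert length so
#' it marks where the canonical stop codon ends in aberrant coordinates
#' (out of frame when the insert length is not a multiple of 3).
#'
#' @param model Canonical [transcript_model()].
#' @param aberrant,canonical Junction records (see [insert_length()]).
#' @param genome Named character vector or `DNAStringSet` holding the contig
#'   named in the junctions' `chrom`.
#' @return The aberrant isoform as a `transcript_model`.
#' @export
aberrant_isoform <- function(model, aberrant, canonical, genome) {
  d <- insert_length(aberrant, canonical)
  contig <- genome[[aberrant$chrom]]
  if (is.null(contig)) stop("contig ", aberrant$chrom, " not in genome")
  contig <- as.character(contig)
  ex <- model$exons
  # the exon whose genomic start (on +) / end (on -) abuts the canonical acceptor
  if (model$strand == "+") {
    k <- which(ex$start == canonical$end)
    if (length(k) != 1L) stop("canonical junction does not match the model's exons")
    ex$start[k] <- ex$start[k] - d
  } else {
    k <- which(ex$end == canonical$start)
    if (length(k) != 1L) stop("canonical junction does not match the model's exons")
    ex$end[k] <- ex$end[k] + d
  }
  seqs <- substring(contig, ex$start + 1L, ex$end)
  tx <- paste(seqs, collapse = "")
  if (model$strand == "-") tx <- .revcomp(tx)
  transcript_model(
    transcript_id = paste0(model$transcript_id, ".aberrant"),
    exons = ex, strand = model$strand,
    cds_start = model$cds_start, cds_end = model$cds_end + d,
    sequence = tx, check_cds_frame = FALSE
  )
}

#' Locate the first premature termination codon of an isoform
#'
#' Translates the transcript codon by codon from the annotated start codon in
#' the (possibly shifted) reading frame and returns the transcript coordinate
#' of the first stop codon, provided it precedes the position where the
#' canonical stop would end (`model$cds_end`). A stop codon exactly at the
#' annotated CDS end is the canonical stop, not a PTC.
#'
#' @param model A [transcript_model()] (typically an aberrant isoform from
#'   [aberrant_isoform()]).
#' @return 0-based transcript coordinate of the PTC's first nucleotide, or
#'   `NA` if translation reaches the canonical stop (or never terminates).
#' @export
scan_ptc <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  start_codon <- substr(model$sequence, model$cds_start + 1L, model$cds_start + 3L)
  if (start_codon != "ATG") {
    stop("no start codon at annotated CDS start (found ", start_codon, ")")
  }
  pos <- .first_stop(model$sequence, model$cds_start)
  if (is.na(pos) || pos >= model$cds_end - 3L) return(NA_integer_)
  pos
}

#' Predict NMD sensitivity under the 50-nt boundary rule
#'
#' A transcript is predicted sensitive to nonsense-mediated decay when it
#' carries a premature termination codon located more than `rule_nt`
#' nucleotides upstream of the last exon-exon junction. Single-exon
#' transcripts (no junction downstream of the stop) are never sensitive.
#'
#' @param ptc_position 0-based transcript coordinate of the PTC (first
#'   nucleotide of the stop codon), or `NA` for no PTC.
#' @param model The [transcript_model()] the position refers to.
#' @param rule_nt Boundary distance in nucleotides (default 50).
#' @return `"NMD-sensitive"` or `"NMD-insensitive"`.
#' @export
predict_nmd <- function(ptc_position, model, rule_nt = 50L) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.na(ptc_position)) return("NMD-insensitive")
  n_ex <- nrow(model$exons)
  if (n_ex < 2L) return("NMD-insensitive")
  widths <- model$exons$end - model$exons$start
  if (model$strand == "-") widths <- rev(widths)
  last_junction <- sum(widths[-n_ex])  # tx coordinate of the last junction
  if (last_junction - ptc_position > rule_nt) "NMD-sensitive" else "NMD-insensitive"
}

#' Annotate aberrant junctions: insert length, frame, PTC, NMD call
#'
#' Convenience wrapper running [insert_length()], [classify_frame()],
#' [aberrant_isoform()], [scan_ptc()] and [predict_nmd()] over every aberrant
#' junction of an annotation.
#'
#' @param junctions Junction table (as in `junction_annotation$junctions` or
#'   read from `junctions.tsv`): canonical and aberrant records with partner
#'   links.
#' @param models Named list of canonical [transcript_model()] objects, keyed
#'   by `<gene_id>.canonical` (as produced by [read_annotation()] or
#'   [transcript_models()]).
#' @param genome Named contig sequences.
#' @param rule_nt NMD boundary rule distance (default 50).
#' @return data.frame: `junction_id`, `gene_id`, `insert_length`, `frame`,
#'   `ptc_position` (NA if none), `nmd`.
#' @export
annotate_junctions <- function(junctions, models, genome, rule_nt = 50L) {
  ab <- junctions[junctions$kind == "aberrant", , drop = FALSE]
  if (nrow(ab) == 0L) stop("no aberrant junctions to annotate")
  rows <- lapply(seq_len(nrow(ab)), function(i) {
    j <- ab[i, ]
    can <- junctions[junctions$junction_id == j$partner, ]
    if (nrow(can) != 1L) stop("aberrant junction ", j$junction_id,
                              " lacks its canonical partner")
    m <- models[[paste0(j$gene_id, ".canonical")]]
    if (is.null(m)) stop("no canonical transcript model for gene ", j$gene_id)
    d <- insert_length(j, can)
    iso <- aberrant_isoform(m, j, can, genome)
    ptc <- scan_ptc(iso)
    data.frame(junction_id = j$junction_id, gene_id = j$gene_id,
               insert_length = d, frame = classify_frame(d),
               ptc_position = ptc,
               nmd = predict_nmd(ptc, iso, rule_nt = rule_nt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
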