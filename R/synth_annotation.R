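BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

.random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

.random_codons <- function(n_codons, pool = NONSTOP_CODONS) {
  if (n_codons <= 0) return("")
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# first stop codon downstream of cds_start (0-based transcript coordinate of
# the stop codon's first nucleotide), or NA if the frame never terminates
.first_stop <- function(seq, cds_start) {
  n_codons <- (nchar(seq) - cds_start) %/% 3L
  if (n_codons < 1L) return(NA_integer_)
  starts <- cds_start + 3L * (seq_len(n_codons) - 1L) + 1L  # 1-based
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(starts[hit[1L]] - 1L)
}

#' Generate synthetic transcript models with cryptic 3' splice sites
#'
#' Builds, for each gene, a three-exon transcript on its own contig with one
#' canonical 3' splice site in the first intron and one cryptic 3' splice
#' site upstream of it inside that intron. Use of the cryptic site includes
#' the last `insert_len` intronic nucleotides in the mature mRNA, mimicking
#' the intron-proximal acceptors selected when a mutant splicing factor
#' recognizes an upstream branchpoint. Insert lengths are drawn so the
#' fraction not divisible by 3 equals `config$frac_frameshift` in
#' expectation; every frameshifting insert carries a stop codon in the
#' shifted frame upstream of the last exon-exon junction, and a configurable
#' share of in-frame inserts carries a planted in-frame stop (a PTC without a
#' frameshift).
#'
#' @param config A [sim_config()].
#' @return An object of class `junction_annotation`: a list with `genes`
#'   (per-gene structural truth: exon/intron lengths, insert length, frame,
#'   PTC transcript coordinate, NMD truth under the 50-nt rule), `junctions`
#'   (BED-convention junction records, canonical and aberrant, with partner
#'   links), and `genome` (named character vector, one contig per gene).
#' @examples
#' ann <- make_annotation(sim_config(seed = 1, n_genes = 5))
#' ann$genes[, c("gene_id", "insert_len", "frame", "nmd")]
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(.stream_seed(config$seed, "annotation"), {
    n <- config$n_genes
    genes <- vector("list", n)
    genome <- character(n)
    for (g in seq_len(n)) {
      strand <- sample(c("+", "-"), 1L)
      e1 <- sample(90:150, 1L)
      e2 <- sample(90:150, 1L)
      e3 <- sample(90:150, 1L)
      frameshift <- runif(1L) < config$frac_frameshift
      d <- if (frameshift) {
        sample(setdiff(10:59, seq(12, 57, by = 3)), 1L)
      } else {
        sample(seq(9, 57, by = 3), 1L)
      }
      i1 <- d + sample(40:120, 1L)
      i2 <- sample(80:160, 1L)
      if (d >= i1) stop("insert length (", d, ") must be smaller than the intron (", i1, ")")
      tx_len <- e1 + e2 + e3
      cds_start <- 12L
      utr3 <- 12L + (tx_len - cds_start - 12L) %% 3L
      cds_len <- tx_len - cds_start - utr3
      canon_tx <- paste0(
        .random_dna(cds_start),
        "ATG",
        .random_codons((cds_len - 6L) %/% 3L),
        sample(STOP_CODONS, 1L),
        .random_dna(utr3)
      )
      # insert = last d nt of intron 1; reading phase where it lands
      phase <- (e1 - cds_start) %% 3L
      off <- (3L - phase) %% 3L  # offset of first full codon inside the insert
      plant_ptc <- frameshift || runif(1L) < config$frac_inframe_ptc
      if (plant_ptc) {
        insert <- .random_dna(d)
        substr(insert, off + 1L, off + 3L) <- sample(STOP_CODONS, 1L)
      } else {
        n_full <- (d - off) %/% 3L
        rest <- d - off - 3L * n_full
        insert <- paste0(.random_dna(off), .random_codons(n_full), .random_dna(rest))
      }
      intron1 <- paste0(.random_dna(i1 - d), insert)
      intron2 <- .random_dna(i2)
      exon1_seq <- substr(canon_tx, 1L, e1)
      exon2_seq <- substr(canon_tx, e1 + 1L, e1 + e2)
      exon3_seq <- substr(canon_tx, e1 + e2 + 1L, tx_len)
      contig_plus <- paste0(exon1_seq, intron1, exon2_seq, intron2, exon3_seq)
      L <- nchar(contig_plus)
      aberr_tx <- paste0(exon1_seq, insert, exon2_seq, exon3_seq)
      canon_stop_ab <- cds_start + cds_len - 3L + d
      ptc <- .first_stop(aberr_tx, cds_start)
      if (!is.na(ptc) && ptc >= canon_stop_ab) ptc <- NA_integer_
      last_junction <- e1 + d + e2
      nmd <- !is.na(ptc) && (last_junction - ptc > 50L)
      contig <- if (strand == "+") contig_plus else
        .revcomp(contig_plus)
      genome[g] <- contig
      genes[[g]] <- data.frame(
        gene_id = sprintf("gene%04d", g), strand = strand,
        e1 = e1, i1 = i1, e2 = e2, i2 = i2, e3 = e3,
        insert_len = d, cds_start = cds_start, cds_len = cds_len,
        frame = if (d %% 3L == 0L) "in-frame" else "out-of-frame",
        ptc_tx = ptc, nmd = nmd, contig_len = L,
        stringsAsFactors = FALSE
      )
    }
    genes <- do.call(rbind, genes)
    names(genome) <- genes$gene_id
    junctions <- .build_junctions(genes)
    structure(list(genes = genes, junctions = junctions, genome = genome,
                   config = config),
              class = "junction_annotation")
  })
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# junction records in BED convention (0-based half-open intron intervals),
# flipped for minus-strand contigs
.build_junctions <- function(genes) {
  recs <- lapply(seq_len(nrow(genes)), function(i) {
    gg <- genes[i, ]
    can <- c(start = gg$e1, end = gg$e1 + gg$i1)
    abr <- c(start = gg$e1, end = gg$e1 + gg$i1 - gg$insert_len)
    if (gg$strand == "-") {
      can <- c(start = gg$contig_len - can[["end"]], end = gg$contig_len - can[["start"]])
      abr <- c(start = gg$contig_len - abr[["end"]], end = gg$contig_len - abr[["start"]])
    }
    can_id <- paste0(gg$gene_id, "_can")
    abr_id <- paste0(gg$gene_id, "_abr")
    data.frame(
      junction_id = c(can_id, abr_id), gene_id = gg$gene_id,
      chrom = gg$gene_id,
      start = c(can[["start"]], abr[["start"]]),
      end = c(can[["end"]], abr[["end"]]),
      strand = gg$strand,
      kind = c("canonical", "aberrant"),
      partner = c(NA_character_, can_id),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Build the transcript models (canonical and aberrant) for one gene
#'
#' @param ann A `junction_annotation` from [make_annotation()].
#' @param gene_id Gene identifier.
#' @return List with elements `canonical` and `aberrant`, each a
#'   [transcript_model()]. The aberrant model's CDS end marks where the
#'   canonical stop codon ends in aberrant-isoform coordinates; for
#'   frameshifting inserts that annotated span is not a multiple of 3, which
#'   is the point.
#' @export
transcript_models <- function(ann, gene_id) {
  stopifnot(inherits(ann, "junction_annotation"))
  gg <- ann$genes[ann$genes$gene_id == gene_id, ]
  if (nrow(gg) != 1L) stop("unknown gene_id: ", gene_id)
  d <- gg$insert_len
  ex_can_plus <- data.frame(
    start = c(0L, gg$e1 + gg$i1, gg$e1 + gg$i1 + gg$e2 + gg$i2),
    end = c(gg$e1, gg$e1 + gg$i1 + gg$e2, gg$contig_len)
  )
  ex_abr_plus <- ex_can_plus
  ex_abr_plus$start[2L] <- ex_abr_plus$start[2L] - d
  flip <- function(ex) {
    if (gg$strand == "+") return(ex)
    out <- data.frame(start = gg$contig_len - rev(ex$end),
                      end = gg$contig_len - rev(ex$start))
    out
  }
  splice <- function(ex_plus) {
    seqs <- substring(ann$genome[[gene_id]],
                      flip(ex_plus)$start + 1L, flip(ex_plus)$end)
    tx <- paste(seqs, collapse = "")
    if (gg$strand == "-") tx <- .revcomp(tx)
    tx
  }
  canonical <- transcript_model(
    transcript_id = paste0(gene_id, ".canonical"),
    exons = flip(ex_can_plus), strand = gg$strand,
    cds_start = gg$cds_start, cds_end = gg$cds_start + gg$cds_len,
    sequence = splice(ex_can_plus)
  )
  aberrant <- transcript_model(
    transcript_id = paste0(gene_id, ".aberrant"),
    exons = flip(ex_abr_plus), strand = gg$strand,
    cds_start = gg$cds_start, cds_end = gg$cds_start + gg$cds_len + d,
    sequence = splice(ex_abr_plus),
    check_cds_frame = FALSE
  )
  list(canonical = canonical, aberrant = aberrant)
}

#' Write a synthetic annotation to BED12 + FASTA
#'
#' Writes the contig sequences (`genome.fa`), the spliced transcript
#' sequences (`transcripts.fa`), the transcript models (`transcripts.bed`,
#' BED12 with CDS as the thick region) and the junction table
#' (`junctions.tsv`).
#'
#' @param ann A `junction_annotation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "junction_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.fa"),
             bed = file.path(dir, "transcripts.bed"),
             junctions = file.path(dir, "junctions.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ann$genome), paths[["genome"]])
  models <- lapply(ann$genes$gene_id, function(g) transcript_models(ann, g))
  txs <- unlist(lapply(models, function(m) {
    setNames(c(m$canonical$sequence, m$aberrant$sequence),
             c(m$canonical$transcript_id, m$aberrant$transcript_id))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(txs), paths[["transcripts"]])
  bed <- do.call(rbind, lapply(models, function(m) {
    rbind(.model_to_bed12(m$canonical, m$canonical$transcript_id),
          .model_to_bed12(m$aberrant, m$aberrant$transcript_id))
  }))
  write.table(bed, paths[["bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(ann$junctions, paths[["junctions"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.model_to_bed12 <- function(m, chrom_name) {
  ex <- m$exons
  thick <- .tx_interval_to_genomic(m, m$cds_start, m$cds_end)
  data.frame(
    chrom = sub("\\..*$", "", chrom_name), start = ex$start[1L],
    end = ex$end[nrow(ex)], name = m$transcript_id, score = 0L,
    strand = m$strand, thickStart = thick[1L], thickEnd = thick[2L],
    itemRgb = "0,0,0", blockCount = nrow(ex),
    blockSizes = paste0(paste(ex$end - ex$start, collapse = ","), ","),
    blockStarts = paste0(paste(ex$start - ex$start[1L], collapse = ","), ","),
    stringsAsFactors = FALSE
  )
}

# genomic footprint [start,end) of a transcript-coordinate interval
.tx_interval_to_genomic <- function(m, tx_start, tx_end) {
  g1 <- .tx_to_genomic(m$exons, m$strand, tx_start)
  g2 <- .tx_to_genomic(m$exons, m$strand, tx_end - 1L)
  c(min(g1, g2), max(g1, g2) + 1L)
}

# map a 0-based transcript coordinate to a 0-based genomic coordinate
.tx_to_genomic <- function(exons, strand, t) {
  widths <- exons$end - exons$start
  if (strand == "-") {
    widths <- rev(widths)
  }
  cum <- cumsum(c(0L, widths))
  k <- findInterval(t, cum, rightmost.closed = FALSE)
  off <- t - cum[k]
  if (strand == "+") {
    exons$start[k] + off
  } else {
    idx <- nrow(exons) - k + 1L
    exons$end[idx] - 1L - off
  }
}

#' Read transcript models back from BED12 + FASTA
#'
#' Reconstructs [transcript_model()] objects from a BED12 file and the contig
#' FASTA written by [write_annotation()] (or any BED12/FASTA pair following
#' the same conventions: one transcript per BED line, CDS as the thick
#' region).
#'
#' @param bed_path BED12 file.
#' @param genome_path FASTA of the contigs named in column 1.
#' @return Named list of `transcript_model` objects.
#' @export
read_annotation <- function(bed_path, genome_path) {
  genome <- Biostrings::readDNAStringSet(genome_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  bed <- read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 12L) stop("expected BED12 (12 columns), got ", ncol(bed))
  colnames(bed)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                           "thickStart", "thickEnd", "itemRgb", "blockCount",
                           "blockSizes", "blockStarts")
  models <- lapply(seq_len(nrow(bed)), function(i) {
    b <- bed[i, ]
    sizes <- as.integer(strsplit(b$blockSizes, ",")[[1L]])
    starts <- as.integer(strsplit(b$blockStarts, ",")[[1L]])
    exons <- data.frame(start = b$start + starts, end = b$start + starts + sizes)
    contig <- as.character(genome[[b$chrom]])
    seqs <- substring(contig, exons$start + 1L, exons$end)
    tx <- paste(seqs, collapse = "")
    if (b$strand == "-") tx <- .revcomp(tx)
    # thick region back to transcript coordinates
    tot <- sum(sizes)
    g2t <- function(g) .genomic_to_tx(exons, b$strand, g)
    if (b$strand == "+") {
      cds_start <- g2t(b$thickStart); cds_end <- g2t(b$thickEnd - 1L) + 1L
    } else {
      cds_start <- g2t(b$thickEnd - 1L); cds_end <- g2t(b$thickStart) + 1L
    }
    transcript_model(b$name, exons, b$strand, cds_start, cds_end, tx,
                     check_cds_frame = FALSE)
  })
  setNames(models, bed$name)
}

.genomic_to_tx <- function(exons, strand, g) {
  widths <- exons$end - exons$start
  k <- which(g >= exons$start & g < exons$end)
  if (length(k) != 1L) stop("genomic position ", g, " not in any exon")
  if (strand == "+") {
    sum(widths[seq_len(k - 1L)]) + (g - exons$start[k])
  } else {
    n <- nrow(exons)
    before <- if (k < n) sum(widths[(k + 1L):n]) else 0L
    before + (exons$end[k] - 1L - g)
  }
}
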