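# Build a small fraction_counts object by hand. `counts` is a junction x
# sample matrix whose rownames follow the <gene>_can / <gene>_abr pairing
# convention and whose colnames follow <genotype>.<pool>.<replicate>.
make_fcm <- function(counts) {
  ids <- rownames(counts)
  gene <- sub("_(can|abr)$", "", ids)
  kind <- ifelse(grepl("_abr$", ids), "aberrant", "canonical")
  junctions <- data.frame(
    junction_id = ids, gene_id = gene, kind = kind,
    partner = ifelse(kind == "aberrant", paste0(gene, "_can"), NA_character_),
    stringsAsFactors = FALSE)
  parts <- strsplit(colnames(counts), ".", fixed = TRUE)
  samples <- data.frame(sample_id = colnames(counts),
                        genotype = vapply(parts, `[`, "", 1L),
                        pool = vapply(parts, `[`, "", 2L),
                        replicate = as.integer(vapply(parts, `[`, "", 3L)),
                        stringsAsFactors = FALSE)
  fraction_counts(counts, samples, junctions)
}

# A single-gene matrix padded with a filler gene so every column total is
# exactly 1e6 (CPM size factor 1): normalized counts equal raw counts, which
# keeps contingency tables exactly as designed.
make_padded_fcm <- function(ab, can, colnames_) {
  stopifnot(length(ab) == length(can), length(ab) == length(colnames_))
  pad <- 1e6 - ab - can
  counts <- rbind(g1_abr = ab, g1_can = can, pad_can = pad)
  colnames(counts) <- colnames_
  normalize_counts(make_fcm(counts))
}
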