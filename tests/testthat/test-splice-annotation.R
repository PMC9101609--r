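test_that("insert length is the strand-aware cryptic-to-canonical distance", {
  can_p <- list(chrom = "c", start = 100L, end = 200L, strand = "+")
  abr_p <- list(chrom = "c", start = 100L, end = 188L, strand = "+")
  expect_equal(insert_length(abr_p, can_p), 12L)

  can_m <- list(chrom = "c", start = 100L, end = 200L, strand = "-")
  abr_m <- list(chrom = "c", start = 112L, end = 200L, strand = "-")
  expect_equal(insert_length(abr_m, can_m), 12L)

  # cryptic site outside the intron
  out <- list(chrom = "c", start = 100L, end = 99L, strand = "+")
  expect_error(insert_length(out, can_p), "inside the intron")
  expect_error(insert_length(can_p, can_p), "inside the intron")
})

test_that("insert length equals the isoform length difference on generated genes", {
  ann <- make_annotation(sim_config(seed = 21, n_genes = 25))
  for (g in ann$genes$gene_id) {
    mods <- transcript_models(ann, g)
    j <- ann$junctions[ann$junctions$gene_id == g, ]
    abr <- j[j$kind == "aberrant", ]; can <- j[j$kind == "canonical", ]
    d <- insert_length(abr, can)
    expect_equal(nchar(mods$aberrant$sequence) - nchar(mods$canonical$sequence), d)
    expect_equal(d, ann$genes$insert_len[ann$genes$gene_id == g])
  }
})

test_that("frame classification is mod-3 with period 3", {
  expect_equal(classify_frame(c(12, 13, 0)),
               c("in-frame", "out-of-frame", "in-frame"))
  expect_error(classify_frame(-1), "non-negative")
  lens <- 0:40
  expect_equal(classify_frame(lens), classify_frame(lens + 3L))
})

test_that("PTC scan finds planted in-frame stops and ignores stop-free inserts", {
  # 2-exon toy gene built by hand: CDS ATG + 4 codons + TAA, insert carries
  # an in-frame TAA (GGG TAA GGG) at a codon boundary
  exon1 <- "ATGCCTGGA"              # ATG CCT GGA
  insert <- "GGGTAAGGG"
  exon2 <- "GCAGAAGCTTAAGCTGCT"     # GCA GAA GCT TAA <- canonical stop
  intron <- paste0("GTAAGTATAT", insert)
  contig <- paste0(exon1, intron, exon2)
  canonical <- transcript_model(
    "toy.canonical",
    exons = data.frame(start = c(0L, nchar(exon1) + nchar(intron)),
                       end = c(nchar(exon1), nchar(contig))),
    strand = "+", cds_start = 0L, cds_end = nchar(exon1) + 12L,
    sequence = paste0(exon1, exon2))
  can_j <- list(chrom = "toy", start = nchar(exon1),
                end = nchar(exon1) + nchar(intron), strand = "+")
  abr_j <- list(chrom = "toy", start = nchar(exon1),
                end = can_j$end - nchar(insert), strand = "+")
  iso <- aberrant_isoform(canonical, abr_j, can_j, setNames(contig, "toy"))
  expect_equal(scan_ptc(iso), nchar(exon1) + 3L)  # the TAA inside the insert

  # same gene with a stop-free in-frame insert: no PTC
  insert2 <- "GGGCCCGGG"
  contig2 <- paste0(exon1, "GTAAGTATAT", insert2, exon2)
  iso2 <- aberrant_isoform(canonical, abr_j, can_j, setNames(contig2, "toy"))
  expect_true(is.na(scan_ptc(iso2)))

  # missing start codon is an error
  bad <- canonical; bad$cds_start <- 3L; bad$cds_end <- 15L
  expect_error(scan_ptc(bad), "start codon")
})

test_that("PTC positions match a codon-by-codon translation oracle", {
  ann <- make_annotation(sim_config(seed = 33, n_genes = 200))
  genome <- ann$genome
  for (g in ann$genes$gene_id) {
    mods <- transcript_models(ann, g)
    iso <- mods$aberrant
    got <- scan_ptc(iso)
    first <- oracle_first_stop(iso$sequence, iso$cds_start)
    expected <- if (!is.na(first) && first < iso$cds_end - 3L) first else NA_integer_
    expect_identical(got, expected)
  }
})

test_that("the 50-nt rule separates NMD-sensitive from insensitive PTCs", {
  # 2-exon model, 200 nt exon1 + 100 nt exon2; last junction at 200
  seqs <- paste(rep("ATGGCT", 50), collapse = "")
  model <- transcript_model("m", data.frame(start = c(0L, 250L),
                                            end = c(200L, 350L)),
                            "+", 0L, 300L, sequence = toupper(seqs))
  expect_equal(predict_nmd(NA, model), "NMD-insensitive")
  expect_equal(predict_nmd(140L, model), "NMD-sensitive")    # 60 nt upstream
  expect_equal(predict_nmd(190L, model), "NMD-insensitive")  # 10 nt upstream
  expect_equal(predict_nmd(150L, model), "NMD-insensitive")  # exactly 50 nt

  single <- transcript_model("s", data.frame(start = 0L, end = 300L),
                             "+", 0L, 300L, sequence = toupper(seqs))
  for (ptc in c(0L, 100L, 249L)) {
    expect_equal(predict_nmd(ptc, single), "NMD-insensitive")
  }
})

test_that("junction annotation reproduces planted frame and NMD truth", {
  ann <- make_annotation(sim_config(seed = 8, n_genes = 60))
  dir <- tempfile()
  paths <- write_annotation(ann, dir)
  models <- read_annotation(paths[["bed"]], paths[["genome"]])
  genome <- Biostrings::readDNAStringSet(paths[["genome"]])
  fp <- annotate_junctions(ann$junctions,
                           models[grepl("\\.canonical$", names(models))],
                           genome)
  expect_equal(fp$insert_length, ann$genes$insert_len)
  expect_equal(fp$frame, ann$genes$frame)
  expect_equal(fp$nmd == "NMD-sensitive", ann$genes$nmd)
  expect_identical(fp$ptc_position, ann$genes$ptc_tx)

  # reconstructed transcript sequences match the written transcript FASTA
  tx <- Biostrings::readDNAStringSet(paths[["transcripts"]])
  expect_equal(as.character(tx[["gene0001.canonical"]]),
               models[["gene0001.canonical"]]$sequence)
})
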