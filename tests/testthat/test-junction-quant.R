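test_that("count table round-trips through TSV and rejects malformed input", {
  counts <- matrix(c(10L, 20L, 5L, 7L, 30L, 40L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1_can", "g1_abr", "g2_can"),
                                   c("WT.monosome.1", "MUT.monosome.1")))
  junctions <- data.frame(
    junction_id = rownames(counts), gene_id = c("g1", "g1", "g2"),
    kind = c("canonical", "aberrant", "canonical"),
    partner = c(NA, "g1_can", NA), stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(counts),
                        genotype = c("WT", "MUT"),
                        pool = "monosome", replicate = 1L,
                        stringsAsFactors = FALSE)
  m <- fraction_counts(counts, samples, junctions)
  expect_equal(dim(m$counts), c(3L, 2L))

  path <- tempfile(fileext = ".tsv")
  write_junction_counts(m, path)
  m2 <- load_junction_counts(path)
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$samples, m$samples)

  # negative count names the offending row
  lines <- readLines(path)
  lines[3] <- sub("\t5\t", "\t-1\t", lines[3])
  bad <- tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(load_junction_counts(bad), "line\\(s\\) 3")

  # constructor-level validation
  expect_error(fraction_counts(rbind(counts, g1_can = c(1L, 1L)),
                               samples, junctions), "duplicate")
  jx <- junctions; jx$partner[2] <- "missing_can"
  expect_error(fraction_counts(counts, samples, jx), "partner")
})

test_that("CPM normalization matches per-column division and conserves zeros", {
  counts <- matrix(c(50L, 0L, 1999950L, 100L, 3L, 999897L), ncol = 2,
                   dimnames = list(c("g1_abr", "g1_can", "g2_can"),
                                   c("WT.whole.1", "WT.whole.2")))
  m <- normalize_counts(make_fcm(counts))
  nm <- normalized_counts(m)
  expect_equal(nm["g1_abr", "WT.whole.1"], 25)  # 50 / (2e6 / 1e6)
  expect_equal(nm, sweep(counts, 2, colSums(counts) / 1e6, "/"))
  expect_true(all(nm[counts == 0] == 0))

  z <- counts; z[, 2] <- 0L
  expect_error(normalize_counts(make_fcm(z)), "all-zero")

  # columns with equal counts get equal normalized values
  eq <- counts; eq[, 2] <- eq[, 1]
  nm_eq <- normalized_counts(normalize_counts(make_fcm(eq)))
  expect_equal(nm_eq[, 1], nm_eq[, 2])
})

test_that("splice index is the normalized aberrant/canonical ratio", {
  counts <- matrix(c(0L, 100L, 999900L,
                     30L, 60L, 999910L), ncol = 2,
                   dimnames = list(c("g1_abr", "g1_can", "g2_can"),
                                   c("WT.monosome.1", "MUT.monosome.1")))
  m <- normalize_counts(make_fcm(counts))
  expect_equal(splice_index(m, "g1_abr", "WT", "monosome")$index, 0)
  expect_equal(splice_index(m, "g1_abr", "MUT", "monosome")$index, 0.5)

  # canonical zero => flagged undefined, not NaN
  z <- counts; z["g1_can", 1] <- 0L
  res <- splice_index(normalize_counts(make_fcm(z)), "g1_abr", "WT", "monosome")
  expect_true(res$undefined)
  expect_true(is.na(res$index))

  # invariant to a sample-wide rescaling (size factors cancel in the ratio)
  sc <- counts; sc[, 2] <- sc[, 2] * 4L
  m_sc <- normalize_counts(make_fcm(sc))
  expect_equal(splice_index(m_sc, "g1_abr", "MUT", "monosome")$index, 0.5)
})

test_that("mutant splice indices exceed wild type for planted aberrant junctions", {
  cfg <- sim_config(seed = 13, n_genes = 40, depth = 2e6)
  sim <- simulate_fraction_counts(cfg, make_annotation(cfg))
  m <- normalize_counts(sim$matrix)
  ab <- sim$truth$junction_id[sim$truth$aberrant]
  idx <- vapply(ab, function(j) {
    splice_index(m, j, "MUT", "monosome")$index -
      splice_index(m, j, "WT", "monosome")$index
  }, 0)
  expect_true(all(idx > 0))
})

test_that("differential junction expression uses an exact test with BH control", {
  # identical genotypes: p = 1, no pass
  counts <- matrix(rep(c(40L, 80L, 999880L), 2), ncol = 2,
                   dimnames = list(c("g1_abr", "g1_can", "g2_can"),
                                   c("WT.whole.1", "MUT.whole.1")))
  dje <- differential_junction_expression(make_fcm(counts))
  expect_equal(dje$p, 1)
  expect_false(dje$pass)

  # designed 2x2 table equals the enumeration oracle
  m <- make_padded_fcm(ab = c(10L, 100L), can = c(100L, 10L),
                       colnames_ = c("WT.whole.1", "MUT.whole.1"))
  dje2 <- differential_junction_expression(m)
  expect_equal(dje2$p, oracle_fisher_p(100L, 10L, 10L, 100L), tolerance = 1e-12)

  # genotype missing is a hard error
  one <- matrix(c(1L, 2L, 999997L), ncol = 1,
                dimnames = list(c("g1_abr", "g1_can", "g2_can"), "WT.whole.1"))
  expect_error(differential_junction_expression(make_fcm(one)), "MUT")
})

test_that("planted differential junctions are recovered at depth", {
  cfg <- sim_config(seed = 17, n_genes = 300, depth = 2e6)
  sim <- simulate_fraction_counts(cfg, make_annotation(cfg))
  dje <- differential_junction_expression(sim$matrix)
  recall <- mean(dje$pass[dje$junction_id %in%
                            sim$truth$junction_id[sim$truth$aberrant]])
  expect_gte(recall, 0.95)
})
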