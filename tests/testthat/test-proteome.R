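# minimal quant-table builder: peptide and intensity replicates per condition
make_quant <- function(pep_wt, pep_mut, int_wt, int_mut,
                       ids = paste0("p", seq_len(nrow(int_wt)))) {
  q <- data.frame(protein_id = ids, gene_id = sub("^p", "g", ids),
                  stringsAsFactors = FALSE)
  for (r in seq_len(ncol(pep_wt))) q[[paste0("pep_WT_", r)]] <- pep_wt[, r]
  for (r in seq_len(ncol(pep_mut))) q[[paste0("pep_MUT_", r)]] <- pep_mut[, r]
  for (r in seq_len(ncol(int_wt))) q[[paste0("int_WT_", r)]] <- int_wt[, r]
  for (r in seq_len(ncol(int_mut))) q[[paste0("int_MUT_", r)]] <- int_mut[, r]
  q
}

test_that("the peptide filter requires >= 3 peptides in every replicate", {
  pep <- rbind(c(3, 3, 3), c(3, 2, 3), c(0, 0, 0))
  q <- make_quant(pep, rbind(c(3, 3, 3), c(3, 3, 3), c(0, 0, 0)),
                  matrix(1e6, 3, 3), matrix(1e6, 3, 3))
  expect_equal(filter_quantified(q), c(TRUE, FALSE, FALSE))
})

test_that("condition-unique proteins need full detection on one side only", {
  pep_wt <- rbind(c(3, 3, 3), c(3, 3, 3), c(0, 0, 0))
  pep_mut <- rbind(c(0, 0, 0), c(0, 1, 0), c(4, 5, 3))
  q <- make_quant(pep_wt, pep_mut, matrix(1e6, 3, 3), matrix(1e6, 3, 3))
  u <- unique_proteins(q)
  expect_equal(u$unique_WT, "p1")
  expect_equal(u$unique_MUT, "p3")
  # quantified and unique sets are disjoint by construction
  expect_length(intersect(q$protein_id[filter_quantified(q)],
                          c(u$unique_WT, u$unique_MUT)), 0)
})

test_that("differential abundance applies fold-change and p thresholds", {
  set.seed(42)
  n <- 40
  int_wt <- matrix(2^rnorm(n * 3, 20, 0.02), n)
  int_mut <- int_wt * c(1 / 1.5, rep(1, n - 1)) * 2^rnorm(n * 3, 0, 0.02)
  q <- make_quant(matrix(5L, n, 3), matrix(5L, n, 3), int_wt, int_mut)
  dp <- differential_abundance(q)
  expect_equal(dp$call[1], "underrepresented")
  expect_true(all(dp$call[-1] == "unchanged"))

  # identical intensities: fold change 1, unchanged
  q_id <- make_quant(matrix(5L, 2, 3), matrix(5L, 2, 3),
                     matrix(1e6, 2, 3), matrix(1e6, 2, 3))
  dp_id <- differential_abundance(q_id)
  expect_equal(dp_id$log2_fc, c(0, 0))
  expect_equal(dp_id$call, c("unchanged", "unchanged"))

  # calls stable under replicate relabeling
  perm_cols <- c("protein_id", "gene_id",
                 paste0("pep_WT_", c(2, 3, 1)), paste0("pep_MUT_", c(3, 1, 2)),
                 paste0("int_WT_", c(2, 3, 1)), paste0("int_MUT_", c(3, 1, 2)))
  q_perm <- q[perm_cols]
  names(q_perm) <- names(q)
  expect_equal(differential_abundance(q_perm)$call, dp$call)
})

test_that("overlap percentages honor the rounding contract", {
  # printed contingency counts: 128 of 1445 aberrant genes, 13 of 181 DEGs
  aberrant <- sprintf("a%04d", 1:1445)
  dp <- data.frame(protein_id = sprintf("p%04d", 1:200),
                   gene_id = c(aberrant[1:128], sprintf("x%03d", 1:72)),
                   log2_fc = rep(c(-1, 1), 100), p = 1e-4, adj_p = 1e-3,
                   call = rep(c("underrepresented", "overrepresented"), 100),
                   stringsAsFactors = FALSE)
  ov_t <- overlap_splice_protein(aberrant, dp, round_mode = "truncate")
  expect_equal(ov_t$n_overlap, 128)
  expect_equal(ov_t$pct_overlap, 8.8)
  ov_h <- overlap_splice_protein(aberrant, dp, round_mode = "half_even")
  expect_equal(ov_h$pct_overlap, 8.9)

  deg <- c(dp$gene_id[1:13], sprintf("d%03d", 1:168))
  ov_e <- overlap_expression_protein(deg, dp, round_mode = "half_even")
  expect_equal(ov_e$n_overlap, 13)
  expect_equal(ov_e$pct_overlap, 7.2)

  # degenerate inputs
  none <- overlap_splice_protein("zzz", dp)
  expect_equal(none$pct_overlap, 0)
  expect_error(overlap_splice_protein(character(0), dp), "empty")
})

test_that("overlaps equal brute-force set intersections on simulated truth", {
  cfg <- sim_config(seed = 29, n_genes = 120)
  sim <- simulate_fraction_counts(cfg, make_annotation(cfg))
  pr <- simulate_proteome(cfg, sim$truth)
  dp <- differential_abundance(pr$quant)
  aberrant <- sim$truth$gene_id[sim$truth$aberrant]
  ov <- overlap_splice_protein(aberrant, dp)
  brute <- unique(dp$gene_id[dp$call %in% c("underrepresented", "overrepresented")])
  expect_equal(ov$n_overlap, length(intersect(aberrant, brute)))
})

test_that("fold changes stratify by splice category with NMD-linked drops", {
  cfg <- sim_config(seed = 31, n_genes = 250, frac_aberrant = 0.5,
                    proteome_link_prob = 1)
  sim <- simulate_fraction_counts(cfg, make_annotation(cfg))
  # restrict the splice annotation to the aberrant genes so non-aberrant
  # genes form the canonical stratum
  fp <- data.frame(gene_id = sim$truth$gene_id[sim$truth$aberrant],
                   nmd = ifelse(sim$truth$nmd[sim$truth$aberrant],
                                "NMD-sensitive", "NMD-insensitive"))
  pr <- simulate_proteome(cfg, sim$truth)
  dp <- differential_abundance(pr$quant)
  st <- stratify_fc_by_splice_category(dp, fp)
  expect_equal(st$category, c("canonical", "NMD-sensitive", "NMD-insensitive"))
  expect_equal(sum(st$n), sum(!is.na(dp$log2_fc)))
  # planted down-folds pull the NMD-sensitive stratum below the others;
  # with link probability 1 every NMD-sensitive aberrant gene is affected
  expect_lt(st$median[st$category == "NMD-sensitive"],
            st$median[st$category == "canonical"])

  # empty stratum reported with n = 0
  st0 <- stratify_fc_by_splice_category(dp[0, ], fp)
  expect_true(all(st0$n == 0))
})
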