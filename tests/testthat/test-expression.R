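expr_row <- function(gene_id, ...) {
  vals <- list(...)
  dplyr::bind_cols(tibble::tibble(gene_id = gene_id), tibble::as_tibble(vals))
}

test_that("expressing-gene selection averages replicates and applies both rules", {
  expr <- tibble::tibble(
    gene_id = c("kept", "zeroed", "weak"),
    t1_1 = c(0.4, 0, 0.9), t1_2 = c(0.6, 0, 0.9),
    t2_1 = c(1.1, 5, 0.8), t2_2 = c(1.3, 5, 0.8),
    t3_1 = c(0.8, 10, 0.7), t3_2 = c(0.8, 10, 0.7)
  )
  # kept: means (0.5, 1.2, 0.8) -> >1 somewhere, never 0
  # zeroed: a zero time point excludes despite high values elsewhere
  # weak: never exceeds 1
  expect_equal(select_expressing(expr), "kept")
  # raising the threshold is monotone: never adds genes
  for (thr in c(0.5, 1, 2, 5)) {
    expect_true(all(select_expressing(expr, thr) %in% select_expressing(expr, 0)))
  }
})

test_that("spearman_rho is standard average-rank Spearman with NA for constant series", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)
  # invariant under strictly monotone transforms
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1.8, 2.8, 1, 8)
  expect_equal(spearman_rho(exp(x), y^3), spearman_rho(x, y))
  expect_true(is.na(spearman_rho(c(5, 5, 5, 5), 1:4)))
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("pair correlations join by gene_id, skip missing genes, keep undefined rho as NA", {
  genes <- rbind(g1("s", "+", 10000, 12000), g1("a", "-", 8000, 9900),
                 g1("s2", "+", 50000, 52000), g1("a2", "-", 48000, 49900),
                 g1("s3", "+", 90000, 92000), g1("a3", "-", 88000, 89900))
  pairs <- find_antisense_pairs(genes, mode = "tss", window = c(-5000, -1))
  expr <- tibble::tibble(
    gene_id = c("s", "a", "s2", "a2", "s3"),
    t1_1 = c(1, 2, 3, 3, 1), t2_1 = c(2, 4, 5, 3, 1),
    t3_1 = c(3, 6, 2, 3, 1), t4_1 = c(4, 8, 8, 3, 1)
  )
  expect_message(rec <- pair_correlations(pairs, expr), "skipped")
  # identical ranking -> rho 1 for s/a (both directions present)
  expect_equal(rec$rho[rec$sense_gene_id == "s"], 1)
  # constant antisense profile -> undefined
  expect_true(is.na(rec$rho[rec$sense_gene_id == "s2"]))
  # the s3/a3 pair lost its antisense gene entirely
  expect_false("s3" %in% rec$sense_gene_id)
})

test_that("count-based binning makes groups of bin_size with boundary ties merged in", {
  rec <- tibble::tibble(as_tss_position = c(-250:-1, 1:6), id = 1:256)
  b <- bin_pairs_by_count(rec, bin_size = 100)
  expect_equal(as.integer(table(b$group)), c(100, 100, 56))
  expect_equal(nrow(b), 256)

  # a tie spanning the 100/101 boundary pulls the tied records into group 1
  tied <- tibble::tibble(as_tss_position = c(seq(-500, -402), rep(-401L, 3),
                                             seq(-400, -303)))
  tb <- bin_pairs_by_count(tied, bin_size = 100)
  expect_equal(sum(tb$group == 1), 102)
  expect_true(all(tb$as_tss_position[tb$group == 1] <= -401))

  empty <- bin_pairs_by_count(tibble::tibble(as_tss_position = integer()))
  expect_equal(nrow(empty), 0)
})

test_that("nearest-pair selection keeps the n smallest absolute offsets with ties", {
  rec <- tibble::tibble(as_tss_position = c(-(1:300), 1:200 + 0L))
  sel <- nearest_pairs(rec, n = 400)
  expect_equal(nrow(sel), 400)
  expect_true(max(abs(sel$as_tss_position)) <= 300)

  tied <- tibble::tibble(as_tss_position = c(1:399, 400L, -400L))
  sel2 <- nearest_pairs(tied, n = 400)
  expect_equal(nrow(sel2), 401)

  expect_warning(all3 <- nearest_pairs(rec, n = 1000), "returning all")
  expect_equal(nrow(all3), nrow(rec))
})

test_that("the random same-chromosome null is seeded, opposite-strand, and centred near zero", {
  genes <- simulate_random_genes(n_genes = 80, seed = 51)
  set.seed(99)
  expr <- tibble::tibble(gene_id = genes$gene_id)
  for (s in sprintf("t%d_1", 1:8)) expr[[s]] <- runif(nrow(genes), 1.5, 50)
  r1 <- random_chromosome_pairs(genes, expr, n = 200, seed = 7)
  r2 <- random_chromosome_pairs(genes, expr, n = 200, seed = 7)
  expect_identical(r1, r2)
  strands <- setNames(genes$strand, genes$gene_id)
  chrs <- setNames(genes$chr, genes$gene_id)
  expect_true(all(strands[r1$sense_gene_id] != strands[r1$as_gene_id]))
  expect_true(all(chrs[r1$sense_gene_id] == chrs[r1$as_gene_id]))
  expect_true(all(r1$sense_gene_id != r1$as_gene_id))
  # i.i.d. noise profiles: mean rho ~ 0 within Monte-Carlo error
  expect_lt(abs(mean(r1$rho)), 3 / sqrt(200))
})

test_that("correlation cutoffs are strict and the screen recovers planted candidates", {
  rho <- c(0.9, 0.95, -0.7, -0.71, NA, 0.2)
  rec <- tibble::tibble(sense_gene_id = paste0("s", 1:6),
                        as_gene_id = paste0("a", 1:6), rho = rho)
  scr <- select_correlated(rec)
  expect_equal(scr$positive$sense_gene_id, "s2")  # 0.9 itself excluded
  expect_equal(scr$negative$sense_gene_id, "s4")  # -0.7 itself excluded
  expect_equal(glance(scr)$n_positive, 1)
  expect_equal(nrow(tidy(scr)), 2)

  # planted sizes: 5 positives above 0.95, 3 negatives below -0.8, 4 decoys
  rec2 <- tibble::tibble(
    sense_gene_id = paste0("s", 1:12), as_gene_id = paste0("a", 1:12),
    rho = c(runif(5, 0.96, 1), runif(3, -1, -0.81), runif(4, -0.5, 0.5))
  )
  scr2 <- select_correlated(rec2)
  expect_equal(nrow(scr2$positive), 5)
  expect_equal(nrow(scr2$negative), 3)
  expect_true(all(diff(scr2$table$rho[scr2$table$direction == "positive"]) <= 0))
})

test_that("the candidate export table carries both genes' expression profiles", {
  rec <- tibble::tibble(sense_gene_id = "s", as_gene_id = "a", rho = 0.99)
  expr <- tibble::tibble(gene_id = c("s", "a"),
                         t1_1 = c(1, 2), t1_2 = c(3, 4), t2_1 = c(5, 6), t2_2 = c(7, 8))
  scr <- select_correlated(rec, expr = expr)
  expect_equal(scr$table$sense_TPM_t1, 2)
  expect_equal(scr$table$as_TPM_t2, 7)
})
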