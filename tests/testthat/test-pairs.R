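test_that("TSS and TES respect strand, including single-bp genes", {
  g <- gt(list("p", "+", 100, 500), list("m", "-", 100, 500),
          list("d", "+", 7, 7), list("e", "-", 7, 7))
  expect_equal(gene_tss(g), c(100, 500, 7, 7))
  expect_equal(gene_tes(g), c(500, 100, 7, 7))
})

test_that("signed anchor offsets follow the sense transcription direction", {
  # plus-strand sense, divergent antisense upstream
  expect_equal(as_tss_position(g1("s", "+", 1000, 2000), g1("a", "-", 200, 667)), -333L)
  # minus-strand sense: upstream means higher coordinates
  expect_equal(as_tss_position(g1("s", "-", 1000, 2000), g1("a", "+", 2500, 3000)), -500L)
  # coincident anchors
  expect_equal(as_tss_position(g1("s", "+", 100, 200), g1("a", "-", 50, 100)), 0L)
  expect_equal(as_tes_position(g1("s", "+", 1000, 2000), g1("a", "-", 2100, 2600)), 100L)
  expect_equal(as_tes_position(g1("s", "-", 1000, 2000), g1("a", "+", 400, 900)), 100L)
  expect_equal(as_tes_position(g1("s", "+", 100, 200), g1("a", "-", 200, 300)), 0L)
  expect_error(as_tss_position(g1("s", "+", 1, 10), g1("a", "+", 20, 30)),
               "opposite strands")
})

test_that("anchor windows convert signed offset ranges to closed coordinate intervals", {
  w <- anchor_window(g1("s", "+", 69471185, 69482699), -500, -1, "tss")
  expect_equal(w$lo, 69470685L)
  expect_equal(w$hi, 69471184L)
  wm <- anchor_window(g1("s", "-", 5000, 10000), -500, -1, "tss")
  expect_equal(c(wm$lo, wm$hi), c(10001L, 10500L))
  w0 <- anchor_window(g1("s", "+", 300, 400), 0, 0, "tss")
  expect_equal(c(w0$lo, w0$hi), c(300L, 300L))
  expect_error(anchor_window(g1("s", "+", 1, 10), 5, -5), "<=")
})

test_that("the eight-type classifier follows the membership and gap rules", {
  s <- g1("s", "+", 1000, 2000)
  expect_equal(classify_pair_type(s, g1("a", "-", 1200, 1800)), "EB")
  # 5' partial overlap is head-to-head from either gene's perspective
  a <- g1("a", "-", 500, 1500)
  expect_equal(classify_pair_type(s, a), "HH")
  expect_equal(classify_pair_type(a, s), "HH")
  # antisense covering the sense gene
  expect_equal(classify_pair_type(s, g1("a", "-", 500, 2500)), "FO")
  # nearby/faraway threshold at exactly 5 kb end-to-end gap
  s2 <- g1("s", "+", 10000, 12000)
  expect_equal(classify_pair_type(s2, g1("a", "-", 4000, 5000)), "nHH")
  expect_equal(classify_pair_type(s2, g1("a", "-", 4000, 4999)), "fHH")
  expect_equal(classify_pair_type(s2, g1("a", "-", 17000, 18000)), "nTT")
  expect_equal(classify_pair_type(s2, g1("a", "-", 17001, 18000)), "fTT")
  # single-base overlap counts as overlap (closed intervals)
  expect_equal(classify_pair_type(s, g1("a", "-", 500, 1000)), "HH")
  # identical extents: both anchors inside -> EB in both roles
  expect_equal(classify_pair_type(s, g1("a", "-", 1000, 2000)), "EB")
  expect_equal(classify_pair_type(g1("a", "-", 1000, 2000), s), "EB")
  expect_error(classify_pair_type(s, g1("a", "-", 1, 10, chr = "2")), "chromosome")
})

test_that("overlap extraction emits both orientations and ignores same-strand genes", {
  genes <- rbind(g1("s", "+", 1000, 2000), g1("a", "-", 1200, 1800))
  p <- find_antisense_pairs(genes, mode = "overlap")
  expect_equal(nrow(p), 2)
  expect_setequal(p$sense_gene_id, c("s", "a"))
  expect_setequal(p$type, c("EB", "FO"))

  plus_only <- rbind(g1("x", "+", 1, 100), g1("y", "+", 50, 150))
  expect_equal(nrow(find_antisense_pairs(plus_only, mode = "overlap")), 0)
})

test_that("TSS-window extraction has inclusive bounds and sees divergent pairs from both sides", {
  s <- g1("s", "+", 10000, 12000)
  a_at <- function(off) {
    # antisense TSS (its end) at sense TSS + off
    g1("a", "-", 10000 + off - 800, 10000 + off)
  }
  win <- c(-500, -1)
  p500 <- find_antisense_pairs(rbind(s, a_at(-500)), mode = "tss", window = win)
  expect_equal(sum(p500$sense_gene_id == "s"), 1)
  p501 <- find_antisense_pairs(rbind(s, a_at(-501)), mode = "tss", window = win)
  expect_equal(sum(p501$sense_gene_id == "s"), 0)

  # a divergent pair is upstream from both genes' perspectives: two rows
  genes <- rbind(g1("s", "+", 10000, 12000), g1("a", "-", 8000, 9667))
  p <- find_antisense_pairs(genes, mode = "tss", window = c(-500, -1))
  expect_equal(nrow(p), 2)
  expect_equal(p$as_tss_position[p$sense_gene_id == "s"], -333L)
  expect_equal(p$as_tss_position[p$sense_gene_id == "a"], -333L)
  expect_equal(unique(p$type), "nHH")

  expect_error(find_antisense_pairs(genes, mode = "tss"), "window")
  expect_error(find_antisense_pairs(genes, mode = "tss", window = c(1, -1)), "min")
})

test_that("TES-window extraction mirrors the TSS mode on convergent pairs", {
  genes <- rbind(g1("s", "+", 1000, 2000), g1("a", "-", 2100, 2600))
  hit <- find_antisense_pairs(genes, mode = "tes", window = c(0, 500))
  expect_true("s" %in% hit$sense_gene_id)
  miss <- find_antisense_pairs(genes, mode = "tes", window = c(-500, -1))
  expect_false("s" %in% miss$sense_gene_id)
})

test_that("numeric mode aliases 1/2/3 resolve to overlap/tss/tes", {
  genes <- rbind(g1("s", "+", 1000, 2000), g1("a", "-", 1200, 1800))
  expect_identical(find_antisense_pairs(genes, mode = 1),
                   find_antisense_pairs(genes, mode = "overlap"))
  expect_identical(find_antisense_pairs(genes, mode = 2, window = c(-100, 100)),
                   find_antisense_pairs(genes, mode = "tss", window = c(-100, 100)))
})

test_that("every extraction mode matches the brute-force oracle on random tables", {
  for (seed in c(11, 12, 13)) {
    genes <- simulate_random_genes(n_genes = 120, seed = seed,
                                   chromosomes = c(chrA = 9e4, chrB = 9e4))
    expect_equal(pair_key(find_antisense_pairs(genes, mode = "overlap")),
                 pair_key(oracle_pairs(genes, "overlap")))
    for (win in list(c(-5000, -1), c(-1000, 4999), c(0, 0))) {
      expect_equal(pair_key(find_antisense_pairs(genes, mode = "tss", window = win)),
                   pair_key(oracle_pairs(genes, "tss", win)))
      expect_equal(pair_key(find_antisense_pairs(genes, mode = "tes", window = win)),
                   pair_key(oracle_pairs(genes, "tes", win)))
    }
  }
})

test_that("window extraction agrees with the anchor-window interval", {
  genes <- simulate_random_genes(n_genes = 150, seed = 21,
                                 chromosomes = c(chrA = 1.2e5))
  win <- c(-2000, 1500)
  p <- find_antisense_pairs(genes, mode = "tss", window = win)
  aw <- anchor_window(genes, win[1], win[2], "tss")
  tssv <- setNames(gene_tss(genes), genes$gene_id)
  lo <- setNames(aw$lo, aw$gene_id)
  hi <- setNames(aw$hi, aw$gene_id)
  # every returned antisense anchor lies inside the sense gene's window
  expect_true(all(tssv[p$as_gene_id] >= lo[p$sense_gene_id] &
                    tssv[p$as_gene_id] <= hi[p$sense_gene_id]))
})

test_that("pair output is deterministically ordered and CSV round trips", {
  genes <- simulate_random_genes(n_genes = 60, seed = 31)
  p <- find_antisense_pairs(genes, mode = "overlap")
  expect_identical(p, find_antisense_pairs(genes, mode = "overlap"))
  ord <- order(p$sense_chr, p$sense_start, p$sense_gene_id, p$as_gene_id)
  expect_identical(ord, seq_len(nrow(p)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(p, path)
  hdr <- names(readr::read_csv(path, show_col_types = FALSE, n_max = 0))
  expect_true(all(c("Type", "AS_TSS_position", "AS_TES_position") %in% hdr))
  back <- read_pairs_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(p))
})
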