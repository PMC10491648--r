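# Terse gene-table row constructor for hand-built cases.
gt <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      gene_id = r[[1]], symbol = r[[1]], chr = if (length(r) >= 5) r[[5]] else "1",
      strand = r[[2]], start = as.integer(r[[3]]), end = as.integer(r[[4]]),
      biotype = if (length(r) >= 6) r[[6]] else "protein_coding",
      gene_source = "test", stringsAsFactors = FALSE
    )
  }))
}

g1 <- function(id, strand, start, end, chr = "1", biotype = "protein_coding") {
  tibble::tibble(
    gene_id = id, symbol = id, chr = chr, strand = strand,
    start = as.integer(start), end = as.integer(end),
    biotype = biotype, gene_source = "test"
  )
}
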