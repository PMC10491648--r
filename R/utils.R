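#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats cor ptukey rnorm runif setNames
#' @importFrom utils head
NULL

# Internal: the canonical internal gene-table columns, in order.
gene_table_cols <- c(
  "gene_id", "symbol", "chr", "strand", "start", "end", "biotype", "gene_source"
)

# Internal: check a data frame looks like a gene table; returns it as a tibble
# with the canonical columns first. Extra columns (TPM_*, padj, ...) are kept.
as_gene_table <- function(genes, call = rlang::caller_env()) {
  if (!is.data.frame(genes)) {
    abort("`genes` must be a data frame.", call = call)
  }
  missing <- setdiff(gene_table_cols, names(genes))
  if (length(missing) > 0) {
    abort(
      paste0("`genes` is missing column(s): ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  genes <- tibble::as_tibble(genes)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  dplyr::relocate(genes, dplyr::all_of(gene_table_cols))
}

# Internal: hard check used by the pair engine; strands must be +/- and ids unique.
assert_valid_gene_table <- function(genes, call = rlang::caller_env()) {
  genes <- as_gene_table(genes, call = call)
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(
      paste0(
        "strand must be \"+\" or \"-\"; offending gene_id(s): ",
        paste(head(genes$gene_id[bad_strand], 5), collapse = ", ")
      ),
      call = call
    )
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0) {
    abort(
      paste0("gene_id must be unique; duplicated: ",
             paste(head(dup, 5), collapse = ", ")),
      call = call
    )
  }
  if (any(genes$start > genes$end)) {
    abort("found record(s) with start > end.", call = call)
  }
  if (any(genes$start < 1L)) {
    abort("coordinates are 1-based; start must be >= 1.", call = call)
  }
  genes
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
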