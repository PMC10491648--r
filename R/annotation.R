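#' Read gene-level records from a GTF annotation
#'
#' Parses an Ensembl-style GTF (optionally gzip-compressed) and keeps only
#' lines whose feature column equals `"gene"`, one row per gene. Transcript,
#' exon and all other features are ignored: downstream pair classification
#' works on a single representative gene structure, so gene-level coordinates
#' are all that is retained.
#'
#' Coordinates are taken verbatim from the GTF (1-based, closed intervals).
#' Records without a `gene_name` attribute get an empty symbol (the gene_id is
#' never copied into the symbol, so id and symbol semantics stay distinct).
#' Genes annotated on the unstranded `"*"` strand are rejected with an error:
#' antisense logic is undefined without an orientation.
#'
#' @param path Path to a GTF file (`.gtf` or `.gtf.gz`).
#' @return A tibble with columns `gene_id`, `symbol`, `chr`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`, `biotype`, `gene_source`.
#' @seealso [read_gene_table()] for the CSV dialect, [write_gtf()] for the
#'   inverse operation.
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0(
#'   "1\thavana\tgene\t100\t500\t.\t-\t.\t",
#'   "gene_id \"g1\"; gene_name \"Abc1\"; gene_biotype \"lncRNA\";"
#' ), gtf)
#' read_gtf_genes(gtf)
read_gtf_genes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GTF file not found: ", path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc)) {
    abort("GTF has no feature (type) column; cannot select gene records.")
  }
  gr <- gr[as.character(mc$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  if (length(gr) > 0 && !"gene_id" %in% names(mc)) {
    abort("gene feature lines lack a gene_id attribute.")
  }
  get_attr <- function(name, default = "") {
    if (name %in% names(mc)) {
      out <- as.character(mc[[name]])
      out[is.na(out)] <- default
      out
    } else {
      rep(default, length(gr))
    }
  }
  gene_id <- get_attr("gene_id", NA_character_)
  if (length(gr) > 0 && anyNA(gene_id)) {
    abort("found gene feature line(s) with a missing gene_id attribute.")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    bad <- gene_id[!strand %in% c("+", "-")]
    abort(paste0(
      "gene(s) with unknown strand rejected (antisense logic needs an ",
      "orientation): ", paste(head(bad, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    gene_id = gene_id,
    symbol = get_attr("gene_name"),
    chr = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    biotype = get_attr("gene_biotype"),
    gene_source = get_attr("gene_source")
  )
}

#' Filter a gene table by annotation source
#'
#' Keeps records whose `gene_source` is among `sources`, preserving row order.
#' Some genomes carry genes from several annotation providers and analyses may
#' be restricted to a single curated source (for example `"ena"` or
#' `"PomBase"`); the sentinel `"all"` keeps every record.
#'
#' @param genes A gene table (see [read_gtf_genes()]).
#' @param sources Character vector of allowed `gene_source` values, or `"all"`.
#' @return The filtered gene table (possibly empty).
#' @export
filter_gene_source <- function(genes, sources = "all") {
  genes <- as_gene_table(genes)
  if (length(sources) == 0) {
    abort("`sources` must be non-empty (use \"all\" to keep every record).")
  }
  if (identical(sources, "all")) {
    return(genes)
  }
  dplyr::filter(genes, .data$gene_source %in% sources)
}

#' Validate a gene table
#'
#' Checks the integrity rules the pair engine relies on: `gene_id` must be
#' unique, coordinates well-formed (`1 <= start <= end`), and strands `"+"` or
#' `"-"`. Duplicate symbols are common in real annotations and are reported as
#' warnings only — they never block an analysis, which is why all joins in
#' this package are by `gene_id` and never by symbol.
#'
#' @param genes A gene table.
#' @return A tibble report with columns `check`, `severity` (`"error"` or
#'   `"warning"`), `gene_id` and `detail`; zero rows with severity `"error"`
#'   means the table is usable. The report carries a logical attribute
#'   `"passed"`.
#' @export
validate_gene_table <- function(genes) {
  genes <- as_gene_table(genes)
  issues <- list()
  dup_id <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup_id) > 0) {
    issues <- c(issues, list(tibble::tibble(
      check = "duplicate_gene_id", severity = "error", gene_id = dup_id,
      detail = "gene_id occurs more than once"
    )))
  }
  bad_coord <- genes$gene_id[genes$start > genes$end | genes$start < 1L]
  if (length(bad_coord) > 0) {
    issues <- c(issues, list(tibble::tibble(
      check = "bad_coordinates", severity = "error", gene_id = bad_coord,
      detail = "start > end or start < 1"
    )))
  }
  bad_strand <- genes$gene_id[!genes$strand %in% c("+", "-")]
  if (length(bad_strand) > 0) {
    issues <- c(issues, list(tibble::tibble(
      check = "unknown_strand", severity = "error", gene_id = bad_strand,
      detail = "strand is not + or -"
    )))
  }
  sym <- genes$symbol[!is.na(genes$symbol) & genes$symbol != ""]
  dup_sym <- unique(sym[duplicated(sym)])
  if (length(dup_sym) > 0) {
    ids <- genes$gene_id[genes$symbol %in% dup_sym]
    issues <- c(issues, list(tibble::tibble(
      check = "duplicate_symbol", severity = "warning", gene_id = ids,
      detail = "symbol shared by several gene_ids (allowed)"
    )))
  }
  report <- if (length(issues) == 0) {
    tibble::tibble(
      check = character(), severity = character(),
      gene_id = character(), detail = character()
    )
  } else {
    dplyr::bind_rows(issues)
  }
  attr(report, "passed") <- !any(report$severity == "error")
  report
}

# Canonical CSV header <-> internal column names
csv_col_map <- c(
  gene_id = "gene_id", GeneSymbol = "symbol", Chr = "chr", Strand = "strand",
  Start = "start", End = "end", Biotype = "biotype", gene_source = "gene_source"
)

#' Read / write the canonical gene-table CSV
#'
#' The CSV dialect has mandatory header columns
#' `gene_id,GeneSymbol,Chr,Strand,Start,End,Biotype,gene_source`; coordinates
#' are 1-based closed intervals, the same convention as GTF. Any extra columns
#' (typically `TPM_<sample>` and `padj`) are carried through untouched, so a
#' write/read round trip is lossless.
#'
#' @param path File path.
#' @param genes A gene table.
#' @return `read_gene_table()` returns a gene table tibble;
#'   `write_gene_table()` invisibly returns `genes`.
#' @export
read_gene_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(names(csv_col_map), names(df))
  if (length(missing) > 0) {
    abort(paste0("CSV is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("Start", "End")) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | x != floor(x))
    if (length(bad) > 0) {
      abort(paste0("non-integer ", col, " at data row(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    df[[col]] <- as.integer(x)
  }
  names(df)[match(names(csv_col_map), names(df))] <- unname(csv_col_map)
  extra <- setdiff(names(df), gene_table_cols)
  for (col in intersect(extra, names(df))) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    if (!anyNA(num[!is.na(df[[col]])])) df[[col]] <- num
  }
  as_gene_table(df)
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  genes <- as_gene_table(genes)
  out <- genes
  inv <- setNames(names(csv_col_map), unname(csv_col_map))
  names(out)[match(names(inv), names(out))] <- unname(inv)
  readr::write_csv(out, path)
  invisible(genes)
}

#' Attach expression values to a gene table
#'
#' Joins a wide TPM matrix (one row per gene, one column per sample) onto the
#' gene table, by `gene_id` only — never by symbol, which is not unique.
#' Sample columns are prefixed with `TPM_`. Genes absent from the expression
#' matrix get `NA` markers; expression rows whose id is not in the table are
#' dropped with a message.
#'
#' @param genes A gene table.
#' @param expr A data frame with a `gene_id` column plus one numeric column per
#'   sample (sample labels `"<timepoint>_<replicate>"`), optionally `padj`.
#' @return The gene table with `TPM_<sample>` (and `padj`) columns appended.
#' @export
attach_expression <- function(genes, expr) {
  genes <- as_gene_table(genes)
  if (!is.data.frame(expr) || !"gene_id" %in% names(expr)) {
    abort("`expr` must be a data frame with a gene_id column.")
  }
  if (anyDuplicated(expr$gene_id)) {
    abort("duplicate gene_id in expression matrix.")
  }
  orphans <- setdiff(expr$gene_id, genes$gene_id)
  if (length(orphans) > 0) {
    inform(paste0(length(orphans),
                  " expression row(s) have no matching gene and are ignored."))
  }
  expr <- tibble::as_tibble(expr)
  sample_cols <- setdiff(names(expr), c("gene_id", "padj"))
  names(expr)[match(sample_cols, names(expr))] <- paste0("TPM_", sample_cols)
  dplyr::left_join(genes, expr, by = "gene_id")
}
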