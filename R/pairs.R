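#' Transcription start and end sites of annotated genes
#'
#' For a plus-strand gene the TSS is its `start` coordinate and the TES its
#' `end`; for a minus-strand gene the roles are reversed (the TSS is the
#' higher plus-strand coordinate). Both are reported on plus-strand
#' coordinates.
#'
#' @param genes A gene table (or any data frame with `strand`, `start`, `end`).
#' @return An integer vector, one coordinate per row.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   gene_id = c("a", "b"), symbol = "", chr = "1",
#'   strand = c("+", "-"), start = c(100L, 100L), end = c(500L, 500L),
#'   biotype = "protein_coding", gene_source = "test"
#' )
#' gene_tss(g) # 100 500
#' gene_tes(g) # 500 100
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) {
  ifelse(genes$strand == "+", genes$end, genes$start)
}

# Internal: signed offset of the antisense anchor relative to the sense
# anchor, measured in the sense gene's transcription direction.
# Negative = antisense anchor upstream of the sense anchor; 0 = coincident.
signed_offset <- function(sense_anchor, as_anchor, sense_strand) {
  ifelse(sense_strand == "+", as_anchor - sense_anchor, sense_anchor - as_anchor)
}

check_opposite <- function(sense, antisense, call = rlang::caller_env()) {
  if (nrow(sense) != nrow(antisense)) {
    abort("`sense` and `antisense` must have the same number of rows.", call = call)
  }
  if (any(sense$strand == antisense$strand)) {
    abort("sense and antisense genes must lie on opposite strands.", call = call)
  }
  if (any(sense$chr != antisense$chr)) {
    abort("sense and antisense genes must share a chromosome.", call = call)
  }
}

#' Signed antisense TSS / TES offsets
#'
#' `as_tss_position()` is the position of the antisense TSS relative to the
#' sense TSS, measured along the sense gene's transcription direction:
#' negative values mean the antisense TSS lies upstream of the sense TSS, 0
#' means the two TSSs coincide. `as_tes_position()` is the identical
#' construction for transcript end sites. Both functions are vectorised over
#' rows of the two tables.
#'
#' @param sense,antisense Gene tables with the same number of rows, row i of
#'   `antisense` paired with row i of `sense`; opposite strands, same
#'   chromosome.
#' @return An integer vector of signed base-pair offsets.
#' @export
as_tss_position <- function(sense, antisense) {
  check_opposite(sense, antisense)
  as.integer(signed_offset(gene_tss(sense), gene_tss(antisense), sense$strand))
}

#' @rdname as_tss_position
#' @export
as_tes_position <- function(sense, antisense) {
  check_opposite(sense, antisense)
  as.integer(signed_offset(gene_tes(sense), gene_tes(antisense), sense$strand))
}

#' Plus-strand coordinate window implied by a signed offset range
#'
#' Converts a signed offset window `[window_min, window_max]` around a sense
#' gene's anchor (TSS or TES) into the closed interval of plus-strand
#' coordinates that an antisense anchor must occupy. For a plus-strand sense
#' gene and a TSS anchor the interval is `[tss + min, tss + max]`; for a
#' minus-strand gene it mirrors to `[tss - max, tss - min]`. Both window
#' bounds are inclusive. A window of `(-500, -1)` therefore selects antisense
#' anchors in the 500 bp immediately upstream of the sense anchor, excluding
#' coincidence.
#'
#' @param genes A gene table (the sense genes).
#' @param window_min,window_max Signed offsets in bp (`window_min <=
#'   window_max`); negative = upstream.
#' @param anchor `"tss"` or `"tes"`.
#' @return A tibble with columns `gene_id`, `lo`, `hi` (closed interval).
#' @export
anchor_window <- function(genes, window_min, window_max, anchor = c("tss", "tes")) {
  anchor <- rlang::arg_match(anchor)
  genes <- as_gene_table(genes)
  if (window_min > window_max) {
    abort("`window_min` must be <= `window_max`.")
  }
  a <- if (anchor == "tss") gene_tss(genes) else gene_tes(genes)
  plus <- genes$strand == "+"
  tibble::tibble(
    gene_id = genes$gene_id,
    lo = as.integer(ifelse(plus, a + window_min, a - window_max)),
    hi = as.integer(ifelse(plus, a + window_max, a - window_min))
  )
}

pair_type_levels <- c("HH", "EB", "FO", "TT", "fHH", "nHH", "fTT", "nTT")

#' Classify a sense/antisense gene pair into one of eight structural types
#'
#' Overlapping pairs fall into four cis-NAT classes decided by membership of
#' the antisense TSS and TES in the sense gene's interval (closed on both
#' ends): both inside = embedded (`EB`); only the antisense TSS inside =
#' head-to-head (`HH`, 5' overlap); only the antisense TES inside =
#' tail-to-tail (`TT`, 3' overlap); neither inside but intervals intersecting
#' = fully overlapped (`FO`, antisense covers the sense gene). Disjoint pairs
#' are split by which side of the sense gene the antisense lies on (its 5'
#' side gives head-to-head, its 3' side tail-to-tail geometry) and by the gap
#' between the facing gene ends: a gap of at most `nearby_bp` (default 5 kb)
#' is "nearby" (`nHH`/`nTT`), anything larger "faraway" (`fHH`/`fTT`). The gap
#' is the absolute difference of the nearest ends, so adjacent genes 1 bp
#' apart have gap 1; with the 5 kb default this makes `nHH` coincide exactly
#' with disjoint upstream pairs whose TSS offset is in `[-5000, -1]`.
#'
#' The five cases are mutually exclusive and exhaustive: every opposite-strand
#' same-chromosome pair receives exactly one type. Vectorised over rows.
#'
#' @inheritParams as_tss_position
#' @param nearby_bp Gap threshold (bp) separating nearby from faraway
#'   non-overlapping pairs.
#' @return A character vector with values in
#'   `c("HH","EB","FO","TT","fHH","nHH","fTT","nTT")`.
#' @export
classify_pair_type <- function(sense, antisense, nearby_bp = 5000) {
  check_opposite(sense, antisense)
  s_lo <- sense$start
  s_hi <- sense$end
  a_tss <- gene_tss(antisense)
  a_tes <- gene_tes(antisense)
  tss_in <- a_tss >= s_lo & a_tss <= s_hi
  tes_in <- a_tes >= s_lo & a_tes <= s_hi
  overlaps <- antisense$start <= s_hi & antisense$end >= s_lo
  # disjoint geometry: which side of the sense gene (in its own orientation)
  plus <- sense$strand == "+"
  upstream <- ifelse(plus, antisense$end < s_lo, antisense$start > s_hi)
  gap <- ifelse(plus & antisense$end < s_lo, s_lo - antisense$end,
         ifelse(plus, antisense$start - s_hi,
         ifelse(antisense$start > s_hi, antisense$start - s_hi,
                s_lo - antisense$end)))
  dplyr::case_when(
    tss_in & tes_in ~ "EB",
    tss_in ~ "HH",
    tes_in ~ "TT",
    overlaps ~ "FO",
    upstream & gap <= nearby_bp ~ "nHH",
    upstream ~ "fHH",
    gap <= nearby_bp ~ "nTT",
    .default = "fTT"
  )
}

# Internal: assemble the pair tibble from index-matched sense/antisense rows.
build_pairs <- function(sense, antisense, nearby_bp) {
  tibble::tibble(
    sense_gene_id = sense$gene_id,
    sense_symbol = sense$symbol,
    sense_biotype = sense$biotype,
    sense_chr = sense$chr,
    sense_strand = sense$strand,
    sense_start = sense$start,
    sense_end = sense$end,
    as_gene_id = antisense$gene_id,
    as_symbol = antisense$symbol,
    as_biotype = antisense$biotype,
    as_strand = antisense$strand,
    as_start = antisense$start,
    as_end = antisense$end,
    type = classify_pair_type(sense, antisense, nearby_bp = nearby_bp),
    as_tss_position = as_tss_position(sense, antisense),
    as_tes_position = as_tes_position(sense, antisense)
  )
}

resolve_mode <- function(mode) {
  if (is.numeric(mode) && length(mode) == 1 && mode %in% 1:3) {
    return(c("overlap", "tss", "tes")[mode])
  }
  rlang::arg_match0(mode, c("overlap", "tss", "tes"))
}

#' Extract sense/antisense gene pairs from a gene table
#'
#' The core extraction engine. Each chromosome is swept twice — once with
#' plus-strand genes as sense and minus-strand genes as antisense, once with
#' the roles reversed — and the two sweeps are concatenated, so every
#' qualifying two-gene configuration appears twice, each gene once in the
#' sense role. Three modes are available:
#'
#' * `"overlap"` (mode 1): every opposite-strand pair whose gene intervals
#'   intersect; types are restricted to the four overlapping classes
#'   `HH`/`EB`/`FO`/`TT` by construction.
#' * `"tss"` (mode 2): every opposite-strand pair whose antisense TSS offset
#'   ([as_tss_position()]) lies in `[window[1], window[2]]`, both bounds
#'   inclusive. This is the divergent-transcription query.
#' * `"tes"` (mode 3): the same with TES offsets ([as_tes_position()]); the
#'   convergent-transcription query.
#'
#' Rows are sorted by `(sense_chr, sense_start, sense_gene_id, as_gene_id)` so
#' output is byte-reproducible.
#'
#' @param genes A validated gene table (unique ids, `+`/`-` strands).
#' @param mode `"overlap"`, `"tss"` or `"tes"` (or 1, 2, 3).
#' @param window Length-2 signed offset window `c(min, max)` in bp, required
#'   for modes `"tss"`/`"tes"`; negative = upstream of the sense anchor.
#' @param nearby_bp Gap threshold passed to [classify_pair_type()].
#' @return A pair tibble with one row per (sense, antisense) assignment:
#'   coordinates and annotations of both genes, the structural `type`, and the
#'   signed `as_tss_position` / `as_tes_position` offsets.
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("s", "a"), symbol = c("S", "A"), chr = "1",
#'   strand = c("+", "-"), start = c(1000L, 1200L), end = c(2000L, 1800L),
#'   biotype = "protein_coding", gene_source = "test"
#' )
#' find_antisense_pairs(genes, mode = "overlap")
find_antisense_pairs <- function(genes, mode = c("overlap", "tss", "tes"),
                                 window = NULL, nearby_bp = 5000) {
  mode <- resolve_mode(mode)
  genes <- assert_valid_gene_table(genes)
  if (mode == "overlap") {
    if (!is.null(window)) {
      abort("`window` applies to modes \"tss\"/\"tes\" only.")
    }
  } else {
    if (is.null(window) || length(window) != 2) {
      abort("modes \"tss\"/\"tes\" need `window = c(min, max)`.")
    }
    if (window[1] > window[2]) {
      abort("`window[1]` (min) must be <= `window[2]` (max).")
    }
  }
  sweeps <- lapply(c("+", "-"), function(ss) {
    sweep_pairs(genes, sense_strand = ss, mode = mode, window = window,
                nearby_bp = nearby_bp)
  })
  out <- dplyr::bind_rows(sweeps)
  dplyr::arrange(out, .data$sense_chr, .data$sense_start,
                 .data$sense_gene_id, .data$as_gene_id)
}

# Internal: one directional sweep (sense on `sense_strand`), per chromosome.
sweep_pairs <- function(genes, sense_strand, mode, window, nearby_bp) {
  sense_all <- genes[genes$strand == sense_strand, , drop = FALSE]
  anti_all <- genes[genes$strand != sense_strand, , drop = FALSE]
  chrs <- intersect(unique(sense_all$chr), unique(anti_all$chr))
  if (length(chrs) == 0 || nrow(sense_all) == 0 || nrow(anti_all) == 0) {
    return(build_pairs(sense_all[0, ], anti_all[0, ], nearby_bp))
  }
  per_chr <- lapply(chrs, function(cc) {
    sense <- sense_all[sense_all$chr == cc, , drop = FALSE]
    anti <- anti_all[anti_all$chr == cc, , drop = FALSE]
    if (mode == "overlap") {
      q <- IRanges::IRanges(sense$start, sense$end)
      s <- IRanges::IRanges(anti$start, anti$end)
    } else {
      win <- anchor_window(sense, window[1], window[2],
                           anchor = if (mode == "tss") "tss" else "tes")
      pt <- if (mode == "tss") gene_tss(anti) else gene_tes(anti)
      q <- IRanges::IRanges(win$lo, win$hi)
      s <- IRanges::IRanges(pt, pt)
    }
    hits <- IRanges::findOverlaps(q, s)
    build_pairs(sense[S4Vectors::queryHits(hits), , drop = FALSE],
                anti[S4Vectors::subjectHits(hits), , drop = FALSE],
                nearby_bp)
  })
  dplyr::bind_rows(per_chr)
}

# Pair CSV header <-> internal column names (only the renamed ones)
pair_csv_renames <- c(Type = "type", AS_TSS_position = "as_tss_position",
                      AS_TES_position = "as_tes_position")

#' Read / write the pair CSV
#'
#' Pair tables are written with the canonical column names `Type`,
#' `AS_TSS_position` and `AS_TES_position`; all other columns (including any
#' `TPM_*`/`padj` passthrough columns) keep their names.
#'
#' @param pairs A pair tibble from [find_antisense_pairs()].
#' @param path File path.
#' @return `read_pairs_csv()` returns the pair tibble; `write_pairs_csv()`
#'   invisibly returns `pairs`.
#' @export
write_pairs_csv <- function(pairs, path) {
  out <- pairs
  inv <- setNames(names(pair_csv_renames), unname(pair_csv_renames))
  hit <- match(names(inv), names(out))
  names(out)[hit[!is.na(hit)]] <- unname(inv)[!is.na(hit)]
  readr::write_csv(out, path)
  invisible(pairs)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  hit <- match(names(pair_csv_renames), names(df))
  names(df)[hit[!is.na(hit)]] <- unname(pair_csv_renames)[!is.na(hit)]
  int_cols <- intersect(
    c("sense_start", "sense_end", "as_start", "as_end",
      "as_tss_position", "as_tes_position"),
    names(df)
  )
  df[int_cols] <- lapply(df[int_cols], as.integer)
  df
}
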