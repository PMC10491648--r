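#' Fixed-width signed-offset bins around a gene anchor
#'
#' Builds the ladder of closed offset bins used by the divergent/convergent
#' profiles: upstream bins `[-range, -range+width-1]` ... `[-width, -1]`, then
#' downstream bins `[0, width-1]` ... `[range-width, range-1]`. With the
#' defaults (5 kb either side, 500 bp bins) this yields 20 bins; the bin
#' immediately upstream of the anchor is `[-500, -1]` and offset 0 (coincident
#' anchors) falls in the first downstream bin `[0, 499]`.
#'
#' @param range_bp Half-range in bp (bins cover `[-range_bp, range_bp - 1]`).
#' @param width_bp Bin width in bp; must divide `range_bp`.
#' @return A tibble with columns `bin` (label `"[lo,hi]"`), `lo`, `hi`.
#' @export
make_offset_bins <- function(range_bp = 5000, width_bp = 500) {
  if (range_bp <= 0 || width_bp <= 0 || range_bp %% width_bp != 0) {
    abort("`range_bp` must be a positive multiple of `width_bp`.")
  }
  lo <- seq(-range_bp, range_bp - width_bp, by = width_bp)
  hi <- lo + width_bp - 1L
  tibble::tibble(
    bin = sprintf("[%d,%d]", lo, hi),
    lo = as.integer(lo),
    hi = as.integer(hi)
  )
}

# Internal: bin lower bound for an offset under a given width.
offset_bin_lo <- function(offset, width_bp) {
  as.integer(width_bp * floor(offset / width_bp))
}

biotype_keep <- function(x, filter) {
  if (identical(filter, "all")) rep(TRUE, length(x)) else x %in% filter
}

#' Binned divergent / convergent transcription profile
#'
#' For every offset bin, counts the sense genes that have at least one
#' antisense transcript whose anchor (TSS for divergent, TES for convergent
#' analysis) falls in that bin, and expresses the count as a percentage of all
#' genes passing the sense-biotype filter. A sense gene with several antisense
#' anchors in one bin is counted once in that bin (but may appear in several
#' bins). The denominator is the full filtered gene set, not just genes with
#' an antisense partner.
#'
#' @param genes A gene table.
#' @param anchor `"tss"` (divergent) or `"tes"` (convergent).
#' @param range_bp,width_bp Bin geometry, see [make_offset_bins()].
#' @param sense_biotypes,antisense_biotypes Character vectors of biotypes to
#'   keep on each side, or `"all"`.
#' @param nearby_bp Passed through to [find_antisense_pairs()].
#' @return A tibble of class `cisnat_profile`: one row per bin with `lo`,
#'   `hi`, `count`, `denominator`, `percentage`, plus attributes recording the
#'   anchor and filters.
#' @export
profile_antisense <- function(genes, anchor = c("tss", "tes"),
                              range_bp = 5000, width_bp = 500,
                              sense_biotypes = "all",
                              antisense_biotypes = "all",
                              nearby_bp = 5000) {
  anchor <- rlang::arg_match(anchor)
  genes <- assert_valid_gene_table(genes)
  bins <- make_offset_bins(range_bp, width_bp)
  denom <- sum(biotype_keep(genes$biotype, sense_biotypes))
  if (denom == 0) {
    abort("no genes pass the sense biotype filter; empty denominator.")
  }
  pairs <- find_antisense_pairs(genes, mode = anchor,
                                window = c(-range_bp, range_bp - 1L),
                                nearby_bp = nearby_bp)
  pairs <- pairs[
    biotype_keep(pairs$sense_biotype, sense_biotypes) &
      biotype_keep(pairs$as_biotype, antisense_biotypes), , drop = FALSE]
  offset <- if (anchor == "tss") pairs$as_tss_position else pairs$as_tes_position
  hits <- tibble::tibble(
    sense_gene_id = pairs$sense_gene_id,
    lo = offset_bin_lo(offset, width_bp)
  )
  counts <- hits |>
    dplyr::distinct() |>
    dplyr::count(.data$lo, name = "count")
  out <- bins |>
    dplyr::left_join(counts, by = "lo") |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      denominator = denom,
      percentage = 100 * .data$count / denom
    )
  structure(out,
            class = c("cisnat_profile", class(out)),
            anchor = anchor,
            sense_biotypes = sense_biotypes,
            antisense_biotypes = antisense_biotypes)
}

#' Count pairs per bin by RNA-biotype combination
#'
#' Cross-tabulates a pair table over (sense biotype, antisense biotype, offset
#' bin), counting distinct sense genes per cell. The caller chooses which
#' anchor's offset to bin on. Ratios between cells (for example lncRNA-
#' antisense over coding-antisense in the peak bin) are computed downstream
#' from the returned table.
#'
#' @param pairs A pair tibble from [find_antisense_pairs()].
#' @param bins A bin tibble from [make_offset_bins()].
#' @param anchor `"tss"` or `"tes"`: which signed offset to bin on.
#' @return A tibble with `sense_biotype`, `as_biotype`, `bin`, `lo`, `hi`,
#'   `count` (distinct sense genes). Empty input gives an empty table.
#' @export
count_biotype_combos <- function(pairs, bins = make_offset_bins(),
                                 anchor = c("tss", "tes")) {
  anchor <- rlang::arg_match(anchor)
  empty <- tibble::tibble(
    sense_biotype = character(), as_biotype = character(),
    bin = character(), lo = integer(), hi = integer(), count = integer()
  )
  if (nrow(pairs) == 0) return(empty)
  width_bp <- bins$hi[1] - bins$lo[1] + 1L
  offset <- if (anchor == "tss") pairs$as_tss_position else pairs$as_tes_position
  cells <- tibble::tibble(
    sense_biotype = pairs$sense_biotype,
    as_biotype = pairs$as_biotype,
    sense_gene_id = pairs$sense_gene_id,
    lo = offset_bin_lo(offset, width_bp)
  ) |>
    dplyr::semi_join(bins, by = "lo") |>
    dplyr::distinct() |>
    dplyr::count(.data$sense_biotype, .data$as_biotype, .data$lo, name = "count")
  if (nrow(cells) == 0) return(empty)
  cells |>
    dplyr::inner_join(bins, by = "lo") |>
    dplyr::select("sense_biotype", "as_biotype", "bin", "lo", "hi", "count") |>
    dplyr::arrange(.data$sense_biotype, .data$as_biotype, .data$lo)
}

#' Plot a binned antisense profile
#'
#' Bar chart of the per-bin percentage of sense genes with an antisense anchor
#' in the bin, upstream bins left of the anchor.
#'
#' @param object A `cisnat_profile` from [profile_antisense()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cisnat_profile <- function(object, ...) {
  anchor <- toupper(attr(object, "anchor") %||% "tss")
  df <- tibble::as_tibble(object)
  df$mid <- (df$lo + df$hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$percentage)) +
    ggplot2::geom_col(width = (df$hi[1] - df$lo[1]) * 0.9, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("antisense %s offset relative to sense %s (bp)", anchor, anchor),
      y = "% of sense genes with an antisense anchor in bin"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.cisnat_profile <- function(x, ...) print(autoplot.cisnat_profile(x, ...))
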