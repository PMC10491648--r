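#' Average replicate TPM columns to time-point means
#'
#' Sample columns are labelled `"<timepoint>_<replicate>"`; everything before
#' the final underscore names the time point. Columns are averaged per time
#' point, preserving the order in which time points first appear.
#'
#' @param expr A data frame with `gene_id` plus numeric sample columns
#'   (optionally `padj`, which is carried through).
#' @return A tibble with `gene_id` and one mean-TPM column per time point.
#' @export
expression_means <- function(expr) {
  expr <- tibble::as_tibble(expr)
  sample_cols <- setdiff(names(expr), c("gene_id", "padj"))
  if (length(sample_cols) == 0) {
    abort("`expr` has no sample columns.")
  }
  tp <- sub("_[^_]*$", "", sample_cols)
  tps <- unique(tp)
  means <- purrr::map(tps, function(t) {
    rowMeans(as.matrix(expr[sample_cols[tp == t]]))
  })
  out <- tibble::as_tibble(setNames(means, tps))
  dplyr::bind_cols(expr["gene_id"], out)
}

#' Select expressing genes from a TPM time course
#'
#' A gene is "expressing" when its time-point mean TPM exceeds `min_tpm` at at
#' least one time point and is non-zero at every time point. Replicates are
#' averaged to time-point means before the test.
#'
#' @param expr A TPM data frame (see [expression_means()]).
#' @param min_tpm Expression threshold that must be exceeded (strictly) at
#'   some time point; default 1 TPM.
#' @return A character vector of expressing `gene_id`s.
#' @export
select_expressing <- function(expr, min_tpm = 1) {
  m <- expression_means(expr)
  vals <- as.matrix(m[setdiff(names(m), "gene_id")])
  keep <- apply(vals, 1, function(v) any(v > min_tpm) && all(v != 0))
  m$gene_id[keep]
}

#' Spearman rank correlation with an undefined-value marker
#'
#' Standard Spearman correlation: the Pearson correlation of the two series'
#' ranks, with ties receiving average ranks. A constant series has no rank
#' ordering, so the correlation is reported as `NA` (never coerced to 0).
#'
#' @param x,y Numeric series of equal length `>= 3`.
#' @return A single numeric in `[-1, 1]`, or `NA` when either series is
#'   constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.")
  }
  if (length(x) < 3) {
    abort("need at least 3 points for a rank correlation.")
  }
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Correlate sense and antisense expression over a time course
#'
#' For each pair, computes the Spearman correlation between the sense and
#' antisense genes' TPM trajectories. By default replicates are averaged to
#' time-point means first; set `use_replicate_means = FALSE` to correlate the
#' raw per-sample series instead. Pairs with either gene missing from the
#' expression matrix are dropped with a message; pairs whose correlation is
#' undefined (constant series) are kept with `rho = NA` so callers can exclude
#' them from grouping explicitly.
#'
#' @param pairs A pair tibble from [find_antisense_pairs()].
#' @param expr A TPM data frame keyed by `gene_id`.
#' @param use_replicate_means Average replicates per time point first?
#' @return The pair tibble with `rho` and `n_points` columns appended.
#' @export
pair_correlations <- function(pairs, expr, use_replicate_means = TRUE) {
  prof <- if (use_replicate_means) expression_means(expr) else tibble::as_tibble(expr)
  val_cols <- setdiff(names(prof), c("gene_id", "padj"))
  if (anyDuplicated(prof$gene_id)) {
    abort("duplicate gene_id in expression matrix.")
  }
  mat <- as.matrix(prof[val_cols])
  rownames(mat) <- prof$gene_id
  present <- pairs$sense_gene_id %in% prof$gene_id &
    pairs$as_gene_id %in% prof$gene_id
  if (any(!present)) {
    inform(paste0(sum(!present),
                  " pair(s) skipped: gene absent from expression matrix."))
  }
  out <- pairs[present, , drop = FALSE]
  n <- length(val_cols)
  out$rho <- purrr::map2_dbl(out$sense_gene_id, out$as_gene_id, function(s, a) {
    spearman_rho(mat[s, ], mat[a, ])
  })
  out$n_points <- n
  out
}

#' Cut pairs into consecutive groups of equal count along an offset axis
#'
#' Sorts pair records by signed offset and slices them into consecutive groups
#' of `bin_size` records. All records tied at a group's boundary offset join
#' that group, so groups may exceed `bin_size`. Each group is labelled by the
#' offset span it covers.
#'
#' @param records A tibble with an offset column (typically correlation
#'   records from [pair_correlations()]).
#' @param bin_size Nominal records per group.
#' @param offset_col Name of the signed offset column, default
#'   `"as_tss_position"`.
#' @return `records` sorted by offset with `group` (integer) and
#'   `group_label` (`"[lo,hi]"` offset span) columns appended.
#' @export
bin_pairs_by_count <- function(records, bin_size = 100,
                               offset_col = "as_tss_position") {
  if (nrow(records) == 0) {
    records$group <- integer()
    records$group_label <- character()
    return(records)
  }
  records <- records[order(records[[offset_col]]), , drop = FALSE]
  off <- records[[offset_col]]
  g <- ceiling(seq_along(off) / bin_size)
  # records sharing a boundary offset collapse into the earlier group
  g <- stats::ave(g, match(off, unique(off)), FUN = min)
  records$group <- as.integer(g)
  spans <- tapply(off, g, function(o) sprintf("[%d,%d]", min(o), max(o)))
  records$group_label <- unname(spans[as.character(g)])
  records
}

#' The n pairs closest to the sense anchor
#'
#' Selects the `n` records with the smallest absolute offset; records tied at
#' the n-th absolute offset are all included, so slightly more than `n` rows
#' may be returned. With fewer than `n` records, all are returned with a
#' warning.
#'
#' @inheritParams bin_pairs_by_count
#' @param n Number of pairs to keep.
#' @return The selected subset, sorted by absolute offset.
#' @export
nearest_pairs <- function(records, n = 400, offset_col = "as_tss_position") {
  if (nrow(records) < n) {
    warn(sprintf("only %d record(s) available (< n = %d); returning all.",
                 nrow(records), n))
    return(records[order(abs(records[[offset_col]])), , drop = FALSE])
  }
  a <- abs(records[[offset_col]])
  ord <- order(a)
  cut <- a[ord[n]]
  records[ord[seq_len(sum(a <= cut))], , drop = FALSE]
}

#' Random same-chromosome gene-pair null for the correlation screen
#'
#' Builds `n` random gene pairs, each formed by drawing two distinct
#' expressing genes on the same chromosome and opposite strands, and computes
#' their Spearman correlations the same way as [pair_correlations()]. This is
#' the null against which sense/antisense correlations are compared.
#' Chromosomes are drawn with probability proportional to the number of
#' opposite-strand pairs they can form.
#'
#' @param genes A gene table restricted (or restrictable) to expressing genes.
#' @param expr A TPM data frame keyed by `gene_id`; genes absent from `expr`
#'   are ignored.
#' @param n Number of random pairs.
#' @param seed Optional integer seed for reproducibility; `NULL` uses the
#'   current RNG state.
#' @return A tibble with `sense_gene_id`, `as_gene_id`, `sense_chr`, `rho`.
#' @export
random_chromosome_pairs <- function(genes, expr, n = 400, seed = NULL) {
  genes <- assert_valid_gene_table(genes)
  prof <- expression_means(expr)
  genes <- genes[genes$gene_id %in% prof$gene_id, , drop = FALSE]
  pool <- split(genes, genes$chr)
  n_plus <- vapply(pool, function(g) sum(g$strand == "+"), integer(1))
  n_minus <- vapply(pool, function(g) sum(g$strand == "-"), integer(1))
  w <- as.numeric(n_plus) * as.numeric(n_minus)
  eligible <- names(pool)[w > 0]
  if (length(eligible) == 0) {
    abort("no chromosome has expressing genes on both strands.")
  }
  w <- w[w > 0]
  mat <- as.matrix(prof[setdiff(names(prof), "gene_id")])
  rownames(mat) <- prof$gene_id
  with_seed_if(seed, {
    chr_draw <- sample(eligible, n, replace = TRUE, prob = w)
    rows <- purrr::map(chr_draw, function(cc) {
      g <- pool[[cc]]
      p <- g[g$strand == "+", , drop = FALSE]
      m <- g[g$strand == "-", , drop = FALSE]
      gi <- p$gene_id[sample.int(nrow(p), 1)]
      gj <- m$gene_id[sample.int(nrow(m), 1)]
      tibble::tibble(sense_gene_id = gi, as_gene_id = gj, sense_chr = cc)
    })
    out <- dplyr::bind_rows(rows)
    out$rho <- purrr::map2_dbl(out$sense_gene_id, out$as_gene_id,
                               function(s, a) spearman_rho(mat[s, ], mat[a, ]))
    out
  })
}

#' Select positively and negatively correlated candidate pairs
#'
#' Applies the strict correlation cutoffs: a pair is a positive candidate when
#' `rho > pos_cut` and a negative candidate when `rho < neg_cut` (a rho equal
#' to a cutoff is excluded). Records with undefined rho are dropped. When an
#' expression matrix is supplied, the candidate table carries both genes'
#' time-point mean TPM profiles (the matrix behind a candidate heatmap).
#'
#' @param records Correlation records from [pair_correlations()].
#' @param pos_cut,neg_cut Strict cutoffs, defaults 0.9 and -0.7.
#' @param expr Optional TPM data frame to append profiles from.
#' @return An object of class `correlation_screen`: a list with `positive` and
#'   `negative` tibbles (sorted by decreasing rho) and `table`, the combined
#'   export table with a `direction` column.
#' @export
select_correlated <- function(records, pos_cut = 0.9, neg_cut = -0.7,
                              expr = NULL) {
  records <- records[!is.na(records$rho), , drop = FALSE]
  pos <- records[records$rho > pos_cut, , drop = FALSE]
  neg <- records[records$rho < neg_cut, , drop = FALSE]
  pos <- pos[order(-pos$rho), , drop = FALSE]
  neg <- neg[order(-neg$rho), , drop = FALSE]
  tab <- dplyr::bind_rows(
    dplyr::mutate(pos, direction = "positive"),
    dplyr::mutate(neg, direction = "negative")
  )
  if (!is.null(expr) && nrow(tab) > 0) {
    prof <- expression_means(expr)
    tps <- setdiff(names(prof), "gene_id")
    sense_prof <- prof
    names(sense_prof) <- c("sense_gene_id", paste0("sense_TPM_", tps))
    as_prof <- prof
    names(as_prof) <- c("as_gene_id", paste0("as_TPM_", tps))
    tab <- tab |>
      dplyr::left_join(sense_prof, by = "sense_gene_id") |>
      dplyr::left_join(as_prof, by = "as_gene_id")
  }
  structure(
    list(positive = pos, negative = neg, table = tab,
         pos_cut = pos_cut, neg_cut = neg_cut),
    class = "correlation_screen"
  )
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf(
    "Correlation screen: %d positive (rho > %g), %d negative (rho < %g)\n",
    nrow(x$positive), x$pos_cut, nrow(x$negative), x$neg_cut
  ))
  invisible(x)
}

#' @export
tidy.correlation_screen <- function(x, ...) x$table

#' @export
glance.correlation_screen <- function(x, ...) {
  tibble::tibble(
    n_positive = nrow(x$positive), n_negative = nrow(x$negative),
    pos_cut = x$pos_cut, neg_cut = x$neg_cut
  )
}
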