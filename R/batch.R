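#' Run a batch of pair-extraction jobs from a YAML job list
#'
#' Runs several extractions (possibly different modes and windows, possibly on
#' different input tables) in one call. The configuration is a YAML file (or
#' an equivalent list) with a top-level `jobs` sequence; each job has fields
#' `input` (gene-table CSV), `mode` (1/2/3 or `"overlap"`/`"tss"`/`"tes"`),
#' `min`/`max` (signed window, modes 2/3 only), optional `nearby_kb` (default
#' 5) and `output` (pair CSV path).
#'
#' @param config Path to a YAML file, or a list with a `jobs` element.
#' @param quiet Suppress per-job chromosome pair-count logging?
#' @return A tibble with one row per job: input, mode, window, output path and
#'   the number of extracted pair rows.
#' @export
run_extraction_jobs <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  jobs <- cfg$jobs
  if (is.null(jobs) || length(jobs) == 0) {
    abort("config has no `jobs` entries.")
  }
  rows <- purrr::map(seq_along(jobs), function(i) {
    job <- jobs[[i]]
    if (is.null(job$input) || is.null(job$mode)) {
      abort(sprintf("job %d is missing `input` or `mode`.", i))
    }
    genes <- read_gene_table(job$input)
    mode <- resolve_mode(job$mode)
    window <- if (mode == "overlap") NULL else {
      if (is.null(job$min) || is.null(job$max)) {
        abort(sprintf("job %d (mode %s) needs `min` and `max`.", i, mode))
      }
      c(as.integer(job$min), as.integer(job$max))
    }
    nearby <- 1000 * (job$nearby_kb %||% 5)
    pairs <- find_antisense_pairs(genes, mode = mode, window = window,
                                  nearby_bp = nearby)
    if (!quiet) {
      counts <- table(pairs$sense_chr)
      inform(sprintf(
        "job %d: %d pair rows (%s)", i, nrow(pairs),
        paste(sprintf("%s: %d", names(counts), as.integer(counts)),
              collapse = ", ")
      ))
    }
    if (!is.null(job$output)) {
      write_pairs_csv(pairs, job$output)
    }
    job_input <- job$input
    job_output <- job$output %||% NA_character_
    tibble::tibble(
      job = i, input = job_input, mode = mode,
      window_min = if (is.null(window)) NA_integer_ else window[1],
      window_max = if (is.null(window)) NA_integer_ else window[2],
      output = job_output,
      n_pairs = nrow(pairs)
    )
  })
  dplyr::bind_rows(rows)
}

#' Histogram of signed antisense offsets in a pair table
#'
#' Quick look at where antisense anchors fall relative to the sense anchor.
#'
#' @param pairs A pair tibble from [find_antisense_pairs()].
#' @param anchor `"tss"` or `"tes"`.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot object.
#' @export
plot_offset_distribution <- function(pairs, anchor = c("tss", "tes"),
                                     binwidth = 500) {
  anchor <- rlang::arg_match(anchor)
  col <- if (anchor == "tss") "as_tss_position" else "as_tes_position"
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data[[col]], fill = .data$type)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("antisense %s offset (bp)", toupper(anchor)),
      y = "pairs", fill = "type"
    ) +
    ggplot2::theme_minimal()
}
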