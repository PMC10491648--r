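#' Plant one sense/antisense pair of a chosen structural type
#'
#' Constructive inverse of [classify_pair_type()]: draws gene lengths and
#' gaps/overlaps from the given ranges and lays out two opposite-strand genes
#' whose classification is guaranteed to be `pair_type`. Pairs for a
#' minus-strand sense gene are built by mirror reflection of the plus-strand
#' layout, which preserves the signed offsets. Uses the current RNG state.
#'
#' @param pair_type One of `"HH"`, `"EB"`, `"FO"`, `"TT"`, `"fHH"`, `"nHH"`,
#'   `"fTT"`, `"nTT"`.
#' @param sense_strand Strand of the sense gene, `"+"` or `"-"`.
#' @param origin Left-most coordinate the planted pair may occupy.
#' @param len_range Integer range `c(min, max)` of gene lengths in bp.
#' @param faraway_gap_range Gap range for the faraway types; must stay
#'   strictly above `nearby_bp`.
#' @param nearby_bp Nearby/faraway gap threshold (bp).
#' @param chromosome Chromosome label.
#' @param ids Length-2 character vector: sense and antisense gene ids.
#' @return A list with `sense` and `antisense` one-row gene tibbles and
#'   `truth`, a one-row tibble with the intended type and signed offsets.
#' @export
plant_pair <- function(pair_type, sense_strand = "+", origin = 1L,
                       len_range = c(500L, 4000L),
                       faraway_gap_range = c(5001L, 20000L),
                       nearby_bp = 5000, chromosome = "chr1",
                       ids = c("sense", "antisense")) {
  pair_type <- rlang::arg_match0(pair_type, pair_type_levels)
  if (pair_type %in% c("fHH", "fTT") && faraway_gap_range[1] <= nearby_bp) {
    abort("faraway gap range must lie strictly above `nearby_bp`.")
  }
  rint <- function(lo, hi) sample(seq.int(lo, hi), 1L)
  s_len <- rint(len_range[1], len_range[2])
  a_len <- rint(len_range[1], len_range[2])
  # lay out in a frame where sense is plus-strand at [s1, s2], antisense minus
  s1 <- 1L
  s2 <- s1 + s_len - 1L
  if (pair_type == "EB") {
    a_len <- min(a_len, s_len - 2L)
    if (a_len < 1L) abort("sense gene too short to embed an antisense gene.")
    a1 <- s1 + rint(1L, s_len - a_len - 1L)
    a2 <- a1 + a_len - 1L
  } else if (pair_type == "HH") {
    ov <- rint(1L, min(a_len - 1L, s_len))
    a2 <- s1 + ov - 1L
    a1 <- a2 - a_len + 1L
  } else if (pair_type == "TT") {
    ov <- rint(1L, min(a_len - 1L, s_len))
    a1 <- s2 - ov + 1L
    a2 <- a1 + a_len - 1L
  } else if (pair_type == "FO") {
    d1 <- rint(1L, 1000L)
    d2 <- rint(1L, 1000L)
    a1 <- s1 - d1
    a2 <- s2 + d2
  } else if (pair_type %in% c("nHH", "fHH")) {
    g <- if (pair_type == "nHH") rint(1L, nearby_bp) else
      rint(faraway_gap_range[1], faraway_gap_range[2])
    a2 <- s1 - g
    a1 <- a2 - a_len + 1L
  } else { # nTT / fTT
    g <- if (pair_type == "nTT") rint(1L, nearby_bp) else
      rint(faraway_gap_range[1], faraway_gap_range[2])
    a1 <- s2 + g
    a2 <- a1 + a_len - 1L
  }
  # shift so every coordinate is >= origin
  shift <- as.integer(origin) - min(s1, a1)
  s1 <- s1 + shift; s2 <- s2 + shift; a1 <- a1 + shift; a2 <- a2 + shift
  # signed offsets in the sense-plus frame (antisense TSS = a2, TES = a1)
  tss_off <- a2 - s1
  tes_off <- a1 - s2
  if (sense_strand == "-") {
    # mirror reflection around the block: flips strands, preserves offsets
    ref <- max(s2, a2) + as.integer(origin)
    new_s <- c(ref - s2, ref - s1)
    new_a <- c(ref - a2, ref - a1)
    s1 <- new_s[1]; s2 <- new_s[2]; a1 <- new_a[1]; a2 <- new_a[2]
  }
  a_strand <- if (sense_strand == "+") "-" else "+"
  mk <- function(id, strand, lo, hi) {
    tibble::tibble(
      gene_id = id, symbol = id, chr = chromosome, strand = strand,
      start = as.integer(lo), end = as.integer(hi),
      biotype = "protein_coding", gene_source = "simulated"
    )
  }
  list(
    sense = mk(ids[1], sense_strand, s1, s2),
    antisense = mk(ids[2], a_strand, a1, a2),
    truth = tibble::tibble(
      sense_gene_id = ids[1], as_gene_id = ids[2], type = pair_type,
      as_tss_position = as.integer(tss_off),
      as_tes_position = as.integer(tes_off)
    )
  )
}

#' Generate a seeded synthetic gene table with planted antisense pairs
#'
#' Plants `n_per_type` pairs of each of the eight structural types (sense
#' strands alternating so both orientations are exercised) plus strand-
#' balanced decoy genes, on randomly chosen chromosomes. Placement is by
#' rejection sampling: a pair's footprint, padded by `2 * nearby_bp + 2000`
#' bp, must not intersect any previously placed footprint, with a bounded
#' retry budget. Decoys are therefore guaranteed to be farther than twice the
#' nearby threshold from every plant, so cross-plant and plant/decoy pairs can
#' only be faraway types and the planted labels stay the exclusive truth for
#' overlap and nearby queries.
#'
#' @param n_per_type Planted pairs per structural type (single integer or a
#'   named vector over the eight types).
#' @param n_decoys Number of isolated decoy genes.
#' @param chromosomes Named integer vector of chromosome lengths (bp).
#' @param seed Integer seed; the whole table is a pure function of the
#'   arguments and this seed.
#' @param decoy_biotypes,antisense_biotypes Biotype pools sampled for decoys /
#'   planted antisense partners (sense plants stay `protein_coding`).
#' @inheritParams plant_pair
#' @param max_tries Retry budget per placement before erroring.
#' @return A list with `genes` (gene table, sorted by chromosome and start)
#'   and `truth` (one row per planted pair: ids, intended type and offsets).
#' @export
simulate_gene_table <- function(n_per_type = 3, n_decoys = 20,
                                chromosomes = c(chrA = 5e6, chrB = 5e6),
                                seed = 1,
                                len_range = c(500L, 4000L),
                                faraway_gap_range = c(5001L, 20000L),
                                nearby_bp = 5000,
                                decoy_biotypes = c("protein_coding", "lncRNA"),
                                antisense_biotypes = c("protein_coding", "lncRNA"),
                                max_tries = 1000) {
  if (length(n_per_type) == 1) {
    n_per_type <- setNames(rep(n_per_type, 8), pair_type_levels)
  }
  stopifnot(all(pair_type_levels %in% names(n_per_type)))
  with_seed_if(seed, {
    occupied <- lapply(chromosomes, function(...) NULL)
    pad <- 2 * nearby_bp + 2000
    place <- function(span) {
      for (try in seq_len(max_tries)) {
        cc <- sample(names(chromosomes), 1)
        limit <- chromosomes[[cc]] - span - 1
        if (limit < 1) next
        pos <- sample.int(limit, 1)
        lo <- pos - pad
        hi <- pos + span + pad
        occ <- occupied[[cc]]
        clash <- !is.null(occ) && any(occ[, 1] <= hi & occ[, 2] >= lo)
        if (!clash) {
          occupied[[cc]] <<- rbind(occ, c(pos, pos + span))
          return(list(chr = cc, origin = pos))
        }
      }
      abort("could not place a gene without collisions; use longer chromosomes.")
    }
    plants <- list()
    truths <- list()
    idx <- 0
    for (tp in pair_type_levels) {
      for (r in seq_len(n_per_type[[tp]])) {
        idx <- idx + 1
        ss <- if (idx %% 2 == 1) "+" else "-"
        # worst-case span: two genes plus the largest gap
        span <- 2 * len_range[2] +
          if (tp %in% c("fHH", "fTT")) faraway_gap_range[2] else nearby_bp
        slot <- place(span)
        ids <- sprintf("PLT_%s_%02d_%s", tp, r, c("S", "A"))
        p <- plant_pair(tp, sense_strand = ss, origin = slot$origin,
                        len_range = len_range,
                        faraway_gap_range = faraway_gap_range,
                        nearby_bp = nearby_bp, chromosome = slot$chr,
                        ids = ids)
        p$antisense$biotype <- sample(antisense_biotypes, 1)
        plants <- c(plants, list(p$sense), list(p$antisense))
        truths <- c(truths, list(p$truth))
      }
    }
    decoys <- purrr::map(seq_len(n_decoys), function(d) {
      len <- sample(seq.int(len_range[1], len_range[2]), 1)
      slot <- place(len)
      tibble::tibble(
        gene_id = sprintf("DCY_%03d", d), symbol = sprintf("Decoy%03d", d),
        chr = slot$chr, strand = if (d %% 2 == 1) "+" else "-",
        start = as.integer(slot$origin),
        end = as.integer(slot$origin + len - 1L),
        biotype = sample(decoy_biotypes, 1), gene_source = "simulated"
      )
    })
    genes <- dplyr::bind_rows(c(plants, decoys)) |>
      dplyr::arrange(.data$chr, .data$start, .data$gene_id)
    list(genes = genes, truth = dplyr::bind_rows(truths))
  })
}

#' Generate a random (unplanted) gene table
#'
#' Genes with uniform random positions, lengths and strands — no structure is
#' guaranteed or avoided. Intended for property tests against brute-force
#' oracles, where accidental overlaps of every flavour are exactly what should
#' be exercised.
#'
#' @param n_genes Number of genes.
#' @param chromosomes Named integer vector of chromosome lengths (bp).
#' @param len_range Gene-length range (bp).
#' @param biotypes Biotype pool sampled uniformly.
#' @param seed Integer seed.
#' @return A gene table tibble.
#' @export
simulate_random_genes <- function(n_genes = 200,
                                  chromosomes = c(chrA = 2e5, chrB = 2e5),
                                  len_range = c(200L, 8000L),
                                  biotypes = c("protein_coding", "lncRNA", "pseudogene"),
                                  seed = 1) {
  with_seed_if(seed, {
    chr <- sample(names(chromosomes), n_genes, replace = TRUE)
    len <- sample(seq.int(len_range[1], len_range[2]), n_genes, replace = TRUE)
    start <- vapply(seq_len(n_genes), function(i) {
      sample.int(max(chromosomes[[chr[i]]] - len[i], 1), 1)
    }, integer(1))
    tibble::tibble(
      gene_id = sprintf("RG_%04d", seq_len(n_genes)),
      symbol = sprintf("Rg%04d", seq_len(n_genes)),
      chr = chr,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      start = as.integer(start),
      end = as.integer(start + len - 1L),
      biotype = sample(biotypes, n_genes, replace = TRUE),
      gene_source = "simulated"
    ) |>
      dplyr::arrange(.data$chr, .data$start, .data$gene_id)
  })
}

#' Simulate a TPM time course with planted pair correlations
#'
#' Every planted pair shares a smooth latent trajectory that ramps up and then
#' down over the time course; for a positively planted pair both genes follow
#' it, for a negatively planted pair the antisense gene follows the inverted
#' trajectory, so at zero noise the rank correlation is exactly +1 or -1.
#' Decoy genes carry no trajectory at all: each is an independent noise series
#' around its own constant baseline, so decoy/decoy correlations are
#' structureless (and undefined at zero noise, which drops decoys from the
#' screen entirely). Values are scaled into a TPM range that keeps every
#' simulated gene above the expressing-gene filter (never zero, above 1 TPM
#' at the trajectory peak); noise is additive Gaussian with standard
#' deviation `noise_sd` expressed as a fraction of the gene's signal range.
#'
#' @param truth Truth tibble from [simulate_gene_table()] (needs
#'   `sense_gene_id`, `as_gene_id`).
#' @param decoy_ids Character vector of additional gene ids to simulate
#'   independently.
#' @param time_points Number of time points (>= 4).
#' @param replicates Replicates per time point.
#' @param rho_sign Planted sign per pair: `+1` or `-1`, recycled over pairs
#'   (default alternates).
#' @param noise_sd Relative noise level (0 = noiseless).
#' @param seed Integer seed.
#' @return A tibble with `gene_id` and TPM columns `t<i>_<rep>`.
#' @export
simulate_expression <- function(truth, decoy_ids = character(),
                                time_points = 6, replicates = 2,
                                rho_sign = NULL, noise_sd = 0.05, seed = 1) {
  if (time_points < 4) {
    abort("`time_points` must be >= 4.")
  }
  n_pairs <- nrow(truth)
  if (is.null(rho_sign)) {
    rho_sign <- rep_len(c(1, -1), n_pairs)
  } else {
    rho_sign <- rep_len(rho_sign, n_pairs)
  }
  with_seed_if(seed, {
    t <- seq_len(time_points)
    latent <- function() {
      peak <- runif(1, 1.5, time_points - 0.5)
      width <- runif(1, time_points / 4, time_points)
      base <- exp(-(t - peak)^2 / (2 * width^2))
      # tiny continuous jitter breaks ties so noiseless rank correlations are exact
      y <- base + runif(time_points, -1e-3, 1e-3)
      (y - min(y)) / (max(y) - min(y))
    }
    emit <- function(mean_tpm, scale) {
      vals <- vapply(seq_len(replicates), function(r) {
        pmax(mean_tpm + scale * noise_sd * rnorm(time_points), 0.01)
      }, numeric(time_points))
      as.vector(vals) # time-major within replicate columns
    }
    rows <- list()
    for (i in seq_len(n_pairs)) {
      traj <- latent()
      anti_traj <- if (rho_sign[i] > 0) traj else 1 - traj
      amp_s <- runif(1, 5, 50)
      amp_a <- runif(1, 5, 50)
      rows[[truth$sense_gene_id[i]]] <- emit(0.5 + amp_s * traj, amp_s)
      rows[[truth$as_gene_id[i]]] <- emit(0.5 + amp_a * anti_traj, amp_a)
    }
    for (d in decoy_ids) {
      base <- runif(1, 2, 20)
      rows[[d]] <- emit(rep(base, time_points), base)
    }
    sample_names <- as.vector(vapply(seq_len(replicates), function(r) {
      sprintf("t%d_%d", t, r)
    }, character(time_points)))
    mat <- do.call(rbind, rows)
    colnames(mat) <- sample_names
    dplyr::bind_cols(
      tibble::tibble(gene_id = names(rows)),
      tibble::as_tibble(mat)
    )
  })
}

#' Write a gene table as a gene-feature GTF
#'
#' Emits one `gene` feature line per record (1-based closed coordinates,
#' attributes `gene_id`, `gene_name`, `gene_biotype`, `gene_source`), the
#' exact inverse of [read_gtf_genes()].
#'
#' @param genes A gene table.
#' @param path Output path (`.gtf`).
#' @return Invisibly, `genes`.
#' @export
write_gtf <- function(genes, path) {
  genes <- as_gene_table(genes)
  if (nrow(genes) == 0) {
    writeLines(character(), path)
    return(invisible(genes))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chr,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = genes$gene_source,
    type = "gene",
    gene_id = genes$gene_id,
    gene_name = genes$symbol,
    gene_biotype = genes$biotype,
    gene_source = genes$gene_source
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(genes)
}
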