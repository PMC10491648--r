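# Independent brute-force oracle for the pair engine.
#
# Works directly from the definitions, enumerating every ordered gene pair
# (O(n^2)); deliberately shares no code with the package's sweep/overlap
# implementation.

oracle_tss <- function(strand, start, end) if (strand == "+") start else end
oracle_tes <- function(strand, start, end) if (strand == "+") end else start

# Scalar classification straight from the membership definitions.
oracle_classify <- function(s, a, nearby = 5000) {
  a_tss <- oracle_tss(a$strand, a$start, a$end)
  a_tes <- oracle_tes(a$strand, a$start, a$end)
  inS <- function(x) x >= s$start && x <= s$end
  if (inS(a_tss) && inS(a_tes)) return("EB")
  if (inS(a_tss)) return("HH")
  if (inS(a_tes)) return("TT")
  if (a$start <= s$end && a$end >= s$start) return("FO")
  # disjoint: find which side and the end-to-end gap
  if (a$end < s$start) {
    gap <- s$start - a$end
    side5 <- s$strand == "+" # antisense left of sense; left is 5' iff sense is +
  } else {
    gap <- a$start - s$end
    side5 <- s$strand == "-"
  }
  if (side5) {
    if (gap <= nearby) "nHH" else "fHH"
  } else {
    if (gap <= nearby) "nTT" else "fTT"
  }
}

oracle_offset <- function(s, a, what = c("tss", "tes")) {
  what <- match.arg(what)
  pick <- if (what == "tss") oracle_tss else oracle_tes
  sa <- pick(s$strand, s$start, s$end)
  aa <- pick(a$strand, a$start, a$end)
  if (s$strand == "+") aa - sa else sa - aa
}

# Enumerate every ordered (sense, antisense) pair satisfying the mode's rule.
oracle_pairs <- function(genes, mode, window = NULL, nearby = 5000) {
  rows <- list()
  n <- nrow(genes)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- as.list(genes[i, ])
      a <- as.list(genes[j, ])
      if (s$chr != a$chr || s$strand == a$strand) next
      keep <- if (mode == "overlap") {
        a$start <= s$end && a$end >= s$start
      } else {
        off <- oracle_offset(s, a, if (mode == "tss") "tss" else "tes")
        off >= window[1] && off <= window[2]
      }
      if (!keep) next
      rows[[length(rows) + 1]] <- data.frame(
        sense_gene_id = s$gene_id, as_gene_id = a$gene_id,
        type = oracle_classify(s, a, nearby),
        as_tss_position = oracle_offset(s, a, "tss"),
        as_tes_position = oracle_offset(s, a, "tes"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sense_gene_id = character(), as_gene_id = character(),
                      type = character(), as_tss_position = integer(),
                      as_tes_position = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$sense_gene_id, out$as_gene_id), , drop = FALSE]
}

# Canonical comparison form for engine output vs oracle output.
pair_key <- function(pairs) {
  df <- as.data.frame(pairs)[, c("sense_gene_id", "as_gene_id", "type",
                                 "as_tss_position", "as_tes_position")]
  df <- df[order(df$sense_gene_id, df$as_gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Tie-free two-sample data realising a prescribed Mann-Whitney U for group x:
# x_i is placed strictly between the c_i-th and (c_i+1)-th y value, with
# sum(c_i) = u.
make_xy_for_u <- function(ni, nj, u) {
  stopifnot(u >= 0, u <= ni * nj)
  k <- u %/% nj
  r <- u %% nj
  counts <- c(rep(nj, k), if (k < ni) r, rep(0, max(ni - k - 1, 0)))
  y <- 10 * seq_len(nj)
  x <- 10 * counts + 5 + 0.1 * seq_len(ni)
  list(x = x, y = y)
}

# Exact permutation distribution of the two-group studentized rank statistic
# at small n. Reports the mid-p (P(T > t) + P(T = t)/2), the standard
# convention when a discrete permutation distribution is compared against a
# continuous reference: the >=-inclusive p systematically exceeds any
# continuous approximation by half the point mass at the observed value.
dscf_exact_p <- function(x, y) {
  pooled <- c(x, y)
  ni <- length(x)
  n <- length(pooled)
  stat_of <- function(a, b) {
    na <- length(a); nb <- length(b); nn <- na + nb
    r <- rank(c(a, b))
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    tt <- table(c(a, b))
    s2 <- na * nb / 12 * ((nn + 1) - sum(tt^3 - tt) / (nn * (nn - 1)))
    if (s2 <= 0) return(0)
    sqrt(2) * abs(u - na * nb / 2) / sqrt(s2)
  }
  obs <- stat_of(x, y)
  combos <- utils::combn(n, ni)
  stats <- apply(combos, 2, function(idx) stat_of(pooled[idx], pooled[-idx]))
  mean(stats > obs + 1e-12) + 0.5 * mean(abs(stats - obs) <= 1e-12)
}
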