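#' Dwass-Steel-Critchlow-Fligner all-pairs rank test (Steel-Dwass)
#'
#' Nonparametric all-pairs multiple comparison controlling the family-wise
#' error rate. For every unordered pair of groups a two-sample rank statistic
#' is computed on the pooled pair only (ties receive average ranks; the rank
#' variance carries the usual tie correction), studentized, and referred to
#' the studentized range distribution over the total number of groups `k`.
#' With `k = 2` it reduces to a studentized two-sample rank-sum test.
#'
#' @param data Either a data frame (with `value` and `group` columns named via
#'   the `value`/`group` arguments) or a named list of numeric vectors, one
#'   per group.
#' @param value,group Column names when `data` is a data frame.
#' @param alpha Family-wise significance level used for the `significant`
#'   flags; exact p-values are always reported.
#' @return An object of class `dscf`: a list with `comparisons` (tibble of
#'   `group1`, `group2`, `statistic` — the studentized range scale value — and
#'   `p_value`, `significant`), plus `k`, `n_total` and `alpha`. [tidy()]
#'   returns the comparison table, [glance()] a one-row summary.
#' @export
#' @examples
#' g <- list(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6), c = c(9, 10, 11, 12, 13))
#' steel_dwass(g)
steel_dwass <- function(data, value = "value", group = "group", alpha = 0.01) {
  groups <- if (is.data.frame(data)) {
    split(data[[value]], data[[group]])
  } else if (is.list(data)) {
    data
  } else {
    abort("`data` must be a data frame or a list of numeric vectors.")
  }
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) {
    abort("need at least 2 groups.")
  }
  if (any(lengths(groups) < 2)) {
    abort("every group needs at least 2 observations.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_len(k))
  }
  combos <- utils::combn(k, 2)
  rows <- purrr::map(seq_len(ncol(combos)), function(ci) {
    i <- combos[1, ci]
    j <- combos[2, ci]
    st <- dscf_statistic(groups[[i]], groups[[j]])
    tibble::tibble(
      group1 = names(groups)[i], group2 = names(groups)[j],
      statistic = st,
      p_value = ptukey(st, nmeans = k, df = Inf, lower.tail = FALSE)
    )
  })
  comparisons <- dplyr::bind_rows(rows)
  comparisons$significant <- comparisons$p_value < alpha
  structure(
    list(comparisons = comparisons, k = k,
         n_total = sum(lengths(groups)), alpha = alpha),
    class = "dscf"
  )
}

# Internal: studentized-range-scale statistic for one group pair.
# Mann-Whitney U on the pooled two-group sample, centred at ni*nj/2,
# scaled by the tie-corrected rank variance, times sqrt(2).
dscf_statistic <- function(x, y) {
  ni <- length(x)
  nj <- length(y)
  n <- ni + nj
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(ni)]) - ni * (ni + 1) / 2
  t <- table(c(x, y))
  tie_term <- sum(t^3 - t) / (n * (n - 1))
  sigma2 <- ni * nj / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  sqrt(2) * abs(u_x - ni * nj / 2) / sqrt(sigma2)
}

#' @export
print.dscf <- function(x, ...) {
  cat(sprintf("Steel-Dwass (DSCF) all-pairs test: %d groups, n = %d\n",
              x$k, x$n_total))
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.dscf <- function(x, ...) x$comparisons

#' @export
glance.dscf <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_total = x$n_total, alpha = x$alpha,
    n_significant = sum(x$comparisons$significant)
  )
}
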