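# Paired one-sided Wilcoxon signed-rank tests (exact enumeration for small
# samples), the all-pairs Bonferroni-corrected test matrix, and the
# two-sample Kolmogorov-Smirnov comparison.

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests `H0: x = y` against `H1: x < y` (elementwise paired samples). Zero
#' differences are dropped; absolute differences are ranked with midranks
#' for ties. With `n <= exact_max` nonzero differences the null distribution
#' of the positive-rank sum is enumerated exactly over all sign
#' assignments (ties included); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Numeric vectors of equal length (`x` is the putatively smaller
#'   sample under the alternative).
#' @param exact_max Largest number of nonzero differences for which the
#'   exact enumeration is used. Default 12.
#' @return An object of class `htest` with the positive-rank sum statistic
#'   `V`, the one-sided `p.value`, and `n_effective` (nonzero differences).
#'   If all differences are zero the test is undefined: `p.value` is `NA`
#'   and the element `undefined` is `TRUE`.
#' @export
#' @examples
#' wilcoxon_one_sided(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7)) # p = 1/64
wilcoxon_one_sided <- function(x, y, exact_max = 12) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  out <- list(
    statistic = c(V = NA_real_),
    p.value = NA_real_,
    alternative = "x is stochastically smaller than y",
    method = "One-sided paired Wilcoxon signed-rank test",
    data.name = "x and y",
    n_effective = n,
    undefined = FALSE
  )
  class(out) <- "htest"
  if (n == 0) {
    out$undefined <- TRUE
    return(out)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  out$statistic <- c(V = v)
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w <- as.numeric(signs %*% r)
    out$p.value <- mean(w <= v + 1e-9)
    out$method <- paste(out$method, "(exact enumeration)")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu + 0.5) / sqrt(sigma2)
    out$p.value <- pnorm(z)
    out$method <- paste(out$method,
                        "(normal approximation, continuity correction)")
  }
  out$p.value <- min(max(out$p.value, .Machine$double.xmin), 1)
  out
}

#' All-pairs one-sided divergence tests with Bonferroni correction
#'
#' For every ordered pair of groups `(a, b)`, pairs their per-tree
#' divergence values over the trees both groups occur in and runs
#' [wilcoxon_one_sided()] with alternative `D_a < D_b`. The resulting
#' p-value matrix is asymmetric (both directions are tested). The Bonferroni
#' multiplier is the number of unordered group pairs tested; a cell is
#' significant when `p * multiplier < alpha`.
#'
#' @param records A data frame with columns `group`, `tree_id`,
#'   `normalized_distance` (e.g. from [group_divergence()], one metric at a
#'   time).
#' @param alpha Significance level after correction. Default 0.05.
#' @param exclude Groups left out of the matrix; defaults to the residual
#'   `"Other Bacteria"` bin.
#' @return An object of class `pairwise_wilcoxon`: a list with matrices `p`
#'   (row = a, column = b, `NA` diagonal and `NA` where no shared trees),
#'   `significant`, `n_shared`, plus `alpha`, `multiplier` and `groups`.
#'   [tidy()], [glance()] and [autoplot()] methods are available.
#' @export
pairwise_divergence_tests <- function(records, alpha = 0.05,
                                      exclude = "Other Bacteria") {
  check_columns(records, c("group", "tree_id", "normalized_distance"),
                "records")
  if ("metric" %in% names(records) &&
      dplyr::n_distinct(records$metric) > 1) {
    abort("`records` mixes metrics; filter to a single metric first")
  }
  records <- dplyr::filter(records, !(.data$group %in% exclude))
  groups <- sort(unique(records$group))
  G <- length(groups)
  if (G < 2) abort("need at least two groups to test")
  vals <- records |>
    dplyr::select("group", "tree_id", "normalized_distance") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = "normalized_distance")
  p <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  n_shared <- matrix(0L, G, G, dimnames = list(groups, groups))
  tested_pairs <- 0L
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      a <- vals[[groups[i]]]
      b <- vals[[groups[j]]]
      ok <- !is.na(a) & !is.na(b)
      n_shared[i, j] <- n_shared[j, i] <- sum(ok)
      if (sum(ok) == 0) next
      tested_pairs <- tested_pairs + 1L
      p[i, j] <- wilcoxon_one_sided(a[ok], b[ok])$p.value
      p[j, i] <- wilcoxon_one_sided(b[ok], a[ok])$p.value
    }
  }
  multiplier <- tested_pairs
  significant <- p * multiplier < alpha
  structure(
    list(p = p, significant = significant, n_shared = n_shared,
         alpha = alpha, multiplier = multiplier, groups = groups),
    class = "pairwise_wilcoxon"
  )
}

#' @export
print.pairwise_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Pairwise one-sided Wilcoxon tests: %d groups, %d pairs (Bonferroni x%d)\n",
    length(x$groups), x$multiplier, x$multiplier))
  cat(sprintf("significant cells (alpha = %g): %d\n", x$alpha,
              sum(x$significant, na.rm = TRUE)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sided KS statistic `D` — the supremum over the pooled
#' sample of the absolute difference between the two empirical CDFs — and an
#' asymptotic p-value from the Kolmogorov distribution evaluated at
#' `sqrt(ne) * D` with effective size `ne = nx * ny / (nx + ny)`.
#'
#' @param x,y Non-empty numeric samples.
#' @return An object of class `htest` with `statistic` `D` and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  Fx <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  p <- if (D == 0) {
    1
  } else {
    lambda <- sqrt(ne) * D
    k <- 1:101
    min(max(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2)), 0), 1)
  }
  structure(
    list(statistic = c(D = D), p.value = p,
         alternative = "two-sided",
         method = "Two-sample Kolmogorov-Smirnov test (asymptotic)",
         data.name = "x and y"),
    class = "htest"
  )
}
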