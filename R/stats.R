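#' Paired Wilcoxon signed-rank test (exact for small samples)
#'
#' Compares per-electrode response probabilities between two conditions,
#' paired by electrode (the same electrodes are measured under each
#' condition). This is the classical Wilcoxon T test: zero differences are
#' dropped (Wilcoxon's original procedure; Pratt's zero-rank method is
#' available as an option), tied absolute differences receive mid-ranks, and
#' the statistic is the sum of ranks of the positive differences.
#'
#' For `n_effective <= exact_max_n` the two-sided p-value is exact,
#' enumerating the null distribution of the statistic over all 2^n equally
#' likely sign assignments of the observed ranks (computed by dynamic
#' programming over the rank multiset, which is arithmetic shorthand for the
#' full enumeration and handles mid-ranks). Above that, a normal
#' approximation with continuity correction is used, with moments
#' `mu = sum(r)/2`, `var = sum(r^2)/4` valid for arbitrary (tied) ranks.
#'
#' @param probs_a,probs_b the two paired measurements: numeric vectors named
#'   by electrode id, data frames with `electrode_id` and `prob` columns, or
#'   `response_probability_table` objects.
#' @param alpha significance level.
#' @param zero_method `"wilcox"` (drop zero differences) or `"pratt"`
#'   (rank with zeros included, then drop the zero ranks).
#' @param exact_max_n largest `n_effective` for which the exact distribution
#'   is enumerated.
#' @return An object of class `stat_result`: `method`, `statistic` (signed
#'   rank sum W of positive differences), `p_value`, `n_effective`,
#'   `significant`, `alpha`, `zero_method`.
#' @examples
#' a <- setNames(c(0.1, 0.2, 0.15, 0.3, 0.25), 1:5)
#' b <- a + 0.1
#' wilcoxon_signed_rank(b, a)$p_value   # 0.0625, the exact floor for n = 5
#' @export
wilcoxon_signed_rank <- function(probs_a, probs_b, alpha = 0.05,
                                 zero_method = c("wilcox", "pratt"),
                                 exact_max_n = 25L) {
  zero_method <- match.arg(zero_method)
  a <- as_prob_vector(probs_a)
  b <- as_prob_vector(probs_b)
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("no common electrodes between the two tables")
  d <- a[common] - b[common]

  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- if (length(d)) rank(abs(d)) else numeric()
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n_eff <- length(d)
  if (n_eff == 0) {
    warning("all paired differences are zero; p-value set to 1")
    return(structure(list(method = "wilcoxon_signed_rank", statistic = 0,
                          p_value = 1, n_effective = 0L, significant = FALSE,
                          alpha = alpha, zero_method = zero_method),
                     class = "stat_result"))
  }
  w <- sum(r[d > 0])

  if (n_eff <= exact_max_n) {
    # exact null distribution of W over all 2^n sign assignments; mid-ranks
    # are multiples of 1/2, so doubled ranks are integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)            # counts of assignments per 2W
    f[1L] <- 1
    for (rk in r2) {
      g <- f
      g[(rk + 1L):(total + 1L)] <- g[(rk + 1L):(total + 1L)] + f[1L:(total + 1L - rk)]
      f <- g
    }
    w2 <- round(2 * w)
    p_le <- sum(f[seq_len(w2 + 1L)]) / 2^n_eff
    p_ge <- sum(f[(w2 + 1L):(total + 1L)]) / 2^n_eff
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(method = "wilcoxon_signed_rank", statistic = w, p_value = p,
                 n_effective = as.integer(n_eff),
                 significant = p <= alpha, alpha = alpha,
                 zero_method = zero_method),
            class = "stat_result")
}

# internal: coerce the accepted inputs to a named numeric vector. For a
# response_probability_table the comparison is restricted to the
# microchannel electrodes, the population the study's statistic is
# defined over.
as_prob_vector <- function(x) {
  if (inherits(x, "response_probability_table")) {
    tab <- x$table
    if (!is.null(x$microchannel_ids))
      tab <- tab[tab$electrode_id %in% x$microchannel_ids, , drop = FALSE]
    x <- tab
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("electrode_id", "prob") %in% names(x)))
    return(setNames(x$prob, as.character(x$electrode_id)))
  }
  if (is.numeric(x)) {
    if (is.null(names(x))) names(x) <- as.character(seq_along(x))
    return(x)
  }
  stop("cannot interpret input as a probability table")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.4g%s\n",
              x$statistic, x$n_effective, x$p_value,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha)
              else ""))
  invisible(x)
}
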