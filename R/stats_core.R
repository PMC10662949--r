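#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Self-contained implementation used by all pipeline comparisons.  The
#' statistic is U for sample `x`: `U = R_x - n1(n1+1)/2` with mid-ranks for
#' ties.  `method = "exact"` enumerates the permutation null over the
#' observed pooled multiset (ties included) and is the default when
#' `n1 + n2 <= 20`; otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used.  Two-sided exact p is the
#' null probability of `|U - n1*n2/2|` at least as large as observed.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_limit maximum pooled size for which `"auto"` picks the exact
#'   enumeration.
#' @return object of class `mw_test`: list with `statistic` (U), `n1`, `n2`,
#'   `p.value`, `method`, `alternative`, `tie_corrected`, `all_ties`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))$p.value  # exact two-sided 1/3
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "greater", "less"),
                         method = c("auto", "exact", "normal"),
                         exact_limit = 20L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  all_ties <- length(ties) == 1L

  if (method == "auto")
    method <- if (N <= exact_limit) "exact" else "normal"

  if (method == "exact") {
    if (all_ties) {
      p <- 1
    } else {
      # full enumeration of which pooled ranks go to x
      idx <- utils::combn(N, n1)
      Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
      eps <- 1e-9
      p <- switch(alternative,
        two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
        greater   = mean(Us >= U - eps),
        less      = mean(Us <= U + eps))
    }
    tc <- has_ties
  } else {
    tie_term <- sum(ties^3 - ties)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      sig <- sqrt(sig2)
      z_hi <- (U - mu - 0.5) / sig   # continuity-corrected
      z_lo <- (U - mu + 0.5) / sig
      p <- switch(alternative,
        two.sided = min(1, 2 * min(stats::pnorm(z_hi, lower.tail = FALSE),
                                   stats::pnorm(z_lo))),
        greater   = stats::pnorm(z_hi, lower.tail = FALSE),
        less      = stats::pnorm(z_lo))
    }
    tc <- has_ties
  }
  structure(list(statistic = U, n1 = n1, n2 = n2,
                 p.value = max(min(p, 1), .Machine$double.xmin),
                 method = if (method == "exact") "exact"
                          else "normal_approximation",
                 alternative = alternative,
                 tie_corrected = tc, all_ties = all_ties),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney-Wilcoxon: U = %g (n1 = %d, n2 = %d), p = %.4g [%s, %s]\n",
              x$statistic, x$n1, x$n2, x$p.value, x$method, x$alternative))
  invisible(x)
}

#' Replicate summary: mean, sample SD, n
#'
#' SD uses the n-1 sample formula; with a single replicate SD is reported as
#' 0 and flagged.
#'
#' @param values numeric vector of per-replicate values (n >= 1).
#' @return list with `mean`, `sd`, `n`, `sd_defined` (FALSE when n = 1).
#' @export
replicate_summary <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, all(is.finite(values)))
  n <- length(values)
  list(mean = mean(values),
       sd = if (n > 1) stats::sd(values) else 0,
       n = n,
       sd_defined = n > 1)
}

#' Holm adjustment of a set of p-values
#'
#' Optional helper; the pipeline reports unadjusted per-comparison p-values
#' by default (decision threshold 0.001).
#'
#' @param p numeric vector of p-values.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")
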