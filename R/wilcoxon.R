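# Paired method comparison with an exact Wilcoxon signed-rank test.

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test of the hypothesis that the paired
#' differences are symmetric about zero. Zero differences are dropped;
#' absolute differences are ranked with average ranks for ties. For n <= 25
#' retained pairs the null distribution of the positive-rank sum W+ is
#' computed exactly by convolving the per-pair generating functions (all 2^n
#' sign assignments, which remains exact under ties — a case the classical
#' tabulated distribution does not cover); for larger n a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param d numeric vector of paired differences.
#' @param exact_limit use the exact distribution for up to this many nonzero
#'   pairs (default 25).
#' @return list with `statistic` (W+, the positive-rank sum), `p_value`
#'   (two-sided), `n` (nonzero pairs), `exact`, and `defined` (`FALSE` when
#'   every difference is zero, in which case `p_value` is `NA`).
#' @export
signed_rank_test <- function(d, exact_limit = 25L) {
  stopifnot(is.numeric(d), all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = NA_real_, n = 0L,
                exact = NA, defined = FALSE))
  r <- rank(abs(d))                       # average ranks for ties
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))        # double ranks -> integer support
    total <- sum(r2)
    f <- numeric(total + 1L); f[1L] <- 1
    for (k in r2) {
      shifted <- c(numeric(k), f[seq_len(total + 1L - k)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w, p_value = p, n = n, exact = exact, defined = TRUE)
}

#' Compare two DSA methods by per-case entropy
#'
#' Takes, for each case, the list of per-frame entropies under each method,
#' reduces each case to its median, and tests the paired per-case medians
#' with the two-sided Wilcoxon signed-rank test ([signed_rank_test()]). This
#' is the study-level comparison: one median per patient per method.
#'
#' @param entropies_a,entropies_b named lists (same names/order) of numeric
#'   vectors: per-frame entropies per case for methods A and B.
#' @param labels length-2 character, display names for the two methods.
#' @return An object of class `method_comparison`: per-case medians, the
#'   signed-rank `statistic` and `p_value`, mean entropy per method, and
#'   `direction` (which method has the lower mean of per-case medians;
#'   `"none"` when all differences are zero).
#' @export
compare_methods <- function(entropies_a, entropies_b,
                            labels = c("A", "B")) {
  if (length(entropies_a) != length(entropies_b))
    stop("case counts differ between methods", call. = FALSE)
  if (length(entropies_a) < 2L)
    stop("at least 2 cases are required for a defined comparison",
         call. = FALSE)
  na <- names(entropies_a); nb <- names(entropies_b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb))
    stop("case names differ between methods", call. = FALSE)
  med_a <- vapply(entropies_a, stats::median, numeric(1))
  med_b <- vapply(entropies_b, stats::median, numeric(1))
  test <- signed_rank_test(med_a - med_b)
  direction <- if (!test$defined || mean(med_a) == mean(med_b)) "none"
               else if (mean(med_a) < mean(med_b)) labels[1] else labels[2]
  structure(list(labels = labels, medians_a = med_a, medians_b = med_b,
                 mean_a = mean(unlist(entropies_a)),
                 mean_b = mean(unlist(entropies_b)),
                 statistic = test$statistic, p_value = test$p_value,
                 n = test$n, exact = test$exact, defined = test$defined,
                 direction = direction),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %s vs %s over %d case(s)\n",
              x$labels[1], x$labels[2], length(x$medians_a)))
  cat(sprintf("  mean entropy: %s = %.4f, %s = %.4f\n",
              x$labels[1], x$mean_a, x$labels[2], x$mean_b))
  if (x$defined) {
    cat(sprintf("  Wilcoxon signed-rank: W+ = %g, p = %.4g (%s), lower: %s\n",
                x$statistic, x$p_value,
                if (isTRUE(x$exact)) "exact" else "normal approx.",
                x$direction))
  } else {
    cat("  all paired differences are zero; test undefined\n")
  }
  invisible(x)
}
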