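# Independent oracles used by both the module tests and the acceptance
# suite. These deliberately share no code with the implementation paths
# they check.

# Wilcoxon signed-rank: enumerate all 2^n sign assignments of the ranked
# absolute differences and read the two-sided tail probability directly.
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Dense translation search: evaluate ZNCC on a 0.05 px grid within
# +/- bound px and return the best shift and score.
grid_search_shift <- function(contrast_patch, frame, origin, bound = 4,
                              step = 0.05) {
  dc <- contrast_patch - mean(contrast_patch)
  vc <- sum(dc * dc)
  shifts <- seq(-bound, bound, by = step)
  best <- c(NA, NA, -Inf)
  for (ty in shifts) {
    for (tx in shifts) {
      p <- sample_shifted_patch(frame, origin, dim(contrast_patch),
                                c(tx, ty))
      if (is.null(p)) next
      dp <- p - mean(p)
      s <- sum(dc * dp) / sqrt(vc * sum(dp * dp))
      if (s > best[3]) best <- c(tx, ty, s)
    }
  }
  list(tx = best[1], ty = best[2], score = best[3])
}
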