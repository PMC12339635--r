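# Shared fixtures, built in code.

# A small, fast phantom for unit tests (full defaults are exercised in the
# end-to-end acceptance tests).
small_phantom_config <- function(...) {
  base <- list(height = 80, width = 104, t_mask = 10, t_contrast = 6,
               cardiac = list(radius = 10),
               bowel = list(radius = 6),
               vessel = list(inflow_frames = 3))
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (nm %in% names(base) && is.list(base[[nm]]))
      utils::modifyList(base[[nm]], over[[nm]]) else over[[nm]]
  }
  do.call(phantom_config, base)
}

# Smooth random field with ~6 px correlation length: enough texture for
# matching/refinement to be well conditioned, smooth enough for a unimodal
# ZNCC surface.
textured_field <- function(H, W, seed) {
  set.seed(seed)
  low <- matrix(rnorm(ceiling(H / 6 + 2) * ceiling(W / 6 + 2)),
                ceiling(H / 6 + 2), ceiling(W / 6 + 2))
  ri <- seq(1, nrow(low) - 1, length.out = H)
  ci <- seq(1, ncol(low) - 1, length.out = W)
  fr <- floor(ri); wr <- ri - fr
  fc <- floor(ci); wc <- ci - fc
  100 + 25 * (low[fr, fc] * ((1 - wr) %o% (1 - wc)) +
                low[fr + 1, fc] * (wr %o% (1 - wc)) +
                low[fr, fc + 1] * ((1 - wr) %o% wc) +
                low[fr + 1, fc + 1] * (wr %o% wc))
}

# Independent reference bilinear sampler (scalar loops, no shared code with
# sample_shifted_patch).
bilinear_at <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  r0 <- min(max(r0, 0), nrow(img) - 2)
  c0 <- min(max(c0, 0), ncol(img) - 2)
  ar <- r - r0; ac <- c - c0
  (1 - ar) * (1 - ac) * img[r0 + 1, c0 + 1] +
    ar * (1 - ac) * img[r0 + 2, c0 + 1] +
    (1 - ar) * ac * img[r0 + 1, c0 + 2] +
    ar * ac * img[r0 + 2, c0 + 2]
}
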