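# Shared fixtures and independent oracles used across the suite.

default_cfg <- acquisition_config()

# Bin-centred cosine frame: amplitude a at bin k (frequency k * df) on DC
# offset d, phase phi.
tone_frame <- function(k, a = 0.05, d = 0.4, phi = 0.3,
                       cfg = default_cfg) {
  n <- cfg$frame_length
  d + a * cos(2 * pi * k * (0:(n - 1)) / n + phi)
}

# Quadrature oracle for a scene's band-limited first moment, deliberately
# independent of scene_truth(): Simpson's rule on a fine grid.
quadrature_moment <- function(shape_fun, band, n = 40001L) {
  stopifnot(n %% 2 == 1)
  f <- seq(band[1], band[2], length.out = n)
  s <- shape_fun(f)
  h <- f[2] - f[1]
  w <- rep(c(2, 4), length.out = n); w[c(1, n)] <- 1
  m0 <- sum(w * s) * h / 3
  m1 <- sum(w * f * s) * h / 3
  m1 / m0
}

# Brute-force two-way ANOVA oracle for ICC(A,1): mean squares taken from
# stats::aov, then the McGraw-Wong single-measure absolute-agreement formula.
icc_a1_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.vector(m),
    row = factor(rep(seq_len(n), times = k)),
    col = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ row + col, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Full 2^n sign-flip enumeration oracle for the exact Wilcoxon signed-rank
# two-sided p-value (mid-ranks allowed).
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

seed_seq <- function(root, n) vapply(seq_len(n), function(i)
  ldfsim:::derive_seed(root, i), integer(1))
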