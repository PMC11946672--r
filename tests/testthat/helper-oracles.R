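# Independent oracles used across test files.

# Exhaustive scan for maximal supra-threshold runs of length >= min_run.
brute_force_runs <- function(v, eta, min_run = 6) {
  above <- v > eta
  n <- length(v)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) out <- rbind(out, c(i, j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2)
  else out
}

# Normal-equation least squares: intercept and slope.
ols_normal_eq <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Within-subject one-way ANOVA via stats::aov with an Error stratum.
aov_rm_oracle <- function(Y) {
  n <- nrow(Y)
  k <- ncol(Y)
  d <- data.frame(y = as.vector(Y),
                  s = factor(rep(seq_len(n), k)),
                  l = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ l + Error(s / l), data = d))[["Error: s:l"]][[1]]
  list(F = tab["l", "F value"], p = tab["l", "Pr(>F)"],
       ss_effect = tab["l", "Sum Sq"], ss_error = tab["Residuals", "Sum Sq"])
}

# Minimal velocity container for detector tests.
fake_velocity <- function(v) {
  data.frame(t_ms = seq_along(v) - 1, theta_x = 0, theta_y = 0,
             vx = v, vy = 0, v = v)
}

# Rotation of vectors about an axis (Rodrigues), for pupil-model tests.
rotate_about <- function(v, axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle_rad) + pracma_cross(axis, v) * sin(angle_rad) +
    axis * sum(axis * v) * (1 - cos(angle_rad))
}
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
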