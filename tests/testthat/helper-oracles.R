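# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: path lengths are accumulated
# point by point with dist(), statistics are recomputed from closed forms.

brute_path_length <- function(pos) {
  total <- 0
  for (i in seq_len(nrow(pos) - 1L)) {
    total <- total + as.numeric(stats::dist(pos[i:(i + 1L), , drop = FALSE]))
  }
  total
}

brute_plane_length <- function(pos, cols) {
  brute_path_length(cbind(pos[, cols, drop = FALSE], 0))
}

random_trajectory <- function(n = 50, frame_rate = 30) {
  pos <- matrix(runif(n * 3), n, 3)
  trajectory_series((0:(n - 1L)) / frame_rate, pos, frame_rate)
}

# Random 3D rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Closed-form pooled two-sample t statistic (independent route from t.test).
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Small, fast cohort configuration for workflow tests.
small_config <- function(seed = 42, ...) {
  cohort_config(n_group_a = 3, n_group_b = 3, seed = seed,
                mvic_duration_s = 1.5, ...)
}
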