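# independent oracles and small utilities used across tests

# circular distance on a ratio scale with the given period
circ_err <- function(a, b, period = 1) {
  d <- abs((a - b) %% period)
  pmin(d, period - d)
}

# exhaustive grid-search oracle for the cosine model: brute-force SSE
# minimisation over an explicit (A, X, x0/X, M) grid. Deliberately
# independent of the package's profiled/polished fitting path.
grid_cosine_oracle <- function(x, y,
                               A_grid = seq(0.5, 6, by = 0.1),
                               X_grid = seq(18, 32, by = 0.25),
                               r_grid = seq(0, 0.995, by = 0.005),
                               M_grid = seq(-8, -2, by = 0.1)) {
  best <- list(sse = Inf)
  for (X in X_grid) {
    for (r in r_grid) {
      cs <- cos(2 * pi * (x - r * X) / X)
      for (A in A_grid) {
        resid0 <- y - A * cs
        # best M on its own grid (still brute force, just vectorised)
        sses <- vapply(M_grid, function(M) sum((resid0 - M)^2), 0)
        j <- which.min(sses)
        if (sses[j] < best$sse) {
          best <- list(sse = sses[j], A = A, X = X, x0_over_X = r, M = M_grid[j])
        }
      }
    }
  }
  best
}

# build an in-memory peak list the way process_spectrum() returns one
fake_peaklist <- function(mz, snr = 20, specimen_id = "manual") {
  structure(data.frame(mz = mz, intensity = snr, snr = snr),
            specimen_id = specimen_id,
            class = c("maldi_peaklist", "data.frame"))
}

make_cosine_seq <- function(id = "t", A = 3, X = 25, x0 = 10, M = -5,
                            step = 1.5, span = 30, d13C = NULL) {
  x <- seq(0, span, by = step)
  tooth_sequence(id, x, A * cos(2 * pi * (x - x0) / X) + M, d13C = d13C)
}
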