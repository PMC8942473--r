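# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Brute-force spike scan: walk the samples, track suprathreshold runs,
# take the argmax of each run, then drop events within dead_time of the
# previously kept one.
oracle_detect <- function(v, t, criterion, dead_time) {
  peaks <- numeric(0)
  in_run <- FALSE
  run_start <- NA
  for (k in seq_along(v)) {
    if (v[k] > criterion && !in_run) { in_run <- TRUE; run_start <- k }
    if ((v[k] <= criterion || k == length(v)) && in_run) {
      run_end <- if (v[k] <= criterion) k - 1L else k
      idx <- run_start:run_end
      peaks <- c(peaks, t[idx[which.max(v[idx])]])
      in_run <- FALSE
    }
  }
  kept <- numeric(0)
  for (p in peaks) {
    if (length(kept) == 0L || p - kept[length(kept)] >= dead_time)
      kept <- c(kept, p)
  }
  kept
}

# Vector strength from raw trigonometric sums (no complex arithmetic).
oracle_vs <- function(phases) {
  n <- length(phases)
  sqrt(sum(cos(phases))^2 + sum(sin(phases))^2) / n
}

# Closed-form OLS line fit.
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(slope = slope, intercept = my - slope * mx)
}

# Theoretical mean resultant length of a von Mises distribution.
oracle_vm_resultant <- function(kappa) {
  besselI(kappa, 1) / besselI(kappa, 0)
}

# Build a voltage trace with triangular excursions at given peak times.
make_ap_trace <- function(peak_times, duration, dt = 0.05, baseline = -60,
                          peak = 20, half_width = 0.5) {
  t <- seq(0, duration, by = dt)
  v <- rep(baseline, length(t))
  for (tp in peak_times) {
    d <- abs(t - tp)
    tri <- pmax(0, 1 - d / half_width)
    v <- pmax(v, baseline + (peak - baseline) * tri)
  }
  trace(v, dt = dt, kind = "voltage")
}
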