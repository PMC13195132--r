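# shared scoring utilities for detector-vs-ground-truth comparisons

# match detected event times against true times within a tolerance;
# one-to-one greedy matching in time order
score_events <- function(detected, truth, tol_s = 0.01) {
  if (length(detected) == 0) {
    return(list(recall = 0, precision = NA_real_, tp = 0L))
  }
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (t in detected) {
    i <- which(!used & abs(truth - t) < tol_s)
    if (length(i)) {
      used[i[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(recall = sum(used) / max(length(truth), 1),
       precision = tp / length(detected), tp = tp)
}

# fraction of [0, dur] covered by epochs
epoch_coverage <- function(epochs, dur) {
  if (nrow(epochs) == 0) return(0)
  sum(pmin(epochs$end_s, dur) - pmax(epochs$start_s, 0)) / dur
}

# von Mises sampler (Best & Fisher rejection scheme); independent of the
# generator's thinning-based sampler so it can serve as its oracle
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (u[2] < c0 * (2 - c0) || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  out
}

# peri-ripple scoring: detected event counts as true if its peak falls in a
# ground-truth window
score_ripples <- function(detected, truth_windows) {
  if (nrow(detected) == 0) {
    return(list(recall = 0, precision = NA_real_))
  }
  tp <- vapply(detected$peak_s, function(p)
    any(p > truth_windows$start_s & p < truth_windows$end_s), logical(1))
  rec <- vapply(seq_len(nrow(truth_windows)), function(i)
    any(detected$peak_s > truth_windows$start_s[i] &
          detected$peak_s < truth_windows$end_s[i]), logical(1))
  list(recall = mean(rec), precision = mean(tp))
}
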