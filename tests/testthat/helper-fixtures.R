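# shared fixture builders for the test suite; everything is generated in
# code so the suite carries no data files

# epoch series with given values at 5 s epochs starting at t0
ep5 <- function(values, t0 = 0) epoch_series(t0 + (seq_along(values) - 1) * 5,
                                             values, 5)

# epoch series of per-minute blocks: rep each value for 12 five-second epochs
ep_minutes <- function(values_per_min) ep5(rep(values_per_min, each = 12))

# constant-orientation recording: n samples of acc (0,0,1) at fs Hz
still_rec <- function(n, fs = 10, temp = NULL, dir = c(0, 0, 1)) {
  raw_recording((seq_len(n) - 1) / fs,
                matrix(rep(dir, each = n), n, 3),
                temperature = if (is.null(temp)) NULL else rep(temp, n),
                sampling_rate = fs)
}

# bout_list from plain durations
bl <- function(durations, state = "SLPA",
               censored = rep(FALSE, length(durations))) {
  structure(list(state = state, durations = durations, censored = censored),
            class = "bout_list")
}

# brute-force oracle: non-overlapping window means
brute_window_means <- function(x, spw) {
  nwin <- length(x) %/% spw
  vapply(seq_len(nwin), function(k) mean(x[((k - 1) * spw + 1):(k * spw)]),
         numeric(1))
}

# brute-force oracle: union of qualifying bout windows (O(n^2), tiny n only)
brute_bout_minutes <- function(inlev, min_ep, criterion, epoch_length) {
  n <- length(inlev)
  covered <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!inlev[i]) next
    for (j in i:n) {
      if (!inlev[j] || j - i + 1 < min_ep) next
      if (sum(inlev[i:j]) >= criterion * (j - i + 1) - 1e-12)
        covered[i:j] <- TRUE
    }
  }
  sum(covered) * epoch_length / 60
}

# random unit 3-vector
runit3 <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
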