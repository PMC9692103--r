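# Independent brute-force oracles: direct summation of the defining
# formulas, written without reference to the package implementations.

oracle_perfusion <- function(x, y) {
  (max(y) - min(y)) / abs(sum(x) / length(x)) * 100
}

oracle_moment <- function(x, k) {
  n <- length(x)
  mu <- sum(x) / n
  sigma <- sqrt(sum((x - mu)^2) / n)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + ((x[i] - mu) / sigma)^k
  acc / n
}

oracle_entropy <- function(x) {
  e <- sum(x^2)
  acc <- 0
  for (i in seq_along(x)) {
    p <- x[i]^2 / e
    if (p > 0) acc <- acc - p * log(p)
  }
  acc
}

# independent centered moving average (replicated edges) by direct summation
oracle_moving_average <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1
  h <- (k - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in (i - h):(i + h)) acc <- acc + x[min(max(j, 1), n)]
    out[i] <- acc / k
  }
  out
}

oracle_variance_ratio <- function(x, k) {
  s <- oracle_moving_average(x, k)
  r <- x - s
  var_ <- function(v) sum((v - mean(v))^2) / (length(v) - 1)
  var_(s) / var_(r)
}

# sign-scan crossing count with carry-forward at the reference level
oracle_crossings <- function(x, ref) {
  s <- integer(0)
  for (v in x) {
    sg <- if (v > ref) 1L else if (v < ref) -1L else 0L
    if (sg != 0L) s <- c(s, sg)
  }
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# band-sum ratio applied directly to a PSD estimate, half-open bands
oracle_band_ratio <- function(freqs, psd, num, den) {
  num_sum <- 0; den_sum <- 0
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    if (f >= num[1] && f < num[2]) num_sum <- num_sum + psd[i]
    if (f >= den[1] && f < den[2]) den_sum <- den_sum + psd[i]
  }
  num_sum / den_sum
}

# direct evaluation of the time-domain HRV formulas over an interval list
oracle_hrv_time <- function(nn) {
  n <- length(nn)
  mean_nni <- sum(nn) / n
  sdnn <- sqrt(sum((nn - mean_nni)^2) / (n - 1))
  d <- nn[-1] - nn[-n]
  rmssd <- sqrt(sum(d^2) / length(d))
  sdsd <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  hr <- 60000 / nn
  list(mean_nni = mean_nni, sdnn = sdnn, sdsd = sdsd, rmssd = rmssd,
       cvsd = rmssd / mean_nni, cvnni = sdnn / mean_nni,
       pnn_50 = sum(abs(d) > 50) / length(d),
       pnn_20 = sum(abs(d) > 20) / length(d),
       hr_mean = mean(hr), hr_std = stats::sd(hr), hr_min = min(hr),
       hr_max = max(hr))
}

# Malik ectopic scan: compare to the last kept interval
oracle_malik_flags <- function(raw) {
  flag <- logical(length(raw))
  ref <- raw[1]
  for (i in seq_along(raw)[-1]) {
    if (abs(raw[i] - ref) > 0.2 * ref) {
      flag[i] <- TRUE
    } else {
      ref <- raw[i]
    }
  }
  flag
}

# rank-based AUC (probability a random accept scores above a random reject)
oracle_rank_auc <- function(score, is_positive) {
  pos <- score[is_positive]
  neg <- score[!is_positive]
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# greedy one-to-one peak matching; returns recall and precision
match_peaks <- function(detected, truth, tol) {
  if (!length(detected)) return(c(recall = 0, precision = 0))
  used <- rep(FALSE, length(detected))
  tp <- 0L
  for (p in truth) {
    d <- abs(detected - p)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(recall = tp / length(truth), precision = tp / length(detected))
}

clean_ppg <- function(duration_s = 60, hr = 60, rate = 100, seed = 1,
                      hrv_sd_ms = 0, noise_sd = 0, wander = c(0, 0)) {
  synth_record(synthesis_spec("ppg", duration_s = duration_s, rate = rate,
                              heart_rate_bpm = hr, hrv_sd_ms = hrv_sd_ms,
                              noise_sd = noise_sd, baseline_wander = wander,
                              seed = seed))
}

random_signal <- function(n, seed) {
  set.seed(seed)
  stats::rnorm(n, mean = stats::runif(1, -2, 2), sd = stats::runif(1, 0.5, 3))
}
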