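# shared builders for small test inputs

sinusoid_record <- function(freq, fs = 250, dur = 20, amp = 1, nch = 1,
                            labels = NULL) {
  t <- (0:(round(dur * fs) - 1)) / fs
  x <- amp * sin(2 * pi * freq * t)
  X <- matrix(rep(x, nch), nrow = nch, byrow = TRUE)
  if (is.null(labels)) labels <- channel_order_1020()[seq_len(nch)]
  suppressWarnings(eeg_record(X, fs, channel_labels = labels))
}

noise_record <- function(fs = 250, dur = 20, nch = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(nch * round(dur * fs)), nrow = nch)
  suppressWarnings(eeg_record(X, fs,
    channel_labels = channel_order_1020()[seq_len(nch)]))
}

# direct reference implementation of the 1976 exhaustive-history parse:
# the next phrase is the shortest prefix of the remainder that is not a
# substring (self-overlap allowed) of the string up to the phrase's
# penultimate symbol
lz76_reference <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  p <- 1L; count <- 0L
  while (p <= n) {
    l <- 0L
    while (p + l <= n) {
      cand <- substr(s, p, p + l)               # length l + 1
      hist <- substr(s, 1, p + l - 1)           # up to penultimate symbol
      if (l + 1 <= nchar(hist) && grepl(cand, hist, fixed = TRUE)) {
        l <- l + 1L
      } else break
    }
    count <- count + 1L
    if (p + l > n) break                        # final (possibly copied) phrase
    p <- p + l + 1L
  }
  count
}

# closed-form Krichevsky-Trofimov sequence probability (log2)
kt_log2prob <- function(bits) {
  a <- 0; b <- 0; lp <- 0
  for (i in seq_along(bits)) {
    cx <- if (bits[i] == 0) a else b
    lp <- lp + log2((cx + 0.5) / (i))
    if (bits[i] == 0) a <- a + 1 else b <- b + 1
  }
  lp
}

# direct O(n^2) fuzzy sample-entropy pair sums in plain R
fuzzy_sampen_direct <- function(x, m, r) {
  n <- length(x); nt <- n - m
  B <- 0; A <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      dm1 <- max(dm, abs(x[i + m] - x[j + m]))
      B <- B + 1 / (1 + exp((dm - 0.5) / r))
      A <- A + 1 / (1 + exp((dm1 - 0.5) / r))
    }
  }
  c(B, A)
}

# exact Mann-Whitney upper tail by enumeration (balanced n per class)
mw_exact_upper_p <- function(u_obs, n) {
  combos <- utils::combn(2 * n, n)
  ranks <- seq_len(2 * n)
  u <- apply(combos, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mean(u >= u_obs)
}
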