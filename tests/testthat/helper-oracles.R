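# Independent brute-force reference implementations used to validate the
# pipeline stages. These deliberately use plain loops and first-principles
# definitions, not the package's code paths.

# Type-7 percentile (linear interpolation between order statistics),
# written out explicitly.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  idx <- 1 + (n - 1) * p
  lo <- floor(idx)
  hi <- ceiling(idx)
  h <- idx - lo
  (1 - h) * x[lo] + h * x[hi]
}

# Percentile clipping: which pixels survive, by direct scan.
oracle_clip <- function(depths, valid, lower_pct, upper_pct, range_mm) {
  inr <- valid & depths >= range_mm[1] & depths <= range_mm[2]
  if (!any(inr)) return(matrix(FALSE, nrow(depths), ncol(depths)))
  p_lo <- oracle_percentile(depths[inr], lower_pct / 100)
  p_hi <- oracle_percentile(depths[inr], upper_pct / 100)
  inr & depths >= p_lo & depths <= p_hi
}

# Windowed masked median by nested loops.
oracle_median_filter <- function(x, valid, k) {
  h <- k %/% 2
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      if (!valid[i, j]) next
      vals <- c()
      for (ii in max(1, i - h):min(nrow(x), i + h))
        for (jj in max(1, j - h):min(ncol(x), j + h))
          if (valid[ii, jj]) vals <- c(vals, x[ii, jj])
      out[i, j] <- median(vals)
    }
  }
  out
}

# Per-pixel median across frames with the majority-invalid rule.
oracle_temporal_median <- function(mats, valids) {
  nf <- length(mats)
  out <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      v <- vapply(seq_len(nf), function(k)
        if (valids[[k]][i, j]) mats[[k]][i, j] else NA_real_, numeric(1))
      ninv <- sum(is.na(v))
      out[i, j] <- if (2 * ninv > nf) 0 else median(v, na.rm = TRUE)
    }
  }
  out
}

# Connected components by recursive flood fill over an explicit stack.
oracle_components <- function(active, connectivity = 8) {
  lab <- matrix(0L, nrow(active), ncol(active))
  nbrs <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (sj in seq_len(ncol(active))) for (si in seq_len(nrow(active))) {
    if (!active[si, sj] || lab[si, sj] > 0) next
    cur <- cur + 1L
    stack <- list(c(si, sj))
    lab[si, sj] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (n in seq_len(nrow(nbrs))) {
        qi <- p[1] + nbrs[n, 1]; qj <- p[2] + nbrs[n, 2]
        if (qi < 1 || qi > nrow(active) || qj < 1 || qj > ncol(active)) next
        if (active[qi, qj] && lab[qi, qj] == 0) {
          lab[qi, qj] <- cur
          stack[[length(stack) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# AUC as the Mann-Whitney pairwise concordance statistic.
oracle_auc <- function(probs, labels) {
  p1 <- probs[labels == 1]
  p0 <- probs[labels == 0]
  tot <- 0
  for (a in p1) for (b in p0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p1) * length(p0))
}

# Optimal threshold by exhaustive enumeration over all swept thresholds;
# the mean of sensitivity and specificity is compared in exact integer
# form (tp * N + tn * P) so ties resolve unambiguously.
oracle_optimal_threshold <- function(probs, labels) {
  thr <- c(-Inf, sort(unique(probs)), Inf)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  best_s <- -Inf
  best_t <- NA_real_
  for (t in thr) {
    pred <- probs > t
    s <- sum(pred & labels == 1) * N + sum(!pred & labels == 0) * P
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}
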