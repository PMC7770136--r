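# Independent brute-force oracles, kept deliberately naive.

# Exhaustive window-enumeration ROH oracle: every window, every candidate
# run, plain loops.
rohOracle <- function(het, mis, pos, params = rohScanParams()) {
  n <- length(het)
  w <- params$windowSnps
  hit <- numeric(n)
  if (n >= w) {
    pass <- logical(n - w + 1L)
    for (s in seq_len(n - w + 1L)) {
      idx <- s:(s + w - 1L)
      pass[s] <- sum(het[idx]) <= params$maxHetPerWindow &&
        sum(mis[idx]) <= params$maxMissingPerWindow
    }
    for (i in seq_len(n)) {
      covering <- which(seq_len(n - w + 1L) <= i &
                          seq_len(n - w + 1L) >= i - w + 1L)
      hit[i] <- mean(pass[covering])
    }
  }
  ok <- hit >= params$hitFractionThreshold
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1L]) j <- j + 1L
      len <- pos[j] - pos[i] + 1L
      nSnps <- j - i + 1L
      if (len >= params$minLengthBp &&
          nSnps >= params$minSnpsPerSegment &&
          len / nSnps <= params$minDensityBpPerSnp) {
        segs[[length(segs) + 1L]] <- data.frame(
          start = pos[i], end = pos[j], length = len, nSnps = nSnps,
          nHet = sum(het[i:j]),
          class = if (len > params$longThresholdBp) "long" else "short",
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  hitOut <- hit
  segsOut <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               nSnps = integer(0), nHet = integer(0), class = character(0),
               stringsAsFactors = FALSE)
  list(hit = hitOut, segments = segsOut)
}

# Exact two-sided rank-sum p by exhaustive enumeration of all
# choose(n1+n2, n1) group assignments.
ranksumOracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  combs <- combn(length(pooled), n1)
  stats <- apply(combs, 2, function(i) sum(rank(pooled)[i]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
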