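# Brute-force oracles, deliberately written as direct transcriptions of the
# definitions (nested loops / straight-line arithmetic) and kept independent
# of the package's execution strategies.

clampIdx <- function(v, n) min(max(v, 1L), n)

convOracle <- function(img, kern) {
  H <- nrow(img); W <- ncol(img); K <- nrow(kern); r <- K %/% 2L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (u in seq_len(K)) for (v in seq_len(K))
      acc <- acc + kern[u, v] *
        img[clampIdx(i + u - 1L - r, H), clampIdx(j + v - 1L - r, W)]
    out[i, j] <- acc
  }
  out
}

crwOracle <- function(t) {
  t <- abs(t)
  if (t <= 1) 1.5 * t^3 - 2.5 * t^2 + 1
  else if (t <= 2) -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2
  else 0
}

crZoomOracle <- function(frame, mag) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(0, H * mag, W * mag)
  for (i in 0:(H * mag - 1L)) for (j in 0:(W * mag - 1L)) {
    y <- i / mag; x <- j / mag
    by <- floor(y); bx <- floor(x)
    acc <- 0
    for (m in -1:2) for (n in -1:2) {
      w <- crwOracle(y - (by + m)) * crwOracle(x - (bx + n))
      py <- clampIdx(by + m + 1L, H)
      px <- clampIdx(bx + n + 1L, W)
      acc <- acc + w * frame[py, px]
    }
    out[i + 1L, j + 1L] <- acc
  }
  out
}

nlmOracle <- function(img, ps, pd, sigma, h) {
  if (ps %% 2L == 0L) ps <- ps + 1L
  pr <- ps %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    wsum <- 0; vsum <- 0
    for (dy in -pd:pd) for (dx in -pd:pd) {
      ss <- 0
      for (py in -pr:pr) for (px in -pr:pr) {
        aa <- img[clampIdx(i + py, H), clampIdx(j + px, W)]
        bb <- img[clampIdx(i + dy + py, H), clampIdx(j + dx + px, W)]
        ss <- ss + (aa - bb)^2
      }
      d2 <- ss / ps^2
      w <- exp(-max(d2 - 2 * sigma^2, 0) / h^2)
      wsum <- wsum + w
      vsum <- vsum + w * img[clampIdx(i + dy, H), clampIdx(j + dx, W)]
    }
    out[i, j] <- vsum / wsum
  }
  out
}

# Straight-line re-implementations of the agent's closed forms.
splitOracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  nf <- ceiling(n / 2)
  fast <- s[1:nf]; slow <- s[(nf + 1):n]
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  list(fastAverage = mean(fast), fastStdDev = psd(fast),
       slowAverage = mean(slow), slowStdDev = psd(slow))
}

detectOracle <- function(measured, fa, fsd) measured > fa + 4 * fsd
factorOracle <- function(measured, fa) measured / fa
adjustedOracle <- function(fa, factor, p) fa * (1 - p) + fa * factor * p
probsOracle <- function(times) {
  inv <- 1 / times^2
  inv / sum(inv)
}
overOracle <- function(measured, fa, fsd, sa, ssd)
  measured < (sa - ssd) || measured < (fa + fsd)

fuzzyScoreOracle <- function(q, cand) {
  total <- 0
  for (f in seq_along(q)) {
    total <- total + if (cand[f] == 0) {
      if (q[f] == 0) 1 else 0
    } else {
      max(0, 1 - abs(q[f] - cand[f]) / cand[f])
    }
  }
  total / length(q)
}

fuzzyMatchOracle <- function(q, sigs) {
  best <- 1L; bestScore <- -Inf
  for (k in seq_along(sigs)) {
    sc <- fuzzyScoreOracle(q, sigs[[k]])
    if (sc > bestScore) { bestScore <- sc; best <- k }
  }
  list(index = best, score = bestScore)
}

# Matrix-scale relative deviation used for cross-implementation equivalence.
relDiff <- function(a, b) {
  scale <- max(max(abs(a)), max(abs(b)), .Machine$double.eps)
  max(abs(a - b)) / scale
}

# Fresh throwaway store / session helpers.
tmpStore <- function() runStore(tempfile("lqtest"))
tmpSession <- function(registry = defaultRegistry())
  liquidSession(registry, tmpStore())
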