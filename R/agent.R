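#' Fast/slow split statistics
#'
#' Sorts the run times ascending and splits them into a fastest and a slowest
#' set of equal length (with an odd count the median value joins the fast
#' set), then computes mean and population standard deviation per set. The
#' fast set estimates the undelayed baseline without contamination from past
#' delays; the slow set gives a lower bound on what a delayed run looks like.
#'
#' @param runTimes numeric vector of at least 2 positive run times, seconds.
#' @return an [ImplementationStats-class].
#' @examples
#' splitStats(c(1, 2, 3, 4))  # fast mean 1.5, slow mean 3.5
#' @export
splitStats <- function(runTimes) {
  n <- length(runTimes)
  if (n < 2L)
    stop("need at least 2 run times to split, got ", n, call. = FALSE)
  if (any(!is.finite(runTimes)) || any(runTimes < 0))
    stop("run times must be finite and non-negative", call. = FALSE)
  s <- sort(runTimes)
  nf <- ceiling(n / 2)
  fast <- s[seq_len(nf)]
  slow <- s[(nf + 1L):n]
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  new("ImplementationStats",
      fastAverage = mean(fast), fastStdDev = popSd(fast),
      slowAverage = mean(slow), slowStdDev = popSd(slow), n = as.integer(n))
}

# Stats from an arbitrary-length sample (used for sparse default baselines):
# a single time yields degenerate stats with zero spread.
statsFromTimes <- function(times) {
  if (length(times) >= 2L) return(splitStats(times))
  new("ImplementationStats", fastAverage = times[1], fastStdDev = 0,
      slowAverage = times[1], slowStdDev = 0, n = 1L)
}

#' Delay detection
#'
#' A run is delayed when its measured time strictly exceeds the fast average
#' plus four times the fast standard deviation.
#'
#' @param measured measured run time, seconds.
#' @param stats an [ImplementationStats-class].
#' @return logical flag.
#' @export
detectDelay <- function(measured, stats) {
  measured > stats@fastAverage + 4 * stats@fastStdDev
}

#' Delay factor
#'
#' Ratio of the measured (delayed) run time to the fast average; used to
#' scale the expected cost of re-running a delayed implementation.
#'
#' @inheritParams detectDelay
#' @return dimensionless ratio.
#' @export
delayFactor <- function(measured, stats) {
  if (stats@fastAverage == 0)
    stop("degenerate statistics: fastAverage is zero", call. = FALSE)
  measured / stats@fastAverage
}

#' Delay recovery test
#'
#' The delay is considered over when the measured run time is either lower
#' than the slow average minus the slow standard deviation, or lower than
#' the fast average plus the fast standard deviation.
#'
#' @inheritParams detectDelay
#' @return logical flag.
#' @export
delayOver <- function(measured, stats) {
  measured < (stats@slowAverage - stats@slowStdDev) ||
    measured < (stats@fastAverage + stats@fastStdDev)
}

#' Adjusted expected run time under a possible delay
#'
#' Probability-weighted mixture of the undelayed baseline and the delayed
#' cost: `fastAverage * (1 - pDelay) + fastAverage * factor * pDelay`.
#'
#' @param stats an [ImplementationStats-class].
#' @param factor delay factor (measured / fast average).
#' @param pDelay probability that the delay recurs on the next run.
#' @return expected run time, seconds.
#' @export
adjustedRunTime <- function(stats, factor, pDelay) {
  stats@fastAverage * (1 - pDelay) + stats@fastAverage * factor * pDelay
}

#' Selection probabilities over implementations
#'
#' Inverse-square weighting of (adjusted) expected run times, normalized
#' over all candidates: `P(k) = (1 / t_k^2) / sum_j (1 / t_j^2)`. Slower
#' candidates keep strictly positive probability, so a delayed
#' implementation is still re-tried occasionally to learn whether its delay
#' has ended.
#'
#' @param adjustedTimes named numeric vector of expected run times, all > 0.
#' @return named numeric probability vector summing to 1.
#' @examples
#' selectionProbabilities(c(A = 1, B = 2))  # A 0.8, B 0.2
#' @export
selectionProbabilities <- function(adjustedTimes) {
  if (!length(adjustedTimes))
    stop("need at least one implementation", call. = FALSE)
  if (any(!is.finite(adjustedTimes)) || any(adjustedTimes <= 0))
    stop("all adjusted run times must be positive and finite", call. = FALSE)
  inv <- 1 / adjustedTimes^2
  inv / sum(inv)
}

#' Construct a delay state
#'
#' @param delayed logical flag.
#' @param delayFactor latest measured/baseline ratio.
#' @param pDelay probability of recurrence.
#' @param history data.frame(index, delayed) of recent observations.
#' @return a [DelayState-class].
#' @export
delayState <- function(delayed = FALSE, delayFactor = 0, pDelay = 0,
                       history = data.frame(index = integer(0),
                                            delayed = logical(0))) {
  new("DelayState", delayed = delayed, delayFactor = delayFactor,
      pDelay = pDelay, history = history)
}

#' Probability that a delay is present on the next run
#'
#' Fits a logistic model of the binary delayed flag against run index over
#' the most recent (up to 50) observations and evaluates it at the next
#' index. Degenerate histories — all delayed or none delayed, or a fit
#' failure — return the Laplace-smoothed empirical frequency
#' `(k + 1) / (n + 2)`. The result is clamped to \[0, 1\].
#'
#' @param state a [DelayState-class] with non-empty history.
#' @return probability in \[0, 1\].
#' @export
estimatePDelay <- function(state) {
  hist <- state@history
  if (!nrow(hist))
    stop("cannot estimate delay probability from empty history",
         call. = FALSE)
  hist <- utils::tail(hist[order(hist$index), , drop = FALSE], 50L)
  k <- sum(hist$delayed)
  n <- nrow(hist)
  laplace <- (k + 1) / (n + 2)
  if (k == 0L || k == n) return(laplace)
  fit <- tryCatch(
    suppressWarnings(stats::glm(delayed ~ index, data = hist,
                                family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit)) return(laplace)
  p <- tryCatch(
    as.numeric(stats::predict(fit,
      newdata = data.frame(index = max(hist$index) + 1L),
      type = "response")),
    error = function(e) laplace)
  if (!is.finite(p)) p <- laplace
  min(max(p, 0), 1)
}

#' Fuzzy similarity of one feature vector to another
#'
#' Per feature, a triangular membership centered on the candidate value `c`
#' with half-width `c` (membership 1 at equality, 0 at 100 % relative
#' difference); a zero candidate feature matches only a zero query feature.
#' The score is the mean membership across features — scale-free, so image
#' sides and unit-scale parameters contribute comparably.
#'
#' @param query,candidate numeric feature vectors of equal length.
#' @return score in \[0, 1\].
#' @export
fuzzyScore <- function(query, candidate) {
  if (length(query) != length(candidate))
    stop("signatures must have equal length", call. = FALSE)
  m <- ifelse(candidate == 0, as.numeric(query == 0),
              pmax(0, 1 - abs(query - candidate) / candidate))
  mean(m)
}

#' Match an input against benchmarked examples
#'
#' Scores every signature in the table with [fuzzyScore()] and returns the
#' most similar benchmarked example together with its recorded
#' per-implementation run times, which serve as baseline expected execution
#' times for the current call. Ties resolve to the earliest entry (file /
#' registration order), deterministically.
#'
#' @param signature numeric query feature vector.
#' @param table a [BenchmarkTable-class] with at least one entry.
#' @return list with `signature` (matched), `score`, `index`, and
#'   `baselines` (named list implId -> numeric run times).
#' @export
fuzzyMatch <- function(signature, table) {
  if (!length(table@entries))
    stop("benchmark table for '", table@methodId, "' is empty",
         call. = FALSE)
  scores <- vapply(table@entries,
                   function(e) fuzzyScore(signature, e$signature), numeric(1))
  i <- which.max(scores)
  e <- table@entries[[i]]
  list(signature = e$signature, score = scores[i], index = i,
       baselines = e$times)
}
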