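#' @import methods
#' @importFrom stats glm median predict binomial runif sd
#' @importFrom utils head tail
NULL

#' Registered implementation of a method
#'
#' One concrete variant of a method (for example the scalar reference loop,
#' the row-chunked parallel strategy, or the array-expression strategy). The
#' engine treats all implementations of a method as interchangeable: they must
#' produce numerically equivalent outputs for the same input, differing only
#' in execution strategy and therefore speed.
#'
#' @slot methodId character, the method this entry implements.
#' @slot implId character, the variant identifier, unique within the method.
#' @slot available logical, whether the variant can run on the current host.
#'   Unavailable entries stay listed but are never selected by the agent.
#' @slot runner function executing the variant; called with the method's
#'   named inputs, returns the output image/stack.
#' @export
setClass("ImplementationEntry",
  representation(methodId = "character", implId = "character",
                 available = "logical", runner = "function"))

setValidity("ImplementationEntry", function(object) {
  if (length(object@methodId) != 1L || !nzchar(object@methodId))
    return("methodId must be a single non-empty string")
  if (length(object@implId) != 1L || !nzchar(object@implId))
    return("implId must be a single non-empty string")
  if (length(object@available) != 1L || is.na(object@available))
    return("available must be TRUE or FALSE")
  TRUE
})

#' Registry of method implementations
#'
#' Mutable (environment-backed) registry mapping (methodId, implId) pairs to
#' [ImplementationEntry-class] objects, preserving registration order.
#'
#' @slot env environment holding the entry list.
#' @seealso [liquidRegistry()], [registerImplementation()],
#'   [listImplementations()]
#' @export
setClass("LiquidRegistry", representation(env = "environment"))

#' Persistent run-time record store
#'
#' Append-only store of timed executions, one JSON-lines file per
#' (method, implementation) under `root/<method>/<impl>.jsonl`. Records are
#' tagged with a device fingerprint so that history from other hardware can be
#' excluded without being deleted.
#'
#' @slot root character, the store directory.
#' @slot device character, fingerprint digest of the current host.
#' @slot cache environment, parsed-file cache keyed by path + mtime + size.
#' @seealso [runStore()], [recordRun()], [loadRecent()]
#' @export
setClass("RunStore",
  representation(root = "character", device = "character",
                 cache = "environment"))

#' Fast/slow split statistics for one implementation
#'
#' The recent run times of an implementation, sorted and split into a fastest
#' and a slowest half; mean and population standard deviation of each half.
#' The fast half estimates the undelayed baseline; the slow half bounds what a
#' worse-than-usual run looks like.
#'
#' @slot fastAverage mean of the fastest half, seconds.
#' @slot fastStdDev population standard deviation of the fastest half.
#' @slot slowAverage mean of the slowest half, seconds.
#' @slot slowStdDev population standard deviation of the slowest half.
#' @slot n integer, number of run times used.
#' @seealso [splitStats()]
#' @export
setClass("ImplementationStats",
  representation(fastAverage = "numeric", fastStdDev = "numeric",
                 slowAverage = "numeric", slowStdDev = "numeric",
                 n = "integer"))

setValidity("ImplementationStats", function(object) {
  v <- c(object@fastAverage, object@fastStdDev, object@slowAverage,
         object@slowStdDev)
  if (any(!is.finite(v)) || any(v < 0))
    return("all statistics must be finite and non-negative")
  if (object@fastAverage > object@slowAverage + 1e-12 * object@slowAverage)
    return("fastAverage must not exceed slowAverage")
  if (object@n < 1L) return("n must be >= 1")
  TRUE
})

#' Delay state of one (method, implementation) pair
#'
#' Tracks whether the implementation is currently considered delayed, the
#' latest delay factor (measured run time / fast average), the estimated
#' probability that the delay recurs on the next run, and the recent history
#' of per-run delay observations used to fit that probability.
#'
#' @slot delayed logical flag.
#' @slot delayFactor dimensionless ratio >= 0.
#' @slot pDelay probability in \[0, 1\].
#' @slot history data.frame with columns `index` (run counter) and `delayed`
#'   (logical observation), ordered by index.
#' @export
setClass("DelayState",
  representation(delayed = "logical", delayFactor = "numeric",
                 pDelay = "numeric", history = "data.frame"))

setValidity("DelayState", function(object) {
  if (object@pDelay < 0 || object@pDelay > 1)
    return("pDelay must lie in [0, 1]")
  if (object@delayFactor < 0) return("delayFactor must be >= 0")
  if (nrow(object@history) &&
      !all(c("index", "delayed") %in% names(object@history)))
    return("history needs columns index and delayed")
  TRUE
})

#' Table of benchmarked run times
#'
#' Maps input signatures to per-implementation sequences of recorded run
#' times, as produced by [runBenchmark()] and shipped as factory defaults.
#'
#' @slot methodId character, the benchmarked method.
#' @slot entries list; each element a list with `signature` (numeric feature
#'   vector) and `times` (named list, implId -> numeric run times in seconds,
#'   first repeat being the warm-up).
#' @seealso [loadDefaults()], [fuzzyMatch()]
#' @export
setClass("BenchmarkTable",
  representation(methodId = "character", entries = "list"))

setValidity("BenchmarkTable", function(object) {
  for (e in object@entries) {
    if (!is.numeric(e$signature) || any(!is.finite(e$signature)) ||
        any(e$signature < 0))
      return("every signature must be a finite non-negative numeric vector")
    if (!length(e$times)) return("every entry needs at least one time series")
    for (tt in e$times)
      if (!length(tt) || any(tt <= 0))
        return("every time series must be non-empty with positive times")
  }
  TRUE
})

#' Engine session: registry + store + delay state
#'
#' Binds an implementation registry to a run-time store and an in-memory
#' delay-state table, providing the context in which the supervisor agent
#' makes its per-call decisions.
#'
#' @slot registry a [LiquidRegistry-class].
#' @slot store a [RunStore-class].
#' @slot state environment mapping "method/impl" keys to
#'   [DelayState-class] objects.
#' @seealso [liquidSession()], [selectImplementation()], [liquidRun()]
#' @export
setClass("LiquidSession",
  representation(registry = "LiquidRegistry", store = "RunStore",
                 state = "environment"))

setMethod("show", "ImplementationEntry", function(object) {
  cat(sprintf("ImplementationEntry %s/%s (%s)\n", object@methodId,
              object@implId,
              if (object@available) "available" else "unavailable"))
})

setMethod("show", "LiquidRegistry", function(object) {
  ent <- registryEntries(object)
  cat(sprintf("LiquidRegistry with %d implementation(s)\n", length(ent)))
  for (e in ent)
    cat(sprintf("  %s/%s%s\n", e@methodId, e@implId,
                if (e@available) "" else " [unavailable]"))
})

setMethod("show", "RunStore", function(object) {
  cat(sprintf("RunStore at '%s'\n  device: %s\n", object@root, object@device))
})

setMethod("show", "ImplementationStats", function(object) {
  cat(sprintf(
    "ImplementationStats (n = %d)\n  fast: %.6g +/- %.6g s\n  slow: %.6g +/- %.6g s\n",
    object@n, object@fastAverage, object@fastStdDev, object@slowAverage,
    object@slowStdDev))
})

setMethod("show", "DelayState", function(object) {
  cat(sprintf(
    "DelayState: %s (factor %.3g, pDelay %.3g, %d observation(s))\n",
    if (object@delayed) "delayed" else "normal", object@delayFactor,
    object@pDelay, nrow(object@history)))
})

setMethod("show", "BenchmarkTable", function(object) {
  cat(sprintf("BenchmarkTable for '%s': %d signature(s)\n", object@methodId,
              length(object@entries)))
})

setMethod("show", "LiquidSession", function(object) {
  cat("LiquidSession\n")
  show(object@registry)
  show(object@store)
})

#' @describeIn ImplementationStats-class accessor for the fast-half mean.
#' @param x an `ImplementationStats` object.
#' @export
fastAverage <- function(x) x@fastAverage

#' @describeIn ImplementationStats-class accessor for the fast-half
#'   population standard deviation.
#' @export
fastStdDev <- function(x) x@fastStdDev

#' @describeIn ImplementationStats-class accessor for the slow-half mean.
#' @export
slowAverage <- function(x) x@slowAverage

#' @describeIn ImplementationStats-class accessor for the slow-half
#'   population standard deviation.
#' @export
slowStdDev <- function(x) x@slowStdDev
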