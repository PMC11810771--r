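#' Open an engine session
#'
#' @param registry a [LiquidRegistry-class]; defaults to the shipped one.
#' @param store a [RunStore-class]; defaults to the user's
#'   `~/.liquid_engine` store.
#' @return a [LiquidSession-class].
#' @export
liquidSession <- function(registry = defaultRegistry(),
                          store = runStore()) {
  new("LiquidSession", registry = registry, store = store,
      state = new.env(parent = emptyenv()))
}

#' Delay state of a (method, implementation) pair within a session
#'
#' @param session a [LiquidSession-class].
#' @param methodId,implId identifiers.
#' @return a [DelayState-class] (a fresh, non-delayed state if none is
#'   recorded yet).
#' @export
getDelayState <- function(session, methodId, implId) {
  st <- session@state[[registryKey(methodId, implId)]]
  if (is.null(st)) delayState() else st
}

#' @rdname getDelayState
#' @param state the new [DelayState-class].
#' @export
setDelayState <- function(session, methodId, implId, state) {
  validObject(state)
  session@state[[registryKey(methodId, implId)]] <- state
  invisible(state)
}

# Baseline statistics for one implementation: recent same-device history for
# the fuzzy-matched signature when at least three runs exist, otherwise the
# factory-default (or user-override) benchmark entry.
implBaseline <- function(session, methodId, implId, signature) {
  hist <- loadRecent(session@store, methodId, implId, signature)
  if (hist$sufficient)
    return(list(stats = splitStats(hist$times), source = "history",
                signature = hist$signature, n = hist$n))
  tbl <- tryCatch(loadDefaults(methodId, session@store),
                  error = function(e) NULL)
  if (!is.null(tbl)) {
    m <- fuzzyMatch(signature, tbl)
    times <- m$baselines[[implId]]
    if (!is.null(times) && length(times))
      return(list(stats = statsFromTimes(times), source = "defaults",
                  signature = m$signature, n = length(times)))
  }
  list(stats = NULL, source = "none", signature = NULL, n = 0L)
}

#' Select the implementation to execute
#'
#' The supervisor decision for one call. Unavailable implementations are
#' ignored. Each remaining implementation gets baseline statistics from its
#' recent recorded history (fuzzy-matched to the call's input signature) or,
#' with fewer than three usable records, from the factory-default benchmark
#' table. When no implementation is in a delayed state the fastest (smallest
#' fast average; ties by registration order) is chosen deterministically.
#' When any is delayed, delayed implementations are priced at their adjusted
#' run time (fast average mixed with the delayed cost by the recurrence
#' probability) and the choice is sampled from the inverse-square
#' probabilities, so the delayed variant is still re-tried occasionally.
#'
#' @param session a [LiquidSession-class].
#' @param methodId method identifier.
#' @param signature numeric input-signature vector (see [inputSignature()]).
#' @param seed integer seed for the stochastic draw (ignored in the
#'   deterministic regime); `NULL` derives one from the store's record
#'   count so replays from a trace are reproducible.
#' @return list with `implId` (the choice) and `trace`, a structured record
#'   of the statistics, delay states, probabilities and the sampled outcome.
#' @export
selectImplementation <- function(session, methodId, signature, seed = NULL) {
  entries <- listImplementations(session@registry, methodId,
                                 onlyAvailable = TRUE)
  if (!length(entries))
    stop("no available implementation for method '", methodId, "'",
         call. = FALSE)
  ids <- vapply(entries, function(e) e@implId, character(1))

  info <- lapply(ids, function(id)
    implBaseline(session, methodId, id, signature))
  names(info) <- ids
  states <- lapply(ids, function(id) getDelayState(session, methodId, id))
  names(states) <- ids

  known <- vapply(info, function(x) !is.null(x$stats), logical(1))
  fastAvg <- vapply(info, function(x)
    if (is.null(x$stats)) Inf else x$stats@fastAverage, numeric(1))
  delayed <- vapply(states, function(s) s@delayed, logical(1)) & known

  traceImpl <- lapply(ids, function(id) {
    s <- info[[id]]
    list(implId = id, source = s$source, n = s$n,
         fastAverage = if (known[[id]]) s$stats@fastAverage else NA_real_,
         delayed = unname(delayed[[id]]),
         delayFactor = states[[id]]@delayFactor,
         pDelay = states[[id]]@pDelay)
  })

  if (!any(delayed)) {
    pick <- if (any(known)) ids[which.min(fastAvg)] else ids[1L]
    trace <- list(method = methodId, signature = as.numeric(signature),
                  mode = "argmin", chosen = pick, impls = traceImpl,
                  probabilities = NULL, seed = NULL, ts = nowSec())
    return(list(implId = pick, trace = trace))
  }

  adj <- fastAvg
  for (id in ids[delayed]) {
    s <- states[[id]]
    adj[[id]] <- adjustedRunTime(info[[id]]$stats, s@delayFactor, s@pDelay)
  }
  usable <- is.finite(adj) & adj > 0
  if (!any(usable)) {
    pick <- ids[1L]
    probs <- NULL
  } else {
    probs <- selectionProbabilities(adj[usable])
    if (is.null(seed)) {
      nrec <- sum(vapply(ids, function(id)
        length(readStoreRecords(session@store, methodId, id)), numeric(1)))
      seed <- (nrec + 1) %% 2147483647
    }
    pick <- withSeed(seed,
      sample(names(probs), 1L, prob = unname(probs)))
  }
  for (k in seq_along(traceImpl)) {
    id <- traceImpl[[k]]$implId
    traceImpl[[k]]$adjusted <- unname(adj[[id]])
    traceImpl[[k]]$probability <-
      if (!is.null(probs) && id %in% names(probs)) unname(probs[[id]])
      else 0
  }
  trace <- list(method = methodId, signature = as.numeric(signature),
                mode = "stochastic", chosen = pick, impls = traceImpl,
                probabilities = as.list(probs), seed = seed, ts = nowSec())
  list(implId = pick, trace = trace)
}

# Post-run bookkeeping: observe whether the measured time is delayed,
# update the per-implementation delay state (flag, factor, recurrence
# probability, observation history) and append the run record.
updateAfterRun <- function(session, methodId, implId, signature, measured,
                           stats) {
  state <- getDelayState(session, methodId, implId)
  idx <- if (nrow(state@history)) max(state@history$index) + 1L else 1L
  if (!is.null(stats) && stats@n >= 2L) {
    if (state@delayed) {
      if (delayOver(measured, stats)) {
        state@delayed <- FALSE
        obs <- FALSE
      } else {
        obs <- TRUE
        state@delayFactor <- delayFactor(measured, stats)
      }
    } else if (detectDelay(measured, stats)) {
      state@delayed <- TRUE
      state@delayFactor <- delayFactor(measured, stats)
      obs <- TRUE
    } else {
      obs <- FALSE
    }
    state@history <- rbind(state@history,
                           data.frame(index = idx, delayed = obs))
    state@history <- utils::tail(state@history, 200L)
    state@pDelay <- estimatePDelay(state)
  }
  setDelayState(session, methodId, implId, state)
  recordRun(session@store, methodId, implId, signature, measured)
  invisible(state)
}

appendTrace <- function(session, trace) {
  path <- file.path(session@store@root, "decisions.jsonl")
  ok <- dir.exists(dirname(path)) ||
    suppressWarnings(dir.create(dirname(path), recursive = TRUE))
  if (!ok) return(invisible(FALSE))
  line <- jsonlite::toJSON(trace, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(as.character(line), con)
  invisible(TRUE)
}

#' Run a method through the engine
#'
#' Executes one call end to end: derives the input signature, lets the agent
#' pick an implementation (unless `implId` pins one), times the kernel call,
#' updates the delay state from the measured time, appends the run record to
#' the store, and logs the decision trace to
#' `<store root>/decisions.jsonl`.
#'
#' @param session a [LiquidSession-class].
#' @param methodId one of the registered methods.
#' @param inputs named list of the method's inputs, e.g.
#'   `list(image = , kernel = )` for `conv2d`.
#' @param implId pin a specific implementation (bypasses the agent);
#'   `NULL` (default) selects adaptively.
#' @param seed seed for the stochastic selection regime.
#' @param record if `FALSE`, skip store/state updates (pure timed call).
#' @return list with `output`, `implId`, `runTime` (seconds) and `trace`.
#' @export
liquidRun <- function(session, methodId, inputs, implId = NULL, seed = NULL,
                      record = TRUE) {
  signature <- inputSignature(methodId, inputs)
  trace <- NULL
  if (is.null(implId)) {
    sel <- selectImplementation(session, methodId, signature, seed = seed)
    implId <- sel$implId
    trace <- sel$trace
  }
  entry <- getImplementation(session@registry, methodId, implId,
                             requireAvailable = TRUE)
  t0 <- nowSec()
  output <- do.call(entry@runner, inputs)
  elapsed <- max(nowSec() - t0, 1e-9)
  if (record) {
    hist <- loadRecent(session@store, methodId, implId, signature)
    stats <- if (hist$sufficient) splitStats(hist$times) else {
      bl <- implBaseline(session, methodId, implId, signature)
      bl$stats
    }
    updateAfterRun(session, methodId, implId, signature, elapsed, stats)
    if (!is.null(trace)) {
      trace$measured <- elapsed
      appendTrace(session, trace)
    }
  }
  list(output = output, implId = implId, runTime = elapsed, trace = trace)
}

defaultRegistryEnv <- new.env(parent = emptyenv())

#' The shipped registry
#'
#' Lazily-created package-level registry holding the three shipped methods
#' with their `unthreaded`, `threaded` and `vectorized` implementations.
#' @return a [LiquidRegistry-class].
#' @export
defaultRegistry <- function() {
  if (is.null(defaultRegistryEnv$registry))
    defaultRegistryEnv$registry <- liquidRegistry(populate = TRUE)
  defaultRegistryEnv$registry
}
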