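#' Inject an artificial delay into one implementation
#'
#' Returns a copy of the registry in which the target implementation's
#' wall-clock cost is inflated by `slowdown` while `activePredicate()`
#' returns `TRUE` (the true computation runs first, then the wrapper sleeps
#' for `(slowdown - 1)` times the measured duration). Outputs are unchanged.
#' This emulates, in-process, an externally contended backend — the
#' observable is the same: one implementation's measured run time spikes
#' while the others stay normal.
#'
#' @param registry a [LiquidRegistry-class].
#' @param methodId,targetImpl the implementation to delay.
#' @param slowdown multiplicative factor > 1.
#' @param activePredicate zero-argument function; the delay applies while it
#'   returns `TRUE`.
#' @return a new [LiquidRegistry-class] with the wrapped runner.
#' @export
injectDelay <- function(registry, methodId, targetImpl, slowdown,
                        activePredicate = function() TRUE) {
  if (slowdown <= 1)
    stop("slowdown must be > 1", call. = FALSE)
  orig <- getImplementation(registry, methodId, targetImpl)
  out <- cloneRegistry(registry)
  wrapped <- orig
  origRunner <- orig@runner
  wrapped@runner <- function(...) {
    t0 <- nowSec()
    res <- origRunner(...)
    el <- nowSec() - t0
    if (isTRUE(activePredicate())) Sys.sleep(el * (slowdown - 1))
    res
  }
  out@env$entries[[registryKey(methodId, targetImpl)]] <- wrapped
  out
}

#' Configure a delay-management experiment
#'
#' Desk-scale defaults mirror the published protocol at reduced size: 60
#' sequential 2D convolutions of a 9x9 all-ones kernel on a 256x256 random
#' image, with an 8-fold delay injected on the preferred implementation
#' during runs 15-30 (1-based, inclusive).
#'
#' @param methodId method to run.
#' @param nRuns total sequential runs.
#' @param delayWindow integer pair (first, last) run index of the injected
#'   delay, 1-based inclusive; must lie within `[1, nRuns]`.
#' @param slowdown multiplicative delay factor > 1.
#' @param targetImpl implementation to delay; `NULL` targets whichever the
#'   warm-up benchmark finds fastest (the "preferred" one).
#' @param seed integer master seed; all randomness in the experiment derives
#'   from it.
#' @param signature input signature of the repeated call.
#' @param warmupRepeats timed warm-up runs recorded per implementation
#'   before the sequence starts (gives the agent usable history).
#' @return a `DelayExperimentConfig` list.
#' @export
delayExperimentConfig <- function(methodId = "conv2d", nRuns = 60L,
                                  delayWindow = c(15L, 30L), slowdown = 8,
                                  targetImpl = NULL, seed = 1L,
                                  signature = NULL, warmupRepeats = 5L) {
  if (slowdown <= 1) stop("slowdown must be > 1", call. = FALSE)
  if (length(delayWindow) != 2L || delayWindow[1] > delayWindow[2] ||
      delayWindow[1] < 1L || delayWindow[2] > nRuns)
    stop("delayWindow must lie within [1, nRuns]", call. = FALSE)
  if (is.null(signature))
    signature <- switch(methodId,
      conv2d = c(1, 256, 256, 9),
      catmull_rom_zoom = c(1, 64, 64, 5),
      nlm_denoise = c(1, 64, 64, 5, 3, 0, 0.1),
      stop("supply a signature for method '", methodId, "'", call. = FALSE))
  structure(list(methodId = methodId, nRuns = as.integer(nRuns),
                 delayWindow = as.integer(delayWindow), slowdown = slowdown,
                 targetImpl = targetImpl, seed = as.integer(seed),
                 signature = as.numeric(signature),
                 warmupRepeats = as.integer(warmupRepeats)),
            class = "DelayExperimentConfig")
}

#' Run the delay-management experiment
#'
#' Executes `nRuns` sequential calls of one method against a fresh
#' throwaway store. First, every available implementation is warm-up
#' benchmarked (`warmupRepeats` recorded runs each) and the fastest by
#' median becomes the preferred implementation, which is also the delay
#' target unless the config names one. Then the sequence runs with the
#' injected slowdown active inside the delay window. With
#' `adaptive = TRUE` each call goes through the agent, which detects the
#' delay from the run-time spike, switches preference probabilistically
#' away from the delayed implementation, and reverts once a re-try shows
#' the delay is over. With `adaptive = FALSE` every call is pinned to the
#' preferred implementation (the non-adaptive control).
#'
#' @param config a `DelayExperimentConfig`.
#' @param adaptive logical; agent-driven selection vs pinned control.
#' @param registry a [LiquidRegistry-class].
#' @param storeRoot directory for the experiment's store; a fresh temporary
#'   directory by default so experiments are independent and reproducible
#'   from (config, seed).
#' @return list with `trace` (data.frame: run, implId, runTime, inWindow,
#'   delayedTarget selection flag) and `summary` (means overall / inside /
#'   outside the window, per-implementation selection shares inside and
#'   outside, preferred and target implementation ids).
#' @export
runDelayExperiment <- function(config, adaptive = TRUE,
                               registry = defaultRegistry(),
                               storeRoot = tempfile("lqdelay")) {
  store <- runStore(storeRoot)
  inputs <- inputFromSignature(config$methodId, config$signature,
                               seed = config$seed)
  avail <- listImplementations(registry, config$methodId,
                               onlyAvailable = TRUE)

  # Warm-up: record baseline history for every implementation.
  med <- numeric(0)
  for (e in avail) {
    tt <- numeric(config$warmupRepeats)
    for (r in seq_len(config$warmupRepeats)) {
      t0 <- nowSec()
      do.call(e@runner, inputs)
      tt[r] <- max(nowSec() - t0, 1e-9)
      recordRun(store, config$methodId, e@implId, config$signature, tt[r])
    }
    med[e@implId] <- stats::median(tt)
  }
  preferred <- names(med)[which.min(med)]
  target <- if (is.null(config$targetImpl)) preferred else config$targetImpl

  runEnv <- new.env(parent = emptyenv())
  runEnv$run <- 0L
  delayedReg <- injectDelay(registry, config$methodId, target,
                            config$slowdown,
                            activePredicate = function()
                              runEnv$run >= config$delayWindow[1] &&
                              runEnv$run <= config$delayWindow[2])
  session <- liquidSession(delayedReg, store)

  trace <- data.frame(run = integer(0), implId = character(0),
                      runTime = numeric(0), inWindow = logical(0))
  for (r in seq_len(config$nRuns)) {
    runEnv$run <- r
    res <- liquidRun(session, config$methodId, inputs,
                     implId = if (adaptive) NULL else preferred,
                     seed = (config$seed * 1009 + r) %% 2147483647)
    trace <- rbind(trace, data.frame(
      run = r, implId = res$implId, runTime = res$runTime,
      inWindow = r >= config$delayWindow[1] & r <= config$delayWindow[2]))
  }

  inside <- trace$inWindow
  share <- function(sel) {
    if (!length(sel)) return(stats::setNames(numeric(0), character(0)))
    tab <- table(factor(sel, levels = vapply(avail, function(e) e@implId,
                                             character(1))))
    stats::setNames(as.numeric(tab) / length(sel), names(tab))
  }
  summary <- list(
    preferred = preferred, target = target, adaptive = adaptive,
    meanOverall = mean(trace$runTime),
    meanWindow = mean(trace$runTime[inside]),
    meanOutside = mean(trace$runTime[!inside]),
    shareWindow = share(trace$implId[inside]),
    shareOutside = share(trace$implId[!inside]))
  list(trace = trace, summary = summary, config = config)
}
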