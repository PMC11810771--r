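#' Create an implementation registry
#'
#' @param populate if `TRUE` (default) the registry is pre-loaded with the
#'   three shipped methods (`conv2d`, `catmull_rom_zoom`, `nlm_denoise`), each
#'   with its `unthreaded`, `threaded` and `vectorized` implementation.
#' @return a [LiquidRegistry-class].
#' @examples
#' reg <- liquidRegistry()
#' listImplementations(reg, "conv2d")
#' @export
liquidRegistry <- function(populate = TRUE) {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  reg <- new("LiquidRegistry", env = env)
  if (populate) registerShippedImplementations(reg)
  reg
}

registryKey <- function(methodId, implId) paste(methodId, implId, sep = "/")

registryEntries <- function(registry) registry@env$entries

#' Register an implementation
#'
#' Adds an [ImplementationEntry-class] to the registry. Registration order is
#' preserved and is the deterministic tie-break order used by the agent.
#' Entries registered as unavailable stay listed (so they can be inspected and
#' re-enabled) but are ignored by the agent, which guarantees that a user can
#' always process images with whatever variants their host supports.
#'
#' @param registry a [LiquidRegistry-class].
#' @param entry an [ImplementationEntry-class]; alternatively supply
#'   `methodId`, `implId`, `runner`, `available` to build one in place.
#' @param methodId,implId,runner,available fields used when `entry` is
#'   missing.
#' @return (invisibly) the number of entries now registered.
#' @export
registerImplementation <- function(registry, entry = NULL, methodId = NULL,
                                   implId = NULL, runner = NULL,
                                   available = TRUE) {
  if (is.null(entry))
    entry <- new("ImplementationEntry", methodId = methodId, implId = implId,
                 available = available, runner = runner)
  validObject(entry)
  key <- registryKey(entry@methodId, entry@implId)
  if (!is.null(registry@env$entries[[key]]))
    stop("implementation '", key, "' is already registered", call. = FALSE)
  registry@env$entries[[key]] <- entry
  invisible(length(registry@env$entries))
}

#' List implementations of a method
#'
#' @param registry a [LiquidRegistry-class].
#' @param methodId method identifier; must have at least one registered entry.
#' @param onlyAvailable if `TRUE`, drop entries whose `available` flag is
#'   `FALSE`.
#' @return list of [ImplementationEntry-class] in registration order.
#' @export
listImplementations <- function(registry, methodId, onlyAvailable = FALSE) {
  ent <- Filter(function(e) e@methodId == methodId, registryEntries(registry))
  if (!length(ent))
    stop("unknown method '", methodId, "'", call. = FALSE)
  if (onlyAvailable) ent <- Filter(function(e) e@available, ent)
  unname(ent)
}

#' Look up one implementation
#'
#' @inheritParams listImplementations
#' @param implId implementation identifier.
#' @param requireAvailable error if the entry is marked unavailable.
#' @return the [ImplementationEntry-class].
#' @export
getImplementation <- function(registry, methodId, implId,
                              requireAvailable = FALSE) {
  e <- registryEntries(registry)[[registryKey(methodId, implId)]]
  if (is.null(e))
    stop("unknown implementation '", registryKey(methodId, implId), "'",
         call. = FALSE)
  if (requireAvailable && !e@available)
    stop("implementation '", registryKey(methodId, implId),
         "' is not available on this host", call. = FALSE)
  e
}

#' Mark an implementation available or unavailable
#'
#' @inheritParams getImplementation
#' @param available new availability flag.
#' @return invisibly, the updated entry.
#' @export
setImplementationAvailable <- function(registry, methodId, implId, available) {
  e <- getImplementation(registry, methodId, implId)
  e@available <- available
  registry@env$entries[[registryKey(methodId, implId)]] <- e
  invisible(e)
}

# Deep-copy a registry (used by the delay-injection harness so that wrapped
# runners do not leak into the caller's registry).
cloneRegistry <- function(registry) {
  env <- new.env(parent = emptyenv())
  env$entries <- registry@env$entries
  new("LiquidRegistry", env = env)
}

registerShippedImplementations <- function(registry) {
  for (impl in c("unthreaded", "threaded", "vectorized")) {
    local({
      s <- impl
      registerImplementation(registry, methodId = "conv2d", implId = s,
        runner = function(image, kernel) convRun(image, kernel, s))
      registerImplementation(registry, methodId = "catmull_rom_zoom",
        implId = s,
        runner = function(stack, magnification)
          zoomRun(stack, magnification, s))
      registerImplementation(registry, methodId = "nlm_denoise", implId = s,
        runner = function(image, params) nlmRun(image, params, s))
    })
  }
  invisible(registry)
}

shippedMethods <- function() c("conv2d", "catmull_rom_zoom", "nlm_denoise")
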