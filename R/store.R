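#' Device fingerprint
#'
#' Stable digest of host descriptors (OS family, machine architecture,
#' processor/node identifiers, logical core count, total memory). Identical
#' hosts yield identical digests across sessions, so recorded run times can
#' be attributed to the hardware that produced them and history from a
#' different machine can be set aside rather than trusted.
#'
#' @return single character digest (16 hex digits).
#' @export
deviceFingerprint <- function() {
  si <- Sys.info()
  mem <- totalMemoryKb()
  desc <- paste(si[["sysname"]], si[["machine"]],
                parallel::detectCores(logical = TRUE), mem, sep = "|")
  fnv1a64(desc)
}

totalMemoryKb <- function() {
  if (file.exists("/proc/meminfo")) {
    ln <- grep("^MemTotal:", readLines("/proc/meminfo", n = 5L), value = TRUE)
    if (length(ln)) return(as.numeric(gsub("[^0-9]", "", ln[1])))
  }
  0
}

#' Default store location
#'
#' The engine keeps its historical record in the user's home folder inside a
#' directory called `.liquid_engine`; override per call via the `root`
#' argument of [runStore()] or the `LIQUID_ENGINE_STORE` environment
#' variable.
#' @return path character.
#' @export
defaultStoreRoot <- function() {
  env <- Sys.getenv("LIQUID_ENGINE_STORE", "")
  if (nzchar(env)) env else path.expand(file.path("~", ".liquid_engine"))
}

#' Open a run-time record store
#'
#' @param root store directory (created lazily on first write); defaults to
#'   [defaultStoreRoot()].
#' @param device fingerprint digest of the current host; defaults to
#'   [deviceFingerprint()].
#' @return a [RunStore-class].
#' @export
runStore <- function(root = defaultStoreRoot(), device = deviceFingerprint()) {
  new("RunStore", root = root, device = device,
      cache = new.env(parent = emptyenv()))
}

storeFile <- function(store, methodId, implId)
  file.path(store@root, methodId, paste0(implId, ".jsonl"))

#' Append a timed execution to the store
#'
#' Records are appended durably, one JSON object per line, to
#' `root/<method>/<impl>.jsonl`. Recency is defined by file order (insertion
#' order), which survives wall-clock adjustments.
#'
#' @param store a [RunStore-class].
#' @param methodId,implId identifiers of the executed variant.
#' @param signature numeric feature vector describing the input (see
#'   [inputSignature()]).
#' @param runTime elapsed wall-clock seconds, > 0.
#' @param timestamp numeric epoch seconds; defaults to now.
#' @param deviceId fingerprint to tag the record with; defaults to the
#'   store's device.
#' @return (invisibly) the number of records now stored for this
#'   (method, impl, signature) key on this device.
#' @export
recordRun <- function(store, methodId, implId, signature, runTime,
                      timestamp = nowSec(), deviceId = store@device) {
  if (!is.numeric(runTime) || length(runTime) != 1L || !is.finite(runTime) ||
      runTime <= 0)
    stop("runTime must be a single positive number", call. = FALSE)
  if (!is.numeric(signature) || any(!is.finite(signature)) ||
      any(signature < 0))
    stop("signature must be a finite non-negative numeric vector",
         call. = FALSE)
  path <- storeFile(store, methodId, implId)
  ok <- dir.exists(dirname(path)) ||
    suppressWarnings(dir.create(dirname(path), recursive = TRUE))
  if (!ok)
    stop("cannot create run record directory '", dirname(path), "'",
         call. = FALSE)
  line <- jsonlite::toJSON(
    list(method = methodId, impl = implId, sig = as.numeric(signature),
         t = runTime, ts = timestamp, dev = deviceId),
    auto_unbox = TRUE, digits = I(17))
  con <- tryCatch(file(path, open = "a"),
                  error = function(e)
                    stop("cannot write run record to '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  writeLines(as.character(line), con)
  close(con)                       # flush before re-reading for the count
  recs <- readStoreRecords(store, methodId, implId)
  n <- sum(vapply(recs, function(r)
    r$dev == deviceId && identical(as.numeric(r$sig), as.numeric(signature)),
    logical(1)))
  invisible(n)
}

# Parse one store file, with a cache keyed on (mtime, size) so repeated
# decisions against an unchanged store avoid re-parsing JSON.
readStoreRecords <- function(store, methodId, implId) {
  path <- storeFile(store, methodId, implId)
  if (!file.exists(path)) return(list())
  info <- file.info(path)
  key <- paste0(methodId, "/", implId)
  hit <- store@cache[[key]]
  if (!is.null(hit) && identical(hit$mtime, info$mtime) &&
      identical(hit$size, info$size))
    return(hit$records)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(txt)]
  recs <- if (length(txt))
    jsonlite::fromJSON(paste0("[", paste(txt, collapse = ","), "]"),
                       simplifyVector = FALSE)
  else list()
  store@cache[[key]] <- list(mtime = info$mtime, size = info$size,
                             records = recs)
  recs
}

#' Load the most recent run times for an input
#'
#' Retrieves up to `window` recorded run times for `(methodId, implId)` on
#' the current device, restricted to the stored signature most similar to
#' `signature` (graded triangular-membership similarity, see
#' [fuzzyMatch()]). Records written by other devices are excluded, never
#' deleted. Fewer than three usable records is reported as insufficient
#' history so the caller can fall back to factory-default benchmarks; three
#' or more proceed with what is available.
#'
#' @inheritParams recordRun
#' @param window maximum number of run times to return (most recent first).
#' @return list with elements `times` (numeric, newest first), `signature`
#'   (the matched stored signature or `NULL`), `n`, and `sufficient`
#'   (`TRUE` iff `n >= 3`).
#' @export
loadRecent <- function(store, methodId, implId, signature, window = 50L) {
  recs <- readStoreRecords(store, methodId, implId)
  recs <- Filter(function(r) identical(r$dev, store@device), recs)
  if (!length(recs))
    return(list(times = numeric(0), signature = NULL, n = 0L,
                sufficient = FALSE))
  sigs <- lapply(recs, function(r) as.numeric(r$sig))
  uniq <- unique(sigs)
  scores <- vapply(uniq, function(s) fuzzyScore(signature, s), numeric(1))
  best <- uniq[[which.max(scores)]]
  keep <- vapply(sigs, function(s) identical(s, best), logical(1))
  times <- vapply(recs[keep], function(r) as.numeric(r$t), numeric(1))
  times <- rev(times)                      # newest first (file order = age)
  if (length(times) > window) times <- times[seq_len(window)]
  list(times = times, signature = best, n = length(times),
       sufficient = length(times) >= 3L)
}

#' Detect a hardware change
#'
#' @param store a [RunStore-class] whose `device` slot is the current host's
#'   fingerprint.
#' @return `TRUE` iff the store contains records written under a different
#'   device fingerprint. Callers must then treat the mismatched history as
#'   unusable and fall back to defaults; the records themselves are kept in
#'   case the user switches back.
#' @export
detectHardwareChange <- function(store) {
  if (!dir.exists(store@root)) return(FALSE)
  files <- list.files(store@root, pattern = "\\.jsonl$", recursive = TRUE,
                      full.names = TRUE)
  for (f in files) {
    rel <- strsplit(sub(paste0("^", store@root, "/?"), "", f), "/")[[1]]
    if (length(rel) != 2L) next
    recs <- readStoreRecords(store, rel[1], sub("\\.jsonl$", "", rel[2]))
    if (any(vapply(recs, function(r) !identical(r$dev, store@device),
                   logical(1))))
      return(TRUE)
  }
  FALSE
}

#' Load factory-default benchmarks for a method
#'
#' Returns the packaged benchmark table for `methodId`, used whenever fewer
#' than three local run times exist (or the store was written by different
#' hardware). A user-supplied table at `<store root>/defaults/<method>.json`
#' overrides the packaged one.
#'
#' @param methodId method identifier.
#' @param store optional [RunStore-class]; its root is searched for a user
#'   override.
#' @return a [BenchmarkTable-class].
#' @export
loadDefaults <- function(methodId, store = NULL) {
  if (!is.null(store)) {
    user <- file.path(store@root, "defaults", paste0(methodId, ".json"))
    if (file.exists(user)) return(readBenchmarkTable(user))
  }
  pkg <- system.file("extdata", "defaults", paste0(methodId, ".json"),
                     package = "LiquidEngine")
  if (!nzchar(pkg) || !file.exists(pkg))
    stop("no factory-default benchmarks for method '", methodId, "'",
         call. = FALSE)
  readBenchmarkTable(pkg)
}

#' Read / write a benchmark table
#'
#' Benchmark tables are stored as plain JSON:
#' `{"method": ..., "entries": [{"signature": [...], "times": {impl: [...]}}]}`.
#'
#' @param path file path.
#' @return [readBenchmarkTable()] returns a [BenchmarkTable-class].
#' @export
readBenchmarkTable <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(obj$entries, function(e)
    list(signature = as.numeric(unlist(e$signature)),
         times = lapply(e$times, function(tt) as.numeric(unlist(tt)))))
  new("BenchmarkTable", methodId = obj$method, entries = entries)
}

#' @rdname readBenchmarkTable
#' @param table a [BenchmarkTable-class].
#' @export
writeBenchmarkTable <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  obj <- list(method = table@methodId,
              entries = lapply(table@entries, function(e)
                list(signature = as.numeric(e$signature), times = e$times)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Input signature of a method call
#'
#' Fixed-order numeric feature vector describing a call's input properties;
#' used to key stored run times and to fuzzy-match against benchmarked
#' examples. Orders: `conv2d` = (frames=1, H, W, kernel side);
#' `catmull_rom_zoom` = (T, H, W, magnification); `nlm_denoise` =
#' (frames=1, H, W, patchSize, patchDistance, sigma, h).
#'
#' @param methodId method identifier.
#' @param inputs named list of the method's inputs (as passed to its runner).
#' @return numeric feature vector.
#' @export
inputSignature <- function(methodId, inputs) {
  switch(methodId,
    conv2d = c(1, nrow(inputs$image), ncol(inputs$image),
               nrow(inputs$kernel)),
    catmull_rom_zoom = {
      a <- asStack(inputs$stack)
      c(dim(a), inputs$magnification)
    },
    nlm_denoise = {
      p <- inputs$params
      if (!inherits(p, "NLMParams"))
        p <- nlmParams(p$patchSize, p$patchDistance, p$sigma, p$h)
      c(1, nrow(inputs$image), ncol(inputs$image), p$patchSize,
        p$patchDistance, p$sigma, p$h)
    },
    stop("no signature definition for method '", methodId, "'",
         call. = FALSE))
}
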