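#' Define a benchmark grid
#'
#' @param methodId method to benchmark.
#' @param signatures list of numeric input signatures (see
#'   [inputSignature()] for the per-method feature order).
#' @param repeats timed repetitions per (signature, implementation) cell;
#'   the first repeat is a warm-up — recorded, but excluded from the median
#'   used to rank implementations.
#' @return a `BenchmarkGrid` list.
#' @export
benchmarkGrid <- function(methodId, signatures, repeats = 3L) {
  if (!length(signatures)) stop("signatures must be non-empty", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  structure(list(methodId = methodId, signatures = signatures,
                 repeats = as.integer(repeats)), class = "BenchmarkGrid")
}

#' Default benchmark grids
#'
#' Scaled-down versions of the published input grids, sized so that factory
#' benchmarking of all three methods finishes in minutes on one CPU:
#' `conv2d` crosses image sides \{100, 500, 1000\} with all-ones kernels of
#' side \{1, 5, 9, 13, 17, 21\}; `catmull_rom_zoom` upsamples stacks of
#' shape 1x10x10, 10x10x10, 10x100x100 and 10x300x300 fivefold;
#' `nlm_denoise` uses sides \{100, 200\} with patch distances \{5, 10\} and
#' patch sizes \{5, 7, 11\}. Arbitrary grids (including full-size ones) can
#' be supplied via [benchmarkGrid()] or a JSON grid file.
#'
#' @param methodId method identifier.
#' @return a `BenchmarkGrid`.
#' @export
defaultGrid <- function(methodId) {
  sigs <- switch(methodId,
    conv2d = {
      g <- expand.grid(side = c(100, 500, 1000), k = c(1, 5, 9, 13, 17, 21))
      lapply(seq_len(nrow(g)), function(i) c(1, g$side[i], g$side[i], g$k[i]))
    },
    catmull_rom_zoom = list(c(1, 10, 10, 5), c(10, 10, 10, 5),
                            c(10, 100, 100, 5), c(10, 300, 300, 5)),
    nlm_denoise = {
      g <- expand.grid(side = c(100, 200), d = c(5, 10), ps = c(5, 7, 11))
      lapply(seq_len(nrow(g)), function(i)
        c(1, g$side[i], g$side[i], g$ps[i], g$d[i], 0, 0.1))
    },
    stop("no default grid for method '", methodId, "'", call. = FALSE))
  benchmarkGrid(methodId, sigs)
}

#' Reconstruct a method input from its signature
#'
#' Generates the synthetic input whose [inputSignature()] equals
#' `signature`: uniform-noise images/stacks plus the method's parameters
#' (all-ones kernel for `conv2d`, matching the published benchmark kernels).
#'
#' @param methodId method identifier.
#' @param signature numeric signature vector.
#' @param seed RNG seed for the noise image.
#' @return named input list suitable for [liquidRun()].
#' @export
inputFromSignature <- function(methodId, signature, seed = 1L) {
  switch(methodId,
    conv2d = list(
      image = generateImage(signature[2], signature[3], seed = seed),
      kernel = matrix(1, signature[4], signature[4])),
    catmull_rom_zoom = list(
      stack = generateImage(signature[2], signature[3],
                            frames = signature[1], seed = seed),
      magnification = signature[4]),
    nlm_denoise = list(
      image = generateImage(signature[2], signature[3], seed = seed),
      params = nlmParams(signature[4], signature[5], signature[6],
                         signature[7])),
    stop("cannot build inputs for method '", methodId, "'", call. = FALSE))
}

#' Run a manual benchmark
#'
#' Times every available implementation of the grid's method on every
#' signature: per cell, `repeats` executions are wall-clock timed (the
#' kernel call only — input generation and store writes are excluded) and
#' each is appended to the store as a run record. Implementations marked
#' unavailable are skipped with a notice. Per cell the fastest
#' implementation by median time (excluding the warm-up repeat) is
#' reported.
#'
#' @param grid a `BenchmarkGrid` from [benchmarkGrid()] / [defaultGrid()].
#' @param registry a [LiquidRegistry-class].
#' @param store a [RunStore-class] receiving the run records.
#' @param seed seed for the synthetic inputs.
#' @param quiet suppress skip notices.
#' @return list with `table` (a [BenchmarkTable-class]) and `report`
#'   (data.frame: signature, implId, median, fastest).
#' @export
runBenchmark <- function(grid, registry = defaultRegistry(),
                         store = runStore(), seed = 1L, quiet = FALSE) {
  entries <- listImplementations(registry, grid$methodId)
  avail <- Filter(function(e) e@available, entries)
  if (!length(avail))
    stop("method '", grid$methodId, "' has no available implementation",
         call. = FALSE)
  if (!quiet)
    for (e in entries)
      if (!e@available)
        message("skipping unavailable implementation ",
                registryKey(e@methodId, e@implId))

  tblEntries <- list()
  report <- NULL
  for (si in seq_along(grid$signatures)) {
    sig <- as.numeric(grid$signatures[[si]])
    inputs <- inputFromSignature(grid$methodId, sig, seed = seed + si)
    times <- list()
    for (e in avail) {
      tt <- numeric(grid$repeats)
      for (r in seq_len(grid$repeats)) {
        t0 <- nowSec()
        do.call(e@runner, inputs)
        tt[r] <- max(nowSec() - t0, 1e-9)
        recordRun(store, grid$methodId, e@implId, sig, tt[r])
      }
      times[[e@implId]] <- tt
    }
    med <- vapply(times, function(tt)
      stats::median(if (length(tt) > 1L) tt[-1] else tt), numeric(1))
    report <- rbind(report, data.frame(
      signature = paste(sig, collapse = "x"),
      implId = names(med), median = unname(med),
      fastest = seq_along(med) == which.min(med), row.names = NULL))
    tblEntries[[si]] <- list(signature = sig, times = times)
  }
  table <- new("BenchmarkTable", methodId = grid$methodId,
               entries = tblEntries)
  list(table = table, report = report)
}

#' Build and write the factory-default benchmark tables
#'
#' Runs the default grid of every shipped method on the current machine and
#' writes one JSON benchmark table per method to `outDir`. Packaged under
#' `inst/extdata/defaults/` these become the baselines used whenever a user
#' has fewer than three recorded runs (or switched hardware).
#'
#' @param registry a [LiquidRegistry-class].
#' @param outDir output directory for `<method>.json` files.
#' @param store store receiving the benchmark run records (a throwaway
#'   temporary store by default).
#' @param seed seed for synthetic inputs.
#' @return (invisibly) named character vector of written file paths.
#' @export
buildFactoryDefaults <- function(registry = defaultRegistry(),
                                 outDir = "defaults",
                                 store = runStore(tempfile("lqstore")),
                                 seed = 1L) {
  paths <- character(0)
  for (m in shippedMethods()) {
    res <- runBenchmark(defaultGrid(m), registry, store, seed = seed)
    p <- file.path(outDir, paste0(m, ".json"))
    writeBenchmarkTable(res$table, p)
    paths[m] <- p
  }
  invisible(paths)
}

#' Read a benchmark grid from a JSON config file
#'
#' Format: `{"method": "conv2d", "repeats": 3, "signatures": [[...], ...]}`.
#' @param path JSON file path.
#' @return a `BenchmarkGrid`.
#' @export
readBenchmarkGrid <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  benchmarkGrid(obj$method,
                lapply(obj$signatures, function(s) as.numeric(unlist(s))),
                repeats = if (is.null(obj$repeats)) 3L
                          else as.integer(obj$repeats))
}
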