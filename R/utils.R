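# Shared internal helpers.

nowSec <- function() as.numeric(Sys.time())

# Run `expr` under a temporarily-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Replicate-pad a matrix by `r` rows/cols on every side; equivalent to
# clamping out-of-bounds reads to the nearest edge pixel.
padReplicate <- function(m, r) {
  if (r == 0L) return(m)
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * r) - r, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * r) - r, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Number of worker processes for the row-chunked strategy. Forking is only
# used where it exists (not on Windows) and can be pinned via options().
chunkCores <- function() {
  n <- getOption("LiquidEngine.cores", parallel::detectCores(logical = TRUE))
  if (!is.finite(n) || n < 1L) n <- 1L
  as.integer(min(n, 8L))
}

chunkLapply <- function(X, FUN) {
  nc <- chunkCores()
  if (nc > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(X, FUN, mc.cores = nc)
  else
    lapply(X, FUN)
}

# Split 1..n into at most k contiguous index blocks.
chunkRanges <- function(n, k) {
  k <- max(1L, min(as.integer(k), n))
  cut <- floor(seq(0L, n, length.out = k + 1L))
  lapply(seq_len(k), function(i) c(cut[i] + 1L, cut[i + 1L]))
}

stopIfNotFiniteImage <- function(x, what = "image") {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop(what, " must be numeric with all values finite", call. = FALSE)
}

# FNV-1a 64-bit hash of a character scalar, returned as 16 hex digits.
# The 64-bit state is carried in two 32-bit halves inside doubles; the FNV
# prime 0x100000001b3 factors as 0x100 * 2^32 + 0x1b3, so all intermediate
# products stay well below 2^53 and remain exact.
fnv1a64 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  lo <- 0x84222325; hi <- 0xcbf29ce4
  for (b in bytes) {
    lo <- lo - (lo %% 256) + bitwXor(as.integer(lo %% 256), as.integer(b))
    p <- lo * 435                        # low-limb product, exact (< 2^41)
    newLo <- p %% 4294967296
    newHi <- (hi * 435 + lo * 256 + p %/% 4294967296) %% 4294967296
    lo <- newLo; hi <- newHi
  }
  toHex32 <- function(v) paste0(sprintf("%04x", as.integer(v %/% 65536)),
                                sprintf("%04x", as.integer(v %% 65536)))
  paste0(toHex32(hi), toHex32(lo))
}
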