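# A registry of trivial fake implementations lets selection tests control
# timing history exactly without running real kernels.
fakeRegistry <- function(ids = c("A", "B"), method = "m",
                         available = rep(TRUE, length(ids))) {
  reg <- liquidRegistry(populate = FALSE)
  for (k in seq_along(ids))
    registerImplementation(reg, methodId = method, implId = ids[k],
                           runner = function(...) 0,
                           available = available[k])
  reg
}

seedHistory <- function(store, method, impl, sig, times) {
  for (t in times) recordRun(store, method, impl, sig, t)
}

test_that("no-delay regime picks the smallest fast average, deterministically", {
  ses <- liquidSession(fakeRegistry(), tmpStore())
  sig <- c(1, 10, 10)
  seedHistory(ses@store, "m", "A", sig, rep(1.0, 6))
  seedHistory(ses@store, "m", "B", sig, rep(5.0, 6))
  picks <- vapply(1:25, function(i)
    selectImplementation(ses, "m", sig, seed = i)$implId, character(1))
  expect_true(all(picks == "A"))
  tr <- selectImplementation(ses, "m", sig)$trace
  expect_identical(tr$mode, "argmin")
  expect_identical(tr$chosen, "A")
  srcs <- vapply(tr$impls, function(x) x$source, character(1))
  expect_true(all(srcs == "history"))
})

test_that("a single available implementation is always chosen", {
  ses <- liquidSession(fakeRegistry(c("A", "B"),
                                    available = c(FALSE, TRUE)), tmpStore())
  sig <- c(1, 10, 10)
  seedHistory(ses@store, "m", "B", sig, rep(2, 5))
  expect_identical(selectImplementation(ses, "m", sig)$implId, "B")
  sesNone <- liquidSession(fakeRegistry(c("A"), available = FALSE),
                           tmpStore())
  expect_error(selectImplementation(sesNone, "m", sig),
               "no available implementation")
})

test_that("delayed regime samples with Eq-4 frequencies", {
  ses <- liquidSession(fakeRegistry(), tmpStore())
  sig <- c(1, 10, 10)
  seedHistory(ses@store, "m", "A", sig, rep(1.0, 10))
  seedHistory(ses@store, "m", "B", sig, rep(2.0, 10))
  # A delayed with factor 7 and pDelay 0.5: adjusted = 1*(0.5) + 1*7*0.5 = 4
  setDelayState(ses, "m", "A",
                delayState(delayed = TRUE, delayFactor = 7, pDelay = 0.5,
                           history = data.frame(index = 1:4,
                                                delayed = rep(TRUE, 4))))
  sel <- selectImplementation(ses, "m", sig, seed = 1)
  expect_identical(sel$trace$mode, "stochastic")
  probs <- unlist(sel$trace$probabilities)
  expect_equal(probs[["A"]], 0.2)
  expect_equal(probs[["B"]], 0.8)
  expect_equal(sum(probs), 1)

  n <- 2000L
  picks <- vapply(seq_len(n), function(i)
    selectImplementation(ses, "m", sig, seed = i)$implId, character(1))
  freqA <- mean(picks == "A")
  sdBin <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(freqA - 0.2), 3 * sdBin)
  expect_gt(freqA, 0)          # delayed variant keeps positive probability
})

test_that("selection probability never increases with adjusted time", {
  for (tA in c(0.5, 1, 2, 4, 8)) {
    p1 <- selectionProbabilities(c(A = tA, B = 2))[["A"]]
    p2 <- selectionProbabilities(c(A = tA * 1.5, B = 2))[["A"]]
    expect_gt(p1, p2)
  }
})

test_that("insufficient history falls back to factory defaults in the trace", {
  ses <- tmpSession()
  sig <- c(1, 128, 128, 9)
  recordRun(ses@store, "conv2d", "unthreaded", sig, 0.01)
  recordRun(ses@store, "conv2d", "unthreaded", sig, 0.01)  # only 2 records
  sel <- selectImplementation(ses, "conv2d", sig)
  srcs <- vapply(sel$trace$impls, function(x) x$source, character(1))
  expect_true(all(srcs == "defaults"))
  expect_true(sel$implId %in% c("unthreaded", "threaded", "vectorized"))
})

test_that("history from foreign hardware is ignored in favor of defaults", {
  st <- tmpStore()
  ses <- liquidSession(defaultRegistry(), st)
  sig <- c(1, 128, 128, 9)
  for (i in 1:10)
    recordRun(st, "conv2d", "unthreaded", sig, 0.001,
              deviceId = "0123456789abcdef")
  expect_true(detectHardwareChange(st))
  sel <- selectImplementation(ses, "conv2d", sig)
  un <- Filter(function(x) x$implId == "unthreaded", sel$trace$impls)[[1]]
  expect_identical(un$source, "defaults")
})

test_that("the decision completes quickly for a three-way registry", {
  ses <- tmpSession()
  sig <- c(1, 128, 128, 9)
  for (impl in c("unthreaded", "threaded", "vectorized"))
    seedHistory(ses@store, "conv2d", impl, sig, runif(10, 0.01, 0.02))
  selectImplementation(ses, "conv2d", sig)  # warm the parse cache
  t0 <- Sys.time()
  for (i in 1:20) selectImplementation(ses, "conv2d", sig, seed = i)
  perCall <- as.numeric(difftime(Sys.time(), t0, units = "secs")) / 20
  expect_lt(perCall, 0.05)
})

test_that("liquidRun times the call, records it and updates delay state", {
  ses <- tmpSession()
  img <- generateImage(32, 32, seed = 5)
  inputs <- list(image = img, kernel = matrix(1, 3, 3))
  sig <- inputSignature("conv2d", inputs)
  res1 <- liquidRun(ses, "conv2d", inputs, implId = "unthreaded")
  expect_equal(res1$output, conv2d(img, matrix(1, 3, 3)))
  expect_gt(res1$runTime, 0)
  h <- loadRecent(ses@store, "conv2d", "unthreaded", sig)
  expect_equal(h$n, 1L)
  # a grossly delayed wrapped run flips the delay state once history exists
  for (i in 1:6) liquidRun(ses, "conv2d", inputs, implId = "unthreaded")
  stBefore <- getDelayState(ses, "conv2d", "unthreaded")
  expect_false(stBefore@delayed)
  slowReg <- injectDelay(defaultRegistry(), "conv2d", "unthreaded", 50)
  sesSlow <- liquidSession(slowReg, ses@store)
  sesSlow@state <- ses@state
  liquidRun(sesSlow, "conv2d", inputs, implId = "unthreaded")
  expect_true(getDelayState(sesSlow, "conv2d", "unthreaded")@delayed)
  expect_gt(getDelayState(sesSlow, "conv2d", "unthreaded")@delayFactor, 1)
})
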