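test_that("split statistics follow the sort-and-halve definition", {
  s <- splitStats(c(1, 2, 3, 4))
  expect_identical(fastAverage(s), 1.5)
  expect_identical(slowAverage(s), 3.5)
  s5 <- splitStats(c(5, 5, 5, 5))
  expect_identical(fastAverage(s5), 5)
  expect_identical(slowAverage(s5), 5)
  expect_identical(fastStdDev(s5), 0)
  expect_identical(slowStdDev(s5), 0)
  # odd length: median joins the fast half
  so <- splitStats(c(3, 1, 2))
  expect_identical(fastAverage(so), 1.5)
  expect_identical(slowAverage(so), 3)
  expect_error(splitStats(2), "at least 2")
})

test_that("split statistics match the independent oracle on random histories", {
  set.seed(20)
  for (rep in 1:50) {
    x <- runif(sample(2:50, 1), 0.001, 10)
    s <- splitStats(x)
    o <- splitOracle(x)
    expect_identical(fastAverage(s), o$fastAverage)
    expect_identical(fastStdDev(s), o$fastStdDev)
    expect_identical(slowAverage(s), o$slowAverage)
    expect_identical(slowStdDev(s), o$slowStdDev)
  }
})

test_that("delay detection uses the strict four-sigma threshold", {
  st <- new("ImplementationStats", fastAverage = 1, fastStdDev = 0.1,
            slowAverage = 3, slowStdDev = 0.2, n = 10L)
  expect_true(detectDelay(1.5, st))    # 1.5 > 1.4
  expect_false(detectDelay(1.4, st))   # strict inequality
  st0 <- new("ImplementationStats", fastAverage = 1, fastStdDev = 0,
             slowAverage = 1, slowStdDev = 0, n = 4L)
  expect_false(detectDelay(1, st0))    # equality is not a delay
})

test_that("delay factor is the measured/baseline ratio with a zero guard", {
  st <- new("ImplementationStats", fastAverage = 2, fastStdDev = 0,
            slowAverage = 2, slowStdDev = 0, n = 4L)
  expect_identical(delayFactor(5, st), 2.5)
  expect_identical(delayFactor(2, st), 1)
  st0 <- new("ImplementationStats", fastAverage = 0, fastStdDev = 0,
             slowAverage = 0, slowStdDev = 0, n = 4L)
  expect_error(delayFactor(1, st0), "degenerate")
})

test_that("adjusted run time mixes baseline and delayed cost by pDelay", {
  st <- new("ImplementationStats", fastAverage = 2, fastStdDev = 0,
            slowAverage = 2, slowStdDev = 0, n = 4L)
  expect_identical(adjustedRunTime(st, 3, 0.5), 4)
  expect_identical(adjustedRunTime(st, 3, 0), 2)
  expect_identical(adjustedRunTime(st, 3, 1), 6)
})

test_that("selection probabilities are inverse-square normalized", {
  expect_equal(selectionProbabilities(c(A = 1, B = 2)),
               c(A = 0.8, B = 0.2))
  expect_identical(unname(selectionProbabilities(c(only = 3))), 1)
  m <- selectionProbabilities(c(a = 2, b = 2, c = 2, d = 2))
  expect_equal(unname(m), rep(0.25, 4))
  expect_error(selectionProbabilities(c(a = 0)), "positive")
  expect_error(selectionProbabilities(c(a = -1, b = 1)), "positive")
})

test_that("delay recovery follows the two lower-than clauses", {
  st <- new("ImplementationStats", fastAverage = 1, fastStdDev = 0.1,
            slowAverage = 3, slowStdDev = 0.2, n = 10L)
  expect_true(delayOver(1.05, st))   # below fast + fastSd
  expect_true(delayOver(2.5, st))    # below slow - slowSd
  expect_false(delayOver(3.5, st))   # neither clause
})

test_that("agent equations match straight-line oracles on random inputs", {
  set.seed(21)
  for (rep in 1:200) {
    x <- runif(sample(2:50, 1), 0.001, 5)
    s <- splitStats(x)
    m <- runif(1, 0, 10)
    expect_identical(detectDelay(m, s),
                     detectOracle(m, s@fastAverage, s@fastStdDev))
    expect_identical(delayFactor(m, s), factorOracle(m, s@fastAverage))
    f <- runif(1, 1, 20); p <- runif(1)
    expect_identical(adjustedRunTime(s, f, p),
                     adjustedOracle(s@fastAverage, f, p))
    expect_identical(delayOver(m, s),
                     overOracle(m, s@fastAverage, s@fastStdDev,
                                s@slowAverage, s@slowStdDev))
    tt <- runif(sample(1:6, 1), 0.01, 3)
    names(tt) <- paste0("i", seq_along(tt))
    expect_identical(selectionProbabilities(tt), probsOracle(tt))
  }
})

test_that("delay-probability estimation: degenerate rules and logistic trend", {
  allYes <- delayState(history = data.frame(index = 1:10,
                                            delayed = rep(TRUE, 10)))
  expect_equal(estimatePDelay(allYes), 11 / 12)
  allNo <- delayState(history = data.frame(index = 1:10,
                                           delayed = rep(FALSE, 10)))
  expect_equal(estimatePDelay(allNo), 1 / 12)
  expect_error(estimatePDelay(delayState()), "empty history")

  # delays early, none recently: prediction below the overall frequency
  hist <- data.frame(index = 1:20, delayed = c(rep(TRUE, 8), rep(FALSE, 12)))
  p <- estimatePDelay(delayState(history = hist))
  expect_lt(p, mean(hist$delayed))

  # agreement with an independent maximum-likelihood fit via optim
  nll <- function(beta)
    -sum(ifelse(hist$delayed,
                stats::plogis(beta[1] + beta[2] * hist$index, log.p = TRUE),
                stats::plogis(beta[1] + beta[2] * hist$index,
                              lower.tail = FALSE, log.p = TRUE)))
  fit <- optim(c(0, 0), nll, method = "BFGS")
  pOracle <- stats::plogis(fit$par[1] + fit$par[2] * 21)
  expect_equal(p, pOracle, tolerance = 1e-4)
})

test_that("fuzzy scoring: exact match scores 1, monotone dominance wins", {
  expect_identical(fuzzyScore(c(512, 512), c(512, 512)), 1)
  expect_gt(fuzzyScore(c(512, 512), c(500, 500)),
            fuzzyScore(c(512, 512), c(4000, 4000)))
  # beyond 100 % relative difference the membership hits zero
  expect_identical(fuzzyScore(c(4000), c(10)), 0)
  # zero candidate feature matches only zero queries
  expect_identical(fuzzyScore(c(0, 5), c(0, 5)), 1)
  expect_identical(fuzzyScore(c(1, 5), c(0, 5)), 0.5)
})

test_that("fuzzy matching equals the exhaustive-scoring oracle", {
  tbl <- new("BenchmarkTable", methodId = "conv2d", entries = list(
    list(signature = c(1, 500, 500, 9), times = list(u = c(1, 1))),
    list(signature = c(1, 4000, 4000, 9), times = list(u = c(2, 2)))))
  m <- fuzzyMatch(c(1, 512, 512, 9), tbl)
  expect_equal(m$signature, c(1, 500, 500, 9))
  mExact <- fuzzyMatch(c(1, 4000, 4000, 9), tbl)
  expect_identical(mExact$score, 1)
  expect_equal(mExact$index, 2L)

  set.seed(22)
  for (rep in 1:30) {
    nf <- sample(2:6, 1)
    sigs <- replicate(sample(2:8, 1),
                      runif(nf, 0.1, 1000), simplify = FALSE)
    entries <- lapply(sigs, function(s)
      list(signature = s, times = list(u = c(1, 1))))
    tab <- new("BenchmarkTable", methodId = "m", entries = entries)
    q <- runif(nf, 0.1, 1000)
    got <- fuzzyMatch(q, tab)
    want <- fuzzyMatchOracle(q, sigs)
    expect_equal(got$index, want$index)
    expect_equal(got$score, want$score)
  }
  expect_error(fuzzyMatch(c(1), new("BenchmarkTable", methodId = "m",
                                    entries = list())), "empty")
})
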