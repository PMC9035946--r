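test_that("hamming distance matches hand-checked cases and rejects bad input", {
  expect_equal(hammingDistance(strtoi("1010", base = 2),
                               strtoi("1010", base = 2), l = 4), 0L)
  expect_equal(hammingDistance(strtoi("0000", base = 2),
                               strtoi("1111", base = 2), l = 4), 4L)
  expect_equal(hammingDistance(strtoi("1100", base = 2),
                               strtoi("1010", base = 2), l = 4), 2L)
  expect_error(hammingDistance(17, 0, l = 4), "invalid")
  expect_error(hammingDistance(0, -1, l = 4), "invalid")
})

test_that("hamming distance is a metric (exhaustive at small l)", {
  l <- 6L
  v <- 0:(2^l - 1)
  pairs <- expand.grid(a = v, b = v)
  d <- hammingDistance(pairs$a, pairs$b, l)
  dm <- matrix(d, 2^l, 2^l)
  expect_true(all(diag(dm) == 0))
  expect_true(all(d[pairs$a != pairs$b] > 0))
  expect_identical(dm, t(dm))
  # triangle inequality over all triples at l = 4
  l4 <- 4L
  v4 <- 0:15
  dm4 <- outer(v4, v4, function(a, b) hammingDistance(a, b, l4))
  for (k in v4 + 1)
    expect_true(all(dm4 <= outer(dm4[, k], dm4[k, ], `+`)))
})

test_that("hamming distance agrees with an independent character-level oracle", {
  l <- 6L
  set.seed(7)
  a <- sample(0:63, 200, replace = TRUE)
  b <- sample(0:63, 200, replace = TRUE)
  expect_equal(hammingDistance(a, b, l),
               mapply(function(x, y) oracleHamming(x, y, l), a, b),
               ignore_attr = TRUE)
})

test_that("binding probability follows the thresholded exponential rule", {
  ap <- AffinityParams(l = 8, dMin = 5, alpha = 0.5, pMax = 1)
  expect_equal(bindingProbability(0L, 255L, ap), 1.0)          # d = l
  expect_equal(bindingProbability(0L, 1L, ap), 0.0)            # d < dMin
  # l=8, d=6 -> 0.5^2 = 0.25
  expect_equal(bindingProbability(0L, strtoi("00111111", base = 2), ap), 0.25)
  expect_error(bindingProbability(256, 0, ap), "invalid")
})

test_that("binding probability equals a brute-force table at l = 6", {
  l <- 6L
  ap <- AffinityParams(l = l, dMin = 3L, alpha = 0.7, pMax = 0.9)
  v <- 0:(2^l - 1)
  pairs <- expand.grid(a = v, b = v)
  got <- bindingProbability(pairs$a, pairs$b, ap)
  want <- mapply(function(x, y) {
    d <- oracleHamming(x, y, l)
    if (d < 3) 0 else 0.9 * 0.7^(l - d)
  }, pairs$a, pairs$b)
  expect_equal(got, want, ignore_attr = TRUE)
  # monotone non-decreasing in d
  d <- hammingDistance(pairs$a, pairs$b, l)
  expect_true(all(tapply(got, d, mean) == sort(tapply(got, d, mean))))
})

test_that("repertoire sampling is uniform, seed-stable, and bounded", {
  expect_identical(sampleRepertoire(0, 8), integer(0))
  expect_error(sampleRepertoire(-1, 8), ">= 0")
  expect_setequal(with_seed_repertoire <- {
    set.seed(1); sampleRepertoire(16, 4, unique = TRUE)
  }, 0:15)
  set.seed(33); r1 <- sampleRepertoire(1000, 12)
  set.seed(33); r2 <- sampleRepertoire(1000, 12)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 < 4096))
  # chi-square goodness of fit against uniform at l = 8
  set.seed(5)
  r <- sampleRepertoire(1e5, 8)
  tab <- tabulate(r + 1L, 256)
  chi <- sum((tab - 1e5 / 256)^2 / (1e5 / 256))
  expect_gt(pchisq(chi, df = 255, lower.tail = FALSE), 0.01)
})

test_that("receptor mutation flips exactly the requested number of bits", {
  set.seed(2)
  expect_identical(mutateReceptor(1234L, 0, 12), 1234L)
  expect_identical(mutateReceptor(1234L, 12, 12), bitwXor(1234L, 4095L))
  expect_error(mutateReceptor(0L, 13, 12), "nBits")
  n <- 1e4
  r <- sampleRepertoire(n, 12)
  k <- sample(0:12, n, replace = TRUE)
  m <- mapply(function(x, nb) mutateReceptor(x, nb, 12), r, k)
  expect_equal(hammingDistance(r, m, 12), k, ignore_attr = TRUE)
})
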