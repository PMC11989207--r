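test_that("percentile ranks follow the Hazen convention with mid-ranks", {
  expect_equal(percentile_ranks(c(10, 20, 30, 40)),
               c(12.5, 37.5, 62.5, 87.5))
  expect_equal(percentile_ranks(c(5, 5)), c(50, 50))
  expect_equal(percentile_ranks(7), 50)
  expect_error(percentile_ranks(numeric(0)), "empty")
  expect_error(percentile_ranks(c(-1, 2)), "non-negative")
})

test_that("percentile ranks are invariant under positive affine transforms", {
  set.seed(42)
  for (i in 1:5) {
    x <- stats::rlnorm(20)
    a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, 0, 100)
    expect_equal(percentile_ranks(a * x + b), percentile_ranks(x))
  }
})

test_that("percentile ranks propagate missing values without using them", {
  x <- c(10, NA, 20, 30, 40)
  p <- percentile_ranks(x)
  expect_true(is.na(p[2]))
  expect_equal(p[-2], percentile_ranks(c(10, 20, 30, 40)))
})

test_that("immunoscore is the mean of the four percentiles, high at >= cutoff", {
  r <- immunoscore(80, 70, 60, 62)
  expect_equal(r$mean_percentile, 68)
  expect_identical(r$is_class, "high")
  r0 <- immunoscore(0, 0, 0, 0)
  expect_equal(r0$mean_percentile, 0)
  expect_identical(r0$is_class, "low")
  # boundary: exactly the cutoff is classed high
  rb <- immunoscore(62, 62, 62, 62)
  expect_equal(rb$mean_percentile, 62)
  expect_identical(rb$is_class, "high")
  expect_error(immunoscore(101, 0, 0, 0), "\\[0, 100\\]")
})

test_that("immunoscore mean is permutation-invariant and monotone", {
  p <- c(81, 17, 55, 42)
  base <- immunoscore(p[1], p[2], p[3], p[4])$mean_percentile
  set.seed(7)
  for (i in 1:5) {
    q <- sample(p)
    expect_equal(immunoscore(q[1], q[2], q[3], q[4])$mean_percentile, base)
  }
  up <- immunoscore(p[1] + 5, p[2], p[3], p[4])$mean_percentile
  expect_gt(up, base)
})

test_that("NAR scores reproduce hand-computed values and categories", {
  r <- nar_pathologic(c(4, 3, 3, 3), c(0, 0, 3, 2), c(0, 0, 1, 0))
  expect_equal(r$value, c(0, 9, 289, 81) / 9.61)
  expect_identical(r$category, c("low", "low", "high", "intermediate"))
  rr <- nar_radiologic(c(4, 3, 2), c(0, 0, 2), c(0, 0, 2))
  expect_equal(rr$value, c(0, 9, 484) / 9.61)
  expect_identical(rr$category, c("low", "low", "high"))
  expect_identical(unique(r$variant), "pathologic")
  expect_identical(unique(rr$variant), "radiologic")
  expect_error(nar_pathologic(5, 0, 0), "out of encoded range")
  expect_error(nar_pathologic(3, 0, 3), "out of encoded range")
})

test_that("NAR categorization splits at 8 and 16, inclusive in the middle", {
  expect_identical(categorize_nar(c(0, 7.9, 8, 12, 16, 16.1, 30)),
                   c("low", "low", "intermediate", "intermediate",
                     "intermediate", "high", "high"))
  expect_error(categorize_nar(-0.1), "non-negative")
})

test_that("attainable NAR values are k^2/9.61 and never hit the boundaries", {
  grid <- expand.grid(ct = 0:4, ypt = 0:4, ypn = 0:2)
  v <- nar_pathologic(grid$ct, grid$ypt, grid$ypn)$value
  k <- sqrt(v * 9.61)
  expect_equal(k, round(k))
  expect_true(all(k >= 0 & k <= 34))
  expect_false(any(v == 8 | v == 16))
})

test_that("NAR is monotone in each stage over the exhaustive domain", {
  val <- function(ct, ypt, ypn) nar_pathologic(ct, ypt, ypn)$value
  for (ct in 0:4) for (ypt in 0:4) for (ypn in 0:2) {
    if (ypn < 2) expect_lte(val(ct, ypt, ypn), val(ct, ypt, ypn + 1))
    if (ypt < 4) expect_lte(val(ct, ypt, ypn), val(ct, ypt + 1, ypn))
    if (ct < 4) expect_gte(val(ct, ypt, ypn), val(ct + 1, ypt, ypn))
  }
})

test_that("a pCR patient with baseline cT 2-4 always has a low NAR score", {
  for (ct in 2:4) {
    r <- nar_pathologic(ct, 0, 0)
    expect_lte(r$value, 36 / 9.61)  # worst case cT2: (12 - 6)^2 / 9.61
    expect_identical(r$category, "low")
  }
})

test_that("the combined stratum is high IS together with mrTRG 1", {
  expect_identical(combined_stratum("high", 1), "is_high_and_trg1")
  expect_identical(combined_stratum("high", 2), "other")
  expect_identical(combined_stratum("low", 1), "other")
  expect_identical(combined_stratum(NA, 1), NA_character_)
  expect_identical(combined_stratum("high", NA), NA_character_)
  expect_error(combined_stratum("medium", 1), "is_class")
})
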