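test_that("complementation frequency arithmetic and display rendering", {
  # 2 selective colonies per 2e6 transformants, both confirmed
  fe <- complementationFrequency(plateCounts(2, 2e6, retested = 2, confirmed = 2))
  expect_equal(fe@raw, 1e-6)
  expect_equal(fe@adjusted, 1e-6)
  expect_identical(fe@display, "~1/1,000,000")
  # false-positive correction: 30 of 40 retested confirm
  fe <- complementationFrequency(plateCounts(40, 120000, retested = 40,
                                             confirmed = 30))
  expect_equal(fe@raw, 40 / 120000)
  expect_equal(fe@adjusted, 2.5e-4)
  # no retesting: adjusted = raw
  fe <- complementationFrequency(plateCounts(5, 1e5))
  expect_equal(fe@adjusted, fe@raw)
  # zero selective colonies: all-zero estimate with a zero lower bound
  fe <- complementationFrequency(plateCounts(0, 1e5))
  expect_equal(fe@raw, 0)
  expect_equal(fe@adjusted, 0)
  expect_equal(fe@ciLow, 0)
  expect_identical(fe@display, "0")
  # dilution correction enters both counts
  fe <- complementationFrequency(plateCounts(3, 500, selDilution = 1,
                                             richDilution = 100))
  expect_equal(fe@raw, 3 / 50000)
  expect_error(complementationFrequency(plateCounts(1, 0)), "undefined")
})

test_that("adjusted <= raw and the CI brackets the adjusted proportion", {
  set.seed(41)
  for (k in 1:50) {
    sel <- sample(0:60, 1); rich <- sample(1e4:1e6, 1)
    ret <- sample(0:sel, 1); conf <- if (ret > 0) sample(0:ret, 1) else 0
    fe <- complementationFrequency(plateCounts(sel, rich, retested = ret,
                                               confirmed = conf))
    expect_lte(fe@adjusted, fe@raw + 1e-12)
    if (conf > 0 || ret == 0 && sel > 0) {
      expect_lte(fe@ciLow, fe@adjusted)
      expect_gte(fe@ciHigh, fe@adjusted)
    }
  }
})

test_that("display rendering reproduces the ~1/X style at one significant figure", {
  cases <- list(c(2.1e-5, "~1/50,000"), c(9.6e-7, "~1/1,000,000"),
                c(3.4e-4, "~1/3,000"), c(1.1e-4, "~1/10,000"))
  for (cs in cases) {
    fe <- complementationFrequency(plateCounts(as.numeric(cs[1]) * 1e7, 1e7))
    expect_identical(fe@display, cs[2], info = cs[1])
  }
})

test_that("Clopper-Pearson coverage is at least nominal in simulation", {
  # 1e4 binomial replicates at p = 1e-4, n = 1e5
  set.seed(42)
  p <- 1e-4; n <- 1e5
  x <- rbinom(1e4, n, p)
  ci <- binpat:::.clopperPearson(x, n)
  coverage <- mean(ci[, "lo"] <= p & p <= ci[, "hi"])
  expect_gte(coverage, 0.95)
})

test_that("rescue probability is stable in log space and monotone", {
  expect_equal(rescueProbability(0, 1e9), 0)
  expect_equal(rescueProbability(0.5, 0), 0)
  expect_equal(rescueProbability(1, 5), 1)
  # 1e-6 frequency, 1e6 transformants: close to 1 - 1/e
  expect_equal(rescueProbability(1e-6, 1e6), 1 - exp(-1), tolerance = 1e-6)
  # Table-1-scale frequency with deep coverage saturates at double precision
  expect_equal(rescueProbability(1 / 3000, 5e6), 1)
  # monotone nondecreasing in both arguments
  fGrid <- c(0, 1e-7, 1e-5, 1e-3, 0.1, 1)
  tGrid <- c(0, 10, 1e3, 1e6)
  for (tt in tGrid)
    expect_true(all(diff(rescueProbability(fGrid, tt)) >= 0))
  for (f in fGrid)
    expect_true(all(diff(rescueProbability(f, tGrid)) >= 0))
})

test_that("expected-unique coverage matches birthday simulation and bounds", {
  expect_equal(expectedUnique(1000, 0)@expectedUnique, 0)
  expect_equal(expectedUnique(1, 100)@expectedUnique, 1)
  # exact small-case comparison against brute-force birthday simulation
  set.seed(43)
  for (cs in list(c(50, 30), c(1000, 1000), c(200, 500))) {
    D <- cs[1]; s <- cs[2]
    sim <- replicate(400, length(unique(sample.int(D, s, replace = TRUE))))
    est <- expectedUnique(D, s)@expectedUnique
    se <- stats::sd(sim) / sqrt(length(sim))
    expect_lt(abs(est - mean(sim)), 3 * se + 1e-9, label = paste(D, s))
    expect_lte(est, min(D, s))
  }
  # astronomically large diversity: essentially every member unique
  cov <- expectedUnique(theoreticalDiversity(defaultTemplate()), 1.5e6)
  expect_equal(cov@expectedUnique, 1.5e6, tolerance = 1e-9)
  expect_lt(cov@collisionBound, 1e-40)
})

test_that("plate-count tables compute per-strain frequency rows", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("strain\tselective\trich\tretested\tconfirmed",
               "dSerB\t20\t1000000\t20\t20",
               "dGltA\t1\t1000000\t1\t1"), tmp)
  tab <- complementationTable(tmp)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$adjusted, c(2e-5, 1e-6))
  expect_identical(tab$display, c("~1/50,000", "~1/1,000,000"))
})

test_that("accession ranges expand to the full identifier list", {
  acc <- parseAccessionRange("FR718891 - FR718908")
  expect_length(acc, 18L)
  expect_identical(acc[1], "FR718891")
  expect_identical(acc[18], "FR718908")
  expect_identical(parseAccessionRange("AB1-AB3"), c("AB1", "AB2", "AB3"))
  expect_identical(parseAccessionRange("X001 - X003"),
                   c("X001", "X002", "X003"))
  expect_error(parseAccessionRange("FR1 - XY2"), "prefixes differ")
  expect_error(parseAccessionRange("FR9 - FR2"), "precedes")
  expect_error(parseAccessionRange("garbage"), "cannot parse")
})

test_that("genome-fraction arithmetic reproduces the headline percentages", {
  gf <- genomeFraction()
  expect_equal(unname(gf["genomePercent"]), 0.1)
  expect_equal(signif(unname(gf["minimalEssentialPercent"]), 1), 1)
  expect_equal(unname(genomeFraction(rescued = 8)["genomePercent"]), 0.2)
})
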