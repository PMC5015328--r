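test_that("Lin's CCC reproduces its defining boundary cases", {
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  expect_equal(lin_ccc(c(1, 2, 3, 4), c(2, 4, 6, 8)), 0.4)
  expect_equal(lin_ccc(c(5, 5, 5), c(5, 5, 5)), 1)   # constant, equal
  expect_equal(lin_ccc(c(5, 5, 5), c(7, 7, 7)), 0)   # constant, unequal
  expect_equal(lin_ccc(c(5, 5, 5), c(1, 2, 3)), 0)   # one constant
  expect_error(lin_ccc(1:3, 1:4), "length")
  expect_error(lin_ccc(c(1, NA, 3), c(1, 2, 3)), "finite")
})

test_that("Lin's CCC equals the brute-force formula on random pairs", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 4))
    y <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 4))
    expect_equal(lin_ccc(x, y), brute_ccc(x, y), tolerance = 1e-12)
  }
})

test_that("CCC is symmetric, shift-penalized and bounded by |Pearson r|", {
  set.seed(19)
  for (i in 1:200) {
    x <- rnorm(4, 10, 3)
    y <- rnorm(4, 10, 3)
    expect_identical(lin_ccc(x, y), lin_ccc(y, x))
    expect_lt(lin_ccc(x, x + 1.5), 1)
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("concordance classification flags only DE genes below the cutoff", {
  prof <- make_profiles(rbind(c(10, 20, 30, 40),
                              c(10, 20, 30, 40),
                              c(50, 40, 30, 20)),
                        rbind(c(10, 20, 30, 40),
                              c(40, 30, 20, 10),
                              c(48, 41, 29, 22)))
  res <- classify_concordance(prof, de_flags = c(TRUE, TRUE, FALSE))
  expect_equal(res$ccc[1], 1)
  expect_false(res$low_concordance_flag[1])
  expect_true(res$low_concordance_flag[2])   # mirrored pattern
  expect_true(is.na(res$low_concordance_flag[3]))  # not DE: no flag
  expect_false(is.na(res$ccc[3]))
  # cutoff 1 flags everything short of perfect concordance
  res1 <- classify_concordance(prof, cutoff = 1)
  expect_identical(res1$low_concordance_flag, c(FALSE, TRUE, TRUE))
  # log2(x+1) switch changes the scale but keeps perfect concordance
  resl <- classify_concordance(prof, transform = "log2p1")
  expect_equal(resl$ccc[1], 1)
})

test_that("side-specific classes sit below shared classes in CCC", {
  ds <- standard_dataset()
  cc <- classify_concordance(ds$profiles, ds$de$de_flag)
  cls <- ds$sim$truth$class
  expect_lt(median(cc$ccc[cls %in% c("oral_specific", "physa_specific")]),
            0.6)
  expect_gt(median(cc$ccc[cls == "shared"]), 0.6)
})

test_that("trend labels follow the 1.6-fold always-up/down rules", {
  prof <- make_profiles(rbind(c(10, 17, 20, 16.6),
                              c(10, 10, 10, 10),
                              c(32, 20, 16, 10)),
                        rbind(c(10, 11, 20, 16.6),
                              c(10, 10, 10, 10),
                              c(32, 18, 15, 12)))
  tr <- trend_labels(prof, fold = 1.6, pseudocount = 0)
  expect_identical(tr$trend_oral, c("always_up", "other", "always_down"))
  expect_identical(tr$trend_physa, c("other", "other", "always_down"))
  expect_identical(tr$side_trend_category, c("oral_only", NA, "both"))
})

test_that("interval calls follow the consecutive-time-point rule", {
  prof <- make_profiles(rbind(c(10, 20, 20, 5), c(7, 7, 7, 7)),
                        rbind(c(10, 15, 26, 26), c(7, 7, 7, 7)))
  ic <- interval_changes(prof, fold = 1.6, pseudocount = 0)
  expect_identical(unname(ic$calls$oral[1, ]), c("up", "flat", "down"))
  expect_identical(unname(ic$calls$oral[2, ]), rep("flat", 3))
  expect_identical(unname(ic$calls$physa[1, ]), c("flat", "up", "flat"))
  # per-interval directions partition the genes
  agg <- aggregate(n ~ side + interval, data = ic$counts, sum)
  expect_true(all(agg$n == 2))
})

test_that("max-change summaries report hour, side and log2 magnitude", {
  prof <- make_profiles(c(1, 1, 1, 100), c(1, 1, 1, 1))
  cs <- change_summaries(prof, pseudocount = 0)
  expect_identical(cs$tmax_vs_t0_hour, 72)
  expect_identical(cs$tmax_vs_t0_side, "oral")
  expect_equal(cs$tmax_vs_t0_log2fc, log2(100))
  expect_identical(cs$interval_max_hour, 72)
  expect_equal(cs$interval_max_log2fc, log2(100))
  expect_identical(cs$higher_activity_side, "oral")  # higher at 1 of 4 + sum
  # identical profiles -> tie
  tie <- change_summaries(make_profiles(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_identical(tie$higher_activity_side, "tie")
  # strict majority beats a larger sum
  mj <- change_summaries(make_profiles(c(10, 10, 10, 1), c(9, 9, 9, 50)),
                         pseudocount = 0)
  expect_identical(mj$higher_activity_side, "oral")
})

test_that("every gene gets exactly one trend label per side", {
  ds <- standard_dataset()
  tr <- trend_labels(ds$profiles)
  expect_true(all(tr$trend_oral %in% c("always_up", "always_down", "other")))
  expect_true(all(tr$trend_physa %in% c("always_up", "always_down", "other")))
  expect_identical(nrow(tr), nrow(ds$profiles$oral))
})

test_that("polarize assembles a complete record per gene", {
  ds <- standard_dataset()
  rec <- polarize(ds$profiles, ds$de)
  expect_identical(nrow(rec), nrow(ds$de))
  expect_identical(colnames(rec), polarseq:::RESULT_COLUMNS)
  expect_true(all(is.finite(rec$tmax_vs_t0_log2fc)))
  expect_true(all(rec$ccc >= -1 & rec$ccc <= 1))
  expect_identical(is.na(rec$low_concordance_flag), !rec$de_flag)
})
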