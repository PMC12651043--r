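test_that("aggregate_profile reproduces the reference control column and edge cases", {
  p <- aggregate_profile(c(discocyte = 911, echinocyte = 35,
                           discocyte_with_ridge = 31, dome_shaped = 12,
                           deflated_ball = 2, degenerative = 5,
                           spherocyte_with_spikes = 4))
  expect_equal(p$D, 91.1)
  expect_equal(p$RD, 97.7)
  expect_equal(p$ID, 2.3)
  expect_equal(sum(p$pct), 100)

  all_d <- aggregate_profile(c(discocyte = 100))
  expect_equal(c(all_d$D, all_d$RD, all_d$ID), c(100, 100, 0))

  all_id <- aggregate_profile(c(spherocyte = 50, stomatocyte = 50))
  expect_equal(c(all_id$D, all_id$RD, all_id$ID), c(0, 0, 100))
})

test_that("aggregate_profile rejects unknown classes and degenerate counts", {
  expect_error(aggregate_profile(c(discocyte = 5, klingon_cell = 1)),
               "klingon_cell")
  expect_error(aggregate_profile(c(discocyte = 0)), "zero total")
  expect_error(aggregate_profile(c(discocyte = -1, echinocyte = 5)), "negative")
  expect_error(aggregate_profile(c(10, 20)), "named")
})

test_that("profiles are scale-invariant and always satisfy RD + ID = 100", {
  set.seed(42)
  for (i in 1:25) {
    cnt <- random_counts()
    p <- aggregate_profile(cnt)
    expect_equal(p$RD + p$ID, 100, tolerance = 1e-12)
    expect_lte(p$D, p$RD + 1e-12)
    for (k in c(2, 7)) {
      pk <- aggregate_profile(cnt * k)
      expect_equal(pk$pct, p$pct, tolerance = 1e-12)
      expect_equal(c(pk$D, pk$RD, pk$ID), c(p$D, p$RD, p$ID), tolerance = 1e-12)
    }
  }
})

test_that("compute_indices matches the reference table and its reporting precision", {
  ref <- reference_cytoarchitectonics()
  for (cond in ref$conditions) {
    cat_col <- ref$category[[cond]]
    ix <- compute_indices(profile_from_percent(D = cat_col[1], RD = cat_col[2],
                                               ID = cat_col[3]))
    expect_equal(unname(ix$reported["TI"]), ref$indices["TI", cond],
                 info = cond)
    expect_equal(unname(ix$reported["RTI"]), ref$indices["RTI", cond],
                 info = cond)
    expect_equal(unname(ix$reported["IRTI"]), ref$indices["IRTI", cond],
                 info = cond)
  }
  # spot-check the unrounded control value
  ctrl <- compute_indices(profile_from_percent(91.1, 97.6, 2.4))
  expect_equal(ctrl$TI, 100 / 91.1, tolerance = 1e-12)
})

test_that("TI decomposes exactly as RTI + IRTI and is undefined at D = 0", {
  set.seed(99)
  for (i in 1:25) {
    p <- aggregate_profile(random_counts())
    if (p$D == 0) next
    ix <- compute_indices(p)
    expect_equal(ix$TI, ix$RTI + ix$IRTI, tolerance = 1e-13)
    expect_gte(ix$TI, 1 - 1e-12)  # RD + ID = 100 >= D
  }
  expect_error(compute_indices(profile_from_percent(0, 0, 100)), "undefined")
})

test_that("round_reported rounds half away from zero at the printed precision", {
  expect_equal(round_reported(1.1725, 1), 1.2)
  expect_equal(round_reported(0.0263, 2), 0.03)
  expect_equal(round_reported(1.0, 1), 1.0)
  expect_equal(round_reported(0.045, 2), 0.05)   # exact half-way case
  expect_equal(round_reported(-0.045, 2), -0.05) # away from zero, not up
  expect_equal(round_reported(2.25, 1), 2.3)     # no banker's rounding
})

test_that("profile_table computes exact per-donor profiles from a long table", {
  fix <- reference_counts_fixture()
  pt <- profile_table(fix)
  expect_equal(nrow(pt), 5)
  expect_true(all(abs(pt$RD + pt$ID - 100) < 1e-9))
  bad <- fix
  bad$shape_class[1] <- "not_a_cell"
  expect_error(profile_table(bad), "not_a_cell")
})
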