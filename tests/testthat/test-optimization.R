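test_that("relative amount reproduces the published class-count arithmetic", {
  amount <- relative_amount(c("2x" = 7, "1x" = 80, "0.2x" = 33,
                              "0.04x" = 8, "drop" = 64), 192)
  expect_equal(amount, (7 * 2 + 80 * 1 + 33 * 0.2 + 8 * 0.04) / 192)
  expect_equal(amount, 0.525625)
  expect_equal(round(amount, 2), 0.53)

  expect_equal(relative_amount(c("1x" = 192), 192), 1)
  expect_equal(relative_amount(c("1x" = 137, "drop" = 55), 192),
               0.713542, tolerance = 1e-6)
  expect_error(relative_amount(c("1x" = 10), 192), "expected n_total")
  expect_error(relative_amount(c("5x" = 192), 192), "unknown")
})

test_that("relative amount is linear and monotone under down-classing", {
  set.seed(23)
  classes <- c("2x", "1x", "0.2x", "0.04x", "drop")
  for (i in 1:50) {
    counts <- stats::setNames(as.vector(stats::rmultinom(1, 192, rep(1, 5))),
                              classes)
    a0 <- relative_amount(counts, 192)
    # move one antibody to a lower-factor class: amount never increases
    from <- sample(classes[counts > 0 & classes != "drop"], 1)
    to <- classes[which(classes == from) + 1L]
    counts2 <- counts
    counts2[from] <- counts2[from] - 1L
    counts2[to] <- counts2[to] + 1L
    expect_lte(relative_amount(counts2, 192), a0)
  }
})

test_that("panel comparisons report the published percent savings", {
  expect_equal(compare_panels(0.525625, 1), 47.4375)
  expect_equal(round(compare_panels(0.525625, 1)), 47)
  expect_equal(round(compare_panels(0.525625, 0.713542)), 26)
  expect_equal(compare_panels(0.5, 0.5), 0)
  expect_error(compare_panels(0.5, 0), "zero")
})

make_calls <- function(det, sep, mode = NULL) {
  arms <- c("2x", "1x", "0.2x", "0.04x")
  if (is.null(mode)) mode <- ifelse(det, "negative95", "none")
  data.frame(antibody_id = "ab", arm_label = arms, detectable = det,
             mode = mode, threshold = ifelse(det, 1, NA),
             separation = sep, positive_fraction = 0.3)
}

test_that("optimal concentration follows the lowest-sufficient rule", {
  arms <- default_arms()
  # detectable at all arms with non-degrading separation -> lowest arm
  expect_equal(select_optimal_concentration(
    make_calls(rep(TRUE, 4), c(8, 8, 8, 8)), arms), "0.04x")
  # detectable nowhere -> drop
  expect_equal(select_optimal_concentration(
    make_calls(rep(FALSE, 4), c(1, 1, 1, 1)), arms), "drop")
  # detectable only at 2x -> 2x
  expect_equal(select_optimal_concentration(
    make_calls(c(TRUE, FALSE, FALSE, FALSE), c(8, 1, 1, 1)), arms), "2x")
  # separation degrades below 1x -> 1x
  expect_equal(select_optimal_concentration(
    make_calls(rep(TRUE, 4), c(8, 8.2, 5, 4)), arms), "1x")
  # detectable at 1x but with degraded quality -> 2x
  expect_equal(select_optimal_concentration(
    make_calls(c(TRUE, TRUE, FALSE, FALSE), c(8, 5, 1, 1)), arms), "2x")
  # ubiquitous antigen: quality criterion does not apply
  expect_equal(select_optimal_concentration(
    make_calls(rep(TRUE, 4), c(8, 3, 2, 1.5), mode = "positive5"), arms),
    "0.04x")
  expect_error(select_optimal_concentration(
    make_calls(rep(TRUE, 4), rep(8, 4))[1:3, ], arms), "missing")
})

test_that("the optimized panel reproduces the published 128plex plan", {
  # calls constructed so the per-antibody rule yields the printed class
  # counts: 7 at 2x, 76 at 1x, 33 at 0.2x, 8 at 0.04x, 64 dropped, with the
  # 4 isotype controls fixed at 1x
  panel <- panel_definition(
    sprintf("AB%03d", 1:192),
    is_isotype_control = c(rep(FALSE, 188), rep(TRUE, 4))
  )
  arms <- default_arms()
  class_of <- rep(c("2x", "1x", "0.2x", "0.04x", "drop"),
                  c(7, 76, 33, 8, 64))
  calls <- do.call(rbind, lapply(1:192, function(i) {
    if (i > 188) {  # isotype controls: pinned to 1x regardless of calls
      return(transform(make_calls(rep(FALSE, 4), rep(0, 4)),
                       antibody_id = sprintf("AB%03d", i)))
    }
    cls <- class_of[i]
    sep <- switch(cls,
                  "2x" = c(8, 5, 1, 1), "1x" = c(8, 8, 5, 4),
                  "0.2x" = c(8, 8, 8, 5), "0.04x" = c(8, 8, 8, 8),
                  "drop" = c(1, 1, 1, 1))
    det <- switch(cls,
                  "2x" = c(TRUE, TRUE, FALSE, FALSE),
                  "drop" = rep(FALSE, 4), rep(TRUE, 4))
    transform(make_calls(det, sep), antibody_id = sprintf("AB%03d", i))
  }))
  plan <- build_optimized_panel(calls, panel, arms)
  expect_equal(plan$n_retained, 128L)
  expect_equal(unname(plan$class_counts), c(7L, 80L, 33L, 8L, 64L))
  expect_equal(plan$relative_amount, 0.525625)
})

test_that("an all-undetectable panel keeps only the isotype controls", {
  panel <- panel_definition(c("a", "b", "ISO1", "ISO2"),
                            is_isotype_control = c(FALSE, FALSE, TRUE, TRUE))
  arms <- default_arms()
  calls <- do.call(rbind, lapply(panel$antibody_id, function(id) {
    transform(make_calls(rep(FALSE, 4), rep(0, 4)), antibody_id = id)
  }))
  plan <- build_optimized_panel(calls, panel, arms)
  expect_equal(plan$n_retained, 2L)
  expect_equal(plan$relative_amount, 2 / 4)
  expect_error(build_optimized_panel(calls[calls$antibody_id != "a", ],
                                     panel, arms), "a")
})

test_that("end-to-end optimization recovers the generator tier structure", {
  pip <- default_pipeline()
  plan <- pip$plan
  tiers <- antibody_tiers(default_config())
  expected <- c("2x" = 7L, "1x" = 76L + 4L, "0.2x" = 33L, "0.04x" = 8L,
                drop = 64L)
  for (cls in names(expected)) {
    expect_lte(abs(plan$class_counts[[cls]] - expected[[cls]]), 3L)
  }
  # isotype controls are pinned to the recommended concentration
  iso <- plan$plan$is_isotype_control
  expect_true(all(plan$plan$optimal_class[iso] == "1x"))
})
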