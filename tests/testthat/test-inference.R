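test_that("bootstrap CIs and test match the brute-force oracle bit-identically", {
  tpl <- make_template_form("box_8")
  ga <- simulate_group(apply_regional_effect(tpl, c("c1", "c2", "c3"),
                                             "radial_scale", 0.08),
                       8, 0.05, "mutant", seed = 2)
  gb <- simulate_group(tpl, 10, 0.05, "unaffected", seed = 3)

  ci <- bootstrap_fdm_intervals(ga, gb, n_boot = 50, confidence_level = 0.90,
                                seed = 17)
  orc <- oracle_bootstrap_ci(ga, gb, n_boot = 50, level = 0.90, seed = 17)
  expect_identical(ci$table$ratio, unname(orc$ratio))
  expect_identical(ci$table$lower, orc$lower)
  expect_identical(ci$table$upper, orc$upper)

  tt <- test_mean_form_difference(ga, gb, n_boot = 50, seed = 17)
  ot <- oracle_form_test(ga, gb, n_boot = 50, seed = 17)
  expect_identical(tt$statistic, ot$statistic)
  expect_identical(tt$p_value, ot$p_value)

  # same seed + inputs reproduce every number bit-identically
  ci2 <- bootstrap_fdm_intervals(ga, gb, n_boot = 50, confidence_level = 0.90,
                                 seed = 17)
  expect_identical(ci$table, ci2$table)
  expect_identical(test_mean_form_difference(ga, gb, n_boot = 50, seed = 17),
                   tt)
})

test_that("inference preconditions and degenerate inputs are handled", {
  tpl <- make_template_form("box_8")
  ga <- simulate_group(tpl, 5, 0.05, "a", seed = 1)
  gb <- simulate_group(tpl, 5, 0.05, "b", seed = 2)
  one <- simulate_group(tpl, 1, 0.05, "a", seed = 3)

  expect_error(bootstrap_fdm_intervals(ga, gb, n_boot = 0, seed = 1),
               "positive integer")
  expect_error(test_mean_form_difference(ga, gb, n_boot = 0, seed = 1),
               "positive integer")
  expect_error(bootstrap_fdm_intervals(one, gb, n_boot = 10, seed = 1),
               "at least 2")
  expect_error(bootstrap_fdm_intervals(ga, gb, n_boot = 10, seed = 1,
                                       confidence_level = 1), "confidence")
  expect_error(bootstrap_fdm_intervals(ga, gb, n_boot = 10), "seed")

  sub <- extract_subset(gb, landmark_labels(gb)[1:4])
  expect_error(test_mean_form_difference(ga, sub, n_boot = 10, seed = 1),
               "share landmark labels")

  # two identical zero-variance groups: T = 1, p = 1
  dup <- simulate_group(tpl, 2, 0, "a", seed = 1)
  dup2 <- simulate_group(tpl, 2, 0, "b", seed = 1)
  tt <- test_mean_form_difference(dup, dup2, n_boot = 25, seed = 5)
  expect_identical(tt$statistic, 1)
  expect_identical(tt$p_value, 1)

  # add-one estimator keeps p in (0, 1]; a gross shape change at tiny
  # noise beats every pooled-null resample, so p hits the floor 1/(B+1)
  warped <- apply_regional_effect(tpl, c("c1", "c8"), "radial_scale", 0.5)
  strong <- simulate_group(warped, 10, 0.01, "a", seed = 4)
  base <- simulate_group(tpl, 10, 0.01, "b", seed = 5)
  tt2 <- test_mean_form_difference(strong, base, n_boot = 40, seed = 6)
  expect_identical(tt2$p_value, 1 / 41)
})

test_that("null self-comparison flags roughly the nominal fraction of distances", {
  tpl <- make_template_form("box_8")
  frac <- sapply(1:40, function(r) {
    ds <- simulate_group(tpl, 10, 0.05, "g", seed = 600 + r)
    copy <- landmark_dataset(ds$coords, setNames(rep("h", 10), specimen_ids(ds)))
    ci <- bootstrap_fdm_intervals(ds, copy, n_boot = 300,
                                  confidence_level = 0.90, seed = 700 + r)
    mean(ci$table$significant)
  })
  # pairs are correlated, so only a wide envelope around the nominal 10%
  expect_gte(mean(frac), 0)
  expect_lte(mean(frac), 0.35)
})

test_that("a strong uniform scaling makes every distance significant", {
  tpl <- make_template_form("mandible_16", 5)
  ga <- simulate_group(tpl * 1.2, 25, 0.05, "mutant", seed = 11)
  gb <- simulate_group(tpl, 25, 0.05, "unaffected", seed = 12)
  ci <- bootstrap_fdm_intervals(ga, gb, n_boot = 500, seed = 13)
  expect_true(all(ci$table$significant))
  expect_true(all(ci$table$lower > 1))
  # the max/min statistic measures ratio spread, so a pure size change
  # leaves it near 1 (noise only), far below the 1.2 scale factor
  tt <- test_mean_form_difference(ga, gb, n_boot = 200, seed = 14)
  expect_lt(tt$statistic, 1.1)
})

test_that("swapping group order inverts ratios and mirrors effect categories", {
  tpl <- make_template_form("mandible_16", 5)
  eff <- apply_regional_effect(tpl, rownames(tpl)[13:16], "radial_scale", 0.12)
  ga <- simulate_group(eff, 20, 0.04, "mutant", seed = 21)
  gb <- simulate_group(tpl, 20, 0.04, "unaffected", seed = 22)

  ab <- bootstrap_fdm_intervals(ga, gb, n_boot = 400, seed = 23)
  ba <- bootstrap_fdm_intervals(gb, ga, n_boot = 400, seed = 23)
  expect_equal(ba$table$ratio, 1 / ab$table$ratio, tolerance = 1e-12)

  cab <- table(classify_fdm_effects(ab)$table$category)
  cba <- table(classify_fdm_effects(ba)$table$category)
  expect_equal(unname(cab[["increase_gt10"]]), unname(cba[["decrease_gt10"]]))
  expect_equal(unname(cab[["decrease_5_10"]]), unname(cba[["increase_5_10"]]))
})

test_that("CI width shrinks as group size grows", {
  tpl <- make_template_form("box_8")
  width <- sapply(c(8, 32), function(n) {
    mean(sapply(1:5, function(r) {
      ga <- simulate_group(tpl, n, 0.06, "a", seed = 100 * n + r)
      gb <- simulate_group(tpl, n, 0.06, "b", seed = 100 * n + 50 + r)
      ci <- bootstrap_fdm_intervals(ga, gb, n_boot = 300, seed = r)
      mean(ci$table$upper - ci$table$lower)
    }))
  })
  expect_lt(width[2], width[1])
})

test_that("effect banding follows the 5% / 10% distance-map conventions", {
  ratios <- c(1.07, 1.12, 0.88, 1.50, 1.02, 0.93, 0.904, 1.10, 1.05)
  sig <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  cls <- classify_fdm_effects(fake_ci(ratios, sig))
  expect_equal(as.character(cls$table$category),
               c("increase_5_10",    # +7%, significant
                 "increase_gt10",    # +12%
                 "decrease_gt10",    # 0.88 < 1/1.10
                 "not_significant",  # large but not significant
                 "significant_lt5",  # significant yet below the 5% band
                 "decrease_5_10",    # 1/1.10 < 0.93 <= 1/1.05
                 "decrease_gt10",    # 0.904 < 1/1.10 (multiplicative bands)
                 "increase_gt10",    # boundary: ratio >= 1.10
                 "increase_5_10"))   # boundary: ratio >= 1.05

  # additive decrease bands move the 0.904 case up a band
  cls2 <- classify_fdm_effects(fake_ci(ratios, sig), decrease = "additive")
  expect_equal(as.character(cls2$table$category[7]), "decrease_5_10")

  # categories are exhaustive and counts sum to the pair count
  expect_equal(sum(cls$counts), length(ratios))
  expect_error(classify_fdm_effects(cls), "edma_ci")
  expect_error(classify_fdm_effects(fake_ci(1.1, TRUE), bands = c(0.1, 0.05)),
               "increasing")
})
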