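test_that("cohort generation is reproducible and well-formed", {
  vocab <- small_vocab()
  cfg <- cohort_config(vocab, n = 300, seed = 3)
  a <- generate_cohort(vocab, cfg)
  b <- generate_cohort(vocab, cfg)
  expect_identical(a, b)

  ind <- a[grep("^(cls|grp|gen|mnt)_", names(a))]
  expect_false(anyNA(a))
  expect_true(all(unlist(ind) %in% c(0L, 1L)))
  expect_true(all(a$cost >= 0))
  expect_true(all(a$risk_score > 0))
  expect_error(cohort_config(vocab, n = 1), "n")
})

test_that("aggregate indicators are exact ORs of member classes", {
  vocab <- small_vocab()
  co <- generate_cohort(vocab, cohort_config(vocab, n = 500, seed = 9))
  cls <- as.matrix(co[vocab$classes$class_id])
  for (g in vocab$group_ids) {
    members <- vocab$classes$class_id[vocab$classes$group_id == g]
    expect_equal(co[[g]],
                 as.integer(rowSums(cls[, members, drop = FALSE]) > 0))
  }
  for (ge in vocab$generic_ids) {
    members <- vocab$classes$class_id[vocab$classes$generic_id == ge]
    expect_equal(co[[ge]],
                 as.integer(rowSums(cls[, members, drop = FALSE]) > 0))
  }
})

test_that("zero-drug-spend fraction matches its configured rate", {
  vocab <- small_vocab()
  n <- 20000
  co <- generate_cohort(vocab, cohort_config(vocab, n = n, seed = 21))
  frac <- mean(co$drug_cost == 0)
  ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), ci)
  # zero drug spending implies no drug indicators at all
  cls <- as.matrix(co[vocab$classes$class_id])
  expect_true(all(rowSums(cls[co$drug_cost == 0, , drop = FALSE]) == 0))
})

test_that("raising a class cost effect cannot lower its users' mean cost", {
  vocab <- small_vocab()
  cfg1 <- cohort_config(vocab, n = 2000, seed = 5)
  eff2 <- cfg1$class_cost_effects
  eff2["cls_004"] <- eff2[["cls_004"]] + 4000
  cfg2 <- cohort_config(vocab, n = 2000, seed = 5, class_cost_effects = eff2)
  co1 <- generate_cohort(vocab, cfg1)
  co2 <- generate_cohort(vocab, cfg2)
  users <- co1$cls_004 == 1
  expect_identical(co1$cls_004, co2$cls_004)  # same seed, same indicators
  expect_gte(mean(co2$cost[users]), mean(co1$cost[users]))
})

test_that("full risk capture neutralizes class selection signal", {
  vocab <- small_vocab()
  ids <- vocab$classes$class_id
  cfg <- cohort_config(
    vocab, n = 40000, seed = 17,
    risk_capture = setNames(rep(1, length(ids)), ids),
    risk_noise_sd = 0,
    baseline_sdlog = 1.0,
    outlier_rate = 0
  )
  co <- add_plan_payments(generate_cohort(vocab, cfg))
  # pick the most prevalent class for power
  prev <- colMeans(co[ids])
  cl <- ids[which.max(prev)]
  users <- co[[cl]] == 1
  gap <- mean(co$unprofit[users]) - mean(co$unprofit[!users])
  se <- sqrt(var(co$unprofit[users]) / sum(users) +
             var(co$unprofit[!users]) / sum(!users))
  expect_lt(abs(gap), 4 * se)
})

test_that("cost moments converge to their configured values", {
  vocab <- small_vocab()
  cfg <- cohort_config(vocab, n = 100000, seed = 29, outlier_rate = 0)
  co <- generate_cohort(vocab, cfg)
  expected_mean <- cfg$baseline_mean +
    (1 - cfg$zero_drug_spend_frac) * cfg$drug_base_mean +
    sum(cfg$class_prevalences * cfg$class_cost_effects)
  expect_lt(abs(mean(co$cost) / expected_mean - 1), 0.03)
  expect_lt(abs(mean(co$risk_score) - 1), 1e-10)
})

test_that("empty and singleton-duplicating indicators are dropped", {
  vocab <- generate_vocabulary(10, 5, 2, 2)
  # hand-built 6-row table; cls_003/004 (all of grp_02), cls_005 (half of
  # grp_03) and cls_007 (half of grp_04) have no positive claims
  cls <- matrix(0L, 6, 10,
                dimnames = list(NULL, vocab$classes$class_id))
  active <- c("cls_001", "cls_002", "cls_006", "cls_008", "cls_009", "cls_010")
  for (j in seq_along(active)) cls[j, active[j]] <- 1L
  or_of <- function(assign_col, ids) {
    vapply(ids, function(a) {
      members <- vocab$classes$class_id[vocab$classes[[assign_col]] == a]
      as.integer(rowSums(cls[, members, drop = FALSE]) > 0)
    }, integer(6))
  }
  data <- dplyr::bind_cols(
    tibble::tibble(id = 1:6, cost = rep(100, 6), risk_score = rep(1, 6)),
    tibble::as_tibble(cls),
    tibble::as_tibble(or_of("group_id", vocab$group_ids)),
    tibble::as_tibble(or_of("generic_id", vocab$generic_ids)),
    tibble::as_tibble(or_of("maintenance_id", vocab$maintenance_ids))
  )
  attr(data, "vocabulary") <- vocab

  pruned <- suppressMessages(drop_empty_variables(data))
  kept <- names(pruned)[grepl("^(cls|grp)_", names(pruned))]
  expect_setequal(kept[startsWith(kept, "cls_")], active)
  # grp_02 empty, grp_03 and grp_04 singleton after the drops
  expect_setequal(kept[startsWith(kept, "grp_")], c("grp_01", "grp_05"))
  # vocabulary pruned in step
  v2 <- cohort_vocabulary(pruned)
  expect_setequal(v2$classes$class_id, active)
  expect_setequal(v2$group_ids, c("grp_01", "grp_05"))

  # a table with nothing to drop is unchanged
  clean <- suppressMessages(drop_empty_variables(pruned))
  expect_identical(names(clean), names(pruned))
})
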