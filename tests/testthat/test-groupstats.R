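test_that("variance-stabilising transforms are the documented closed forms", {
  expect_equal(apply_transform(0, "log1p"), 0)
  expect_equal(apply_transform(exp(1) - 1, "log1p"), 1)
  expect_equal(apply_transform(1, "arcsine_sqrt"), pi / 2)
  expect_equal(apply_transform(0.25, "arcsine_sqrt"), asin(0.5))
  expect_error(apply_transform(1.2, "arcsine_sqrt"), "\\[0, 1\\]")
  expect_equal(apply_transform(c(3, 4), "none"), c(3, 4))
})

test_that("assumption screening is calibrated and detects violations", {
  # well-behaved normal data pass both screens in >= 90% of seeds
  set.seed(2024)
  pass <- logical(1000)
  for (i in seq_len(1000)) {
    tb <- data.frame(treatment = rep(c("0", "3", "30", "300"), each = 3),
                     value = rnorm(12, mean = 100, sd = 5))
    pass[i] <- screen_assumptions(tb)$pass
  }
  expect_gte(mean(pass), 0.90)
  # a group with 100x the spread trips the Levene screen
  set.seed(9)
  tb <- data.frame(treatment = rep(c("a", "b", "c", "d"), each = 5),
                   value = c(rnorm(15, 10, 0.1), rnorm(5, 10, 10)))
  expect_lt(screen_assumptions(tb)$levene_p, 0.05)
  # constant values cannot be assessed
  tb <- data.frame(treatment = rep(c("a", "b"), each = 3), value = rep(1, 6))
  scr <- screen_assumptions(tb)
  expect_false(scr$assessable)
  expect_false(scr$pass)
  expect_error(screen_assumptions(data.frame(treatment = "a", value = 1)),
               "2 treatments")
})

test_that("the decision procedure branches and letters correctly", {
  # four identical groups: no separation, one shared letter, p in the 1 region
  tb <- data.frame(treatment = rep(c("0", "3", "30", "300"), each = 3),
                   value = rep(7, 12))
  res <- compare_groups(tb)
  expect_equal(res$omnibus$p, 1)
  expect_equal(length(unique(res$letters)), 1)
  # extreme separation: every pair gets its own letter
  set.seed(3)
  tb <- data.frame(treatment = rep(c("a", "b", "c"), each = 3),
                   value = c(0, 0, 0, 10, 10, 10, 20, 20, 20) + rnorm(9, 0, 1e-3))
  res <- compare_groups(tb)
  expect_equal(length(unique(res$letters)), 3)
  # heavy-tailed data fall through to Kruskal-Wallis + Dunn-Holm
  set.seed(8)
  tb <- data.frame(treatment = rep(c("a", "b", "c", "d"), each = 6),
                   value = rcauchy(24)^2)
  res <- compare_groups(tb)
  expect_equal(res$test_used, "KruskalWallis+Dunn-Holm")
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  # synthetic hormetic endpoint: the 30 mg group ranks highest
  ep <- simulate_endpoints(default_endpoint_params("SOD"), seed = 5)
  res <- compare_groups(ep)
  expect_equal(names(which.max(res$group_means)), "30")
})

test_that("Holm adjustment is monotone and order-preserving", {
  set.seed(4)
  v <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 3))
  g <- rep(c("a", "b", "c"), each = 5)
  d <- twosexlt:::.dunn_test(v, g)
  expect_true(all(d$p_adj >= d$p_raw))
  expect_equal(order(d$p_adj), order(d$p_raw))
  expect_true(all(d$p_adj >= 0 & d$p_adj <= 1))
  # agrees with stats::p.adjust on the raw values
  expect_equal(d$p_adj, p.adjust(d$p_raw, "holm"))
})

test_that("the full procedure holds its nominal type-I error under the null", {
  set.seed(777)
  nsim <- 2000
  reject <- logical(nsim)
  for (i in seq_len(nsim)) {
    tb <- data.frame(treatment = rep(c("0", "3", "30", "300"), each = 3),
                     value = rnorm(12, mean = 50, sd = 4))
    reject[i] <- compare_groups(tb)$omnibus$p < 0.05
  }
  band <- 2 * sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(mean(reject) - 0.05), band)
})

test_that("endpoint tables are compared per endpoint with a flat summary", {
  ep <- simulate_endpoint_table(seed = 6, endpoints = c("SOD", "MDA"))
  res <- compare_endpoints(ep)
  expect_named(res, c("MDA", "SOD"))
  summ <- attr(res, "summary")
  expect_equal(nrow(summ), 8)  # 2 endpoints x 4 treatments
  expect_true(all(c("test_used", "letters") %in% names(summ)))
})
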