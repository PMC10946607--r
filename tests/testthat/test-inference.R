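# Model-based tests on fabricated score tables (exact arithmetic oracles)
# and on simulated experiments (sanity of the quasi-GLM machinery).

test_that("median split reproduces the arithmetic oracle", {
  sc <- toy_scores(order_index = c(0.2, 0.4, 0.6, 0.8),
                   paternity_share = c(0.1, 0.3, 0.7, 0.9))
  ms <- median_split(sc)
  low <- ms[ms$side == "<= median", ]
  high <- ms[ms$side == "> median", ]
  expect_equal(low$mean_ps, mean(c(0.1, 0.3)))
  expect_equal(high$mean_ps, mean(c(0.7, 0.9)))
  expect_identical(low$n, 2L)
  expect_identical(high$n, 2L)
  expect_equal(low$se_ps, sd(c(0.1, 0.3)) / sqrt(2))
  # even counts with distinct values split evenly
  expect_identical(low$n, high$n)
})

test_that("median-split sides pool back to the group grand mean", {
  set.seed(11)
  sc <- toy_scores(order_index = runif(13), paternity_share = runif(13))
  ms <- median_split(sc)
  pooled <- sum(ms$mean_ps * ms$n) / sum(ms$n)
  expect_equal(pooled, mean(sc$paternity_share))
})

test_that("an all-tied order index collapses to one side with a warning", {
  sc <- toy_scores(order_index = rep(0.5, 5), paternity_share = runif(5))
  expect_warning(ms <- median_split(sc), class = "mq_one_sided_split")
  expect_identical(nrow(ms), 1L)
  expect_identical(ms$side, "<= median")
  expect_identical(ms$n, 5L)
})

test_that("order/repeat correlation matches the closed form", {
  sc <- toy_scores(order_index = c(0.1, 0.5, 0.9, 0.3),
                   paternity_share = runif(4),
                   repetitive_count = c(1, 5, 9, 3))
  expect_equal(unname(order_repeat_correlation(sc)$estimate), 1)
  set.seed(12)
  o <- runif(20); r <- rpois(20, 4)
  sc2 <- toy_scores(order_index = o, paternity_share = runif(20),
                    repetitive_count = r)
  ct <- order_repeat_correlation(sc2)
  r_oracle <- sum((o - mean(o)) * (r - mean(r))) /
    sqrt(sum((o - mean(o))^2) * sum((r - mean(r))^2))
  expect_equal(unname(ct$estimate), r_oracle, tolerance = 1e-12)
  expect_true(ct$p.value >= 0 && ct$p.value <= 1)
  sc3 <- toy_scores(order_index = rep(0.4, 5), paternity_share = runif(5))
  expect_error(order_repeat_correlation(sc3), class = "mq_degenerate_input")
})

test_that("quasi-GLM tables are well formed on simulated data", {
  d <- simulate_experiment("M", n_het = 10, n_hom = 8, seed = 14)
  sc <- focal_scores(d)
  for (mt in list(fit_order_glm(sc), fit_repeat_glm(sc))) {
    expect_s3_class(mt, "mq_model_table")
    expect_true(all(mt$terms$p_value >= 0 & mt$terms$p_value <= 1))
    expect_true(all(mt$terms$statistic >= 0))
    expect_true(all(mt$terms$df >= 1))
    expect_gt(mt$dispersion, 0)
  }
})

test_that("a constant response is refused before fitting", {
  sc <- toy_scores(order_index = rep(0.5, 8), paternity_share = runif(8),
                   social = rep(c("Hom", "Het"), 4))
  expect_error(fit_order_glm(sc), class = "mq_degenerate_response")
  sc$repetitive_count <- rep(2L, 8)
  expect_error(fit_repeat_glm(sc), class = "mq_degenerate_response")
})

test_that("backward selection leaves a single-term model unchanged", {
  set.seed(15)
  n <- 30
  x <- rnorm(n)
  y <- plogis(2 * x + rnorm(n, sd = 0.3))
  dat <- data.frame(y = y, x = x)
  fit <- do.call(glm, list(formula = y ~ x, family = quasibinomial(),
                           data = dat))
  sel <- select_model(fit)
  expect_identical(attr(terms(sel$fit), "term.labels"), "x")
  expect_identical(nrow(sel$trace), 1L)  # only the full model is logged
})

test_that("backward selection drops interactions before main effects", {
  d <- simulate_experiment("M", n_het = 10, n_hom = 8, seed = 16)
  sc <- focal_scores(d)
  sel <- select_model(fit_order_glm(sc))
  dropped <- sel$trace$dropped[-1]
  kept <- attr(terms(sel$fit), "term.labels")
  if ("social:focal_size" %in% kept) {
    # marginality respected: main effects stay while their interaction is in
    expect_true(all(c("social", "focal_size") %in% kept))
  } else if (length(dropped)) {
    main_pos <- match(c("social", "focal_size"), dropped)
    int_pos <- match("social:focal_size", dropped)
    if (!is.na(int_pos)) {
      expect_true(all(is.na(main_pos) | main_pos > int_pos))
    }
  }
  expect_true(all(diff(sel$trace$criterion) < 0))
})

test_that("interaction models need at least two treatment levels", {
  sc <- toy_scores(order_index = runif(10), paternity_share = runif(10),
                   social = "Hom", focal_size = "large")
  expect_error(interaction_models(sc), class = "mq_single_level")
})

test_that("interaction models recover a simulated steeper Het slope", {
  # Het vials get a strong order -> paternity relationship, Hom a flat one
  set.seed(17)
  n <- 60
  social <- rep(c("Hom", "Het"), each = n / 2)
  order_raw <- runif(n)
  slope <- ifelse(social == "Het", 0.8, 0.1)
  ps <- pmin(pmax(0.4 + slope * (order_raw - 0.5) + rnorm(n, sd = 0.03), 0), 1)
  sc <- toy_scores(order_index = order_raw, paternity_share = ps,
                   repetitive_count = rpois(n, 3), experiment = "M",
                   social = social)
  im <- interaction_models(sc)
  mt <- im$M$order
  co <- coef(mt$fit)
  # with Het as the reference level, the Hom interaction must be negative
  expect_lt(co[["order_std:socialHom"]], 0)
  p_int <- mt$terms$p_value[mt$terms$term == "order_std:social"]
  expect_lt(p_int, 0.05)
})

test_that("treatment-balanced null slopes centre on zero", {
  set.seed(18)
  diffs <- replicate(60, {
    n <- 40
    social <- rep(c("Hom", "Het"), each = n / 2)
    order_raw <- runif(n)
    ps <- pmin(pmax(0.5 + 0.4 * (order_raw - 0.5) + rnorm(n, sd = 0.1), 0), 1)
    sc <- toy_scores(order_index = order_raw, paternity_share = ps,
                     repetitive_count = rpois(n, 3), social = social)
    coef(interaction_models(sc)$M$order$fit)[["order_std:socialHom"]]
  })
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 0.02)
})

test_that("assortative test is exact-null on perfectly balanced matings", {
  # two HetF vials; the focal male mates each female size class equally often
  roster <- rbind(
    toy_roster(vial = "V1", female_sizes = c("large", "large", "small", "small")),
    toy_roster(vial = "V2", female_sizes = c("large", "large", "small", "small"))
  )
  roster$id <- paste0(roster$id, "_", roster$vial)
  # within each vial the two size classes get equal counts, but counts
  # differ between vials so the residual variance is positive
  ev <- rbind(
    toy_events(c(1, 1, "M1_V1", "F1_V1"), c(1, 2, "M1_V1", "F3_V1"),
               c(2, 1, "M1_V1", "F2_V1"), c(2, 2, "M1_V1", "F4_V1"), vial = "V1"),
    toy_events(c(1, 1, "M1_V2", "F2_V2"), c(1, 2, "M1_V2", "F4_V2"), vial = "V2")
  )
  d <- toy_dataset(events = ev, roster = roster)
  mt <- assortative_test(d)
  f_stat <- mt$terms$statistic[mt$terms$term == "female_size"]
  expect_equal(f_stat, 0, tolerance = 1e-12)
  # and a homogeneous-female dataset cannot be tested at all
  d_hom <- toy_dataset(events = toy_events(c(1, 1, "M1", "F1")))
  expect_error(assortative_test(d_hom), class = "mq_single_level")
})

test_that("a strong size-assortative preference is detected", {
  # large focal males mate large females 5x more often than small females
  set.seed(19)
  n_vials <- 12
  rosters <- list(); evs <- list()
  for (i in seq_len(n_vials)) {
    v <- paste0("V", i)
    r <- toy_roster(vial = v, female_sizes = c("large", "large", "small", "small"))
    r$id <- paste0(r$id, "_", v)
    rosters[[i]] <- r
    n_large <- rpois(1, 5); n_small <- rpois(1, 1)
    fem_large <- paste0(c("F1", "F2"), "_", v)
    fem_small <- paste0(c("F3", "F4"), "_", v)
    picks <- c(sample(fem_large, n_large, replace = TRUE),
               sample(fem_small, n_small, replace = TRUE))
    if (!length(picks)) next
    evs[[i]] <- data.frame(vial = v, day = 1L, seq = seq_along(picks),
                           male_id = paste0("M1_", v), female_id = picks,
                           stringsAsFactors = FALSE)
  }
  d <- toy_dataset(events = do.call(rbind, evs),
                   roster = do.call(rbind, rosters))
  mt <- assortative_test(d)
  expect_lt(mt$terms$p_value[mt$terms$term == "female_size"], 0.05)
})

test_that("Holm pairwise contrasts run only below the trigger", {
  set.seed(20)
  n <- 40
  g <- rep(c("Hom", "Het"), each = n / 2)
  y <- rnorm(n, mean = ifelse(g == "Het", 2, 0))
  dat <- data.frame(y = y, social = g)
  fit <- do.call(lm, list(formula = y ~ social, data = dat))
  mt <- matequeue:::model_table(fit, "toy")
  out <- pairwise_contrasts(mt, "social", trigger = 0.07)
  expect_s3_class(out, "data.frame")
  expect_identical(nrow(out), 1L)
  expect_lt(out$p.value, 0.05)
  # trigger not met -> NULL
  expect_null(pairwise_contrasts(mt, "social", trigger = 1e-12))
})

test_that("selection drops noise terms and keeps strong interactions", {
  set.seed(21)
  noise_dropped <- replicate(50, {
    n <- 40
    z <- rnorm(n); x <- rnorm(n)                      # z real, x pure noise
    y <- rpois(n, exp(0.5 + 0.6 * z))
    fit <- do.call(glm, list(formula = y ~ x + z, family = quasipoisson(),
                             data = data.frame(y = y, x = x, z = z)))
    !"x" %in% attr(terms(select_model(fit)$fit), "term.labels")
  })
  expect_gt(mean(noise_dropped), 0.5)

  int_kept <- replicate(50, {
    n <- 50
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + x2 + 2 * x1 * x2 + rnorm(n, sd = 0.5)
    fit <- do.call(lm, list(formula = y ~ x1 * x2,
                            data = data.frame(y = y, x1 = x1, x2 = x2)))
    "x1:x2" %in% attr(terms(select_model(fit)$fit), "term.labels")
  })
  expect_gte(mean(int_kept), 0.8)
})
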