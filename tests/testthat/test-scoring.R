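# Scoring rules: eligibility, the sperm-competition window, the carry-forward
# last-male indicator, repetitive matings and the fecundity covariates.

test_that("eligibility requires the focal male plus at least one rival", {
  d <- toy_dataset(events = toy_events(
    c(1, 1, "M1", "F1"),              # F1: focal only -> excluded
    c(1, 2, "M2", "F2"), c(2, 1, "M3", "F2"),  # F2: rivals only -> excluded
    c(1, 3, "M1", "F3"), c(3, 1, "M2", "F3")   # F3: focal d1 + rival d3 -> in
  ))
  expect_identical(eligible_females(d, "V1"), "F3")
})

test_that("competition starts when both a focal and a rival mating exist", {
  d <- toy_dataset(events = toy_events(
    c(1, 1, "M1", "F1"), c(3, 1, "M2", "F1"),   # focal d1, rival d3 -> 3
    c(1, 2, "M2", "F2"), c(2, 1, "M1", "F2"),   # rival d1, focal d2 -> 2
    c(1, 3, "M1", "F3"), c(1, 4, "M3", "F3")    # both d1 -> 1
  ))
  expect_identical(competition_start_day(d, "V1", "F1"), 3L)
  expect_identical(competition_start_day(d, "V1", "F2"), 2L)
  expect_identical(competition_start_day(d, "V1", "F3"), 1L)
  expect_identical(competition_start_day(d, "V1", "F4"), NA_integer_)
})

test_that("paternity share pools window counts (and averages on request)", {
  # F1 eligible from day 1; batches (wt 6, spa 2) and (wt 0, spa 2)
  d <- toy_dataset(
    events = toy_events(c(1, 1, "M1", "F1"), c(1, 2, "M2", "F1")),
    offspring = toy_offspring(c("F1", 1, 6, 2), c("F1", 2, 0, 2))
  )
  expect_equal(paternity_share(d, "V1"), 0.6)
  # per-female proportions: F1 = 6/10; add F2 with 1/1
  d2 <- toy_dataset(
    events = toy_events(c(1, 1, "M1", "F1"), c(1, 2, "M2", "F1"),
                        c(1, 3, "M1", "F2"), c(1, 4, "M4", "F2")),
    offspring = toy_offspring(c("F1", 1, 6, 2), c("F1", 2, 0, 2),
                              c("F2", 3, 1, 0))
  )
  expect_equal(paternity_share(d2, "V1", pooling = "pooled"), 7 / 11)
  expect_equal(paternity_share(d2, "V1", pooling = "per_female_mean"),
               mean(c(0.6, 1)))
})

test_that("offspring laid before the competition window are excluded", {
  # focal day 1, rival day 3: only lay-days 3 and 4 count
  d <- toy_dataset(
    events = toy_events(c(1, 1, "M1", "F1"), c(3, 1, "M2", "F1")),
    offspring = toy_offspring(c("F1", 1, 10, 0), c("F1", 2, 10, 0),
                              c("F1", 3, 2, 3), c("F1", 4, 1, 4))
  )
  expect_equal(paternity_share(d, "V1"), 3 / 10)
})

test_that("all-wild-type window offspring give a share of exactly 1", {
  d <- toy_dataset(
    events = toy_events(c(1, 1, "M2", "F1"), c(2, 1, "M1", "F1")),
    offspring = toy_offspring(c("F1", 2, 7, 0), c("F1", 3, 5, 0))
  )
  expect_identical(paternity_share(d, "V1"), 1)
})

test_that("order index carries the last male forward across silent days", {
  # rival d1 then focal d2, nothing after: indicator 1 on days 2, 3, 4
  d <- toy_dataset(events = toy_events(
    c(1, 1, "M2", "F1"), c(2, 1, "M1", "F1")
  ))
  expect_equal(order_index(d, "V1"), 1)
  # the mirror image: focal d1 then rival d2 -> 0 on days 2, 3, 4
  d2 <- toy_dataset(events = toy_events(
    c(1, 1, "M1", "F1"), c(2, 1, "M2", "F1")
  ))
  expect_equal(order_index(d2, "V1"), 0)
  # one all-1 female and one all-0 female with equal scored days -> 0.5
  d3 <- toy_dataset(events = toy_events(
    c(1, 1, "M2", "F1"), c(2, 1, "M1", "F1"),
    c(1, 2, "M1", "F2"), c(2, 2, "M3", "F2")
  ))
  expect_equal(order_index(d3, "V1"), 0.5)
})

test_that("within-day order is resolved by the copulation rank", {
  # both matings on day 1; focal is last by seq -> indicator 1 on all 4 days
  d <- toy_dataset(events = toy_events(
    c(1, 1, "M2", "F1"), c(1, 2, "M1", "F1")
  ))
  expect_equal(order_index(d, "V1"), 1)
  expect_identical(competition_start_day(d, "V1", "F1"), 1L)
})

test_that("the from-first-mating option scores pre-competition days too", {
  # rival d1, focal d3: competition window is days 3..4 (both 1);
  # from the first mating the rival holds days 1..2 (both 0)
  d <- toy_dataset(events = toy_events(
    c(1, 1, "M2", "F1"), c(3, 1, "M1", "F1")
  ))
  expect_equal(order_index(d, "V1", prestart = "exclude"), 1)
  expect_equal(order_index(d, "V1", prestart = "from_first"), 0.5)
})

test_that("repetitive matings count focal matings with eligible partners", {
  d <- toy_dataset(events = toy_events(
    c(1, 1, "M1", "F1"), c(1, 2, "M2", "F1"),
    c(2, 1, "M1", "F1"), c(3, 1, "M1", "F1"),   # 3 focal matings with F1
    c(1, 3, "M1", "F2"), c(2, 2, "M4", "F2"),   # 1 with F2
    c(1, 4, "M1", "F3")                          # F3 ineligible
  ))
  expect_identical(repetitive_count(d, "V1", "total"), 4L)
  expect_identical(repetitive_count(d, "V1", "rematings"), 2L)
  # single eligible female mated three times by the focal male
  d2 <- toy_dataset(events = toy_events(
    c(1, 1, "M1", "F1"), c(1, 2, "M2", "F1"),
    c(2, 1, "M1", "F1"), c(4, 1, "M1", "F1")
  ))
  expect_identical(repetitive_count(d2, "V1"), 3L)
  # no eligible females -> 0 under both conventions
  d3 <- toy_dataset(events = toy_events(c(1, 1, "M1", "F1")))
  expect_identical(repetitive_count(d3, "V1"), 0L)
  expect_identical(repetitive_count(d3, "V1", "rematings"), 0L)
})

test_that("a focal male who never mates has no order index and zero repeats", {
  d <- toy_dataset(events = toy_events(c(1, 1, "M2", "F1"), c(2, 1, "M3", "F1")))
  expect_identical(order_index(d, "V1"), NA_real_)
  expect_identical(paternity_share(d, "V1"), NA_real_)
  expect_identical(repetitive_count(d, "V1"), 0L)
  sc <- focal_scores(d)
  expect_identical(sc$n_eligible_females, 0L)
  expect_true(is.na(sc$mate_mean_fecundity))
})

test_that("standardize matches the closed form and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize(c(2, 2, 2)), class = "mq_degenerate_input")
  expect_error(standardize(3), class = "mq_degenerate_input")
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(20, mean = runif(1, -5, 5), sd = runif(1, 0.1, 10))
    z <- standardize(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
    expect_equal(standardize(z), z, tolerance = 1e-12)
  }
})

test_that("assortative count matches a brute-force event filter", {
  roster <- toy_roster(male_sizes = c("large", "small", "small", "large"),
                       female_sizes = c("large", "small", "large", "small"))
  set.seed(7)
  for (rep in 1:5) {
    n <- 12
    ev <- data.frame(vial = "V1",
                     day = sample(1:4, n, replace = TRUE),
                     seq = integer(n),
                     male_id = sample(paste0("M", 1:4), n, replace = TRUE),
                     female_id = sample(paste0("F", 1:4), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    ev <- ev[order(ev$day), ]
    ev$seq <- as.integer(stats::ave(seq_len(n), ev$day, FUN = seq_along))
    d <- toy_dataset(events = ev, roster = roster)
    fem_size <- setNames(roster$size_class[roster$sex == "female"],
                         roster$id[roster$sex == "female"])
    brute <- sum(ev$male_id == "M1" & fem_size[ev$female_id] == "large")
    expect_identical(assortative_count(d, "V1"), as.integer(brute))
  }
})

test_that("scores are invariant to event row order and to ineligible matings", {
  d <- simulate_experiment("M", n_het = 3, n_hom = 2, seed = 12)
  v <- d$design$vial[1]
  base <- list(ps = paternity_share(d, v), oi = order_index(d, v),
               rc = repetitive_count(d, v))
  perm <- mating_dataset(d$roster, d$events[sample(nrow(d$events)), ],
                         d$offspring, d$design)
  expect_equal(paternity_share(perm, v), base$ps)
  expect_equal(order_index(perm, v), base$oi)
  expect_equal(repetitive_count(perm, v), base$rc)

  # a new mating by a never-eligible female changes nothing: F2 only ever
  # mates rivals, before and after the extra event
  ev <- toy_events(c(1, 1, "M2", "F1"), c(2, 1, "M1", "F1"),
                   c(1, 2, "M3", "F2"))
  off <- toy_offspring(c("F1", 2, 5, 5), c("F2", 2, 0, 9))
  d3 <- toy_dataset(events = ev, offspring = off)
  d4 <- toy_dataset(events = rbind(ev, toy_events(c(4, 1, "M4", "F2"))),
                    offspring = off)
  expect_equal(paternity_share(d4, "V1"), paternity_share(d3, "V1"))
  expect_equal(order_index(d4, "V1"), order_index(d3, "V1"))
  expect_equal(repetitive_count(d4, "V1"), repetitive_count(d3, "V1"))
})

test_that("defined scores always lie in [0, 1] across simulated vials", {
  d <- simulate_experiment("FM", n_het = 10, n_hom = 5, seed = 33)
  sc <- focal_scores(d)
  ps <- sc$paternity_share[!is.na(sc$paternity_share)]
  oi <- sc$order_index[!is.na(sc$order_index)]
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(oi >= 0 & oi <= 1))
  expect_true(all(sc$repetitive_count >= 0))
  expect_true(all(sc$repetitive_count >= sc$n_eligible_females))
  expect_true(all(is.na(sc$paternity_share) == (sc$n_eligible_females == 0) |
                    sc$n_eligible_females > 0))
})

test_that("fecundity covariates average the right females", {
  d <- toy_dataset(
    events = toy_events(c(1, 1, "M1", "F1"), c(1, 2, "M2", "F1")),
    offspring = toy_offspring(c("F1", 1, 4, 6), c("F2", 1, 0, 8),
                              c("F3", 2, 0, 2))
  )
  sc <- focal_scores(d)
  expect_equal(sc$group_mean_fecundity, (10 + 8 + 2 + 0) / 4)
  expect_equal(sc$mate_mean_fecundity, 10)  # F1 is the only eligible mate
})
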