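# Focal-male scores derived from the mating log and offspring counts.
#
# All scores are conditioned on "eligible" females -- those that mated the
# focal male and at least one rival -- because only their offspring are under
# sperm competition that involves the focal male.

vial_context <- function(dataset, vial) {
  roster <- dataset$roster
  if (!vial %in% roster$vial) {
    mq_error("mq_unknown_vial", sprintf("vial %s not in dataset", vial))
  }
  rv <- roster[roster$vial == vial, ]
  ev <- dataset$events[dataset$events$vial == vial, , drop = FALSE]
  ev <- ev[order(ev$day, ev$seq), , drop = FALSE]
  off <- dataset$offspring[dataset$offspring$vial == vial, , drop = FALSE]
  list(
    roster = rv,
    events = ev,
    offspring = off,
    focal_id = rv$id[rv$role == "focal_male"],
    females = rv[rv$sex == "female", , drop = FALSE],
    days = attr(dataset, "days")
  )
}

#' Females under focal-male sperm competition
#'
#' A female is eligible when, across all days, she mated with at least two
#' males, one of them the focal male -- i.e. she mated the focal male at
#' least once and at least one rival male at least once. Only these females'
#' offspring can express sperm competition involving the focal male.
#'
#' @param dataset a `mating_dataset`.
#' @param vial vial identifier.
#' @return character vector of eligible female ids (possibly empty).
#' @export
eligible_females <- function(dataset, vial) {
  ctx <- vial_context(dataset, vial)
  ev <- ctx$events
  if (!nrow(ev)) return(character(0))
  mated_focal <- unique(ev$female_id[ev$male_id == ctx$focal_id])
  mated_rival <- unique(ev$female_id[ev$male_id != ctx$focal_id])
  sort(intersect(mated_focal, mated_rival))
}

#' First day on which sperm competition is possible for a female
#'
#' Returns the earliest day `d` such that, by the end of day `d`, the female
#' has mated both the focal male and at least one rival. Offspring laid from
#' this day onwards are under direct sperm competition; for example a female
#' who mates the focal male on day 1 and a rival on day 3 enters the window
#' on day 3. Returns `NA` for females that never meet the eligibility
#' condition.
#'
#' @inheritParams eligible_females
#' @param female_id female identifier.
#' @return integer day, or `NA_integer_`.
#' @export
competition_start_day <- function(dataset, vial, female_id) {
  ctx <- vial_context(dataset, vial)
  ev <- ctx$events[ctx$events$female_id == female_id, , drop = FALSE]
  if (!nrow(ev)) return(NA_integer_)
  d_focal <- suppressWarnings(min(ev$day[ev$male_id == ctx$focal_id]))
  d_rival <- suppressWarnings(min(ev$day[ev$male_id != ctx$focal_id]))
  if (!is.finite(d_focal) || !is.finite(d_rival)) return(NA_integer_)
  as.integer(max(d_focal, d_rival))
}

#' Focal-male paternity share under sperm competition
#'
#' The proportion of offspring sired by the focal male (wild-type eye
#' phenotype, dominant over the recessive *spa* marker carried by rivals and
#' females), counted only where sperm competition involving the focal male
#' was possible: offspring batches of eligible females laid on or after that
#' female's [competition_start_day()].
#'
#' With `pooling = "pooled"` (default) the share is the ratio of summed
#' counts, `sum(wt) / sum(wt + spa)`, over all contributing female-days; with
#' `"per_female_mean"` it is the unweighted mean of each eligible female's
#' own proportion (females whose window batches total zero offspring are
#' dropped from the mean).
#'
#' @inheritParams eligible_females
#' @param pooling `"pooled"` or `"per_female_mean"`.
#' @return proportion in `[0, 1]`, or `NA_real_` when no eligible female has
#'   a positive offspring total inside her competition window.
#' @export
paternity_share <- function(dataset, vial,
                            pooling = c("pooled", "per_female_mean")) {
  pooling <- match.arg(pooling)
  elig <- eligible_females(dataset, vial)
  if (!length(elig)) return(NA_real_)
  off <- dataset$offspring[dataset$offspring$vial == vial, , drop = FALSE]
  per <- vapply(elig, function(f) {
    start <- competition_start_day(dataset, vial, f)
    b <- off[off$female_id == f & off$lay_day >= start, , drop = FALSE]
    c(wt = sum(b$count_wildtype), tot = sum(b$count_wildtype + b$count_spa))
  }, numeric(2))
  if (pooling == "pooled") {
    tot <- sum(per["tot", ])
    if (tot == 0) return(NA_real_)
    sum(per["wt", ]) / tot
  } else {
    ok <- per["tot", ] > 0
    if (!any(ok)) return(NA_real_)
    mean(per["wt", ok] / per["tot", ok])
  }
}

# last male to have mated `female` by the end of day d, or NA if unmated
last_male_by_day <- function(ev_female, d) {
  e <- ev_female[ev_female$day <= d, , drop = FALSE]
  if (!nrow(e)) return(NA_character_)
  e$male_id[which.max(e$day * 1e6 + e$seq)]
}

#' Focal-male mating-order index
#'
#' For each eligible female and each day in her scoring range, an indicator
#' is 1 if the focal male was the last male to have mated her by the end of
#' that day (within-day order resolved by the copulation rank `seq`), else 0.
#' Last-male status carries forward automatically: a female who stops mating
#' keeps scoring her last mate on every remaining day. The index is the mean
#' of these indicators pooled over all scored female-days; values near 1 mean
#' the focal male typically held the last-male position.
#'
#' The scoring range defaults to the days on which sperm competition was
#' possible (`prestart = "exclude"`, range
#' [competition_start_day()] .. last day). `prestart = "from_first"` instead
#' scores from the female's first mating day.
#'
#' @inheritParams eligible_females
#' @param prestart `"exclude"` (default) or `"from_first"`.
#' @return proportion in `[0, 1]`, or `NA_real_` when there are no scored
#'   female-days.
#' @export
order_index <- function(dataset, vial, prestart = c("exclude", "from_first")) {
  prestart <- match.arg(prestart)
  ctx <- vial_context(dataset, vial)
  elig <- eligible_females(dataset, vial)
  if (!length(elig)) return(NA_real_)
  indicators <- unlist(lapply(elig, function(f) {
    evf <- ctx$events[ctx$events$female_id == f, , drop = FALSE]
    start <- switch(prestart,
                    exclude = competition_start_day(dataset, vial, f),
                    from_first = min(evf$day))
    vapply(seq.int(start, ctx$days), function(d) {
      as.numeric(identical(last_male_by_day(evf, d), ctx$focal_id))
    }, numeric(1))
  }))
  if (!length(indicators)) return(NA_real_)
  mean(indicators)
}

#' Focal-male repetitive matings
#'
#' The sum over eligible females (mates that also mated rival males) of the
#' number of matings the focal male had with each. Under the default
#' `"total"` convention every focal mating with an eligible partner counts;
#' `"rematings"` counts only matings beyond the first with each such partner
#' (total minus the number of eligible females).
#'
#' @inheritParams eligible_females
#' @param convention `"total"` (default) or `"rematings"`.
#' @return non-negative integer.
#' @export
repetitive_count <- function(dataset, vial,
                             convention = c("total", "rematings")) {
  convention <- match.arg(convention)
  ctx <- vial_context(dataset, vial)
  elig <- eligible_females(dataset, vial)
  if (!length(elig)) return(0L)
  ev <- ctx$events
  total <- sum(ev$male_id == ctx$focal_id & ev$female_id %in% elig)
  if (convention == "total") as.integer(total)
  else as.integer(total - length(elig))
}

#' Size-assortative matings by the focal male
#'
#' Number of focal-male copulations in which the female's size class matched
#' the focal male's own size class.
#'
#' @inheritParams eligible_females
#' @return non-negative integer.
#' @export
assortative_count <- function(dataset, vial) {
  ctx <- vial_context(dataset, vial)
  ev <- ctx$events[ctx$events$male_id == ctx$focal_id, , drop = FALSE]
  if (!nrow(ev)) return(0L)
  focal_size <- ctx$roster$size_class[ctx$roster$role == "focal_male"]
  fem_size <- ctx$females$size_class[match(ev$female_id, ctx$females$id)]
  as.integer(sum(fem_size == focal_size))
}

#' Standardize a numeric vector (z-scores)
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (denominator `n - 1`). Used throughout so that mating order and repetitive
#' matings enter models on a common scale.
#'
#' @param x numeric vector with at least two finite values.
#' @return numeric vector with mean 0 and sd 1.
#' @export
standardize <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) {
    mq_error("mq_degenerate_input",
             "standardize needs at least two finite values")
  }
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    mq_error("mq_degenerate_input",
             "standardize is undefined for a zero-variance vector")
  }
  (x - mean(x[ok])) / s
}

#' Per-vial focal-male score table
#'
#' Computes every per-vial statistic the downstream analyses consume:
#' paternity share, mating-order index, repetitive matings, the number of
#' eligible females, total focal matings, size-assortative matings, and two
#' fecundity covariates -- `group_mean_fecundity` (mean total offspring over
#' all four females in the vial) and `mate_mean_fecundity` (mean total
#' offspring of the focal male's competition-eligible mates). Design labels
#' are joined on.
#'
#' @param dataset a `mating_dataset`.
#' @param ps_pooling passed to [paternity_share()].
#' @param repetitive passed to [repetitive_count()].
#' @param order_prestart passed to [order_index()].
#' @return data frame, one row per vial.
#' @export
#' @examples
#' d <- simulate_experiment("FM", n_het = 4, n_hom = 2, seed = 7)
#' head(focal_scores(d))
focal_scores <- function(dataset,
                         ps_pooling = c("pooled", "per_female_mean"),
                         repetitive = c("total", "rematings"),
                         order_prestart = c("exclude", "from_first")) {
  ps_pooling <- match.arg(ps_pooling)
  repetitive <- match.arg(repetitive)
  order_prestart <- match.arg(order_prestart)
  vials <- sort(unique(dataset$roster$vial))
  rows <- lapply(vials, function(v) {
    ctx <- vial_context(dataset, v)
    elig <- eligible_females(dataset, v)
    off <- ctx$offspring
    fem_tot <- vapply(ctx$females$id, function(f) {
      sum(off$count_wildtype[off$female_id == f]) +
        sum(off$count_spa[off$female_id == f])
    }, numeric(1))
    data.frame(
      vial = v,
      focal_id = ctx$focal_id,
      paternity_share = paternity_share(dataset, v, ps_pooling),
      order_index = order_index(dataset, v, order_prestart),
      repetitive_count = repetitive_count(dataset, v, repetitive),
      n_eligible_females = length(elig),
      n_focal_matings = sum(ctx$events$male_id == ctx$focal_id),
      assortative_count = assortative_count(dataset, v),
      group_mean_fecundity = mean(fem_tot),
      mate_mean_fecundity = if (length(elig))
        mean(fem_tot[match(elig, ctx$females$id)]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  scores <- do.call(rbind, rows)
  merge(dataset$design, scores, by = "vial", sort = TRUE)
}
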