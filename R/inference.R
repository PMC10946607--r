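# Model-based tests: quasi-binomial / quasi-Poisson GLMs of the focal-male
# scores on group composition, AIC-guided backward selection, interaction
# models of paternity share on standardized scores, the assortative-mating
# ANOVA, the order/repeat collinearity check and the median-split summary.

# build "resp ~ social * focal_size + covariate", dropping factors with a
# single observed level
composition_formula <- function(scores, response, covariate) {
  terms <- character(0)
  two_levels <- function(col) length(unique(stats::na.omit(scores[[col]]))) > 1L
  if (two_levels("social") && two_levels("focal_size")) {
    terms <- "social * focal_size"
  } else if (two_levels("social")) {
    terms <- "social"
  } else if (two_levels("focal_size")) {
    terms <- "focal_size"
  }
  terms <- c(terms, covariate)
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

# F-tests on dispersion-scaled deviance differences for every term
model_table <- function(fit, name) {
  at <- stats::anova(fit, test = "F")
  is_lm <- inherits(fit, "lm") && !inherits(fit, "glm")
  if (is_lm) {
    tab <- data.frame(term = rownames(at),
                      df = at$Df,
                      statistic = at$`F value`,
                      den_df = stats::df.residual(fit),
                      p_value = at$`Pr(>F)`)
    tab <- tab[tab$term != "Residuals", , drop = FALSE]
    dispersion <- summary(fit)$sigma^2
  } else {
    tab <- data.frame(term = rownames(at),
                      df = at$Df,
                      statistic = at$F,
                      den_df = stats::df.residual(fit),
                      p_value = at$`Pr(>F)`)
    tab <- tab[tab$term != "NULL", , drop = FALSE]
    dispersion <- summary(fit)$dispersion
  }
  rownames(tab) <- NULL
  structure(list(model = name, terms = tab, dispersion = dispersion,
                 fit = fit, trace = NULL),
            class = "mq_model_table")
}

#' @export
print.mq_model_table <- function(x, digits = 4, ...) {
  cat("Model:", x$model, "\n")
  cat("dispersion:", format(x$dispersion, digits = digits), "\n")
  print(x$terms, digits = digits, row.names = FALSE)
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("selection trace:\n")
    print(x$trace, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

check_model_rows <- function(scores, response) {
  s <- scores[is.finite(scores[[response]]), , drop = FALSE]
  if (nrow(s) < 4L) {
    mq_error("mq_degenerate_input",
             sprintf("too few vials with defined %s (%d)", response, nrow(s)))
  }
  if (stats::var(s[[response]]) == 0) {
    mq_error("mq_degenerate_response",
             sprintf("%s is constant across vials; nothing to model", response))
  }
  s
}

#' Quasi-binomial model of the mating-order index
#'
#' Fits the focal male's mating-order index (a proportion of female-days in
#' the last-male position) on group composition (`social`, Hom vs Het),
#' focal-male size and their interaction, controlling for mean group
#' fecundity, with a quasi-binomial error structure to absorb
#' over-dispersion. Terms are tested with F statistics on dispersion-scaled
#' deviance differences. The index enters as a continuous proportion without
#' weights by default; `weight_by_days = TRUE` weights each vial by its
#' number of scored female-days.
#'
#' @param scores score table from [focal_scores()], typically one experiment.
#' @param covariate fecundity covariate column (default
#'   `"group_mean_fecundity"`).
#' @param weight_by_days weight vials by scored female-days (approximated by
#'   the number of eligible females times days scored; default `FALSE`).
#' @return an `mq_model_table`.
#' @export
fit_order_glm <- function(scores, covariate = "group_mean_fecundity",
                          weight_by_days = FALSE) {
  s <- check_model_rows(scores, "order_index")
  f <- composition_formula(s, "order_index", covariate)
  args <- list(formula = f, family = stats::quasibinomial(), data = s)
  if (weight_by_days) args$weights <- pmax(s$n_eligible_females, 1L)
  fit <- suppressWarnings(do.call(stats::glm, args))
  model_table(fit, "order_index ~ composition (quasi-binomial)")
}

#' Quasi-Poisson model of repetitive matings
#'
#' As [fit_order_glm()] but for the focal male's repetitive-mating count,
#' with a quasi-Poisson error structure.
#'
#' @inheritParams fit_order_glm
#' @return an `mq_model_table`.
#' @export
fit_repeat_glm <- function(scores, covariate = "group_mean_fecundity") {
  s <- check_model_rows(scores, "repetitive_count")
  f <- composition_formula(s, "repetitive_count", covariate)
  fit <- do.call(stats::glm,
                 list(formula = f, family = stats::quasipoisson(), data = s))
  model_table(fit, "repetitive_count ~ composition (quasi-Poisson)")
}

paired_family <- function(fit) {
  switch(stats::family(fit)$family,
         quasibinomial = stats::binomial(),
         quasipoisson = stats::poisson(),
         NULL)
}

model_criterion <- function(fit, criterion, c_hat = NULL) {
  fam <- paired_family(fit)
  if (is.null(fam)) return(stats::AIC(fit))
  refit <- suppressWarnings(
    stats::update(fit, family = fam))
  ll <- as.numeric(stats::logLik(refit))
  k <- attr(stats::logLik(refit), "df")
  if (criterion == "qaic") {
    stopifnot(!is.null(c_hat), c_hat > 0)
    -2 * ll / c_hat + 2 * k
  } else {
    -2 * ll + 2 * k
  }
}

#' Backward model selection by AIC
#'
#' Backward single-term elimination. Candidate deletions respect marginality
#' (interactions are considered before the main effects they contain, as in
#' [stats::drop1()]). Because the AIC is undefined under quasi-likelihood,
#' the criterion for quasi fits is computed on the paired non-quasi refit
#' (binomial for quasi-binomial, Poisson for quasi-Poisson) while the
#' selected model itself is refitted and returned with the original quasi
#' family; `criterion = "qaic"` instead penalises by the full model's
#' dispersion estimate. Ordinary `lm`/`glm` fits use their own AIC.
#'
#' @param x an `mq_model_table` or a fitted model.
#' @param criterion `"aic"` (default) or `"qaic"`.
#' @return an `mq_model_table` for the selected model, with the elimination
#'   trace in `$trace`.
#' @export
select_model <- function(x, criterion = c("aic", "qaic")) {
  criterion <- match.arg(criterion)
  fit <- if (inherits(x, "mq_model_table")) x$fit else x
  name <- if (inherits(x, "mq_model_table")) x$model else deparse(stats::formula(fit))
  c_hat <- tryCatch(summary(fit)$dispersion, error = function(e) NULL)
  current <- model_criterion(fit, criterion, c_hat)
  trace <- data.frame(step = 0L, dropped = "<full>", criterion = current,
                      stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    droppable <- rownames(stats::drop1(fit, test = "none"))
    droppable <- setdiff(droppable, "<none>")
    if (!length(droppable)) break
    crit <- vapply(droppable, function(tm) {
      reduced <- suppressWarnings(
        stats::update(fit, stats::as.formula(paste(". ~ . -", tm))))
      model_criterion(reduced, criterion, c_hat)
    }, numeric(1))
    best <- which.min(crit)
    if (crit[best] >= current) break
    step_i <- step_i + 1L
    fit <- suppressWarnings(
      stats::update(fit, stats::as.formula(paste(". ~ . -", droppable[best]))))
    current <- crit[best]
    trace <- rbind(trace, data.frame(step = step_i, dropped = droppable[best],
                                     criterion = current))
  }
  out <- model_table(fit, paste(name, "[selected]"))
  out$trace <- trace
  out
}

#' Interaction models of paternity share on standardized scores
#'
#' For each experiment in the score table, fits two linear models of
#' paternity share: one on the standardized mating-order index and one on
#' standardized repetitive matings, each interacting with the group-
#' composition factors. Where only `social` varies (female-size experiment)
#' the interaction is `score * social`; where focal-male size varies too,
#' both two-way interactions `score * social + score * focal_size` enter.
#' Scores are standardized within experiment.
#'
#' @param scores score table from [focal_scores()].
#' @return named list (by experiment) of lists with elements `order` and
#'   `repet`, each an `mq_model_table`.
#' @export
interaction_models <- function(scores) {
  out <- list()
  for (exp_code in unique(scores$experiment)) {
    s <- scores[scores$experiment %in% exp_code, , drop = FALSE]
    s <- s[stats::complete.cases(
      s[c("paternity_share", "order_index", "repetitive_count")]), , drop = FALSE]
    if (nrow(s) < 6L) {
      mq_error("mq_degenerate_input",
               sprintf("experiment %s has too few complete vials (%d)",
                       exp_code, nrow(s)))
    }
    n_social <- length(unique(s$social))
    n_size <- length(unique(s$focal_size))
    if (n_social < 2L && n_size < 2L) {
      mq_error("mq_single_level",
               sprintf("experiment %s has a single treatment level; interaction inestimable",
                       exp_code))
    }
    s$order_std <- standardize(s$order_index)
    s$repeat_std <- standardize(s$repetitive_count)
    rhs <- function(score) {
      parts <- character(0)
      if (n_social > 1L) parts <- c(parts, paste(score, "* social"))
      if (n_size > 1L) parts <- c(parts, paste(score, "* focal_size"))
      paste(parts, collapse = " + ")
    }
    fit1 <- do.call(stats::lm, list(
      formula = stats::as.formula(paste("paternity_share ~", rhs("order_std"))),
      data = s))
    fit2 <- do.call(stats::lm, list(
      formula = stats::as.formula(paste("paternity_share ~", rhs("repeat_std"))),
      data = s))
    out[[exp_code]] <- list(
      order = model_table(fit1, sprintf("[%s] paternity ~ order_std x composition", exp_code)),
      repet = model_table(fit2, sprintf("[%s] paternity ~ repeat_std x composition", exp_code))
    )
  }
  out
}

#' Median-split summary of paternity share by mating-order position
#'
#' Within each group, vials are split at the group median of the mating-order
#' index: vials at or below the median (focal male more often in a non-last
#' position) versus above it (more often last). For each side the mean
#' paternity share, its standard error (`sd / sqrt(n)`) and `n` are reported.
#' When every vial in a group has the same order index the group collapses to
#' one side and a warning is issued.
#'
#' @param scores score table.
#' @param group_cols columns defining the groups (default
#'   `c("experiment", "social")`).
#' @return data frame with one row per group x side.
#' @export
median_split <- function(scores, group_cols = c("experiment", "social")) {
  s <- scores[stats::complete.cases(
    scores[c("paternity_share", "order_index")]), , drop = FALSE]
  key <- interaction(s[group_cols], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(s, key), function(g) {
    med <- stats::median(g$order_index)
    side <- ifelse(g$order_index <= med, "<= median", "> median")
    if (length(unique(side)) == 1L) {
      mq_warn("mq_one_sided_split",
              sprintf("group %s: all order indices identical; one-sided split",
                      paste(unlist(g[1, group_cols]), collapse = "/")))
    }
    parts <- lapply(split(g$paternity_share, side), function(ps) {
      data.frame(mean_ps = mean(ps),
                 se_ps = stats::sd(ps) / sqrt(length(ps)),
                 n = length(ps))
    })
    cbind(g[rep(1, length(parts)), group_cols, drop = FALSE],
          data.frame(median_order = med, side = names(parts)),
          do.call(rbind, parts))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between mating order and repetitive matings
#'
#' Pearson correlation with its t-test: the collinearity check run before
#' entering both scores into the same paternity model.
#'
#' @param scores score table.
#' @return `htest` object from [stats::cor.test()].
#' @export
order_repeat_correlation <- function(scores) {
  s <- scores[stats::complete.cases(
    scores[c("order_index", "repetitive_count")]), , drop = FALSE]
  if (nrow(s) < 3L) {
    mq_error("mq_degenerate_input", "need at least 3 vials for a correlation")
  }
  if (stats::var(s$order_index) == 0 || stats::var(s$repetitive_count) == 0) {
    mq_error("mq_degenerate_input",
             "zero variance in one of the scores; correlation undefined")
  }
  stats::cor.test(s$order_index, s$repetitive_count, method = "pearson")
}

# per-vial focal matings split by female size class (rows only for size
# classes present among the vial's females)
assortative_long <- function(dataset) {
  vials <- sort(unique(dataset$roster$vial))
  rows <- lapply(vials, function(v) {
    ctx <- vial_context(dataset, v)
    focal_size <- ctx$roster$size_class[ctx$roster$role == "focal_male"]
    ev <- ctx$events[ctx$events$male_id == ctx$focal_id, , drop = FALSE]
    fem_sizes <- sort(unique(ctx$females$size_class))
    mated_sizes <- ctx$females$size_class[match(ev$female_id, ctx$females$id)]
    data.frame(vial = v, focal_size = focal_size, female_size = fem_sizes,
               n_matings = vapply(fem_sizes,
                                  function(sz) sum(mated_sizes == sz),
                                  numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ANOVA test for size-assortative mating
#'
#' Tests whether focal males direct more matings towards females of a
#' particular size class, using vials in which both female size classes were
#' present (the heterogeneous-female treatments). The response is the
#' focal male's mating count per female size class within each vial. For the
#' female-size experiment the model is `n_matings ~ female_size`; where focal
#' male size also varies the `female_size * focal_size` interaction tests
#' whether large and small focal males prefer same-size females.
#'
#' @param dataset a `mating_dataset`.
#' @return an `mq_model_table` from the fitted [stats::aov()].
#' @export
assortative_test <- function(dataset) {
  long <- assortative_long(dataset)
  both <- names(which(table(unique(long[c("vial", "female_size")])$vial) == 2L))
  long <- long[long$vial %in% both, , drop = FALSE]
  if (!nrow(long) || length(unique(long$female_size)) < 2L) {
    mq_error("mq_single_level",
             "no vials with both female size classes; assortative test inestimable")
  }
  f <- if (length(unique(long$focal_size)) > 1L) {
    n_matings ~ female_size * focal_size
  } else {
    n_matings ~ female_size
  }
  model_table(do.call(stats::lm, list(formula = f, data = long)),
              "assortative matings ~ female size")
}

#' Holm-corrected pairwise contrasts
#'
#' Replacement for sequential range-based post-hoc tests: all pairwise
#' comparisons of a factor's (or factor combination's) cell means from a
#' fitted model, with Holm-adjusted p-values via \pkg{emmeans}. By
#' convention the contrasts are only run when the omnibus F-test p-value
#' falls below `trigger` (default 0.07, covering marginally non-significant
#' effects); pass `trigger = 1` to run unconditionally.
#'
#' @param x an `mq_model_table`.
#' @param term character, the factor term to compare (e.g. `"social"` or
#'   `"social:focal_size"`).
#' @param trigger omnibus p-value threshold for running the contrasts.
#' @return data frame of contrasts, or `NULL` when the trigger is not met.
#' @export
pairwise_contrasts <- function(x, term, trigger = 0.07) {
  stopifnot(inherits(x, "mq_model_table"))
  if (!requireNamespace("emmeans", quietly = TRUE)) {
    mq_error("mq_bad_value", "pairwise_contrasts requires the emmeans package")
  }
  p_omni <- x$terms$p_value[x$terms$term == term]
  if (!length(p_omni)) {
    mq_error("mq_bad_value", sprintf("term '%s' not in the model table", term))
  }
  if (p_omni >= trigger) return(NULL)
  spec <- stats::as.formula(paste("~", gsub(":", "*", term)))
  em <- emmeans::emmeans(x$fit, spec)
  as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "holm"))
}
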