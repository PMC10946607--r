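# Commonality analysis: all-possible-subsets decomposition of a linear
# model's R-squared into unique and shared (common) components.
#
# The decomposition is defined by the linear system
#     R2(W) = sum over subsets S with S n W != 0 of C(S),   for every W,
# whose unique solution is obtained in closed form by Moebius inversion:
# with P the full predictor set and R2(empty) = 0,
#     C(S) = sum_{T subset of S} (-1)^(|S|-|T|+1) R2(P \ T).
# Subsets are indexed by bitmask for the enumeration and the verification
# of the defining system (a fast zeta transform), so the identity is checked
# on every run rather than assumed.

subset_key <- function(mask, predictors) {
  paste(predictors[bitwAnd(mask, bitwShiftL(1L, seq_along(predictors) - 1L)) != 0L],
        collapse = "+")
}

#' Coefficient of determination of an ordinary least-squares fit
#'
#' Fits `response ~ intercept + design` by QR decomposition and returns the
#' R-squared. A rank-deficient design (e.g. duplicated predictor columns)
#' raises a singularity error rather than silently dropping columns.
#'
#' @param response numeric vector.
#' @param design numeric matrix or data frame of predictors (may have zero
#'   columns, giving the intercept-only model with R-squared 0).
#' @return R-squared in `[0, 1]`.
#' @export
fit_r2 <- function(response, design) {
  y <- as.numeric(response)
  X <- as.matrix(design)
  if (anyNA(y) || anyNA(X)) {
    mq_error("mq_degenerate_input", "fit_r2 does not accept missing values")
  }
  n <- length(y)
  if (n <= ncol(X) + 1L) {
    mq_error("mq_degenerate_input",
             "need more observations than predictors plus intercept")
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    mq_error("mq_degenerate_input", "response has zero variance")
  }
  if (ncol(X) == 0L) return(0)
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    mq_error("mq_singular_design",
             "model matrix is rank deficient (collinear predictors)")
  }
  res <- qr.resid(qx, y)
  max(0, min(1, 1 - sum(res^2) / tss))
}

#' R-squared of every non-empty predictor subset
#'
#' Evaluates [fit_r2()] on the design restricted to each of the `2^k - 1`
#' non-empty subsets of the `k` predictors. Guarded at `k <= 15`.
#'
#' @inheritParams fit_r2
#' @return named numeric vector; names are predictor names joined by `"+"`
#'   in the original column order, with attribute `predictors`.
#' @export
all_subsets_r2 <- function(response, design) {
  X <- as.matrix(design)
  predictors <- colnames(X)
  if (is.null(predictors) || any(predictors == "")) {
    mq_error("mq_bad_value", "design columns must be named")
  }
  k <- ncol(X)
  if (k > 15L) {
    mq_error("mq_too_many_predictors",
             sprintf("subset enumeration guarded at k <= 15 (got k = %d)", k))
  }
  masks <- seq_len(bitwShiftL(1L, k) - 1L)
  r2 <- vapply(masks, function(m) {
    cols <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    fit_r2(response, X[, cols, drop = FALSE])
  }, numeric(1))
  names(r2) <- vapply(masks, subset_key, character(1), predictors = predictors)
  attr(r2, "predictors") <- predictors
  r2
}

#' Commonality coefficients from subset R-squared values
#'
#' Solves the defining system of commonality analysis -- for every non-empty
#' subset `W` of predictors, `R2(W)` equals the sum of the commonality
#' coefficients of all subsets intersecting `W` -- by Moebius inversion.
#' Coefficients of singleton subsets are the predictors' unique
#' contributions; larger subsets carry the variance shared by exactly that
#' set of predictors. Negative coefficients (suppression) are returned
#' verbatim with a warning. The reconstruction of every `R2(W)` from the
#' coefficients is asserted to `1e-10` before returning.
#'
#' @param subset_r2 the complete map produced by [all_subsets_r2()].
#' @return named numeric vector of coefficients `C(S)`, same names as the
#'   input, with attribute `predictors`.
#' @export
commonality_coefficients <- function(subset_r2) {
  predictors <- attr(subset_r2, "predictors")
  if (is.null(predictors)) {
    # reconstruct from the singleton names
    predictors <- names(subset_r2)[!grepl("+", names(subset_r2), fixed = TRUE)]
  }
  k <- length(predictors)
  n_sub <- bitwShiftL(1L, k) - 1L
  expected <- vapply(seq_len(n_sub), subset_key, character(1),
                     predictors = predictors)
  if (length(subset_r2) != n_sub || !all(expected %in% names(subset_r2))) {
    mq_error("mq_incomplete_subsets",
             "subset_r2 must contain an R-squared for every non-empty subset")
  }
  r2 <- as.numeric(subset_r2[expected])  # indexed by bitmask 1..2^k-1
  full <- n_sub
  r2_at <- function(mask) if (mask == 0L) 0 else r2[mask]

  coef <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    # enumerate T subseteq S via the standard submask walk
    size_s <- sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1L))) != 0L)
    t <- s
    acc <- 0
    repeat {
      size_t <- sum(bitwAnd(t, bitwShiftL(1L, 0:(k - 1L))) != 0L)
      sign <- if ((size_s - size_t) %% 2L == 0L) -1 else 1
      acc <- acc + sign * r2_at(bitwAnd(full, bitwNot(t)))
      if (t == 0L) break
      t <- bitwAnd(t - 1L, s)
    }
    coef[s] <- acc
  }

  # verify the defining system with a zeta transform: g(A) = sum_{T<=A} C(T)
  g <- c(0, coef)  # g[mask + 1]
  for (b in 0:(k - 1L)) {
    bit <- bitwShiftL(1L, b)
    for (m in 0:n_sub) {
      if (bitwAnd(m, bit) != 0L) g[m + 1L] <- g[m + 1L] + g[bitwXor(m, bit) + 1L]
    }
  }
  recon <- g[full + 1L] - g[bitwAnd(full, bitwNot(seq_len(n_sub))) + 1L]
  if (max(abs(recon - r2)) > 1e-10) {
    mq_error("mq_bad_value",
             "commonality system not satisfied to 1e-10; input R2 map is inconsistent")
  }

  names(coef) <- expected
  if (any(coef < -1e-12)) {
    mq_warn("mq_suppression",
            sprintf("negative commonality coefficient(s) (suppression): %s",
                    paste(expected[coef < -1e-12], collapse = ", ")))
  }
  attr(coef, "predictors") <- predictors
  coef
}

#' Full commonality analysis of a linear model
#'
#' Convenience wrapper: computes all subset R-squared values, the
#' commonality coefficients and the total model R-squared.
#'
#' @inheritParams fit_r2
#' @return object of class `commonality_result`: a list with `predictors`,
#'   `subset_r2`, `coefficients` and `total_r2`.
#' @export
#' @examples
#' set.seed(1)
#' x1 <- rnorm(50); x2 <- 0.5 * x1 + rnorm(50)
#' y <- x1 + x2 + rnorm(50)
#' commonality_analysis(y, cbind(x1 = x1, x2 = x2))
commonality_analysis <- function(response, design) {
  subset_r2 <- all_subsets_r2(response, design)
  coefficients <- commonality_coefficients(subset_r2)
  structure(
    list(predictors = attr(subset_r2, "predictors"),
         subset_r2 = subset_r2,
         coefficients = coefficients,
         total_r2 = unname(subset_r2[length(subset_r2)])),
    class = "commonality_result"
  )
}

#' @export
print.commonality_result <- function(x, digits = 4, ...) {
  cat("Commonality analysis of", paste(x$predictors, collapse = ", "), "\n")
  cat("total R-squared:", format(x$total_r2, digits = digits), "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Three-bucket partition of explained variance
#'
#' Collapses the commonality coefficients into the reporting buckets used for
#' mating-order analyses: the variance attributed to the mating-order
#' predictor, to the repetitive-mating predictor, and everything else
#' (common components and covariate contributions).
#'
#' Under the default `rule = "unique"` the order and repeat buckets are the
#' two predictors' unique coefficients and `remaining` absorbs all common
#' components plus covariate-unique variance. `rule = "split_common"` instead
#' shares every common component equally among its member predictors before
#' bucketing.
#'
#' @param x a `commonality_result`.
#' @param roles named character vector mapping each predictor to one of
#'   `"order"`, `"repeat"`, `"covariate"`; exactly one predictor must be
#'   `"order"` and one `"repeat"`.
#' @param rule `"unique"` (default) or `"split_common"`.
#' @return list with `order_variance`, `repeat_variance`,
#'   `remaining_variance`, the same as percentages of the total
#'   (`order_pct`, `repeat_pct`, `remaining_pct`) and `total_r2`.
#' @export
bucket_partition <- function(x, roles, rule = c("unique", "split_common")) {
  rule <- match.arg(rule)
  stopifnot(inherits(x, "commonality_result"))
  if (!all(x$predictors %in% names(roles)) ||
      sum(roles == "order") != 1L || sum(roles == "repeat") != 1L) {
    mq_error("mq_bad_value",
             "roles must cover every predictor with exactly one 'order' and one 'repeat'")
  }
  order_pred <- names(roles)[roles == "order"]
  repeat_pred <- names(roles)[roles == "repeat"]
  co <- x$coefficients
  members <- strsplit(names(co), "+", fixed = TRUE)

  if (rule == "unique") {
    order_var <- unname(co[order_pred])
    repeat_var <- unname(co[repeat_pred])
  } else {
    share <- function(pred) {
      sum(vapply(seq_along(co), function(i) {
        if (pred %in% members[[i]]) co[i] / length(members[[i]]) else 0
      }, numeric(1)))
    }
    order_var <- share(order_pred)
    repeat_var <- share(repeat_pred)
  }
  remaining <- x$total_r2 - order_var - repeat_var
  pct <- function(v) if (x$total_r2 > 0) 100 * v / x$total_r2 else NA_real_
  list(order_variance = order_var,
       repeat_variance = repeat_var,
       remaining_variance = remaining,
       order_pct = pct(order_var),
       repeat_pct = pct(repeat_var),
       remaining_pct = pct(remaining),
       total_r2 = x$total_r2)
}

#' Commonality partition of paternity share for a score table
#'
#' Fits the linear model of paternity share on standardized mating order and
#' standardized repetitive matings, controlling for a fecundity covariate,
#' and partitions its R-squared. Mating order and repetitive matings are
#' standardized within the supplied rows before fitting (R-squared and the
#' commonality decomposition are invariant to this rescaling; it fixes the
#' coefficient scale). Rows with an undefined score are dropped.
#'
#' @param scores score table from [focal_scores()] (or any subset of rows).
#' @param covariate `"mate"` (mean fecundity of the focal male's eligible
#'   mates, default) or `"group"` (mean fecundity of all females in the
#'   vial).
#' @param rule bucketing rule, see [bucket_partition()].
#' @return list with the `commonality_result` (`analysis`), the `buckets`,
#'   and `n` (rows used).
#' @export
paternity_commonality <- function(scores, covariate = c("mate", "group"),
                                  rule = c("unique", "split_common")) {
  covariate <- match.arg(covariate)
  rule <- match.arg(rule)
  cov_col <- if (covariate == "mate") "mate_mean_fecundity" else "group_mean_fecundity"
  use <- stats::complete.cases(
    scores[c("paternity_share", "order_index", "repetitive_count", cov_col)])
  s <- scores[use, , drop = FALSE]
  if (nrow(s) < 6L) {
    mq_error("mq_degenerate_input",
             sprintf("need at least 6 complete vials for the partition (got %d)",
                     nrow(s)))
  }
  design <- cbind(order = standardize(s$order_index),
                  repet = standardize(s$repetitive_count),
                  fecundity = s[[cov_col]])
  ca <- commonality_analysis(s$paternity_share, design)
  buckets <- bucket_partition(
    ca, roles = c(order = "order", repet = "repeat", fecundity = "covariate"),
    rule = rule)
  list(analysis = ca, buckets = buckets, n = nrow(s))
}

#' Variance-partition table across experiments or treatments
#'
#' Applies [paternity_commonality()] to groups of vials and assembles the
#' familiar reporting table: explained variance in paternity, of which mating
#' order, repetitive mating and remaining (absolute and percent of total).
#' With `by = "experiment"` one row per experiment is produced; with
#' `by = "treatment"` vials are grouped by (experiment, social, focal_size).
#' Cells with fewer than `min_n` usable vials are reported with `NA` values
#' and a message.
#'
#' @param scores score table from [focal_scores()].
#' @param by `"experiment"` or `"treatment"`.
#' @param min_n minimum usable vials per cell (default 6: predictors + 3).
#' @inheritParams paternity_commonality
#' @return data frame, one row per group.
#' @export
partition_table <- function(scores, by = c("experiment", "treatment"),
                            covariate = c("mate", "group"),
                            rule = c("unique", "split_common"),
                            min_n = 6L) {
  by <- match.arg(by)
  covariate <- match.arg(covariate)
  rule <- match.arg(rule)
  group_cols <- if (by == "experiment") "experiment"
                else c("experiment", "social", "focal_size")
  key <- interaction(scores[group_cols], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(scores, key), function(s) {
    labels <- s[1, group_cols, drop = FALSE]
    usable <- sum(stats::complete.cases(
      s[c("paternity_share", "order_index", "repetitive_count")]))
    if (usable < min_n) {
      message(sprintf("partition_table: skipping %s (only %d usable vials)",
                      paste(unlist(labels), collapse = "/"), usable))
      part <- list(order_variance = NA_real_, repeat_variance = NA_real_,
                   remaining_variance = NA_real_, order_pct = NA_real_,
                   repeat_pct = NA_real_, remaining_pct = NA_real_,
                   total_r2 = NA_real_)
      n <- usable
    } else {
      pc <- paternity_commonality(s, covariate = covariate, rule = rule)
      part <- pc$buckets
      n <- pc$n
    }
    cbind(labels,
          data.frame(n = n,
                     total_r2 = part$total_r2,
                     order = part$order_variance,
                     order_pct = part$order_pct,
                     repet = part$repeat_variance,
                     repeat_pct = part$repeat_pct,
                     remaining = part$remaining_variance,
                     remaining_pct = part$remaining_pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
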