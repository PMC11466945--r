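#' Assign within-pen size classes from body weights
#'
#' Pigs are ranked by weight within their pen close to the time of
#' observation: the 3 lightest of 8 are `small`, the middle 2 `medium`, and
#' the 3 heaviest `large`.  Weight ties are broken by `pig_id` order.  For
#' pen sizes other than 8 the 37.5/25/37.5% split is kept, with the small
#' and large groups rounded to the nearest integer and the middle group
#' absorbing the remainder.
#'
#' @param weights Numeric body weights.
#' @param pig_ids Ids (tie-break order); default the element order.
#' @return Factor `small`/`medium`/`large`, parallel to `weights`.
#' @export
assign_size_classes <- function(weights, pig_ids = seq_along(weights)) {
  n <- length(weights)
  if (n < 3L) stop("need at least 3 pigs to rank sizes", call. = FALSE)
  if (n == 8L) {
    n_small <- 3L; n_large <- 3L
  } else {
    n_small <- as.integer(round(0.375 * n))
    n_large <- as.integer(round(0.375 * n))
  }
  n_med <- n - n_small - n_large
  o <- order(weights, pig_ids)
  cls <- rep(c("small", "medium", "large"), times = c(n_small, n_med, n_large))
  out <- character(n)
  out[o] <- cls
  factor(out, levels = c("small", "medium", "large"))
}

#' Aggregate a pig's size class across observation periods
#'
#' The aggregated class is the modal class over the periods; when the mode
#' is tied, the middle period's class is used.
#'
#' @param classes Character/factor vector of per-period classes, in period
#'   order.
#' @return Single size class (character).
#' @export
aggregate_size_class <- function(classes) {
  classes <- as.character(classes)
  tab <- table(classes)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) top else classes[ceiling(length(classes) / 2)]
}

#' Pairwise-correlation screen for collinear metrics
#'
#' Computes pairwise Pearson correlations among candidate metric columns
#' and removes one member of every pair with `|r| > threshold`: when the
#' pair is an (unweighted, weighted) version of the same quantity the
#' unweighted member is dropped, otherwise the later-listed metric.
#' Constant columns have undefined correlations; they are reported and
#' retained.  The result depends only on the column list and the data, not
#' on row order.
#'
#' @param table Data frame holding the metric columns.
#' @param metrics Character vector of column names, in priority order.
#' @param threshold Absolute-correlation cutoff (default 0.8).
#' @param unweighted Names within `metrics` that are unweighted versions of
#'   a weighted metric.
#' @return List with `retained` (character), `dropped` (data frame
#'   `metric_a,metric_b,r,dropped`), and `constant` (character).
#' @export
correlation_screen <- function(table, metrics, threshold = 0.8,
                               unweighted = character()) {
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  stopifnot(all(metrics %in% names(table)))
  X <- as.matrix(table[, metrics, drop = FALSE])
  const <- metrics[apply(X, 2L, function(z) stats::sd(z) == 0 || all(is.na(z)))]
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  keep <- rep(TRUE, length(metrics))
  names(keep) <- metrics
  drops <- list()
  for (i in seq_along(metrics)[-length(metrics)]) {
    for (j in (i + 1L):length(metrics)) {
      a <- metrics[i]; b <- metrics[j]
      if (!keep[a] || !keep[b]) next
      r <- R[a, b]
      if (is.na(r) || abs(r) <= threshold) next
      victim <- if (a %in% unweighted && !(b %in% unweighted)) {
        a
      } else if (b %in% unweighted && !(a %in% unweighted)) {
        b
      } else {
        b  # later-listed
      }
      keep[victim] <- FALSE
      drops[[length(drops) + 1L]] <-
        data.frame(metric_a = a, metric_b = b, r = r, dropped = victim,
                   stringsAsFactors = FALSE)
    }
  }
  list(
    retained = metrics[keep],
    dropped = if (length(drops)) do.call(rbind, drops) else
      data.frame(metric_a = character(), metric_b = character(),
                 r = numeric(), dropped = character()),
    constant = const
  )
}

#' Kruskal-Wallis rank-sum test with post hoc comparisons
#'
#' The omnibus H statistic (mid-ranks, tie correction, chi-square reference
#' with `k - 1` df) is computed by [stats::kruskal.test()].  Post hoc
#' pairwise group comparisons use the pooled-rank least-significant-
#' difference criterion: for groups i, j the statistic
#' \deqn{t = \frac{|\bar R_i - \bar R_j|}{\sqrt{S^2 \frac{N-1-H}{N-k}
#' (1/n_i + 1/n_j)}}}
#' is referred to a t distribution with `N - k` degrees of freedom, where
#' \eqn{S^2} is the variance of the pooled ranks; an optional Bonferroni
#' adjustment multiplies the p-values.
#'
#' @param values Numeric response.
#' @param groups Grouping vector/factor (>= 2 levels).
#' @param posthoc_adjust `"none"` (LSD) or `"bonferroni"`.
#' @return List with `H`, `df`, `p_value`, and `posthoc` (data frame of
#'   pairwise comparisons).
#' @export
kruskal_wallis <- function(values, groups,
                           posthoc_adjust = c("none", "bonferroni")) {
  posthoc_adjust <- match.arg(posthoc_adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(values) < 2L) stop("need >= 2 observations", call. = FALSE)
  if (length(unique(values)) == 1L) {
    H <- 0; df <- nlevels(groups) - 1L; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    H <- unname(kt$statistic); df <- unname(kt$parameter)
    p <- unname(kt$p.value)
  }
  N <- length(values); k <- nlevels(groups)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  S2 <- stats::var(r)
  pairs <- utils::combn(levels(groups), 2L)
  ph <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    mean_rank_a = rbar[pairs[1, ]], mean_rank_b = rbar[pairs[2, ]],
    row.names = NULL, stringsAsFactors = FALSE
  )
  se <- sqrt(S2 * (N - 1 - H) / (N - k) *
               (1 / ni[pairs[1, ]] + 1 / ni[pairs[2, ]]))
  tstat <- abs(ph$mean_rank_a - ph$mean_rank_b) / se
  ph$p_value <- 2 * stats::pt(tstat, df = N - k, lower.tail = FALSE)
  if (posthoc_adjust == "bonferroni") {
    ph$p_value <- stats::p.adjust(ph$p_value, "bonferroni")
  }
  ph$p_value <- pmin(1, ph$p_value)
  list(H = H, df = df, p_value = p, posthoc = ph)
}

file_md5 <- function(path) unname(tools::md5sum(path))

data_hash <- function(df) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(df, f, row.names = FALSE)
  file_md5(f)
}

fit_result <- function(model, formula, coef_table, aic, converged, n,
                       data, emm = NULL, contrasts = NULL, or_table = NULL,
                       extra = list()) {
  structure(c(list(
    model = model,
    formula = deparse1(formula),
    coefficients = coef_table,
    emmeans = emm,
    contrasts = contrasts,
    odds_ratios = or_table,
    AIC = aic,
    converged = converged,
    n = n,
    data_hash = data_hash(data)
  ), extra), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model:", x$formula, "\n")
  cat(sprintf("n = %d, AIC = %.2f, converged: %s\n", x$n, x$AIC,
              x$converged))
  if (!is.null(x$odds_ratios)) {
    if (isTRUE(x$reported) || is.null(x$reported)) {
      print(x$odds_ratios)
    } else {
      cat("Odds ratios withheld: proportional-odds assumption rejected",
          sprintf("(LR p = %.3g)\n", x$po_test$p_value))
    }
  } else if (!is.null(x$emmeans)) {
    print(x$emmeans)
  }
  invisible(x)
}

#' Linear mixed model for a network metric with Tukey-adjusted EMMs
#'
#' Fits `response ~ fixed effects + (1 | grouping)` by REML with
#' [lme4::lmer()], then computes estimated marginal means for the
#' treatment factor (averaging over the other factors with equal weights)
#' and all pairwise treatment contrasts with Tukey-style multiplicity
#' adjustment via the multivariate-t reference distribution
#' ([emmeans::emmeans()]).
#'
#' @param table Metric table (one row per pig-period or pen-period).
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names; the first is
#'   the factor for which EMMs and contrasts are produced.
#' @param grouping Random-intercept specification, e.g. `"pen_id"` or
#'   `"pen_id/pig_id"` for pigs nested within pens.
#' @param sqrt_transform Square-root-transform the response first (used for
#'   skewed betweenness distributions)?
#' @return A `fit_result` with coefficients, EMMs, Tukey contrasts, AIC and
#'   a convergence flag (singular random-effect fits are flagged, not
#'   refused).
#' @export
fit_metric_lmm <- function(table, response, fixed = c("treatment", "period"),
                           grouping = "pen_id", sqrt_transform = FALSE) {
  dat <- table
  if (sqrt_transform) {
    if (any(dat[[response]] < 0)) {
      stop("cannot square-root-transform negative values", call. = FALSE)
    }
    dat[[response]] <- sqrt(dat[[response]])
  }
  for (f in fixed) {
    if (!is.numeric(dat[[f]])) dat[[f]] <- factor(dat[[f]])
  }
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", response,
                                   paste(fixed, collapse = " + "), grouping))
  fit <- lme4::lmer(fml, data = dat, REML = TRUE)
  singular <- lme4::isSingular(fit)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L && !singular
  if (singular) {
    warning("random-effect variance estimated at zero (singular fit)",
            call. = FALSE)
  }
  emm <- emmeans::emmeans(fit, stats::as.formula(paste0("~", fixed[1])),
                          weights = "equal")
  ctr <- summary(emmeans::contrast(emm, method = "pairwise"),
                 adjust = "tukey")
  co <- as.data.frame(summary(fit)$coefficients)
  fit_result(fit, fml, co, stats::AIC(fit), conv, nrow(dat), dat,
             emm = as.data.frame(summary(emm, level = 0.95)),
             contrasts = as.data.frame(ctr))
}

wald_or_table <- function(est, se, labels) {
  data.frame(
    term = labels,
    estimate = est,
    se = se,
    odds_ratio = exp(est),
    ci_lower = exp(est - stats::qnorm(0.975) * se),
    ci_upper = exp(est + stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(abs(est / se), lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Proportional-odds model for the ordinal maximal tail score
#'
#' Fits a proportional-odds logistic regression of MTS on pig-level
#' network metrics and design factors by maximum likelihood
#' ([MASS::polr()]), reporting per-unit odds ratios with 95% Wald
#' confidence intervals.  No pen random effect is included.  A
#' proportional-odds diagnostic — the likelihood-ratio test of the
#' proportional-odds fit against an unconstrained multinomial logit — is
#' always computed; when it rejects (p < 0.05) the odds ratios are flagged
#' as withheld, since cumulative odds ratios are then not interpretable.
#'
#' @param table Metric table with an `mts` column.
#' @param predictors Character vector of predictor column names.
#' @param collapse_sparse Merge MTS levels 3-4 into 2 before fitting
#'   (optional guard for sparse top levels)?
#' @param sqrt_betweenness Square-root-transform a `betweenness` predictor?
#' @return A `fit_result`; `odds_ratios` holds the OR table, `po_test` the
#'   diagnostic, `reported` whether the assumption held.
#' @export
fit_ordinal_mts <- function(table, predictors, collapse_sparse = FALSE,
                            sqrt_betweenness = FALSE) {
  dat <- table
  mts <- dat$mts
  if (collapse_sparse) mts <- pmin(mts, 2L)
  if (length(unique(mts)) < 2L) {
    stop("MTS has a single observed level; ordinal model undefined",
         call. = FALSE)
  }
  dat$.mts <- factor(mts, ordered = TRUE)
  if (sqrt_betweenness && "betweenness" %in% predictors) {
    dat$betweenness <- sqrt(dat$betweenness)
  }
  for (f in predictors) {
    if (!is.numeric(dat[[f]])) dat[[f]] <- factor(dat[[f]])
  }
  fml <- stats::as.formula(paste(".mts ~", paste(predictors, collapse = " + ")))
  fit <- tryCatch(
    MASS::polr(fml, data = dat, Hess = TRUE),
    error = function(e) {
      stop("proportional-odds fit failed (possible complete separation): ",
           conditionMessage(e), call. = FALSE)
    })
  sm <- summary(fit)
  ct <- sm$coefficients
  slope <- seq_along(fit$coefficients)
  ors <- wald_or_table(ct[slope, "Value"], ct[slope, "Std. Error"],
                       rownames(ct)[slope])
  # proportional-odds diagnostic: LR against the unconstrained multinomial
  mn <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500)
  g <- as.numeric(2 * (stats::logLik(mn) - stats::logLik(fit)))
  df_g <- attr(stats::logLik(mn), "df") - attr(stats::logLik(fit), "df")
  po <- list(statistic = max(g, 0), df = df_g,
             p_value = stats::pchisq(max(g, 0), df_g, lower.tail = FALSE))
  fit_result(fit, fml, as.data.frame(ct), stats::AIC(fit),
             fit$convergence == 0, nrow(dat), dat, or_table = ors,
             extra = list(po_test = po, reported = po$p_value >= 0.05))
}

#' Mixed-effects logistic model for victimization status
#'
#' Fits `victim ~ predictors + (1 | pen_id)` with a binomial logit link
#' ([lme4::glmer()]) and reports odds ratios with 95% Wald confidence
#' intervals.  Association-network variants square-root-transform
#' betweenness.
#'
#' @param table Metric table with logical/0-1 `victim` and `pen_id`.
#' @param predictors Character vector of predictor column names.
#' @param sqrt_betweenness Square-root-transform a `betweenness` predictor?
#' @return A `fit_result` with the OR table.
#' @export
fit_victim_logit <- function(table, predictors, sqrt_betweenness = FALSE) {
  dat <- table
  v <- as.integer(dat$victim)
  if (all(v == 0L) || all(v == 1L)) {
    stop("victimization is constant; logistic model undefined",
         call. = FALSE)
  }
  dat$.victim <- v
  if (sqrt_betweenness && "betweenness" %in% predictors) {
    dat$betweenness <- sqrt(dat$betweenness)
  }
  for (f in predictors) {
    if (!is.numeric(dat[[f]])) dat[[f]] <- factor(dat[[f]])
  }
  fml <- stats::as.formula(sprintf(".victim ~ %s + (1 | pen_id)",
                                   paste(predictors, collapse = " + ")))
  fit <- lme4::glmer(fml, data = dat, family = stats::binomial())
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  co <- summary(fit)$coefficients
  idx <- rownames(co) != "(Intercept)"
  ors <- wald_or_table(co[idx, "Estimate"], co[idx, "Std. Error"],
                       rownames(co)[idx])
  fit_result(fit, fml, as.data.frame(co), stats::AIC(fit), conv,
             nrow(dat), dat, or_table = ors)
}

#' Rank candidate models by AIC
#'
#' @param ... Two or more `fit_result` objects (or a single list of them)
#'   fitted to identical data rows.
#' @return Data frame sorted by AIC with `delta_aic`.
#' @export
compare_models_aic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "fit_result")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2L) stop("need at least two fits", call. = FALSE)
  n <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(n)) != 1L) {
    stop("fits use differing numbers of rows; AIC not comparable",
         call. = FALSE)
  }
  res <- data.frame(
    model = vapply(fits, function(f) f$formula, character(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$AIC), , drop = FALSE]
  res$delta_aic <- res$AIC - res$AIC[1]
  rownames(res) <- NULL
  res
}

#' Assemble the pig-level metric table for the indicator models
#'
#' Joins pig-level network metrics with the roster (treatment, sex), the
#' injury outcomes (MTS, victim flag), and — when body weights are
#' supplied — the within-pen size class at the week nearest each
#' observation period.  Per-period metric tables (association networks)
#' get one size class per pig-period; aggregated tables (bite networks)
#' get the modal class across the observation periods, ties resolved to
#' the middle period.
#'
#' @param metrics Pig-level metric data frame as from [pig_metrics()]
#'   (rows for one network type, with a `period` or `periods` column).
#' @param roster Data frame with `pig_id`, `pen_id`, `treatment`, `sex`.
#' @param scores Tail-score data frame (`pig_id,assessment_index,score`).
#' @param weights Optional data frame `pig_id, week, weight_kg`.
#' @param periods Observation-period weeks used for size classing when
#'   `metrics` is aggregated; defaults to the weeks present in `weights`
#'   that match the `periods` label.
#' @return Data frame with one row per pig(-period): identifiers, design
#'   factors, `size_class` (when weights given), the metrics, `mts`,
#'   `mts_class`, `victim`.
#' @export
build_metric_table <- function(metrics, roster, scores, weights = NULL,
                               periods = NULL) {
  out <- merge(metrics, roster[, c("pig_id", "treatment", "sex")],
               by = "pig_id", sort = FALSE)
  out <- merge(out, score_tails(scores), by = "pig_id", sort = FALSE)
  if (!is.null(weights)) {
    size_at <- function(pen_pigs, wk) {
      wsub <- weights[weights$pig_id %in% pen_pigs, , drop = FALSE]
      near <- wsub[abs(wsub$week - wk) == min(abs(wsub$week - wk)), ]
      near <- near[!duplicated(near$pig_id), ]
      near <- near[match(pen_pigs, near$pig_id), ]
      stats::setNames(as.character(assign_size_classes(near$weight_kg,
                                                       pen_pigs)),
                      pen_pigs)
    }
    if ("period" %in% names(out)) {
      out$size_class <- NA_character_
      for (pp in unique(out[, c("pen_id", "period")]$pen_id)) {
        for (per in unique(out$period[out$pen_id == pp])) {
          rows <- out$pen_id == pp & out$period == per
          cls <- size_at(sort(unique(out$pig_id[rows])), per)
          out$size_class[rows] <- cls[out$pig_id[rows]]
        }
      }
    } else {
      if (is.null(periods)) {
        periods <- sort(unique(as.integer(unlist(
          strsplit(as.character(out$periods[1]), "+", fixed = TRUE)))))
      }
      out$size_class <- NA_character_
      for (pp in unique(out$pen_id)) {
        rows <- out$pen_id == pp
        pigs <- sort(unique(out$pig_id[rows]))
        per_cls <- vapply(periods, function(per) size_at(pigs, per),
                          character(length(pigs)))
        agg <- apply(per_cls, 1L, aggregate_size_class)
        names(agg) <- pigs
        out$size_class[rows] <- agg[out$pig_id[rows]]
      }
    }
    out$size_class <- factor(out$size_class,
                             levels = c("small", "medium", "large"))
  }
  rownames(out) <- NULL
  out
}
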