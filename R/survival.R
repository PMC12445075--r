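# Survival stage: product-limit curves, log-rank tests, binary Cox hazard
# ratios (Breslow ties, via the survival package), censoring at a threshold,
# and the auto-best-cutoff stratification used for every survival claim.

as_surv_table <- function(table) {
  need <- c("time", "event")
  if (!all(need %in% names(table))) abort("need columns time and event")
  if (any(table$time <= 0)) abort("times must be positive")
  if (!all(table$event %in% c(0, 1))) abort("event must be 0/1")
  table
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator with median survival defined as the smallest time
#' at which the curve drops to 0.5 or below (undefined when it never does).
#'
#' @param table Tibble with `time` (> 0) and `event` (0 censored / 1 event).
#' @return Object of class `km_curve`: list with `steps` (tibble: time,
#'   n_risk, n_event, surv), `median_survival` (`NA` if undefined), `n`.
#' @export
km_curve <- function(table) {
  table <- as_surv_table(table)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(table))
  steps <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, surv = fit$surv)
  med <- {
    drop <- steps$time[steps$surv <= 0.5]
    if (length(drop) == 0) NA_real_ else min(drop)
  }
  structure(list(steps = steps, median_survival = med, n = nrow(table)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "\n")
  cat("  median survival:",
      if (is.na(x$median_survival)) "not reached" else x$median_survival,
      "\n")
  invisible(x)
}

#' @export
tidy.km_curve <- function(x, ...) x$steps

#' @export
glance.km_curve <- function(x, ...) {
  tibble(n = x$n, n_events = sum(x$steps$n_event),
         median_survival = x$median_survival)
}

#' @rdname km_curve
#' @param object A `km_curve`.
#' @param ... Ignored.
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- bind_rows(tibble(time = 0, surv = 1), object$steps[, c("time", "surv")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability")
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance; p from the
#' chi-square distribution with 1 df. When neither group has any event the
#' statistic is 0 and p is 1.
#'
#' @param table_a,table_b Survival tibbles (`time`, `event`).
#' @return Tibble with `chi2` and `p`.
#' @export
logrank <- function(table_a, table_b) {
  table_a <- as_surv_table(table_a); table_b <- as_surv_table(table_b)
  if (nrow(table_a) == 0 || nrow(table_b) == 0) abort("both groups non-empty")
  if (sum(table_a$event) + sum(table_b$event) == 0) {
    return(tibble(chi2 = 0, p = 1))
  }
  d <- data.frame(time = c(table_a$time, table_b$time),
                  event = c(table_a$event, table_b$event),
                  grp = rep(c("A", "B"), c(nrow(table_a), nrow(table_b))))
  fit <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  tibble(chi2 = fit$chisq, p = pchisq(fit$chisq, 1, lower.tail = FALSE))
}

#' Binary-covariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit of a single two-level covariate with Breslow tie
#' handling. The reported hazard ratio is for the second level versus the
#' first: factor levels are respected if `group_labels` is a factor, otherwise
#' the first label encountered becomes the reference. Under
#' complete separation the log hazard ratio is capped at +/- 10 and flagged.
#'
#' @param table Survival tibble (`time`, `event`).
#' @param group_labels Two-level vector aligned with `table` rows.
#' @return Object of class `cox_binary`: `beta`, `hr`, `se`, `ci95`
#'   (length-2), `p` (Wald), `flagged`, `levels`, `n`, `n_events`.
#' @export
cox_binary <- function(table, group_labels) {
  table <- as_surv_table(table)
  g <- if (is.factor(group_labels)) group_labels
       else factor(group_labels, levels = unique(group_labels))
  if (nlevels(g) != 2) abort("need exactly two groups")
  if (any(table(g) == 0)) abort("both groups must be non-empty")
  if (sum(table$event) < 1) abort("need at least one event")
  d <- data.frame(time = table$time, event = table$event, grp = g)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ grp, data = d,
                    ties = "breslow")
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  flagged <- !is.finite(beta) || abs(beta) > 10 || !is.finite(se)
  if (flagged) {
    beta <- if (is.finite(beta)) sign(beta) * 10 else 0
    if (!is.finite(se)) se <- Inf
    warn("possible complete separation; log hazard ratio capped at +/- 10")
  }
  p <- 2 * pnorm(-abs(beta / se))
  structure(list(
    beta = beta, hr = exp(beta), se = se,
    ci95 = exp(beta + c(-1, 1) * 1.96 * se),
    p = p, flagged = flagged, levels = levels(g),
    n = nrow(table), n_events = sum(table$event)
  ), class = "cox_binary")
}

#' @export
print.cox_binary <- function(x, ...) {
  cat("Binary Cox fit:", x$levels[2], "vs", x$levels[1], "\n")
  cat(sprintf("  HR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$hr, x$ci95[1], x$ci95[2], x$p))
  if (x$flagged) cat("  [flagged: separation]\n")
  invisible(x)
}

#' @export
tidy.cox_binary <- function(x, ...) {
  tibble(term = paste0(x$levels[2], "_vs_", x$levels[1]),
         estimate = x$beta, std.error = x$se, p.value = x$p,
         hr = x$hr, conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @export
glance.cox_binary <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, hr = x$hr, p.value = x$p,
         flagged = x$flagged)
}

#' Censor a survival table at a threshold
#'
#' Times beyond `t_star` are set to `t_star` with the event indicator cleared;
#' all other rows are unchanged.
#'
#' @param table Survival tibble (`time`, `event`).
#' @param t_star Censoring threshold (> 0).
#' @return Survival tibble.
#' @export
censor_at <- function(table, t_star) {
  table <- as_surv_table(table)
  if (t_star <= 0) abort("t_star must be > 0")
  over <- table$time > t_star
  table$time[over] <- t_star
  table$event[over] <- 0L
  table
}

#' Auto-select the best survival cutoff for a score
#'
#' Scans every distinct score value whose high/low split leaves both groups
#' between the `lower_q` and `upper_q` cohort fractions, computes the log-rank
#' p for each, and returns the cutoff minimizing p (ties resolved toward the
#' cutoff nearest the median score). "High" means score strictly above the
#' cutoff. No multiplicity correction is applied over the scanned cutoffs,
#' mirroring the common web tool; the number of cutoffs scanned is reported so
#' the optimism is auditable.
#'
#' @param scores Named numeric vector (names = sample ids) or tibble with
#'   `sample` and `score`.
#' @param table Survival tibble with `sample`, `time`, `event`.
#' @param lower_q,upper_q Allowed group-fraction band (default 0.25-0.75).
#' @param t_censor Optional follow-up threshold applied first via
#'   [censor_at()].
#' @return Object of class `best_cutoff`: `cutoff`, `groups` (tibble: sample,
#'   group), `chi2`, `p`, `cox` (a [cox_binary()] fit), `n_high`, `n_low`,
#'   `n_cutoffs_scanned`, `median_survival` (tibble per group).
#' @export
best_cutoff <- function(scores, table, lower_q = 0.25, upper_q = 0.75,
                        t_censor = NULL) {
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$sample)
  }
  if (!"sample" %in% names(table)) abort("table needs a sample column")
  common <- intersect(names(scores), table$sample)
  if (length(common) < 10) abort("need at least 10 shared samples")
  table <- table[match(common, table$sample), ]
  scores <- scores[common]
  table <- as_surv_table(table)
  if (!is.null(t_censor)) table <- censor_at(table, t_censor)
  n <- length(scores)
  cand <- sort(unique(scores))
  frac_high <- vapply(cand, function(c) mean(scores > c), numeric(1))
  ok <- frac_high >= lower_q & frac_high <= upper_q &
    (1 - frac_high) >= lower_q & (1 - frac_high) <= upper_q
  cand <- cand[ok]
  if (length(cand) < 1) abort("no candidate cutoffs in the quantile band")
  res <- map_dfr(cand, function(c) {
    hi <- scores > c
    lr <- logrank(table[hi, ], table[!hi, ])
    tibble(cutoff = c, chi2 = lr$chi2, p = lr$p)
  })
  best_p <- min(res$p)
  tied <- res[res$p == best_p, ]
  pick <- tied$cutoff[order(abs(tied$cutoff - median(scores)))][1]
  hi <- scores > pick
  fit <- cox_binary(table, factor(ifelse(hi, "high", "low"),
                                  levels = c("low", "high")))
  med <- bind_rows(
    mutate(glance(km_curve(table[hi, ]))["median_survival"], group = "high"),
    mutate(glance(km_curve(table[!hi, ]))["median_survival"], group = "low")
  )
  structure(list(
    cutoff = pick,
    groups = tibble(sample = common, group = ifelse(hi, "high", "low")),
    chi2 = res$chi2[res$cutoff == pick],
    p = res$p[res$cutoff == pick],
    cox = fit,
    n_high = sum(hi), n_low = sum(!hi),
    n_cutoffs_scanned = length(cand),
    median_survival = med[, c("group", "median_survival")],
    table = table
  ), class = "best_cutoff")
}

#' @export
print.best_cutoff <- function(x, ...) {
  cat("Best-cutoff stratification\n")
  cat(sprintf("  cutoff = %.4g (scanned %d), n_high = %d, n_low = %d\n",
              x$cutoff, x$n_cutoffs_scanned, x$n_high, x$n_low))
  cat(sprintf("  log-rank chi2 = %.3f, p = %.3g\n", x$chi2, x$p))
  cat(sprintf("  HR (high vs low) = %.3f, p = %.3g\n", x$cox$hr, x$cox$p))
  invisible(x)
}

#' @export
tidy.best_cutoff <- function(x, ...) x$groups

#' @export
glance.best_cutoff <- function(x, ...) {
  tibble(cutoff = x$cutoff, n_high = x$n_high, n_low = x$n_low,
         chi2 = x$chi2, p = x$p, hr = x$cox$hr,
         hr_conf.low = x$cox$ci95[1], hr_conf.high = x$cox$ci95[2],
         cox_p = x$cox$p, n_cutoffs_scanned = x$n_cutoffs_scanned)
}

#' @rdname best_cutoff
#' @param object A `best_cutoff`.
#' @param ... Ignored.
#' @export
autoplot.best_cutoff <- function(object, ...) {
  hi <- object$groups$group == "high"
  d <- bind_rows(
    mutate(tidy(km_curve(object$table[hi, ])), group = "high"),
    mutate(tidy(km_curve(object$table[!hi, ])), group = "low")
  )
  d <- bind_rows(tibble(time = 0, surv = 1, group = c("high", "low")), d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time", y = "Survival probability",
      subtitle = sprintf("HR = %.2f, log-rank p = %.2g", object$cox$hr,
                         object$p)
    )
}
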