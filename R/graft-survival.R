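#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning a tidy step-function
#' table. Censored subjects remain at risk through their censoring time, in
#' the conventional way.
#'
#' @param records a data frame with numeric `time` (> 0) and `event`
#'   (1 = graft loss, 0 = censored) columns.
#' @return a tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (one row per distinct observed time).
#' @export
km_estimate <- function(records) {
  records <- validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 survival = fit$surv)
}

validate_survival <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) < 1) stop("no survival records", call. = FALSE)
  if (any(records$time <= 0)) stop("time must be > 0", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (graft loss)", call. = FALSE)
  }
  records
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank over the pooled event times,
#' via [survival::survdiff()].
#'
#' @param records survival records as in [km_estimate()].
#' @param grouping vector of group labels, one per record (>= 2 distinct
#'   labels, >= 1 event overall).
#' @return list with `chisq`, `df`, `p_value`, and the per-group
#'   observed/expected table `obs_exp`.
#' @export
logrank_test <- function(records, grouping) {
  records <- validate_survival(records)
  g <- factor(grouping)
  if (nlevels(g) < 2) stop("logrank_test() needs >= 2 groups", call. = FALSE)
  if (sum(records$event) < 1) {
    stop("logrank_test(): no events observed", call. = FALSE)
  }
  records$..g <- g
  sd <- survival::survdiff(survival::Surv(time, event) ~ ..g, data = records)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       obs_exp = data.frame(group = levels(g), observed = sd$obs,
                            expected = sd$exp))
}

#' Split a cohort into high/low expression groups at a given ratio
#'
#' A ratio `"a:b"` assigns the top `a / (a + b)` fraction of the covariate
#' to the `"high"` group (with `ceiling` rounding of the group size); ties
#' at the cut value go to `"high"`. A 1:3 split of 282 subjects therefore
#' puts `ceiling(282/4) = 71` in the high group (more with ties).
#'
#' @param records survival records with the covariate as a numeric column.
#' @param covariate name of the covariate column (no missing values).
#' @param ratio a string `"a:b"` with positive integers a, b.
#' @return `records` with an added factor column `strat_group`
#'   (levels `high`, `low`); attribute `cut_value` holds the threshold.
#' @export
stratify_by_ratio <- function(records, covariate, ratio = "1:1") {
  records <- validate_survival(records)
  parts <- suppressWarnings(as.integer(strsplit(ratio, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || any(is.na(parts)) || any(parts < 1)) {
    stop("ratio must be of the form \"a:b\" with positive integers",
         call. = FALSE)
  }
  x <- records[[covariate]]
  if (is.null(x) || any(is.na(x))) {
    stop("covariate ", covariate, " missing or has NA values", call. = FALSE)
  }
  if (length(unique(x)) == 1) {
    stop("cannot stratify a constant covariate", call. = FALSE)
  }
  n_high <- ceiling(nrow(records) * parts[1] / sum(parts))
  cut_value <- sort(x, decreasing = TRUE)[n_high]
  records$strat_group <- factor(ifelse(x >= cut_value, "high", "low"),
                                levels = c("high", "low"))
  attr(records, "cut_value") <- cut_value
  records
}

#' Cox proportional-hazards fit with Efron tie handling
#'
#' Multivariate Cox regression via [survival::coxph()] (partial-likelihood
#' Newton-Raphson, `ties = "efron"`). Hazard ratios are per unit of each
#' covariate; confidence intervals are Wald-based at `conf_level`.
#' Suspected separation (a diverging coefficient with an enormous standard
#' error) is flagged rather than silently reported.
#'
#' @param records survival records containing the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return a tibble with one row per covariate: `term`, `coef`, `hr`, `se`,
#'   `ci_lower`, `ci_upper`, `p_value`, `flagged_separation`; attribute
#'   `iterations` reports the Newton iteration count.
#' @export
cox_fit <- function(records, covariates, conf_level = 0.95) {
  records <- validate_survival(records)
  if (sum(records$event) < 2) {
    stop("cox_fit() needs >= 2 events", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$fail)) {
    stop("cox_fit(): partial-likelihood maximization failed", call. = FALSE)
  }
  s <- summary(fit, conf.int = conf_level)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- s$coefficients
  out <- tibble::tibble(
    term = rownames(co),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    se = co[, "se(coef)"],
    ci_lower = exp(co[, "coef"] - z * co[, "se(coef)"]),
    ci_upper = exp(co[, "coef"] + z * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"],
    flagged_separation = abs(co[, "coef"]) > 10 | co[, "se(coef)"] > 10)
  attr(out, "iterations") <- fit$iter
  out
}
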