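#' Median-split expression groups
#'
#' Samples above the median are `"high"`, samples below are `"low"`;
#' samples exactly at the median join the low group (deterministic,
#' documented tie rule). Errors when the split would leave a group
#' empty (e.g. constant expression).
#'
#' @param expr numeric expression vector (n >= 2), names preserved.
#' @return factor with levels `low`, `high`.
#' @export
median_dichotomize <- function(expr) {
  if (length(expr) < 2) stop("need at least 2 samples")
  if (anyNA(expr)) stop("missing expression values")
  med <- stats::median(expr)
  g <- ifelse(expr > med, "high", "low")
  if (length(unique(g)) < 2) {
    stop("median split produced an empty group (constant expression?)")
  }
  factor(stats::setNames(g, names(expr)), levels = c("low", "high"))
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate per group (or a single pooled curve), backed
#' by the survival package. The returned step function is
#' right-continuous with S(0) = 1.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group optional grouping factor.
#' @return data frame with columns `group`, `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("negative survival times")
  if (is.null(group)) group <- rep("all", length(time))
  df <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  smry <- summary(fit, censored = FALSE)
  grp <- if (is.null(smry$strata)) {
    rep(levels(df$group)[1], length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  data.frame(group = grp, time = smry$time, n_risk = smry$n.risk,
             n_event = smry$n.event, surv = smry$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance at each
#' distinct event time; p-value from the chi-square distribution with
#' one degree of freedom.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = death, 0 = censored).
#' @param group two-level grouping.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("exactly two non-empty groups required")
  }
  if (sum(event) < 1) stop("at least one event required")
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling via
#' `survival::coxph`. In `"univariate"` mode each covariate is fit in
#' its own model; in `"multivariate"` mode all covariates enter
#' jointly. Hazard ratios with Wald 95% confidence intervals and
#' p-values are reported per coefficient; a `converged` flag marks fits
#' that hit the iteration limit or produced unstable estimates.
#'
#' @param data data frame containing `time`, `event` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data frame with columns `covariate`, `term`, `mode`, `HR`,
#'   `CI_low`, `CI_high`, `p`, `converged`.
#' @export
cox_regression <- function(data, covariates,
                           mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  if (sum(data$event) < length(covariates) + 1) {
    stop("too few events for the requested number of covariates")
  }
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv)
    if (length(unique(v[!is.na(v)])) < 2) {
      stop("constant covariate: ", cv)
    }
  }
  fit_one <- function(cvs) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(cvs, collapse = " + ")))
    ok <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "efron"),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(
      term = rownames(co),
      HR = unname(co[, "exp(coef)"]),
      CI_low = unname(ci[, "lower .95"]),
      CI_high = unname(ci[, "upper .95"]),
      p = unname(co[, "Pr(>|z|)"]),
      converged = ok,
      stringsAsFactors = FALSE
    )
  }
  if (mode == "univariate") {
    out <- do.call(rbind, lapply(covariates, function(cv) {
      r <- fit_one(cv)
      r$covariate <- cv
      r
    }))
  } else {
    out <- fit_one(covariates)
    out$covariate <- covariates[
      vapply(out$term, function(tm) {
        which(vapply(covariates, function(cv) startsWith(tm, cv),
                     logical(1)))[1]
      }, integer(1))]
  }
  out$mode <- mode
  rownames(out) <- NULL
  out[, c("covariate", "term", "mode", "HR", "CI_low", "CI_high", "p",
          "converged")]
}

#' Survival screen for candidate master-regulator biomarkers
#'
#' For one miRNA: dichotomize tumor samples at the median expression,
#' run the log-rank test, and fit univariate (group only) plus
#' multivariate (group adjusted for the clinical covariates) Cox
#' models.
#'
#' @param expr named expression vector over tumor samples (VST scale).
#' @param clinical data frame with columns `sample_id`, `time`,
#'   `event` and the adjustment covariates.
#' @param covariates covariate columns for the multivariate model
#'   (default `age_group`, `stage_num`, `er_status`, `pr_status`).
#' @return list with `group`, `logrank` (chi2, p) and `cox` (combined
#'   table).
#' @export
mmr_survival <- function(expr, clinical,
                         covariates = c("age_group", "stage_num",
                                        "er_status", "pr_status")) {
  idx <- match(clinical$sample_id, names(expr))
  keep <- !is.na(idx) & !is.na(clinical$time) & !is.na(clinical$event)
  cl <- clinical[keep, , drop = FALSE]
  ex <- expr[idx[keep]]
  grp <- median_dichotomize(ex)
  df <- cbind(cl, expr_group = as.integer(grp == "high"))
  lr <- logrank_test(df$time, df$event, grp)
  covariates <- covariates[covariates %in% names(df)]
  covariates <- covariates[vapply(covariates, function(cv) {
    length(unique(df[[cv]][!is.na(df[[cv]])])) > 1
  }, logical(1))]
  uni <- cox_regression(df, "expr_group", mode = "univariate")
  multi <- cox_regression(df, c("expr_group", covariates),
                          mode = "multivariate")
  list(group = grp, logrank = lr, cox = rbind(uni, multi))
}
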