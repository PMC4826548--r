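#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step estimate of recurrence-free survival; censored
#' patients leave the risk set after their censoring time. Backed by
#' [survival::survfit()].
#'
#' @param times nonnegative follow-up times (months).
#' @param events logical event indicators (TRUE = recurrence observed).
#' @return object of class `km_curve`: data.frame with `time` (ascending
#'   event times), `n_risk`, `n_event`, `surv`; attribute `fit` holds the
#'   underlying survfit object for plotting.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (length(times) != length(events)) stop("'times' and 'events' lengths differ")
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep],
                    n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep],
                    surv = fit$surv[keep])
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability from a Kaplan-Meier curve
#'
#' @param curve a `km_curve`.
#' @param t time(s) at which to evaluate S(t).
#' @return survival probabilities (1 before the first event).
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Multi-group log-rank test
#'
#' Observed-minus-expected events with hypergeometric variance at each event
#' time, chi-square reference on (groups - 1) degrees of freedom. Backed by
#' [survival::survdiff()].
#'
#' @param times nonnegative follow-up times.
#' @param events logical event indicators.
#' @param groups group labels (>= 2 non-empty groups).
#' @return object of class `logrank_result`: list with `chisq`, `df`,
#'   `p_value`, `n_groups`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2)
    stop("log-rank test needs at least 2 non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ groups)
  df <- nlevels(groups) - 1L
  structure(list(chisq = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n_groups = nlevels(groups)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4g on %d df, p = %.2g (%d groups)\n",
              x$chisq, x$df, x$p_value, x$n_groups))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via [survival::coxph()] with Efron tie
#' handling by default (Breslow available) and Wald 95% confidence
#' intervals. Zero-variance covariates are reported with coefficient 0 and
#' hazard ratio 1 (warning). A coefficient magnitude above 20 is treated as
#' monotone likelihood / complete separation and raised as an error advising
#' a penalized or grouped analysis.
#'
#' @param times nonnegative follow-up times.
#' @param events logical event indicators (at least one TRUE).
#' @param covariates numeric matrix or data.frame of covariates (columns
#'   named); factors in a data.frame are expanded to model-matrix columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_result`: data.frame with one row per
#'   coefficient: `term`, `coef`, `hr`, `ci_low`, `ci_high`, `se`, `p_value`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(events) == 0) stop("no events: Cox model cannot be fitted")
  if (is.data.frame(covariates)) {
    covariates <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (any(!is.finite(covariates))) stop("non-finite covariate values")

  const <- apply(covariates, 2, function(v) diff(range(v)) == 0)
  out_rows <- vector("list", ncol(covariates))
  active <- covariates[, !const, drop = FALSE]
  if (ncol(active) > 0) {
    fit <- survival::coxph(
      survival::Surv(times, as.integer(events)) ~ active, ties = ties)
    coef <- unname(fit$coefficients)
    if (any(!is.finite(coef)) || any(abs(coef) > 20))
      stop("monotone partial likelihood / complete separation detected ",
           "(|coefficient| > 20); consider a penalized (Firth-type) or grouped analysis")
    se <- sqrt(diag(fit$var))
    res <- data.frame(term = colnames(active), coef = coef,
                      hr = exp(coef),
                      ci_low = exp(coef - 1.96 * se),
                      ci_high = exp(coef + 1.96 * se),
                      se = se,
                      p_value = 2 * stats::pnorm(-abs(coef / se)),
                      stringsAsFactors = FALSE)
  } else {
    res <- NULL
  }
  if (any(const)) {
    warning("zero-variance covariate(s) reported with coefficient 0: ",
            paste(colnames(covariates)[const], collapse = ", "))
    res0 <- data.frame(term = colnames(covariates)[const], coef = 0, hr = 1,
                       ci_low = NA_real_, ci_high = NA_real_, se = NA_real_,
                       p_value = NA_real_, stringsAsFactors = FALSE)
    res <- rbind(res, res0)
  }
  res <- res[match(colnames(covariates), res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cox_result", "data.frame")
  res
}

#' Build patient survival strata
#'
#' Scheme `"cluster"` stratifies patients by their heterogeneity group
#' (`C1_ONLY`, `C2_ONLY`, `MIXED`), ignoring Milan status. Scheme
#' `"milan_cluster"` keeps all within-Milan patients together and subdivides
#' only the outside-Milan patients by group: `WITHIN_MILAN`, `OUT_C1`,
#' `OUT_C2`, `OUT_MIXED`.
#'
#' @param groups a `patient_groups` object (or data.frame with `patient_id`,
#'   `group`).
#' @param milan named character vector per patient, `"WITHIN"`/`"OUTSIDE"`
#'   (needed for `"milan_cluster"`).
#' @param scheme `"cluster"` or `"milan_cluster"`.
#' @return named character vector of stratum labels per patient.
#' @export
build_strata <- function(groups, milan = NULL,
                         scheme = c("cluster", "milan_cluster")) {
  scheme <- match.arg(scheme)
  grp <- stats::setNames(as.character(groups$group), groups$patient_id)
  if (scheme == "cluster") return(grp)
  mil <- as.character(lookup(milan, names(grp), "Milan status"))
  out <- ifelse(mil == "WITHIN", "WITHIN_MILAN",
                c(C1_ONLY = "OUT_C1", C2_ONLY = "OUT_C2",
                  MIXED = "OUT_MIXED")[grp])
  stats::setNames(out, names(grp))
}
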