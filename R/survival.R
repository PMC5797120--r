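#' @importFrom survival Surv survfit survdiff coxph
NULL

.checkSurv <- function(time, event) {
  if (any(time < 0)) stop("survival times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  drop0 <- time == 0 & event == 0
  if (any(drop0))
    warning(sum(drop0), " record(s) censored at time 0 excluded")
  !drop0
}

#' Kaplan-Meier product-limit estimate
#'
#' Stepwise survival function per group: survival is 1 at time 0 and drops
#' only at event times.
#'
#' @param time,event follow-up time and event indicator (1 = event,
#'   0 = censored).
#' @param group optional group labels (single group if NULL).
#' @return data.frame(group, time, n_risk, n_event, n_censor, survival).
#' @export
kmEstimate <- function(time, event, group = NULL) {
  if (length(time) < 1L) stop("need at least one record")
  keep <- .checkSurv(time, event)
  time <- time[keep]; event <- event[keep]
  group <- if (is.null(group)) rep("all", length(time)) else
    as.character(group)[keep]
  fit <- survfit(Surv(time, event) ~ grp,
                 data = data.frame(time = time, event = event, grp = group))
  s <- summary(fit, censored = TRUE)
  g <- if (is.null(s$strata)) rep(unique(group), length(s$time)) else
    sub("^grp=", "", as.character(s$strata))
  data.frame(group = g, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor,
             survival = s$surv, row.names = NULL)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events with hypergeometric variance at each
#' distinct event time; p from the 1-df chi-square.
#'
#' @param time,event follow-up time and event indicator.
#' @param group two-level group labels, both groups non-empty.
#' @return list(chisq, df = 1, p).
#' @export
logrankTest <- function(time, event, group) {
  keep <- .checkSurv(time, event)
  d <- data.frame(time = time[keep], event = event[keep],
                  grp = factor(as.character(group)[keep]))
  if (nlevels(d$grp) != 2L || any(table(d$grp) == 0L))
    stop("need two non-empty groups")
  sd <- survdiff(Surv(time, event) ~ grp, data = d)
  list(chisq = sd$chisq, df = 1L,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Maximizes the Efron-tie-corrected partial likelihood (Newton iterations
#' to the survival package's convergence tolerance) and reports per-
#' covariate Wald tests. Monotone-likelihood (perfect separation) shows up
#' as a non-converged flag or exploding standard errors and is reported,
#' not hidden.
#'
#' @param data data.frame holding time, event and covariate columns.
#' @param timeCol,eventCol column names of the endpoint.
#' @param covariates character vector of covariate column names.
#' @return list(coefficients = data.frame(term, coef, hr, se, z, p),
#'   logLik, converged, n, nEvents).
#' @export
coxFit <- function(data, covariates, timeCol = "time", eventCol = "event") {
  stopifnot(all(c(timeCol, eventCol, covariates) %in% names(data)))
  keep <- .checkSurv(data[[timeCol]], data[[eventCol]])
  d <- data[keep, , drop = FALSE]
  if (sum(d[[eventCol]]) < 1L) stop("need at least one event")
  if (nrow(d) <= length(covariates))
    stop("need more records than covariates")
  form <- stats::as.formula(paste0("Surv(", timeCol, ", ", eventCol, ") ~ ",
                                   paste(covariates, collapse = " + ")))
  fit <- coxph(form, data = d, ties = "efron")
  sm <- summary(fit)
  converged <- fit$iter < 20L && all(is.finite(stats::coef(fit))) &&
    all(sm$coefficients[, "se(coef)"] < 1e3)
  list(coefficients = data.frame(term = rownames(sm$coefficients),
                                 coef = sm$coefficients[, "coef"],
                                 hr = sm$coefficients[, "exp(coef)"],
                                 se = sm$coefficients[, "se(coef)"],
                                 z = sm$coefficients[, "z"],
                                 p = sm$coefficients[, "Pr(>|z|)"],
                                 row.names = NULL),
       logLik = fit$loglik[2L], converged = converged,
       n = fit$n, nEvents = fit$nevent)
}
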