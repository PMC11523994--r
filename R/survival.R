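#' Kaplan-Meier curves with at-risk truncation
#'
#' Product-limit estimates per group with Greenwood variance and confidence
#' intervals on the log-survival scale. For reporting, each curve carries a
#' right-truncation time: the first time at which fewer than
#' \code{at_risk_frac} of the group remains at risk (estimates beyond it are
#' kept but should not be displayed). Truncation is a reporting limit, not
#' data deletion.
#'
#' @param time follow-up times (months), non-negative.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group optional grouping factor; one curve per level.
#' @param conf_level confidence level (default 0.95).
#' @param at_risk_frac at-risk fraction defining the truncation time
#'   (default 0.10).
#' @return Object of class \code{km_curves}: list with \code{curves} (named
#'   list of per-group data.frames: time, n_risk, n_event, surv, lower,
#'   upper), \code{truncation} (named numeric), \code{n} (group sizes) and
#'   the underlying \code{survfit} object.
#' @export
km_fit <- function(time, event, group = NULL, conf_level = 0.95,
                   at_risk_frac = 0.10) {
  if (any(time < 0)) stop_input("km_fit: negative times")
  if (!all(event %in% c(0, 1))) stop_input("km_fit: event must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  if (any(table(group) == 0)) group <- droplevels(group)
  dat <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat,
                           conf.type = "log", conf.int = conf_level)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) factor(rep(levels(group)[1], length(sm$time)))
         else factor(sub("^group=", "", as.character(sm$strata)),
                     levels = levels(group))
  curves <- lapply(levels(group), function(g) {
    i <- grp == g
    data.frame(time = sm$time[i], n_risk = sm$n.risk[i],
               n_event = sm$n.event[i], surv = sm$surv[i],
               lower = sm$lower[i], upper = sm$upper[i])
  })
  names(curves) <- levels(group)
  n_by <- table(group)
  trunc <- vapply(levels(group), function(g) {
    cv <- curves[[g]]
    lim <- at_risk_frac * n_by[[g]]
    t_low <- cv$time[cv$n_risk < lim]
    if (length(t_low) == 0) Inf else min(t_low)
  }, 0)
  structure(list(curves = curves, truncation = trunc,
                 n = as.integer(n_by), groups = levels(group), fit = fit,
                 conf_level = conf_level),
            class = "km_curves")
}

#' @export
print.km_curves <- function(x, ...) {
  cat("Kaplan-Meier curves (", length(x$groups), " group(s), ",
      round(100 * x$conf_level), "% CI, log scale)\n", sep = "")
  for (i in seq_along(x$groups)) {
    g <- x$groups[i]
    cat(sprintf("  %-16s n = %4d  events = %3d  truncation at %s months\n",
                g, x$n[i], sum(x$curves[[g]]$n_event),
                format(x$truncation[[g]], digits = 4)))
  }
  invisible(x)
}

#' @export
plot.km_curves <- function(x, col = seq_along(x$groups), truncate = TRUE,
                           xlab = "Months", ylab = "Survival", ...) {
  xmax <- max(vapply(x$curves, function(cv) max(cv$time), 0))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(x$groups)) {
    cv <- x$curves[[i]]
    if (truncate && is.finite(x$truncation[i]))
      cv <- cv[cv$time <= x$truncation[i], , drop = FALSE]
    lines(c(0, cv$time), c(1, cv$surv), type = "s", col = col[i])
  }
  legend("bottomleft", legend = x$groups, col = col, lty = 1, bty = "n")
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Step-function evaluation: the estimate (and CI) from the latest step time
#' at or before \code{t}; 1 before the first event. Evaluation beyond the last
#' follow-up time is returned with \code{beyond_followup = TRUE} and a
#' warning.
#'
#' @param km a \code{\link{km_fit}} object.
#' @param t time (months), non-negative.
#' @param group group name(s); default all groups.
#' @return data.frame with columns \code{group}, \code{time}, \code{surv},
#'   \code{lower}, \code{upper}, \code{beyond_followup}.
#' @export
survival_at <- function(km, t, group = km$groups) {
  if (t < 0) stop_input("survival_at: t must be >= 0")
  rows <- lapply(group, function(g) {
    cv <- km$curves[[g]]
    if (is.null(cv)) stop_input("survival_at: unknown group ", g)
    beyond <- t > max(cv$time)
    i <- max(which(cv$time <= t), 0)
    if (i == 0)
      data.frame(group = g, time = t, surv = 1, lower = 1, upper = 1,
                 beyond_followup = FALSE)
    else
      data.frame(group = g, time = t, surv = cv$surv[i], lower = cv$lower[i],
                 upper = cv$upper[i], beyond_followup = beyond)
  })
  out <- do.call(rbind, rows)
  if (any(out$beyond_followup))
    warning("survival_at: t beyond last follow-up for: ",
            paste(out$group[out$beyond_followup], collapse = ", "))
  out
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank chi-square test across k groups, k-1
#' degrees of freedom.
#'
#' @param time,event follow-up and event indicator.
#' @param group grouping factor with >= 2 non-empty levels.
#' @return list of class \code{logrank_test}: \code{statistic}, \code{df},
#'   \code{p_value}.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop_input("logrank_test: need >= 2 groups")
  if (any(table(group) == 0))
    stop_input("logrank_test: empty group: ",
               paste(names(which(table(group) == 0)), collapse = ", "))
  dat <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- nlevels(group) - 1
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; per-term hazard
#' ratios with Wald confidence intervals and p-values. Possible complete
#' separation (unbounded coefficients) is flagged rather than silently
#' reported.
#'
#' @param formula model formula with a \code{survival::Surv} response (or
#'   supply \code{time}/\code{event} columns named in \code{response}).
#' @param data data.frame of covariates.
#' @param conf_level Wald CI level (default 0.95).
#' @return Object of class \code{gscin_cox}: list with the \code{coxph}
#'   \code{fit}, a coefficient \code{table} (term, beta, HR, lower, upper,
#'   se, p), \code{loglik}, and \code{separation_flag}.
#' @export
cox_fit <- function(formula, data, conf_level = 0.95) {
  if (sum(eval(formula[[2]], data, environment(formula))[, 2]) < 1)
    stop_stat("cox_fit: no events")
  flag <- NULL
  fit <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron"),
    warning = function(w) {
      flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop_stat("cox_fit: non-convergence / inestimable coefficients after ",
              fit$iter, " iterations")
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  sep <- (!is.null(flag) && grepl("infinite|converge", flag)) ||
    any(abs(beta) > 15)
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    HR = exp(unname(beta)),
                    lower = exp(unname(beta) - z * se),
                    upper = exp(unname(beta) + z * se),
                    se = se,
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(fit = fit, table = tab, loglik = fit$loglik[2],
                 separation_flag = sep),
            class = "gscin_cox")
}

#' @export
print.gscin_cox <- function(x, digits = 4, ...) {
  cat("Cox proportional hazards (Efron ties), log-likelihood",
      format(x$loglik, digits = digits), "\n")
  if (x$separation_flag) cat("  [flag] possible complete separation\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.gscin_cox <- function(object, ...) stats::coef(object$fit)

# log partial likelihood of a fitted coxph at its solution, or refit without
# one term, for factor-level LRTs
term_lrt_p <- function(full, data, response, terms, drop_term) {
  reduced_terms <- setdiff(terms, drop_term)
  rhs <- if (length(reduced_terms) == 0) "1" else
    paste(reduced_terms, collapse = " + ")
  f_red <- stats::as.formula(paste(response, "~", rhs))
  red <- survival::coxph(f_red, data = data, ties = "efron")
  lr <- 2 * (full$loglik[2] - if (length(reduced_terms) == 0) red$loglik[1]
             else red$loglik[2])
  df <- length(stats::coef(full)) -
    (if (length(reduced_terms) == 0) 0 else length(stats::coef(red)))
  pchisq(max(lr, 0), df = max(df, 1), lower.tail = FALSE)
}

#' Stepwise backward selection for Cox models
#'
#' Starting from the full model, iteratively removes the term with the
#' largest likelihood-ratio p-value at or above \code{threshold} and refits,
#' until every retained term has p below the threshold. Whole factors are
#' removed, not individual dummy levels: the p-value per term is the LRT
#' comparing the model with and without that term.
#'
#' @param data data.frame containing \code{time}, \code{event} and the
#'   covariates.
#' @param terms character vector of covariate names to start from.
#' @param threshold retention threshold on the term-level LRT p (default
#'   0.10).
#' @param time_col,event_col names of the time/event columns (defaults
#'   \code{"time"}, \code{"event"}).
#' @return Object of class \code{backward_cox}: list with \code{retained}
#'   (character), \code{fit} (a \code{\link{cox_fit}} or NULL for the null
#'   model) and \code{history} (data.frame of dropped terms and their p).
#' @export
backward_select <- function(data, terms, threshold = 0.10,
                            time_col = "time", event_col = "event") {
  if (length(terms) == 0) stop_input("backward_select: empty term list")
  response <- paste0("survival::Surv(", time_col, ", ", event_col, ")")
  history <- data.frame(dropped = character(0), p = numeric(0))
  repeat {
    if (length(terms) == 0) {
      return(structure(list(retained = character(0), fit = NULL,
                            history = history), class = "backward_cox"))
    }
    f <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
    full <- survival::coxph(f, data = data, ties = "efron")
    pv <- vapply(terms, function(tm)
      term_lrt_p(full, data, response, terms, tm), 0)
    if (max(pv) < threshold) {
      return(structure(list(retained = terms, fit = cox_fit(f, data),
                            history = history, p_values = pv),
                       class = "backward_cox"))
    }
    worst <- terms[which.max(pv)]
    history <- rbind(history, data.frame(dropped = worst, p = max(pv)))
    terms <- setdiff(terms, worst)
  }
}

#' @export
print.backward_cox <- function(x, ...) {
  cat("backward selection:", length(x$retained), "term(s) retained")
  if (length(x$retained)) cat(":", paste(x$retained, collapse = ", "))
  cat("\n")
  if (nrow(x$history)) {
    cat("dropped (in order):\n")
    print(format(x$history, digits = 3), row.names = FALSE)
  }
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
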