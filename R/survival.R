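#' Survival-analysis inclusion filter
#'
#' Restricts the clinical table to the malignant patients eligible for
#' survival analysis: neoadjuvant-treated, metastatic-at-diagnosis and
#' non-standard-treatment patients are excluded.
#'
#' @param clinical Clinical data frame with `group`, `neoadjuvant`,
#'   `metastatic_at_diagnosis`, `nonstandard_treatment` columns.
#' @return The included subset of rows.
#' @export
survival_exclusion_filter <- function(clinical) {
  clinical[clinical$group == "malignant" &
             !clinical$neoadjuvant &
             !clinical$metastatic_at_diagnosis &
             !clinical$nonstandard_treatment, , drop = FALSE]
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function under right censoring.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical event indicators (TRUE = event observed).
#' @return Data frame of step points: time, n_risk, n_event, n_censor,
#'   surv.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1)
    stop("at least one record is required", call. = FALSE)
  fit <- survfit(Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling (configurable to
#' Efron), Wald p-values and 95% normal confidence intervals on the log
#' scale. Categorical covariates use reference-level coding; multi-level
#' terms additionally get a joint Wald test used by the elimination
#' procedure.
#'
#' @param time,event Survival outcome (months, logical event flag).
#' @param covariates Data frame of covariates (continuous metabolites on
#'   the centered log2 scale; no constant column allowed).
#' @param ties Tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return Object of class `cox_fit`: `coefficients` data frame (variable,
#'   coef, hazard_ratio, ci_low, ci_high, p_value), per-term Wald p-values
#'   `term_p`, `n`, `events`, `loglik`, and the underlying `model`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(event) < 2)
    stop("at least 2 events are required", call. = FALSE)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2, logical(1))
  if (any(const))
    stop(sprintf("constant covariate(s): %s",
                 paste(names(covariates)[const], collapse = ", ")), call. = FALSE)
  dat <- data.frame(.time = time, .event = event, covariates, check.names = FALSE)
  fit <- withCallingHandlers(
    coxph(Surv(.time, .event) ~ ., data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit)))
    stop("Cox fit failed: singular or separated covariate", call. = FALSE)
  s <- summary(fit)
  co <- data.frame(
    variable = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hazard_ratio = s$coefficients[, "exp(coef)"],
    ci_low = s$conf.int[, "lower .95"],
    ci_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  # joint Wald test per model term (equals the coefficient test for
  # single-coefficient terms)
  b <- coef(fit); v <- fit$var
  term_p <- vapply(fit$assign, function(ix) {
    w <- drop(t(b[ix]) %*% solve(v[ix, ix, drop = FALSE]) %*% b[ix])
    pchisq(w, df = length(ix), lower.tail = FALSE)
  }, numeric(1))
  structure(list(coefficients = co, term_p = term_p, n = s$n,
                 events = s$nevent, loglik = fit$loglik[2], model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d\n", x$n, x$events))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], signif, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Backwards-elimination Cox regression
#'
#' Starts from the model with all covariates. At each step the variable
#' with the largest Wald p-value is identified; if that p-value exceeds the
#' retention threshold the variable is removed and the model refitted. The
#' loop stops when every remaining variable has p at or below the threshold
#' (a boundary p equal to the threshold retains the variable) or no
#' variables remain. The full elimination record is returned.
#'
#' @param time,event Survival outcome.
#' @param covariates Data frame of candidate covariates.
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @param ties Tie handling, passed to [cox_fit()].
#' @return Object of class `elimination_trace`: `trace` data frame (step,
#'   variable_removed, p_value), `final_variables`, `final_fit` (a
#'   [cox_fit()], or `NULL` when everything was eliminated).
#' @export
cox_backwards_eliminate <- function(time, event, covariates, alpha = 0.05,
                                    ties = "breslow") {
  vars <- names(covariates)
  trace <- data.frame(step = integer(0), variable_removed = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  fit <- cox_fit(time, event, covariates[, vars, drop = FALSE], ties = ties)
  step <- 0L
  repeat {
    worst <- which.max(fit$term_p)
    if (fit$term_p[worst] <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     variable_removed = names(fit$term_p)[worst],
                                     p_value = unname(fit$term_p[worst]),
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, names(fit$term_p)[worst])
    if (length(vars) == 0) {
      fit <- NULL
      break
    }
    fit <- cox_fit(time, event, covariates[, vars, drop = FALSE], ties = ties)
  }
  structure(list(trace = trace, final_variables = vars, final_fit = fit),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("elimination_trace: %d variable(s) removed, %d retained\n",
              nrow(x$trace), length(x$final_variables)))
  if (nrow(x$trace) > 0) print(x$trace, row.names = FALSE)
  if (!is.null(x$final_fit)) print(x$final_fit)
  invisible(x)
}

#' Dichotomize values at their mean
#'
#' Labels each value "above" or "below" (at-or-below) the mean of the
#' provided values — the split used to contrast Kaplan-Meier curves for
#' high versus low Phenylalanine.
#'
#' @param values Numeric vector (>= 2 values, not all equal).
#' @return Factor with levels below/above.
#' @export
dichotomize_by_mean <- function(values) {
  if (length(values) < 2)
    stop("at least 2 values are required", call. = FALSE)
  if (diff(range(values)) == 0)
    stop("degenerate split: all values equal", call. = FALSE)
  factor(ifelse(values > mean(values), "above", "below"),
         levels = c("below", "above"))
}

#' Pearson correlation
#'
#' Standard product-moment correlation (used for the RFS-OS association).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  cor(x, y)
}
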