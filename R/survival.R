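# Median-split prognosis analysis: Kaplan-Meier estimation, log-rank test and
# univariate Cox proportional-hazards regression (Efron tie handling), built
# on the survival package.

#' Median split of an expression vector
#'
#' Dichotomizes samples at the median: values greater than or equal to the
#' median are labelled `"high"`, the rest `"low"` (for even n the median is
#' the midpoint of the two central order statistics, so the split is exact).
#' Equal-to-median values join the high group — a deterministic, documented
#' tie rule.
#'
#' @param values numeric vector, length >= 2.
#' @return character vector of `"high"`/`"low"` labels, same length/names.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 samples to split")
  if (anyNA(values)) stop("missing values in expression vector")
  if (length(unique(values)) == 1L)
    stop("degenerate split: all values identical")
  med <- stats::median(values)
  labels <- ifelse(values >= med, "high", "low")
  names(labels) <- names(values)
  labels
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator. With no censoring the curve equals the empirical
#' survivor function; censored subjects leave the risk set after their time.
#'
#' @param times nonnegative durations.
#' @param events event indicators, 1 = event, 0 = censored.
#' @return object of class `km_curve`: list with `event_times` (ascending),
#'   `survival` (nonincreasing, starts below 1 only after the first event),
#'   `at_risk`, and `n`.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(event_times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,",
      length(x$event_times), "distinct times\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "time", ylab = "survival", ...) {
  graphics::plot(stats::stepfun(x$event_times, c(1, x$survival)),
                 do.points = FALSE, xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the shared event times;
#' p-value from the chi-square distribution with 1 degree of freedom. The
#' statistic is invariant to label exchange and to any common strictly
#' increasing transform of the times.
#'
#' @param times_a,events_a survival data for group A.
#' @param times_b,events_b survival data for group B.
#' @return list with `chi2`, `p_value`, `n_a`, `n_b`, `events_total`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  check_surv_input(times_a, events_a)
  check_surv_input(times_b, events_b)
  ev <- sum(events_a) + sum(events_b)
  if (ev == 0) stop("no events in either group")
  grp <- c(rep("a", length(times_a)), rep("b", length(times_b)))
  sd <- survival::survdiff(
    survival::Surv(c(times_a, times_b), c(events_a, events_b)) ~ grp)
  list(chi2 = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       n_a = length(times_a), n_b = length(times_b), events_total = ev)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood maximization with Efron handling of tied event times;
#' hazard ratio with Wald 95% confidence interval and p-value. The covariate
#' may be a binary group indicator (e.g. the median-split label) or a
#' continuous expression value. Fewer than 10 events triggers a warning.
#'
#' @param times nonnegative durations.
#' @param events event indicators (0/1).
#' @param covariate numeric vector (or 2-level factor/character, coded 0/1 in
#'   level order).
#' @return list with `hr`, `hr_ci` (lower, upper), `cox_p`, `log_hr`, `se`,
#'   `n`, `n_events`.
#' @export
cox_univariate <- function(times, events, covariate) {
  check_surv_input(times, events)
  if (is.character(covariate) || is.factor(covariate)) {
    f <- factor(covariate)
    if (nlevels(f) != 2L)
      stop("categorical covariate must have exactly 2 levels")
    covariate <- as.numeric(f) - 1
  }
  if (length(covariate) != length(times))
    stop("covariate length mismatch")
  if (length(unique(covariate)) == 1L)
    stop("constant covariate")
  if (sum(events) < 10)
    warning("fewer than 10 events; Cox estimates may be unstable")
  fit <- survival::coxph(survival::Surv(times, events) ~ covariate,
                         ties = "efron")
  if (is.na(fit$coefficients) || !is.finite(fit$coefficients))
    stop("Cox partial-likelihood maximization failed to converge")
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1L, 1L]))
  z <- beta / se
  list(hr = exp(beta),
       hr_ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       cox_p = 2 * stats::pnorm(-abs(z)),
       log_hr = beta, se = se,
       n = length(times), n_events = sum(events))
}

check_surv_input <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (length(times) == 0L) stop("empty survival data")
  if (anyNA(times) || anyNA(events)) stop("missing survival values")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  invisible(TRUE)
}

#' Median-split survival analysis per gene and cancer
#'
#' For each target gene and each cancer type: tumor samples with known
#' survival are split at the gene's median expression into high/low groups,
#' compared by the log-rank test, and the gene's association with overall
#' survival is quantified by univariate Cox regression (continuous expression
#' by default, or the binary split when `cox_covariate = "binary"`). Samples
#' with missing survival are dropped with a message.
#'
#' @param matrix genes x samples expression matrix.
#' @param clinical validated clinical table (see [read_clinical()]).
#' @param genes target gene identifiers; default all matrix genes.
#' @param cox_covariate `"continuous"` (default) or `"binary"`.
#' @param min_samples minimum usable tumor samples per cancer (default 10).
#' @return `data.frame`: one row per (gene, cancer) with group sizes,
#'   log-rank chi-square and p, hazard ratio with 95% CI and Cox p, plus a
#'   `note` column for skipped combinations.
#' @export
survival_analysis <- function(matrix, clinical, genes = rownames(matrix),
                              cox_covariate = c("continuous", "binary"),
                              min_samples = 10L) {
  cox_covariate <- match.arg(cox_covariate)
  validate_expression_matrix(matrix)
  check_sample_overlap(colnames(matrix), clinical$sample_id)
  genes <- intersect(genes, rownames(matrix))
  tum <- clinical[clinical$tissue == "tumor" &
                    clinical$sample_id %in% colnames(matrix), , drop = FALSE]
  n_missing <- sum(is.na(tum$os_time) | is.na(tum$os_event))
  if (n_missing > 0)
    message(n_missing, " tumor sample(s) without survival dropped")
  tum <- tum[!is.na(tum$os_time) & !is.na(tum$os_event), , drop = FALSE]
  rows <- list()
  for (ca in sort(unique(as.character(tum$cancer_type)))) {
    sub <- tum[tum$cancer_type == ca, , drop = FALSE]
    for (g in genes) {
      expr <- matrix[g, sub$sample_id]
      row <- data.frame(gene = g, cancer_type = ca,
                        n_high = NA_integer_, n_low = NA_integer_,
                        logrank_chi2 = NA_real_, logrank_p = NA_real_,
                        hr = NA_real_, hr_lower = NA_real_, hr_upper = NA_real_,
                        cox_p = NA_real_, note = "", stringsAsFactors = FALSE)
      if (nrow(sub) < min_samples || sum(sub$os_event) == 0) {
        row$note <- "too few samples or no events"
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- tryCatch({
        lab <- median_split(expr)
        hi <- lab == "high"
        lr <- logrank_test(sub$os_time[hi], sub$os_event[hi],
                           sub$os_time[!hi], sub$os_event[!hi])
        cov <- if (cox_covariate == "continuous") expr else as.numeric(hi)
        cx <- suppressWarnings(cox_univariate(sub$os_time, sub$os_event, cov))
        row$n_high <- sum(hi); row$n_low <- sum(!hi)
        row$logrank_chi2 <- lr$chi2; row$logrank_p <- lr$p_value
        row$hr <- cx$hr; row$hr_lower <- cx$hr_ci[1L]
        row$hr_upper <- cx$hr_ci[2L]; row$cox_p <- cx$cox_p
        row
      }, error = function(e) {
        row$note <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), cancer_type = character(),
                      n_high = integer(), n_low = integer(),
                      logrank_chi2 = numeric(), logrank_p = numeric(),
                      hr = numeric(), hr_lower = numeric(),
                      hr_upper = numeric(), cox_p = numeric(),
                      note = character(), stringsAsFactors = FALSE)
  out
}
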