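## Recurrence-free survival: Kaplan-Meier product-limit estimation and
## log-rank comparison of predicted outcome groups.  Estimation is
## delegated to the survival package; this module fixes the package's
## conventions (events before censorings at tied times, five-year readout
## as the step value at the last event time <= 60 months).

#' Kaplan--Meier product-limit estimate
#'
#' @param records Data frame with `time` (months, > 0) and `event`
#'   (logical; `FALSE` = censored).
#' @return An object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `std_err` (Greenwood standard error of S),
#'   `five_year_rfs` (S at 60 months), `median_followup`.
#' @export
#' @examples
#' km <- km_estimate(data.frame(time = 1:4, event = c(TRUE, TRUE, FALSE, TRUE)))
#' km$surv  # 0.75 0.50 0.50 0.00
km_estimate <- function(records) {
  if (!nrow(records)) stop("no survival records", call. = FALSE)
  if (any(records$time <= 0)) stop("times must be > 0", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records, conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  s60 <- summary(fit, times = 60, extend = TRUE)$surv
  structure(list(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                 n_censor = sm$n.censor, surv = sm$surv, std_err = sm$std.err,
                 five_year_rfs = s60,
                 median_followup = stats::median(records$time),
                 n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median follow-up %.1f months\n",
              x$n, sum(x$n_event), x$median_followup))
  cat(sprintf("  five-year RFS: %.1f%%\n", 100 * x$five_year_rfs))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, add = FALSE, col = 1, xlab = "Months",
                          ylab = "Recurrence-free survival", ...) {
  t <- c(0, x$time); s <- c(1, x$surv)
  if (!add)
    graphics::plot(t, s, type = "s", ylim = c(0, 1), col = col,
                   xlab = xlab, ylab = ylab, ...)
  else graphics::lines(t, s, type = "s", col = col, ...)
  invisible(x)
}

#' Log-rank test between two record sets
#'
#' Standard one-degree-of-freedom log-rank comparison of two
#' recurrence-free survival distributions.
#'
#' @param group_a,group_b Data frames with `time` and `event`.
#' @return List (class `logrank_test`) with `statistic` (chi-square),
#'   `p_value`, `df`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  dat <- rbind(
    data.frame(time = group_a$time, event = group_a$event, grp = "a"),
    data.frame(time = group_b$time, event = group_b$event, grp = "b"))
  if (!any(dat$event)) stop("no events in either group", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  structure(list(statistic = sd$chisq,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 df = 1L),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (df = 1), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Survival of predicted outcome groups
#'
#' Partitions patients by the classifier's predicted label, estimates a
#' Kaplan--Meier curve per predicted group, and compares them with the
#' log-rank test -- the survival read-out of the prediction model.
#'
#' @param preds Data frame with `patient_id` and `pred` (from
#'   [lopo_predict()] or a `qus_model`'s `preds`).
#' @param records Data frame with `patient_id`, `time`, `event`.
#' @return Object of class `qus_survival`: `curves` (named list of
#'   `km_curve`), `test` (`logrank_test`), `five_year_rfs` (named vector).
#' @export
predicted_group_survival <- function(preds, records) {
  ids <- match(preds$patient_id, records$patient_id)
  if (anyNA(ids))
    stop("patient_id mismatch between predictions and survival records",
         call. = FALSE)
  rec <- records[ids, ]
  groups <- split(rec, factor(preds$pred))
  groups <- Filter(nrow, groups)
  if (length(groups) < 2)
    stop("all patients predicted into one class: no groups to compare",
         call. = FALSE)
  curves <- lapply(groups, km_estimate)
  test <- logrank_test(groups[[1]], groups[[2]])
  structure(list(curves = curves, test = test,
                 five_year_rfs = vapply(curves, `[[`, numeric(1),
                                        "five_year_rfs")),
            class = "qus_survival")
}

#' @export
print.qus_survival <- function(x, ...) {
  cat("Predicted-group recurrence-free survival:\n")
  for (nm in names(x$curves))
    cat(sprintf("  predicted %-14s five-year RFS %.1f%% (n = %d)\n",
                nm, 100 * x$curves[[nm]]$five_year_rfs, x$curves[[nm]]$n))
  print(x$test)
  invisible(x)
}

#' @export
plot.qus_survival <- function(x, col = c(2, 4), ...) {
  plot(x$curves[[1]], col = col[1], ...)
  if (length(x$curves) > 1) plot(x$curves[[2]], add = TRUE, col = col[2])
  graphics::legend("bottomleft", legend = paste("predicted", names(x$curves)),
                   col = col, lty = 1, bty = "n")
  invisible(x)
}
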