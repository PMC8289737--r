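# Bland-Altman agreement between subject metrics derived from manual and
# automatic hypnograms. Differences are taken automatic - manual.

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference (bias), 95% limits of agreement
#' `bias +/- z * sd(d)`, a 95% confidence band for the bias
#' (`bias +/- z * sd(d)/sqrt(n)`), the fraction of points inside the
#' limits, and a Kolmogorov-Smirnov p-value for normality of the
#' differences (standardised by their sample mean and SD, so the usual
#' Lilliefors caveat applies).
#'
#' @param manual numeric vector of reference (manual-staging) values.
#' @param automatic numeric vector of comparison (automatic-staging) values.
#' @param z limit multiplier; 1.96 for 95% limits (some authors use 2.0).
#' @param cohort optional per-subject cohort labels carried into the plot
#'   data.
#' @return an object of class `rbd_bland_altman`.
#' @export
bland_altman <- function(manual, automatic, z = 1.96, cohort = NULL) {
  stopifnot(length(manual) == length(automatic))
  ok <- is.finite(manual) & is.finite(automatic)
  manual <- manual[ok]; automatic <- automatic[ok]
  n <- length(manual)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 finite pairs")
  d <- automatic - manual
  m <- (automatic + manual) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * z * s
  ci <- bias + c(-1, 1) * z * s / sqrt(n)
  ks_p <- if (s > 0)
    suppressWarnings(stats::ks.test((d - bias) / s, "pnorm")$p.value)
  else NA_real_
  structure(
    list(n = n, bias = bias, sd_d = s, loa_low = loa[1], loa_high = loa[2],
         bias_ci = ci, ks_p = ks_p,
         within_loa_frac = mean(d >= loa[1] & d <= loa[2]),
         z = z, direction = "automatic - manual",
         data = tibble::tibble(mean = m, diff = d,
                               cohort = if (is.null(cohort)) NA_character_
                                        else as.character(cohort)[ok])),
    class = "rbd_bland_altman")
}

#' @export
print.rbd_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n=%d  bias=%.4g [%.4g, %.4g]  loa=[%.4g, %.4g]  ks p=%.3g\n",
    x$n, x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_low, x$loa_high, x$ks_p))
  invisible(x)
}

#' One-row tidy summary of a Bland-Altman result
#'
#' @param x an `rbd_bland_altman`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.rbd_bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_d,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 bias_ci_low = x$bias_ci[1], bias_ci_high = x$bias_ci[2],
                 ks_p = x$ks_p, within_loa_frac = x$within_loa_frac)
}

#' @rdname tidy.rbd_bland_altman
#' @export
glance.rbd_bland_altman <- function(x, ...) tidy(x)

#' Bland-Altman plot
#'
#' Mean-difference scatter coloured by cohort with the bias line, a shaded
#' bias confidence band and dashed limits of agreement.
#'
#' @param object an `rbd_bland_altman`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rbd_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$bias_ci[1], ymax = object$bias_ci[2],
                      alpha = 0.2) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cohort)) +
    ggplot2::labs(x = "Mean of methods", y = "Automatic - manual",
                  subtitle = sprintf("bias %.3g, LoA [%.3g, %.3g], KS p = %.3g",
                                     object$bias, object$loa_low,
                                     object$loa_high, object$ks_p))
}

#' Agreement suite over the headline RBD metrics
#'
#' Runs [bland_altman()] for each requested metric between two
#' subject-metric tables computed from manual and automatic staging.
#' Subjects are matched by `subject_id`; a mismatch is an error naming the
#' offending ids.
#'
#' @param manual_metrics,auto_metrics subject metric tibbles with
#'   `subject_id`, `cohort` and metric columns.
#' @param metrics metric names to compare; defaults to the three most
#'   important EMG detection metrics.
#' @return named list of `rbd_bland_altman` objects with a `tidy()`-style
#'   summary attached as attribute `"summary"`.
#' @export
agreement_suite <- function(manual_metrics, auto_metrics,
                            metrics = c("AtoniaIndex_REM", "AtoniaIndexRatio",
                                        "FractalExponentRatio")) {
  miss <- c(setdiff(manual_metrics$subject_id, auto_metrics$subject_id),
            setdiff(auto_metrics$subject_id, manual_metrics$subject_id))
  if (length(miss))
    stop("subject mismatch between metric tables: ",
         paste(unique(miss), collapse = ", "))
  auto <- auto_metrics[match(manual_metrics$subject_id,
                             auto_metrics$subject_id), ]
  out <- lapply(metrics, function(mm) {
    bland_altman(manual_metrics[[mm]], auto[[mm]],
                 cohort = manual_metrics$cohort)
  })
  names(out) <- metrics
  smry <- dplyr::bind_rows(lapply(out, tidy), .id = "metric")
  attr(out, "summary") <- smry
  out
}
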