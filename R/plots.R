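#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hypnogram
#'
#' Classic step-trace with wake on top, NREM at the bottom and REM
#' highlighted.
#'
#' @param object a [hypnogram()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hypnogram <- function(object, ...) {
  df <- as_tibble(object)
  df$level <- dplyr::case_match(df$stage, "W" ~ 3, "REM" ~ 2, "NREM" ~ 1,
                                .default = NA_real_)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$onset_s / 3600, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$stage == "REM", ], colour = "red",
                        size = 0.4) +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = c("NREM", "REM", "W"),
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = "Hours", y = NULL)
}
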