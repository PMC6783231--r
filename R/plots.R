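#' Plot observed vs expected count frequencies for a fitted model
#'
#' A hanging-rootogram-style diagnostic: bars are observed frequencies of each
#' count, points/lines the frequencies the fitted model expects
#' (`sum_i P(Y_i = j)` at the fitted parameters). Zero-inflated fits that
#' track the zero spike closely will show matched bars at zero.
#'
#' @param object A `zicount_fit`.
#' @param max_count Largest count displayed; defaults to the observed maximum.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zicount_fit <- function(object, max_count = NULL, ...) {
  max_count <- max_count %||% max(object$y)
  mu <- fitted_mu(object)
  pi <- fitted_pi(object)
  counts <- 0:max_count
  expected <- vapply(counts, function(j) {
    sum(exp(log_pmf(object$family, rep(j, object$n_obs), mu, pi, object$k)))
  }, numeric(1))
  observed <- vapply(counts, function(j) sum(object$y == j), numeric(1))
  df <- tibble(
    count = rep(counts, 2),
    frequency = c(observed, expected),
    kind = rep(c("observed", "expected"), each = length(counts))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$frequency)) +
    ggplot2::geom_col(
      data = function(d) d[d$kind == "observed", ],
      fill = "grey70", width = 0.8
    ) +
    ggplot2::geom_point(data = function(d) d[d$kind == "expected", ]) +
    ggplot2::geom_line(data = function(d) d[d$kind == "expected", ]) +
    ggplot2::labs(
      title = paste0(toupper(object$family), " fit: observed vs expected counts"),
      x = "count", y = "frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the fit statistics of a model comparison
#'
#' Dot plot of AIC and BIC per family (smaller is better); the selected
#' family, when the three criteria agree, is highlighted.
#'
#' @param object A `zicount_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zicount_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$fit_stats[!is.na(object$fit_stats$loglik), ],
    cols = c("AIC", "BIC"), names_to = "criterion", values_to = "value"
  )
  df$selected <- df$family == (object$selected %||% NA_character_)
  ggplot2::ggplot(df, ggplot2::aes(x = toupper(.data$family), y = .data$value,
                                   shape = .data$criterion,
                                   colour = .data$selected)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(title = "Model comparison (smaller is better)",
                  x = NULL, y = "information criterion") +
    ggplot2::theme_minimal()
}
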