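#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a battery of domain-index analyses
#'
#' @param x A `metstop_battery` object from [run_paper_battery()].
#' @param ... Unused.
#' @return A tibble with one row per regression/correlation pair: `response`,
#'   `predictor`, `slope`, `intercept`, `r_squared`, `F`, `df_model`,
#'   `df_residual`, `p` (regression), `n`, `r`, `p_correlation`.
#' @export
tidy.metstop_battery <- function(x, ...) {
  x$analyses
}

#' One-row summary of a battery of domain-index analyses
#'
#' @param x A `metstop_battery` object.
#' @param alpha Significance level for the significant-analysis count
#'   (default 0.05, the level the analyses are reported at).
#' @param ... Unused.
#' @return A one-row tibble: `n_domains`, `n_analyses`, `n_significant`,
#'   `n_skipped`.
#' @export
glance.metstop_battery <- function(x, alpha = 0.05, ...) {
  tibble(
    n_domains = nrow(x$data),
    n_analyses = nrow(x$analyses),
    n_significant = sum(x$analyses$p < alpha),
    n_skipped = sum(grepl("skipped", x$notes))
  )
}

#' Scatter plots of the battery analyses
#'
#' One panel per analysis with the fitted least-squares line, annotated with
#' r and the regression p-value.
#'
#' @param object A `metstop_battery` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metstop_battery <- function(object, ...) {
  panels <- purrr::pmap(
    list(object$analyses$response, object$analyses$predictor,
         object$analyses$r, object$analyses$p),
    function(resp, pred, r, p) {
      d <- object$data[, c(pred, resp)]
      names(d) <- c("x", "y")
      d <- d[complete.cases(d), ]
      tibble(x = d$x, y = d$y,
             panel = sprintf("%s ~ %s  (r = %.3f, p = %.4f)", resp, pred, r, p))
    }
  )
  dat <- bind_rows(panels)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "predictor", y = "response") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the modification map of one domain
#'
#' Shows each residue position of a domain along the x axis with the three
#' site windows shaded, K/R positions ticked, and located modification
#' records as points.
#'
#' @param aligned_seq The domain's aligned sequence.
#' @param windows A `metstop_windows` tibble.
#' @param ptms Located PTM tibble (with `position`), may be empty.
#' @return A ggplot object.
#' @export
plot_site_map <- function(aligned_seq, windows, ptms) {
  seq_chars <- strsplit(gsub("-", "", aligned_seq, fixed = TRUE), "")[[1]]
  n_res <- length(seq_chars)
  res <- tibble(
    position = seq_len(n_res),
    letter = toupper(seq_chars),
    site = residue_site(aligned_seq, seq_len(n_res), windows)
  )
  cols <- position_to_column(aligned_seq, seq_len(n_res))
  shade <- tibble(
    site = windows$site,
    xmin = vapply(windows$start, function(s) {
      hits <- which(cols >= s); if (length(hits)) min(hits) else NA_real_
    }, numeric(1)),
    xmax = vapply(windows$end, function(e) {
      hits <- which(cols <= e); if (length(hits)) max(hits) else NA_real_
    }, numeric(1))
  )
  shade <- shade[!is.na(shade$xmin) & shade$xmax >= shade$xmin, ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = shade,
                       ggplot2::aes(xmin = .data$xmin - 0.5,
                                    xmax = .data$xmax + 0.5,
                                    ymin = 0, ymax = 1, fill = .data$site),
                       alpha = 0.25) +
    ggplot2::geom_point(data = dplyr::filter(res, .data$letter %in% c("K", "R")),
                        ggplot2::aes(x = .data$position, y = 0.25),
                        shape = 3, size = 1.5)
  if (nrow(ptms) > 0) {
    p <- p + ggplot2::geom_point(
      data = ptms,
      ggplot2::aes(x = .data$position, y = 0.75, colour = .data$ptm_type),
      size = 2
    )
  }
  p +
    ggplot2::scale_y_continuous(breaks = c(0.25, 0.75),
                                labels = c("K/R residues", "modifications"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "sequence position", y = NULL, fill = "window") +
    ggplot2::theme_minimal()
}
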