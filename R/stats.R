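#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-deletes incomplete pairs, then computes the sample Pearson
#' correlation; the p-value comes from the t transform
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `r`, `p`, `n`, `df`.
#' @examples
#' pearson(1:10, (1:10) + rnorm(10))
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("degenerate input: zero variance")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = n, df = n - 2L)
}

#' Simple least-squares regression
#'
#' Ordinary least squares of `y` on a single predictor `x`, with the model F
#' statistic on (1, n - 2) degrees of freedom and its two-sided p-value.
#' Incomplete pairs are dropped.
#'
#' @param y Response vector.
#' @param x Predictor vector.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `F`,
#'   `df_model`, `df_residual`, `p`, `n`.
#' @examples
#' ols_simple(c(1, 1, 3, 3), c(0, 1, 2, 3))
#' @export
ols_simple <- function(y, x) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0) abort("degenerate input: zero variance in x")
  fit <- lm(y ~ x)
  s <- summary(fit)
  fstat <- unname(s$fstatistic)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    F = fstat[1],
    df_model = as.integer(fstat[2]),
    df_residual = as.integer(fstat[3]),
    p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    n = n
  )
}

#' Paired t-test
#'
#' Two-sided paired t-test: `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1`
#' degrees of freedom, where `d = a - b`. Pairs with a missing member are
#' dropped.
#'
#' @param a,b Numeric vectors of equal length (paired observations).
#' @return One-row tibble: `t`, `df`, `p`, `n`.
#' @examples
#' paired_t(c(2, 4, 3), c(1, 1, 2))
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) abort("need at least 2 complete pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    abort("degenerate input: all paired differences are identical")
  }
  tt <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  tibble(t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
         p = tt$p.value, n = n)
}

#' Class-count summaries of a domain table
#'
#' Counts domains per Membrane Affinity Index label (S/W/N; undetermined rows
#' excluded) and per membrane-selectivity class computed from LSI recomputed
#' out of the ligand column (undetermined ligand sets excluded).
#'
#' @param domains A domain feature tibble.
#' @return Tibble with columns `index` ("mai" or "selectivity"), `class`, `n`.
#' @examples
#' summarize_classes(px_domain_table())
#' @export
summarize_classes <- function(domains) {
  mai_levels <- c("S", "W", "N")
  mai_col <- if ("mai" %in% names(domains)) domains$mai else character(0)
  mai_n <- vapply(mai_levels, function(l) sum(mai_col == l, na.rm = TRUE),
                  integer(1))
  ligands <- if ("ligands" %in% names(domains)) domains$ligands else list()
  determined <- map_lgl(ligands, function(l) {
    !(length(l) == 1 && is.na(l))
  })
  lsi <- map_int(ligands[determined],
                 function(l) compute_lsi(l)$lsi)
  sel <- selectivity_class(lsi)
  sel_levels <- levels(sel)
  sel_n <- vapply(sel_levels, function(l) sum(sel == l), integer(1))
  bind_rows(
    tibble(index = "mai", class = mai_levels, n = unname(mai_n)),
    tibble(index = "selectivity", class = sel_levels, n = unname(sel_n))
  )
}

#' Run the full regression/correlation battery on a domain feature table
#'
#' Runs the five analyses relating the domain indices -- PSS on MSS, PSS on
#' LSI, MSS on LSI, expression on MSS, expression on PSS -- each as a simple
#' regression plus the matching Pearson correlation, together with the class
#' count summaries. Missing values are deleted pairwise per analysis, so
#' LSI-based analyses run on the LSI-determined subset while the others use
#' every row.
#'
#' @param domains A domain feature tibble with columns `mss`, `pss`, `lsi`,
#'   `expression` (NA allowed).
#' @return An object of class `metstop_battery`: a list with `analyses` (one
#'   row per predictor/response pair), `class_counts`, and `notes` (character
#'   vector recording skipped analyses and caveats). Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on it.
#' @examples
#' bat <- run_paper_battery(px_domain_table())
#' tidy(bat)
#' @export
run_paper_battery <- function(domains) {
  specs <- list(
    c(response = "pss", predictor = "mss"),
    c(response = "pss", predictor = "lsi"),
    c(response = "mss", predictor = "lsi"),
    c(response = "expression", predictor = "mss"),
    c(response = "expression", predictor = "pss")
  )
  notes <- character(0)
  rows <- list()
  for (sp in specs) {
    y <- domains[[sp[["response"]]]]
    x <- domains[[sp[["predictor"]]]]
    res <- tryCatch({
      reg <- ols_simple(y, x)
      ct <- pearson(x, y)
      dplyr::bind_cols(
        tibble(response = sp[["response"]], predictor = sp[["predictor"]]),
        reg,
        tibble(r = ct$r, p_correlation = ct$p)
      )
    }, error = function(e) {
      notes <<- c(notes, paste0(sp[["response"]], " ~ ", sp[["predictor"]],
                                ": skipped (", conditionMessage(e), ")"))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) {
    abort(paste0("no analysis could be run:\n",
                 paste(notes, collapse = "\n")))
  }
  analyses <- bind_rows(rows)
  class_counts <- tryCatch(summarize_classes(domains), error = function(e) {
    notes <<- c(notes, paste0("class counts skipped (", conditionMessage(e), ")"))
    NULL
  })
  notes <- c(notes, paste0(
    "correlation degrees of freedom are n - 2; LSI-based analyses use the ",
    "LSI-determined subset (pairwise deletion)"))
  structure(
    list(analyses = analyses, class_counts = class_counts,
         notes = notes, data = domains),
    class = "metstop_battery"
  )
}

#' @export
print.metstop_battery <- function(x, ...) {
  cat("Domain index battery:", nrow(x$analyses), "analyses\n\n")
  df <- as.data.frame(x$analyses)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  if (!is.null(x$class_counts)) {
    cat("\nClass counts:\n")
    print(as.data.frame(x$class_counts), row.names = FALSE)
  }
  if (length(x$notes) > 0) {
    cat("\nNotes:\n")
    cat(paste0(" - ", x$notes, collapse = "\n"), "\n")
  }
  invisible(x)
}
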