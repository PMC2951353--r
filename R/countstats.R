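#' Aberration counts for one cell line
#'
#' Container for per-preparation chromosomal aberration scoring: the
#' number of metaphase spreads analyzed and the counts of each
#' aberration subtype (chromatid gaps/breaks, isochromatid gaps/breaks).
#'
#' @param n_cells Number of cells (metaphase spreads) analyzed.
#' @param chromatid_gaps,chromatid_breaks,isochromatid_gaps,isochromatid_breaks
#'   Subtype counts (non-negative integers).
#' @param label Optional cell-line label.
#' @return An object of class `"aberration_count"` with the subtype
#'   counts and the total `x`.
#' @export
aberration_count <- function(n_cells, chromatid_gaps = 0L,
                             chromatid_breaks = 0L, isochromatid_gaps = 0L,
                             isochromatid_breaks = 0L, label = NA_character_) {
  counts <- c(chromatid_gaps = as.integer(chromatid_gaps),
              chromatid_breaks = as.integer(chromatid_breaks),
              isochromatid_gaps = as.integer(isochromatid_gaps),
              isochromatid_breaks = as.integer(isochromatid_breaks))
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  if (any(counts < 0L)) stop("subtype counts must be >= 0", call. = FALSE)
  structure(list(label = label, n_cells = n_cells, counts = counts,
                 x = sum(counts)),
            class = "aberration_count")
}

#' Poisson rate estimate for event counts over N cells
#'
#' For x events observed over N cells the per-cell rate is estimated as
#' `x/N` with standard error `sqrt(x)/N`, the standard error of a
#' Poisson count.  Values are reported at full precision together with
#' the half-up 2-decimal rounding used in printed tables (so x = 12,
#' N = 100 prints as `0.12 +/- 0.03`).
#'
#' @param x Total event count, or an [aberration_count()] (in which case
#'   `n` is taken from it).
#' @param n Number of cells.
#' @return An object of class `"rate_estimate"` with `mean`, `se`,
#'   `mean_2dp`, `se_2dp`, `x`, `n`.
#' @export
poisson_rate <- function(x, n = NULL) {
  if (inherits(x, "aberration_count")) {
    n <- x$n_cells
    x <- x$x
  }
  x <- as.numeric(x); n <- as.numeric(n)
  if (is.null(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (x < 0) stop("x must be >= 0", call. = FALSE)
  m <- x / n
  se <- sqrt(x) / n
  structure(list(mean = m, se = se,
                 mean_2dp = round_half_up(m, 2L),
                 se_2dp = round_half_up(se, 2L),
                 x = x, n = n),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f per cell (x = %g, N = %g)\n",
              x$mean_2dp, x$se_2dp, x$x, x$n))
  invisible(x)
}

#' Mann-Whitney U test for two SCE samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of per-cell
#' sister-chromatid-exchange counts.  With `mode = "auto"` the exact
#' distribution is used when the smaller sample has at most 8
#' observations and there are no ties (two-sided p as twice the
#' one-sided exact tail, capped at 1); otherwise the normal
#' approximation with tie and continuity corrections is used.  The
#' computation is delegated to [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors of per-cell counts (non-empty).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A list with `U` (the statistic for sample `a`), `p`
#'   (two-sided), and `method`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(mode,
                  auto = min(length(a), length(b)) <= 8L && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties) {
    stop("exact mode is unavailable with ties; use mode = 'approx'",
         call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' UV-induced SCE by subtraction of the spontaneous level
#'
#' The induced number of SCEs per cell is the mean of the treated
#' sample minus the mean of the untreated control, with standard error
#' combined in quadrature from the two samples' standard errors of the
#' mean.
#'
#' @param treated,control Numeric vectors of per-cell SCE counts.
#' @return A list with `mean` (induced SCEs per cell), `se`, and the
#'   two sample summaries.
#' @export
induced_sce <- function(treated, control) {
  treated <- as.numeric(treated); control <- as.numeric(control)
  if (length(treated) == 0L || length(control) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  se_t <- sem(treated); se_c <- sem(control)
  list(mean = mean(treated) - mean(control),
       se = sqrt(se_t^2 + se_c^2),
       treated = list(mean = mean(treated), se = se_t, n = length(treated)),
       control = list(mean = mean(control), se = se_c, n = length(control)))
}
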