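#' Cell length statistics for one condition
#'
#' Arithmetic mean and sample standard deviation of tip-to-tip cell lengths.
#'
#' @param cells data.frame with a `length_um` column (> 0); at least 2 cells.
#' @return list with `mean_um`, `sd_um`, `n`.
#' @export
length_stats <- function(cells) {
  if (nrow(cells) < 2) stop("insufficient data: need >= 2 cells")
  if (any(cells$length_um <= 0)) stop("cell lengths must be > 0")
  list(mean_um = mean(cells$length_um), sd_um = stats::sd(cells$length_um),
       n = nrow(cells))
}

#' Myoblast fusion index
#'
#' Fraction of scored cells that are syncytial: cells with three or more
#' nuclei are scored as fused, and the denominator is all scored cells
#' (mono- plus multi-nucleated).
#'
#' @param cells data.frame with an integer `nuclei` column (>= 1).
#' @return fusion index in \[0, 1\].
#' @examples
#' fusion_index(data.frame(nuclei = c(2, 3, 5)))  # 2/3
#' @export
fusion_index <- function(cells) {
  if (nrow(cells) < 1) stop("empty input: no cells")
  nuc <- cells$nuclei
  if (any(nuc < 1) || any(nuc != round(nuc))) {
    stop("nuclei counts must be integers >= 1")
  }
  mean(nuc >= 3)
}

#' Microtubule orderliness versus cell length regression
#'
#' Unweighted ordinary least-squares fit of the per-condition Kuiper
#' alignment statistic against mean cell length, the relationship used to
#' link array order to a cell's ability to elongate.
#'
#' @param summaries data.frame with one row per condition: columns
#'   `mean_length_um` and `kuiper_K` (plus any identifiers, carried through
#'   to the residuals).
#' @return list with `slope` (per micrometre), `intercept`, `r` (Pearson
#'   correlation), and `residuals` (per-condition).
#' @export
orderliness_vs_length <- function(summaries) {
  if (nrow(summaries) < 3) stop("insufficient data: need >= 3 conditions")
  fit <- stats::lm(kuiper_K ~ mean_length_um, data = summaries)
  r <- if (stats::sd(summaries$kuiper_K) == 0) 0 else {
    stats::cor(summaries$mean_length_um, summaries$kuiper_K)
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r,
       residuals = unname(stats::residuals(fit)))
}
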