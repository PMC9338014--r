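#' Maximum growth rate and doubling time from an OD curve
#'
#' Sliding-window log-linear estimator: within every window of
#' \code{window} consecutive time points whose OD readings all exceed
#' \code{floor}, ln(OD) is regressed on time; the maximum slope over
#' windows is the maximum specific growth rate mu_max (per minute) and the
#' doubling time is ln(2)/mu_max.
#'
#' @param time numeric vector of time points in minutes, strictly
#'   increasing.
#' @param od numeric vector of OD readings (same length).
#' @param window number of consecutive points per regression window
#'   (default 9, i.e. 90 min at 10-min sampling; wide enough that the
#'   per-window slope variance keeps the max-over-windows bias within a
#'   few percent at 1 percent read noise).
#' @param floor OD noise floor; windows containing readings at or below it
#'   are skipped (default 0.02).
#' @param blank optional blank value subtracted from all readings first.
#' @return list with \code{mu_max} (per minute), \code{doubling_time}
#'   (minutes; \code{Inf} with \code{degenerate = TRUE} when no growth is
#'   detected).
#' @export
maxGrowthRate <- function(time, od, window = 9L, floor = 0.02,
                          blank = 0) {
    stopifnot(length(time) == length(od), window >= 2)
    if (any(diff(time) <= 0)) stop("time must be strictly increasing")
    od <- od - blank
    n <- length(od)
    if (n < window) stop("fewer points than the window size")
    slopes <- rep(NA_real_, n - window + 1L)
    for (i in seq_len(n - window + 1L)) {
        idx <- i:(i + window - 1L)
        if (any(od[idx] <= floor)) next
        slopes[i] <- stats::coef(stats::lm(log(od[idx]) ~ time[idx]))[2L]
    }
    if (all(is.na(slopes)))
        stop("no window of ", window, " points above the OD floor ", floor)
    mu <- max(slopes, na.rm = TRUE)
    if (mu <= 1e-10)  # numerically flat: no detectable growth
        return(list(mu_max = mu, doubling_time = Inf, degenerate = TRUE))
    list(mu_max = mu, doubling_time = log(2) / mu, degenerate = FALSE)
}

#' Fitness defect as a doubling-time difference
#'
#' @param dtTreated,dtUntreated doubling times in minutes (finite).
#' @return dtTreated - dtUntreated (minutes; may be negative).
#' @export
fitnessDefect <- function(dtTreated, dtUntreated) {
    stopifnot(is.finite(dtTreated), is.finite(dtUntreated))
    dtTreated - dtUntreated
}

#' Sporulation sensitivity to an Hsp90-inhibitor pre-treatment
#'
#' sensitivity = 1 - (sporulation frequency with GdA pre-treatment /
#' sporulation frequency without).
#'
#' @param freqGda,freqCtrl sporulation frequencies in [0, 1];
#'   \code{freqCtrl} must be positive.
#' @return value <= 1 (1 = complete loss of sporulation under GdA).
#' @export
sporulationSensitivity <- function(freqGda, freqCtrl) {
    stopifnot(freqGda >= 0, freqGda <= 1, freqCtrl <= 1)
    if (freqCtrl <= 0) stop("control sporulation frequency must be > 0")
    1 - freqGda / freqCtrl
}

#' Percentage of cells with Hsp104 foci
#'
#' @param nFociCells number of cells with at least one focus.
#' @param nTotal total cells scored (>= 1); counts below 500 are flagged
#'   low-N, mirroring the scoring standard of at least 500 cells per time
#'   point.
#' @return list with \code{percent} and logical \code{low_n}.
#' @export
fociPercent <- function(nFociCells, nTotal) {
    stopifnot(nTotal >= 1, nFociCells >= 0)
    if (nFociCells > nTotal)
        stop("more foci-positive cells than total cells")
    list(percent = 100 * nFociCells / nTotal, low_n = nTotal < 500)
}

#' Correlate a phenotype with per-line chimeric-complex counts
#'
#' Spearman correlation (with p value) between the number of complexes
#' containing replaced-chromosome subunits and a chosen phenotype across
#' replacement lines.
#'
#' @param records data.frame with one row per line, a
#'   \code{complex_count} column and the phenotype column.
#' @param phenotypeField name of the phenotype column.
#' @param minLines minimum number of lines (default 5).
#' @return list with \code{rho}, \code{p}, \code{n}.
#' @export
phenotypeComplexCorrelation <- function(records, phenotypeField,
                                        minLines = 5L) {
    stopifnot("complex_count" %in% names(records),
              phenotypeField %in% names(records))
    x <- records$complex_count
    y <- records[[phenotypeField]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < minLines)
        stop("need at least ", minLines, " lines with both values")
    if (length(unique(y[ok])) == 1L || length(unique(x[ok])) == 1L)
        stop("constant phenotype or count: correlation undefined")
    ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
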