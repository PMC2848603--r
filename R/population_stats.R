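#' Geometric mean
#'
#' `exp(mean(log(x)))` — the appropriate centre for per-cell signal amounts,
#' whose distributions are closer to lognormal than normal. Non-positive
#' values (possible after baseline subtraction) are excluded and counted.
#'
#' @param x Numeric vector.
#' @param na.rm Drop `NA`s first.
#' @return The geometric mean, with attribute `n_excluded` giving the number
#'   of non-positive values dropped.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0) stop("geometric_mean of an empty vector", call. = FALSE)
  pos <- x > 0
  if (!any(pos)) stop("geometric_mean needs at least one positive value",
                      call. = FALSE)
  structure(exp(mean(log(x[pos]))), n_excluded = sum(!pos))
}

#' Per-timepoint distribution statistics for a channel pair
#'
#' For each time point computes, over the per-cell totals of two channels:
#' the geometric means, the SDs of the natural-log-transformed values, and
#' the Pearson correlation of the log-transformed values. These are the
#' trajectories that expose how tightly a downstream signal follows its
#' upstream kinase and how cell-to-cell variability evolves.
#'
#' @param table Per-cell table with a `time_min` column and per-cell totals.
#' @param channels Length-2 character vector naming the channels (columns
#'   `total_<channel>` are used, or the names themselves if absent).
#' @param min_cells Time points with fewer cells are omitted with a warning
#'   (default 2).
#' @return A data frame with one row per time point: `time_min`, `n_cells`,
#'   `n_excluded` (non-positive totals), `geo_mean_<ch>`, `log_sd_<ch>`,
#'   `log_pearson`.
#' @export
timepoint_stats <- function(table, channels, min_cells = 2L) {
  stopifnot(length(channels) == 2, "time_min" %in% names(table))
  cols <- vapply(channels, function(ch) {
    cand <- paste0("total_", ch)
    if (cand %in% names(table)) cand
    else if (ch %in% names(table)) ch
    else stop(sprintf("no column for channel '%s'", ch), call. = FALSE)
  }, character(1))
  times <- sort(unique(table$time_min))
  rows <- lapply(times, function(t) {
    sub <- table[table$time_min == t, , drop = FALSE]
    x <- sub[[cols[1]]]
    y <- sub[[cols[2]]]
    ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    if (sum(ok) < min_cells) {
      warning(sprintf("time %g min: only %d usable cells, omitted",
                      t, sum(ok)), call. = FALSE)
      return(NULL)
    }
    lx <- log(x[ok]); ly <- log(y[ok])
    out <- data.frame(time_min = t, n_cells = sum(ok),
                      n_excluded = sum(!ok))
    out[[paste0("geo_mean_", channels[1])]] <- exp(mean(lx))
    out[[paste0("geo_mean_", channels[2])]] <- exp(mean(ly))
    out[[paste0("log_sd_", channels[1])]] <- sd(lx)
    out[[paste0("log_sd_", channels[2])]] <- sd(ly)
    out$log_pearson <- if (sd(lx) == 0 || sd(ly) == 0) NA_real_ else cor(lx, ly)
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    stop("no time point had enough usable cells", call. = FALSE)
  do.call(rbind, rows)
}

#' Inter-experiment normalization by per-experiment scaling factors
#'
#' Replicated experiments measured in arbitrary fluorescence units differ by
#' unknown multiplicative factors. Treating all K samples as internal
#' standards, a scaling factor \eqn{a_j} is assigned to each experiment j so
#' the scaled replicates agree as closely as possible:
#' the default `"iterative"` method minimizes
#' \eqn{\sum_{j,k} (a_j x_{jk} - m_k)^2} with \eqn{m_k} the cross-experiment
#' mean of the scaled k-th sample, alternating updates of \eqn{m_k} and
#' \eqn{a_j} to convergence under the gauge constraint `mean(a) = 1` (the
#' overall scale being unidentifiable). The `"geometric"` method is the
#' closed form \eqn{a_j = \exp(-\mathrm{mean}_k(\log x_{jk} -
#' \overline{\log x_{\cdot k}}))}, gauge-fixed the same way. Both reproduce
#' a pure rescaling exactly and leave within-experiment ratios untouched.
#'
#' @param x J x K matrix of raw measurements (experiments x samples), all
#'   positive.
#' @param method `"iterative"` (least squares, default) or `"geometric"`.
#' @param tol,max_iter Convergence control for the iterative method.
#' @return A list of class `"experiment_set"`: `x_raw`, `scaling_factors`
#'   (length J, mean 1), `x_norm = a_j * x_raw[j, ]`, `method`, `n_iter`.
#' @export
normalize_experiments <- function(x, method = c("iterative", "geometric"),
                                  tol = 1e-12, max_iter = 500L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all measurements must be positive and finite", call. = FALSE)
  J <- nrow(x)
  a <- rep(1, J)
  n_iter <- 0L
  if (J > 1) {
    if (method == "iterative") {
      repeat {
        n_iter <- n_iter + 1L
        m <- colMeans(a * x)
        a_new <- as.vector((x %*% m) / rowSums(x^2))
        a_new <- a_new / mean(a_new)
        if (max(abs(a_new - a)) < tol || n_iter >= max_iter) {
          a <- a_new
          break
        }
        a <- a_new
      }
    } else {
      lx <- log(x)
      dev <- sweep(lx, 2, colMeans(lx))
      a <- exp(-rowMeans(dev))
      a <- a / mean(a)
    }
  }
  structure(list(x_raw = x, scaling_factors = a, x_norm = a * x,
                 method = method, n_iter = n_iter),
            class = "experiment_set")
}

#' Baseline subtraction with clipping floor
#'
#' Subtracts a scalar baseline (the highest defensible background, e.g. the
#' smaller of a regression x-intercept and the lowest observed value) and
#' clips results at a small positive floor so that log-scale statistics
#' remain defined; the number of clipped values is reported.
#'
#' @param values Numeric vector.
#' @param baseline Scalar baseline; defaults to the minimum of `values`.
#' @param floor Positive clipping floor (default `1e-8`).
#' @return `pmax(values - baseline, floor)` with attribute `n_clipped`.
#' @export
baseline_subtract <- function(values, baseline = NULL, floor = 1e-8) {
  stopifnot(floor > 0)
  if (is.null(baseline)) baseline <- min(values)
  if (baseline > max(values))
    stop("baseline exceeds every value", call. = FALSE)
  out <- values - baseline
  n_clipped <- sum(out < floor)
  out <- pmax(out, floor)
  attr(out, "n_clipped") <- n_clipped
  out
}
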