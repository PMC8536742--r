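#' MCCV sampling design: subsample sizes and repetition counts
#'
#' A `sample_grid` is the design of a Monte Carlo cross-validation run: the
#' strictly increasing subsample sizes at which p-values are computed, and the
#' number of independent subsample draws (repetitions) performed at each size.
#'
#' @param sizes Strictly increasing integer vector of subsample sizes, all
#'   `>= 2`.
#' @param reps Positive integer vector of repetition counts, one per size.
#' @return An object of class `sample_grid`: a data frame with columns
#'   `size` and `reps`.
#' @examples
#' sample_grid(c(5, 20, 100), c(50, 25, 10))
#' @seealso [build_grid()] for the log-spaced constructor used by the
#'   default analysis profile.
#' @export
sample_grid <- function(sizes, reps) {
  if (length(sizes) == 0L) stop("invalid grid: 'sizes' is empty")
  if (length(sizes) != length(reps))
    stop("invalid grid: 'sizes' and 'reps' must have the same length")
  sizes <- as.integer(round(sizes))
  reps <- as.integer(round(reps))
  if (any(sizes < 2L)) stop("invalid grid: all sizes must be >= 2")
  if (is.unsorted(sizes, strictly = TRUE))
    stop("invalid grid: sizes must be strictly increasing")
  if (any(reps < 1L)) stop("invalid grid: all reps must be >= 1")
  structure(data.frame(size = sizes, reps = reps),
            class = c("sample_grid", "data.frame"))
}

#' Build a log-spaced MCCV grid
#'
#' Constructs `num_sizes` approximately log-spaced subsample sizes spanning
#' `[n_min, n_max]` with repetition counts interpolated geometrically from
#' `rep_max` at the smallest size to `rep_min` at the largest.  Duplicate
#' sizes produced by rounding on the log scale are dropped (the grid then has
#' fewer than `num_sizes` rows; a message reports the shrinkage).
#'
#' Log spacing concentrates sizes where the p-value curve changes fastest;
#' the repetition schedule controls both the computational budget and the
#' weight each size carries in the all-points exponential fit.
#'
#' @param n_min,n_max Smallest and largest subsample size, `2 <= n_min <
#'   n_max`.
#' @param num_sizes Number of grid sizes before duplicate removal (>= 2).
#' @param rep_max,rep_min Repetitions at `n_min` and `n_max`; interpolated
#'   geometrically in between.  `rep_max >= rep_min` gives a decreasing
#'   schedule, `rep_max <= rep_min` an increasing one.
#' @return A [sample_grid()].
#' @examples
#' build_grid(10, 1000, 3, 100, 10)   # sizes 10, 100, 1000; reps 100, 32, 10
#' @export
build_grid <- function(n_min = 2, n_max = 2500, num_sizes = 30,
                       rep_max = 500, rep_min = 20) {
  if (n_min < 2) stop("invalid grid: n_min must be >= 2")
  if (n_max <= n_min) stop("invalid grid: n_max must exceed n_min")
  if (num_sizes < 2) stop("invalid grid: num_sizes must be >= 2")
  if (rep_max < 1 || rep_min < 1) stop("invalid grid: reps must be >= 1")
  sizes <- round(exp(seq(log(n_min), log(n_max), length.out = num_sizes)))
  reps <- round(rep_max * (rep_min / rep_max)^(seq(0, 1, length.out = num_sizes)))
  keep <- !duplicated(sizes)
  if (any(!keep))
    message("build_grid: dropped ", sum(!keep),
            " duplicate size(s) after rounding; grid has ", sum(keep), " sizes")
  sample_grid(sizes[keep], reps[keep])
}

#' Default grid of the simulation-study profile
#'
#' Thirty log-spaced sizes on `[2, min(2500, cap)]` with repetitions
#' decreasing geometrically from 500 to 20.
#'
#' @param cap Upper bound on the largest size (usually the smaller group
#'   size).
#' @return A [sample_grid()].
#' @export
default_grid <- function(cap = 2500) {
  build_grid(2, min(2500, cap), 30, 500, 20)
}

#' @export
print.sample_grid <- function(x, ...) {
  cat(sprintf("MCCV sample grid: %d sizes in [%d, %d], %s total draws\n",
              nrow(x), min(x$size), max(x$size),
              format(sum(x$reps), big.mark = ",")))
  invisible(x)
}
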