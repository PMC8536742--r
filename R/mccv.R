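#' A labelled group of observations
#'
#' Bundles a label with a numeric vector of measurements from one
#' experimental condition.  Non-finite values (NA, NaN, +/-Inf) are removed
#' at construction; a message reports how many were dropped.
#'
#' @param label Character scalar naming the condition.
#' @param values Numeric vector of measurements; at least 2 finite values
#'   must remain after cleaning.
#' @return An object of class `observation_group`.
#' @examples
#' observation_group("control", rnorm(100))
#' @export
observation_group <- function(label, values) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("invalid input: 'label' must be a non-empty string")
  values <- as.numeric(values)
  bad <- !is.finite(values)
  if (any(bad)) {
    message("observation_group('", label, "'): dropped ", sum(bad),
            " non-finite value(s)")
    values <- values[!bad]
  }
  if (length(values) < 2L)
    stop("invalid input: group '", label,
         "' has fewer than 2 finite observations")
  structure(list(label = label, values = values, n_dropped = sum(bad)),
            class = "observation_group")
}

#' @export
print.observation_group <- function(x, ...) {
  cat(sprintf("observation_group '%s': %d values (median %.4g)\n",
              x$label, length(x$values), stats::median(x$values)))
  invisible(x)
}

#' Run MCCV subsampling and assemble the p-value cloud
#'
#' For each size `n_i` of the grid, draws `f_i` independent subsample pairs
#' -- `n_i` observations sampled *without replacement* from each group,
#' independently -- and computes the two-sample test p-value for each pair.
#' The collection of all `(n_i, p_i^j)` points is the p-value cloud on which
#' the exponential model is fitted.
#'
#' Reproducibility: a master `seed` deterministically spawns one RNG
#' substream per individual draw, so the same seed always yields the
#' identical cloud, and clouds for different sizes can be reproduced in
#' isolation.
#'
#' @param group_a,group_b [observation_group()] objects (plain numeric
#'   vectors are accepted and wrapped with labels "a" and "b").
#' @param grid A [sample_grid()]; its largest size must not exceed the
#'   smaller group size.
#' @param test,tail_mode,exact Passed to [two_sample_p()].  The
#'   simulation-study profile uses `tail_mode = "folded_one_sided"` and
#'   `exact = FALSE`.
#' @param seed Integer master seed.
#' @return An object of class `pvalue_cloud`: a list with
#'   \describe{
#'     \item{points}{data frame with columns `n`, `rep`, `p` (one row per
#'       draw);}
#'     \item{summaries}{data frame with one row per size: `n`, `f` (draw
#'       count), `p_mean`, `p_sem` (standard error of the mean, 0 when
#'       `f = 1`).}
#'   }
#' @examples
#' a <- observation_group("a", rnorm(200))
#' b <- observation_group("b", rnorm(200, 1))
#' cl <- run_mccv(a, b, sample_grid(c(5, 10, 20), c(8, 8, 8)), seed = 1)
#' cl$summaries
#' @export
run_mccv <- function(group_a, group_b, grid = NULL,
                     test = "mann_whitney",
                     tail_mode = c("two_sided", "folded_one_sided"),
                     seed = 1L, exact = NULL) {
  if (!inherits(group_a, "observation_group"))
    group_a <- observation_group("a", group_a)
  if (!inherits(group_b, "observation_group"))
    group_b <- observation_group("b", group_b)
  tail_mode <- match.arg(tail_mode)
  na <- length(group_a$values)
  nb <- length(group_b$values)
  if (is.null(grid)) grid <- default_grid(min(na, nb))
  if (!inherits(grid, "sample_grid")) stop("'grid' must be a sample_grid")
  if (max(grid$size) > min(na, nb))
    stop("invalid grid: size ", max(grid$size),
         " exceeds the smaller group size ", min(na, nb))

  total <- sum(grid$reps)
  seeds <- derive_seeds(seed, total)
  n_out <- integer(total)
  rep_out <- integer(total)
  p_out <- numeric(total)
  k <- 0L
  fast_mw <- identical(test, "mann_whitney")
  for (i in seq_len(nrow(grid))) {
    n <- grid$size[i]
    for (j in seq_len(grid$reps[i])) {
      k <- k + 1L
      p_out[k] <- with_seed(seeds[k], {
        xs <- group_a$values[sample.int(na, n)]
        ys <- group_b$values[sample.int(nb, n)]
        if (fast_mw) min(max(mw_p(xs, ys, tail_mode, exact),
                             .Machine$double.xmin), 1)
        else two_sample_p(xs, ys, test, tail_mode)
      })
      n_out[k] <- n
      rep_out[k] <- j
    }
  }
  points <- data.frame(n = n_out, rep = rep_out, p = p_out)
  structure(list(points = points,
                 summaries = summarise_cloud(points),
                 test = test, tail_mode = tail_mode, seed = seed,
                 labels = c(group_a$label, group_b$label),
                 group_sizes = c(na, nb)),
            class = "pvalue_cloud")
}

summarise_cloud <- function(points) {
  sizes <- sort(unique(points$n))
  out <- lapply(sizes, function(n) {
    p <- points$p[points$n == n]
    f <- length(p)
    data.frame(n = n, f = f, p_mean = mean(p),
               p_sem = if (f > 1L) sd(p) / sqrt(f) else 0)
  })
  do.call(rbind, out)
}

#' @export
print.pvalue_cloud <- function(x, ...) {
  cat(sprintf(
    "p-value cloud '%s' vs '%s': %d points at %d sizes in [%d, %d] (%s, %s)\n",
    x$labels[1], x$labels[2], nrow(x$points), nrow(x$summaries),
    min(x$points$n), max(x$points$n), x$test, x$tail_mode))
  invisible(x)
}
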