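#' Piecewise-constant reality functions
#'
#' Reality `r(t)` represents external events and is modelled as a
#' piecewise-constant, right-continuous function: `r(t) = levels[i]` for
#' `t` in the right-open interval `[jump_times[i], jump_times[i+1])`, with
#' the last level extending to `horizon`.
#'
#' @name reality
#' @rdname reality
NULL

new_reality <- function(jump_times, levels, horizon,
                        kind = "custom", meta = list()) {
  stopifnot(length(jump_times) == length(levels), length(levels) >= 1L)
  if (jump_times[1L] != 0)
    stop("the first reality segment must start at t = 0")
  if (is.unsorted(jump_times, strictly = TRUE))
    stop("reality jump times must be strictly increasing")
  if (horizon <= jump_times[length(jump_times)])
    stop("horizon must exceed the last jump time")
  structure(list(jump_times = as.numeric(jump_times),
                 levels = as.numeric(levels),
                 horizon = as.numeric(horizon),
                 kind = kind, meta = meta),
            class = "reality")
}

#' @rdname reality
#' @param r0 the constant reality level.
#' @param horizon end time (weeks).
#' @return A `reality` object.
#' @examples
#' r <- constant_reality(0, horizon = 50)
#' reality_at(r, c(0, 10, 49.9))
#' @export
constant_reality <- function(r0, horizon) {
  stopifnot(horizon > 0)
  new_reality(0, r0, horizon, kind = "constant")
}

#' @rdname reality
#' @param breaks a two-column matrix or data.frame of `(time, level)` rows,
#'   sorted by time with the first row at `t = 0`, or a list of such pairs.
#' @examples
#' # downward step followed by an upward step
#' step_reality(rbind(c(0, -4), c(1, 4)), horizon = 2)
#' @export
step_reality <- function(breaks, horizon) {
  if (is.list(breaks) && !is.data.frame(breaks))
    breaks <- do.call(rbind, lapply(breaks, function(b) as.numeric(b)))
  breaks <- as.matrix(breaks)
  if (ncol(breaks) != 2L) stop("breaks must have columns (time, level)")
  tt <- as.numeric(breaks[, 1L]); lv <- as.numeric(breaks[, 2L])
  if (anyDuplicated(tt)) stop("duplicate break times")
  if (is.unsorted(tt, strictly = TRUE)) stop("break times must be sorted")
  new_reality(tt, lv, horizon, kind = "step")
}

#' Seeded stochastic reality process
#'
#' Draws a piecewise-constant reality realization: levels are i.i.d.
#' `Normal(0, sigma_r^2)` and segment durations are i.i.d. log-normal with
#' both mean and standard deviation of the *log* duration equal to
#' `1/k_r`. Segments are generated past `horizon` and then truncated, so
#' the realization for a given seed does not depend on the horizon in the
#' retained window. Draws use R's Mersenne-Twister generator with
#' inversion sampling for normals; the ambient RNG state is left untouched.
#'
#' @param sigma_r standard deviation of the reality levels (>= 0).
#' @param k_r inverse mean log-duration (1/weeks, > 0).
#' @param seed integer RNG seed; identical seeds give identical
#'   realizations.
#' @param horizon end time (weeks).
#' @return A `reality` object; the drawn levels and durations (before
#'   truncation) are retained in `$meta`.
#' @examples
#' r <- random_reality(sigma_r = 2, k_r = 1, seed = 1, horizon = 50)
#' head(r$jump_times); head(r$levels)
#' @export
random_reality <- function(sigma_r, k_r, seed, horizon) {
  stopifnot(sigma_r >= 0, k_r > 0, horizon > 0)
  seg <- draw_reality_segments(sigma_r, k_r, seed,
                               stop_when = function(lv, du) sum(du) > horizon)
  starts <- c(0, cumsum(seg$duration))
  keep <- which(starts < horizon)
  keep <- keep[keep <= nrow(seg)]
  new_reality(starts[keep], seg$level[keep], horizon, kind = "random",
              meta = list(sigma_r = sigma_r, k_r = k_r,
                          seed = as.integer(seed)))
}

# Draws (level, duration) pairs in fixed-size blocks from a private
# Mersenne-Twister stream, so the retained prefix of a realization is the
# same for every horizon under a given seed.
draw_reality_segments <- function(sigma_r, k_r, seed, stop_when,
                                  block = 256L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  mulog <- 1 / k_r
  levels <- numeric(0); durations <- numeric(0)
  repeat {
    levels <- c(levels, stats::rnorm(block, mean = 0, sd = sigma_r))
    durations <- c(durations, stats::rlnorm(block, meanlog = mulog,
                                            sdlog = mulog))
    if (stop_when(levels, durations)) break
  }
  data.frame(level = levels, duration = durations)
}

#' @rdname random_reality
#' @param n number of segments to draw.
#' @return `random_reality_segments()` returns a data frame with columns
#'   `level` and `duration` holding the first `n` draws of the stream
#'   for the given seed, the same draws a [random_reality()] realization
#'   is built from.
#' @export
random_reality_segments <- function(sigma_r, k_r, seed, n) {
  seg <- draw_reality_segments(sigma_r, k_r, seed,
                               stop_when = function(lv, du) length(lv) >= n)
  seg[seq_len(n), , drop = FALSE]
}

#' Evaluate a reality function
#'
#' @param reality a `reality` object (or a plain function of time).
#' @param t time(s) at which to evaluate; a query exactly at a jump time
#'   returns the new level (right-open interval convention).
#' @return Numeric reality value(s).
#' @export
reality_at <- function(reality, t) {
  if (is.function(reality)) return(reality(t))
  stopifnot(inherits(reality, "reality"))
  idx <- findInterval(t, reality$jump_times, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  reality$levels[idx]
}

#' @export
print.reality <- function(x, ...) {
  cat(sprintf("reality (%s): %d segment(s) on [0, %g] weeks\n",
              x$kind, length(x$levels), x$horizon))
  if (length(x$levels) <= 6L) {
    cat(sprintf("  t=%g: r=%g\n", x$jump_times, x$levels), sep = "")
  } else {
    cat(sprintf("  levels: mean %.3g, sd %.3g\n",
                mean(x$levels), stats::sd(x$levels)))
  }
  invisible(x)
}

# jump times strictly inside (t0, t1); integration breakpoints
reality_breakpoints <- function(reality, t0, t1) {
  if (is.function(reality)) return(numeric(0))
  jt <- reality$jump_times
  jt[jt > t0 & jt < t1]
}
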