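#' Centered moving-average smoothing of a masked count series
#'
#' A centered window of `window_s` seconds (odd), shrunk symmetrically at
#' the series edges, averages the unmasked values around each second.
#' Masked seconds contribute nothing to their neighbours' averages; a window
#' containing no usable value yields `NA`.
#'
#' @param cs a `count_series`, or a numeric vector (then `mask` applies).
#' @param window_s window width in seconds (odd, >= 1; default 5).
#' @param mask logical vector when `cs` is a plain vector.
#' @return Numeric vector of smoothed values, `NA` where undefined.
#' @export
smooth_counts <- function(cs, window_s = 5, mask = NULL) {
  if (inherits(cs, "count_series")) {
    x <- as.numeric(cs$counts)
    mask <- cs$mask
  } else {
    x <- as.numeric(cs)
    if (is.null(mask)) mask <- rep(TRUE, length(x))
  }
  if (window_s < 1 || window_s %% 2 == 0)
    stop("`window_s` must be odd and >= 1", call. = FALSE)
  n <- length(x)
  h <- (window_s - 1) %/% 2
  x[!mask] <- NA_real_
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    w <- x[(i - hh):(i + hh)]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

# Best single split of x[lo..hi] (indices into the full series).
# Returns c(gain, split index = last index of the left segment) or NULL.
# kind "mean": gain = RSS reduction / sigma2 (twice the Gaussian
# log-likelihood gain with segment means and common known variance sigma2;
# sigma2 = 1 is the standard known-variance convention of binary-
# segmentation implementations).  kind "variance": gain = reduction in
# n*log(sigmahat^2) around the common mean mu.
best_split <- function(S, S2, lo, hi, kind, min_seg, sigma2, mu) {
  n <- hi - lo + 1L
  if (n < 2L * min_seg) return(NULL)
  t <- (lo + min_seg - 1L):(hi - min_seg)        # candidate left ends
  sum_ab <- function(a, b) S[b + 1L] - S[a]      # S is 0-padded cumsum
  sq_ab <- function(a, b) S2[b + 1L] - S2[a]
  nl <- t - lo + 1L
  nr <- hi - t
  sl <- sum_ab(lo, t); sr <- sum_ab(lo, hi) - sl
  ql <- sq_ab(lo, t); qr <- sq_ab(lo, hi) - ql
  if (kind == "mean") {
    rss_par <- sq_ab(lo, hi) - sum_ab(lo, hi)^2 / n
    rss <- (ql - sl^2 / nl) + (qr - sr^2 / nr)
    gain <- (rss_par - rss) / sigma2
  } else {
    ss <- function(q, s, m) q - 2 * mu * s + m * mu^2  # sum (x - mu)^2
    eps <- 1e-8
    v_par <- max(ss(sq_ab(lo, hi), sum_ab(lo, hi), n) / n, eps)
    vl <- pmax(ss(ql, sl, nl) / nl, eps)
    vr <- pmax(ss(qr, sr, nr) / nr, eps)
    gain <- n * log(v_par) - nl * log(vl) - nr * log(vr)
  }
  i <- which.max(gain)
  c(gain = gain[i], split = t[i])
}

binseg_core <- function(x, kind, penalty, max_cpts, min_seg, sigma2 = 1) {
  n <- length(x)
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  mu <- mean(x)
  segs <- list(c(lo = 1L, hi = n))
  cand <- list(best_split(S, S2, 1L, n, kind, min_seg, sigma2, mu))
  cpts <- integer(0)
  while (length(cpts) < max_cpts) {
    gains <- vapply(cand, function(z) if (is.null(z)) -Inf else z[["gain"]],
                    0)
    k <- which.max(gains)
    if (!is.finite(gains[k]) || gains[k] <= penalty) break
    sp <- as.integer(cand[[k]][["split"]])
    cpts <- sort(c(cpts, sp))
    seg <- segs[[k]]
    left <- c(lo = seg[["lo"]], hi = sp)
    right <- c(lo = sp + 1L, hi = seg[["hi"]])
    segs[[k]] <- left
    segs[[length(segs) + 1L]] <- right
    cand[[k]] <- best_split(S, S2, left[["lo"]], left[["hi"]], kind,
                            min_seg, sigma2, mu)
    cand[[length(cand) + 1L]] <- best_split(S, S2, right[["lo"]],
                                            right[["hi"]], kind, min_seg,
                                            sigma2, mu)
  }
  bounds <- c(0L, cpts, n)
  params <- vapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- x[(bounds[i] + 1L):bounds[i + 1L]]
    if (kind == "mean") mean(seg) else mean((seg - mu)^2)
  }, 0)
  list(cpts = cpts, params = params)
}

#' Binary-segmentation changepoint detection
#'
#' Greedy binary segmentation on a (smoothed) per-second series: at each
#' step the segment split with the largest reduction in cost is taken, where
#' cost is twice the negative Gaussian log-likelihood of a segment — for
#' mean-type changes, segment-specific means with a common variance fixed
#' at 1, the known-variance convention of standard binary-segmentation
#' implementations (the gain is then the raw residual-sum-of-squares
#' reduction); for variance-type changes, segment-specific variances around
#' the common mean.
#' Recursion stops when the best reduction no longer exceeds the penalty or
#' `max_cpts` is reached.  Masked (`NA`) stretches split the series into
#' contiguous runs that are segmented independently; changepoints are never
#' placed across a gap.
#'
#' @param x numeric series (typically from [smooth_counts()]); `NA` = masked.
#' @param kind `"mean"` or `"variance"`.
#' @param penalty cost reduction required per added changepoint; default is
#'   the MBIC-like `3 * log(n)` on the analyzed length.
#' @param max_cpts maximum number of changepoints; default `floor(n / 10)`.
#' @param min_seg minimum segment length; defaults to 1 for mean-type and 2
#'   for variance-type (a sample variance needs two points).
#' @return An object of class `cpt_result`: `kind`, `indices` (each the last
#'   index of a segment, strictly increasing, 1-s resolution),
#'   `segment_params` (per-segment mean or variance), `penalty_value`,
#'   `max_cpts`, `n`, `n_used`.
#' @export
binseg <- function(x, kind = c("mean", "variance"), penalty = NULL,
                   max_cpts = NULL, min_seg = NULL) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(min_seg)) min_seg <- if (kind == "mean") 1L else 2L
  ok <- !is.na(x)
  n_used <- sum(ok)
  if (is.null(penalty)) penalty <- 3 * log(max(n_used, 2))
  if (is.null(max_cpts)) max_cpts <- max(1L, floor(n_used / 10))
  out <- structure(
    list(kind = kind, indices = integer(0), segment_params = numeric(0),
         penalty_value = penalty, max_cpts = max_cpts, n = n,
         n_used = n_used),
    class = "cpt_result")
  if (n_used < 2L * min_seg) {
    warning("series too short for changepoint detection", call. = FALSE)
    return(out)
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- integer(0)
  params <- numeric(0)
  remaining <- max_cpts
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    seg <- x[starts[r]:ends[r]]
    if (length(seg) < 2L * min_seg) {
      if (kind == "mean") params <- c(params, mean(seg))
      else params <- c(params, stats::var(seg))
      next
    }
    res <- binseg_core(seg, kind, penalty, remaining, min_seg)
    remaining <- remaining - length(res$cpts)
    idx <- c(idx, res$cpts + starts[r] - 1L)
    params <- c(params, res$params)
    if (remaining <= 0L) break
  }
  out$indices <- sort(idx)
  out$segment_params <- params
  out
}

#' @export
print.cpt_result <- function(x, ...) {
  cat(sprintf("<cpt_result (%s): %d changepoint(s) in %d analyzed s>\n",
              x$kind, length(x$indices), x$n_used))
  invisible(x)
}

#' Count changepoints per experimental period
#'
#' A changepoint at series index `i` (second `i - 1`) belongs to the period
#' containing that second.  The pre-exposure vs exposure absolute difference
#' is the study's period-contrast statistic; post-exposure changepoints are
#' counted but excluded from the delta.
#'
#' @param result a `cpt_result`.
#' @param phase_bounds phase boundaries in seconds.
#' @return A list: `pre`, `exposure`, `post` counts and `delta`
#'   (`|pre - exposure|`).
#' @export
count_by_period <- function(result, phase_bounds = c(0, 600, 1200, 1800)) {
  stopifnot(inherits(result, "cpt_result"))
  secs <- result$indices - 1L
  labs <- c("pre", "exposure", "post")[seq_len(length(phase_bounds) - 1L)]
  per <- table(cut(secs, breaks = phase_bounds, right = FALSE,
                   labels = labs))
  out <- as.list(as.integer(per))
  names(out) <- labs
  if (!"post" %in% names(out)) out$post <- 0L
  out$delta <- abs(out$pre - out$exposure)
  out
}

#' Vocal state-switching rate from changepoint results
#'
#' Total detected changepoints divided by the total analyzed minutes, the
#' baseline "vocal state changes per minute" statistic.
#'
#' @param results a `cpt_result` or list of them.
#' @param minutes total analyzed minutes; defaults to the summed unmasked
#'   length of the input series.
#' @return Switches per minute.
#' @export
switch_rate <- function(results, minutes = NULL) {
  if (inherits(results, "cpt_result")) results <- list(results)
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "cpt_result")))
  if (is.null(minutes))
    minutes <- sum(vapply(results, function(r) r$n_used, 0)) / 60
  if (minutes <= 0) stop("zero analyzed minutes", call. = FALSE)
  sum(vapply(results, function(r) length(r$indices), 0L)) / minutes
}
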