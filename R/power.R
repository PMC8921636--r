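#' Detection power of a sequencing experiment
#'
#' Probability that a clonotype with body frequency `f_body` is detected,
#' i.e. observed with strictly more than `c_thresh` reads, when `t_samp`
#' T cells are sampled and sequenced to depth `t_read`:
#' `P(C_read > c_thresh) = 1 - sum_{i=0}^{c_thresh} P(C_read = i)`.
#' The marginal over the sampled-cell count uses the truncated Poisson
#' window of [marginal_control]; within each term the negative-binomial
#' upper tail is evaluated directly, which is algebraically identical to
#' summing the conditional pmf over `0..c_thresh` but numerically stable
#' for thresholds far from the mean.
#'
#' @inheritParams marginal_read_pmf
#' @param c_thresh Detection read threshold (non-negative integer); a read
#'   count must exceed it for the clonotype to count as detected.
#' @return A single detection probability in `[0, 1]`.
#' @examples
#' p <- read_model_params(r_e = 0.6, eta = 0, lambda = 1)
#' detection_power(1e-4, t_samp = 1e5, t_read = 1e6, params = p)
#' @export
detection_power <- function(f_body, t_samp, t_read, params, c_thresh = 0,
                            control = marginal_control()) {
  check_sampling(f_body, t_samp)
  check_count(c_thresh, "c_thresh")
  if (t_read < 1) stop("'t_read' must be >= 1", call. = FALSE)
  params <- as_read_model_params(params)
  if (f_body == 0) return(0)
  win <- p1_window(f_body, t_samp, control)
  sf <- nb_survival(c_thresh, (win$c_samp / t_samp) * params$r_e * t_read,
                    params)
  pw <- sum(exp(win$log_p1) * sf)
  min(max(pw, 0), 1)
}

# P(C_read > c_thresh | mu), vectorised over mu.
nb_survival <- function(c_thresh, mu, params) {
  out <- numeric(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    m <- mu[pos]
    size <- nb_size(m, params)
    pois <- !is.finite(size) | size > .size_poisson_cutoff
    sf <- numeric(length(m))
    if (any(pois))
      sf[pois] <- stats::ppois(c_thresh, m[pois], lower.tail = FALSE)
    if (any(!pois))
      sf[!pois] <- stats::pnbinom(c_thresh, size = size[!pois],
                                  mu = m[!pois], lower.tail = FALSE)
    out[pos] <- sf
  }
  out
}

#' Minimal detectable body frequency
#'
#' Smallest clonotype frequency in the body detectable with probability
#' `alpha` at the given sample size, depth and read threshold. Detection
#' power is strictly increasing in `f_body`, so the root of
#' `detection_power(f) = alpha` is found by bisection on `log(f_body)`.
#'
#' @inheritParams detection_power
#' @param alpha Target detection probability, in `(0, 1)`.
#' @param tol Absolute tolerance on the achieved power.
#' @return The minimal detectable frequency (scalar).
#' @examples
#' p <- read_model_params(r_e = 1, eta = 0, lambda = 1)
#' min_detectable_fbody(0.95, t_samp = 1e9, t_read = 1e6, params = p)
#' @export
min_detectable_fbody <- function(alpha, t_samp, t_read, params,
                                 c_thresh = 0, tol = 1e-4,
                                 control = marginal_control()) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  params <- as_read_model_params(params)
  pw <- function(f) detection_power(f, t_samp, t_read, params, c_thresh,
                                    control)
  p_max <- pw(1)
  if (p_max < alpha)
    stop(sprintf(paste0("detection probability %.4f at f_body = 1 is ",
                        "below alpha = %.4f; increase t_samp or t_read"),
                 p_max, alpha), call. = FALSE)
  lo <- log(1e-12)
  hi <- log(1)
  while (pw(exp(lo)) >= alpha && lo > log(1e-300)) lo <- lo - log(100)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pm <- pw(exp(mid))
    if (abs(pm - alpha) < tol && (hi - lo) < 1e-6) break
    if (pm < alpha) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Detection-power grid over sample size and sequencing depth
#'
#' Evaluates [detection_power] for a fixed clonotype frequency at every
#' combination of sampled T-cell counts and read depths. The Poisson
#' sampling weights depend only on `(f_body, t_samp)` and are computed once
#' per row and reused across the read-depth axis.
#'
#' @inheritParams detection_power
#' @param t_samp_axis,t_read_axis Ascending positive integer axes.
#' @return An object of class `"power_grid"`: a list with the two axes, the
#'   power `matrix` (rows indexed by `t_samp_axis`, columns by
#'   `t_read_axis`), `f_body` and `c_thresh`.
#' @seealso [power_contour] for extracting an iso-power contour,
#'   [plot.power_grid].
#' @export
power_grid <- function(f_body, t_samp_axis, t_read_axis, params,
                       c_thresh = 0, control = marginal_control()) {
  stopifnot(length(t_samp_axis) >= 1, length(t_read_axis) >= 1)
  if (is.unsorted(t_samp_axis, strictly = TRUE) ||
      is.unsorted(t_read_axis, strictly = TRUE))
    stop("axes must be strictly ascending", call. = FALSE)
  if (any(t_samp_axis < 1) || any(t_read_axis < 1))
    stop("axes must be positive", call. = FALSE)
  params <- as_read_model_params(params)
  pw <- matrix(0, nrow = length(t_samp_axis), ncol = length(t_read_axis),
               dimnames = list(t_samp = format(t_samp_axis, trim = TRUE,
                                               scientific = FALSE),
                               t_read = format(t_read_axis, trim = TRUE,
                                               scientific = FALSE)))
  if (f_body > 0) {
    for (i in seq_along(t_samp_axis)) {
      ts <- t_samp_axis[i]
      win <- p1_window(f_body, ts, control)  # reused across the read axis
      p1 <- exp(win$log_p1)
      for (j in seq_along(t_read_axis)) {
        mu <- (win$c_samp / ts) * params$r_e * t_read_axis[j]
        pw[i, j] <- min(max(sum(p1 * nb_survival(c_thresh, mu, params)),
                            0), 1)
      }
    }
  }
  structure(list(t_samp_axis = t_samp_axis, t_read_axis = t_read_axis,
                 power = pw, f_body = f_body, c_thresh = c_thresh,
                 params = params),
            class = "power_grid")
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf(paste0("Detection power grid: %d x %d (t_samp x t_read), ",
                     "f_body = %g, c_thresh = %d\n"),
              length(x$t_samp_axis), length(x$t_read_axis), x$f_body,
              x$c_thresh))
  cat(sprintf("  power range: [%.4g, %.4g]\n", min(x$power), max(x$power)))
  invisible(x)
}

#' Iso-power contour of a power grid
#'
#' For each sampled-cell count (grid row), the read depth at which detection
#' power first reaches `level`, linearly interpolated between grid nodes on
#' the log read-depth axis. Rows that never reach `level` yield `NA`.
#'
#' @param grid A [power_grid] object.
#' @param level Power level of the contour (default 0.95).
#' @return A data frame with columns `t_samp` and `t_read`.
#' @export
power_contour <- function(grid, level = 0.95) {
  stopifnot(inherits(grid, "power_grid"), level > 0, level < 1)
  lt <- log(grid$t_read_axis)
  t_read <- vapply(seq_along(grid$t_samp_axis), function(i) {
    pw <- grid$power[i, ]
    j <- which(pw >= level)
    if (!length(j)) return(NA_real_)
    j <- j[1L]
    if (j == 1L) return(grid$t_read_axis[1L])
    # linear interpolation of power on log(t_read)
    w <- (level - pw[j - 1L]) / (pw[j] - pw[j - 1L])
    exp(lt[j - 1L] + w * (lt[j] - lt[j - 1L]))
  }, numeric(1))
  data.frame(t_samp = grid$t_samp_axis, t_read = t_read)
}

#' Heatmap of a detection-power grid
#'
#' @param x A [power_grid] object.
#' @param level Iso-power contour to overlay (set `NULL` to omit).
#' @param ... Passed to [graphics::image].
#' @return `x`, invisibly.
#' @export
plot.power_grid <- function(x, level = 0.95, ...) {
  graphics::image(log10(x$t_samp_axis), log10(x$t_read_axis), x$power,
                  xlab = "log10 sampled TCRs", ylab = "log10 reads",
                  main = sprintf("Detection power, f_body = %g, c_thresh = %d",
                                 x$f_body, x$c_thresh),
                  zlim = c(0, 1), ...)
  if (!is.null(level) && max(x$power) >= level) {
    graphics::contour(log10(x$t_samp_axis), log10(x$t_read_axis), x$power,
                      levels = level, add = TRUE, lwd = 2)
  }
  invisible(x)
}
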