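#' Minimal detectable sample frequency
#'
#' The smallest in-sample clonotype frequency detectable with probability
#' `alpha` at read depth `t_read` and read threshold `c_thresh`, using the
#' negative-binomial read model alone (the sample frequency is treated as
#' known, as for spike-ins; blood sampling is not involved). Solves
#' `P(C_read > c_thresh | mu = f * r_e * t_read) = alpha` for `f` by
#' bisection on `log f`; detection probability is strictly increasing in
#' `f`.
#'
#' @param object A `readmodel_fit` or [read_model_params].
#' @param alpha Target detection probability (default 0.95).
#' @param t_read Read depth; defaults to the calibration depth when
#'   `object` is a fit, otherwise required.
#' @param c_thresh Detection read threshold (default 0).
#' @param rel_tol Relative tolerance on `f` (default 1e-6).
#' @return An object of class `"detection_limit"`: a list with `f_samp95`
#'   (the limit, whatever `alpha`), `alpha`, `t_read`, `c_thresh`,
#'   `achieved` (detection probability at the limit) and empty CI slots.
#' @examples
#' p <- read_model_params(r_e = 1, eta = 0, lambda = 1)
#' detection_limit(p, alpha = 0.95, t_read = 1e6)$f_samp95  # ~ log(20)/1e6
#' @export
detection_limit <- function(object, alpha = 0.95, t_read = NULL,
                            c_thresh = 0, rel_tol = 1e-6) {
  params <- as_read_model_params(object)
  if (is.null(t_read)) {
    if (inherits(object, "readmodel_fit")) t_read <- object$t_read
    else stop("'t_read' is required when 'object' carries no depth",
              call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1)
  check_count(c_thresh, "c_thresh")
  pdet <- function(f) nb_survival(c_thresh, f * params$r_e * t_read, params)
  p_max <- pdet(1)
  if (p_max < alpha)
    stop(sprintf(paste0("alpha = %.4f unreachable: detection probability ",
                        "at f = 1 is %.4f"), alpha, p_max), call. = FALSE)
  lo <- log(1e-12)
  hi <- 0
  while (pdet(exp(lo)) >= alpha && lo > log(1e-300)) lo <- lo - log(100)
  while ((hi - lo) > rel_tol) {
    mid <- (lo + hi) / 2
    if (pdet(exp(mid)) < alpha) lo <- mid else hi <- mid
  }
  f <- exp((lo + hi) / 2)
  structure(list(f_samp95 = f, alpha = alpha, t_read = t_read,
                 c_thresh = c_thresh, achieved = pdet(f),
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "detection_limit")
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf(paste0("Minimal sample frequency detectable with %.0f%% ",
                     "probability\n  (t_read = %s, read threshold > %d)\n"),
              100 * x$alpha, format(x$t_read, big.mark = ","), x$c_thresh))
  cat(sprintf("  f = %.4g", x$f_samp95))
  if (!is.na(x$ci_low))
    cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Confidence interval for the detection limit
#'
#' Parametric bootstrap: parameter vectors are drawn from the multivariate
#' normal at the MLE (truncated to the feasible box `r_e` in `(0, 1]`,
#' `eta >= 0`), the detection limit is recomputed for each draw, and the
#' 2.5/97.5 percentiles are returned. A Wald (delta-method) interval on
#' `log f` is available as an alternative.
#'
#' @param object A `readmodel_fit` with a finite covariance matrix.
#' @inheritParams detection_limit
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap draws.
#' @param method `"bootstrap"` (default) or `"wald"`.
#' @param level Interval coverage (default 0.95).
#' @return A `"detection_limit"` object with `ci_low` and `ci_high` filled
#'   in.
#' @export
detection_limit_ci <- function(object, alpha = 0.95, t_read = NULL,
                               c_thresh = 0, n_boot = 1000, seed = NULL,
                               method = c("bootstrap", "wald"),
                               level = 0.95) {
  stopifnot(inherits(object, "readmodel_fit"))
  method <- match.arg(method)
  if (is.null(t_read)) t_read <- object$t_read
  dl <- detection_limit(object, alpha = alpha, t_read = t_read,
                        c_thresh = c_thresh)
  V <- object$vcov
  if (any(!is.finite(V)))
    stop("covariance matrix unavailable; cannot form an interval",
         call. = FALSE)
  cf <- object$coefficients
  if (all(V == 0)) {
    dl$ci_low <- dl$ci_high <- dl$f_samp95
    return(dl)
  }
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  a2 <- (1 - level) / 2
  if (method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 3)
    draws <- t(cf + L %*% matrix(stats::rnorm(3 * n_boot), 3))
    draws[, 1] <- pmin(pmax(draws[, 1], 1e-8), 1)  # r_e in (0, 1]
    draws[, 2] <- pmax(draws[, 2], 0)              # eta >= 0
    fs <- apply(draws, 1L, function(b) {
      p <- read_model_params(b[1], b[2], b[3])
      tryCatch(detection_limit(p, alpha = alpha, t_read = t_read,
                               c_thresh = c_thresh)$f_samp95,
               error = function(e) NA_real_)
    })
    fs <- fs[is.finite(fs)]
    if (!length(fs))
      stop("all bootstrap draws failed to reach alpha", call. = FALSE)
    qs <- stats::quantile(fs, c(a2, 1 - a2), names = FALSE)
  } else {
    # delta method on log f: numeric gradient of the limit wrt parameters
    g <- vapply(1:3, function(i) {
      h <- pmax(abs(cf[i]), 1e-4) * 1e-4
      up <- dn <- cf
      up[i] <- up[i] + h
      dn[i] <- max(dn[i] - h, if (i == 2) 0 else -Inf)
      lu <- log(detection_limit(read_model_params(up[1], up[2], up[3]),
                                alpha, t_read, c_thresh)$f_samp95)
      ld <- log(detection_limit(read_model_params(min(dn[1], 1), dn[2],
                                                  dn[3]),
                                alpha, t_read, c_thresh)$f_samp95)
      (lu - ld) / (up[i] - dn[i])
    }, numeric(1))
    se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
    z <- stats::qnorm(1 - a2)
    qs <- exp(log(dl$f_samp95) + c(-1, 1) * z * se)
  }
  dl$ci_low <- min(qs[1], dl$f_samp95)
  dl$ci_high <- max(qs[2], dl$f_samp95)
  dl
}
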