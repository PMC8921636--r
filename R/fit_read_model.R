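#' Calibrate the read-count model from spike-in observations
#'
#' Maximum-likelihood estimation of the read efficiency `r_e`, the
#' overdispersion scale `eta` and the mean-variance exponent `lambda` from
#' spike-in clonotypes of known in-sample frequency. Each observation
#' contributes `log P(c_read | mu, sigma^2)` with `mu = f_samp * r_e *
#' t_read` and `sigma^2 = mu + eta * mu^lambda`; blood sampling plays no
#' role because the sample frequencies are known.
#'
#' Optimisation runs on a transformed scale (logit `r_e`, log `eta`,
#' `lambda` boxed in `lambda_box`) by L-BFGS-B, from a method-of-moments
#' start (ratio estimate of `r_e`, log-regression of excess variance on log
#' mean across frequency tiers for `eta`, `lambda`) plus a fixed 3 x 3 grid
#' of `(eta, lambda)` starts; the best optimum is kept. A Poisson
#' (`eta = 0`) submodel is fitted alongside; because `eta` and `lambda`
#' are unidentified when the counts carry no excess variance, the Poisson
#' submodel is selected unless the negative binomial improves the
#' log-likelihood by more than 2 (AIC with two extra parameters).
#' The parameter covariance is obtained from the numeric Hessian on the
#' transformed scale, mapped to the natural scale by the delta method.
#'
#' @param data A data frame with numeric columns `f_samp` (known spike-in
#'   frequency in `(0, 1]`) and `c_read` (non-negative integer read count).
#'   Further columns (`chain`, `set_id`, `replicate_id`) are carried along
#'   but not used: calibrate each chain x set combination separately.
#' @param t_read Total read count of the chain/set the observations come
#'   from.
#' @param lambda_box Search interval for `lambda` (default `c(0.5, 3)`).
#' @param extra_starts Optional matrix or data frame of additional starts
#'   with columns `r_e`, `eta`, `lambda`.
#' @return An object of class `"readmodel_fit"` with components
#'   `coefficients` (named vector `r_e`, `eta`, `lambda`), `vcov`,
#'   `logLik`, `n_obs`, `t_read`, `converged`, `poisson` (the `eta = 0`
#'   submodel: `r_e` and log-likelihood) and the data. Supports `coef`,
#'   `vcov`, `logLik`, `print`, `summary`, `predict`, `simulate`,
#'   `residuals` and `plot`.
#' @examples
#' des <- spikein_design(n_replicates = 3)
#' truth <- read_model_params(0.7, 1.5, 1.3)
#' obs <- simulate_calibration_data(des, truth, t_read = 1e6, seed = 1)
#' fit <- fit_read_model(obs, t_read = 1e6)
#' coef(fit)
#' @export
fit_read_model <- function(data, t_read, lambda_box = c(0.5, 3),
                           extra_starts = NULL) {
  stopifnot(is.data.frame(data), all(c("f_samp", "c_read") %in% names(data)))
  f <- as.numeric(data$f_samp)
  y <- data$c_read
  check_count(y, "c_read")
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    stop("'f_samp' must lie in (0, 1]", call. = FALSE)
  if (t_read < 1) stop("'t_read' must be >= 1", call. = FALSE)
  if (length(unique(f)) < 3L)
    stop("need >= 3 distinct f_samp values to identify the mean-variance ",
         "exponent", call. = FALSE)
  if (all(y == 0))
    stop("all read counts are zero; the read model is not identifiable",
         call. = FALSE)
  stopifnot(length(lambda_box) == 2L, lambda_box[1] < lambda_box[2])

  nll <- function(th) {
    r_e <- stats::plogis(th[1])
    eta <- exp(th[2])
    lam <- th[3]
    mu <- f * r_e * t_read
    size <- mu^(2 - lam) / eta
    ll <- ifelse(size > .size_poisson_cutoff,
                 stats::dpois(y, mu, log = TRUE),
                 stats::dnbinom(y, size = size, mu = mu, log = TRUE))
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }

  starts <- rbind(moments_start(f, y, t_read, lambda_box),
                  as.matrix(expand.grid(r_e = NA_real_,
                                        eta = c(0.1, 1, 5),
                                        lambda = c(0.8, 1.3, 2.0))))
  if (!is.null(extra_starts))
    starts <- rbind(starts, as.matrix(extra_starts)[, c("r_e", "eta",
                                                        "lambda"),
                                                    drop = FALSE])
  # grid rows inherit the moments r_e
  starts[is.na(starts[, "r_e"]), "r_e"] <- starts[1, "r_e"]
  starts[, "lambda"] <- pmin(pmax(starts[, "lambda"],
                                  lambda_box[1] + 1e-6),
                             lambda_box[2] - 1e-6)

  lower <- c(-30, log(1e-8), lambda_box[1])
  upper <- c(30, log(1e8), lambda_box[2])
  best <- NULL
  start_nll <- numeric(nrow(starts))
  for (k in seq_len(nrow(starts))) {
    th0 <- c(stats::qlogis(min(max(starts[k, "r_e"], 1e-6), 1 - 1e-6)),
             log(max(starts[k, "eta"], 1e-8)),
             starts[k, "lambda"])
    start_nll[k] <- nll(th0)
    opt <- tryCatch(
      stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("maximum-likelihood fit failed from every start", call. = FALSE)

  # eta = 0 Poisson submodel: 1-D profile over r_e
  pois_nll <- function(t1) -sum(stats::dpois(y, f * stats::plogis(t1) *
                                               t_read, log = TRUE))
  popt <- stats::optimize(pois_nll, interval = c(-30, 30))
  poisson_sub <- list(r_e = stats::plogis(popt$minimum),
                      logLik = -popt$objective)

  th <- unname(best$par)
  cf <- c(r_e = stats::plogis(th[1]), eta = exp(th[2]), lambda = th[3])
  H <- tryCatch(stats::optimHess(th, nll), error = function(e) NULL)
  V <- delta_vcov(H, th)
  converged <- best$convergence == 0 && -best$value >= poisson_sub$logLik - 1e-6
  if (!converged && -best$value < poisson_sub$logLik - 1e-6) {
    # NB likelihood can never fall below its eta -> 0 limit at the same
    # r_e; reaching here means the optimiser stalled, so restart near the
    # Poisson solution.
    th0 <- c(stats::qlogis(poisson_sub$r_e), log(1e-6), cf[["lambda"]])
    opt <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lower,
                        upper = upper, control = list(maxit = 500))
    if (opt$value < best$value) {
      best <- opt
      th <- unname(best$par)
      cf <- c(r_e = stats::plogis(th[1]), eta = exp(th[2]), lambda = th[3])
      H <- tryCatch(stats::optimHess(th, nll), error = function(e) NULL)
      V <- delta_vcov(H, th)
    }
    converged <- best$convergence == 0 &&
      -best$value >= poisson_sub$logLik - 1e-6
  }

  # Boundary model selection: eta is unidentified when the data carry no
  # overdispersion, so keep the eta = 0 submodel unless the NB fit earns
  # its two extra parameters on AIC (delta logLik > 2).
  model <- "negbin"
  logLik <- -best$value
  if (logLik - poisson_sub$logLik <= 2) {
    model <- "poisson"
    cf <- c(r_e = poisson_sub$r_e, eta = 0, lambda = 1)
    logLik <- poisson_sub$logLik
    h <- stats::optimHess(stats::qlogis(poisson_sub$r_e), pois_nll)
    V <- matrix(0, 3, 3, dimnames = dimnames(delta_vcov(NULL, NULL)))
    p <- poisson_sub$r_e
    V[1, 1] <- (p * (1 - p))^2 / drop(h)
    converged <- TRUE
  }

  structure(list(coefficients = cf, vcov = V, logLik = logLik,
                 n_obs = length(y), t_read = t_read,
                 converged = converged, poisson = poisson_sub,
                 model = model, lambda_box = lambda_box,
                 start_logLik = -start_nll, data = data),
            class = "readmodel_fit")
}

# Method-of-moments start: ratio estimate of r_e; regression of
# log(variance excess) on log(mean) across frequency tiers for eta, lambda.
moments_start <- function(f, y, t_read, lambda_box) {
  r_e <- min(max(sum(y) / sum(f * t_read), 1e-6), 1 - 1e-6)
  tier <- factor(f)
  m <- tapply(y, tier, mean)
  v <- tapply(y, tier, stats::var)
  ok <- !is.na(v) & v > m & m > 0
  eta <- 1
  lambda <- 1.3
  if (sum(ok) >= 2) {
    fitlm <- stats::lm(log(v[ok] - m[ok]) ~ log(m[ok]))
    eta <- exp(stats::coef(fitlm)[1])
    lambda <- stats::coef(fitlm)[2]
    if (!is.finite(eta) || eta <= 0) eta <- 1
    if (!is.finite(lambda)) lambda <- 1.3
    lambda <- min(max(lambda, lambda_box[1]), lambda_box[2])
  }
  matrix(c(r_e, eta, lambda), nrow = 1,
         dimnames = list(NULL, c("r_e", "eta", "lambda")))
}

# Natural-scale covariance via the delta method from the transformed-scale
# Hessian. th = (logit r_e, log eta, lambda).
delta_vcov <- function(H, th) {
  fallback <- matrix(NA_real_, 3, 3,
                     dimnames = list(c("r_e", "eta", "lambda"),
                                     c("r_e", "eta", "lambda")))
  if (is.null(H)) return(fallback)
  Vt <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Vt)) return(fallback)
  p <- stats::plogis(th[1])
  J <- diag(c(p * (1 - p), exp(th[2]), 1))
  V <- J %*% Vt %*% J
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(fallback)
  V
}

#' @export
coef.readmodel_fit <- function(object, ...) object$coefficients

#' @export
vcov.readmodel_fit <- function(object, ...) object$vcov

#' @export
logLik.readmodel_fit <- function(object, ...) {
  structure(object$logLik, df = 3L, nobs = object$n_obs, class = "logLik")
}

#' @export
print.readmodel_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Calibrated read-count model (%s)\n",
              if (identical(x$model, "poisson"))
                "Poisson: no excess variance detected"
              else "negative binomial"))
  cat(sprintf("  n = %d spike-in observations, t_read = %s\n", x$n_obs,
              format(x$t_read, big.mark = ",", scientific = FALSE)))
  print(round(x$coefficients, digits))
  cat(sprintf("  log-likelihood %.2f (Poisson submodel %.2f)%s\n",
              x$logLik, x$poisson$logLik,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
summary.readmodel_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `CI 2.5%` = object$coefficients - 1.96 * se,
               `CI 97.5%` = object$coefficients + 1.96 * se)
  structure(list(coefficients = tab, logLik = object$logLik,
                 poisson_logLik = object$poisson$logLik,
                 n_obs = object$n_obs, t_read = object$t_read,
                 converged = object$converged),
            class = "summary.readmodel_fit")
}

#' @export
print.summary.readmodel_fit <- function(x, digits = 4, ...) {
  cat("Calibrated negative-binomial read-count model\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, cs.ind = 1:2,
                      tst.ind = integer(0), P.values = FALSE,
                      has.Pvalue = FALSE)
  cat(sprintf("\nn = %d, t_read = %s, logLik = %.2f", x$n_obs,
              format(x$t_read, big.mark = ","), x$logLik))
  cat(sprintf(", Poisson submodel logLik = %.2f\n", x$poisson_logLik))
  if (!x$converged) cat("Warning: fit did not converge\n")
  invisible(x)
}

#' Predicted read counts for given sample frequencies
#'
#' @param object A `readmodel_fit`.
#' @param newdata Data frame with a column `f_samp`; defaults to the
#'   calibration data.
#' @param t_read Read depth for the prediction (defaults to the
#'   calibration depth).
#' @param interval `"none"` or `"prediction"` for negative-binomial
#'   prediction quantiles at `level`.
#' @param level Prediction-interval coverage.
#' @param ... Unused.
#' @return A data frame with `f_samp`, `mu` and, if requested, `lwr`/`upr`.
#' @export
predict.readmodel_fit <- function(object, newdata = NULL, t_read = NULL,
                                  interval = c("none", "prediction"),
                                  level = 0.95, ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) newdata <- object$data
  if (is.null(t_read)) t_read <- object$t_read
  f <- newdata$f_samp
  p <- as_read_model_params(object)
  mu <- f * p$r_e * t_read
  out <- data.frame(f_samp = f, mu = mu)
  if (interval == "prediction") {
    a <- (1 - level) / 2
    size <- nb_size(mu, p)
    pois <- !is.finite(size) | size > .size_poisson_cutoff
    q <- function(prob) ifelse(pois, stats::qpois(prob, mu),
                               stats::qnbinom(prob, size = size, mu = mu))
    out$lwr <- q(a)
    out$upr <- q(1 - a)
  }
  out
}

#' @export
residuals.readmodel_fit <- function(object, type = c("pearson", "response"),
                                    ...) {
  type <- match.arg(type)
  p <- as_read_model_params(object)
  mu <- object$data$f_samp * p$r_e * object$t_read
  r <- object$data$c_read - mu
  if (type == "pearson") r <- r / sqrt(mu + p$eta * mu^p$lambda)
  r
}

#' Simulate read counts from a calibrated model
#'
#' @param object A `readmodel_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param newdata Data frame with `f_samp` (defaults to calibration data).
#' @param t_read Read depth (defaults to calibration depth).
#' @param ... Unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.readmodel_fit <- function(object, nsim = 1, seed = NULL,
                                   newdata = NULL, t_read = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data
  if (is.null(t_read)) t_read <- object$t_read
  p <- as_read_model_params(object)
  mu <- newdata$f_samp * p$r_e * t_read
  out <- replicate(nsim, rnegbin_powerlaw(length(mu), mu, p))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Calibration data and fitted mean on log-log axes
#'
#' @param x A `readmodel_fit`.
#' @param level Prediction-interval coverage to shade.
#' @param ... Passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.readmodel_fit <- function(x, level = 0.95, ...) {
  d <- x$data
  fgrid <- exp(seq(log(min(d$f_samp)), log(max(d$f_samp)), length.out = 60))
  pr <- predict(x, newdata = data.frame(f_samp = fgrid),
                interval = "prediction", level = level)
  graphics::plot(d$f_samp, pmax(d$c_read, 0.5), log = "xy",
                 xlab = "spike-in sample frequency",
                 ylab = "read count (zeros plotted at 0.5)",
                 main = "Calibrated read-count model", ...)
  graphics::lines(fgrid, pr$mu, lwd = 2)
  graphics::lines(fgrid, pmax(pr$lwr, 0.5), lty = 2)
  graphics::lines(fgrid, pmax(pr$upr, 0.5), lty = 2)
  invisible(x)
}
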