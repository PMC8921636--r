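#' Read-model parameters
#'
#' Container for the three calibrated parameters of the negative-binomial
#' read-count model: the read efficiency `r_e`, the overdispersion scale
#' `eta` and the mean-variance exponent `lambda`. For a clonotype with
#' in-sample frequency `f_samp` sequenced at depth `t_read`, the expected
#' read count is `mu = f_samp * r_e * t_read` and its variance is
#' `mu + eta * mu^lambda`. `eta = 0` recovers the Poisson model of perfectly
#' even subsampling.
#'
#' @param r_e Read efficiency, in `[0, 1]`.
#' @param eta Overdispersion scale, `>= 0`.
#' @param lambda Mean-variance exponent (any real; typical fits lie in
#'   `[0.5, 3]`).
#' @return An object of class `"read_model_params"`: a named list with
#'   elements `r_e`, `eta`, `lambda`.
#' @examples
#' read_model_params(r_e = 0.7, eta = 1.5, lambda = 1.3)
#' @export
read_model_params <- function(r_e, eta = 0, lambda = 1) {
  stopifnot(is.numeric(r_e), length(r_e) == 1L, is.finite(r_e),
            is.numeric(eta), length(eta) == 1L, is.finite(eta),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  if (r_e < 0 || r_e > 1)
    stop("'r_e' must lie in [0, 1]", call. = FALSE)
  if (eta < 0)
    stop("'eta' must be non-negative", call. = FALSE)
  structure(list(r_e = r_e, eta = eta, lambda = lambda),
            class = "read_model_params")
}

#' @export
print.read_model_params <- function(x, digits = 4, ...) {
  cat("Read-count model parameters\n")
  cat(sprintf("  r_e (read efficiency):     %s\n", format(x$r_e, digits = digits)))
  cat(sprintf("  eta (overdispersion):      %s\n", format(x$eta, digits = digits)))
  cat(sprintf("  lambda (variance exponent): %s\n", format(x$lambda, digits = digits)))
  invisible(x)
}

as_read_model_params <- function(x) {
  if (inherits(x, "read_model_params")) return(x)
  if (inherits(x, "readmodel_fit")) {
    cf <- stats::coef(x)
    return(read_model_params(cf[["r_e"]], cf[["eta"]], cf[["lambda"]]))
  }
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    nm <- names(x)
    if (all(c("r_e", "eta", "lambda") %in% nm))
      return(read_model_params(x$r_e, x$eta, x$lambda))
  }
  stop("cannot interpret 'params' as read-model parameters; supply ",
       "read_model_params() or a readmodel_fit", call. = FALSE)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
      any(x != floor(x)))
    stop(sprintf("'%s' must be integer-valued and >= %s", name, min),
         call. = FALSE)
  invisible(x)
}
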