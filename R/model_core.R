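#' Poisson blood-sampling pmf
#'
#' Probability of drawing `c_samp` cells carrying the target receptor when a
#' blood sample of `t_samp` T cells is taken from a body in which the
#' clonotype has frequency `f_body`. Sampling is modelled as
#' `C_samp ~ Poisson(f_body * t_samp)`.
#'
#' @param c_samp Non-negative integer count(s) of sampled target cells.
#' @param f_body Clonotype frequency in the body, in `[0, 1]`.
#' @param t_samp Total number of T cells (TCRs) in the sample, `>= 1`.
#' @param log Return log-probabilities?
#' @return Probabilities (or log-probabilities) of the same length as
#'   `c_samp`.
#' @examples
#' poisson_sample_pmf(2, f_body = 3e-6, t_samp = 1e6) # rate 3
#' @export
poisson_sample_pmf <- function(c_samp, f_body, t_samp, log = FALSE) {
  check_count(c_samp, "c_samp")
  check_sampling(f_body, t_samp)
  stats::dpois(c_samp, lambda = f_body * t_samp, log = log)
}

check_sampling <- function(f_body, t_samp) {
  stopifnot(is.numeric(f_body), length(f_body) == 1L,
            is.numeric(t_samp), length(t_samp) == 1L)
  if (!is.finite(f_body) || f_body < 0 || f_body > 1)
    stop("'f_body' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(t_samp) || t_samp < 1)
    stop("'t_samp' must be >= 1", call. = FALSE)
  invisible(TRUE)
}

# Negative-binomial size parameter implied by the power-law mean-variance
# relationship sigma^2 = mu + eta * mu^lambda. Returns Inf when the model
# degenerates to Poisson (eta == 0).
nb_size <- function(mu, params) {
  if (params$eta == 0) return(rep(Inf, length(mu)))
  mu^(2 - params$lambda) / params$eta
}

# Largest finite size treated as negative binomial; beyond this the
# eta-term contributes less than double precision can resolve and the
# Poisson pmf is used instead.
.size_poisson_cutoff <- 1e12

#' Negative-binomial read-count pmf
#'
#' Probability of observing `c_read` sequencing reads of a clonotype whose
#' expected read count is `mu`, under the overdispersed read model
#' `C_read ~ NB(mu, sigma^2)` with `sigma^2 = mu + eta * mu^lambda`. The
#' distribution is parameterised through `size = mu^(2 - lambda) / eta`
#' (continuous, gamma-function form). With `eta = 0`, or when the implied
#' size is too large for the overdispersion term to be representable, the
#' Poisson pmf with rate `mu` is returned; `mu = 0` gives a point mass at 0.
#'
#' @param c_read Non-negative integer read count(s).
#' @param mu Expected read count, `>= 0` (scalar).
#' @param params A [read_model_params] object (or coercible).
#' @param log Return log-probabilities?
#' @return Probabilities of the same length as `c_read`.
#' @examples
#' p <- read_model_params(r_e = 1, eta = 1, lambda = 1)
#' negbin_read_pmf(0, mu = 10, p) # (1/2)^10
#' @export
negbin_read_pmf <- function(c_read, mu, params, log = FALSE) {
  check_count(c_read, "c_read")
  params <- as_read_model_params(params)
  stopifnot(is.numeric(mu), length(mu) == 1L)
  if (!is.finite(mu) || mu < 0)
    stop("'mu' must be finite and >= 0", call. = FALSE)
  if (mu == 0) {
    lp <- ifelse(c_read == 0, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  size <- nb_size(mu, params)
  if (!is.finite(size) || size > .size_poisson_cutoff)
    return(stats::dpois(c_read, lambda = mu, log = log))
  if (size <= 1e-300)
    stop("implied negative-binomial size underflows (variance ",
         "astronomically large); check eta and lambda", call. = FALSE)
  stats::dnbinom(c_read, size = size, mu = mu, log = log)
}

#' Read-count pmf conditional on the number of sampled cells
#'
#' Conditional on `c_samp` target cells in the sample, the in-sample
#' frequency is `f_samp = c_samp / t_samp` and the expected read count is
#' `mu = f_samp * r_e * t_read`. With `c_samp = 0` all mass sits at
#' `c_read = 0`.
#'
#' @inheritParams negbin_read_pmf
#' @param c_samp Number of sampled target cells (non-negative integer).
#' @param t_samp Total T cells in the sample.
#' @param t_read Total sequencing reads for the chain/set.
#' @return Probabilities of the same length as `c_read`.
#' @export
p2_given_csamp <- function(c_read, c_samp, t_samp, t_read, params,
                           log = FALSE) {
  check_count(c_samp, "c_samp")
  stopifnot(length(c_samp) == 1L)
  if (t_samp < 1 || t_read < 1)
    stop("'t_samp' and 't_read' must be >= 1", call. = FALSE)
  mu <- (c_samp / t_samp) * as_read_model_params(params)$r_e * t_read
  negbin_read_pmf(c_read, mu, params, log = log)
}

#' Truncation control for the compound marginal
#'
#' The marginal read-count pmf sums the conditional read model over the
#' (unbounded) Poisson support of `C_samp`. The sum is truncated to a window
#' around the Poisson mean, `mean +/- nsd * sd`, widened to the
#' `tail_prob` / `1 - tail_prob` Poisson quantiles, and individual terms
#' whose Poisson weight falls below `p1_rel_tol` times the largest weight
#' are dropped. The `c_samp = 0` term is always retained so the marginal
#' normalises.
#'
#' @param nsd Half-width of the window in Poisson standard deviations.
#' @param p1_rel_tol Relative weight threshold below which terms are dropped.
#' @param tail_prob Poisson tail probability used to widen the window at
#'   small rates.
#' @return A list of truncation settings.
#' @export
marginal_control <- function(nsd = 10, p1_rel_tol = 1e-16,
                             tail_prob = 1e-14) {
  stopifnot(nsd > 0, p1_rel_tol > 0, p1_rel_tol < 1,
            tail_prob > 0, tail_prob < 0.5)
  list(nsd = nsd, p1_rel_tol = p1_rel_tol, tail_prob = tail_prob)
}

# Truncated support of C_samp with log Poisson weights. Always includes 0.
p1_window <- function(f_body, t_samp, control = marginal_control()) {
  rate <- f_body * t_samp
  if (rate == 0)
    return(list(c_samp = 0L, log_p1 = 0))
  sdv <- sqrt(rate)
  lo <- floor(min(rate - control$nsd * sdv,
                  stats::qpois(control$tail_prob, rate)))
  hi <- ceiling(max(rate + control$nsd * sdv,
                    stats::qpois(control$tail_prob, rate,
                                 lower.tail = FALSE), 1))
  lo <- max(0, lo)
  cs <- lo:hi
  lp1 <- stats::dpois(cs, rate, log = TRUE)
  keep <- lp1 >= max(lp1) + log(control$p1_rel_tol)
  cs <- cs[keep]
  lp1 <- lp1[keep]
  if (cs[1L] != 0L) {
    cs <- c(0L, cs)
    lp1 <- c(stats::dpois(0, rate, log = TRUE), lp1)
  }
  if (!length(cs))
    stop("internal error: empty truncation window", call. = FALSE)
  list(c_samp = cs, log_p1 = lp1)
}

#' Marginal read-count pmf of the two-step model
#'
#' Probability of observing `c_read` reads of a clonotype with body
#' frequency `f_body`, marginalising over the unknown number of sampled
#' cells: `P(C_read) = sum_c P2(C_read | C_samp = c) * P1(C_samp = c)`,
#' where `P1` is Poisson blood sampling and `P2` the negative-binomial read
#' model. The sum is truncated as described in [marginal_control]; terms are
#' combined in log space.
#'
#' @inheritParams p2_given_csamp
#' @param f_body Clonotype frequency in the body.
#' @param control Truncation settings from [marginal_control].
#' @return Probabilities of the same length as `c_read`.
#' @examples
#' p <- read_model_params(r_e = 0.6, eta = 0, lambda = 1)
#' marginal_read_pmf(0, f_body = 1e-4, t_samp = 1e5, t_read = 1e6, p)
#' @export
marginal_read_pmf <- function(c_read, f_body, t_samp, t_read, params,
                              log = FALSE, control = marginal_control()) {
  check_count(c_read, "c_read")
  check_sampling(f_body, t_samp)
  if (t_read < 1) stop("'t_read' must be >= 1", call. = FALSE)
  params <- as_read_model_params(params)
  win <- p1_window(f_body, t_samp, control)
  # log P(c_read) = logsumexp_c [ log P2(c_read | c) + log P1(c) ]
  lmat <- vapply(seq_along(win$c_samp), function(i) {
    p2_given_csamp(c_read, win$c_samp[i], t_samp, t_read, params,
                   log = TRUE) + win$log_p1[i]
  }, numeric(length(c_read)))
  lmat <- matrix(lmat, nrow = length(c_read))
  lp <- apply(lmat, 1L, logsumexp)
  if (log) lp else exp(lp)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
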