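# Independent oracles used across tests.

# Untruncated double-sum marginal pmf (for small instances).
brute_marginal <- function(c_read, f_body, t_samp, t_read, params,
                           c_max = 2000) {
  cs <- 0:c_max
  p1 <- dpois(cs, f_body * t_samp)
  vapply(c_read, function(cr) {
    sum(vapply(cs, function(c) {
      mu <- (c / t_samp) * params$r_e * t_read
      negbin_read_pmf(cr, mu, params) * p1[c + 1L]
    }, numeric(1)))
  }, numeric(1))
}

# Closed-form P(C_read = 0) of the compound model when eta = 0, from the
# Poisson probability generating function.
closed_p0 <- function(f_body, t_samp, t_read, r_e) {
  exp(f_body * t_samp * (exp(-r_e * t_read / t_samp) - 1))
}

default_truth <- function() read_model_params(0.7, 1.5, 1.3)
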