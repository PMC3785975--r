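# Zero-inflated negative binomial (ZINB) count model.
#
# Weekly drinks and maximum drinks per occasion are overdispersed counts
# with excess zeros (abstainers): the reported mean/SD pairs (e.g. 14.1 /
# 16.1 drinks per week) imply variance far above the mean, so the simulator
# draws them from a ZINB whose NB parameters are solved from the target
# moments by method of moments given the structural-zero share.

#' Solve ZINB parameters from target mean and SD
#'
#' Given the structural zero probability `pi0`, solves the negative
#' binomial mean `mu` and size `size` such that the ZINB mixture has the
#' requested marginal mean and standard deviation.
#'
#' @param mean,sd target marginal moments (sd^2 must exceed the variance of
#'   a zero-inflated Poisson with the same mean, otherwise no NB size > 0
#'   exists).
#' @param pi0 probability of a structural zero.
#' @return List with `pi0`, `mu`, `size`.
#' @export
zinb_moments <- function(mean, sd, pi0) {
  if (pi0 < 0 || pi0 >= 1) abort_config("pi0 must be in [0, 1)")
  mu <- mean / (1 - pi0)
  denom <- sd^2 - (1 - pi0) * mu - pi0 * (1 - pi0) * mu^2
  if (denom <= 0)
    abort_config("target sd too small for a zero-inflated negative binomial")
  size <- (1 - pi0) * mu^2 / denom
  list(pi0 = pi0, mu = mu, size = size)
}

#' ZINB distribution functions
#'
#' Quantile (`qzinb`), distribution (`pzinb`) and mid-distribution latent
#' (`zinb_latent`) of the zero-inflated negative binomial. The mid-CDF
#' latent `qnorm((F(x-1) + F(x)) / 2)` maps an observed count to a standard
#' normal score and is the Gaussian-copula anchor used for within-person
#' pre-post correlation of counts.
#'
#' @param p probabilities; `q`/`x` counts.
#' @param par parameter list from [zinb_moments()].
#' @return Numeric vector.
#' @export
qzinb <- function(p, par) {
  ifelse(p <= par$pi0, 0,
         qnbinom(pmin(pmax((p - par$pi0) / (1 - par$pi0), 0), 1),
                 mu = par$mu, size = par$size))
}

#' @rdname qzinb
#' @export
pzinb <- function(q, par) {
  ifelse(q < 0, 0, par$pi0 + (1 - par$pi0) * pnbinom(q, mu = par$mu, size = par$size))
}

#' @rdname qzinb
#' @export
zinb_latent <- function(x, par) {
  lo <- pzinb(x - 1, par)
  hi <- pzinb(x, par)
  qnorm(pmin(pmax((lo + hi) / 2, 1e-12), 1 - 1e-12))
}
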