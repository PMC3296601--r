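#' Sample a death time from the Gompertz residual-life distribution
#'
#' Ages each patient under a Gompertz mortality law with sex-specific rate,
#' a common shape, and a dementia hazard multiplier: the hazard at attained
#' age `x + t` is `a * m * exp(b * (x + t))`. The residual-life survival
#' from age `x` is
#' `S(t | x) = exp(-(a m / b) * exp(b x) * (exp(b t) - 1))`
#' and the draw `u` is interpreted as a survival probability, giving the
#' closed-form inverse
#' `t = (1/b) * log(1 - (b / (a m exp(b x))) * log(u))`.
#' Under this orientation `u` near 1 gives death times near 0.
#'
#' Death is sampled once per patient before arm cloning, so survival is
#' identical in all treatment arms by construction.
#'
#' @param age Patient age(s) at baseline in years.
#' @param male 0/1 patient sex (vectorised).
#' @param u Uniform draw(s) in (0, 1), shared across arms.
#' @param params Mortality parameter list (`shape`, `rate_female`,
#'   `rate_male`, `dementia_multiplier`), e.g.
#'   `default_parameters()$mortality`.
#' @return Death time(s) in years from baseline.
#' @export
#' @examples
#' p <- default_parameters()$mortality
#' sample_death_time(75, 0, 0.5, p)   # median residual life, female aged 75
sample_death_time <- function(age, male, u, params) {
  if (any(u <= 0 | u >= 1))
    stop("invalid argument: u must lie strictly in (0, 1)")
  if (any(age < 0)) stop("invalid argument: age must be >= 0")
  b <- params$shape
  a <- ifelse(male == 1, params$rate_male, params$rate_female) *
    params$dementia_multiplier
  (1 / b) * log(1 - (b / (a * exp(b * age))) * log(u))
}
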