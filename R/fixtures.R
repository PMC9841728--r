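#' Published summary statistics of the MJ LTPA duration question
#'
#' Aggregate quantities published for the MJ health-screening weekly LTPA
#' duration item around its 1997 -> 1998 revision.  The individual-level MJ
#' data are access-restricted; these printed vectors and matrices (3-4
#' significant digits) are what is publicly available, and they are enough
#' for worked examples and regression checks.  Because of print rounding the
#' matrix columns sum to 1 only within about 1e-3.
#'
#' @return A list:
#' \describe{
#'   \item{u_1997}{Cohort probability vector, 1997 responses on the 1997
#'     scale.}
#'   \item{v_prime_1997}{Cohort probability vector, 1998 responses on the
#'     1998 scale.}
#'   \item{T_1997}{Cohort transition matrix 1997 -> 1998 (5 x 4), spanning
#'     the revision.}
#'   \item{B_1998}{Cohort transition matrix 1998 -> 1999 (5 x 5), free of
#'     revision effects.}
#'   \item{A_hat_1997}{The published estimated revision matrix (5 x 4).}
#'   \item{G_1997}{The published ideal revision matrix (5 x 4).  Note it is
#'     numerically near-identical to `A_hat_1997` and is inconsistent with
#'     the conditional-probability construction for nested intervals, so it
#'     serves only as a linear-algebra fixture, not as a reference output of
#'     [ideal_revision_matrix()].}
#'   \item{y_1997}{Population probability vector, 1997 on the 1997 scale.}
#'   \item{z_1997}{Published aligned population vector, 1997 on the 1998
#'     scale.}
#'   \item{v_1997}{Published aligned cohort vector, 1997 on the 1998 scale.}
#'   \item{theta_1997}{Published Gamma parameters (shape 0.801, scale 2.028)
#'     behind `G_1997`.}
#'   \item{annual_means}{Data frame of published annual mean estimates
#'     1997-2008: columns `year`, `n`, `midpoint`, `mle`.}
#' }
#' @examples
#' fx <- mj_summaries()
#' round(apply_transition(fx$A_hat_1997, fx$u_1997), 3)  # reproduces v_1997
#' @export
mj_summaries <- function() {
  list(
    u_1997 = c(0.4502, 0.251, 0.117, 0.179),
    v_prime_1997 = c(0.4307, 0.235, 0.156, 0.0857, 0.0911),
    T_1997 = matrix(c(
      0.686,   0.19002, 0.0721, 0.0288, 0.0223,
      0.342,   0.374,   0.183,  0.0613, 0.0388,
      0.161,   0.283,   0.313,  0.143,  0.0975,
      0.0915,  0.124,   0.227,  0.224,  0.332), 5, 4),
    B_1998 = matrix(c(
      0.685,   0.2001,  0.07009, 0.0245,  0.0193,
      0.288,   0.417,   0.194,   0.0631,  0.0367,
      0.142,   0.264,   0.377,   0.142,   0.0741,
      0.09503, 0.126,   0.285,   0.293,   0.199,
      0.0681,  0.0784,  0.112,   0.2205,  0.52004), 5, 5),
    A_hat_1997 = matrix(c(
      0.944,   0.0209,  0.01405, 0.0119,  0.00898,
      0.175,   0.778,   0.0125,  0.01101, 0.0231,
      0.00412, 0.325,   0.582,   0.0825,  0.00531,
      7.88e-7, 8.32e-7, 0.302,   0.289,   0.407), 5, 4),
    G_1997 = matrix(c(
      0.944,   0.0209,  0.0140,  0.0119,  0.00898,
      0.175,   0.778,   0.0125,  0.0110,  0.0231,
      0.00412, 0.325,   0.582,   0.0825,  0.00531,
      7.88e-7, 8.32e-7, 0.302,   0.289,   0.407), 5, 4),
    y_1997 = c(0.491, 0.233, 0.104, 0.1701),
    z_1997 = c(0.505, 0.226, 0.122, 0.0663, 0.0797),
    v_1997 = c(0.469, 0.243, 0.132, 0.070008, 0.0839),
    theta_1997 = c(shape = 0.801, scale = 2.028),
    annual_means = data.frame(
      year = 1997:2008,
      n = c(75242L, 73940L, 70316L, 74962L, 67811L, 69715L, 63852L,
            71137L, 74616L, 77411L, 76808L, 76503L),
      midpoint = c(1.36833, 2.05077, 2.04756, 2.05653, 2.05691, 2.03665,
                   2.05765, 2.01045, 1.93659, 1.98527, 1.97690, 2.03243),
      mle = c(1.62673, 2.22051, 2.19150, 2.17430, 2.15717, 2.12588,
              2.13179, 2.06681, 1.94131, 1.99804, 1.98742, 2.05356))
  )
}
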