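# Independent oracles used across tests. These deliberately avoid the
# package's voxel pipeline: closed forms, radial quadrature, and naive loops.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Recovery coefficient of a uniform sphere under isotropic Gaussian blur,
# by the closed-form blurred-sphere profile integrated radially.
# Value at distance d from the centre of a unit-concentration sphere of
# radius R blurred with sigma:
#   f(d) = 1/2 [erf((R-d)/(s*sqrt(2))) + erf((R+d)/(s*sqrt(2)))]
#          - s/(d*sqrt(2*pi)) [exp(-(R-d)^2/2s^2) - exp(-(R+d)^2/2s^2)]
# RC = (3/R^3) * int_0^R f(d) d^2 dd.
sphere_rc_oracle <- function(volume_ml, sigma_mm) {
  R <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  s <- sigma_mm
  f <- function(d) {
    0.5 * (erf((R - d) / (s * sqrt(2))) + erf((R + d) / (s * sqrt(2)))) -
      s / (d * sqrt(2 * pi)) *
        (exp(-(R - d)^2 / (2 * s^2)) - exp(-(R + d)^2 / (2 * s^2)))
  }
  stats::integrate(function(d) f(d) * 4 * pi * d^2, 1e-9, R,
                   rel.tol = 1e-10)$value / (4 / 3 * pi * R^3)
}

# Naive triple-loop weighted sum over a VOI (oracle for voi_counts).
naive_voi_sum <- function(values, weights) {
  d <- dim(values)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- acc + values[i, j, k] * weights[i, j, k]
  }
  acc
}

# Brute-force Pearson correlation from first principles.
naive_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
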