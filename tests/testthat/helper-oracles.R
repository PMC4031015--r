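# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths: quadrature is plain trapezoid sums, the
# viscoelastic reference is the hereditary convolution integral evaluated
# segment by segment.

# revolved volume of the cell profile by high-resolution trapezoid rule
trapz_profile_volume <- function(geom, exponent, n = 1e5) {
  r <- seq(0, geom$radius, length.out = n + 1)
  h <- geom$foot_thickness + (geom$max_height - geom$foot_thickness) *
    cos(pi * r / (2 * geom$radius))^exponent
  f <- 2 * pi * r * h
  sum((f[-1] + f[-length(f)]) / 2) * (geom$radius / n)
}

# exponent calibration by bisection on the trapezoid volume
bisect_profile_exponent <- function(geom, lo = 0.5, hi = 50, iters = 60) {
  f <- function(p) trapz_profile_volume(geom, p) - geom$target_volume
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# deviatoric stress history by direct evaluation of the convolution
# integral for a piecewise-linear scalar strain history e(t):
# sigma(t_n) = 2 G0 [ e(t_n) - g1 * sum_k int (1 - exp(-(t_n-s)/tau)) de ]
# with the integral over each linear segment done in closed form.
convolution_stress <- function(times, e, g1, tau, G0) {
  n <- length(times)
  out <- numeric(n)
  for (k in 2:n) {
    tn <- times[k]
    h <- 0
    for (j in 2:k) {
      dtj <- times[j] - times[j - 1]
      rate <- (e[j] - e[j - 1]) / dtj
      h <- h + rate * (dtj - tau * (exp(-(tn - times[j]) / tau) -
                                      exp(-(tn - times[j - 1]) / tau)))
    }
    out[k] <- 2 * G0 * (e[k] - g1 * h)
  }
  out
}

# plane-stress closed form for the bonded equibiaxial slab
slab_oracle <- function(E = 6500, nu = 0.499, eps = 1e-3) {
  list(inplane_stress = E * eps / (1 - nu),
       von_mises = E * eps / (1 - nu),
       out_of_plane_strain = -2 * nu * eps / (1 - nu))
}
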