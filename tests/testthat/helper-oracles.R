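# Independent brute-force reference implementations used as oracles.

# triangle threshold: maximize the true point-to-line distance over candidate
# bins on the longer-tail side (explicit geometric projection)
brute_triangle <- function(h) {
  nz <- which(h > 0)
  peak <- which.max(h)
  lo <- nz[1]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)
  end <- if (right) hi else lo
  p1 <- c(peak, h[peak]); p2 <- c(end, h[end])
  v <- p2 - p1
  cand <- if (right) peak:end else end:peak
  d <- vapply(cand, function(i) {
    w <- c(i, h[i]) - p1
    proj <- sum(w * v) / sum(v * v)
    sqrt(sum((w - proj * v)^2))
  }, 0)
  cand[which.max(d)] - 1L
}

# intermeans fixed-point property of a threshold level on a histogram
intermeans_residual <- function(h, level) {
  v <- 0:255
  below <- v <= level
  m1 <- sum(h[below] * v[below]) / sum(h[below])
  m2 <- sum(h[!below] * v[!below]) / sum(h[!below])
  (m1 + m2) / 2 - level
}

# random histogram mixing two Gaussian-ish humps plus uniform noise
random_histogram <- function(seed) {
  set.seed(seed)
  x <- 0:255
  m1 <- runif(1, 20, 90); m2 <- runif(1, 140, 230)
  s1 <- runif(1, 5, 25); s2 <- runif(1, 5, 40)
  a <- runif(1, 0.2, 5)
  h <- round(4000 * exp(-(x - m1)^2 / (2 * s1^2)) +
               a * 1000 * exp(-(x - m2)^2 / (2 * s2^2)) +
               rpois(256, 2))
  h
}

# closed-form spherical-cap volume from contact radius and angle
cap_volume <- function(rc, theta_deg) {
  h <- rc * tan(theta_deg * pi / 360)
  pi * h * (3 * rc^2 + h^2) / 6
}

# analytic hemisphere interface profile pinned at rc = R
hemisphere_profile <- function(R, n = 2000) {
  t <- seq(0, pi / 2, length.out = n)
  structure(list(r = R * sin(t), z = R * cos(t), contact_radius = R,
                 volume = 2 / 3 * pi * R^3, wall_contact = FALSE,
                 apparent_angle = 90), class = "interface_profile")
}

default_noise_off <- c(gaussian_sd = 0, poisson_scale = 0)
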