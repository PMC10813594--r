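# Independent oracles used across the suite. These deliberately use naive
# direct computation (loops, explicit enumeration, dense quadrature) so they
# share no code path with the package implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-pixel fundamental (bin 1) DFT amplitude by direct summation,
# normalization 2/N. vstack: (row, col, frame) array.
oracle_dft_bin1 <- function(vstack) {
  d <- dim(vstack)
  n <- d[3]
  out <- matrix(0, d[1], d[2])
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      re <- 0; im <- 0
      for (k in seq_len(n)) {
        ang <- -2 * pi * (k - 1) / n
        re <- re + vstack[r, c, k] * cos(ang)
        im <- im + vstack[r, c, k] * sin(ang)
      }
      out[r, c] <- 2 * sqrt(re^2 + im^2) / n
    }
  }
  out
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
# Zeros dropped, mid-ranks for ties; same p definition as the package
# (doubled minimum tail), computed from the explicit enumeration.
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

# True stroke volume (uL per cycle) of a disc/annulus region by dense
# quadrature: spatial sum of the profile at pixel centers times pixel area,
# times the half-integral of |waveform| over one cycle on a fine grid.
oracle_region_sv <- function(region, grid_shape, pixel_spacing,
                             cycle_duration, nfine = 2^17) {
  s_sum <- 0
  for (r in seq_len(grid_shape[1])) {
    for (c in seq_len(grid_shape[2])) {
      d <- sqrt((r - region$center[1])^2 + (c - region$center[2])^2)
      if (region$geometry == "disc" && d < region$radius) {
        s_sum <- s_sum + if (region$profile == "parabolic")
          1 - (d / region$radius)^2 else 1
      } else if (region$geometry == "annulus" &&
                 d >= region$radii[1] && d < region$radii[2]) {
        s_sum <- s_sum + if (region$profile == "parabolic") {
          mid <- mean(region$radii); half <- diff(region$radii) / 2
          1 - ((d - mid) / half)^2
        } else 1
      }
    }
  }
  tt <- (seq_len(nfine) - 0.5) / nfine * cycle_duration  # midpoint rule
  w <- rep(region$waveform$constant %||% 0, nfine)
  amps <- region$waveform$amplitudes
  phs <- rep_len(region$waveform$phases %||% 0, length(amps))
  for (h in seq_along(amps))
    w <- w + amps[h] * sin(2 * pi * h * tt / cycle_duration + phs[h])
  q_ml <- 0.01 * region$peak_velocity * s_sum * pixel_spacing^2 * w
  1000 * 0.5 * mean(abs(q_ml)) * cycle_duration
}

# Fine-grid directional volume integrals for an analytic flow function
# q_fun(t) in mL/s; returns sv in uL.
oracle_sv_from_flow <- function(q_fun, cycle_duration, nfine = 2^17) {
  tt <- (seq_len(nfine) - 0.5) / nfine * cycle_duration
  q <- q_fun(tt)
  h <- cycle_duration / nfine
  vp <- 1000 * h * sum(pmax(q, 0))
  vm <- 1000 * h * sum(pmax(-q, 0))
  (vp + vm) / 2
}

# Default background ring used with the default phantoms: a square ring
# between Chebyshev radii 5 and 8 around the region center, clear of both
# the aqueduct disc (r=2) and the cervical annulus would need a wider one.
default_bg <- function(dim = c(64, 64), center = c(33, 33)) {
  background_ring(center, 5, 8, dim = dim)
}
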