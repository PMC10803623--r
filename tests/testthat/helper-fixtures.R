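# Shared fixtures built in code.

circle_ring <- function(R = 500, n = 360, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1L] + R * cos(th), centre[2L] + R * sin(th))
}

square_ring <- function(side = 1000) {
  h <- side / 2
  rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
}

# depth grid for an affine plane depth = a*x + b*y + c over a square
plane_grid <- function(a, b, c = 0, n = 21, cell = 1) {
  xs <- (seq_len(n) - 1) * cell
  z <- outer(xs, xs, function(y, x) a * x + b * y + c)
  depth_grid(c(0, 0), cell, z)
}

# oracle circular mean via the two-argument arctangent
ldm_oracle <- function(deg) {
  th <- deg * pi / 180
  (atan2(sum(sin(th)), sum(cos(th))) * 180 / pi) %% 360
}

# brute-force Dufrene-Legendre IndVal for one syntaxon/group pair
indval_brute <- function(x, groups, g) {
  idx <- groups == g
  means <- tapply(x, groups, mean)
  A <- if (sum(means) == 0) 0 else means[[g]] / sum(means)
  B <- sum(x[idx] > 0) / sum(idx)
  A * B
}
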