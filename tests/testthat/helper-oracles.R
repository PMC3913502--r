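# Independent stencil oracle: a literal, node-by-node transcription of the
# three-point second-derivative scheme and each mixed-derivative scheme as
# one-sided difference compositions.  Deliberately written as plain loops
# over stencil indices, sharing no code with the vectorized assembler.

slow_stencil_apply <- function(sigma, grid, scheme, u) {
  n <- grid$n
  h <- grid$h
  uv <- if (inherits(u, "scalar_volume")) u$values else u
  out <- array(0, n)
  comp <- list(sigma$xx, sigma$yy, sigma$zz)
  plane_comp <- list("12" = sigma$xy, "13" = sigma$xz, "23" = sigma$yz)

  # mixed term d/da1 (s d/da2 u) + d/da2 (s d/da1 u) at node p
  mixed_at <- function(s, p, a1, a2, scheme) {
    # potential / conductivity at p + i*e1 + j*e2
    U <- function(i, j) {
      q <- p; q[a1] <- q[a1] + i; q[a2] <- q[a2] + j
      uv[q[1], q[2], q[3]]
    }
    S <- function(i, j) {
      q <- p; q[a1] <- q[a1] + i; q[a2] <- q[a2] + j
      s[q[1], q[2], q[3]]
    }
    f <- 1 / (4 * h[a1] * h[a2])
    if (scheme %in% c("A", "D")) {
      t1 <- if (scheme == "A") {
        # average of the four one-sided conservative splittings
        (S(1, 0) * (U(1, 1) - U(1, 0)) - S(0, 0) * (U(0, 1) - U(0, 0))) +
        (S(0, 0) * (U(0, 0) - U(0, -1)) - S(-1, 0) * (U(-1, 0) - U(-1, -1))) +
        (S(1, 0) * (U(1, 0) - U(1, -1)) - S(0, 0) * (U(0, 0) - U(0, -1))) +
        (S(0, 0) * (U(0, 1) - U(0, 0)) - S(-1, 0) * (U(-1, 1) - U(-1, 0)))
      } else {
        S(1, 0) * (U(1, 1) - U(1, -1)) - S(-1, 0) * (U(-1, 1) - U(-1, -1))
      }
      t2 <- if (scheme == "A") {
        (S(0, 1) * (U(1, 1) - U(0, 1)) - S(0, 0) * (U(1, 0) - U(0, 0))) +
        (S(0, 0) * (U(0, 0) - U(-1, 0)) - S(0, -1) * (U(0, -1) - U(-1, -1))) +
        (S(0, 1) * (U(0, 1) - U(-1, 1)) - S(0, 0) * (U(0, 0) - U(-1, 0))) +
        (S(0, 0) * (U(1, 0) - U(0, 0)) - S(0, -1) * (U(1, -1) - U(0, -1)))
      } else {
        S(0, 1) * (U(1, 1) - U(-1, 1)) - S(0, -1) * (U(1, -1) - U(-1, -1))
      }
      return(f * (t1 + t2))
    }
    if (scheme == "B") {
      sp <- function(i, j) { v <- S(i, j); v + abs(v) }
      sm <- function(i, j) { v <- S(i, j); v - abs(v) }
      t1 <- (sp(1, 0) * (U(1, 1) - U(1, 0)) - sp(0, 0) * (U(0, 1) - U(0, 0))) +
        (sp(0, 0) * (U(0, 0) - U(0, -1)) -
           sp(-1, 0) * (U(-1, 0) - U(-1, -1))) +
        (sm(1, 0) * (U(1, 0) - U(1, -1)) - sm(0, 0) * (U(0, 0) - U(0, -1))) +
        (sm(0, 0) * (U(0, 1) - U(0, 0)) - sm(-1, 0) * (U(-1, 1) - U(-1, 0)))
      t2 <- (sp(0, 1) * (U(1, 1) - U(0, 1)) - sp(0, 0) * (U(1, 0) - U(0, 0))) +
        (sp(0, 0) * (U(0, 0) - U(-1, 0)) -
           sp(0, -1) * (U(0, -1) - U(-1, -1))) +
        (sm(0, 1) * (U(0, 1) - U(-1, 1)) - sm(0, 0) * (U(0, 0) - U(-1, 0))) +
        (sm(0, 0) * (U(1, 0) - U(0, 0)) - sm(0, -1) * (U(1, -1) - U(0, -1)))
      return(f * (t1 + t2))
    }
    if (scheme == "C") {
      av <- function(i1, j1, i2, j2) (S(i1, j1) + S(i2, j2)) / 2
      t1 <- av(1, 0, 1, 1) * (U(1, 1) - U(1, 0)) +
        av(1, 0, 1, -1) * (U(1, 0) - U(1, -1)) -
        av(-1, 0, -1, -1) * (U(-1, 0) - U(-1, -1)) -
        av(-1, 0, -1, 1) * (U(-1, 1) - U(-1, 0))
      t2 <- av(0, 1, 1, 1) * (U(1, 1) - U(0, 1)) +
        av(0, 1, -1, 1) * (U(0, 1) - U(-1, 1)) -
        av(0, -1, -1, -1) * (U(0, -1) - U(-1, -1)) -
        av(0, -1, 1, -1) * (U(1, -1) - U(0, -1))
      return(f * (t1 + t2))
    }
    # scheme E: face-averaged coefficients, central differences
    a0p <- (S(0, 0) + S(1, 0)) / 2
    a0m <- (S(0, 0) + S(-1, 0)) / 2
    b0p <- (S(0, 0) + S(0, 1)) / 2
    b0m <- (S(0, 0) + S(0, -1)) / 2
    t1 <- a0p * (U(1, 1) - U(1, -1) + U(0, 1) - U(0, -1)) -
      a0m * (U(0, 1) - U(0, -1) + U(-1, 1) - U(-1, -1))
    t2 <- b0p * (U(1, 1) - U(-1, 1) + U(1, 0) - U(-1, 0)) -
      b0m * (U(1, -1) - U(-1, -1) + U(1, 0) - U(-1, 0))
    f * (t1 + t2)
  }

  for (k in 2:(n[3] - 1)) for (j in 2:(n[2] - 1)) for (i in 2:(n[1] - 1)) {
    p <- c(i, j, k)
    val <- 0
    for (ax in 1:3) {
      s <- comp[[ax]]
      pp <- pm <- p; pp[ax] <- pp[ax] + 1L; pm[ax] <- pm[ax] - 1L
      s0 <- s[i, j, k]
      sP <- s[pp[1], pp[2], pp[3]]; sM <- s[pm[1], pm[2], pm[3]]
      uP <- uv[pp[1], pp[2], pp[3]]; uM <- uv[pm[1], pm[2], pm[3]]
      val <- val + ((s0 + sP) / 2 * (uP - uv[i, j, k]) -
                      (s0 + sM) / 2 * (uv[i, j, k] - uM)) / h[ax]^2
    }
    val <- val + mixed_at(sigma$xy, p, 1L, 2L, scheme)
    val <- val + mixed_at(sigma$xz, p, 1L, 3L, scheme)
    val <- val + mixed_at(sigma$yz, p, 2L, 3L, scheme)
    out[i, j, k] <- val
  }
  bm <- eitfdm:::boundary_mask(grid)
  out[bm] <- uv[bm]
  out
}

# Smooth random positive-definite tensor field (diagonally dominant).
random_pd_field <- function(grid, seed = 1, off_scale = 0.2) {
  set.seed(seed)
  n <- grid$n
  arr <- function(lo, hi) array(stats::runif(prod(n), lo, hi), n)
  tensor_field(grid, xx = arr(1, 2), yy = arr(1, 2), zz = arr(1, 2),
               xy = arr(-off_scale, off_scale),
               xz = arr(-off_scale, off_scale),
               yz = arr(-off_scale, off_scale))
}
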