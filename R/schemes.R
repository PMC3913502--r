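# Stencil coefficient construction for the 19-point discretization.
#
# The operator is the discrete nabla . (sigma nabla u): for each axis the
# three-point conservative second-derivative scheme with face-averaged
# coefficients, plus, for each of the three coordinate planes, one of five
# second-order approximations of the mixed-derivative pair
# d/dx1 (s d/dx2 u) + d/dx2 (s d/dx1 u).  Sign convention: the assembled
# operator is the negative-definite one (interior centre coefficient < 0;
# for unit isotropic conductivity the interior rows are the 7-point
# Laplacian with +1/h^2 off-diagonals and -6/h^2 centre).
#
# Scheme tags and their defining properties:
#   A - conservative average of the four one-sided splittings
#       Dx+-(s Dy+- u); the centre-coefficient terms cancel algebraically,
#       so A assembles the same matrix as D (kept as a separate tag).
#   B - upwind flux splitting s+- = s +- |s| (maximum-principle scheme);
#       the positive part pairs aligned one-sided differences (++/--),
#       the negative part the opposed ones (+-/-+).
#   C - one-sided differences in the i+-1 columns with edge-averaged
#       coefficients (extra averaging nodes in the stencil).
#   D - four-point scheme with plain node coefficients at the i+-1 nodes,
#       the generalization of the constant-coefficient cross stencil.
#   E - flux form using the same face averages (s0+sE)/2, (s0+sW)/2 as the
#       second-derivative scheme, so diagonal and off-diagonal tensor
#       components are sampled at the same stencil nodes.

SCHEME_TAGS <- c("A", "B", "C", "D", "E")

# 19 stencil offsets: centre, 6 axis neighbours, 12 plane diagonals.
stencil_offsets <- function() {
  o <- rbind(c(0, 0, 0),
             c(1, 0, 0), c(-1, 0, 0),
             c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1),
             c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
             c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
             c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  storage.mode(o) <- "integer"
  o
}

# b[i,j,k] = a[i+d1, j+d2, k+d3] where defined, 0 elsewhere.
shift_array <- function(a, d) {
  n <- dim(a)
  b <- array(0, n)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(n[ax] - d[ax])
      src[[ax]] <- seq_len(n[ax] - d[ax]) + d[ax]
    } else {
      dst[[ax]] <- seq_len(n[ax] + d[ax]) - d[ax]
      src[[ax]] <- seq_len(n[ax] + d[ax])
    }
  }
  b[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  b
}

#' Upwind splitting of an off-diagonal conductivity component
#'
#' Splits a conductivity value into non-negative and non-positive parts,
#' `s+ = s + |s|` and `s- = s - |s|` (so `s+ + s- = 2 s`), as used by the
#' maximum-principle mixed-derivative scheme B.  The conventional halved
#' variant `(s +- |s|)/2` is available for comparison; with the scheme's
#' fixed `1/(4 h1 h2)` prefactor it halves the mixed-derivative term and
#' is therefore inconsistent (see the methods vignette).
#'
#' @param s numeric vector or array of conductivity values (S/m).
#' @param halved use the halved variant (default `FALSE`).
#' @return A list with components `plus` (>= 0) and `minus` (<= 0).
#' @examples
#' scheme_b_split(2)   # plus = 4, minus = 0
#' scheme_b_split(-2)  # plus = 0, minus = -4
#' @export
scheme_b_split <- function(s, halved = FALSE) {
  p <- s + abs(s)
  m <- s - abs(s)
  if (halved) list(plus = p / 2, minus = m / 2)
  else list(plus = p, minus = m)
}

# Coefficient arrays for all 19 offsets, valid on interior nodes.
# Returns list(offsets = 19x3 matrix, coef = list of 19 full-size arrays).
stencil_coefficients <- function(sigma, grid, scheme,
                                 b_split = c("printed", "halved")) {
  scheme <- match.arg(toupper(scheme), SCHEME_TAGS)
  b_split <- match.arg(b_split)
  offs <- stencil_offsets()
  key <- function(d) paste(d, collapse = ",")
  cf <- new.env(parent = emptyenv())
  add <- function(d, v) {
    k <- key(d)
    cur <- get0(k, envir = cf)
    assign(k, if (is.null(cur)) v else cur + v, envir = cf)
  }
  unit <- function(ax) { e <- c(0L, 0L, 0L); e[ax] <- 1L; e }
  h <- grid$h

  # second derivatives: d/dx (sxx d/dx u) etc., face-averaged coefficients
  diag_comp <- list(sigma$xx, sigma$yy, sigma$zz)
  for (ax in 1:3) {
    s <- diag_comp[[ax]]
    e <- unit(ax)
    sp <- (s + shift_array(s, e)) / 2    # sigma^{0,+}
    sm <- (s + shift_array(s, -e)) / 2   # sigma^{0,-}
    add(e, sp / h[ax]^2)
    add(-e, sm / h[ax]^2)
    add(c(0L, 0L, 0L), -(sp + sm) / h[ax]^2)
  }

  # mixed derivatives, one plane at a time
  planes <- list(list(a1 = 1L, a2 = 2L, s = sigma$xy),
                 list(a1 = 1L, a2 = 3L, s = sigma$xz),
                 list(a1 = 2L, a2 = 3L, s = sigma$yz))
  for (pl in planes) {
    s <- pl$s
    if (all(s == 0)) next
    e1 <- unit(pl$a1); e2 <- unit(pl$a2)
    q <- 1 / (4 * h[pl$a1] * h[pl$a2])
    sE <- shift_array(s, e1);  sW <- shift_array(s, -e1)
    sN <- shift_array(s, e2);  sS <- shift_array(s, -e2)
    if (scheme %in% c("A", "D")) {
      # d1(s d2 u): node coefficients in the +-e1 columns
      add(e1 + e2, q * sE);  add(e1 - e2, -q * sE)
      add(-e1 + e2, -q * sW); add(-e1 - e2, q * sW)
      # d2(s d1 u)
      add(e1 + e2, q * sN);  add(-e1 + e2, -q * sN)
      add(e1 - e2, -q * sS); add(-e1 - e2, q * sS)
    } else if (scheme == "C") {
      sEN <- shift_array(s, e1 + e2); sES <- shift_array(s, e1 - e2)
      sWN <- shift_array(s, -e1 + e2); sWS <- shift_array(s, -e1 - e2)
      # d1(s d2 u): edge averages in the +-e1 columns
      a26 <- (sE + sEN) / 2; a25 <- (sE + sES) / 2
      a47 <- (sW + sWN) / 2; a48 <- (sW + sWS) / 2
      add(e1 + e2, q * a26); add(e1, q * (a25 - a26)); add(e1 - e2, -q * a25)
      add(-e1 + e2, -q * a47); add(-e1, q * (a47 - a48)); add(-e1 - e2, q * a48)
      # d2(s d1 u): edge averages in the +-e2 rows
      b36 <- (sN + sEN) / 2; b37 <- (sN + sWN) / 2
      b15 <- (sS + sES) / 2; b18 <- (sS + sWS) / 2
      add(e1 + e2, q * b36); add(e2, q * (b37 - b36)); add(-e1 + e2, -q * b37)
      add(e1 - e2, -q * b15); add(-e2, q * (b15 - b18)); add(-e1 - e2, q * b18)
    } else if (scheme == "E") {
      # d1(s d2 u): face averages along axis 1 (same nodes as Eq-(5) terms)
      a0p <- (s + sE) / 2; a0m <- (s + sW) / 2
      add(e1 + e2, q * a0p); add(e1 - e2, -q * a0p)
      add(e2, q * (a0p - a0m)); add(-e2, -q * (a0p - a0m))
      add(-e1 + e2, -q * a0m); add(-e1 - e2, q * a0m)
      # d2(s d1 u): face averages along axis 2
      b0p <- (s + sN) / 2; b0m <- (s + sS) / 2
      add(e1 + e2, q * b0p); add(-e1 + e2, -q * b0p)
      add(e1, q * (b0p - b0m)); add(-e1, -q * (b0p - b0m))
      add(e1 - e2, -q * b0m); add(-e1 - e2, q * b0m)
    } else { # scheme B
      sp0 <- scheme_b_split(s, halved = b_split == "halved")
      spE <- scheme_b_split(sE, halved = b_split == "halved")
      spW <- scheme_b_split(sW, halved = b_split == "halved")
      spN <- scheme_b_split(sN, halved = b_split == "halved")
      spS <- scheme_b_split(sS, halved = b_split == "halved")
      ab0 <- (sp0$plus - sp0$minus) / 2   # |s| (or |s|/2 when halved)
      abE <- (spE$plus - spE$minus) / 2
      abW <- (spW$plus - spW$minus) / 2
      abN <- (spN$plus - spN$minus) / 2
      abS <- (spS$plus - spS$minus) / 2
      # d1(s d2 u)
      add(e1 + e2, q * spE$plus); add(e1 - e2, -q * spE$minus)
      add(e1, -2 * q * abE)
      add(-e1 + e2, -q * spW$minus); add(-e1 - e2, q * spW$plus)
      add(-e1, -2 * q * abW)
      add(e2, -2 * q * ab0); add(-e2, -2 * q * ab0)
      add(c(0L, 0L, 0L), 4 * q * ab0)
      # d2(s d1 u)
      add(e1 + e2, q * spN$plus); add(-e1 + e2, -q * spN$minus)
      add(e2, -2 * q * abN)
      add(e1 - e2, -q * spS$minus); add(-e1 - e2, q * spS$plus)
      add(-e2, -2 * q * abS)
      add(e1, -2 * q * ab0); add(-e1, -2 * q * ab0)
      add(c(0L, 0L, 0L), 4 * q * ab0)
    }
  }

  coef <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    v <- get0(key(offs[r, ]), envir = cf)
    coef[[r]] <- if (is.null(v)) array(0, grid$n) else v
  }
  list(offsets = offs, coef = coef, scheme = scheme)
}
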