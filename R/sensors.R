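#' Quasi-uniform sensor montage on a sphere
#'
#' Places sensors "evenly along the geodesic lines": vertices of an
#' icosahedron subdivided towards the requested count (achievable counts
#' are 12, 42, 162, 642, 2562; the nearest is used), scaled to the given
#' radius around the centre.
#'
#' @param n_sensors requested sensor count (>= 4).
#' @param radius sphere radius in metres (scalp radius, typically).
#' @param centre sphere centre (metres).
#' @return An object of class `"sensor_montage"`: a data frame with
#'   columns `id`, `x`, `y`, `z` plus attributes `radius`, `centre`.
#' @export
geodesic_sensors <- function(n_sensors, radius, centre = c(0, 0, 0)) {
  n_sensors <- as.integer(n_sensors)
  if (is.na(n_sensors) || n_sensors < 4L)
    stop("need at least 4 sensors", call. = FALSE)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  ico <- icosphere_levels()
  counts <- vapply(ico, function(l) nrow(l$v), integer(1))
  lvl <- which.min(abs(counts - n_sensors))
  v <- ico[[lvl]]$v
  pts <- sweep(v * radius, 2L, as.numeric(centre), `+`)
  m <- data.frame(id = seq_len(nrow(pts)), x = pts[, 1], y = pts[, 2],
                  z = pts[, 3])
  structure(m, class = c("sensor_montage", "data.frame"),
            radius = radius, centre = as.numeric(centre))
}

# Unit icosahedron and three midpoint-subdivision refinements.
icosphere_levels <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  levels <- list(list(v = v, f = f))
  for (l in 2:4) {
    prev <- levels[[l - 1]]
    levels[[l]] <- subdivide_icosphere(prev$v, prev$f)
  }
  levels
}

subdivide_icosphere <- function(v, f) {
  key <- function(a, b) paste(min(a, b), max(a, b))
  mids <- new.env(parent = emptyenv())
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(a, b) {
    k <- key(a, b)
    id <- get0(k, envir = mids)
    if (!is.null(id)) return(id)
    p <- (verts[[a]] + verts[[b]]) / 2
    p <- p / sqrt(sum(p^2))
    verts[[length(verts) + 1L]] <<- p
    id <- length(verts)
    assign(k, id, envir = mids)
    id
  }
  newf <- matrix(0L, nrow(f) * 4L, 3L)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    newf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
  }
  list(v = do.call(rbind, verts), f = newf)
}

#' Sample a potential volume at sensor positions
#'
#' Trilinear interpolation of the scalar volume at each sensor position
#' (exact for fields linear in the coordinates); optionally subtracts the
#' average over sensors (average-reference montage, the usual EEG
#' convention).
#'
#' @param u a [scalar_volume()].
#' @param montage a [geodesic_sensors()] montage (or any data frame with
#'   `x`, `y`, `z` columns); all sensors must lie inside the grid.
#' @param reference `"none"` (default) or `"average"`.
#' @return Numeric vector of per-sensor potentials.
#' @export
sample_sensors <- function(u, montage, reference = c("none", "average")) {
  reference <- match.arg(reference)
  stopifnot(inherits(u, "scalar_volume"))
  grid <- u$grid
  ax <- grid_axes(grid)
  pts <- cbind(montage$x, montage$y, montage$z)
  tix <- sweep(sweep(pts, 2L, grid$origin, `-`), 2L, grid$h, `/`)
  if (any(tix < -1e-9) || any(t(t(tix) - (grid$n - 1)) > 1e-9))
    stop("sensor outside the grid", call. = FALSE)
  i0 <- pmin(pmax(floor(tix), 0), matrix(rep(grid$n - 2, each = nrow(tix)),
                                         ncol = 3))
  tt <- tix - i0
  out <- numeric(nrow(pts))
  for (s in seq_len(nrow(pts))) {
    i <- i0[s, 1] + 1L; j <- i0[s, 2] + 1L; k <- i0[s, 3] + 1L
    tx <- tt[s, 1]; ty <- tt[s, 2]; tz <- tt[s, 3]
    c00 <- u$values[i, j, k] * (1 - tx) + u$values[i + 1, j, k] * tx
    c10 <- u$values[i, j + 1, k] * (1 - tx) + u$values[i + 1, j + 1, k] * tx
    c01 <- u$values[i, j, k + 1] * (1 - tx) + u$values[i + 1, j, k + 1] * tx
    c11 <- u$values[i, j + 1, k + 1] * (1 - tx) +
      u$values[i + 1, j + 1, k + 1] * tx
    out[s] <- ((c00 * (1 - ty) + c10 * ty) * (1 - tz) +
                 (c01 * (1 - ty) + c11 * ty) * tz)
  }
  if (reference == "average") out <- out - mean(out)
  out
}

#' Write a sensor montage as CSV
#'
#' @param montage a [geodesic_sensors()] montage.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_montage_csv <- function(montage, path) {
  utils::write.csv(as.data.frame(montage)[, c("id", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}
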