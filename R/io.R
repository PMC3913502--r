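# Single-file volume container.
#
# A volume container is an RDS file holding one list:
#   $format  "eitfdm-volume/1"
#   $grid    list(n, h, origin)  -- grid metadata
#   $arrays  named list of numeric 3D arrays (e.g. "values" for a scalar
#            volume; "xx","yy","zz","xy","xz","yz" for a tensor field)
#   $kind    "scalar_volume" | "tensor_field" | "raw"
# This keeps user-supplied models and generated fixtures in one
# exchangeable file per volume without inventing a binary layout.

#' Write a volume (scalar or tensor) to a single-file container
#'
#' @param x a [scalar_volume()], [tensor_field()], or named list of 3D
#'   arrays together with a `grid`.
#' @param path output file path (`.rds`).
#' @param grid required only when `x` is a plain list of arrays.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "scalar_volume")) {
    payload <- list(format = "eitfdm-volume/1",
                    grid = x$grid[c("n", "h", "origin")],
                    arrays = list(values = x$values),
                    kind = "scalar_volume")
  } else if (inherits(x, "tensor_field")) {
    payload <- list(format = "eitfdm-volume/1",
                    grid = x$grid[c("n", "h", "origin")],
                    arrays = x[c("xx", "yy", "zz", "xy", "xz", "yz")],
                    kind = "tensor_field")
  } else if (is.list(x) && !is.null(grid)) {
    payload <- list(format = "eitfdm-volume/1",
                    grid = grid[c("n", "h", "origin")],
                    arrays = x, kind = "raw")
  } else {
    stop("cannot serialize this object as a volume container", call. = FALSE)
  }
  saveRDS(payload, path)
  invisible(path)
}

#' Read a volume container written by [write_volume()]
#'
#' @param path container file path.
#' @return The reconstructed [scalar_volume()], [tensor_field()], or list.
#' @export
read_volume <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "eitfdm-volume/1"))
    stop("not an eitfdm volume container", call. = FALSE)
  grid <- regular_grid(payload$grid$n, payload$grid$h, payload$grid$origin)
  switch(payload$kind,
         scalar_volume = scalar_volume(grid, payload$arrays$values),
         tensor_field = tensor_field(grid,
                                     xx = payload$arrays$xx,
                                     yy = payload$arrays$yy,
                                     zz = payload$arrays$zz,
                                     xy = payload$arrays$xy,
                                     xz = payload$arrays$xz,
                                     yz = payload$arrays$yz,
                                     check = FALSE),
         c(payload["arrays"], list(grid = grid)))
}
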