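#' Define a regular latitude-longitude grid
#'
#' Cell-center registration. Cells are enumerated with longitude varying
#' fastest, so cell `k` has coordinates
#' `(lon[(k - 1) %% nlon + 1], lat[(k - 1) %/% nlon + 1])`.
#'
#' @param lat numeric, strictly increasing cell-center latitudes (degrees
#'   north, all strictly inside (-90, 90)).
#' @param lon numeric, strictly increasing cell-center longitudes (degrees
#'   east).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(lat = seq(36.5, 42.5, length.out = 8),
#'                lon = seq(-9.5, -6, length.out = 8))
#' n_cells(g)
#' @export
grid_spec <- function(lat, lon) {
  stopifnot(is.numeric(lat), is.numeric(lon),
            length(lat) >= 1, length(lon) >= 1,
            all(is.finite(lat)), all(is.finite(lon)))
  if (any(abs(lat) >= 90)) stop("grid latitudes must satisfy |lat| < 90")
  if (length(lat) > 1 && any(diff(lat) <= 0))
    stop("lat must be strictly increasing")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("lon must be strictly increasing")
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  length(grid$lat) * length(grid$lon)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a `grid_spec`.
#' @return data.frame with columns `cell`, `lon`, `lat` in cell order.
#' @export
cell_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  data.frame(cell = seq_len(n_cells(grid)),
             lon  = rep(grid$lon, times = length(grid$lat)),
             lat  = rep(grid$lat, each = length(grid$lon)))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells; lat %.3f..%.3f, lon %.3f..%.3f\n",
              length(x$lat), length(x$lon),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol)
}
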