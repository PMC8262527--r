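#' Define a fruit-region mask
#'
#' A region is given either as an explicit vector of grid cell indices or
#' as a polygon (matrix/data.frame of `lon`, `lat` vertices); a cell
#' belongs to a polygon region if its center lies inside (even-odd rule).
#'
#' @param id unique region identifier.
#' @param cells integer cell indices (alternative to `polygon`).
#' @param polygon two-column `lon`/`lat` vertex matrix or data.frame.
#' @param fruit optional fruit label ("apple", "pear", "plum", "orange").
#' @return object of class `region_mask`.
#' @export
region_mask <- function(id, cells = NULL, polygon = NULL, fruit = NA_character_) {
  if (is.null(cells) && is.null(polygon))
    stop("provide cells or polygon")
  if (!is.null(polygon)) {
    polygon <- as.matrix(as.data.frame(polygon)[, 1:2])
    colnames(polygon) <- c("lon", "lat")
    if (nrow(polygon) < 3) stop("polygon needs >= 3 vertices")
  }
  structure(list(id = as.character(id), cells = cells, polygon = polygon,
                 fruit = fruit),
            class = "region_mask")
}

# ray-casting (even-odd) point-in-polygon; boundary points count as inside
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Resolve the member cells of a region on a grid
#'
#' @param mask a [region_mask()].
#' @param grid a [grid_spec()].
#' @return integer cell indices; errors if the intersection is empty.
#' @export
region_cells <- function(mask, grid) {
  stopifnot(inherits(mask, "region_mask"), inherits(grid, "grid_spec"))
  if (!is.null(mask$cells)) {
    cells <- intersect(as.integer(mask$cells), seq_len(n_cells(grid)))
  } else {
    cc <- cell_coords(grid)
    cells <- cc$cell[point_in_polygon(cc$lon, cc$lat,
                                      mask$polygon[, "lon"],
                                      mask$polygon[, "lat"])]
  }
  if (length(cells) == 0)
    stop(sprintf("region %s does not intersect the grid", mask$id))
  cells
}

#' Read region masks from a GeoJSON FeatureCollection
#'
#' Expects Polygon features with properties `id` (or `name`) and
#' optionally `fruit`; only the outer ring is used.
#'
#' @param path GeoJSON file path.
#' @return named list of [region_mask()] objects.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  masks <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    id <- f$properties$id
    if (is.null(id)) id <- f$properties$name
    fruit <- f$properties$fruit
    region_mask(id, polygon = ring,
                fruit = if (is.null(fruit)) NA_character_ else fruit)
  })
  names(masks) <- vapply(masks, `[[`, "", "id")
  if (anyDuplicated(names(masks))) stop("region ids must be unique")
  masks
}

#' Extract region member values from a gridded field
#'
#' @param field data.frame with columns `cell` and a value column
#'   (`value`, `mean` or `delta`), e.g. a `safe_index` field.
#' @param mask a [region_mask()].
#' @param grid the [grid_spec()] the field lives on.
#' @param value_col value column name; default the first of
#'   `value`/`mean`/`delta` present.
#' @return numeric vector of member-cell values; missing cells are dropped
#'   and their count reported via a message.
#' @export
extract_region <- function(field, mask, grid, value_col = NULL) {
  stopifnot(is.data.frame(field), "cell" %in% names(field))
  if (is.null(value_col))
    value_col <- intersect(c("value", "mean", "delta"), names(field))[1]
  cells <- region_cells(mask, grid)
  v <- field[[value_col]][match(cells, field$cell)]
  n_miss <- sum(is.na(v))
  if (n_miss > 0)
    message(sprintf("region %s: %d missing cell value(s) dropped",
                    mask$id, n_miss))
  v[!is.na(v)]
}

#' Boxplot statistics of a set of regional values
#'
#' Order statistics use the same percentile convention as [safe_index()]
#' (type 7); the mean is arithmetic. Satisfies
#' `min <= q25 <= median <= q75 <= max` and `min <= mean <= max`.
#'
#' @param values numeric vector (>= 1 finite value).
#' @return one-row data.frame: `min`, `q25`, `mean`, `median`, `q75`, `max`, `n`.
#' @export
regional_boxstats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(min = min(values), q25 = q[1], mean = mean(values),
             median = q[2], q75 = q[3], max = max(values),
             n = length(values))
}
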