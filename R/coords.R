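#' Bregma-anchored coordinate system
#'
#' Widefield recordings are referenced to the skull landmark bregma. Pixel
#' coordinates are 0-based with `x` = column increasing rightward and `y` =
#' row increasing downward; anatomical micron coordinates are signed offsets
#' from bregma with `+x` = animal's right (mediolateral) and `+y` = anterior.
#' Anterior therefore maps to smaller row indices (the sign flip in
#' [um_to_px()]).
#'
#' @param origin numeric length-2, bregma position `(x_px, y_px)` in pixels.
#' @param um_per_px microns per pixel (> 0); e.g. a 10.5 mm field of view on
#'   a 256-pixel sensor gives 41 um/px.
#' @return A `coordinate_system` list.
#' @examples
#' cs <- coordinate_system(c(136.28, 145.06), 41)
#' um_to_px(c(-2516.8, -4267.8), cs)  # left V1
#' @export
coordinate_system <- function(origin, um_per_px) {
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("coordinate_system: origin must be finite (x_px, y_px)")
  if (!is.numeric(um_per_px) || um_per_px <= 0)
    stop("coordinate_system: um_per_px must be > 0")
  structure(list(origin = as.numeric(origin),
                 um_per_px = as.numeric(um_per_px)),
            class = "coordinate_system")
}

#' Microns-per-pixel from field of view
#'
#' @param fov_mm field-of-view width in millimetres.
#' @param sensor_px sensor width in pixels.
#' @return Microns per pixel, rounded to the nearest integer.
#' @examples
#' fov_um_per_px(10.5, 256)  # 41
#' @export
fov_um_per_px <- function(fov_mm, sensor_px) {
  if (fov_mm <= 0 || sensor_px < 1) stop("fov_um_per_px: invalid arguments")
  round(fov_mm * 1000 / sensor_px)
}

#' Average bregma clicks into the project origin
#'
#' Bregma is clicked once per calibration stack and the clicks are averaged
#' componentwise to reduce pointing error.
#'
#' @param clicks numeric n x 2 matrix (or length-2 vector) of `(x_px, y_px)`
#'   click positions.
#' @return Length-2 numeric `(x_px, y_px)`.
#' @export
set_origin <- function(clicks) {
  if (is.null(dim(clicks))) clicks <- matrix(clicks, ncol = 2, byrow = TRUE)
  if (nrow(clicks) < 1L) stop("set_origin: at least one click required")
  colMeans(clicks)
}

#' Convert between micron and pixel coordinates
#'
#' Exact algebraic inverses: `px_to_um(um_to_px(p, cs), cs) == p`.
#'
#' @param p numeric length-2 point, or n x 2 matrix of points.
#' @param cs a [coordinate_system()].
#' @return Point(s) in the other unit, same shape as `p`.
#' @export
um_to_px <- function(p, cs) {
  .check_cs(cs)
  if (is.null(dim(p))) {
    c(cs$origin[1] + p[1] / cs$um_per_px, cs$origin[2] - p[2] / cs$um_per_px)
  } else {
    cbind(cs$origin[1] + p[, 1] / cs$um_per_px,
          cs$origin[2] - p[, 2] / cs$um_per_px)
  }
}

#' @rdname um_to_px
#' @export
px_to_um <- function(p, cs) {
  .check_cs(cs)
  if (is.null(dim(p))) {
    c((p[1] - cs$origin[1]) * cs$um_per_px,
      (cs$origin[2] - p[2]) * cs$um_per_px)
  } else {
    cbind((p[, 1] - cs$origin[1]) * cs$um_per_px,
          (cs$origin[2] - p[, 2]) * cs$um_per_px)
  }
}

.check_cs <- function(cs) {
  if (!inherits(cs, "coordinate_system"))
    stop("a coordinate_system with origin and um_per_px is required")
}

#' Import square seed RoIs from CSV
#'
#' The CSV carries one row per seed with header `name,length,x,y`: a region
#' name, the square side length in pixels, and the centre in microns
#' relative to bregma. Row order is preserved.
#'
#' @param path CSV path.
#' @return A data frame with columns `name`, `length`, `x`, `y`.
#' @export
import_roi_csv <- function(path) {
  if (!file.exists(path)) stop("import_roi_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "length", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("import_roi_csv: missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  if (nrow(df) == 0L) return(df)
  for (col in c("length", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop("import_roi_csv: non-numeric value in column '", col, "'")
    df[[col]] <- v
  }
  if (anyDuplicated(df$name))
    stop("import_roi_csv: duplicate RoI name: ",
         df$name[duplicated(df$name)][1])
  if (any(df$length < 1))
    stop("import_roi_csv: RoI length must be >= 1 pixel")
  df
}

# round half away from zero (0.5 -> 1, -0.5 -> -1); seed centres must not
# depend on R's banker's rounding
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Pixels covered by a square seed RoI
#'
#' Converts the seed centre from microns to pixels, rounds half-away-from-
#' zero to a pixel, and returns the `length x length` block centred there,
#' clipped to the frame.
#'
#' @param roi a one-row data frame (or list) with `x`, `y` (microns) and
#'   `length` (pixels).
#' @param cs a [coordinate_system()].
#' @param img_dim frame size `c(height, width)` in pixels.
#' @return Integer n x 2 matrix of 0-based `(x_px, y_px)` pixel coordinates.
#' @export
seed_pixels <- function(roi, cs, img_dim) {
  ctr <- um_to_px(c(roi$x, roi$y), cs)
  cx <- .round_half_away(ctr[1]); cy <- .round_half_away(ctr[2])
  if (cx < 0 || cx >= img_dim[2] || cy < 0 || cy >= img_dim[1])
    stop(sprintf("seed_pixels: RoI centre (%.1f, %.1f) px outside the %dx%d image",
                 ctr[1], ctr[2], img_dim[1], img_dim[2]))
  half <- floor(roi$length / 2)
  lo <- -half; hi <- lo + roi$length - 1
  xs <- (cx + lo):(cx + hi); ys <- (cy + lo):(cy + hi)
  g <- expand.grid(x = xs, y = ys)
  g <- g[g$x >= 0 & g$x < img_dim[2] & g$y >= 0 & g$y < img_dim[1], ]
  cbind(x = as.integer(g$x), y = as.integer(g$y))
}

# even-odd point-in-polygon for all pixel centres at once; boundary pixels
# count as inside
.polygon_hits <- function(height, width, verts) {
  px <- rep(0:(width - 1), each = height)
  py <- rep(0:(height - 1), times = width)
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    # on-segment test
    d <- abs((xj - xi) * (py - yi) - (yj - yi) * (px - xi))
    len2 <- (xj - xi)^2 + (yj - yi)^2
    tproj <- ((px - xi) * (xj - xi) + (py - yi) * (yj - yi))
    onedge <- onedge | (d < 1e-9 * max(1, sqrt(len2)) &
                          tproj >= -1e-9 & tproj <= len2 + 1e-9)
    j <- i
  }
  matrix(inside | onedge, nrow = height)
}

#' Mask a stack to polygon RoIs
#'
#' Pixels whose centres fall inside any polygon keep their values; all other
#' pixels become undefined (`NaN`) in every frame. Used to crop away the
#' cortex border and midline sinus before filtering.
#'
#' @param stack an [image_stack()].
#' @param polygons list of n x 2 vertex matrices, 0-based `(x_px, y_px)`;
#'   each polygon needs at least 3 vertices. An empty list masks everything.
#' @return The masked [image_stack()].
#' @export
polygon_mask <- function(stack, polygons) {
  d <- frame_dim(stack)
  keep <- matrix(FALSE, d[1], d[2])
  for (p in polygons) {
    p <- as.matrix(p)
    if (nrow(p) < 3L)
      stop("polygon_mask: polygons need at least 3 vertices")
    keep <- keep | .polygon_hits(d[1], d[2], p)
  }
  m <- .stack_to_mat(stack)
  m[, !as.vector(keep)] <- NaN
  .mat_to_stack(m, d, stack$fps)
}

#' Shift a stack onto a common bregma origin
#'
#' Translates the stack by `target_origin - own_origin` (bilinear
#' resampling) so stacks from different animals share one coordinate
#' system; pixels exposed by the shift become undefined.
#'
#' @param stack an [image_stack()].
#' @param own_origin,target_origin length-2 `(x_px, y_px)` bregma positions.
#' @return The shifted [image_stack()].
#' @export
shift_to_common_origin <- function(stack, own_origin, target_origin) {
  d <- as.numeric(target_origin) - as.numeric(own_origin)
  if (all(d == 0)) return(stack)
  apply_transform(stack, rigid_transform(dx = d[1], dy = d[2]))
}
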