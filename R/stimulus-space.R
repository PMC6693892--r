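#' Quantity dimensions of a dot-array stimulus
#'
#' The five quantitative dimensions carried by every condition of the
#' factorial design: numerosity (\code{number}), average item area
#' (\code{avg_item_area}, vd^2), total field area (\code{total_field_area},
#' vd^2), total surface area (\code{total_surface_area} = N x S, vd^2) and
#' density (\code{density} = N / TFA, dots/vd^2).
#'
#' @export
quantity_dimensions <- c("number", "avg_item_area", "total_field_area",
                         "total_surface_area", "density")

#' Build the factorial quantity condition grid
#'
#' Crosses numerosity, average item area and total field area into the full
#' factorial stimulus set, deriving total surface area (TSA = N x S) and
#' density (D = N / TFA) for each cell. The default levels are 6/10/17 dots,
#' item areas 0.04/0.07/0.12 vd^2 and field areas 20/44 vd^2, giving the
#' 18-condition design. Field areas are the nominal circle areas; pass
#' \code{exact_field_areas = TRUE} to use the disc areas implied by 5 and
#' 7.5 degree diameters (19.635 and 44.179 vd^2) instead.
#'
#' Condition order is deterministic: number varies slowest, then item area,
#' then field area, so the grid is stable across calls and serialisation
#' round-trips.
#'
#' @param numbers numerosity levels (dot counts), positive and distinct.
#' @param item_areas average item area levels in vd^2.
#' @param field_areas total field area levels in vd^2.
#' @param exact_field_areas replace the default nominal 20/44 vd^2 with the
#'   exact disc areas of 5 and 7.5 degree diameter circles. Ignored when
#'   \code{field_areas} is supplied explicitly.
#' @return A data frame of class \code{"stimulus_set"} with columns
#'   \code{label}, \code{number}, \code{avg_item_area},
#'   \code{total_field_area}, \code{total_surface_area}, \code{density},
#'   and a \code{"factor_levels"} attribute.
#' @examples
#' grid <- condition_grid()
#' nrow(grid)  # 18
#' @export
condition_grid <- function(numbers = c(6, 10, 17),
                           item_areas = c(0.04, 0.07, 0.12),
                           field_areas = c(20, 44),
                           exact_field_areas = FALSE) {
  if (exact_field_areas && missing(field_areas))
    field_areas <- pi * c(5, 7.5)^2 / 4
  check_levels(numbers, "numbers")
  check_levels(item_areas, "item_areas")
  check_levels(field_areas, "field_areas")

  idx <- expand.grid(tfa = seq_along(field_areas),
                     s = seq_along(item_areas),
                     n = seq_along(numbers))
  n <- numbers[idx$n]
  s <- item_areas[idx$s]
  tfa <- field_areas[idx$tfa]
  out <- data.frame(
    label = sprintf("N%d-S%d-TFA%d", idx$n, idx$s, idx$tfa),
    number = n,
    avg_item_area = s,
    total_field_area = tfa,
    total_surface_area = n * s,
    density = n / tfa,
    stringsAsFactors = FALSE
  )
  structure(out,
            factor_levels = list(numbers = numbers, item_areas = item_areas,
                                 field_areas = field_areas),
            class = c("stimulus_set", "data.frame"))
}

check_levels <- function(x, what) {
  if (length(x) < 1L)
    stop("'", what, "' must contain at least one level", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("'", what, "' must be strictly positive and finite", call. = FALSE)
  if (anyDuplicated(x))
    stop("'", what, "' levels must be distinct", call. = FALSE)
  invisible(x)
}

#' @export
print.stimulus_set <- function(x, ...) {
  fl <- attr(x, "factor_levels")
  cat(sprintf("Stimulus set: %d conditions (%d numerosities x %d item areas x %d field areas)\n",
              nrow(x), length(fl$numbers), length(fl$item_areas),
              length(fl$field_areas)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Correlation between two quantity dimensions across conditions
#'
#' Product-moment correlation between two stimulus dimensions, treating each
#' condition of the grid as one observation. This is the design audit that
#' quantifies how strongly the derived magnitudes (TSA, density) covary with
#' numerosity despite the orthogonal manipulation of item area and field
#' area.
#'
#' @param set a \code{stimulus_set}.
#' @param dim_a,dim_b dimension names among
#'   \code{number}, \code{avg_item_area}, \code{total_field_area},
#'   \code{total_surface_area}, \code{density}.
#' @param tsa_values optional explicit per-condition total surface areas
#'   (length \code{nrow(set)}) replacing the stored \code{N x S} values, for
#'   auditing a design against measured rather than nominal areas.
#' @return the correlation coefficient.
#' @export
dimension_correlation <- function(set, dim_a, dim_b, tsa_values = NULL) {
  stopifnot(inherits(set, "stimulus_set"))
  dim_a <- match.arg(dim_a, quantity_dimensions)
  dim_b <- match.arg(dim_b, quantity_dimensions)
  vals <- set
  if (!is.null(tsa_values)) {
    if (length(tsa_values) != nrow(set))
      stop("'tsa_values' must have one value per condition", call. = FALSE)
    vals$total_surface_area <- tsa_values
  }
  a <- vals[[dim_a]]
  b <- vals[[dim_b]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("dimension has zero variance across conditions; correlation undefined",
         call. = FALSE)
  stats::cor(a, b)
}

#' Render one dot array for a stimulus condition
#'
#' Places \code{condition$number} non-overlapping dots uniformly at random
#' inside the virtual circle whose area is the condition's total field area.
#' Per-dot areas are heterogeneous: drawn uniformly in
#' \code{avg_item_area * (1 +/- size_jitter)} and rescaled so their mean is
#' exactly the condition's average item area. Half the dots are black and
#' half white (the extra dot is black for odd counts), so total luminance
#' carries no numerosity cue on a mid-gray background.
#'
#' @param condition a single-row \code{stimulus_set} (one condition).
#' @param seed integer seed; identical seeds give identical arrays.
#' @param size_jitter half-width of the relative item-area spread, in
#'   \code{[0, 1)}.
#' @param min_gap minimum edge-to-edge gap between dots, visual degrees.
#' @param max_attempts rejection-sampling budget for the whole array.
#' @return an object of class \code{"dot_array"}: list with \code{condition},
#'   \code{centers} (n x 2 matrix, visual degrees), \code{item_areas},
#'   \code{colors} ("black"/"white") and \code{field_radius}.
#' @export
render_dot_array <- function(condition, seed = 1L, size_jitter = 0.4,
                             min_gap = 0.05, max_attempts = 10000L) {
  condition <- as_condition(condition)
  n <- condition$number
  s <- condition$avg_item_area
  stopifnot(size_jitter >= 0, size_jitter < 1, min_gap >= 0)
  field_radius <- sqrt(condition$total_field_area / pi)

  res <- with_seed(seed, {
  areas <- stats::runif(n, s * (1 - size_jitter), s * (1 + size_jitter))
  areas <- areas * (s / mean(areas))  # mean exactly S
  radii <- sqrt(areas / pi)
  if (max(radii) >= field_radius)
    stop("dot larger than field for condition ", condition$label, call. = FALSE)

  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " dots for condition ", condition$label,
           " within ", max_attempts, " attempts", call. = FALSE)
    r_i <- radii[placed + 1L]
    # uniform in the disc of radius (field_radius - r_i)
    rho <- (field_radius - r_i) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    cand <- c(rho * cos(th), rho * sin(th))
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
      ok <- all(d >= radii[seq_len(placed)] + r_i + min_gap)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  list(centers = centers, areas = areas)
  })
  n_black <- ceiling(n / 2)
  colors <- c(rep("black", n_black), rep("white", n - n_black))
  structure(list(condition = condition, centers = res$centers,
                 item_areas = res$areas, colors = colors,
                 field_radius = field_radius),
            class = "dot_array")
}

as_condition <- function(condition) {
  if (inherits(condition, "stimulus_set") || is.data.frame(condition)) {
    if (nrow(condition) != 1L)
      stop("'condition' must be a single condition (one row)", call. = FALSE)
    return(as.list(condition))
  }
  stopifnot(is.list(condition),
            all(c("number", "avg_item_area", "total_field_area") %in%
                  names(condition)))
  if (is.null(condition$label)) condition$label <- "<unnamed>"
  condition
}

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("Dot array '%s': %d dots (%d black/%d white), field radius %.3f deg\n",
              x$condition$label, nrow(x$centers),
              sum(x$colors == "black"), sum(x$colors == "white"),
              x$field_radius))
  invisible(x)
}

#' Plot a rendered dot array
#'
#' Draws the array as filled black and white circles on a mid-gray
#' background, with the virtual field circle dashed.
#'
#' @param x a \code{dot_array}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.dot_array <- function(x, ...) {
  r <- x$field_radius
  op <- graphics::par(bg = "gray50", pty = "s")
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-r, r) * 1.05, ylim = c(-r, r) * 1.05,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = x$condition$label, ...)
  graphics::symbols(0, 0, circles = r, inches = FALSE, add = TRUE,
                    fg = "gray30", lty = 2)
  graphics::symbols(x$centers[, 1], x$centers[, 2],
                    circles = sqrt(x$item_areas / pi), inches = FALSE,
                    add = TRUE, bg = x$colors, fg = NA)
  invisible(x)
}

#' Convex hull area of a dot array
#'
#' Area (vd^2) of the convex hull of dot centers, the a-posteriori spread
#' statistic of an array. By convention the hull is computed on centers;
#' set \code{boundary = "edge"} to use each dot's outermost point instead
#' (centers pushed radially outwards by the dot radius).
#'
#' @param array a \code{dot_array}, or an n x 2 matrix of centers.
#' @param boundary \code{"center"} (default) or \code{"edge"}.
#' @return hull area; 0 for fewer than 3 dots or collinear centers.
#' @export
convex_hull_area <- function(array, boundary = c("center", "edge")) {
  boundary <- match.arg(boundary)
  if (inherits(array, "dot_array")) {
    pts <- array$centers
    if (boundary == "edge") {
      rad <- sqrt(array$item_areas / pi)
      nrm <- sqrt(rowSums(pts^2))
      scl <- ifelse(nrm > 0, (nrm + rad) / nrm, 1)
      pts <- pts * scl
    }
  } else {
    pts <- as.matrix(array)
  }
  if (nrow(pts) == 0L) stop("empty point set", call. = FALSE)
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3L) return(0)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Write / read a stimulus set as CSV
#'
#' @param set a \code{stimulus_set}.
#' @param path file path.
#' @export
write_stimulus_set <- function(set, path) {
  stopifnot(inherits(set, "stimulus_set"))
  utils::write.csv(as.data.frame(set), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "number", "avg_item_area", "total_field_area",
            "total_surface_area", "density")
  stopifnot(all(need %in% names(df)))
  structure(df[need],
            factor_levels = list(numbers = unique(df$number),
                                 item_areas = unique(df$avg_item_area),
                                 field_areas = unique(df$total_field_area)),
            class = c("stimulus_set", "data.frame"))
}

#' Export a dot array as CSV
#'
#' One row per dot: x, y, item area, color.
#' @param array a \code{dot_array}.
#' @param path file path.
#' @export
write_dot_array <- function(array, path) {
  stopifnot(inherits(array, "dot_array"))
  df <- data.frame(x = array$centers[, 1], y = array$centers[, 2],
                   item_area = array$item_areas, color = array$colors)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
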