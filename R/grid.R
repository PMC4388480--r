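#' Grid geometry for image-scale analysis
#'
#' Defines the square grid used to average per-pixel orientations into
#' per-square directors. The default square size of 30 pixels corresponds
#' to roughly 4.2 um at the imaging scale for which the pipeline was
#' designed — about two sarcomere complexes, so that each square contains
#' at least one natural biological unit. Squares are half-open
#' `[k*s, (k+1)*s)` in both axes and tile the full image extent; squares
#' clipped by the image edge keep their clipped area.
#'
#' @param square_size side of a grid square in pixels.
#' @param extent numeric `(width, height)` of the image in pixels.
#' @param origin numeric `(x, y)` offset of the grid, default `(0, 0)`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(square_size = 30, extent, origin = c(0, 0)) {
  if (!is.numeric(square_size) || square_size <= 0) {
    stop("grid_spec: 'square_size' must be positive", call. = FALSE)
  }
  extent <- as.numeric(extent)
  if (length(extent) != 2L || any(extent <= 0)) {
    stop("grid_spec: 'extent' must be positive (width, height)",
         call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2L) {
    stop("grid_spec: 'origin' must be (x, y)", call. = FALSE)
  }
  structure(list(square_size = square_size, extent = extent, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g px squares over %g x %g (origin %g, %g)\n",
              x$square_size, x$extent[1L], x$extent[2L],
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$square_size, b$square_size)) &&
    isTRUE(all.equal(a$extent, b$extent)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Partition an orientation field onto a grid
#'
#' Assigns every pixel to exactly one square and summarizes each square by
#' the mean order tensor of its pseudo-vectors: the director angle, the
#' square's OOP, the pixel count, the clipped square area and the area
#' density `rho` (non-empty angle count / area). Empty squares are
#' retained with `rho = 0` and an undefined (`NA`) director so that
#' downstream weighting can null them explicitly rather than silently.
#'
#' @param field an [orientation_field()] with coordinates.
#' @param spec a [grid_spec()] covering all coordinates.
#' @return a `grid_summary`: data.frame with one row per square (columns
#'   `square`, `ix`, `iy`, `n_pixels`, `area`, `density`, `oop`,
#'   `director_angle`), carrying the spec as attribute `"spec"`.
#' @export
grid_partition <- function(field, spec) {
  if (!inherits(field, "orientation_field") || is.null(field$coords)) {
    stop("grid_partition: 'field' must be an orientation_field with coords",
         call. = FALSE)
  }
  if (!inherits(spec, "grid_spec")) {
    stop("grid_partition: 'spec' must be a grid_spec", call. = FALSE)
  }
  x <- field$coords[, 1L] - spec$origin[1L]
  y <- field$coords[, 2L] - spec$origin[2L]
  bad <- which(x < 0 | x >= spec$extent[1L] | y < 0 | y >= spec$extent[2L])
  if (length(bad)) {
    stop(sprintf(
      "grid_partition: %d coordinate(s) outside the extent (first offenders: %s)",
      length(bad),
      paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  s <- spec$square_size
  nx <- ceiling(spec$extent[1L] / s)
  ny <- ceiling(spec$extent[2L] / s)
  ix <- pmin(floor(x / s), nx - 1)
  iy <- pmin(floor(y / s), ny - 1)
  square <- ix + nx * iy + 1L

  all_ix <- rep(seq_len(nx) - 1L, times = ny)
  all_iy <- rep(seq_len(ny) - 1L, each = nx)
  w_clip <- pmin(s, spec$extent[1L] - all_ix * s)
  h_clip <- pmin(s, spec$extent[2L] - all_iy * s)
  area <- w_clip * h_clip

  n_pixels <- tabulate(square, nbins = nx * ny)
  oop_v <- rep(NA_real_, nx * ny)
  dir_v <- rep(NA_real_, nx * ny)
  by_square <- split(field$angles, square)
  for (key in names(by_square)) {
    i <- as.integer(key)
    ot <- order_tensor(by_square[[key]])
    oop_v[i] <- ot$max_eigenvalue
    dir_v[i] <- director_angle(ot$director)
  }
  out <- data.frame(square = seq_len(nx * ny), ix = all_ix, iy = all_iy,
                    n_pixels = n_pixels, area = area,
                    density = n_pixels / area,
                    oop = oop_v, director_angle = dir_v)
  attr(out, "spec") <- spec
  attr(out, "label") <- field$label
  class(out) <- c("grid_summary", "data.frame")
  out
}

#' Per-square weights for a pair of gridded constructs
#'
#' Aligns two `grid_summary` objects on a common grid and assigns each
#' square the weight `W_i = OOP_P_i * OOP_Q_i * rho_P_i * rho_Q_i`:
#' sparse, disordered or partial squares are down-weighted and squares
#' where either construct is absent contribute nothing.
#'
#' @param p,q `grid_summary` objects from [grid_partition()] on the same
#'   [grid_spec()].
#' @return a `weighted_pair_grid`: data.frame with per-square directors,
#'   OOPs, densities and `weight`.
#' @export
grid_weights <- function(p, q) {
  if (!inherits(p, "grid_summary") || !inherits(q, "grid_summary")) {
    stop("grid_weights: inputs must be grid_summary objects", call. = FALSE)
  }
  sp <- attr(p, "spec")
  sq <- attr(q, "spec")
  if (!same_grid(sp, sq)) {
    stop("grid_weights: incompatible grids (square size, extent or origin differ)",
         call. = FALSE)
  }
  stopifnot(nrow(p) == nrow(q))
  w <- p$oop * q$oop * p$density * q$density
  w[is.na(w)] <- 0   # either construct absent in the square
  out <- data.frame(square = p$square, ix = p$ix, iy = p$iy,
                    director_p = p$director_angle,
                    director_q = q$director_angle,
                    oop_p = p$oop, oop_q = q$oop,
                    density_p = p$density, density_q = q$density,
                    weight = w)
  attr(out, "spec") <- sp
  class(out) <- c("weighted_pair_grid", "data.frame")
  out
}

#' Weighted COOP of a gridded construct pair
#'
#' Computes the COOP on the per-square director pairs, with the mean
#' tensor of the relative-angle field formed as the weight-normalized
#' average over squares. With equal weights on every non-empty square this
#' reduces to the unweighted COOP of the directors; in the
#' one-pixel-per-square limit it reproduces the pixel-level COOP.
#'
#' @param wpg a `weighted_pair_grid` from [grid_weights()].
#' @return a `coop_result` (see [coop()]).
#' @export
weighted_coop <- function(wpg) {
  if (!inherits(wpg, "weighted_pair_grid")) {
    stop("weighted_coop: input must be a weighted_pair_grid", call. = FALSE)
  }
  keep <- wpg$weight > 0
  if (!any(keep)) {
    stop("weighted_coop: all grid weights are zero (no co-occupied squares)",
         call. = FALSE)
  }
  coop(paired_field(wpg$director_p[keep], wpg$director_q[keep],
                    weights = wpg$weight[keep]))
}

#' Pairwise consistency matrix across samples
#'
#' For one construct imaged across several co-registered samples (e.g.
#' cells patterned on identical matrix islands), computes the weighted
#' COOP between every pair of samples' per-square directors. The diagonal
#' is 1 (a sample against itself) and the matrix is symmetric.
#'
#' @param summaries list of `grid_summary` objects sharing a
#'   [grid_spec()].
#' @return symmetric numeric matrix with unit diagonal; attribute
#'   `"off_diagonal_mean"` carries the mean of the upper off-diagonal
#'   entries.
#' @export
consistency_matrix <- function(summaries) {
  k <- length(summaries)
  if (k < 2L) {
    stop("consistency_matrix: need at least two samples", call. = FALSE)
  }
  m <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      cij <- weighted_coop(grid_weights(summaries[[i]], summaries[[j]]))$coop
      m[i, j] <- cij
      m[j, i] <- cij
    }
  }
  labels <- vapply(summaries, function(s) {
    l <- attr(s, "label")
    if (is.null(l)) "" else l
  }, character(1L))
  if (any(nzchar(labels))) dimnames(m) <- list(labels, labels)
  attr(m, "off_diagonal_mean") <- mean(m[upper.tri(m)])
  m
}

#' Mean and spread of the inter-construct angle across samples
#'
#' Combines per-sample COOP directors into a single mean angle and its
#' standard deviation, respecting the period-pi ambiguity. The director of
#' the directors (the order tensor of the per-sample director angles)
#' fixes a common arccos/arcsin branch (see [director_to_angle()]), every
#' sample director is converted to an angle on that branch, and the
#' arithmetic mean and standard deviation are returned. When the overall
#' order of the directors is weak the branch is arbitrary and the result
#' unstable; a warning is issued.
#'
#' @param directors list of unit 2-vectors, or an n x 2 matrix, one
#'   director per sample.
#' @param min_order warn below this overall director order.
#' @return list with `theta0_mean`, `theta0_sd`, `angles` (per-sample
#'   branch-consistent angles) and `overall_order`.
#' @export
multi_sample_angle_stats <- function(directors, min_order = 0.2) {
  if (is.matrix(directors)) {
    directors <- lapply(seq_len(nrow(directors)), function(i) directors[i, ])
  }
  if (length(directors) < 2L) {
    stop("multi_sample_angle_stats: need at least two samples", call. = FALSE)
  }
  for (d in directors) check_unit_vector(d, "directors")
  angles <- vapply(directors, function(d) atan2(d[2L], d[1L]), numeric(1L))
  ot <- order_tensor(angles)
  if (ot$max_eigenvalue < min_order) {
    warning(paste("multi_sample_angle_stats: overall director order is",
                  "near zero; the mean angle is unstable"), call. = FALSE)
  }
  theta <- vapply(directors, director_to_angle, numeric(1L),
                  reference = ot$director)
  list(theta0_mean = mean(theta), theta0_sd = stats::sd(theta),
       angles = theta, overall_order = ot$max_eigenvalue)
}
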