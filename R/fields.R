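#' Orientation field of axial angles
#'
#' An orientation field is a non-empty set of axial angles (period pi),
#' optionally tagged with 2D pixel coordinates. It is the container for a
#' single biological construct (e.g. actin fibrils or sarcomeric Z-lines)
#' whose per-pixel directions have been extracted upstream.
#'
#' Angles are stored canonically in `[0, pi)`. Because every downstream
#' formula acts on unit pseudo-vectors through double-angle trigonometry,
#' the choice of representative is unobservable except through the symmetry
#' tests.
#'
#' @param angles numeric vector of angles in radians, interpreted modulo pi.
#' @param coords optional two-column matrix or data.frame of (x, y) pixel
#'   positions, index-aligned with `angles`.
#' @param label free-text identifier carried through summaries.
#'
#' @return An object of class `orientation_field`: a list with elements
#'   `angles` (canonicalized to `[0, pi)`), `coords` (matrix or `NULL`) and
#'   `label`.
#' @examples
#' of <- orientation_field(c(0, pi / 4, 3 * pi / 2))
#' of$angles  # 3*pi/2 stored as pi/2
#' @seealso [paired_field()], [oop()]
#' @export
orientation_field <- function(angles, coords = NULL, label = "") {
  if (length(angles) == 0L) {
    stop("orientation_field: 'angles' must be non-empty", call. = FALSE)
  }
  angles <- as.numeric(angles)
  if (anyNA(angles)) {
    stop("orientation_field: 'angles' contains NA", call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(angles) || ncol(coords) != 2L) {
      stop("orientation_field: 'coords' must be an n x 2 matrix aligned with 'angles'",
           call. = FALSE)
    }
    storage.mode(coords) <- "double"
    colnames(coords) <- c("x", "y")
  }
  structure(
    list(angles = canonical_angle(angles), coords = coords,
         label = as.character(label)[1L]),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat("<orientation_field>", if (nzchar(x$label)) x$label else NULL, "\n")
  cat("  n =", length(x$angles),
      if (is.null(x$coords)) "(no coordinates)" else "(with coordinates)", "\n")
  o <- oop(x$angles)
  cat(sprintf("  OOP = %.4f, director angle = %.4f rad\n",
              o$oop, director_angle(o$director)))
  invisible(x)
}

#' @export
length.orientation_field <- function(x) length(x$angles)

#' Index-aligned pair of orientation fields
#'
#' A paired field holds the angles of two constructs P and Q measured at the
#' same locations, the input from which the relative-angle field and the
#' co-orientational order parameter are computed. Optional non-negative
#' weights scale each pair's contribution to every tensor average (used by
#' the grid pipeline, where per-square weights combine order and density).
#'
#' @param p_angles,q_angles numeric vectors of equal length: angles in
#'   radians modulo pi for constructs P and Q.
#' @param weights optional non-negative numeric vector, index-aligned, with
#'   a positive sum.
#' @param coords optional two-column matrix of (x, y) positions.
#' @param label free-text identifier.
#'
#' @return An object of class `paired_field`.
#' @examples
#' pf <- paired_field(c(0, pi / 4), c(pi / 2, 3 * pi / 4))
#' coop(pf)$coop
#' @export
paired_field <- function(p_angles, q_angles, weights = NULL, coords = NULL,
                         label = "") {
  n <- length(p_angles)
  if (n < 1L || length(q_angles) != n) {
    stop("paired_field: 'p_angles' and 'q_angles' must have equal length >= 1",
         call. = FALSE)
  }
  p_angles <- as.numeric(p_angles)
  q_angles <- as.numeric(q_angles)
  if (anyNA(p_angles) || anyNA(q_angles)) {
    stop("paired_field: angles contain NA", call. = FALSE)
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != n) {
      stop("paired_field: 'weights' must be index-aligned with the angles",
           call. = FALSE)
    }
    if (anyNA(weights) || any(weights < 0)) {
      stop("paired_field: 'weights' must be non-negative", call. = FALSE)
    }
    if (sum(weights) <= 0) {
      stop("paired_field: 'weights' must have a positive sum", call. = FALSE)
    }
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2L) {
      stop("paired_field: 'coords' must be an n x 2 matrix", call. = FALSE)
    }
    storage.mode(coords) <- "double"
    colnames(coords) <- c("x", "y")
  }
  structure(
    list(p_angles = canonical_angle(p_angles),
         q_angles = canonical_angle(q_angles),
         weights = weights, coords = coords, label = as.character(label)[1L]),
    class = "paired_field"
  )
}

#' @export
print.paired_field <- function(x, ...) {
  cat("<paired_field>", if (nzchar(x$label)) x$label else NULL, "\n")
  cat("  n =", length(x$p_angles),
      if (is.null(x$weights)) "(unweighted)" else "(weighted)", "\n")
  invisible(x)
}

#' @export
length.paired_field <- function(x) length(x$p_angles)

# Canonical representative of an axial angle in [0, pi).
canonical_angle <- function(theta) {
  out <- theta %% pi
  # (%%) can return pi for tiny negative inputs through rounding
  out[out >= pi] <- 0
  out
}
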