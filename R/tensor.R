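#' Mean nematic order tensor of an axial angle set
#'
#' Computes the 2x2 symmetric traceless mean order tensor
#' `T = 2 <k k^T> - I` of a set of unit pseudo-vectors
#' `k_i = (cos theta_i, sin theta_i)`, where `< >` is the (optionally
#' weighted) arithmetic mean. In double-angle form the independent entries
#' are `t_xx = <cos 2 theta>` and `t_xy = <sin 2 theta>`, which is how they
#' are evaluated here; the eigen-decomposition of a traceless symmetric 2x2
#' matrix is closed form: eigenvalues `+/- sqrt(t_xx^2 + t_xy^2)`, with the
#' maximal eigenvector at angle `atan2(t_xy, t_xx) / 2`.
#'
#' @param angles numeric vector of axial angles (radians, modulo pi), or an
#'   [orientation_field()].
#' @param weights optional non-negative weights with positive sum.
#'
#' @return An object of class `order_tensor`: list with `components` (2x2
#'   matrix), `max_eigenvalue`, and `director` (unit 2-vector with canonical
#'   sign: first non-zero component positive). For an exactly isotropic
#'   tensor the director is the degenerate default `(1, 0)`.
#' @examples
#' order_tensor(c(0, 0, 0))$max_eigenvalue       # 1: perfectly aligned
#' order_tensor(c(0, pi / 2))$max_eigenvalue     # 0: orthogonal pair cancels
#' @seealso [oop()]
#' @export
order_tensor <- function(angles, weights = NULL) {
  if (inherits(angles, "orientation_field")) angles <- angles$angles
  check_tensor_input(angles, weights)
  m <- tensor_moments(angles, weights)
  new_order_tensor(m[1L], m[2L])
}

# Weighted first moments <cos 2t>, <sin 2t> of the double angle.
tensor_moments <- function(angles, weights = NULL) {
  a2 <- 2 * angles
  if (is.null(weights)) {
    c(mean(cos(a2)), mean(sin(a2)))
  } else {
    sw <- sum(weights)
    c(sum(weights * cos(a2)) / sw, sum(weights * sin(a2)) / sw)
  }
}

check_tensor_input <- function(angles, weights) {
  if (length(angles) == 0L) {
    stop("order_tensor: empty angle set", call. = FALSE)
  }
  if (!is.null(weights)) {
    if (length(weights) != length(angles)) {
      stop("order_tensor: weights not index-aligned with angles", call. = FALSE)
    }
    if (any(weights < 0)) {
      stop("order_tensor: negative weights", call. = FALSE)
    }
    if (sum(weights) <= 0) {
      stop("order_tensor: weights sum to zero", call. = FALSE)
    }
  }
  invisible(NULL)
}

new_order_tensor <- function(txx, txy) {
  lambda <- sqrt(txx^2 + txy^2)
  phi <- 0.5 * atan2(txy, txx)
  structure(
    list(components = matrix(c(txx, txy, txy, -txx), 2L, 2L),
         max_eigenvalue = lambda,
         director = canonical_director(c(cos(phi), sin(phi)))),
    class = "order_tensor"
  )
}

# Sign convention: first non-zero component positive.
canonical_director <- function(d) {
  if (d[1L] < 0 || (d[1L] == 0 && d[2L] < 0)) -d else d
}

# Axial angle of a director, canonical in [0, pi).
director_angle <- function(d) canonical_angle(atan2(d[2L], d[1L]))

#' @export
print.order_tensor <- function(x, ...) {
  cat("<order_tensor>\n")
  print(round(x$components, 6))
  cat(sprintf("  max eigenvalue = %.6f, director = (%.4f, %.4f)\n",
              x$max_eigenvalue, x$director[1L], x$director[2L]))
  invisible(x)
}

#' Orientational order parameter (OOP)
#'
#' The OOP of an axial angle set is the maximum eigenvalue of its mean order
#' tensor: 0 for an isotropic field, 1 for a perfectly aligned one. The
#' associated eigenvector (the director) is the mean orientation.
#'
#' @inheritParams order_tensor
#' @return list with `oop` (in `[0, 1]`) and `director` (unit 2-vector).
#' @examples
#' oop(rep(0.7, 10))$oop            # 1
#' oop(c(-pi / 8, pi / 8))$oop      # cos(pi/4)
#' @export
oop <- function(angles, weights = NULL) {
  ot <- order_tensor(angles, weights)
  list(oop = ot$max_eigenvalue, director = ot$director)
}

#' Relative-angle field between two constructs
#'
#' For paired unit pseudo-vectors `p_i` and `q_i` the relative-angle vector
#' is `f_i = (p_i . q_i, |p_i x q_i|) = (cos(b_i - a_i), sin(b_i - a_i))`,
#' a unit vector encoding the angle between the constructs at location `i`.
#' The co-orientational order parameter is the OOP-style eigenvalue of the
#' mean order tensor of this field.
#'
#' @param p,q numeric vectors of equal length: angles (radians mod pi), or a
#'   single [paired_field()] passed as `p`.
#' @return an n x 2 matrix with columns `fx`, `fy`; every row has unit norm.
#' @examples
#' pair_field(c(0.3), c(1.0))  # (cos 0.7, sin 0.7)
#' @export
pair_field <- function(p, q = NULL) {
  if (inherits(p, "paired_field")) {
    q <- p$q_angles
    p <- p$p_angles
  }
  if (length(p) != length(q)) {
    stop("pair_field: 'p' and 'q' must have equal length", call. = FALSE)
  }
  delta <- q - p
  cbind(fx = cos(delta), fy = sin(delta))
}
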