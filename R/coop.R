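#' Co-orientational order parameter (COOP)
#'
#' Quantifies how consistently two co-localized axial fields are oriented
#' relative to each other. The relative-angle field `f_i` (see
#' [pair_field()]) is treated as a pseudo-vector field in its own right and
#' its mean order tensor eigen-decomposed: the maximal eigenvalue is the
#' COOP (0 = no orientational correlation, 1 = a fixed relative angle
#' everywhere) and the corresponding director encodes the mean
#' inter-construct angle `theta0`.
#'
#' The COOP is invariant to rotating either field by a constant, to the
#' pseudo-vector sign ambiguity (any angle replaced by angle + pi), and to
#' swapping P and Q. Alongside the raw value the result carries the two
#' analytic reference points: the uncorrelated bound
#' `COOP_u = OOP_P * OOP_Q` (statistically independent constructs) and the
#' correlated bound `COOP_c = min(OOP)/max(OOP)` (one construct equal to
#' the other plus independent noise), plus the normalized COOP and a regime
#' label (see [normalized_coop()]).
#'
#' @param pf a [paired_field()], or a numeric vector of P angles when `q`
#'   is supplied.
#' @param q optional numeric vector of Q angles (radians mod pi).
#' @param weights optional non-negative weights applied to every tensor
#'   average (P, Q and relative-angle field alike).
#'
#' @return An object of class `coop_result`: list with elements `coop`,
#'   `director`, `theta0`, `oop_p`, `oop_q`, `coop_u`, `coop_c`,
#'   `normalized_coop` (`NA` when the normal range degenerates), `regime`
#'   (one of `"anti-correlated"`, `"normal"`, `"ultra-correlated"`,
#'   `"degenerate"`), and `n`.
#' @examples
#' a <- runif(500, 0, pi)
#' coop(a, a)$coop                     # 1: any field vs itself
#' coop(a, a + 0.9)$theta0             # recovers the constant offset
#' @seealso [coop_uncorrelated()], [coop_correlated()], [normalized_coop()]
#' @export
coop <- function(pf, q = NULL, weights = NULL) {
  if (!inherits(pf, "paired_field")) {
    pf <- paired_field(pf, q, weights = weights)
  }
  w <- pf$weights
  delta <- pf$q_angles - pf$p_angles
  m <- tensor_moments(delta, w)
  ot <- new_order_tensor(m[1L], m[2L])

  oop_p <- order_tensor(pf$p_angles, w)$max_eigenvalue
  oop_q <- order_tensor(pf$q_angles, w)$max_eigenvalue
  cu <- coop_uncorrelated(oop_p, oop_q)
  cc <- coop_correlated(oop_p, oop_q)
  nc <- normalized_coop(ot$max_eigenvalue, cu, cc)

  structure(
    list(coop = ot$max_eigenvalue,
         director = ot$director,
         theta0 = director_to_angle(ot$director),
         oop_p = oop_p, oop_q = oop_q,
         coop_u = cu, coop_c = cc,
         normalized_coop = nc,
         regime = classify_regime(ot$max_eigenvalue, cu, cc),
         n = length(pf$p_angles)),
    class = "coop_result"
  )
}

#' @export
print.coop_result <- function(x, ...) {
  cat("<coop_result>  n =", x$n, "\n")
  cat(sprintf("  COOP = %.4f   (COOP_u = %.4f, COOP_c = %.4f)\n",
              x$coop, x$coop_u, x$coop_c))
  cat(sprintf("  OOP_P = %.4f, OOP_Q = %.4f\n", x$oop_p, x$oop_q))
  cat(sprintf("  theta0 = %.4f rad (%.1f deg)\n", x$theta0,
              x$theta0 * 180 / pi))
  cat(sprintf("  normalized COOP = %s, regime: %s\n",
              if (is.na(x$normalized_coop)) "undefined"
              else sprintf("%.4f", x$normalized_coop),
              x$regime))
  invisible(x)
}

#' Uncorrelated COOP bound
#'
#' The COOP attained by two statistically independent constructs:
#' `COOP_u = OOP_P * OOP_Q`. A COOP below this value indicates
#' anti-correlation (a spatially structured mixture of correlation modes).
#'
#' @param oop_p,oop_q orientational order parameters in `[0, 1]`.
#' @return numeric in `[0, 1]`.
#' @examples
#' coop_uncorrelated(0.6, 0.6)  # 0.36
#' @export
coop_uncorrelated <- function(oop_p, oop_q) {
  check_unit_interval(oop_p, "oop_p")
  check_unit_interval(oop_q, "oop_q")
  oop_p * oop_q
}

#' Correlated COOP bound
#'
#' The COOP attained when the less organized construct equals the better
#' organized one plus independent random noise:
#' `COOP_c = min(OOP_P, OOP_Q) / max(OOP_P, OOP_Q)`. A COOP above this
#' value indicates ultra-correlation (a non-random, e.g. rank-matched,
#' pairing of angles). At `OOP_P = OOP_Q = 0` the bound is 1 by convention
#' (the normal range is the full `[0, 1]`); when exactly one OOP is zero it
#' is 0 (the normal range vanishes).
#'
#' @inheritParams coop_uncorrelated
#' @return numeric in `[0, 1]`, symmetric in its arguments.
#' @examples
#' coop_correlated(0.8, 0.4)  # 0.5
#' @export
coop_correlated <- function(oop_p, oop_q) {
  check_unit_interval(oop_p, "oop_p")
  check_unit_interval(oop_q, "oop_q")
  hi <- max(oop_p, oop_q)
  if (hi == 0) return(1)
  min(oop_p, oop_q) / hi
}

#' Normalized COOP
#'
#' Positions the COOP relative to its analytic bounds:
#' `(COOP - COOP_u) / (COOP_c - COOP_u)`. Negative values are
#' anti-correlated, 0 is uncorrelated, 1 is correlated, values above 1 are
#' ultra-correlated. When the two bounds coincide within `tol` the normal
#' range has vanished and the normalization is undefined: `NA` is returned
#' rather than a division blow-up.
#'
#' @param coop COOP value in `[0, 1]`.
#' @param coop_u,coop_c the bounds, in `[0, 1]`.
#' @param tol width below which the normal range is treated as degenerate.
#' @return numeric, or `NA_real_` when `coop_c - coop_u < tol`.
#' @examples
#' normalized_coop(0, 0.25, 0.5)  # -1: anti-correlated
#' @export
normalized_coop <- function(coop, coop_u, coop_c, tol = 1e-9) {
  check_unit_interval(coop, "coop")
  check_unit_interval(coop_u, "coop_u")
  check_unit_interval(coop_c, "coop_c")
  if (abs(coop_c - coop_u) < tol) return(NA_real_)
  (coop - coop_u) / (coop_c - coop_u)
}

#' Classify the correlation regime of a COOP value
#'
#' Compares a COOP against its bounds: below `coop_u` is
#' `"anti-correlated"`, above `coop_c` is `"ultra-correlated"`, in between
#' is `"normal"`. When the bounds coincide (no normal range, e.g. both
#' constructs perfectly aligned or exactly one isotropic) the regime is
#' `"degenerate"`. Comparisons use a fixed tolerance since the framework
#' itself defines the regimes only by position relative to the bounds.
#'
#' @inheritParams normalized_coop
#' @param tol comparison tolerance against the bounds.
#' @param degenerate_tol bound-coincidence width treated as degenerate.
#' @return character scalar.
#' @export
classify_regime <- function(coop, coop_u, coop_c, tol = 1e-6,
                            degenerate_tol = 1e-9) {
  if (abs(coop_c - coop_u) < degenerate_tol) return("degenerate")
  if (coop < coop_u - tol) return("anti-correlated")
  if (coop > coop_c + tol) return("ultra-correlated")
  "normal"
}

#' Convert a COOP director to a mean inter-construct angle
#'
#' A director determines an angle only up to the four-fold pseudo-vector
#' ambiguity `{theta0, -theta0, pi - theta0, theta0 - pi}`. The branch is
#' chosen from a reference director (by default the director itself; for
#' multi-sample statistics the director-of-directors): when the reference
#' points within pi/4 of the vertical the arccos branch is used, reporting
#' in `[0, pi)`; otherwise the arcsin branch, reporting in
#' `[-pi/2, pi/2]`. Centering the reported range on the reference prevents
#' wrap-around artifacts when averaging angles across samples (e.g. -5 and
#' +5 degrees never average through 90).
#'
#' The sign convention matches mathematical axes (y up, counter-clockwise
#' positive); under raster image axes (y down) the same number reads as the
#' clockwise angle from P to Q.
#'
#' @param director unit 2-vector (eigenvector of a mean order tensor).
#' @param reference optional unit 2-vector fixing the branch choice.
#' @return angle in radians.
#' @examples
#' director_to_angle(c(0, 1))            # pi/2: perpendicular constructs
#' director_to_angle(c(cos(.3), sin(.3)))  # 0.3
#' @export
director_to_angle <- function(director, reference = NULL) {
  check_unit_vector(director, "director")
  if (is.null(reference)) {
    reference <- director
  } else {
    check_unit_vector(reference, "reference")
  }
  clamp <- function(x) min(1, max(-1, x))
  if (abs(reference[1L]) < cos(pi / 4)) {
    # arccos branch: reference near vertical; report in [0, pi)
    if (director[2L] < 0) director <- -director
    acos(clamp(director[1L]))
  } else {
    # arcsin branch: reference near horizontal; report in [-pi/2, pi/2]
    if (director[1L] < 0) director <- -director
    asin(clamp(director[2L]))
  }
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x < -1e-12 || x > 1 + 1e-12) {
    stop(sprintf("'%s' must be a number in [0, 1]", name), call. = FALSE)
  }
  invisible(NULL)
}

check_unit_vector <- function(v, name, tol = 1e-8) {
  if (!is.numeric(v) || length(v) != 2L || anyNA(v) ||
      abs(sum(v^2) - 1) > tol) {
    stop(sprintf("'%s' must be a unit 2-vector", name), call. = FALSE)
  }
  invisible(NULL)
}
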