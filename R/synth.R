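#' Synthetic orientation fields
#'
#' Seeded generators for the validation regimes of the framework: perfectly
#' aligned and isotropic fields, truncated-Gaussian angle distributions of
#' chosen width, independent and noise-coupled pairs bracketing the COOP
#' between its analytic bounds, and the exact anti-correlated and
#' ultra-correlated constructions that fall outside them.
#'
#' All generators restore the caller's RNG state, so a fixed `seed` gives
#' bit-identical output regardless of surrounding code.
#'
#' @name synthetic-fields
NULL

# Evaluate expr under a local, seeded RNG without disturbing the caller's
# stream. seed = NULL uses (and advances) the global stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Perfectly aligned field
#'
#' Every angle identical; OOP is exactly 1.
#'
#' @param n number of angles.
#' @param angle the common orientation (radians mod pi).
#' @return an [orientation_field()].
#' @export
gen_aligned <- function(n, angle = 0) {
  if (n < 1) stop("gen_aligned: n must be >= 1", call. = FALSE)
  orientation_field(rep(canonical_angle(angle), n), label = "aligned")
}

#' Isotropic field
#'
#' Angles i.i.d. uniform on `[0, pi)`; the expected OOP decays as
#' `O(1/sqrt(n))`.
#'
#' @param n number of angles.
#' @param seed optional integer seed.
#' @return an [orientation_field()].
#' @export
gen_isotropic <- function(n, seed = NULL) {
  if (n < 1) stop("gen_isotropic: n must be >= 1", call. = FALSE)
  a <- with_local_seed(seed, stats::runif(n, 0, pi))
  orientation_field(a, label = "isotropic")
}

#' Truncated-Gaussian field
#'
#' Angles i.i.d. from a Gaussian truncated to `mean +/- half_width` and
#' wrapped into `[0, pi)`. With the default half-width of pi/2 the support
#' covers exactly one axial period, making the sample a proper axial
#' density for any sigma; `sigma -> 0` degenerates to an aligned field and
#' large sigma approaches isotropy. Sampling is by inverse-CDF, so a draw
#' of size n consumes exactly n uniforms.
#'
#' @param n sample count.
#' @param mean center of the distribution (radians).
#' @param sigma positive standard deviation of the parent Gaussian
#'   (radians).
#' @param half_width truncation half-width in `(0, pi/2]`.
#' @param seed optional integer seed.
#' @return an [orientation_field()].
#' @export
gen_truncated_gaussian <- function(n, mean = pi / 2, sigma, half_width = pi / 2,
                                   seed = NULL) {
  if (n < 1) stop("gen_truncated_gaussian: n must be >= 1", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("gen_truncated_gaussian: sigma must be positive", call. = FALSE)
  }
  if (half_width <= 0 || half_width > pi / 2) {
    stop("gen_truncated_gaussian: half_width must lie in (0, pi/2]",
         call. = FALSE)
  }
  a <- with_local_seed(seed, rtruncnorm(n, mean, sigma, half_width))
  orientation_field(a, label = sprintf("truncated-gaussian(sigma=%.3g)", sigma))
}

# Inverse-CDF draw from N(mean, sigma) truncated to mean +/- half_width.
rtruncnorm <- function(n, mean, sigma, half_width) {
  plo <- stats::pnorm(-half_width / sigma)
  u <- stats::runif(n, plo, 1 - plo)
  mean + sigma * stats::qnorm(u)
}

#' Independent (uncorrelated) pair of truncated-Gaussian fields
#'
#' P and Q are drawn independently, each from its own truncated-Gaussian
#' specification, so as `n` grows the COOP converges to the uncorrelated
#' bound `OOP_P * OOP_Q`.
#'
#' @param n pair count.
#' @param sigma_p,sigma_q widths of the two distributions (radians);
#'   `Inf` gives an isotropic construct.
#' @param mean_p,mean_q centers.
#' @param half_width truncation half-width shared by both.
#' @param seed optional integer seed.
#' @return a [paired_field()].
#' @export
gen_uncorrelated_pair <- function(n, sigma_p, sigma_q, mean_p = pi / 2,
                                  mean_q = pi / 2, half_width = pi / 2,
                                  seed = NULL) {
  if (n < 1) stop("gen_uncorrelated_pair: n must be >= 1", call. = FALSE)
  with_local_seed(seed, {
    p <- draw_construct(n, mean_p, sigma_p, half_width)
    q <- draw_construct(n, mean_q, sigma_q, half_width)
    paired_field(p, q, label = "uncorrelated-pair")
  })
}

draw_construct <- function(n, mean, sigma, half_width) {
  if (is.infinite(sigma)) {
    stats::runif(n, 0, pi)
  } else if (sigma <= 0) {
    rep(mean, n)
  } else {
    rtruncnorm(n, mean, sigma, half_width)
  }
}

#' Noise-coupled (correlated) pair
#'
#' Q is P plus independent truncated-Gaussian noise whose width is
#' calibrated so that Q's orientational order hits `target_oop_q`. This is
#' the maximally correlated arrangement subject to random noise, so as `n`
#' grows the COOP converges to the correlated bound
#' `min(OOP)/max(OOP) = OOP_Q / OOP_P`.
#'
#' Because the order parameter of a sum of independent symmetric angular
#' variables factorizes, the noise width is found by bisection on the
#' empirical OOP of zero-centered noise (20 iterations on a fixed-seed
#' calibration sample of 1e5 draws), targeting `target_oop_q / OOP_P`.
#'
#' @param n pair count.
#' @param sigma_p width of construct P (radians); `Inf` for isotropic.
#' @param target_oop_q desired empirical OOP of Q; must not exceed the
#'   OOP of P (P is the better-organized construct).
#' @param mean_p center of P.
#' @param half_width truncation half-width for P and the noise.
#' @param seed optional integer seed.
#' @param calibration_n,calibration_seed size and seed of the calibration
#'   sample used in the noise-width bisection.
#' @return a [paired_field()]; attribute `"noise_sigma"` records the
#'   calibrated width (0 when `target_oop_q` equals P's order).
#' @export
gen_correlated_pair <- function(n, sigma_p, target_oop_q, mean_p = pi / 2,
                                half_width = pi / 2, seed = NULL,
                                calibration_n = 1e5, calibration_seed = 719) {
  if (n < 1) stop("gen_correlated_pair: n must be >= 1", call. = FALSE)
  check_unit_interval(target_oop_q, "target_oop_q")
  with_local_seed(seed, {
    p <- draw_construct(n, mean_p, sigma_p, half_width)
    oop_p <- oop(p)$oop
    if (target_oop_q > oop_p + 1e-9) {
      stop(sprintf(paste0("gen_correlated_pair: infeasible target: ",
                          "target_oop_q = %.4f exceeds OOP_P = %.4f"),
                   target_oop_q, oop_p), call. = FALSE)
    }
    target_noise_oop <- min(1, target_oop_q / oop_p)
    ns <- calibrate_noise_sigma(target_noise_oop, half_width,
                                calibration_n, calibration_seed)
    noise <- if (ns == 0) rep(0, n) else rtruncnorm(n, 0, ns, half_width)
    pf <- paired_field(p, p + noise, label = "correlated-pair")
    attr(pf, "noise_sigma") <- ns
    pf
  })
}

# Bisection on the empirical OOP of truncated-Gaussian noise, which is
# monotone decreasing in the noise width.
calibrate_noise_sigma <- function(target_oop, half_width, calibration_n,
                                  calibration_seed) {
  if (target_oop >= 1 - 1e-12) return(0)
  emp_oop <- function(s) {
    a <- with_local_seed(calibration_seed,
                         rtruncnorm(calibration_n, 0, s, half_width))
    oop(a)$oop
  }
  lo <- 1e-4
  hi <- 10
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    if (emp_oop(mid) > target_oop) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Anti-correlated two-pair construction
#'
#' The exact construction showing the COOP can fall below the uncorrelated
#' bound: half the pairs are `(alpha, alpha + pi/2)` and half are
#' `(-alpha, -alpha)`. The relative-angle vectors of the two pair types
#' cancel, so the mean tensor is exactly zero and COOP = 0, while
#' `OOP_P = cos(2 alpha)`, `OOP_Q = |sin(2 alpha)|` and so
#' `COOP_u = |cos(2 alpha) sin(2 alpha)| > 0` for generic alpha. Multiples
#' of pi/4 make `COOP_u` zero too and the construction degenerate (a
#' warning is issued).
#'
#' @param alpha construction angle (radians).
#' @param n total pair count (must be even; n/2 of each type).
#' @return a [paired_field()].
#' @examples
#' r <- coop(gen_anticorrelated_pair(pi / 8))
#' c(r$coop, r$coop_u)  # 0 and 0.5
#' @export
gen_anticorrelated_pair <- function(alpha, n = 2) {
  if (n < 2 || n %% 2 != 0) {
    stop("gen_anticorrelated_pair: n must be even and >= 2", call. = FALSE)
  }
  if (abs(sin(4 * alpha)) < 1e-12) {
    warning(paste("gen_anticorrelated_pair: alpha is a multiple of pi/4;",
                  "the construction is degenerate (COOP_u = 0 as well)"),
            call. = FALSE)
  }
  h <- n / 2L
  p <- c(rep(alpha, h), rep(-alpha, h))
  q <- c(rep(alpha + pi / 2, h), rep(-alpha, h))
  paired_field(p, q, label = "anti-correlated")
}

#' Ultra-correlated mirrored construction
#'
#' The exact construction showing the COOP can exceed the correlated
#' bound: for each `alpha_i` the pairs `(alpha_i, alpha_i + theta)` and
#' `(-alpha_i, -alpha_i - theta)` are included, i.e. the two fields are
#' matched in sorted order rather than randomly within the noise. Under
#' the admissibility conditions (`alpha_i`, `theta` in `[0, pi/2]`,
#' `sum cos(2 alpha_i) >= 0`, `sum cos(2 alpha_i + 2 theta) >= 0`, and
#' `cos(2 theta) >= 0`) every term of `COOP - COOP_c` is non-negative, with
#' strict excess whenever some `alpha_i != 0` and `theta != 0`.
#'
#' @param alphas numeric vector of half-spread angles in `[0, pi/2]`.
#' @param theta constant offset in `[0, pi/2]`.
#' @return a [paired_field()] of `2 * length(alphas)` pairs.
#' @examples
#' r <- coop(gen_ultracorrelated_pair(pi / 8, pi / 8))
#' r$coop > r$coop_c
#' @export
gen_ultracorrelated_pair <- function(alphas, theta) {
  if (length(alphas) < 1L) {
    stop("gen_ultracorrelated_pair: need at least one alpha", call. = FALSE)
  }
  if (any(alphas < 0 | alphas > pi / 2)) {
    stop("gen_ultracorrelated_pair: alphas must lie in [0, pi/2]",
         call. = FALSE)
  }
  if (theta < 0 || theta > pi / 2) {
    stop("gen_ultracorrelated_pair: theta must lie in [0, pi/2]",
         call. = FALSE)
  }
  if (sum(cos(2 * alphas)) < 0) {
    stop("gen_ultracorrelated_pair: sum(cos(2 alpha)) must be >= 0",
         call. = FALSE)
  }
  if (sum(cos(2 * alphas + 2 * theta)) < 0) {
    stop("gen_ultracorrelated_pair: sum(cos(2 alpha + 2 theta)) must be >= 0",
         call. = FALSE)
  }
  if (cos(2 * theta) < 0) {
    stop("gen_ultracorrelated_pair: cos(2 theta) must be >= 0",
         call. = FALSE)
  }
  p <- c(alphas, -alphas)
  q <- c(alphas + theta, -alphas - theta)
  paired_field(p, q, label = "ultra-correlated")
}
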