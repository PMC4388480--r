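#' Propagated standard deviation of the uncorrelated COOP bound
#'
#' First-order (delta-method) error propagation through
#' `COOP_u = OOP_P * OOP_Q` for independent, normally distributed OOP
#' estimates: `sigma_COOP_u = sqrt(OOP_Q^2 s_P^2 + OOP_P^2 s_Q^2)`.
#'
#' @param oop_p,oop_q orientational order parameters in `[0, 1]`.
#' @param sigma_p,sigma_q non-negative standard deviations of the OOP
#'   estimates.
#' @return non-negative numeric.
#' @examples
#' sigma_coop_u(0.6, 0.6, 0.04, 0.04)  # 0.6 * 0.04 * sqrt(2)
#' @export
sigma_coop_u <- function(oop_p, oop_q, sigma_p, sigma_q) {
  check_unit_interval(oop_p, "oop_p")
  check_unit_interval(oop_q, "oop_q")
  check_nonneg(sigma_p, "sigma_p")
  check_nonneg(sigma_q, "sigma_q")
  sqrt(oop_q^2 * sigma_p^2 + oop_p^2 * sigma_q^2)
}

#' Propagated standard deviation of the correlated COOP bound
#'
#' Delta-method propagation through `COOP_c = min(OOP)/max(OOP)`, applying
#' the branch with the larger OOP in the denominator:
#' for `OOP_P > OOP_Q`,
#' `sigma_COOP_c = sqrt((OOP_Q / OOP_P^2)^2 s_P^2 + (1 / OOP_P)^2 s_Q^2)`,
#' and symmetrically otherwise. The derivative does not exist at
#' `OOP_P = OOP_Q`, but both branch formulas coincide there by the P/Q
#' symmetry of the parameter, and that common value is used as the
#' estimate. Both OOPs zero has no defined derivative at all and errors.
#'
#' @inheritParams sigma_coop_u
#' @return non-negative numeric.
#' @examples
#' sigma_coop_c(1, 0.5, 0, 0.1)  # 0.1
#' @export
sigma_coop_c <- function(oop_p, oop_q, sigma_p, sigma_q) {
  check_unit_interval(oop_p, "oop_p")
  check_unit_interval(oop_q, "oop_q")
  check_nonneg(sigma_p, "sigma_p")
  check_nonneg(sigma_q, "sigma_q")
  if (max(oop_p, oop_q) == 0) {
    stop("sigma_coop_c: undefined when both OOPs are zero", call. = FALSE)
  }
  if (oop_p >= oop_q) {
    sqrt((oop_q / oop_p^2)^2 * sigma_p^2 + (1 / oop_p)^2 * sigma_q^2)
  } else {
    sqrt((1 / oop_q)^2 * sigma_p^2 + (oop_p / oop_q^2)^2 * sigma_q^2)
  }
}

#' Welch t-test separating the COOP bounds
#'
#' Tests the null hypothesis `COOP_u = COOP_c` for a study measuring both
#' OOPs with a common per-estimate error `sigma_oop` and per-group sample
#' size `n`. Group standard deviations come from [sigma_coop_u()] and
#' [sigma_coop_c()]; the statistic is the two-sample Welch t with
#' Satterthwaite degrees of freedom and a two-tailed p-value. Rejection
#' means the study can tell an uncorrelated arrangement from a correlated
#' one at the given error level.
#'
#' @param oop_p,oop_q orientational order parameters in `[0, 1]`.
#' @param sigma_oop positive common standard deviation of each OOP estimate.
#' @param n per-group sample size, `>= 2`.
#' @return list with `t_value`, `dof`, `p_value`, `coop_u`, `coop_c`.
#' @examples
#' bound_separation_test(0.6, 0.6, 0.18, 4)$p_value  # ~0.05
#' @export
bound_separation_test <- function(oop_p, oop_q, sigma_oop, n) {
  check_unit_interval(oop_p, "oop_p")
  check_unit_interval(oop_q, "oop_q")
  if (!is.numeric(sigma_oop) || sigma_oop <= 0) {
    stop("bound_separation_test: 'sigma_oop' must be positive", call. = FALSE)
  }
  if (n < 2) {
    stop("bound_separation_test: 'n' must be >= 2", call. = FALSE)
  }
  cu <- coop_uncorrelated(oop_p, oop_q)
  cc <- coop_correlated(oop_p, oop_q)
  s <- welch_stat(oop_p, oop_q, sigma_oop, n)
  list(t_value = s$t, dof = s$df, p_value = s$p, coop_u = cu, coop_c = cc)
}

# Vectorized Welch machinery over (oop_p, oop_q, sigma, n); the backbone of
# the power surfaces. Undefined cells (both OOPs zero) propagate NA.
welch_stat <- function(op, oq, sigma, n) {
  cu <- op * oq
  hi <- pmax(op, oq)
  lo <- pmin(op, oq)
  cc <- ifelse(hi == 0, 1, lo / hi)
  su2 <- (oq^2 + op^2) * sigma^2
  sc2 <- ifelse(hi == 0, NA_real_,
                ((lo / hi^2)^2 + (1 / hi)^2) * sigma^2)
  se2 <- (su2 + sc2) / n
  t <- (cc - cu) / sqrt(se2)
  df <- se2^2 / (((su2 / n)^2 + (sc2 / n)^2) / (n - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, cu = cu, cc = cc)
}

#' Maximum tolerable OOP error for distinguishing the COOP bounds
#'
#' The largest per-estimate OOP standard deviation `sigma_oop` at which
#' [bound_separation_test()] still rejects `COOP_u = COOP_c` at level
#' `alpha` with per-group size `n`. Found by bisection (the p-value is
#' monotone increasing in `sigma_oop`). Returns 0 when the bounds coincide
#' (no error level separates them) and `NA` where the correlated-bound
#' error is undefined (both OOPs exactly zero). Vectorized over
#' `oop_p`/`oop_q`.
#'
#' @inheritParams bound_separation_test
#' @param alpha significance level, default 0.05.
#' @param tol absolute bisection tolerance on sigma.
#' @return numeric vector of sigma values (bisection bracket `[1e-6, 2]`).
#' @examples
#' round(max_tolerable_error(0.6, 0.6, n = 4), 2)  # 0.18
#' @export
max_tolerable_error <- function(oop_p, oop_q, n = 4, alpha = 0.05,
                                tol = 1e-4) {
  k <- max(length(oop_p), length(oop_q))
  op <- rep_len(as.numeric(oop_p), k)
  oq <- rep_len(as.numeric(oop_q), k)
  if (any(op < 0 | op > 1 | oq < 0 | oq > 1)) {
    stop("max_tolerable_error: OOPs must lie in [0, 1]", call. = FALSE)
  }
  lo <- rep(1e-6, k)
  hi <- rep(2, k)
  iters <- ceiling(log2((2 - 1e-6) / tol))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    p <- welch_stat(op, oq, mid, n)$p
    reject <- !is.na(p) & p < alpha
    lo[reject] <- mid[reject]
    hi[!reject] <- mid[!reject]
  }
  sep <- ifelse(pmax(op, oq) == 0, 1, pmin(op, oq) / pmax(op, oq)) - op * oq
  out <- lo
  out[sep <= 1e-12] <- 0          # bounds coincide: nothing to separate
  out[op == 0 & oq == 0] <- NA_real_  # sigma_coop_c undefined
  out
}

#' Minimum sample size for distinguishing the COOP bounds
#'
#' The smallest per-group `n >= 2` at which [bound_separation_test()]
#' rejects at level `alpha` for the given OOP error. Because the Welch
#' statistic grows as `sqrt(n)`, the search doubles `n` until significance
#' then bisects to the smallest such integer. Returns `Inf` when the
#' bounds coincide or no `n` up to `cap` achieves significance, and `NA`
#' when the test is undefined (both OOPs zero). Vectorized over
#' `oop_p`/`oop_q`.
#'
#' @inheritParams max_tolerable_error
#' @param sigma_oop positive common standard deviation of each OOP estimate.
#' @param cap largest sample size searched before declaring `Inf`.
#' @return numeric vector: integers, `Inf`, or `NA`.
#' @examples
#' min_sample_size(0.6, 0.6, sigma_oop = 0.04)  # 2
#' @export
min_sample_size <- function(oop_p, oop_q, sigma_oop, alpha = 0.05,
                            cap = 1e6) {
  if (!is.numeric(sigma_oop) || length(sigma_oop) != 1L || sigma_oop <= 0) {
    stop("min_sample_size: 'sigma_oop' must be a positive number",
         call. = FALSE)
  }
  k <- max(length(oop_p), length(oop_q))
  op <- rep_len(as.numeric(oop_p), k)
  oq <- rep_len(as.numeric(oop_q), k)
  if (any(op < 0 | op > 1 | oq < 0 | oq > 1)) {
    stop("min_sample_size: OOPs must lie in [0, 1]", call. = FALSE)
  }
  rejects <- function(idx, n) {
    p <- welch_stat(op[idx], oq[idx], sigma_oop, n)$p
    !is.na(p) & p < alpha
  }
  undef <- op == 0 & oq == 0
  sep <- ifelse(pmax(op, oq) == 0, 1, pmin(op, oq) / pmax(op, oq)) - op * oq
  hopeless <- sep <= 1e-12
  # doubling phase: bracket the smallest significant n in (lo, hi]
  lo <- rep(1, k)           # exclusive floor (n = 1 is never a valid size)
  hi <- rep(NA_real_, k)
  done <- rep(FALSE, k)
  r <- rejects(seq_len(k), 2)
  done[r] <- TRUE
  hi[r] <- 2
  cur <- 2
  while (cur < cap && any(active <- !done & !undef & !hopeless)) {
    nxt <- min(cur * 2, cap)
    idx <- which(active)
    lo[idx] <- cur
    r <- rejects(idx, nxt)
    done[idx[r]] <- TRUE
    hi[idx[r]] <- nxt
    cur <- nxt
  }
  # integer bisection inside each bracket
  while (any(need <- done & (hi - lo > 1))) {
    idx <- which(need)
    mid <- floor((lo[idx] + hi[idx]) / 2)
    r <- rejects(idx, mid)
    hi[idx[r]] <- mid[r]
    lo[idx[!r]] <- mid[!r]
  }
  out <- ifelse(done, hi, Inf)
  out[undef] <- NA_real_
  out
}

#' Power surfaces over an OOP grid
#'
#' Tabulates [max_tolerable_error()] (at fixed `n`) and [min_sample_size()]
#' (at fixed `sigma_oop`) over a square grid of `(OOP_P, OOP_Q)` values.
#'
#' @param spacing grid spacing in OOP units (grid runs `spacing` to
#'   `1 - spacing`; the corner `OOP_P = OOP_Q = 0` has no defined test).
#' @param n per-group sample size for the max-error surface.
#' @param sigma_oop OOP error for the min-sample-size surface.
#' @param alpha significance level.
#' @return data.frame with columns `oop_p`, `oop_q`, `max_sigma`, `min_n`.
#' @examples
#' s <- power_surface(spacing = 0.2)
#' s[which.max(s$max_sigma), ]
#' @export
power_surface <- function(spacing = 0.01, n = 4, sigma_oop = 0.04,
                          alpha = 0.05) {
  if (spacing <= 0 || spacing >= 1) {
    stop("power_surface: 'spacing' must lie in (0, 1)", call. = FALSE)
  }
  g <- seq(spacing, 1 - spacing, by = spacing)
  grid <- expand.grid(oop_p = g, oop_q = g, KEEP.OUT.ATTRS = FALSE)
  grid$max_sigma <- max_tolerable_error(grid$oop_p, grid$oop_q,
                                        n = n, alpha = alpha)
  grid$min_n <- min_sample_size(grid$oop_p, grid$oop_q,
                                sigma_oop = sigma_oop, alpha = alpha)
  grid
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a non-negative number", name), call. = FALSE)
  }
  invisible(NULL)
}
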