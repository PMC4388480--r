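# Shared fixtures: small random fields and an independent brute-force
# order-tensor oracle built from explicit outer products + eigen().

random_angles <- function(n) stats::runif(n, -pi, pi)

# Independent oracle: T = 2 <k k^T> - I via explicit outer products,
# eigen-decomposed numerically. Never uses the package's closed form.
brute_force_tensor <- function(angles, weights = NULL) {
  k <- cbind(cos(angles), sin(angles))
  if (is.null(weights)) weights <- rep(1, length(angles))
  w <- weights / sum(weights)
  m <- matrix(0, 2, 2)
  for (i in seq_along(angles)) {
    m <- m + w[i] * (k[i, ] %o% k[i, ])
  }
  t_mat <- 2 * m - diag(2)
  e <- eigen(t_mat, symmetric = TRUE)
  list(tensor = t_mat, max_eigenvalue = e$values[1L],
       director = e$vectors[, 1L])
}

# Brute-force COOP: build f vectors explicitly from pseudo-vector algebra
# (dot and cross products), then eigen-decompose their mean tensor.
brute_force_coop <- function(p, q, weights = NULL) {
  px <- cos(p); py <- sin(p)
  qx <- cos(q); qy <- sin(q)
  fx <- px * qx + py * qy
  fy <- px * qy - py * qx
  f_angles <- atan2(fy, fx)
  brute_force_tensor(f_angles, weights)$max_eigenvalue
}

# Smallest distance between two axial angles (period pi).
axial_dist <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

# A gridded orientation field: one angle per integer pixel of a w x h
# raster, angles supplied by `angle_fun(x, y)`.
raster_field <- function(w, h, angle_fun, label = "") {
  g <- expand.grid(x = seq_len(w) - 1L, y = seq_len(h) - 1L)
  orientation_field(angle_fun(g$x, g$y), coords = cbind(g$x, g$y),
                    label = label)
}
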