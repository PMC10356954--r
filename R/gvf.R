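# Reflective-padding separable Gaussian smoothing.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  R <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-R:R, sd = sigma)
  k <- k / sum(k)
  reflect <- function(n) c((R + 1):2, 1:n, (n - 1):(n - R))
  conv_rows <- function(m) {
    p <- m[reflect(nrow(m)), , drop = FALSE]
    out <- 0
    for (j in seq_along(k)) out <- out + k[j] * p[j:(j + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

# Central differences with replicated edges; x along columns, y along rows.
grad_xy <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xr <- m[, c(2:nc, nc), drop = FALSE]; xl <- m[, c(1, 1:(nc - 1)), drop = FALSE]
  yd <- m[c(2:nr, nr), , drop = FALSE]; yu <- m[c(1, 1:(nr - 1)), , drop = FALSE]
  list(x = (xr - xl) / 2, y = (yd - yu) / 2)
}

# 5-point Laplacian, replicated (zero-flux) boundaries.
laplacian5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(2:nr, nr), ] + m[c(1, 1:(nr - 1)), ] +
    m[, c(2:nc, nc)] + m[, c(1, 1:(nc - 1))] - 4 * m
}

#' Gradient-of-Gaussian edge map
#'
#' `f(x, y) = |grad(G_sigma * I)|`: the image is smoothed with a Gaussian of
#' scale `sigma_px` (reflective boundaries) and the gradient magnitude
#' taken. The map is normalised to `[0, 1]` so the GVF regularisation
#' weight `mu` has a consistent meaning across images.
#'
#' @param image A [ct_image] or numeric matrix.
#' @param sigma_px Gaussian scale in pixels (> 0).
#' @param normalize Scale the map so its maximum is 1 (default TRUE).
#' @return An object of class `edge_map`: list with `values`, `sigma_px`.
#' @export
edge_map <- function(image, sigma_px = 1.5, normalize = TRUE) {
  if (sigma_px <= 0) mar_abort("sigma_px must be > 0", "bad_input")
  px <- if (inherits(image, "ct_image")) image$pixels else image
  g <- grad_xy(gauss_smooth(px, sigma_px))
  f <- sqrt(g$x^2 + g$y^2)
  if (normalize && max(f) > 0) f <- f / max(f)
  structure(list(values = f, sigma_px = sigma_px), class = "edge_map")
}

# Monotone stability bound of the explicit update: the diffusion term
# contributes 4*mu per unit step and the reaction term up to max(|grad f|^2).
gvf_dt_bound <- function(mu, bmax = 0) 1 / (4 * mu + bmax)

#' Gradient vector flow field
#'
#' Diffuses the edge-map gradient into a dense external-force field
#' `vf = (u, v)` by explicit time-stepping of the Euler-Lagrange equations
#' of the GVF energy: `du/dt = mu lap(u) - |grad f|^2 (u - f_x)` (and
#' likewise for `v` with `f_y`), with a 5-point Laplacian and zero-flux
#' boundaries. The field is initialised at `(f_x, f_y)`. On the unit pixel
#' grid the explicit scheme is monotone-stable for
#' `dt <= 1 / (4 mu + max |grad f|^2)`; a `dt` above the bound is refused
#' rather than allowed to diverge.
#'
#' @param edge An [edge_map].
#' @param mu Regularisation weight (> 0): larger values give a smoother,
#'   farther-reaching field.
#' @param n_iter Maximum number of iterations.
#' @param dt Time step; default 0.9 times the stability bound.
#' @param tol Stop early when the maximum PDE residual
#'   `|mu lap(u) - |grad f|^2 (u - f_x)|` falls below `tol` (set 0 to run
#'   all `n_iter` steps).
#' @return An object of class `vector_field`: list with `u`, `v`, `mu`,
#'   `iterations` (performed), `dt`, `residual` (final max PDE residual).
#' @export
gvf <- function(edge, mu = 0.2, n_iter = 200, dt = NULL, tol = 1e-6) {
  if (!inherits(edge, "edge_map")) mar_abort("`edge` must be an edge_map", "bad_input")
  if (mu <= 0) mar_abort("mu must be > 0", "bad_input")
  g <- grad_xy(edge$values)
  fx <- g$x; fy <- g$y
  b <- fx^2 + fy^2
  bound <- gvf_dt_bound(mu, max(b))
  if (is.null(dt)) dt <- 0.9 * bound
  if (dt > bound) {
    mar_abort(sprintf(
      "dt = %g exceeds the explicit-scheme stability bound 1/(4 mu + max|grad f|^2) = %g",
      dt, bound), "unstable_dt")
  }
  u <- fx; v <- fy
  res <- Inf; it <- 0L
  while (it < n_iter) {
    ru <- mu * laplacian5(u) - b * (u - fx)
    rv <- mu * laplacian5(v) - b * (v - fy)
    u <- u + dt * ru
    v <- v + dt * rv
    it <- it + 1L
    res <- max(max(abs(ru)), max(abs(rv)))
    if (res < tol) break
  }
  structure(list(u = u, v = v, mu = mu, iterations = it, dt = dt, residual = res),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d, mu %.3g, %d iterations, residual %.3g\n",
              nrow(x$u), ncol(x$u), x$mu, x$iterations, x$residual))
  invisible(x)
}

#' Direct steady-state GVF solve
#'
#' Solves the linear steady state of the GVF equations,
#' `mu lap(u) = |grad f|^2 (u - f_x)`, exactly via a sparse direct
#' factorisation of the 5-point Laplacian with zero-flux boundaries.
#' Intended for small grids; the iterative [gvf()] converges to this
#' solution.
#'
#' @inheritParams gvf
#' @return A `vector_field` (with `iterations = NA`).
#' @export
gvf_steady_state <- function(edge, mu = 0.2) {
  if (!inherits(edge, "edge_map")) mar_abort("`edge` must be an edge_map", "bad_input")
  g <- grad_xy(edge$values)
  fx <- g$x; fy <- g$y
  b <- as.vector(fx^2 + fy^2)
  nr <- nrow(fx); nc <- ncol(fx); n <- nr * nc
  idx <- function(r, c) (c - 1L) * nr + r
  rr <- rep(seq_len(nr), nc); cc <- rep(seq_len(nc), each = nr)
  pairs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  ii <- jj <- integer(0)
  for (p in pairs) {
    r2 <- rr + p[1]; c2 <- cc + p[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ii <- c(ii, idx(rr[ok], cc[ok]))
    jj <- c(jj, idx(r2[ok], c2[ok]))
  }
  deg <- tabulate(ii, nbins = n)
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(rep(1, length(ii)), -deg), dims = c(n, n))
  A <- mu * L - Matrix::Diagonal(n, b)
  u <- matrix(as.numeric(Matrix::solve(A, -b * as.vector(fx))), nr, nc)
  v <- matrix(as.numeric(Matrix::solve(A, -b * as.vector(fy))), nr, nc)
  structure(list(u = u, v = v, mu = mu, iterations = NA_integer_, dt = NA_real_,
                 residual = 0), class = "vector_field")
}
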