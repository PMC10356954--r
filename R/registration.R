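#' Rigid 2D transform
#'
#' In-plane rotation about the geometric image centre followed by a pixel
#' translation. This is the motion model for the small table/gantry
#' displacement between the metal-bearing scan and the metal-free reference
#' scan: shape and size are preserved, only position and orientation change.
#'
#' @param theta_deg Rotation in degrees, in `(-180, 180]` (counter-clockwise
#'   in (x, y) = (col, row) coordinates).
#' @param tx_px,ty_px Translation in pixels along columns (x) and rows (y).
#' @return An object of class `rigid_transform`.
#' @examples
#' t <- rigid_transform(1.5, 2.3, -1.7)
#' invert_transform(t)
#' @export
rigid_transform <- function(theta_deg = 0, tx_px = 0, ty_px = 0) {
  vals <- c(theta_deg, tx_px, ty_px)
  if (!all(is.finite(vals))) mar_abort("transform components must be finite", "bad_input")
  theta_deg <- ((theta_deg + 180) %% 360) - 180
  if (theta_deg == -180) theta_deg <- 180
  structure(list(theta_deg = theta_deg, tx_px = tx_px, ty_px = ty_px),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> theta %.4f deg, t (%.4f, %.4f) px\n",
              x$theta_deg, x$tx_px, x$ty_px))
  invisible(x)
}

#' Invert a rigid transform
#'
#' With rotation about the image centre, the forward map is
#' `T(p) = R (p - c) + c + t`; its inverse is a rotation by `-theta` and
#' translation `-R(-theta) t`.
#'
#' @param t A [rigid_transform].
#' @return The inverse [rigid_transform].
#' @export
invert_transform <- function(t) {
  th <- -t$theta_deg * pi / 180
  tx <- -(cos(th) * t$tx_px - sin(th) * t$ty_px)
  ty <- -(sin(th) * t$tx_px + cos(th) * t$ty_px)
  rigid_transform(-t$theta_deg, tx, ty)
}

transform_is_identity <- function(t) {
  t$theta_deg == 0 && t$tx_px == 0 && t$ty_px == 0
}

#' Resample an image under a rigid transform
#'
#' Applies `T(p) = R(theta) (p - c) + c + t` to the image content: the output
#' pixel at `p` takes the bilinearly interpolated input value at `T^{-1}(p)`.
#' Rotation is about the geometric image centre, matching
#' [register_rigid()], so transforms are interchangeable between the two.
#' The identity transform is a fast path returning the input bit-for-bit.
#'
#' @param image A [ct_image].
#' @param transform A [rigid_transform].
#' @param fill_hu Value assigned to output pixels that map outside the input
#'   domain (default -1000, air).
#' @return A resampled [ct_image].
#' @export
resample_rigid <- function(image, transform, fill_hu = -1000) {
  if (!inherits(transform, "rigid_transform")) {
    mar_abort("`transform` must be a rigid_transform", "bad_input")
  }
  if (transform_is_identity(transform)) return(image)
  res <- resample_with_mask(image$pixels, transform, fill_hu)
  ct_image(res$values, image$spacing_mm, origin_tag = image$origin_tag)
}

# Shared resampling core; also reports which output pixels mapped inside
# the source domain (the registration metric restricts itself to those).
resample_with_mask <- function(px, transform, fill_hu) {
  nr <- nrow(px); nc <- ncol(px)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  th <- transform$theta_deg * pi / 180
  # inverse map: src = R(-theta) (dst - c - t) + c
  xd <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx - transform$tx_px
  yd <- matrix(seq_len(nr), nr, nc) - cy - transform$ty_px
  ct_ <- cos(th); st_ <- sin(th)
  xs <- ct_ * xd + st_ * yd + cx
  ys <- -st_ * xd + ct_ * yd + cy
  list(values = bilinear_sample(px, xs, ys, fill = fill_hu),
       inside = xs >= 1 & xs <= nc & ys >= 1 & ys <= nr)
}

# Vectorised bilinear interpolation of matrix `px` at (x = col, y = row)
# coordinate arrays; `fill` outside [1, nc] x [1, nr].
bilinear_sample <- function(px, xs, ys, fill = 0) {
  nr <- nrow(px); nc <- ncol(px)
  x0 <- floor(xs); y0 <- floor(ys)
  dx <- xs - x0; dy <- ys - y0
  inside <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
  # clamp corner indices so arithmetic stays legal; fill applied afterwards
  x0c <- pmin(pmax(x0, 1), nc); x1c <- pmin(x0c + 1, nc)
  y0c <- pmin(pmax(y0, 1), nr); y1c <- pmin(y0c + 1, nr)
  idx <- function(r, c) (c - 1) * nr + r
  v00 <- px[idx(y0c, x0c)]; v10 <- px[idx(y0c, x1c)]
  v01 <- px[idx(y1c, x0c)]; v11 <- px[idx(y1c, x1c)]
  out <- (1 - dy) * ((1 - dx) * v00 + dx * v10) + dy * ((1 - dx) * v01 + dx * v11)
  out[!inside] <- fill
  matrix(out, nrow(xs), ncol(xs))
}

default_registration_config <- function() {
  list(
    metric = "mse",
    grid_halfwidth_px = 5, grid_step_px = 2.5,
    grid_halfwidth_deg = 3, grid_step_deg = 1.5,
    max_iter = 400,
    exclusion_dilate_px = 3,
    smooth_sigma_px = 1.5,
    fill_hu = -1000
  )
}

#' Rigidly register a moving image to a target image
#'
#' Estimates the translation + rotation aligning `moving` to `target` by
#' minimising the mean squared HU difference over pixels outside the
#' exclusion mask (the metal mask, dilated, when registering the metal-free
#' reference to a metal-bearing image: the reference has nothing to match
#' there). A coarse multistart grid over the expected displacement range is
#' followed by derivative-free Nelder-Mead refinement; the whole procedure
#' is deterministic. The identity transform is always a candidate and wins
#' ties, so self-registration returns the exact identity.
#'
#' @param moving,target [ct_image]s sharing shape and spacing.
#' @param exclusion Optional [region_mask] (or logical matrix) of pixels to
#'   exclude from the cost; dilated by `config$exclusion_dilate_px`.
#' @param config Named list overriding the defaults: `grid_halfwidth_px`,
#'   `grid_step_px`, `grid_halfwidth_deg`, `grid_step_deg`, `max_iter`,
#'   `exclusion_dilate_px`, `smooth_sigma_px` (Gaussian pre-smoothing of
#'   both images inside the metric; suppresses the sub-pixel bias bilinear
#'   interpolation of sharp edges induces in the MSE minimum), `fill_hu`.
#' @return A [rigid_transform] mapping `moving` onto `target` (apply with
#'   [resample_rigid()]), with attributes `cost` (MSE at the optimum) and
#'   `cost_identity`.
#' @export
register_rigid <- function(moving, target, exclusion = NULL, config = list()) {
  check_same_grid(moving, target)
  cfg <- modifyList(default_registration_config(), config)
  valid <- matrix(TRUE, nrow(target$pixels), ncol(target$pixels))
  if (!is.null(exclusion)) {
    ex <- if (inherits(exclusion, "region_mask")) exclusion$pixels else exclusion
    if (!identical(dim(ex), dim(target$pixels))) {
      mar_abort("exclusion mask shape does not match images", "shape_mismatch")
    }
    if (cfg$exclusion_dilate_px > 0) {
      ex <- EBImage::dilate(ex * 1, EBImage::makeBrush(2 * cfg$exclusion_dilate_px + 1, "disc")) > 0
    }
    valid <- !ex
  }
  # Mild pre-smoothing of both images before the metric suppresses the
  # sub-pixel bias that bilinear interpolation of sharp edges induces in
  # the MSE minimum; the returned transform applies to the originals.
  if (cfg$smooth_sigma_px > 0) {
    tgt <- gauss_smooth(target$pixels, cfg$smooth_sigma_px)
    mov <- ct_image(gauss_smooth(moving$pixels, cfg$smooth_sigma_px),
                    moving$spacing_mm, origin_tag = moving$origin_tag)
  } else {
    tgt <- target$pixels
    mov <- moving
  }
  # MSE over pixels that are outside the exclusion mask AND map inside the
  # moving image's domain, so fill values never drive the metric.
  cost <- function(par) {
    tr <- rigid_transform(par[1], par[2], par[3])
    if (transform_is_identity(tr)) {
      d <- mov$pixels - tgt
      return(mean(d[valid]^2))
    }
    res <- resample_with_mask(mov$pixels, tr, cfg$fill_hu)
    sel <- valid & res$inside
    d <- res$values[sel] - tgt[sel]
    mean(d^2)
  }

  steps_px <- seq(-cfg$grid_halfwidth_px, cfg$grid_halfwidth_px, by = cfg$grid_step_px)
  steps_deg <- seq(-cfg$grid_halfwidth_deg, cfg$grid_halfwidth_deg, by = cfg$grid_step_deg)
  grid <- expand.grid(theta = steps_deg, tx = steps_px, ty = steps_px)
  grid_costs <- apply(grid, 1, function(p) cost(c(p[["theta"]], p[["tx"]], p[["ty"]])))

  spread <- max(grid_costs) - min(grid_costs)
  if (!is.finite(spread) || spread <= 1e-12 * max(abs(grid_costs), 1e-300)) {
    mar_abort("registration cost is flat across all starts; images share no structure",
              "registration_failed")
  }

  best <- as.numeric(grid[which.min(grid_costs), ])
  opt <- optim(best, cost, method = "Nelder-Mead",
               control = list(maxit = cfg$max_iter, reltol = 1e-12,
                              parscale = c(0.5, 1, 1)))
  id_cost <- cost(c(0, 0, 0))
  cand <- list(
    list(par = c(0, 0, 0), cost = id_cost),          # identity wins ties
    list(par = best, cost = min(grid_costs)),
    list(par = opt$par, cost = opt$value)
  )
  pick <- cand[[which.min(vapply(cand, `[[`, numeric(1), "cost"))]]
  out <- rigid_transform(pick$par[1], pick$par[2], pick$par[3])
  attr(out, "cost") <- pick$cost
  attr(out, "cost_identity") <- id_cost
  out
}
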