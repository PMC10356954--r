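#' Closed contour
#'
#' An ordered list of sub-pixel vertices in `(x, y) = (col, row)` pixel
#' coordinates describing a deformable curve.
#'
#' @param vertices Two-column numeric matrix `(x, y)`.
#' @param closed Logical; closed contours need at least 3 vertices.
#' @return An object of class `mar_contour`.
#' @export
make_contour <- function(vertices, closed = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || !all(is.finite(vertices))) {
    mar_abort("contour vertices must be a finite two-column matrix", "bad_input")
  }
  if (closed && nrow(vertices) < 3) {
    mar_abort("a closed contour needs at least 3 vertices", "bad_input")
  }
  structure(list(vertices = vertices, closed = closed), class = "mar_contour")
}

#' @rdname make_contour
#' @param cx,cy Centre in pixel coordinates (x = col, y = row).
#' @param r Radius in pixels.
#' @param n Number of vertices.
#' @export
circle_contour <- function(cx, cy, r, n = 64) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  make_contour(cbind(cx + r * cos(a), cy + r * sin(a)))
}

contour_perimeter <- function(verts) {
  d <- verts - verts[c(2:nrow(verts), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

contour_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  xn <- x[c(2:length(x), 1)]; yn <- y[c(2:length(y), 1)]
  abs(sum(x * yn - xn * y)) / 2
}

# Resample a closed polygon to n_out vertices at uniform arc length.
resample_closed <- function(verts, n_out) {
  v <- rbind(verts, verts[1, , drop = FALSE])
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(verts[rep(1, n_out), , drop = FALSE])
  target <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  x <- stats::approx(s, v[, 1], xout = target, ties = "ordered")$y
  y <- stats::approx(s, v[, 2], xout = target, ties = "ordered")$y
  cbind(x, y)
}

# Circular moving-average smoothing of a closed polygon.
smooth_closed <- function(verts, k = 2) {
  if (k <= 0) return(verts)
  n <- nrow(verts)
  out <- verts
  for (j in seq(-k, k)) {
    if (j == 0) next
    out <- out + verts[((seq_len(n) - 1 + j) %% n) + 1, , drop = FALSE]
  }
  out / (2 * k + 1)
}

# Point-in-polygon (even-odd ray casting), vectorised over query points.
point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  x <- verts[, 1]; y <- verts[, 2]
  xj <- x[c(n, 1:(n - 1))]; yj <- y[c(n, 1:(n - 1))]
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (yj[i] > py)) &
      (px < (xj[i] - x[i]) * (py - y[i]) / (yj[i] - y[i]) + x[i])
    inside <- xor(inside, crosses)
  }
  inside
}

cyclic_internal_matrix <- function(n, alpha, beta, gamma) {
  shift <- function(j) ((seq_len(n) - 1 + j) %% n) + 1
  A <- matrix(0, n, n)
  add <- function(A, j, val) { A[cbind(seq_len(n), shift(j))] <- A[cbind(seq_len(n), shift(j))] + val; A }
  # -alpha * D2 (tension) + beta * D4 (rigidity)
  A <- add(A, 0, 2 * alpha + 6 * beta)
  A <- add(A, -1, -alpha - 4 * beta); A <- add(A, 1, -alpha - 4 * beta)
  A <- add(A, -2, beta); A <- add(A, 2, beta)
  diag(n) + gamma * A
}

#' Evolve an active contour in a GVF field
#'
#' Semi-implicit snake iteration: internal tension/rigidity forces are
#' handled implicitly through a cyclic pentadiagonal system, the GVF
#' external force is sampled at the vertices by bilinear interpolation.
#' Vertices are resampled to uniform arc length every iteration; evolution
#' stops at `n_iter` or when the largest vertex motion (before resampling)
#' drops below `tol`.
#'
#' @param field A `vector_field` from [gvf()] or [gvf_steady_state()].
#' @param init A closed [make_contour()].
#' @param alpha Tension (first-derivative penalty).
#' @param beta Rigidity (second-derivative penalty).
#' @param n_iter Iteration cap.
#' @param gamma Time step of the semi-implicit update.
#' @param kappa External-force weight.
#' @param tol Vertex-motion stopping tolerance in pixels.
#' @param spacing_px Target vertex spacing for arc-length resampling.
#' @return The evolved `mar_contour` with attribute `iterations`.
#' @export
evolve_snake <- function(field, init, alpha = 0.01, beta = 0.02, n_iter = 150,
                         gamma = 1, kappa = 4, tol = 0.01, spacing_px = 2) {
  if (!inherits(init, "mar_contour") || !init$closed) {
    mar_abort("`init` must be a closed contour", "bad_input")
  }
  u <- field$u; v <- field$v
  n <- max(8L, round(contour_perimeter(init$vertices) / spacing_px))
  X <- resample_closed(init$vertices, n)
  Minv <- solve(cyclic_internal_matrix(n, alpha, beta, gamma))
  it <- 0L
  while (it < n_iter) {
    fx <- bilinear_sample(u, matrix(X[, 1], 1), matrix(X[, 2], 1), fill = 0)
    fy <- bilinear_sample(v, matrix(X[, 1], 1), matrix(X[, 2], 1), fill = 0)
    Xn <- Minv %*% (X + gamma * kappa * cbind(as.numeric(fx), as.numeric(fy)))
    disp <- max(sqrt(rowSums((Xn - X)^2)))
    X <- resample_closed(Xn, n)
    it <- it + 1L
    if (contour_area(X) < 0.5 || nrow(unique(round(X, 6))) < 3) {
      mar_abort("contour collapsed during evolution", "contour_collapsed")
    }
    if (disp < tol) break
  }
  out <- make_contour(X)
  attr(out, "iterations") <- it
  out
}

#' Rasterise and flood-fill a closed contour
#'
#' The contour is rasterised onto the pixel grid, the interior is filled by
#' flood fill from a validated interior seed (the polygon centroid, or the
#' first interior pixel if the centroid is not usable), and the mask is the
#' union of the interior and the boundary pixels whose centres lie inside
#' the polygon. If the rasterised boundary is not closed on the grid the
#' fill escapes to the image border and the operation fails rather than
#' returning a leaked mask.
#'
#' @param contour A closed [make_contour()].
#' @param grid_shape Integer `(rows, cols)` of the target grid.
#' @param structure Structure tag for the returned mask.
#' @param spacing_mm Pixel spacing recorded on the mask.
#' @return A [region_mask].
#' @export
fill_structure <- function(contour, grid_shape, structure = "body", spacing_mm = c(1, 1)) {
  if (!inherits(contour, "mar_contour") || !contour$closed) {
    mar_abort("`contour` must be a closed contour", "bad_input")
  }
  verts <- contour$vertices
  nr <- grid_shape[1]; nc <- grid_shape[2]
  # rasterise edges at fine steps
  v2 <- rbind(verts, verts[1, , drop = FALSE])
  bx <- by <- numeric(0)
  for (i in seq_len(nrow(verts))) {
    p <- v2[i, ]; q <- v2[i + 1, ]
    steps <- max(2L, ceiling(max(abs(q - p)) / 0.25))
    tt <- seq(0, 1, length.out = steps)
    bx <- c(bx, p[1] + tt * (q[1] - p[1]))
    by <- c(by, p[2] + tt * (q[2] - p[2]))
  }
  bc <- pmin(pmax(round(bx), 1), nc); br <- pmin(pmax(round(by), 1), nr)
  bidx <- unique(cbind(br, bc))
  boundary <- matrix(FALSE, nr, nc)
  boundary[bidx] <- TRUE

  # seed: centroid if interior, else scan the bounding box
  ctr <- colMeans(verts)
  seed <- c(round(ctr[2]), round(ctr[1]))  # (row, col)
  seed_ok <- function(s) {
    s[1] >= 1 && s[1] <= nr && s[2] >= 1 && s[2] <= nc &&
      !boundary[s[1], s[2]] && point_in_polygon(s[2], s[1], verts)
  }
  if (!seed_ok(seed)) {
    r0 <- max(1, floor(min(verts[, 2]))); r1 <- min(nr, ceiling(max(verts[, 2])))
    c0 <- max(1, floor(min(verts[, 1]))); c1 <- min(nc, ceiling(max(verts[, 1])))
    if (r0 > r1 || c0 > c1) mar_abort("contour lies outside the grid", "contour_collapsed")
    cand <- expand.grid(row = r0:r1, col = c0:c1)
    ok <- !boundary[cbind(cand$row, cand$col)] &
      point_in_polygon(cand$col, cand$row, verts)
    if (!any(ok)) mar_abort("contour encloses no interior pixel", "contour_collapsed")
    seed <- as.numeric(cand[which(ok)[1], ])
  }

  interior <- flood_interior(boundary, seed)
  keep_b <- bidx[point_in_polygon(bidx[, 2], bidx[, 1], verts), , drop = FALSE]
  mask <- interior
  mask[keep_b] <- TRUE
  region_mask(mask, structure, spacing_mm = spacing_mm)
}

# Flood fill the region containing `seed` (row, col) over non-boundary
# pixels; a fill that reaches the image border means the rasterised
# boundary has a gap, which is an error, not a mask.
flood_interior <- function(boundary, seed) {
  nr <- nrow(boundary); nc <- ncol(boundary)
  filled <- EBImage::floodFill(boundary * 1, pt = c(seed[1], seed[2]), col = 2)
  interior <- matrix(filled == 2, nr, nc)
  if (any(interior[1, ]) || any(interior[nr, ]) || any(interior[, 1]) || any(interior[, nc])) {
    mar_abort("rasterised contour is not closed on the grid: flood fill reached the border",
              "contour_not_closed")
  }
  interior
}

#' Threshold-based metal segmentation
#'
#' Connected components of `HU > hu_threshold`; components smaller than
#' `min_label_px` are removed as noise labels, and the union of the
#' survivors is the metal mask.
#'
#' @param image A [ct_image].
#' @param hu_threshold HU threshold (default 2000).
#' @param min_label_px Minimum component size in pixels (default 100).
#' @return A [region_mask] with `structure = "metal"`.
#' @export
segment_metal <- function(image, hu_threshold = 2000, min_label_px = 100) {
  bw <- image$pixels > hu_threshold
  if (!any(bw)) mar_abort("no pixels above the metal threshold", "no_metal")
  lab <- EBImage::bwlabel(bw * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_label_px)
  if (length(keep) == 0) {
    mar_abort("no metal component survives the label size filter", "no_metal")
  }
  region_mask(matrix(lab %in% keep, nrow(bw), ncol(bw)), "metal",
              spacing_mm = image$spacing_mm)
}

#' Split a structure mask into near and far zones
#'
#' Pixels whose centre lies within `radius_mm` (Euclidean, in mm) of the
#' metal centroid form the near zone; the remainder is the far zone. The
#' two zones partition the input mask.
#'
#' @param mask A whole-zone [region_mask].
#' @param metal_center Sub-pixel `(row, col)` of the metal centroid.
#' @param radius_mm Split radius in mm (default 20).
#' @param spacing_mm Pixel spacing; defaults to the mask's.
#' @return List with `near` and `far` [region_mask]s.
#' @export
split_near_far <- function(mask, metal_center, radius_mm = 20, spacing_mm = NULL) {
  if (mask$zone != "whole") mar_abort("split_near_far expects a whole-zone mask", "bad_input")
  if (radius_mm <= 0) mar_abort("radius_mm must be > 0", "bad_input")
  sp <- spacing_mm %||% mask$spacing_mm
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  dr <- (matrix(seq_len(nr), nr, nc) - metal_center[1]) * sp[1]
  dc <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - metal_center[2]) * sp[2]
  near <- sqrt(dr^2 + dc^2) < radius_mm
  list(
    near = region_mask(mask$pixels & near, mask$structure, "near", sp),
    far = region_mask(mask$pixels & !near, mask$structure, "far", sp)
  )
}

#' Overlap ratio between two masks
#'
#' `100 * |A intersect B| / |A union B|` (Jaccard index as a percentage),
#' the agreement measure between the evaluation-image and reference-image
#' segmentations. Symmetric; 100 iff the masks are equal; errors if both
#' masks are empty (the ratio is undefined).
#'
#' @param a,b [region_mask]s (or logical matrices) on the same grid.
#' @return Percentage in `[0, 100]`.
#' @seealso [dice_coefficient()] for the Dice variant.
#' @export
overlap_ratio <- function(a, b) {
  pa <- if (inherits(a, "region_mask")) a$pixels else a
  pb <- if (inherits(b, "region_mask")) b$pixels else b
  if (!identical(dim(pa), dim(pb))) mar_abort("masks must share grid shape", "shape_mismatch")
  uni <- sum(pa | pb)
  if (uni == 0) mar_abort("overlap ratio undefined: both masks are empty", "empty_region")
  100 * sum(pa & pb) / uni
}

#' Dice coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, reported as a secondary agreement
#' measure alongside [overlap_ratio()].
#'
#' @inheritParams overlap_ratio
#' @return Value in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  pa <- if (inherits(a, "region_mask")) a$pixels else a
  pb <- if (inherits(b, "region_mask")) b$pixels else b
  if (!identical(dim(pa), dim(pb))) mar_abort("masks must share grid shape", "shape_mismatch")
  denom <- sum(pa) + sum(pb)
  if (denom == 0) mar_abort("Dice undefined: both masks are empty", "empty_region")
  2 * sum(pa & pb) / denom
}

#' Default segmentation configuration
#'
#' @return Named list of tunable parameters consumed by
#'   [segment_structures()] and [run_evaluation()].
#' @export
default_seg_config <- function() {
  list(
    metal_threshold_hu = 2000, min_label_px = 100,
    near_radius_mm = 20,
    edge_sigma_px = 1.0,
    gvf_mu = 0.1, gvf_iters = 200, gvf_tol = 1e-4,
    snake_alpha = 0.01, snake_beta = 0.02, snake_gamma = 1, snake_kappa = 4,
    snake_iters = 120, snake_tol = 0.01, snake_spacing_px = 2,
    bone_init_hu = 200, tissue_init_hu = c(-200, 200),
    clip_hu = c(-1000, 1600),
    min_component_px = 150, metal_dilate_px = 2,
    init_smooth_k = 2
  )
}

# Outer contours of a binary mask as (x, y) vertex matrices, one per object.
mask_outer_contours <- function(bw) {
  lab <- EBImage::bwlabel(bw * 1)
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(m) cbind(x = m[, 2] + 1, y = m[, 1] + 1))
}

dilate_mask <- function(px, radius_px) {
  if (radius_px <= 0) return(px)
  EBImage::dilate(px * 1, EBImage::makeBrush(2 * radius_px + 1, "disc")) > 0
}

#' Automatic bone and tissue segmentation
#'
#' Implements the edge-map -> GVF -> active contour -> flood fill chain with
#' deterministic threshold-based contour initialisation, so the whole
#' delineation runs without human intervention: bone contours start from
#' connected components of `HU > bone_init_hu`, the tissue (body) contour
#' from the largest above-air component; each is refined in the shared GVF
#' field and filled. When a metal mask is supplied, the metal dilated by
#' `metal_dilate_px` is excluded from both outputs so metal blooming does
#' not contaminate the HU histograms. Bone and tissue masks are disjoint by
#' construction.
#'
#' @param image A [ct_image].
#' @param metal Optional metal [region_mask] from [segment_metal()].
#' @param config Named list overriding [default_seg_config()].
#' @return Named list of whole-zone [region_mask]s (`bone`, `tissue`) with
#'   attribute `contours` (the refined snakes).
#' @export
segment_structures <- function(image, metal = NULL, config = list()) {
  cfg <- modifyList(default_seg_config(), config)
  px <- pmin(pmax(image$pixels, cfg$clip_hu[1]), cfg$clip_hu[2])
  nr <- nrow(px); nc <- ncol(px)
  metal_px <- if (!is.null(metal)) metal$pixels else matrix(FALSE, nr, nc)
  metal_ex <- dilate_mask(metal_px, cfg$metal_dilate_px)

  em <- edge_map(px, cfg$edge_sigma_px)
  field <- gvf(em, mu = cfg$gvf_mu, n_iter = cfg$gvf_iters, tol = cfg$gvf_tol)

  refine <- function(verts, name) {
    init <- make_contour(smooth_closed(
      resample_closed(verts, max(12L, round(contour_perimeter(verts) / cfg$snake_spacing_px))),
      cfg$init_smooth_k
    ))
    tryCatch(
      evolve_snake(field, init, alpha = cfg$snake_alpha, beta = cfg$snake_beta,
                   n_iter = cfg$snake_iters, gamma = cfg$snake_gamma,
                   kappa = cfg$snake_kappa, tol = cfg$snake_tol,
                   spacing_px = cfg$snake_spacing_px),
      marref_error = function(e) {
        mar_abort(sprintf("%s segmentation failed: %s", name, conditionMessage(e)),
                  "segmentation")
      }
    )
  }
  fill_named <- function(contour, name) {
    tryCatch(
      fill_structure(contour, c(nr, nc), structure = "body",
                     spacing_mm = image$spacing_mm),
      marref_error = function(e) {
        mar_abort(sprintf("%s segmentation failed: %s", name, conditionMessage(e)),
                  "segmentation")
      }
    )
  }

  # --- bone: components above the bone threshold ---------------------------
  bw_bone <- px > cfg$bone_init_hu
  lab <- EBImage::bwlabel(bw_bone * 1)
  sizes <- tabulate(lab[lab > 0])
  bone_fill <- matrix(FALSE, nr, nc)
  bone_contours <- list()
  for (k in which(sizes >= cfg$min_component_px)) {
    comp <- lab == k
    if (any(metal_px) && sum(comp & metal_px) / sum(comp) > 0.5) next  # the metal itself
    verts <- mask_outer_contours(comp)[[1]]
    snake <- refine(verts, "bone")
    bone_fill <- bone_fill | fill_named(snake, "bone")$pixels
    bone_contours[[length(bone_contours) + 1]] <- snake
  }

  # --- tissue: outer body contour ------------------------------------------
  bw_body <- px > cfg$tissue_init_hu[1]
  labb <- EBImage::bwlabel(bw_body * 1)
  sizesb <- tabulate(labb[labb > 0])
  if (length(sizesb) == 0) mar_abort("no body component found", "segmentation")
  body_comp <- labb == which.max(sizesb)
  body_snake <- refine(mask_outer_contours(body_comp)[[1]], "tissue")
  body_fill <- fill_named(body_snake, "tissue")$pixels

  bone_mask <- bone_fill & !metal_ex
  tissue_mask <- body_fill & !bone_fill & !metal_ex
  out <- list(
    bone = region_mask(bone_mask, "bone", spacing_mm = image$spacing_mm),
    tissue = region_mask(tissue_mask, "tissue", spacing_mm = image$spacing_mm)
  )
  attr(out, "contours") <- c(bone_contours, list(body_snake))
  attr(out, "gvf_residual") <- field$residual
  out
}
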