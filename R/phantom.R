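#' Parametric labyrinth phantom specification
#'
#' Describes a synthetic T2-like volume containing two stylized inner ears:
#' per side a tapering helical tube (cochlea), an ellipsoid (vestibule) and
#' three tori in roughly orthogonal planes (semicircular canals), mirrored
#' about the midline with per-case jitter. The structures appear as a bright
#' plateau (contrast at least three background standard deviations),
#' modulated by a smooth multiplicative bias field, over a smooth tissue
#' texture with additive Gaussian noise. The geometry is stylized rather
#' than anatomically exact: what matters for exercising the pipeline is a
#' small, thin, bilateral bright structure occupying well under 1% of the
#' voxels. Pathology flags drop components from both the mask and the bright
#' signal (emulating post-resection anatomy) or attenuate the cochlear
#' signal while keeping it in the mask (emulating altered signal intensity).
#'
#' @param grid_shape Voxel grid, default `c(160, 160, 64)`.
#' @param spacing Voxel size in mm, default isotropic 0.45. Use
#'   `c(0.3, 0.3, 0.65)` for the anisotropic-acquisition mode that exercises
#'   the resampling path.
#' @param volume_range Target range (mm^3) for the intact bilateral
#'   ground-truth volume, default `c(250, 550)`; the global geometry scale
#'   is derived from the per-case volume draw, so smaller ranges give
#'   proportionally smaller labyrinths.
#' @param contrast Foreground plateau height in background-texture units;
#'   the default keeps the realized contrast at or above three background
#'   standard deviations after bias-field and noise corruption.
#' @param noise_sd Additive Gaussian noise SD (intensity units; background
#'   texture has SD 1 before noise).
#' @param bias_amplitude Relative amplitude of the smooth multiplicative
#'   bias field (0 disables).
#' @param pathology Optional list with entries `side` ("left"/"right"),
#'   `drop_canals`, `drop_vestibule`, `attenuate_cochlea` (logicals).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(160L, 160L, 64L),
                         spacing = c(0.45, 0.45, 0.45),
                         volume_range = c(250, 550),
                         contrast = 5,
                         noise_sd = 0.6,
                         bias_amplitude = 0.15,
                         pathology = NULL) {
  if (any(volume_range <= 0) || volume_range[1] >= volume_range[2]) {
    abort("volume_range must be positive and increasing",
          class = "otoseg_spec_error")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 volume_range = volume_range,
                 contrast = contrast, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 pathology = pathology),
            class = "phantom_spec")
}

#' Desk-scale phantom specification
#'
#' A reduced grid (64 x 64 x 32 voxels at 0.45 mm) with geometry scaled so
#' the labyrinths fit the field of view and the foreground stays below 1%
#' of the voxels, preserving the class imbalance that motivates the Tversky
#' loss. Intended for CPU-scale training demonstrations and tests.
#'
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_spec_desk <- function(...) {
  args <- modifyList(
    list(grid_shape = c(64L, 64L, 32L), spacing = c(0.45, 0.45, 0.45),
         volume_range = c(45, 95)),
    list(...))
  do.call(phantom_spec, args)
}

# --- geometry helpers -------------------------------------------------------

# world coordinates (mm) of every voxel centre, as three arrays
grid_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

sub_box <- function(gc, lo, hi) {
  ix <- which(gc$x >= lo[1] & gc$x <= hi[1])
  iy <- which(gc$y >= lo[2] & gc$y <= hi[2])
  iz <- which(gc$z >= lo[3] & gc$z <= hi[3])
  list(ix = ix, iy = iy, iz = iz)
}

# rasterize |f(p)| <= 0 inside a bounding box; mask modified in place-ish
raster_region <- function(mask, gc, lo, hi, inside_fn) {
  sb <- sub_box(gc, lo, hi)
  if (!length(sb$ix) || !length(sb$iy) || !length(sb$iz)) return(mask)
  xs <- gc$x[sb$ix]; ys <- gc$y[sb$iy]; zs <- gc$z[sb$iz]
  pts <- expand.grid(x = xs, y = ys, z = zs)
  inside <- inside_fn(pts$x, pts$y, pts$z)
  if (any(inside)) {
    sel <- array(inside, c(length(xs), length(ys), length(zs)))
    mask[sb$ix, sb$iy, sb$iz] <- mask[sb$ix, sb$iy, sb$iz] | sel
  }
  mask
}

rotate_frame <- function(axis_angles) {
  # small rotation matrix from yaw/pitch/roll (radians)
  cz <- cos(axis_angles[3]); sz <- sin(axis_angles[3])
  cy <- cos(axis_angles[2]); sy <- sin(axis_angles[2])
  cx <- cos(axis_angles[1]); sx <- sin(axis_angles[1])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

raster_ellipsoid <- function(mask, gc, center, semi, R) {
  r <- max(semi)
  raster_region(mask, gc, center - r - 0.5, center + r + 0.5,
                function(x, y, z) {
                  p <- rbind(x - center[1], y - center[2], z - center[3])
                  q <- t(R) %*% p
                  (q[1, ] / semi[1])^2 + (q[2, ] / semi[2])^2 +
                    (q[3, ] / semi[3])^2 <= 1
                })
}

raster_torus <- function(mask, gc, center, ring_r, tube_r, R) {
  r <- ring_r + tube_r
  raster_region(mask, gc, center - r - 0.5, center + r + 0.5,
                function(x, y, z) {
                  p <- rbind(x - center[1], y - center[2], z - center[3])
                  q <- t(R) %*% p
                  (sqrt(q[1, ]^2 + q[2, ]^2) - ring_r)^2 + q[3, ]^2 <=
                    tube_r^2
                })
}

# tapering helical tube: 2.5 turns, radius and tube width shrinking apically
raster_cochlea <- function(mask, gc, center, s, R) {
  tt <- seq(0, 1, length.out = 160)
  helix_r <- s * 2.6 * (1 - 0.55 * tt)
  ang <- 2.5 * 2 * pi * tt
  zz <- s * 2.8 * tt
  tube_r <- s * 1.05 * (1 - 0.45 * tt)
  pts <- R %*% rbind(helix_r * cos(ang), helix_r * sin(ang), zz - s * 1.4)
  ext <- max(s * 2.6 + s * 1.05)
  lo <- center - ext - s * 2.9; hi <- center + ext + s * 2.9
  raster_region(mask, gc, lo, hi, function(x, y, z) {
    inside <- rep(FALSE, length(x))
    for (i in seq_along(tt)) {
      dx <- x - (center[1] + pts[1, i])
      dy <- y - (center[2] + pts[2, i])
      dz <- z - (center[3] + pts[3, i])
      inside <- inside | (dx * dx + dy * dy + dz * dz <= tube_r[i]^2)
    }
    inside
  })
}

# smooth random field: coarse white noise trilinearly upsampled to the grid
smooth_field <- function(shape, spacing, coarse = c(8L, 8L, 4L)) {
  coarse <- pmin(coarse, shape)
  g <- array(rnorm(prod(coarse)), coarse)
  ratio <- (coarse - 1) / pmax(shape - 1, 1)
  arr <- .resample_grid(g, coarse, c(1, 1, 1), as.integer(shape),
                        as.numeric(ratio), "linear")
  array(arr, shape)
}

rasterize_side <- function(mask, gc, center, s, side_sign, jitter, drop) {
  # component layout: cochlea antero-medial, vestibule central, canals
  # posterior in three near-orthogonal planes
  base_rot <- rotate_frame(jitter$angles)
  if (!drop$cochlea) {
    mask <- raster_cochlea(mask, gc,
                           center + jitter$cochlea_shift +
                             c(side_sign * -s * 2.2, -s * 3.2, 0),
                           s, base_rot)
  }
  if (!drop$vestibule) {
    mask <- raster_ellipsoid(mask, gc, center + jitter$vestibule_shift,
                             s * c(2.1, 1.5, 1.4), base_rot)
  }
  if (!drop$canals) {
    canal_planes <- list(c(0, 0, 0), c(pi / 2, 0, pi / 8),
                         c(0, pi / 2, -pi / 8))
    offs <- list(c(0, s * 3.0, s * 1.2), c(s * side_sign * 2.0, s * 3.2, 0),
                 c(0, s * 3.4, -s * 1.0))
    for (k in 1:3) {
      mask <- raster_torus(mask, gc, center + offs[[k]] + jitter$canal_shift,
                           ring_r = s * 2.9, tube_r = s * 0.62,
                           R = base_rot %*% rotate_frame(canal_planes[[k]]))
    }
  }
  mask
}

# empirical rasterized-volume calibration: mm^3 of the full bilateral
# structure at geometry scale 1 (component overlap makes this smaller than
# the sum of the analytic component volumes); volumes scale with the cube
# of the geometry scale
VOL_BASE <- 280

#' Generate one labyrinth phantom
#'
#' Draws a target intact volume uniformly from an interior sub-range of
#' `spec$volume_range` (8% margins, absorbing voxel-quantization scatter),
#' sets the global geometry scale accordingly (volumes scale with the cube
#' of the geometry scale), rasterizes both sides with mirrored jitter,
#' applies any pathology, and synthesizes the image as smooth background
#' texture + bright foreground x bias field + noise. Deterministic given
#' `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return List with `image` ([volume_image()]), `mask` ([binary_mask()]),
#'   and `info`, a one-row tibble (seed, volumes, pathology flags).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shape <- spec$grid_shape
  gc <- grid_coords(shape, spec$spacing)
  fov <- (shape - 1) * spec$spacing
  vr <- spec$volume_range
  margin <- 0.08 * (vr[2] - vr[1])
  target <- runif(1, vr[1] + margin, vr[2] - margin)
  s <- (target / VOL_BASE)^(1 / 3)  # geometry scale for ~target mm^3
  lat <- 0.25 * fov[1]
  centers <- list(left = c(fov[1] / 2 - lat, fov[2] / 2, fov[3] / 2),
                  right = c(fov[1] / 2 + lat, fov[2] / 2, fov[3] / 2))
  reach <- 8 * s  # outermost component extent incl. jitter headroom
  for (ctr in centers) {
    if (any(ctr - reach < -spec$spacing) || any(ctr + reach > fov + spec$spacing)) {
      abort("phantom components would exceed the grid; enlarge the grid or lower volume_range",
            class = "otoseg_spec_error")
    }
  }
  jits <- lapply(c(left = 1, right = 2), function(i) {
    list(angles = runif(3, -0.25, 0.25),
         cochlea_shift = rnorm(3, 0, 0.3),
         vestibule_shift = rnorm(3, 0, 0.3),
         canal_shift = rnorm(3, 0, 0.3))
  })
  path <- spec$pathology
  drop_none <- list(cochlea = FALSE, vestibule = FALSE, canals = FALSE)
  mask <- array(FALSE, shape)
  atten_mask <- array(FALSE, shape)
  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    drop <- drop_none
    if (!is.null(path) && identical(path$side, side)) {
      drop$canals <- isTRUE(path$drop_canals)
      drop$vestibule <- isTRUE(path$drop_vestibule)
      if (isTRUE(path$attenuate_cochlea)) {
        # cochlea stays in the mask but its signal is attenuated
        atten_mask <- rasterize_side(atten_mask, gc, centers[[side]], s, sgn,
                                     jits[[side]],
                                     list(cochlea = FALSE, vestibule = TRUE,
                                          canals = TRUE))
      }
    }
    mask <- rasterize_side(mask, gc, centers[[side]], s, sgn, jits[[side]],
                           drop)
  }
  dropped_any <- !is.null(path) && (isTRUE(path$drop_canals) ||
                                    isTRUE(path$drop_vestibule))
  intact_voxels <- if (dropped_any) {
    intact <- array(FALSE, shape)
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      intact <- rasterize_side(intact, gc, centers[[side]], s, sgn,
                               jits[[side]], drop_none)
    }
    sum(intact)
  } else {
    NULL
  }
  # image synthesis: bright plateau over smooth texture, bias field, noise
  bg <- smooth_field(shape, spec$spacing)        # texture, SD ~ 1
  bias <- 1 + spec$bias_amplitude * smooth_field(shape, spec$spacing)
  fg <- spec$contrast * as.numeric(mask & !atten_mask) +
    0.35 * spec$contrast * as.numeric(atten_mask)
  img <- (10 + bg + fg) * bias + rnorm(prod(shape), sd = spec$noise_sd)
  vv <- prod(spec$spacing)
  mask_num <- array(as.numeric(mask), shape)
  info <- tibble(
    seed = as.integer(seed),
    target_volume_mm3 = target,
    volume_mm3 = sum(mask_num) * vv,
    intact_volume_mm3 = if (is.null(intact_voxels)) sum(mask_num) * vv else
      intact_voxels * vv,
    pathology = !is.null(path),
    pathology_side = if (is.null(path)) NA_character_ else path$side,
    drop_canals = !is.null(path) && isTRUE(path$drop_canals),
    drop_vestibule = !is.null(path) && isTRUE(path$drop_vestibule),
    attenuate_cochlea = !is.null(path) && isTRUE(path$attenuate_cochlea))
  list(image = volume_image(array(img, shape), spec$spacing),
       mask = binary_mask(mask_num, spec$spacing),
       info = info)
}

draw_pathology <- function() {
  side <- sample(c("left", "right"), 1)
  kind <- sample(c("resection", "attenuation"), 1)
  if (kind == "resection") {
    list(side = side, drop_canals = TRUE,
         drop_vestibule = runif(1) < 0.7, attenuate_cochlea = FALSE)
  } else {
    list(side = side, drop_canals = FALSE, drop_vestibule = FALSE,
         attenuate_cochlea = TRUE)
  }
}

#' Generate a phantom cohort with a manifest
#'
#' @param n Number of cases (>= 1).
#' @param spec A [phantom_spec()] shared by all cases (per-case parameters
#'   are drawn inside [generate_phantom()]).
#' @param seed Integer master seed; case seeds derive from it.
#' @param pathology_fraction Fraction of cases receiving a random pathology
#'   (rounded to a count).
#' @return List with `cases` (list of `generate_phantom()` results) and
#'   `manifest` (tibble, one row per case with `case_id` plus the phantom
#'   info columns).
#' @export
generate_cohort <- function(n, spec = phantom_spec(), seed = 1L,
                            pathology_fraction = 0) {
  if (n < 1L) abort("n must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_path <- round(pathology_fraction * n)
  path_idx <- if (n_path > 0) sample.int(n, n_path) else integer(0)
  case_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    if (i %in% path_idx) {
      set.seed(case_seeds[i] + 1L)
      sp$pathology <- draw_pathology()
    }
    cases[[i]] <- generate_phantom(sp, seed = case_seeds[i])
    rows[[i]] <- dplyr::bind_cols(tibble(case_id = sprintf("case_%03d", i)),
                                  cases[[i]]$info)
  }
  list(cases = cases, manifest = dplyr::bind_rows(rows))
}
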