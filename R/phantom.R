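#' Digitize an ellipsoid haematoma mask
#'
#' Rasterises an axis-aligned ellipsoid, centred at the grid centre, onto a
#' voxel grid: voxels whose centre satisfies
#' \eqn{\sum_i ((x_i - c_i)/a_i)^2 \le 1} receive label 1. The ellipsoid is
#' the idealised haematoma shape underlying the ABC/2 estimator; irregular
#' shapes are derived from it with [perturb_mask()].
#'
#' @param semi_axes_mm positive triple of semi-axes (mm); the third axis is
#'   axial.
#' @param spacing_mm voxel spacing (mm), default 1 mm isotropic.
#' @param grid_shape integer triple of grid dimensions, default `c(128, 128, 128)`.
#'   Even dimensions place the centre between voxel centres, which gives the
#'   least biased digitization of symmetric shapes.
#' @return A [labeled_volume()].
#' @examples
#' sph <- make_ellipsoid_mask(c(10, 10, 10), c(1, 1, 1), c(24, 24, 24))
#' voxel_volume_mL(sph, 1)  # close to 4/3 * pi * 1^3 = 4.18879 mL
#' @export
make_ellipsoid_mask <- function(semi_axes_mm,
                                spacing_mm = c(1, 1, 1),
                                grid_shape = c(128L, 128L, 128L)) {
  semi_axes_mm <- as.numeric(semi_axes_mm)
  spacing_mm <- as.numeric(spacing_mm)
  grid_shape <- as.integer(grid_shape)
  if (length(semi_axes_mm) != 3L || any(semi_axes_mm <= 0)) {
    stop("`semi_axes_mm` must be a positive triple")
  }
  centre <- (grid_shape - 1) / 2 * spacing_mm
  half_extent <- (grid_shape - 1) * spacing_mm / 2
  if (any(semi_axes_mm > half_extent - spacing_mm)) {
    stop(sprintf(
      "ellipsoid (semi-axes %s mm) exceeds grid bounds %s voxels at spacing %s mm",
      paste(semi_axes_mm, collapse = "x"),
      paste(grid_shape, collapse = "x"),
      paste(spacing_mm, collapse = "x")))
  }
  labels <- array(0L, grid_shape)
  # restrict rasterisation to the ellipsoid's bounding box
  rng <- lapply(1:3, function(i) {
    lo <- max(1L, floor((centre[i] - semi_axes_mm[i]) / spacing_mm[i]) + 1L)
    hi <- min(grid_shape[i], ceiling((centre[i] + semi_axes_mm[i]) / spacing_mm[i]) + 1L)
    lo:hi
  })
  off <- lapply(1:3, function(i) {
    ((rng[[i]] - 1) * spacing_mm[i] - centre[i]) / semi_axes_mm[i]
  })
  d2 <- outer(outer(off[[1]]^2, off[[2]]^2, "+"), off[[3]]^2, "+")
  sub <- array(0L, dim(d2))
  sub[d2 <= 1] <- 1L
  labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
  n1 <- sum(sub)
  new_lv(labels, spacing_mm,
         counts = c(prod(grid_shape) - n1, n1, 0L, 0L))
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fib_dirs <- function(n = 1024L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Band-limited angular noise: a random homogeneous polynomial of degree <= 3
# in the unit direction vector (the span of spherical harmonics up to l = 3),
# standardised to unit SD over the sphere. Returns the evaluator plus the
# clamped-field statistics used for amplitude normalisation.
angular_field <- function(seed) {
  coef <- with_seed(seed, stats::rnorm(19L))
  f_raw <- function(ux, uy, uz) {
    x2 <- ux * ux; y2 <- uy * uy; z2 <- uz * uz
    coef[1] * ux + coef[2] * uy + coef[3] * uz +
      coef[4] * x2 + coef[5] * y2 + coef[6] * z2 +
      coef[7] * ux * uy + coef[8] * ux * uz + coef[9] * uy * uz +
      coef[10] * x2 * ux + coef[11] * y2 * uy + coef[12] * z2 * uz +
      coef[13] * x2 * uy + coef[14] * x2 * uz + coef[15] * y2 * ux +
      coef[16] * y2 * uz + coef[17] * z2 * ux + coef[18] * z2 * uy +
      coef[19] * ux * uy * uz
  }
  dirs <- fib_dirs(1024L)
  f0 <- f_raw(dirs[, 1], dirs[, 2], dirs[, 3])
  mu <- mean(f0)
  sdev <- stats::sd(f0)
  f <- function(ux, uy, uz) {
    pmax(pmin((f_raw(ux, uy, uz) - mu) / sdev, 2.5), -2.5)
  }
  c0 <- pmax(pmin((f0 - mu) / sdev, 2.5), -2.5)
  list(f = f, c0 = c0)
}

# Radial scale function of the deformation and its bounds/normalisation.
# The volume of a star-shaped region is (1/3) * integral of R(u)^3 over the
# sphere, so volume preservation requires the angular mean of scale^3 to be
# 1 *weighted by the base shape's R^3*; `weights` carries R^3 on the
# Fibonacci grid (uniform for a sphere or a generic mask).
deform_scale <- function(field, irregularity, max_amplitude, weights = NULL) {
  amp <- irregularity * max_amplitude
  s3 <- (1 + amp * field$c0)^3
  cnorm <- if (is.null(weights)) {
    mean(s3)^(1 / 3)
  } else {
    (sum(s3 * weights) / sum(weights))^(1 / 3)
  }
  list(amp = amp, cnorm = cnorm,
       smin = (1 + amp * max(-2.5, min(field$c0) - 0.3)) / cnorm,
       smax = (1 + amp * min(2.5, max(field$c0) + 0.3)) / cnorm)
}

#' Radially perturb a haematoma mask
#'
#' Applies a smooth, band-limited radial deformation to the label-1 boundary
#' about its centroid, producing the irregular haematoma shapes for which
#' ABC/2 is known to be biased. The deformation scales the radius along each
#' direction \eqn{\hat u} by \eqn{(1 + a f(\hat u))/c}, where \eqn{f} is a
#' fixed-seed random polynomial of the direction vector of degree at most 3
#' (the span of spherical harmonics up to order 3: band-limited angular
#' noise), \eqn{a} is proportional to `irregularity`,
#' and \eqn{c} normalises the angular mean of the cubed scale so the volume
#' is approximately preserved. The warp is radial and bounded, so a
#' star-shaped input remains a single connected component.
#'
#' @param volume a [labeled_volume()] with a nonempty label-1 region.
#' @param irregularity deformation amplitude in \[0, 1\]; 0 returns the
#'   input unchanged.
#' @param seed integer seed for the random angular field.
#' @param max_amplitude maximal relative radial modulation at
#'   `irregularity = 1` (default 0.35).
#' @return A [labeled_volume()] with the deformed label-1 region; labels 2
#'   and 3 are untouched.
#' @export
perturb_mask <- function(volume, irregularity, seed,
                         max_amplitude = 0.35) {
  stopifnot_volume(volume)
  if (!is.numeric(irregularity) || irregularity < 0 || irregularity > 1) {
    stop("`irregularity` must be in [0, 1]")
  }
  lab <- volume$labels
  if (!any(lab == 1L)) stop("perturb_mask requires a nonempty ICH (label 1) region")
  if (irregularity == 0) return(volume)
  sp <- volume$spacing_mm
  dm <- dim(lab)

  field <- angular_field(seed)
  sc <- deform_scale(field, irregularity, max_amplitude)
  amp <- sc$amp
  cnorm <- sc$cnorm
  smin <- sc$smin
  smax <- sc$smax

  idx1 <- which(lab == 1L, arr.ind = TRUE)
  world1 <- sweep(idx1 - 1, 2, sp, "*")
  ctr <- colMeans(world1)
  rmax1 <- sqrt(max(colSums((t(world1) - ctr)^2)))
  bb_lo <- apply(idx1, 2, min)
  bb_hi <- apply(idx1, 2, max)
  # nearest background voxel inside the lesion bounding box: sources closer
  # to the centroid than this are certainly label 1
  in_bb <- lab[bb_lo[1]:bb_hi[1], bb_lo[2]:bb_hi[2], bb_lo[3]:bb_hi[3]]
  idx_bg <- which(in_bb != 1L, arr.ind = TRUE)
  rmin_bg <- if (nrow(idx_bg)) {
    wbg <- sweep(sweep(idx_bg, 2, bb_lo - 1L, "+") - 1, 2, sp, "*")
    sqrt(min(colSums((t(wbg) - ctr)^2)))
  } else Inf
  # never beyond the first voxel outside the lesion bounding box
  rmin_bg <- min(rmin_bg,
                 min(pmin(ctr - (bb_lo - 2) * sp, bb_hi * sp - ctr)))

  pad_vox <- ceiling((rmax1 * max(smax - 1, 0) + 2 * max(sp)) / sp)
  rng <- lapply(1:3, function(i) {
    max(1L, bb_lo[i] - pad_vox[i]):min(dm[i], bb_hi[i] + pad_vox[i])
  })
  nb <- lengths(rng)
  ox <- (rng[[1]] - 1) * sp[1] - ctr[1]
  oy <- (rng[[2]] - 1) * sp[2] - ctr[2]
  oz <- (rng[[3]] - 1) * sp[3] - ctr[3]
  ux <- rep.int(ox, nb[2] * nb[3])
  uy <- rep.int(rep(oy, each = nb[1]), nb[3])
  uz <- rep(oz, each = nb[1] * nb[2])
  r <- sqrt(ux^2 + uy^2 + uz^2)
  # only voxels whose radius can straddle the deformed boundary need the
  # angular field; nearer voxels are certainly inside, farther certainly out
  new1 <- r < rmin_bg * smin
  shell <- which(r >= rmin_bg * smin & r <= rmax1 * smax & r > 0)
  if (length(shell)) {
    rs <- r[shell]
    scale <- (1 + amp * field$f(ux[shell] / rs, uy[shell] / rs,
                                uz[shell] / rs)) / cnorm
    inv <- 1 / scale
    si <- round((ux[shell] * inv + ctr[1]) / sp[1]) + 1
    sj <- round((uy[shell] * inv + ctr[2]) / sp[2]) + 1
    sk <- round((uz[shell] * inv + ctr[3]) / sp[3]) + 1
    inside <- si >= 1 & si <= dm[1] & sj >= 1 & sj <= dm[2] &
      sk >= 1 & sk <= dm[3]
    hit <- logical(length(shell))
    hit[inside] <- lab[cbind(si[inside], sj[inside], sk[inside])] == 1L
    new1[shell] <- hit
  }

  out <- lab
  lin <- rep.int(rng[[1]], nb[2] * nb[3]) +
    dm[1] * (rep.int(rep(rng[[2]], each = nb[1]), nb[3]) - 1L) +
    dm[1] * dm[2] * (rep(rng[[3]], each = nb[1] * nb[2]) - 1L)
  editable <- lab[lin] <= 1L  # leave IVH/distractor labels untouched
  le <- lin[editable]
  out[le] <- 0L
  out[le[new1[editable]]] <- 1L
  new_lv(out, sp)
}

# Rasterise a radially deformed ellipsoid directly: a voxel at offset u
# from the centre is inside iff q(u) <= scale(u/|u|)^2, where q is the
# ellipsoid quadratic form and scale the same radial deformation used by
# perturb_mask (same angular field, same seed convention). Only voxels in
# the thin q-shell [smin^2, smax^2] need the angular field, which makes
# cohort-scale phantom generation cheap. Used by build_phantom.
rasterize_deformed_ellipsoid <- function(semi_axes_mm, spacing_mm, grid_shape,
                                         irregularity, seed,
                                         max_amplitude = 0.35) {
  if (irregularity == 0) {
    return(make_ellipsoid_mask(semi_axes_mm, spacing_mm, grid_shape))
  }
  field <- angular_field(seed)
  dirs <- fib_dirs(1024L)
  r_ell3 <- (colSums(t(dirs)^2 / semi_axes_mm^2))^(-3 / 2)
  sc <- deform_scale(field, irregularity, max_amplitude, weights = r_ell3)
  centre <- (grid_shape - 1) / 2 * spacing_mm
  half_extent <- (grid_shape - 1) * spacing_mm / 2
  if (any(semi_axes_mm * sc$smax > half_extent - spacing_mm)) {
    stop(sprintf(
      "deformed ellipsoid (semi-axes %s mm, max scale %.2f) exceeds grid bounds",
      paste(round(semi_axes_mm, 1), collapse = "x"), sc$smax))
  }
  labels <- array(0L, grid_shape)
  rng <- lapply(1:3, function(i) {
    reach <- semi_axes_mm[i] * sc$smax
    lo <- max(1L, floor((centre[i] - reach) / spacing_mm[i]) + 1L)
    hi <- min(grid_shape[i], ceiling((centre[i] + reach) / spacing_mm[i]) + 1L)
    lo:hi
  })
  nbx <- lengths(rng)
  ox <- (rng[[1]] - 1) * spacing_mm[1] - centre[1]
  oy <- (rng[[2]] - 1) * spacing_mm[2] - centre[2]
  oz <- (rng[[3]] - 1) * spacing_mm[3] - centre[3]
  ux <- rep.int(ox, nbx[2] * nbx[3])
  uy <- rep.int(rep(oy, each = nbx[1]), nbx[3])
  uz <- rep(oz, each = nbx[1] * nbx[2])
  q <- (ux / semi_axes_mm[1])^2 + (uy / semi_axes_mm[2])^2 +
    (uz / semi_axes_mm[3])^2
  inside <- q <= sc$smin^2
  shell <- which(q > sc$smin^2 & q <= sc$smax^2)
  if (length(shell)) {
    r <- sqrt(ux[shell]^2 + uy[shell]^2 + uz[shell]^2)
    r[r == 0] <- 1
    scale <- (1 + sc$amp * field$f(ux[shell] / r, uy[shell] / r,
                                   uz[shell] / r)) / sc$cnorm
    inside[shell] <- q[shell] <= scale^2
  }
  sub <- array(0L, nbx)
  sub[inside] <- 1L
  labels[rng[[1]], rng[[2]], rng[[3]]] <- sub
  n1 <- sum(inside)
  new_lv(labels, spacing_mm,
         counts = c(prod(grid_shape) - n1, n1, 0L, 0L))
}

#' Attach an intraventricular haemorrhage component
#'
#' Grows a contiguous label-2 (IVH) region abutting the existing label-1
#' (ICH) region, emulating extension of the haematoma into the ventricular
#' system. The region is grown voxel-by-voxel by breadth-first search from a
#' background voxel on the ICH surface, so its voxel volume matches the
#' target exactly (to one voxel) and it always shares a face with the ICH.
#' Label-1 voxels are never modified: IVH is, by the study convention, not
#' part of the ICH volume.
#'
#' @param volume a [labeled_volume()] with a nonempty label-1 region.
#' @param target_ivh_volume_mL positive target IVH volume (mL).
#' @param seed integer seed controlling the growth direction.
#' @return A [labeled_volume()] with the added label-2 region.
#' @export
add_ivh_component <- function(volume, target_ivh_volume_mL, seed) {
  stopifnot_volume(volume)
  if (!is.numeric(target_ivh_volume_mL) || target_ivh_volume_mL <= 0) {
    stop("`target_ivh_volume_mL` must be positive")
  }
  lab <- volume$labels
  if (!any(lab == 1L)) stop("add_ivh_component requires a nonempty ICH (label 1) region")
  sp <- volume$spacing_mm
  dm <- dim(lab)
  n_target <- max(1L, round(target_ivh_volume_mL / voxel_mL(volume)))
  if (n_target > sum(lab == 0L)) {
    stop(sprintf("IVH target of %.1f mL (%d voxels) exceeds remaining grid capacity",
                 target_ivh_volume_mL, n_target))
  }
  idx1 <- which(lab == 1L, arr.ind = TRUE)
  ctr <- colMeans(idx1)
  seed_idx <- with_seed(seed, {
    found <- NULL
    for (try in 1:50) {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      # surface voxel of the ICH furthest along d, then step outward
      proj <- as.vector((t(t(idx1) - ctr) %*% d))
      p <- idx1[which.max(proj), ]
      for (step in 1:5) {
        cand <- round(p + step * d)
        if (all(cand >= 1) && all(cand <= dm) &&
            lab[cand[1], cand[2], cand[3]] == 0L) {
          found <- cand
          break
        }
      }
      if (!is.null(found)) break
    }
    found
  })
  if (is.null(seed_idx)) {
    stop("could not place an IVH seed adjacent to the ICH: grid too tight")
  }
  # grow inside a local sub-box around the seed (ample for a compact blob)
  half <- ceiling(2.5 * (3 * n_target / (4 * pi))^(1 / 3)) + 4L
  lo <- pmax(seed_idx - half, 1L)
  hi <- pmin(seed_idx + half, dm)
  sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == 0L
  picked <- grow_region(sub, seed_idx - lo + 1L, n_target, sp)
  picked <- sweep(picked, 2, lo - 1L, "+")
  lab[picked] <- 2L
  counts <- volume$counts
  if (!is.null(counts)) {
    counts[1] <- counts[1] - nrow(picked)
    counts[3] <- counts[3] + nrow(picked)
  }
  new_lv(lab, sp, counts = counts)
}

#' Add distractor hyperdensities
#'
#' Adds small label-3 blobs away from the haematoma (emulating dura, skull
#' base, vessels and calcifications that automated segmenters pick up) and,
#' optionally, a thin label-3 shell at the grid boundary. Labels 1 and 2 are
#' unchanged. With `n_blobs = 0` and `rim = FALSE` the volume is returned
#' unchanged.
#'
#' @param volume a [labeled_volume()].
#' @param n_blobs number of distractor blobs (each 1--2 mL).
#' @param rim if `TRUE`, add a one-voxel-thick boundary shell.
#' @param seed integer seed.
#' @param clearance_vox margin (voxels) kept between blobs and the
#'   haematoma bounding box.
#' @return A [labeled_volume()] with added label-3 voxels.
#' @export
add_distractors <- function(volume, n_blobs, rim = FALSE, seed = 1L,
                            clearance_vox = 4L) {
  stopifnot_volume(volume)
  n_blobs <- as.integer(n_blobs)
  if (n_blobs < 0) stop("`n_blobs` must be nonnegative")
  if (n_blobs == 0L && !rim) return(volume)
  lab <- volume$labels
  sp <- volume$spacing_mm
  dm <- dim(lab)

  with_seed(seed, {
    if (n_blobs > 0L) {
      lesion <- which(lab == 1L | lab == 2L, arr.ind = TRUE)
      in_box <- array(FALSE, dm)
      if (nrow(lesion)) {
        lo <- pmax(apply(lesion, 2, min) - clearance_vox, 1)
        hi <- pmin(apply(lesion, 2, max) + clearance_vox, dm)
        in_box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
      }
      # base eligibility: background, away from the lesion, off the
      # 2-voxel boundary margin so a later rim shell stays separate
      base_ok <- lab == 0L & !dilate6(lab == 1L | lab == 2L)
      base_ok[c(1:2, dm[1] - 1:0), , ] <- FALSE
      base_ok[, c(1:2, dm[2] - 1:0), ] <- FALSE
      base_ok[, , c(1:2, dm[3] - 1:0)] <- FALSE
      forb3 <- dilate6(lab == 3L)  # updated incrementally per blob
      nxy <- dm[1] * dm[2]
      for (b in seq_len(n_blobs)) {
        target_mL <- stats::runif(1, 1, 2)
        n_target <- max(1L, round(target_mL / voxel_mL(volume)))
        allowed <- base_ok & !forb3
        candidates <- which(allowed & !in_box)
        if (!length(candidates)) candidates <- which(allowed)  # tight grid
        if (!length(candidates)) {
          stop("could not place a distractor blob away from the lesion")
        }
        seed_lin <- candidates[sample.int(length(candidates), 1)]
        seed_idx <- arrayInd(seed_lin, dm)
        picked <- grow_region(allowed, as.integer(seed_idx), n_target, sp)
        lab[picked] <- 3L
        # mark the blob and its 6-neighbourhood as forbidden (blobs sit
        # >= 2 voxels from the grid faces, so offset arithmetic is safe)
        plin <- picked[, 1] + dm[1] * (picked[, 2] - 1L) + nxy * (picked[, 3] - 1L)
        forb3[c(plin, plin + 1L, plin - 1L, plin + dm[1], plin - dm[1],
                plin + nxy, plin - nxy)] <- TRUE
      }
    }
    if (rim) {
      shell <- array(FALSE, dm)
      shell[c(1L, dm[1]), , ] <- TRUE
      shell[, c(1L, dm[2]), ] <- TRUE
      shell[, , c(1L, dm[3])] <- TRUE
      lab[shell & lab == 0L] <- 3L
    }
    NULL
  })
  new_lv(lab, sp)
}

# 6-neighbour binary dilation
dilate6 <- function(mask) {
  if (!any(mask)) return(mask)
  padded <- pad_false(mask)
  dmp <- dim(padded)
  out <- padded
  for (o in padded_offsets(dmp)) {
    lin <- which(padded) + o
    out[lin] <- TRUE
  }
  dm <- dim(mask)
  out[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
}

#' Reslice a volume to a thicker axial slice
#'
#' Aggregates groups of axial slices into slabs, assigning each output voxel
#' the majority label across the slab. Ties are broken toward the higher
#' clinical priority 1 (ICH) > 2 (IVH) > 3 (distractor) > 0 (background),
#' so the measurand is preserved at slab boundaries. Emulates CT
#' acquisitions at 1, 3 or 5 mm slice thickness.
#'
#' @param volume a [labeled_volume()].
#' @param new_thickness_mm target axial thickness; must be an integer
#'   multiple of the current z-spacing.
#' @return A [labeled_volume()] with unchanged in-plane spacing and
#'   z-spacing equal to `new_thickness_mm`.
#' @export
reslice_axial <- function(volume, new_thickness_mm) {
  stopifnot_volume(volume)
  sz <- volume$spacing_mm[3]
  k <- new_thickness_mm / sz
  if (abs(k - round(k)) > 1e-8 || k < 1) {
    stop(sprintf("new thickness %.3g mm is not an integer multiple of the current z-spacing %.3g mm",
                 new_thickness_mm, sz))
  }
  k <- as.integer(round(k))
  if (k == 1L) return(volume)
  lab <- volume$labels
  dm <- dim(lab)
  nz_out <- as.integer(ceiling(dm[3] / k))
  out <- array(0L, c(dm[1], dm[2], nz_out))
  for (s in seq_len(nz_out)) {
    zz <- ((s - 1L) * k + 1L):min(s * k, dm[3])
    slab <- lab[, , zz, drop = FALSE]
    best_count <- rowSums(slab == 0L, dims = 2)
    best_label <- array(0L, dm[1:2])
    for (L in c(3L, 2L, 1L)) {  # increasing priority; >= lets priority win ties
      cnt <- rowSums(slab == L, dims = 2)
      take <- cnt >= best_count & cnt > 0L
      best_label[take] <- L
      best_count <- pmax(best_count, cnt)
    }
    out[, , s] <- best_label
  }
  new_lv(out, c(volume$spacing_mm[1:2], new_thickness_mm))
}
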