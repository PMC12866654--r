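#' Labeled voxel volume
#'
#' The common container of the phantom and volumetry code: a 3D integer
#' label grid with per-axis voxel spacing. Label codes follow the study
#' convention: 0 = background, 1 = intracerebral haemorrhage (ICH),
#' 2 = intraventricular haemorrhage (IVH), 3 = distractor hyperdensity
#' (dura-like, calcification-like or rim artefacts). The third array axis
#' is the axial (slice) axis. Voxel centres sit at
#' `(index - 1) * spacing_mm` in world millimetres (0-based world origin,
#' no rotation).
#'
#' @param labels 3D integer array with values in \{0, 1, 2, 3\}.
#' @param spacing_mm positive numeric triple `(sx, sy, sz)`; `sz` is the
#'   axial slice thickness.
#' @return An object of class `labeled_volume`: a list with elements
#'   `labels` and `spacing_mm`.
#' @examples
#' vol <- labeled_volume(array(0L, c(8, 8, 8)), c(1, 1, 1))
#' dim(vol$labels)
#' @export
labeled_volume <- function(labels, spacing_mm) {
  if (length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array")
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be a positive numeric triple")
  }
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% 0:3)
  if (any(bad)) {
    stop("labels must be in {0, 1, 2, 3}; found ",
         paste(unique(labels[bad]), collapse = ", "))
  }
  structure(list(labels = labels, spacing_mm = spacing_mm),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  dm <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              dm[1], dm[2], dm[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  counts <- label_counts(x)
  cat(sprintf("  ICH %.2f mL, IVH %.2f mL, distractor %.2f mL\n",
              counts[["1"]] * voxel_mL(x), counts[["2"]] * voxel_mL(x),
              counts[["3"]] * voxel_mL(x)))
  invisible(x)
}

# Internal fast constructor for label grids already known to be valid.
# `counts` optionally carries the exact per-label voxel counts when the
# builder knows them, sparing a full-grid rescan downstream.
new_lv <- function(labels, spacing_mm, counts = NULL) {
  structure(list(labels = labels, spacing_mm = spacing_mm, counts = counts),
            class = "labeled_volume")
}

# all four label volumes (mL), from cached counts or one pass over the grid
label_volumes_mL <- function(volume) {
  counts <- volume$counts
  if (is.null(counts)) counts <- tabulate(volume$labels + 1L, nbins = 4L)
  stats::setNames(counts * voxel_mL(volume), c("0", "1", "2", "3"))
}

#' Test for the labeled_volume class
#' @param x object to test.
#' @return `TRUE` if `x` is a `labeled_volume`.
#' @export
is_labeled_volume <- function(x) inherits(x, "labeled_volume")

# volume of one voxel in mL
voxel_mL <- function(volume) prod(volume$spacing_mm) / 1000

label_counts <- function(volume) {
  out <- c("0" = 0, "1" = 0, "2" = 0, "3" = 0)
  tab <- table(volume$labels)
  out[names(tab)] <- as.numeric(tab)
  out
}

stopifnot_volume <- function(volume) {
  if (!is_labeled_volume(volume)) stop("expected a `labeled_volume`")
  invisible(volume)
}

#' Write a labeled mask as NIfTI
#'
#' Masks are written with an integer datatype and a diagonal affine that
#' carries the voxel spacing (no rotation component).
#'
#' @param volume a [labeled_volume()].
#' @param path output path; conventionally ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(volume, path) {
  stopifnot_volume(volume)
  img <- RNifti::asNifti(volume$labels, internal = FALSE)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read a labeled mask from NIfTI
#'
#' @param path path to a NIfTI file written by [write_mask_nifti()] or any
#'   integer-valued label image with a diagonal affine.
#' @return A [labeled_volume()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  labeled_volume(array(as.integer(round(img)), dim(img)),
                 RNifti::pixdim(img)[1:3])
}

# ---- low-level voxel utilities ------------------------------------------

# Pad a logical array with one layer of FALSE so 6-neighbour linear-index
# arithmetic never wraps across faces.
pad_false <- function(mask) {
  dm <- dim(mask)
  out <- array(FALSE, dm + 2L)
  out[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- mask
  out
}

padded_offsets <- function(dmp) {
  c(-1L, 1L, -dmp[1], dmp[1], -dmp[1] * dmp[2], dmp[1] * dmp[2])
}

# linear index in padded array for 1-based original array indices (n x 3)
pad_linear <- function(idx, dmp) {
  (idx[, 1] + 1L) + dmp[1] * (idx[, 2]) + dmp[1] * dmp[2] * (idx[, 3])
}

unpad_arr_ind <- function(lin, dmp) {
  k <- (lin - 1L) %/% (dmp[1] * dmp[2])
  r <- (lin - 1L) %% (dmp[1] * dmp[2])
  j <- r %/% dmp[1]
  i <- r %% dmp[1]
  cbind(i, j, k)  # 0-based padded -> equals 1-based original indices
}

#' Count 6-connected components of a label
#'
#' Flood fill over the face-adjacency graph; used to check contiguity of
#' generated haematoma and distractor regions.
#'
#' @param volume a [labeled_volume()].
#' @param label label code whose components are counted.
#' @return integer component count (0 for an absent label).
#' @export
mask_components <- function(volume, label = 1L) {
  stopifnot_volume(volume)
  mask <- volume$labels == label
  if (!any(mask)) return(0L)
  dm <- dim(mask)
  padded <- pad_false(mask)
  dmp <- dim(padded)
  offs <- padded_offsets(dmp)
  todo <- which(padded)
  remaining <- padded
  n_comp <- 0L
  while (length(todo)) {
    seedlin <- todo[1]
    if (!remaining[seedlin]) {
      todo <- todo[remaining[todo]]
      next
    }
    n_comp <- n_comp + 1L
    frontier <- seedlin
    remaining[frontier] <- FALSE
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[remaining[nb]]
      remaining[nb] <- FALSE
      frontier <- nb
    }
    todo <- todo[remaining[todo]]
  }
  n_comp
}

# Voxel surface area (mm^2) of a label region: count of faces exposed to a
# different label, times the face area. Used for shape-irregularity checks.
mask_surface_area <- function(volume, label = 1L) {
  mask <- volume$labels == label
  if (!any(mask)) return(0)
  sp <- volume$spacing_mm
  padded <- pad_false(mask)
  dmp <- dim(padded)
  lin <- which(padded)
  offs <- padded_offsets(dmp)
  face_area <- c(sp[2] * sp[3], sp[2] * sp[3], sp[1] * sp[3],
                 sp[1] * sp[3], sp[1] * sp[2], sp[1] * sp[2])
  total <- 0
  for (d in seq_along(offs)) {
    total <- total + sum(!padded[lin + offs[d]]) * face_area[d]
  }
  total
}

# Grow a contiguous region of `n_target` voxels by breadth-first search
# from `seed_idx` (1-based [i, j, k]) over `allowed` (logical array).
# The final BFS layer is trimmed by world distance to the seed so the
# voxel count is met exactly. Returns a matrix of 1-based voxel indices.
grow_region <- function(allowed, seed_idx, n_target, spacing_mm) {
  dm <- dim(allowed)
  padded <- pad_false(allowed)
  dmp <- dim(padded)
  offs <- padded_offsets(dmp)
  seed_lin <- pad_linear(matrix(seed_idx, 1L), dmp)
  if (!padded[seed_lin]) stop("seed voxel is not in the allowed region")
  picked <- integer(0)
  frontier <- seed_lin
  padded[frontier] <- FALSE
  while (length(picked) < n_target && length(frontier)) {
    need <- n_target - length(picked)
    if (length(frontier) > need) {
      # trim by distance to the seed centre to keep the blob compact
      idx0 <- unpad_arr_ind(frontier, dmp)
      d2 <- colSums((t(idx0) - as.numeric(seed_idx))^2 * spacing_mm^2)
      frontier <- frontier[order(d2)][seq_len(need)]
    }
    picked <- c(picked, frontier)
    nb <- unique(as.vector(outer(frontier, offs, "+")))
    nb <- nb[padded[nb]]
    padded[nb] <- FALSE
    frontier <- nb
  }
  if (length(picked) < n_target) {
    stop(sprintf("could not grow region to %d voxels (reached %d): grid capacity exhausted",
                 n_target, length(picked)))
  }
  unpad_arr_ind(picked, dmp)
}

# Evaluate a function with a temporary RNG state; restores (or removes)
# .Random.seed afterwards so seeded helpers do not disturb the caller.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}
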