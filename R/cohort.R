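#' Cohort configuration
#'
#' Parameters of the synthetic haematoma cohort. Defaults reproduce the
#' study conditions: lognormal ICH volumes calibrated to a median of
#' 26.0 mL with IQR 9.3--59.2 mL, 50% IVH prevalence, 66% basal
#' ganglia/thalamus location, and 1 mm axial slices (the thinnest
#' acquisition, which most scans in the study had).
#'
#' The lognormal is calibrated from the printed quantiles:
#' \eqn{\mu = \ln(\mathrm{median})} and
#' \eqn{\sigma = \ln(q_{75}/q_{25}) / (2 \cdot 0.67449)}, where 0.67449 is
#' the 75th percentile of the standard normal.
#'
#' @param n_cases number of cases.
#' @param volume_median_mL median true ICH volume (mL).
#' @param volume_iqr_mL quartile pair `c(q25, q75)` (mL).
#' @param ivh_prevalence probability that a case has accompanying IVH.
#' @param basal_ganglia_fraction probability of a basal ganglia/thalamus
#'   (vs lobar) location.
#' @param irregularity_range range of the shape-irregularity parameter;
#'   basal ganglia/thalamus cases are drawn from the lower half of the
#'   range and lobar cases from the upper half (deep haematomas are the
#'   more ellipsoid ones).
#' @param ivh_fraction_range IVH volume as a fraction of ICH volume,
#'   drawn uniformly for IVH-positive cases.
#' @param slice_thickness_mm axial slice thickness: 1, 3 or 5 mm.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 300L,
                          volume_median_mL = 26.0,
                          volume_iqr_mL = c(9.3, 59.2),
                          ivh_prevalence = 0.5,
                          basal_ganglia_fraction = 0.66,
                          irregularity_range = c(0.1, 0.6),
                          ivh_fraction_range = c(0.05, 0.40),
                          slice_thickness_mm = 1,
                          seed = 1L) {
  n_cases <- as.integer(n_cases)
  if (n_cases < 1L) stop("`n_cases` must be >= 1")
  if (!(volume_iqr_mL[1] < volume_median_mL &&
        volume_median_mL < volume_iqr_mL[2])) {
    stop("need q25 < median < q75")
  }
  if (ivh_prevalence < 0 || ivh_prevalence > 1) {
    stop("`ivh_prevalence` must be in [0, 1]")
  }
  if (basal_ganglia_fraction < 0 || basal_ganglia_fraction > 1) {
    stop("`basal_ganglia_fraction` must be in [0, 1]")
  }
  if (!slice_thickness_mm %in% c(1, 3, 5)) {
    stop("`slice_thickness_mm` must be 1, 3 or 5")
  }
  structure(list(
    n_cases = n_cases,
    volume_median_mL = volume_median_mL,
    volume_iqr_mL = as.numeric(volume_iqr_mL),
    ivh_prevalence = ivh_prevalence,
    basal_ganglia_fraction = basal_ganglia_fraction,
    irregularity_range = as.numeric(irregularity_range),
    ivh_fraction_range = as.numeric(ivh_fraction_range),
    slice_thickness_mm = slice_thickness_mm,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Lognormal parameters implied by a median and IQR
#'
#' @param median_mL distribution median.
#' @param iqr_mL quartile pair `c(q25, q75)`.
#' @return `c(meanlog, sdlog)`.
#' @examples
#' lognormal_from_quantiles(26.0, c(9.3, 59.2))  # sdlog approx 1.372
#' @export
lognormal_from_quantiles <- function(median_mL, iqr_mL) {
  c(meanlog = log(median_mL),
    sdlog = log(iqr_mL[2] / iqr_mL[1]) / (2 * stats::qnorm(0.75)))
}

# draw per-case parameters (no masks); the single source of cohort randomness
sample_cohort_params <- function(config) {
  lp <- lognormal_from_quantiles(config$volume_median_mL, config$volume_iqr_mL)
  n <- config$n_cases
  with_seed(config$seed, {
    vol <- stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
    ivh <- stats::runif(n) < config$ivh_prevalence
    ivh_frac <- stats::runif(n, config$ivh_fraction_range[1],
                             config$ivh_fraction_range[2])
    loc <- ifelse(stats::runif(n) < config$basal_ganglia_fraction,
                  "basal_ganglia_thalamus", "lobar")
    ir <- config$irregularity_range
    mid <- mean(ir)
    irregularity <- ifelse(loc == "basal_ganglia_thalamus",
                           stats::runif(n, ir[1], mid),
                           stats::runif(n, mid, ir[2]))
    # ellipsoid aspect ratios (b/a, c/a); axial axis the shortest
    rb <- stats::runif(n, 0.6, 0.95)
    rc <- stats::runif(n, 0.4, 0.8)
    data.frame(
      case_id = sprintf("case_%04d", seq_len(n)),
      true_ich_volume_mL = vol,
      true_ivh_volume_mL = ifelse(ivh, ivh_frac * vol, 0),
      location = loc,
      ivh_present = ivh,
      irregularity = irregularity,
      slice_thickness_mm = config$slice_thickness_mm,
      axis_ratio_b = rb,
      axis_ratio_c = rc,
      n_distractors = sample(0:3, n, replace = TRUE),
      rim = stats::runif(n) < 0.5,
      case_seed = sample.int(.Machine$integer.max - 1L, n),
      stringsAsFactors = FALSE
    )
  })
}

# build one phantom mask from a parameter row; 1 mm generation grid resliced
# to the configured axial thickness
build_phantom <- function(par, gen_spacing_mm = 1, distractors = TRUE) {
  v_mm3 <- par$true_ich_volume_mL * 1000
  a <- (3 * v_mm3 / (4 * pi * par$axis_ratio_b * par$axis_ratio_c))^(1 / 3)
  semi <- c(a, a * par$axis_ratio_b, a * par$axis_ratio_c)
  # auto-size the grid: deformation margin + room for the IVH component
  ivh_r <- if (par$ivh_present) {
    (3 * par$true_ivh_volume_mL * 1000 / (4 * pi))^(1 / 3)
  } else 0
  # margin: the case's own radial deformation bound, plus room for the
  # IVH component and a border for distractors/rim
  sc <- deform_scale(angular_field(par$case_seed), par$irregularity, 0.35)
  need <- 2 * semi * sc$smax + 2 * ivh_r + 14
  shape <- pmax(48L, as.integer(ceiling(need / gen_spacing_mm)))
  shape <- shape + shape %% 2L
  vol <- rasterize_deformed_ellipsoid(semi, rep(gen_spacing_mm, 3), shape,
                                      par$irregularity,
                                      seed = par$case_seed)
  if (par$ivh_present) {
    vol <- add_ivh_component(vol, par$true_ivh_volume_mL,
                             seed = par$case_seed + 1L)
  }
  if (distractors && (par$n_distractors > 0 || par$rim)) {
    vol <- add_distractors(vol, par$n_distractors, rim = par$rim,
                           seed = par$case_seed + 2L)
  }
  if (par$slice_thickness_mm != gen_spacing_mm) {
    vol <- reslice_axial(vol, par$slice_thickness_mm)
  }
  vol
}

#' Sample a synthetic haematoma cohort
#'
#' Draws the cohort-level ground truth (volumes, IVH status, location,
#' irregularity) and, optionally, rasterises a 3D phantom mask per case.
#' True ICH volumes are lognormal with parameters implied by the configured
#' median and IQR (see [lognormal_from_quantiles()]). IVH-positive cases
#' receive an IVH volume that is a uniform fraction of the ICH volume.
#' When masks are generated, the ground-truth volumes are re-measured from
#' the final voxel masks so the truth table and mask volumes agree exactly.
#'
#' @param config a [cohort_config()].
#' @param masks if `TRUE` (default) generate a phantom mask per case;
#'   `FALSE` returns only the ground-truth table (useful for large-n
#'   distributional checks and for the parametric auto-segmentation
#'   simulator, which needs no voxels).
#' @return A list with `truth` (data frame: case_id, true_ich_volume_mL,
#'   true_ivh_volume_mL, location, ivh_present, irregularity,
#'   slice_thickness_mm) and, if `masks`, `volumes` (named list of
#'   [labeled_volume()]). Per-case generation failures abort with the case
#'   id in the message.
#' @export
sample_cohort <- function(config, masks = TRUE) {
  params <- sample_cohort_params(config)
  truth_cols <- c("case_id", "true_ich_volume_mL", "true_ivh_volume_mL",
                  "location", "ivh_present", "irregularity",
                  "slice_thickness_mm")
  if (!masks) {
    return(list(truth = params[truth_cols], params = params))
  }
  vols <- vector("list", nrow(params))
  names(vols) <- params$case_id
  for (i in seq_len(nrow(params))) {
    vols[[i]] <- tryCatch(build_phantom(params[i, ]),
                          error = function(e) {
                            stop(sprintf("case %s: %s", params$case_id[i],
                                         conditionMessage(e)), call. = FALSE)
                          })
    lv <- label_volumes_mL(vols[[i]])
    params$true_ich_volume_mL[i] <- lv[["1"]]
    params$true_ivh_volume_mL[i] <- lv[["2"]]
  }
  list(truth = params[truth_cols], volumes = vols, params = params)
}

#' Write / read the cohort ground-truth table
#'
#' @param truth ground-truth data frame from [sample_cohort()].
#' @param path CSV path.
#' @return `path` (write) or the truth data frame (read).
#' @export
write_cohort_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_truth
#' @export
read_cohort_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a cohort configuration as YAML
#'
#' Field names in the YAML file match the arguments of [cohort_config()]
#' one-to-one.
#'
#' @param path YAML path.
#' @param config a [cohort_config()].
#' @return A [cohort_config()] (read) or `path` (write).
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
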