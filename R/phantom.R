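#' Synthetic TOF-MRA phantom configuration
#'
#' Describes a synthetic vascular phantom emulating the statistical structure
#' of a TOF-MRA aneurysm study: a large, mostly empty noisy volume, bright
#' tubular vessels (random-walk capsule chains), and a handful of tiny bright
#' saccular lesions attached to vessel walls.  The aneurysm voxels are a
#' minuscule fraction of the volume, reproducing the severe class imbalance
#' that motivates disequilibrium culling and the loss ensembles.
#'
#' Lesions are given slightly higher intensity than vessels so a reduced
#' network can identify them at CPU scale; real TOF-MRA aneurysms are
#' essentially isointense with their parent vessel, and this deliberate
#' simplification is documented in the methods vignette.
#'
#' @param volume_shape Integer length-3 (Z, Y, X); default 128x256x256.
#' @param spacing Voxel spacing (Z, Y, X) mm; default (0.8, 0.5, 0.5).
#' @param n_vessels Number of vessel random walks.
#' @param vessel_radius_mm Range of vessel radii (mm), one radius per vessel.
#' @param n_aneurysms Number of saccular lesions to attach to vessel walls.
#' @param aneurysm_diameter_mm Diameter range (mm); the default 3-7 mm is the
#'   clinically common size class for detectable intracranial aneurysms.
#' @param vessel_intensity,aneurysm_intensity,background_intensity Pre-noise
#'   intensities (arbitrary units).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `oto_phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(128, 256, 256),
                           spacing = c(0.8, 0.5, 0.5),
                           n_vessels = 6, vessel_radius_mm = c(1, 2.5),
                           n_aneurysms = 3, aneurysm_diameter_mm = c(3, 7),
                           vessel_intensity = 150, aneurysm_intensity = 220,
                           background_intensity = 20, noise_sigma = 15,
                           seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 8L),
            length(spacing) == 3L, all(spacing > 0),
            n_vessels >= 1, n_aneurysms >= 0,
            diff(range(vessel_radius_mm)) >= 0, all(vessel_radius_mm > 0),
            all(aneurysm_diameter_mm > 0), noise_sigma >= 0)
  if (aneurysm_intensity <= background_intensity + 3 * noise_sigma)
    stop("aneurysm intensity must exceed background by > 3 noise sigma",
         call. = FALSE)
  structure(list(volume_shape = volume_shape, spacing = as.numeric(spacing),
                 n_vessels = n_vessels, vessel_radius_mm = vessel_radius_mm,
                 n_aneurysms = n_aneurysms,
                 aneurysm_diameter_mm = aneurysm_diameter_mm,
                 vessel_intensity = vessel_intensity,
                 aneurysm_intensity = aneurysm_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "oto_phantom_config")
}

# One smooth random-walk vessel as a chain of capsule segments, bouncing off
# the physical bounding box.  Returns a matrix of segments (z0,y0,x0,
# z1,y1,x1, radius) in mm.
walk_vessel <- function(ext, radius, step_mm = 8, wobble = 0.35) {
  margin <- radius + 1
  lo <- rep(margin, 3); hi <- ext - margin
  p <- lo + stats::runif(3) * (hi - lo)
  d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
  n_steps <- max(4L, ceiling(1.2 * max(ext) / step_mm))
  segs <- matrix(0, n_steps, 7)
  for (i in seq_len(n_steps)) {
    d <- d + wobble * stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    q <- p + step_mm * d
    for (k in 1:3) {           # reflect at the padded box faces
      if (q[k] < lo[k]) { q[k] <- 2 * lo[k] - q[k]; d[k] <- -d[k] }
      if (q[k] > hi[k]) { q[k] <- 2 * hi[k] - q[k]; d[k] <- -d[k] }
      q[k] <- min(max(q[k], lo[k]), hi[k])
    }
    segs[i, ] <- c(p, q, radius)
    p <- q
  }
  segs
}

#' Generate one synthetic phantom case
#'
#' Rasterizes the configured vessels, attaches aneurysm spheres to randomly
#' chosen vessel-wall points (retrying placement until the lesion fits
#' inside the volume and does not touch a previously placed lesion), adds
#' Gaussian noise, and returns the image, the aneurysm-only label mask
#' (vessels are background -- the segmentation target is the lesion, not the
#' vasculature), and per-lesion truth metadata.
#'
#' @param cfg An [phantom_config()].
#' @return A list of class `oto_phantom_case` with `image` ([volume()]),
#'   `label` ([label_mask()]), and `meta` (data frame of lesion centres in
#'   mm and diameters).
#' @export
generate_case <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "oto_phantom_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  d <- cfg$volume_shape
  sp <- cfg$spacing
  ext <- (d - 1) * sp  # physical position of the last voxel centre

  radii <- stats::runif(cfg$n_vessels, min(cfg$vessel_radius_mm),
                        max(cfg$vessel_radius_mm))
  segs <- do.call(rbind, lapply(radii, function(r) walk_vessel(ext, r)))

  img <- array(cfg$background_intensity, d)
  img <- cpp_paint_capsules(img, d, sp, segs,
                            rep(cfg$vessel_intensity, nrow(segs)))

  meta <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                     diameter = numeric(0))
  spheres <- NULL
  if (cfg$n_aneurysms > 0) {
    placed <- 0
    tries <- 0
    sep_pad <- 2 * max(sp)
    while (placed < cfg$n_aneurysms) {
      tries <- tries + 1
      if (tries > 200 * cfg$n_aneurysms)
        stop("could not place all aneurysms on vessel walls; reduce their ",
             "number or size", call. = FALSE)
      diam <- stats::runif(1, min(cfg$aneurysm_diameter_mm),
                           max(cfg$aneurysm_diameter_mm))
      ra <- diam / 2
      si <- sample.int(nrow(segs), 1)
      t <- stats::runif(1)
      axis_pt <- segs[si, 1:3] + t * (segs[si, 4:6] - segs[si, 1:3])
      nrm <- stats::rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
      centre <- axis_pt + segs[si, 7] * nrm  # on the vessel wall
      if (any(centre < ra) || any(centre > ext - ra)) next
      if (!is.null(spheres)) {
        dc <- sqrt(rowSums(sweep(spheres[, 1:3, drop = FALSE], 2, centre)^2))
        if (any(dc < spheres[, 4] + ra + sep_pad)) next
      }
      spheres <- rbind(spheres, c(centre, ra))
      meta <- rbind(meta, data.frame(z = centre[1], y = centre[2],
                                     x = centre[3], diameter = diam))
      placed <- placed + 1
    }
    sph_segs <- cbind(spheres[, 1:3, drop = FALSE],
                      spheres[, 1:3, drop = FALSE],
                      spheres[, 4, drop = FALSE])
    img <- cpp_paint_capsules(img, d, sp, sph_segs,
                              rep(cfg$aneurysm_intensity, nrow(sph_segs)))
    lab <- cpp_paint_capsules(array(0, d), d, sp, sph_segs,
                              rep(1, nrow(sph_segs)))
  } else {
    lab <- array(0, d)
  }
  dim(img) <- d; dim(lab) <- d

  frac <- mean(lab > 0)
  if (frac >= 0.01)
    stop(sprintf(paste0("phantom foreground fraction %.3g violates the < 1%% ",
                        "imbalance guarantee; enlarge the volume or shrink ",
                        "lesions"), frac), call. = FALSE)

  if (cfg$noise_sigma > 0)
    img <- img + array(stats::rnorm(prod(d), 0, cfg$noise_sigma), d)

  id <- sprintf("phantom-seed%d", cfg$seed)
  structure(list(image = volume(img, sp, id),
                 label = label_mask(lab, sp, paste0(id, "-label")),
                 meta = meta),
            class = "oto_phantom_case")
}

#' @export
print.oto_phantom_case <- function(x, ...) {
  cat(sprintf("<phantom case> %s, %d lesion(s), foreground %.4g%%\n",
              paste(dim(x$image$data), collapse = "x"), nrow(x$meta),
              100 * mean(x$label$data)))
  invisible(x)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` image/label NIfTI pairs plus a `manifest.csv` with a
#' train/test split.  Per-case seeds are derived deterministically from the
#' config seed, so regenerating with the same config reproduces identical
#' files.
#'
#' @param cfg An [phantom_config()]; its `seed` seeds the whole dataset.
#' @param n_cases Number of cases.
#' @param out_dir Output directory (created if needed).
#' @param n_train Number of cases tagged `train`; the rest are `test`
#'   (labels are written for test cases too, for evaluation).
#' @return The [load_manifest()]-validated manifest, invisibly.
#' @export
generate_dataset <- function(cfg = phantom_config(), n_cases = 5,
                             out_dir, n_train = ceiling(0.6 * n_cases)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    ci <- cfg
    ci$seed <- cfg$seed + i * 7919L  # distinct deterministic per-case seeds
    cs <- generate_case(ci)
    img_p <- sprintf("case%03d_image.nii.gz", i)
    lab_p <- sprintf("case%03d_label.nii.gz", i)
    write_volume(cs$image, file.path(out_dir, img_p))
    write_volume(cs$label, file.path(out_dir, lab_p))
    rows[[i]] <- data.frame(image = img_p, label = lab_p,
                            split = if (i <= n_train) "train" else "test")
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(load_manifest(file.path(out_dir, "manifest.csv")))
}
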