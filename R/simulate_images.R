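# Synthetic fluorescence microscopy: filamentous and fragmented
# mitochondria-like objects, Gaussian PSF, Poisson shot noise, and a
# two-group x two-treatment study generator with planted effects.

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards; with seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for one simulated microscopy field
#'
#' Defaults describe a fibroblast-like field: a mostly filamentous network
#' (curvilinear objects ~5 um long, ~0.4 um wide) with a minority of
#' fragmented (elliptical) mitochondria, imaged at 0.1 um/px through a
#' Gaussian point-spread function with Poisson shot noise.
#'
#' @param image_shape Field size in pixels, `c(rows, cols)`.
#' @param n_slices Number of z-slices (1 = single plane; slices share object
#'   placement with per-slice Gaussian z-weighting, 0.2 um step).
#' @param pixel_size_um Pixel size (um/px).
#' @param n_objects Number of mitochondrial objects per field.
#' @param filament_length_um Mean and sd of filament length, `c(mean, sd)`.
#' @param filament_width_um Rendered filament width (um).
#' @param branching_prob Probability a filament carries one side-branch.
#' @param fragment_fraction Proportion of objects drawn as ellipses
#'   (fragments) instead of filaments.
#' @param fragment_axes_um Mean full major/minor axes of fragments, um.
#' @param psf_sigma_um Gaussian PSF standard deviation (um).
#' @param background_level Mean background photon count per pixel.
#' @param photon_scale Photon count per unit of object signal.
#' @param marker_enrichment Multiplicative marker-channel intensity on the
#'   mitochondrial signal.
#' @param seed Integer seed; the same config gives bit-identical output.
#' @return Validated list of class `image_sim_config`.
#' @export
image_sim_config <- function(image_shape = c(256L, 256L), n_slices = 1L,
                             pixel_size_um = 0.1, n_objects = 30L,
                             filament_length_um = c(5, 1.5),
                             filament_width_um = 0.4,
                             branching_prob = 0.3,
                             fragment_fraction = 0.2,
                             fragment_axes_um = c(0.9, 0.55),
                             psf_sigma_um = 0.15,
                             background_level = 10,
                             photon_scale = 120,
                             marker_enrichment = 1,
                             seed = NULL) {
  cfg <- list(image_shape = as.integer(image_shape), n_slices = as.integer(n_slices),
              pixel_size_um = pixel_size_um, n_objects = as.integer(n_objects),
              filament_length_um = filament_length_um,
              filament_width_um = filament_width_um,
              branching_prob = branching_prob,
              fragment_fraction = fragment_fraction,
              fragment_axes_um = fragment_axes_um,
              psf_sigma_um = psf_sigma_um,
              background_level = background_level,
              photon_scale = photon_scale,
              marker_enrichment = marker_enrichment,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (length(cfg$image_shape) != 2L || any(cfg$image_shape < 8L))
    stop("image_shape must be two positive dimensions (>= 8 px)")
  if (cfg$n_slices < 1L) stop("n_slices must be >= 1")
  for (p in c("branching_prob", "fragment_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  for (p in c("pixel_size_um", "filament_width_um", "psf_sigma_um"))
    if (cfg[[p]] <= 0) stop(p, " must be positive")
  if (any(cfg$filament_length_um <= 0) || any(cfg$fragment_axes_um <= 0))
    stop("lengths and axes must be positive")
  if (cfg$background_level < 0 || cfg$photon_scale < 0)
    stop("background_level and photon_scale must be non-negative")
  if (cfg$marker_enrichment < 0) stop("marker_enrichment must be non-negative")
  structure(cfg, class = "image_sim_config")
}

disc_offsets <- function(radius_px) {
  r <- max(0L, as.integer(round(radius_px)))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius_px^2 + 1e-9, , drop = FALSE]
}

# smooth random-walk centerline; returns integer pixel coordinates
filament_pixels <- function(start, length_px, nr, nc) {
  n_steps <- max(4L, as.integer(round(length_px)))
  theta0 <- stats::runif(1, 0, 2 * pi)
  dtheta <- pmax(-0.5, pmin(0.5, stats::rnorm(n_steps, 0, 0.22)))
  theta <- theta0 + cumsum(dtheta)
  xr <- start[1] + cumsum(sin(theta))
  xc <- start[2] + cumsum(cos(theta))
  # cubic-spline smoothing through every 4th knot, densely resampled
  knots <- unique(c(seq(1L, n_steps, by = 4L), n_steps))
  if (length(knots) >= 4L) {
    tt <- seq(1, n_steps, length.out = 2L * n_steps)
    xr <- stats::spline(knots, xr[knots], xout = tt, method = "natural")$y
    xc <- stats::spline(knots, xc[knots], xout = tt, method = "natural")$y
  }
  rr <- pmin(pmax(round(xr), 1L), nr)
  cc <- pmin(pmax(round(xc), 1L), nc)
  unique(cbind(rr, cc))
}

fragment_pixels <- function(center, a_px, b_px, phi, nr, nc) {
  r <- ceiling(max(a_px, b_px)) + 1L
  g <- expand.grid(dr = -r:r, dc = -r:r)
  u <- g$dc * cos(phi) + g$dr * sin(phi)
  v <- -g$dc * sin(phi) + g$dr * cos(phi)
  g <- g[(u / a_px)^2 + (v / b_px)^2 <= 1, , drop = FALSE]
  rr <- pmin(pmax(center[1] + g$dr, 1L), nr)
  cc <- pmin(pmax(center[2] + g$dc, 1L), nc)
  unique(cbind(rr, cc))
}

dilate_pixels <- function(px, offsets, nr, nc) {
  rr <- outer(px[, 1], offsets$dr, `+`)
  cc <- outer(px[, 2], offsets$dc, `+`)
  keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  unique(cbind(as.vector(rr)[keep], as.vector(cc)[keep]))
}

#' Simulate one two-channel microscopy field
#'
#' Renders filaments as spline-smoothed random-walk curves of the configured
#' length (optionally with one side-branch) and fragments as filled ellipses,
#' convolves the clean rendering with the Gaussian PSF, and applies Poisson
#' noise to `background + photon_scale * signal`. The marker channel carries
#' `marker_enrichment` times the mitochondrial signal over the same
#' background. The truth mask is the pre-blur binary rendering.
#'
#' @param config An [image_sim_config()].
#' @return List: `mito` and `marker` (`calibrated_image`, 2D or z-stack),
#'   `truth_mask` (logical 2D), `truth_table` (one row per object: type,
#'   size, pixel count, z-center).
#' @export
simulate_mito_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  with_seed(config$seed, {
    nr <- config$image_shape[1]; nc <- config$image_shape[2]
    px_um <- config$pixel_size_um
    nz <- config$n_slices
    width_off <- disc_offsets(config$filament_width_um / 2 / px_um)
    margin_r <- max(2L, round(nr * 0.08)); margin_c <- max(2L, round(nc * 0.08))
    signal <- array(0, c(nr, nc, nz))
    truth_mask <- matrix(FALSE, nr, nc)
    rows <- list()
    n_frag <- if (config$n_objects > 0)
      stats::rbinom(1, config$n_objects, config$fragment_fraction) else 0L
  types <- c(rep("fragment", n_frag),
             rep("filament", config$n_objects - n_frag))
    for (i in seq_len(config$n_objects)) {
      type <- types[i]
      start <- c(sample(margin_r:(nr - margin_r), 1),
                 sample(margin_c:(nc - margin_c), 1))
      if (type == "filament") {
        len_um <- max(0.5, stats::rnorm(1, config$filament_length_um[1],
                                        config$filament_length_um[2]))
        ctr <- filament_pixels(start, len_um / px_um, nr, nc)
        if (stats::runif(1) < config$branching_prob) {
          j <- sample(nrow(ctr), 1)
          br <- filament_pixels(c(ctr[j, 1], ctr[j, 2]),
                                0.45 * len_um / px_um, nr, nc)
          ctr <- unique(rbind(ctr, br))
        }
        obj <- dilate_pixels(ctr, width_off, nr, nc)
        size_um <- len_um
      } else {
        a <- max(2 * px_um, stats::rnorm(1, config$fragment_axes_um[1],
                                         0.15 * config$fragment_axes_um[1]))
        b <- max(1.5 * px_um, stats::rnorm(1, config$fragment_axes_um[2],
                                           0.15 * config$fragment_axes_um[2]))
        phi <- stats::runif(1, 0, pi)
        obj <- fragment_pixels(start, a / 2 / px_um, b / 2 / px_um, phi, nr, nc)
        size_um <- a
      }
      inten <- stats::runif(1, 0.7, 1.3)
      zc <- if (nz > 1L) stats::runif(1, 1, nz) else 1
      zw <- if (nz > 1L) exp(-(seq_len(nz) - zc)^2 / 2) else 1
      for (z in seq_len(nz))
        signal[, , z][obj] <- signal[, , z][obj] + inten * zw[z]
      truth_mask[obj] <- TRUE
      rows[[i]] <- data.frame(object = i, type = type, size_um = size_um,
                              n_px = nrow(obj), intensity = inten, z_center = zc)
    }
    truth_table <- if (length(rows)) do.call(rbind, rows) else
      data.frame(object = integer(0), type = character(0), size_um = numeric(0),
                 n_px = integer(0), intensity = numeric(0), z_center = numeric(0))
    psf_px <- config$psf_sigma_um / px_um
    mito <- array(0, c(nr, nc, nz)); marker <- array(0, c(nr, nc, nz))
    for (z in seq_len(nz)) {
      blurred <- gaussian_blur2d(signal[, , z], psf_px)
      mito_clean <- config$background_level + config$photon_scale * blurred
      marker_clean <- config$background_level +
        config$marker_enrichment * config$photon_scale * blurred
      mito[, , z] <- stats::rpois(nr * nc, as.vector(mito_clean))
      marker[, , z] <- stats::rpois(nr * nc, as.vector(marker_clean))
    }
    if (nz == 1L) { mito <- mito[, , 1]; marker <- marker[, , 1] }
    list(mito = calibrated_image(mito, px_um, "mito", bit_depth = 16L),
         marker = calibrated_image(marker, px_um, "marker", bit_depth = 16L),
         truth_mask = truth_mask,
         truth_table = truth_table)
  })
}

#' Balanced two-group x two-treatment imaging study design
#'
#' @param base_config An [image_sim_config()] shared by all study cells.
#' @param n_subjects_per_group Subjects per genotype group.
#' @param n_fov_per_sample Fields of view per subject and treatment.
#' @param groups,treatments Level names (reference levels first).
#' @param overrides Named list, names `"GROUP.TREATMENT"`, each a list of
#'   config fields replacing the base config in that cell. The default
#'   plants elevated fragmentation in depolarized (CCCP) cells of both
#'   genotypes, and none in the mutant genotype per se.
#' @param seed Study-level seed; per-field seeds are derived from it.
#' @return List of class `study_design`.
#' @export
study_design <- function(base_config = image_sim_config(),
                         n_subjects_per_group = 5L, n_fov_per_sample = 5L,
                         groups = c("CTRL", "MUT"),
                         treatments = c("DMSO", "CCCP"),
                         overrides = list(
                           CTRL.CCCP = list(fragment_fraction = 0.8),
                           MUT.CCCP = list(fragment_fraction = 0.8)),
                         seed = 1L) {
  if (n_subjects_per_group < 1L || n_fov_per_sample < 1L)
    stop("need at least one subject and one field of view per sample")
  stopifnot(inherits(base_config, "image_sim_config"))
  bad <- setdiff(names(overrides),
                 as.vector(outer(groups, treatments, paste, sep = ".")))
  if (length(bad)) stop("override names must be GROUP.TREATMENT; bad: ",
                        paste(bad, collapse = ", "))
  structure(list(base_config = base_config,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_fov_per_sample = as.integer(n_fov_per_sample),
                 groups = groups, treatments = treatments,
                 overrides = overrides, seed = as.integer(seed)),
            class = "study_design")
}

cell_config <- function(design, group, treatment, seed) {
  cfg <- unclass(design$base_config)
  ov <- design$overrides[[paste(group, treatment, sep = ".")]]
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg$seed <- seed
  do.call(image_sim_config, cfg)
}

#' Simulate a full imaging study
#'
#' One image set per subject x treatment x field of view, with per-field
#' seeds derived deterministically from the study seed.
#'
#' @param design A [study_design()].
#' @return List of class `image_study_set`: `images` (list of
#'   [simulate_mito_image()] results) and `metadata` (one row per field:
#'   subject, group, treatment, fov, index into `images`).
#' @export
simulate_population <- function(design) {
  stopifnot(inherits(design, "study_design"))
  images <- list(); meta <- list(); idx <- 0L
  for (gi in seq_along(design$groups)) {
    for (si in seq_len(design$n_subjects_per_group)) {
      subject <- sprintf("%s%d", substr(design$groups[gi], 1, 1), si)
      for (trt in design$treatments) {
        for (fov in seq_len(design$n_fov_per_sample)) {
          idx <- idx + 1L
          seed_i <- (design$seed + 7919L * idx) %% 2147483629L
          cfg <- cell_config(design, design$groups[gi], trt, seed_i)
          images[[idx]] <- simulate_mito_image(cfg)
          meta[[idx]] <- data.frame(subject = subject,
                                    group = design$groups[gi],
                                    treatment = trt, fov = fov, index = idx)
        }
      }
    }
  }
  structure(list(images = images, metadata = do.call(rbind, meta),
                 design = design),
            class = "image_study_set")
}

#' Write a simulated study to TIFF files plus metadata and truth CSVs
#'
#' Each channel goes to a 16-bit multi-page TIFF (one page per z-slice);
#' `metadata.csv` lists subject, group, treatment, fov and the two file
#' paths, `truth.csv` concatenates the per-field truth tables.
#'
#' @param study An `image_study_set`.
#' @param dir Output directory (created if needed).
#' @return The metadata data.frame (invisibly), with path columns.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "image_study_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  md <- study$metadata
  md$path_mito <- NA_character_; md$path_marker <- NA_character_
  truth <- list()
  for (i in seq_len(nrow(md))) {
    tag <- sprintf("%s_%s_fov%d", md$subject[i], md$treatment[i], md$fov[i])
    sim <- study$images[[md$index[i]]]
    for (ch in c("mito", "marker")) {
      path <- file.path(dir, sprintf("%s_%s.tif", tag, ch))
      px <- sim[[ch]]$pixels / 65535
      EBImage::writeImage(EBImage::Image(px), path, type = "tiff",
                          bits.per.sample = 16L)
      md[[paste0("path_", ch)]][i] <- path
    }
    tt <- sim$truth_table
    tt$subject <- md$subject[i]; tt$treatment <- md$treatment[i]
    tt$fov <- md$fov[i]
    truth[[i]] <- tt
  }
  utils::write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(md)
}

#' Read a calibrated TIFF written by [write_study()]
#' @param path TIFF path.
#' @param pixel_size_um Calibration (um/px).
#' @param channel Channel label.
#' @return A `calibrated_image` (photon-count scale).
#' @export
read_calibrated_tiff <- function(path, pixel_size_um, channel = "gray") {
  px <- EBImage::imageData(EBImage::readImage(path)) * 65535
  px <- round(px)
  dimnames(px) <- NULL
  if (length(dim(px)) == 3L && dim(px)[3L] == 1L) px <- px[, , 1]
  calibrated_image(px, pixel_size_um, channel, bit_depth = 16L)
}

#' Fast distribution-level study generator for statistical calibration
#'
#' Draws per-particle shape-descriptor values directly from condition-level
#' mixture distributions, bypassing image rendering: each field of view gets
#' a Poisson number of particles, each particle is a fragment with the
#' cell's `fragment_fraction` probability, and fragments/filaments draw
#' circularity, roundness and solidity from beta distributions whose modes
#' match what the image pipeline measures on rendered objects. This is the
#' generator used for type-I-error and power calibration of the KS-distance
#' plus ANOVA procedure, where hundreds of simulated studies are needed.
#'
#' @param fragment_fraction Named numeric, one entry per study cell
#'   (`"GROUP.TREATMENT"`). Defaults plant fragmentation under CCCP only.
#' @param n_subjects_per_group,n_fov_per_sample Design size.
#' @param n_particles_mean Mean particles per field of view.
#' @param seed Integer seed.
#' @return Particle data.frame with subject, group, treatment, fov,
#'   circularity, roundness, solidity.
#' @export
simulate_particle_study <- function(fragment_fraction = c(CTRL.DMSO = 0.2,
                                                          CTRL.CCCP = 0.8,
                                                          MUT.DMSO = 0.2,
                                                          MUT.CCCP = 0.8),
                                    n_subjects_per_group = 5L,
                                    n_fov_per_sample = 5L,
                                    n_particles_mean = 120,
                                    seed = NULL) {
  groups <- c("CTRL", "MUT"); treatments <- c("DMSO", "CCCP")
  with_seed(seed, {
    out <- list()
    for (g in groups) for (si in seq_len(n_subjects_per_group))
      for (trt in treatments) for (fov in seq_len(n_fov_per_sample)) {
        ff <- fragment_fraction[[paste(g, trt, sep = ".")]]
        n <- stats::rpois(1, n_particles_mean) + 20L
        frag <- stats::runif(n) < ff
        circ <- ifelse(frag, stats::rbeta(n, 9, 2.5), stats::rbeta(n, 1.8, 6))
        rnd <- ifelse(frag, stats::rbeta(n, 8, 3), stats::rbeta(n, 2, 6))
        sol <- ifelse(frag, stats::rbeta(n, 12, 2), stats::rbeta(n, 5, 4))
        out[[length(out) + 1L]] <- data.frame(
          subject = sprintf("%s%d", substr(g, 1, 1), si), group = g,
          treatment = trt, fov = fov,
          circularity = circ, roundness = rnd, solidity = sol)
      }
    do.call(rbind, out)
  })
}
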