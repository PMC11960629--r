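#' Phantom parameter ranges
#'
#' Ranges (in micrometres unless stated) from which cloacal phantom geometry
#' is drawn. The discriminative anatomy is the number of phallic cones on
#' the tissue surface: three for males, two for females. Cone size ranges
#' default to 200–600 µm width and 150–400 µm height so that cones are
#' resolvable at a 4 µm lateral pitch yet still survive aggressive
#' downsampling of the final image.
#'
#' @param surface_depth range of the mean tissue-surface depth below the
#'   zero-delay line.
#' @param surface_tilt range of surface slope (µm depth per µm lateral).
#' @param cone_width,cone_height,cone_amplitude ranges for cone geometry and
#'   backscatter amplitude (amplitude is a reflectivity in \[0, 1\]).
#' @param cone_spacing range of lateral spacing between neighbouring cones.
#' @param layer_thickness,layer_reflectivity ranges for the sub-surface
#'   tissue layers (three layers are drawn).
#' @param attenuation_coeff range of the per-µm exponential depth
#'   attenuation inside tissue.
#' @param speckle_scale multiplicative speckle magnitude passed through to
#'   the scanner (0 = noise free).
#' @param lateral_fov lateral field of view in µm (phantom coordinates).
#' @return a list of ranges with class `"phantom_params"`.
#' @export
phantom_params <- function(surface_depth = c(700, 1100),
                           surface_tilt = c(-0.04, 0.04),
                           cone_width = c(200, 600),
                           cone_height = c(150, 400),
                           cone_amplitude = c(0.7, 1.0),
                           cone_spacing = c(700, 1100),
                           layer_thickness = c(150, 400),
                           layer_reflectivity = c(0.15, 0.45),
                           attenuation_coeff = c(0.0008, 0.0018),
                           speckle_scale = 0.15,
                           lateral_fov = 4000) {
  p <- list(surface_depth = surface_depth, surface_tilt = surface_tilt,
            cone_width = cone_width, cone_height = cone_height,
            cone_amplitude = cone_amplitude, cone_spacing = cone_spacing,
            layer_thickness = layer_thickness,
            layer_reflectivity = layer_reflectivity,
            attenuation_coeff = attenuation_coeff,
            speckle_scale = speckle_scale, lateral_fov = lateral_fov)
  structure(p, class = "phantom_params")
}

runif_range <- function(r, n = 1L) {
  if (length(r) == 1L) rep(r, n) else runif(n, r[1L], r[2L])
}

#' Generate a cloacal tissue phantom
#'
#' Draws a parametric cross-section of the chick cloaca: a gently tilted
#' tissue surface with layered interior, and phallic cones protruding from
#' the surface — three if `sex` is `"male"`, two if `"female"`. For
#' `"ambiguous"` phantoms the cones are fully occluded (absent), emulating
#' frames where the anatomy cannot be seen.
#'
#' @param sex `"female"`, `"male"` or `"ambiguous"`.
#' @param params ranges from [phantom_params()].
#' @param seed integer; identical `(sex, params, seed)` gives a
#'   bit-identical phantom.
#' @return an object of class `"oct_phantom"`: fields `sex`, `cone_count`,
#'   `cones` (data frame: `lateral_center`, `depth_apex`, `width`, `height`,
#'   `amplitude`), `layers` (data frame: `depth`, `thickness`,
#'   `reflectivity`), `surface_depth`, `surface_tilt`, `attenuation_coeff`,
#'   `speckle_scale`, `seed`.
#' @examples
#' ph <- make_phantom("male", seed = 7)
#' ph$cone_count  # 3
#' @export
make_phantom <- function(sex, params = phantom_params(), seed = 1L) {
  if (!is.character(sex) || length(sex) != 1L ||
      !sex %in% c(SEX_LEVELS, "ambiguous"))
    stopf("sex must be one of 'female', 'male', 'ambiguous', got '%s'",
          paste(sex, collapse = ","))
  with_seed(seed, {
    n_cones <- switch(sex, male = 3L, female = 2L, ambiguous = 0L)
    surf <- runif_range(params$surface_depth)
    tilt <- runif_range(params$surface_tilt)
    fov <- params$lateral_fov

    cones <- if (n_cones > 0L) {
      spacing <- runif_range(params$cone_spacing)
      centers <- fov / 2 + (seq_len(n_cones) - (n_cones + 1) / 2) * spacing +
        runif(n_cones, -60, 60)
      w <- runif_range(params$cone_width, n_cones)
      h <- runif_range(params$cone_height, n_cones)
      a <- runif_range(params$cone_amplitude, n_cones)
      data.frame(lateral_center = centers,
                 depth_apex = surf + tilt * (centers - fov / 2) - h,
                 width = w, height = h, amplitude = a)
    } else {
      data.frame(lateral_center = numeric(0), depth_apex = numeric(0),
                 width = numeric(0), height = numeric(0),
                 amplitude = numeric(0))
    }
    layers <- data.frame(
      depth = cumsum(c(0, runif_range(params$layer_thickness, 2L))),
      thickness = runif_range(params$layer_thickness, 3L),
      reflectivity = c(runif(1, 0.45, 0.65),
                      runif_range(params$layer_reflectivity, 2L)))
    structure(list(
      sex = sex, cone_count = n_cones, cones = cones, layers = layers,
      surface_depth = surf, surface_tilt = tilt,
      attenuation_coeff = runif_range(params$attenuation_coeff),
      speckle_scale = params$speckle_scale,
      lateral_fov = fov, seed = seed), class = "oct_phantom")
  })
}

#' @export
print.oct_phantom <- function(x, ...) {
  cat(sprintf("cloacal phantom: sex=%s, %d cone(s), surface %.0f um, seed %d\n",
              x$sex, x$cone_count, x$surface_depth, x$seed))
  invisible(x)
}

# perturb a base (per-chick) phantom for one frame: ±10 % size jitter,
# small lateral/axial shifts — frames of one chick share base anatomy
jitter_phantom <- function(phantom, seed, occlude = FALSE,
                           size_jitter = 0.10) {
  with_seed(seed, {
    ph <- phantom
    if (occlude) {
      ph$cones <- ph$cones[0, ]
      ph$cone_count <- 0L
      ph$sex_frame <- "ambiguous"
    } else if (nrow(ph$cones) > 0L) {
      n <- nrow(ph$cones)
      ph$cones$width <- ph$cones$width * runif(n, 1 - size_jitter, 1 + size_jitter)
      ph$cones$height <- ph$cones$height * runif(n, 1 - size_jitter, 1 + size_jitter)
      ph$cones$lateral_center <- ph$cones$lateral_center + runif(n, -50, 50)
      ph$cones$depth_apex <- ph$surface_depth +
        ph$surface_tilt * (ph$cones$lateral_center - ph$lateral_fov / 2) -
        ph$cones$height
    }
    ph$surface_depth <- ph$surface_depth + runif(1, -30, 30)
    ph
  })
}

#' Rasterize a phantom onto a reflectivity grid
#'
#' Renders the phantom into a `depth_rows x n_lateral` grid of backscatter
#' reflectivities in \[0, 1\] — the forward-model input of the OCT engine.
#' Column `j` is lateral position `j * lateral_pitch` µm; row `i` is depth
#' `i * depth_pitch` µm. Cones appear as bright wedges protruding above the
#' layered tissue surface; reflectivity decays exponentially with depth
#' below the local tissue top (attenuation).
#'
#' @param phantom an `"oct_phantom"`.
#' @param depth_rows,n_lateral grid dimensions.
#' @param depth_pitch,lateral_pitch pixel pitches in µm (positive).
#' @return list of class `"reflectivity_map"`: `values` (matrix in \[0,1\]),
#'   `depth_pitch`, `lateral_pitch`, `cone_mask` (logical matrix marking the
#'   protruding cone region).
#' @examples
#' m <- rasterize_phantom(make_phantom("female", seed = 2),
#'                        depth_rows = 150, n_lateral = 200,
#'                        depth_pitch = 16, lateral_pitch = 20)
#' range(m$values)
#' @export
rasterize_phantom <- function(phantom, depth_rows, n_lateral,
                              depth_pitch, lateral_pitch) {
  if (depth_pitch <= 0 || lateral_pitch <= 0)
    stopf("pixel pitches must be positive")
  x <- seq_len(n_lateral) * lateral_pitch
  z <- seq_len(depth_rows) * depth_pitch
  fov_mid <- phantom$lateral_fov / 2

  surf <- phantom$surface_depth + phantom$surface_tilt * (x - fov_mid)

  prot <- numeric(n_lateral)
  amp <- numeric(n_lateral)
  if (nrow(phantom$cones) > 0L) {
    for (k in seq_len(nrow(phantom$cones))) {
      cone <- phantom$cones[k, ]
      p <- cone$height * pmax(0, 1 - 2 * abs(x - cone$lateral_center) / cone$width)
      take <- p > prot
      prot[take] <- p[take]
      amp[take] <- cone$amplitude
    }
  }
  top <- surf - prot

  Z <- matrix(z, nrow = depth_rows, ncol = n_lateral)
  TOPm <- matrix(top, nrow = depth_rows, ncol = n_lateral, byrow = TRUE)
  SURFm <- matrix(surf, nrow = depth_rows, ncol = n_lateral, byrow = TRUE)

  tissue <- Z >= TOPm
  cone_region <- tissue & (Z < SURFm)
  if (!any(tissue) && phantom$sex != "ambiguous")
    warning("phantom structures entirely outside the imaging field")

  vals <- matrix(0, depth_rows, n_lateral)
  # layered interior: reflectivity by depth below the nominal surface
  below <- Z - SURFm
  breaks <- phantom$layers$depth
  li <- findInterval(pmax(below, 0), c(breaks[-1L], Inf)) + 1L
  li <- pmin(li, nrow(phantom$layers))
  interior <- tissue & !cone_region
  vals[interior] <- phantom$layers$reflectivity[li[interior]]
  # cone wedges take the cone amplitude
  AMPm <- matrix(amp, nrow = depth_rows, ncol = n_lateral, byrow = TRUE)
  vals[cone_region] <- AMPm[cone_region]
  # exponential attenuation with depth into tissue
  vals[tissue] <- vals[tissue] *
    exp(-phantom$attenuation_coeff * (Z - TOPm))[tissue]

  structure(list(values = clip01(vals), depth_pitch = depth_pitch,
                 lateral_pitch = lateral_pitch, cone_mask = cone_region),
            class = "reflectivity_map")
}

#' Cohort specification
#'
#' Describes a simulated flock: the study design is 30 chicks (half male),
#' 50 frames captured per chick of which 40 are retained by quality
#' selection, giving 1200 images.
#'
#' @param n_chicks number of chicks (default 30; at least 2).
#' @param frames_per_chick frames captured per chick (default 50).
#' @param keep_per_chick frames retained after quality selection
#'   (default 40; at most `frames_per_chick`).
#' @param sex_balance fraction of male chicks (default 0.5).
#' @param ambiguous_rate fraction of frames with fully occluded anatomy
#'   (true "not detect" frames; default 0.05).
#' @param seed integer master seed.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_chicks = 30L, frames_per_chick = 50L,
                        keep_per_chick = 40L, sex_balance = 0.5,
                        ambiguous_rate = 0.05, seed = 1L) {
  n_chicks <- as.integer(n_chicks)
  if (n_chicks < 2L) stopf("need at least 2 chicks (cannot split otherwise)")
  if (keep_per_chick > frames_per_chick)
    stopf("keep_per_chick (%d) exceeds frames_per_chick (%d)",
          keep_per_chick, frames_per_chick)
  if (sex_balance < 0 || sex_balance > 1) stopf("sex_balance must be in [0,1]")
  structure(list(n_chicks = n_chicks,
                 frames_per_chick = as.integer(frames_per_chick),
                 keep_per_chick = as.integer(keep_per_chick),
                 sex_balance = sex_balance, ambiguous_rate = ambiguous_rate,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a phantom cohort
#'
#' Samples per-chick base anatomy once, then jitters it per frame, so that
#' the frames of one chick share geometry — emulating repeated scans at
#' different locations around the cloacal region. A fraction
#' `ambiguous_rate` of frames have their cones occluded and carry the frame
#' label `"ambiguous"`.
#'
#' @param spec a [cohort_spec()].
#' @param params [phantom_params()] ranges shared by all chicks.
#' @return data-frame-like list of class `"oct_cohort"` with elements
#'   `frames` (list of phantoms) and `manifest` (data frame: `chick_id`,
#'   `frame_index`, `sex` of the chick, `label` of the frame).
#' @examples
#' co <- make_cohort(cohort_spec(n_chicks = 4, frames_per_chick = 3))
#' nrow(co$manifest)  # 12
#' @export
make_cohort <- function(spec = cohort_spec(), params = phantom_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_male <- as.integer(round(spec$n_chicks * spec$sex_balance))
  sexes <- rep(c("male", "female"), c(n_male, spec$n_chicks - n_male))
  seeds <- derive_seeds(spec$seed, spec$n_chicks * (spec$frames_per_chick + 2L))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }

  frames <- vector("list", spec$n_chicks * spec$frames_per_chick)
  rows <- vector("list", length(frames))
  idx <- 0L
  for (c_i in seq_len(spec$n_chicks)) {
    base <- make_phantom(sexes[c_i], params, seed = nxt())
    occl <- with_seed(nxt(),
      runif(spec$frames_per_chick) < spec$ambiguous_rate)
    for (f_i in seq_len(spec$frames_per_chick)) {
      idx <- idx + 1L
      frames[[idx]] <- jitter_phantom(base, seed = nxt(), occlude = occl[f_i])
      rows[[idx]] <- data.frame(
        chick_id = c_i, frame_index = f_i, sex = sexes[c_i],
        label = if (occl[f_i]) "ambiguous" else sexes[c_i])
    }
  }
  structure(list(frames = frames, manifest = do.call(rbind, rows),
                 spec = spec), class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  tab <- table(x$manifest$sex[!duplicated(x$manifest$chick_id)])
  cat(sprintf("OCT phantom cohort: %d chicks (%s), %d frames\n",
              x$spec$n_chicks,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$manifest)))
  invisible(x)
}

#' Serialize a cohort to JSON
#'
#' One record per frame: chick ID, frame index, sex, frame label, and the
#' frame's cone geometry.
#'
#' @param cohort an `"oct_cohort"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
cohort_to_json <- function(cohort, path) {
  recs <- lapply(seq_along(cohort$frames), function(i) {
    ph <- cohort$frames[[i]]
    m <- cohort$manifest[i, ]
    list(chick_id = m$chick_id, frame_index = m$frame_index,
         sex = m$sex, label = m$label, seed = ph$seed,
         cone_count = ph$cone_count, surface_depth = ph$surface_depth,
         cones = ph$cones)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
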