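# Deterministic sub-seed for a named generator stream, derived from the
# master seed. Keeps every derived seed a valid 32-bit integer.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Sample aggregate lengths from the truncated geometric law
#'
#' Draws monomer counts by inverse-CDF sampling on the finite support
#' `[n_min, n_max]` of the truncated geometric distribution (see
#' [dtruncgeom()]) and converts them to nanometre lengths by dividing by
#' the monomers-per-nm factor.
#'
#' @param alpha decay parameter in (0, 1).
#' @param n_min,n_max inclusive support bounds (monomers).
#' @param count number of draws (may be 0).
#' @param seed optional integer seed.
#' @param conversion_factor monomers per nm (length_nm = monomers / factor).
#' @return data frame with columns `monomers` (integer) and `length_nm`.
#' @export
generate_length_sample <- function(alpha, n_min = 500L, n_max = 1200L,
                                   count, seed = NULL,
                                   conversion_factor = 4) {
  check_alpha(alpha)
  check_support(n_min, n_max)
  if (count < 0) stop("`count` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (count == 0L)
    return(data.frame(monomers = integer(0), length_nm = numeric(0)))
  support <- n_min:n_max
  pmf <- dtruncgeom(support, alpha, n_min, n_max)
  cdf <- cumsum(pmf)
  cdf[length(cdf)] <- 1
  u <- stats::runif(count)
  m <- support[findInterval(u, cdf, left.open = TRUE) + 1L]
  data.frame(monomers = as.integer(m), length_nm = m / conversion_factor)
}

#' Scene specification for the synthetic localisation generator
#'
#' Collects every tunable of the synthetic imaging scene: field-of-view
#' geometry, synaptosome population, aggregate length/shape law, the
#' localisation budget per aggregate, background localisation density and
#' the membrane-stain image model. Defaults emulate a widefield acquisition
#' (210 nm camera pixels) of antibody-captured synaptosomes with
#' super-resolved localisations at 20 nm precision.
#'
#' @param fov_size_nm field of view, `c(width, height)` in nm.
#' @param pixel_size_nm camera pixel size of the membrane-stain image (nm).
#' @param n_synaptosomes number of synaptosome discs to place.
#' @param synaptosome_radius_nm mean disc radius (nm).
#' @param synaptosome_radius_sd_nm disc radius spread (nm).
#' @param occupancy_fraction probability that a synaptosome contains at
#'   least one aggregate.
#' @param aggregates_per_occupied distribution of aggregate counts in an
#'   occupied synaptosome: `list(type = "shifted_poisson", lambda = ...)`
#'   draws `1 + Poisson(lambda)`; `list(type = "constant", value = k)` is
#'   deterministic.
#' @param aggregate_length_law either
#'   `list(type = "truncgeom", alpha=, n_min=, n_max=, conversion_factor=,
#'   ecc_high_frac=, ecc_high_range=, ecc_low_range=)` (lengths from the
#'   truncated geometric law, eccentricities from a two-component uniform
#'   mixture) or `list(type = "pairs", length_nm=, eccentricity=)` with
#'   explicit per-aggregate values recycled as needed.
#' @param localisations_per_aggregate
#'   `list(type = "shifted_poisson", lambda = , min = )`: draws
#'   `Poisson(lambda)` truncated below at `min`.
#' @param localisation_precision_nm nominal localisation precision reported
#'   in the table's `sigma` column (nm).
#' @param background_density spurious localisations per square micrometre.
#' @param extra_synaptic_aggregate_count aggregates placed outside all
#'   synaptosome discs.
#' @param membrane_background,membrane_peak membrane-stain image model:
#'   constant background counts and peak blob amplitude above background
#'   (Poisson shot noise is applied to the sum).
#' @param seed master integer seed; all sub-streams derive from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(fov_size_nm = c(40000, 40000),
                       pixel_size_nm = 210,
                       n_synaptosomes = 50L,
                       synaptosome_radius_nm = 500,
                       synaptosome_radius_sd_nm = 50,
                       occupancy_fraction = 0.2,
                       aggregates_per_occupied = list(type = "shifted_poisson", lambda = 0.5),
                       aggregate_length_law = list(type = "truncgeom", alpha = 0.995,
                                                   n_min = 500L, n_max = 1200L,
                                                   conversion_factor = 4,
                                                   ecc_high_frac = 0.25,
                                                   ecc_high_range = c(0.93, 0.99),
                                                   ecc_low_range = c(0.2, 0.8)),
                       localisations_per_aggregate = list(type = "shifted_poisson",
                                                          lambda = 150, min = 20L),
                       localisation_precision_nm = 20,
                       background_density = 0.05,
                       extra_synaptic_aggregate_count = 0L,
                       membrane_background = 100,
                       membrane_peak = 300,
                       seed = 1L) {
  spec <- list(fov_size_nm = fov_size_nm, pixel_size_nm = pixel_size_nm,
               n_synaptosomes = as.integer(n_synaptosomes),
               synaptosome_radius_nm = synaptosome_radius_nm,
               synaptosome_radius_sd_nm = synaptosome_radius_sd_nm,
               occupancy_fraction = occupancy_fraction,
               aggregates_per_occupied = aggregates_per_occupied,
               aggregate_length_law = aggregate_length_law,
               localisations_per_aggregate = localisations_per_aggregate,
               localisation_precision_nm = localisation_precision_nm,
               background_density = background_density,
               extra_synaptic_aggregate_count = as.integer(extra_synaptic_aggregate_count),
               membrane_background = membrane_background,
               membrane_peak = membrane_peak,
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (length(fov_size_nm) != 2L || any(fov_size_nm <= 0))
      stop("`fov_size_nm` must be two positive lengths")
    if (pixel_size_nm <= 0) stop("`pixel_size_nm` must be positive")
    if (n_synaptosomes < 0) stop("`n_synaptosomes` must be non-negative")
    if (synaptosome_radius_nm <= 0) stop("`synaptosome_radius_nm` must be positive")
    if (occupancy_fraction < 0 || occupancy_fraction > 1)
      stop("`occupancy_fraction` must lie in [0, 1]")
    if (localisation_precision_nm <= 0)
      stop("`localisation_precision_nm` must be positive")
    if (background_density < 0) stop("`background_density` must be non-negative")
    if (extra_synaptic_aggregate_count < 0)
      stop("`extra_synaptic_aggregate_count` must be non-negative")
  })
  invisible(spec)
}

draw_count <- function(dist, n) {
  switch(dist$type,
    shifted_poisson = {
      minv <- if (is.null(dist$min)) 1L else as.integer(dist$min)
      if (is.null(dist$min)) {
        1L + stats::rpois(n, dist$lambda)
      } else {
        pmax(minv, stats::rpois(n, dist$lambda))
      }
    },
    constant = rep(as.integer(dist$value), n),
    stop("unknown count distribution type: ", dist$type)
  )
}

# variance of a standard normal hard-truncated at +/- 2 sd, as a fraction
# of the untruncated variance; used to convert planted length/eccentricity
# into cloud covariance so that measured moments match the planted values
TRUNC2_VAR_FACTOR <- local({
  z <- 2
  1 - 2 * z * stats::dnorm(z) / (2 * stats::pnorm(z) - 1)
})

# sample n draws from N(0, sigma^2) truncated at +/- 2 sigma (inverse CDF)
rtnorm2 <- function(n, sigma) {
  p <- stats::pnorm(-2)
  u <- stats::runif(n, p, 1 - p)
  sigma * stats::qnorm(u)
}

draw_length_ecc <- function(law, n) {
  if (law$type == "pairs") {
    idx <- rep_len(seq_along(law$length_nm), n)
    return(data.frame(length_nm = law$length_nm[idx],
                      eccentricity = law$eccentricity[idx]))
  }
  if (law$type != "truncgeom") stop("unknown aggregate_length_law type: ", law$type)
  cf <- if (is.null(law$conversion_factor)) 4 else law$conversion_factor
  support <- law$n_min:law$n_max
  pmf <- dtruncgeom(support, law$alpha, law$n_min, law$n_max)
  cdf <- cumsum(pmf); cdf[length(cdf)] <- 1
  m <- support[findInterval(stats::runif(n), cdf, left.open = TRUE) + 1L]
  hi <- stats::runif(n) < law$ecc_high_frac
  ecc <- ifelse(hi,
                stats::runif(n, law$ecc_high_range[1], law$ecc_high_range[2]),
                stats::runif(n, law$ecc_low_range[1], law$ecc_low_range[2]))
  data.frame(length_nm = m / cf, eccentricity = ecc)
}

# localisation cloud for one aggregate: anisotropic Gaussian, hard-truncated
# at +/- length/2 along the major axis so the planted length is the full
# extent of the noise-free support
sample_aggregate_cloud <- function(n_loc, cx, cy, length_nm, ecc, theta) {
  s_maj <- length_nm / 4
  lam_maj <- TRUNC2_VAR_FACTOR * s_maj^2
  s_min <- sqrt(pmax(0, (1 - ecc^2) * lam_maj))
  u <- rtnorm2(n_loc, s_maj)
  v <- stats::rnorm(n_loc, 0, s_min)
  x <- cx + u * cos(theta) - v * sin(theta)
  y <- cy + u * sin(theta) + v * cos(theta)
  cbind(x, y)
}

#' Generate a synthetic localisation scene with planted ground truth
#'
#' Builds a complete single-FoV dataset: synaptosome discs placed without
#' overlap by rejection sampling, aggregates realised as anisotropic
#' Gaussian localisation clouds with planted length and eccentricity,
#' uniform background localisations, and a membrane-stain image with one
#' Gaussian blob per synaptosome over Poisson noise. Everything is
#' reproducible from the spec's single master seed.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{localisations}{data frame (`frame`, `x`, `y`, `sigma`,
#'       `intensity`, `source_id`): `source_id` 0 marks background,
#'       positive values index `ground_truth$aggregates`.}
#'     \item{membrane_image}{numeric matrix (rows = y, cols = x) of
#'       membrane-stain counts.}
#'     \item{ground_truth}{list with `synaptosomes` and `aggregates` data
#'       frames holding every planted value.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_localisation_scene <- function(spec) {
  validate_scene_spec(spec)
  fov <- spec$fov_size_nm

  # --- synaptosome placement (no overlap, fully inside FoV) ---
  set.seed(substream_seed(spec$seed, "synaptosomes"))
  ns <- spec$n_synaptosomes
  sx <- sy <- sr <- numeric(0)
  if (ns > 0) {
    radii <- pmax(0.2 * spec$synaptosome_radius_nm,
                  stats::rnorm(ns, spec$synaptosome_radius_nm,
                               spec$synaptosome_radius_sd_nm))
    sx <- sy <- numeric(ns)
    tries <- 0L
    for (i in seq_len(ns)) {
      repeat {
        tries <- tries + 1L
        if (tries > 10000L)
          stop("could not place synaptosomes without overlap; FoV too small")
        px <- stats::runif(1, radii[i], fov[1] - radii[i])
        py <- stats::runif(1, radii[i], fov[2] - radii[i])
        if (i == 1L) { ok <- TRUE } else {
          j <- seq_len(i - 1L)
          ok <- all((sx[j] - px)^2 + (sy[j] - py)^2 > (radii[j] + radii[i])^2)
        }
        if (ok) { sx[i] <- px; sy[i] <- py; break }
      }
    }
    sr <- radii
  }
  occupied <- if (ns > 0) {
    set.seed(substream_seed(spec$seed, "occupancy"))
    stats::runif(ns) < spec$occupancy_fraction
  } else logical(0)

  # --- aggregates: synaptic then extra-synaptic ---
  set.seed(substream_seed(spec$seed, "aggregates"))
  n_per <- integer(ns)
  n_per[occupied] <- draw_count(spec$aggregates_per_occupied, sum(occupied))
  syn_parent <- rep(seq_len(ns), n_per)
  n_syn_agg <- length(syn_parent)
  n_extra <- spec$extra_synaptic_aggregate_count
  n_agg <- n_syn_agg + n_extra

  agg <- NULL
  loc_list <- list()
  if (n_agg > 0) {
    shape <- draw_length_ecc(spec$aggregate_length_law, n_agg)
    theta <- stats::runif(n_agg, 0, pi)
    nloc <- draw_count(spec$localisations_per_aggregate, n_agg)
    cx <- cy <- numeric(n_agg)
    if (n_syn_agg > 0) {
      # centroid uniform in a concentric disc at 70% of the parent radius
      rr <- 0.7 * sr[syn_parent] * sqrt(stats::runif(n_syn_agg))
      aa <- stats::runif(n_syn_agg, 0, 2 * pi)
      cx[seq_len(n_syn_agg)] <- sx[syn_parent] + rr * cos(aa)
      cy[seq_len(n_syn_agg)] <- sy[syn_parent] + rr * sin(aa)
    }
    if (n_extra > 0) {
      idx <- n_syn_agg + seq_len(n_extra)
      margin <- shape$length_nm[idx] / 2 + 1
      for (k in seq_len(n_extra)) {
        i <- idx[k]
        repeat {
          px <- stats::runif(1, margin[k], fov[1] - margin[k])
          py <- stats::runif(1, margin[k], fov[2] - margin[k])
          if (ns == 0 || all((sx - px)^2 + (sy - py)^2 > sr^2)) break
        }
        cx[i] <- px; cy[i] <- py
      }
    }
    for (i in seq_len(n_agg)) {
      pts <- sample_aggregate_cloud(nloc[i], cx[i], cy[i],
                                    shape$length_nm[i], shape$eccentricity[i],
                                    theta[i])
      pts[, 1] <- pmin(pmax(pts[, 1], 0), fov[1])
      pts[, 2] <- pmin(pmax(pts[, 2], 0), fov[2])
      loc_list[[i]] <- cbind(pts, i)
    }
    agg <- data.frame(
      id = seq_len(n_agg),
      centroid_x_nm = cx, centroid_y_nm = cy,
      length_nm = shape$length_nm, eccentricity = shape$eccentricity,
      orientation = theta, n_localisations = nloc,
      compartment = rep(c("synaptic", "extra_synaptic"), c(n_syn_agg, n_extra)),
      synaptosome_id = c(syn_parent, rep(NA_integer_, n_extra)),
      fibril_like = classify_fibril_like(shape$length_nm, shape$eccentricity)
    )
  }

  # --- background localisations ---
  set.seed(substream_seed(spec$seed, "background"))
  area_um2 <- prod(fov) / 1e6
  n_bg <- stats::rpois(1, spec$background_density * area_um2)
  if (n_bg > 0) {
    bg <- cbind(stats::runif(n_bg, 0, fov[1]), stats::runif(n_bg, 0, fov[2]), 0)
    loc_list[[length(loc_list) + 1L]] <- bg
  }

  locs <- if (length(loc_list)) do.call(rbind, loc_list) else
    matrix(numeric(0), ncol = 3)
  set.seed(substream_seed(spec$seed, "photons"))
  n_tot <- nrow(locs)
  loc_tab <- data.frame(
    frame = seq_len(n_tot),
    x = locs[, 1], y = locs[, 2],
    sigma = rep(spec$localisation_precision_nm, n_tot),
    intensity = if (n_tot) round(stats::rgamma(n_tot, shape = 4, scale = 250)) else numeric(0),
    source_id = as.integer(locs[, 3])
  )

  # --- membrane-stain image: Gaussian blob per synaptosome + Poisson noise ---
  set.seed(substream_seed(spec$seed, "membrane"))
  dims <- c(ceiling(fov[2] / spec$pixel_size_nm), ceiling(fov[1] / spec$pixel_size_nm))
  img <- matrix(spec$membrane_background, dims[1], dims[2])
  if (ns > 0) {
    xs <- (seq_len(dims[2]) - 0.5) * spec$pixel_size_nm
    ys <- (seq_len(dims[1]) - 0.5) * spec$pixel_size_nm
    for (i in seq_len(ns)) {
      sig <- sr[i] / 2
      gx <- exp(-(xs - sx[i])^2 / (2 * sig^2))
      gy <- exp(-(ys - sy[i])^2 / (2 * sig^2))
      img <- img + spec$membrane_peak * (gy %o% gx)
    }
  }
  img <- matrix(stats::rpois(length(img), img), nrow(img), ncol(img))

  synap <- data.frame(id = seq_len(ns), centre_x_nm = sx, centre_y_nm = sy,
                      radius_nm = sr, occupied = occupied,
                      n_aggregates = n_per)
  list(localisations = loc_tab,
       membrane_image = img,
       ground_truth = list(synaptosomes = synap, aggregates = agg),
       spec = spec)
}

#' Generate matched bead coordinates under a planted affine distortion
#'
#' Reference beads are scattered uniformly over the field of view; the
#' moving set is the affine image of the reference set plus isotropic
#' Gaussian noise. Used to validate channel registration.
#'
#' @param true_affine 2x3 matrix `[A | t]`: linear part and offset (nm).
#' @param n_beads number of beads (>= 3).
#' @param noise_sigma_nm isotropic Gaussian noise on the moving set (nm).
#' @param seed optional integer seed.
#' @param fov_size_nm field of view for bead placement.
#' @return list with matrices `reference` and `moving` (columns x, y in nm).
#' @export
generate_bead_pair <- function(true_affine, n_beads, noise_sigma_nm = 0,
                               seed = NULL, fov_size_nm = c(80000, 80000)) {
  if (!is.matrix(true_affine) || any(dim(true_affine) != c(2, 3)))
    stop("`true_affine` must be a 2x3 matrix")
  if (n_beads < 3) stop("`n_beads` must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    ref <- cbind(stats::runif(n_beads, 0, fov_size_nm[1]),
                 stats::runif(n_beads, 0, fov_size_nm[2]))
    # guard against (numerically) collinear configurations
    if (qr(cbind(1, ref))$rank == 3L) break
  }
  mov <- ref %*% t(true_affine[, 1:2]) +
    matrix(true_affine[, 3], n_beads, 2, byrow = TRUE)
  if (noise_sigma_nm > 0)
    mov <- mov + matrix(stats::rnorm(2 * n_beads, 0, noise_sigma_nm), ncol = 2)
  colnames(ref) <- colnames(mov) <- c("x", "y")
  list(reference = ref, moving = mov)
}

#' Generate a per-synaptosome marker presence/absence table
#'
#' Each synaptosome independently carries AT8-positive tau with probability
#' `f_at8`; conditional on the AT8 state, it carries the second marker with
#' probability `f_signal_given_at8` or `f_signal_given_not_at8`.
#'
#' @param n_synaptosomes number of rows.
#' @param f_at8 probability of AT8 positivity.
#' @param f_signal_given_at8,f_signal_given_not_at8 conditional marker
#'   probabilities.
#' @param seed optional integer seed.
#' @return data frame (`synaptosome_id`, `at8`, `signal`), logical flags.
#' @export
generate_cooccurrence_table <- function(n_synaptosomes, f_at8,
                                        f_signal_given_at8,
                                        f_signal_given_not_at8,
                                        seed = NULL) {
  probs <- c(f_at8, f_signal_given_at8, f_signal_given_not_at8)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (n_synaptosomes < 0) stop("`n_synaptosomes` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  at8 <- stats::runif(n_synaptosomes) < f_at8
  p <- ifelse(at8, f_signal_given_at8, f_signal_given_not_at8)
  signal <- stats::runif(n_synaptosomes) < p
  data.frame(synaptosome_id = seq_len(n_synaptosomes), at8 = at8,
             signal = signal)
}
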