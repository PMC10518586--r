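# pN per nm^1.5 Hertz prefactor for E in Pa, R in nm:
# F[N] = (4/3) E/(1-nu^2) sqrt(R[m]) d[m]^1.5 ; nm^1.5 * sqrt(nm) = 1e-18 m^2
.hertz_coef <- function(modulus, tip_radius, poisson) {
  4 / 3 * modulus / (1 - poisson^2) * sqrt(tip_radius * 1e-9) *
    (1e-9)^1.5 * 1e12            # -> pN at delta in nm
}

#' Generate a synthetic AFM approach force curve
#'
#' Piecewise contact model on a decreasing separation grid: zero force until
#' the tip touches the film surface, Hertz sphere indentation
#' \eqn{F = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}} up to the
#' breakthrough force, then a rupture jump (force falls to zero across the
#' stated separation width) and finally a stiff linear substrate wall at
#' zero separation. Without a breakthrough the film surface sits at zero
#' separation and the curve is pure Hertz. Seeded Gaussian noise is added
#' to the force channel.
#'
#' @param modulus Young's modulus of the film (Pa, > 0).
#' @param tip_radius tip radius (nm).
#' @param breakthrough `NULL`, or `c(force_pN, width_nm)`: yield force and
#'   jump width (the film thickness).
#' @param noise force noise standard deviation (pN).
#' @param seed integer seed.
#' @param poisson Poisson ratio (default 0.5, incompressible film).
#' @param s_range separation range (nm), sampled decreasing.
#' @param ds separation step (nm).
#' @param substrate_stiffness substrate wall slope (pN/nm).
#' @return data.frame of class `mp_force_curve` (separation nm, force pN)
#'   with attributes tip_radius, poisson_ratio and `truth`.
#' @export
generate_force_curve <- function(modulus, tip_radius = 2,
                                 breakthrough = NULL, noise = 0, seed = 1L,
                                 poisson = 0.5, s_range = c(-0.5, 10),
                                 ds = 0.01, substrate_stiffness = 1e4) {
  if (modulus <= 0) stop("modulus must be > 0")
  if (!is.null(breakthrough)) {
    if (breakthrough[1] <= 0) stop("breakthrough force must be > 0")
    if (breakthrough[2] <= 0) stop("breakthrough width must be > 0")
  }
  coef <- .hertz_coef(modulus, tip_radius, poisson)
  s <- seq(s_range[2], s_range[1], by = -ds)
  if (is.null(breakthrough)) {
    contact <- 0
    F <- ifelse(s < contact, coef * (contact - s)^1.5, 0)
  } else {
    Fb <- breakthrough[1]; width <- breakthrough[2]
    delta_b <- (Fb / coef)^(2 / 3)
    contact <- width + delta_b       # film surface above the substrate
    F <- numeric(length(s))
    film <- s <= contact & s >= width
    F[film] <- coef * (contact - s[film])^1.5
    # ruptured region: flat at zero across the jump width
    wall <- s <= 0
    F[wall] <- substrate_stiffness * (-s[wall])
  }
  if (noise > 0) {
    set.seed(seed)
    F <- F + stats::rnorm(length(F), 0, noise)
  }
  out <- data.frame(separation = s, force = F)
  attr(out, "tip_radius") <- tip_radius
  attr(out, "poisson_ratio") <- poisson
  attr(out, "truth") <- list(modulus = modulus, breakthrough = breakthrough,
                             noise = noise, seed = seed, contact = contact)
  class(out) <- c("mp_force_curve", "data.frame")
  out
}

#' Detect the breakthrough (rupture jump) in an approach force curve
#'
#' Scans the approach (decreasing separation) for the largest force drop of
#' at least `drop_threshold` occurring within at most `drop_window` of
#' separation; the force immediately before the drop is the yield force.
#' The film thickness is the separation at the drop minus the zero-force
#' intercept of the substrate contact branch (linear fit of the rising
#' post-jump segment), which is exact for a linear wall at zero noise.
#'
#' @param curve an approach force curve (separation nm, force pN).
#' @param drop_threshold minimum force drop (pN); default 50.
#' @param drop_window maximum separation span of the drop (nm); default 0.5.
#' @return list with `found`; when `found`, also `yield_force` (pN, relative
#'   to the non-contact baseline), `thickness` (nm) and `drop_separation`;
#'   otherwise a `diagnostic` message.
#' @export
detect_breakthrough <- function(curve, drop_threshold = 50, drop_window = 0.5) {
  o <- order(curve$separation, decreasing = TRUE)
  s <- curve$separation[o]; F <- curve$force[o]
  # force baseline from the far (non-contact) end makes detection invariant
  # to a constant force offset
  F <- F - stats::median(F[s >= stats::quantile(s, 0.9)])
  if (max(F) < drop_threshold)
    return(list(found = FALSE,
                diagnostic = "no contact: peak force below the drop threshold"))
  dF <- F[-length(F)] - F[-1]
  dS <- s[-length(s)] - s[-1]
  cand <- which(dF >= drop_threshold & dS <= drop_window)
  if (!length(cand))
    return(list(found = FALSE,
                diagnostic = "no force drop exceeding the threshold"))
  i <- cand[which.max(dF[cand])]
  yield <- F[i]; s_drop <- s[i]
  # substrate branch: rising contact after the jump
  sub <- which(s < s[i + 1] & F >= drop_threshold / 2)
  if (length(sub) >= 2) {
    fit <- stats::lm(F[sub] ~ s[sub])
    s0 <- -stats::coef(fit)[[1]] / stats::coef(fit)[[2]]
  } else s0 <- min(s)
  list(found = TRUE, yield_force = yield, thickness = s_drop - s0,
       drop_separation = s_drop)
}

#' Fit a Hertz sphere modulus to the pre-breakthrough contact segment
#'
#' Linearizes the Hertz sphere model, \eqn{F^{2/3} = c^{2/3}(t - s)}, and
#' fits it by least squares on the contact segment before any breakthrough
#' (points above `min_force`, at separations larger than the rupture jump).
#' Both the contact point t and the modulus are estimated; at zero noise the
#' generating modulus is recovered exactly.
#'
#' @param curve a force curve; tip radius and Poisson ratio are read from
#'   its attributes unless given.
#' @param tip_radius tip radius (nm).
#' @param poisson Poisson ratio (default 0.5).
#' @param min_force lower force bound of the contact segment (pN); raised
#'   automatically to six times the far-field force noise so that
#'   noise-inflated points outside the contact region cannot flatten the
#'   linearized fit.
#' @param breakthrough optional precomputed [detect_breakthrough()] result.
#' @return list with `modulus` (Pa), `contact_point` (nm), `n_points`.
#' @export
fit_modulus <- function(curve, tip_radius = attr(curve, "tip_radius"),
                        poisson = attr(curve, "poisson_ratio") %||% 0.5,
                        min_force = 10, breakthrough = NULL) {
  if (is.null(tip_radius)) stop("tip_radius required")
  if (is.null(breakthrough)) breakthrough <- detect_breakthrough(curve)
  s <- curve$separation; F <- curve$force
  far <- s >= stats::quantile(s, 0.9)
  F <- F - stats::median(F[far])          # force baseline from the far field
  noise_sd <- stats::sd(F[far])
  thresh <- max(min_force, 6 * noise_sd)
  keep <- F > thresh
  if (breakthrough$found) keep <- keep & s >= breakthrough$drop_separation
  if (sum(keep) < 3) stop("no usable contact segment before the breakthrough")
  y <- F[keep]^(2 / 3)
  fit <- stats::lm(y ~ s[keep])
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) stop("contact segment does not stiffen on approach")
  c23 <- -slope
  coef_pn <- c23^1.5                       # pN / nm^1.5
  modulus <- coef_pn * 3 / 4 * (1 - poisson^2) /
    (sqrt(tip_radius * 1e-9) * (1e-9)^1.5 * 1e12)
  list(modulus = modulus,
       contact_point = stats::coef(fit)[[1]] / c23,
       n_points = sum(keep))
}

#' Generate a synthetic AFM height map
#'
#' Planted surfaces with known roughness statistics: `flat` (all zeros),
#' `sinusoid` (height A sin(2 pi x / period + phase) along x; over whole
#' periods the average roughness is 2A/pi and the RMS roughness A/sqrt(2)),
#' or `gaussian_noise` (iid N(0, sigma^2), RMS -> sigma for large grids).
#'
#' @param shape grid dimensions (rows, cols), each >= 2.
#' @param waveform `"flat"`, `"sinusoid"` or `"gaussian_noise"`.
#' @param amplitude sinusoid amplitude A (nm).
#' @param period sinusoid period (nm).
#' @param phase sinusoid phase (radians).
#' @param sigma Gaussian surface sigma (nm).
#' @param pixel pixel size (nm).
#' @param seed integer seed (gaussian_noise only).
#' @return list of class `mp_height_map`: `heights` (matrix, nm), `pixel`.
#' @export
generate_height_map <- function(shape = c(128, 128),
                                waveform = c("flat", "sinusoid", "gaussian_noise"),
                                amplitude = 1, period = 8, phase = 0,
                                sigma = 0.3, pixel = 0.1, seed = 1L) {
  waveform <- match.arg(waveform)
  if (any(shape < 2)) stop("grid must be at least 2 x 2")
  h <- switch(waveform,
    flat = matrix(0, shape[1], shape[2]),
    sinusoid = {
      x <- (seq_len(shape[2]) - 1) * pixel
      matrix(amplitude * sin(2 * pi * x / period + phase),
             shape[1], shape[2], byrow = TRUE)
    },
    gaussian_noise = {
      set.seed(seed)
      matrix(stats::rnorm(prod(shape), 0, sigma), shape[1], shape[2])
    })
  structure(list(heights = h, pixel = pixel, waveform = waveform),
            class = "mp_height_map")
}

#' Roughness statistics over random regions of a height map
#'
#' Samples `n_regions` square regions (seeded), removes a first-order plane
#' (or just the mean) from each, and reports the average roughness
#' R_a = mean|z - fit| and RMS roughness per region, plus their mean with
#' standard error over regions. Adding a constant or a tilted plane to the
#' map leaves the default (plane-detrended) statistics unchanged.
#'
#' @param map an `mp_height_map` (or plain matrix).
#' @param n_regions number of regions (default 4).
#' @param region_size region size in pixels, one value (square) or
#'   `c(rows, cols)`; default the whole map (then all regions coincide).
#' @param seed integer seed for region placement.
#' @param detrend `"plane"` (first-order flattening, default), `"mean"` or
#'   `"none"`.
#' @return list of class `mp_roughness`: `per_region` (data.frame Ra, rms,
#'   row, col), `Ra` / `rms` (mean), `Ra_se` / `rms_se`.
#' @export
roughness <- function(map, n_regions = 4, region_size = NULL, seed = 1L,
                      detrend = c("plane", "mean", "none")) {
  detrend <- match.arg(detrend)
  h <- if (inherits(map, "mp_height_map")) map$heights else as.matrix(map)
  nr <- nrow(h); nc <- ncol(h)
  if (is.null(region_size)) region_size <- c(nr, nc)
  region_size <- rep_len(as.integer(region_size), 2)
  if (region_size[1] > nr || region_size[2] > nc)
    stop("region larger than the map")
  set.seed(seed)
  res <- NULL
  for (k in seq_len(n_regions)) {
    r0 <- if (nr == region_size[1]) 1L else sample.int(nr - region_size[1] + 1L, 1)
    c0 <- if (nc == region_size[2]) 1L else sample.int(nc - region_size[2] + 1L, 1)
    z <- h[r0:(r0 + region_size[1] - 1L), c0:(c0 + region_size[2] - 1L)]
    resid <- switch(detrend,
      none = z,
      mean = z - mean(z),
      plane = {
        g <- expand.grid(i = seq_len(nrow(z)), j = seq_len(ncol(z)))
        fit <- stats::lm.fit(cbind(1, g$i, g$j), as.vector(z))
        matrix(fit$residuals, nrow(z), ncol(z))
      })
    res <- rbind(res, data.frame(row = r0, col = c0,
                                 Ra = mean(abs(resid)),
                                 rms = sqrt(mean(resid^2))))
  }
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(per_region = res,
                 Ra = mean(res$Ra), Ra_se = se(res$Ra),
                 rms = mean(res$rms), rms_se = se(res$rms)),
            class = "mp_roughness")
}

#' Mean, standard error and directional contrasts across systems
#'
#' Summarizes replicate measurements (thickness, yield force, roughness,
#' modulus, ...) per system as mean with standard error (sd/sqrt(n); flagged
#' NA for n = 1) and reports the sign of the change of each system relative
#' to the first (reference, typically the untreated control).
#'
#' @param values named list of numeric vectors, one per system; the first
#'   is the reference.
#' @return list of class `mp_mech_summary`: `table` (system, n, mean, se),
#'   `contrasts` (system, delta, sign vs reference; NULL for one system).
#' @export
summarize_measurements <- function(values) {
  if (!length(values)) stop("need at least one system")
  if (is.null(names(values))) names(values) <- paste0("system_", seq_along(values))
  tab <- do.call(rbind, lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (!length(v)) stop("system ", nm, " has no values")
    data.frame(system = nm, n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  contrasts <- NULL
  if (length(values) > 1) {
    ref <- tab$mean[1]
    contrasts <- data.frame(system = tab$system[-1],
                            delta = tab$mean[-1] - ref,
                            sign = sign(tab$mean[-1] - ref))
  }
  structure(list(table = tab, contrasts = contrasts),
            class = "mp_mech_summary")
}

#' Write / read force curves and height maps as tabular text
#'
#' Force curves: two columns (separation nm, force pN) with tip radius and
#' Poisson ratio in `#` header comments. Height maps: whitespace-separated
#' matrix rows with the pixel size in a `#` comment.
#'
#' @param curve,map objects to write.
#' @param path file path.
#' @return `path` (writers) or the object (readers).
#' @export
write_force_curve <- function(curve, path) {
  writeLines(c(sprintf("# tip_radius_nm %g", attr(curve, "tip_radius") %||% NA),
               sprintf("# poisson_ratio %g", attr(curve, "poisson_ratio") %||% 0.5),
               "# separation_nm force_pN",
               sprintf("%.6f %.8g", curve$separation, curve$force)), path)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           col.names = c("separation", "force"))
  gv <- function(key) {
    m <- grep(paste0("^# ", key), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, " "), "", m[1])) else NULL
  }
  attr(tab, "tip_radius") <- gv("tip_radius_nm")
  attr(tab, "poisson_ratio") <- gv("poisson_ratio") %||% 0.5
  class(tab) <- c("mp_force_curve", "data.frame")
  tab
}

#' @rdname write_force_curve
#' @export
write_height_map <- function(map, path) {
  writeLines(c(sprintf("# pixel_nm %g", map$pixel),
               apply(map$heights, 1, function(r) paste(sprintf("%.9f", r),
                                                       collapse = " "))), path)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_height_map <- function(path) {
  lines <- readLines(path)
  px <- as.numeric(sub("^# pixel_nm ", "", grep("^# pixel_nm", lines, value = TRUE)[1]))
  h <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
  dimnames(h) <- NULL
  structure(list(heights = h, pixel = px, waveform = "file"),
            class = "mp_height_map")
}
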