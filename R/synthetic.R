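# Parametric synthetic nautilid conchs: logarithmic-spiral coiling with a
# harmonically deformed elliptical whorl outline swept along the spiral,
# lobed suture curves on the whorl surface, and a septal-spacing schedule with
# a hatching signal (steep rise, then a drop at chamber 7 or 8), a stable
# mid-ontogeny band, and terminal crowding.

# run expr with a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Shell coiling and septation parameters
#'
#' Parameters of the synthetic conch model. Lengths are mm, angles degrees;
#' other quantities are dimensionless. The conch is a logarithmic spiral whose
#' diameter multiplies by `whorl_expansion_rate` per whorl; the whorl
#' cross-section is an ellipse of height/width ratio `section_aspect` deformed
#' by low-order harmonics `section_shape_coeffs` (cos 2phi and cos 3phi
#' amplitudes); sutures are outline-following closed curves displaced
#' adapically by one shallow lateral lobe per flank of relative depth
#' `suture_lobe_amplitude`. `angle_pre` is the peak septal angle reached just
#' before hatching, `angle_mid` the stable mid-ontogeny septal angle, and the
#' last `crowding_chambers` septal angles decrease strictly (septal crowding).
#'
#' @param whorl_expansion_rate diameter multiplier per 360 degrees (> 1).
#' @param umbilical_ratio umbilicus radius / conch radius, in \[0, 1).
#' @param section_aspect whorl height / width ratio (> 0).
#' @param section_shape_coeffs length-3 numeric, cos(2 phi), cos(3 phi) and
#'   cos(4 phi) amplitudes deforming the elliptical outline (bilateral
#'   symmetry is preserved: cosine terms only).
#' @param suture_lobe_amplitude lobe depth relative to whorl height (>= 0).
#' @param n_chambers chamber count at maturity.
#' @param hatching_chamber chamber at which septal spacing drops (7 or 8 in
#'   modern nautilids).
#' @param angle_pre peak pre-hatching septal angle, degrees.
#' @param angle_mid mean mid-ontogeny septal angle, degrees; must lie in
#'   `angle_band` and be at most 0.8 * `angle_pre` so the post-hatching drop
#'   is at least 20 percent.
#' @param angle_band admissible band for `angle_mid`, degrees.
#' @param crowding_chambers number of terminally crowded septa.
#' @param angle_noise_sd sd of chamber-to-chamber septal-angle noise, degrees.
#' @param initial_diameter conch diameter at the first septum, mm.
#' @return an object of class `shell_params`.
#' @export
shell_params <- function(whorl_expansion_rate = 3.0,
                         umbilical_ratio = 0.10,
                         section_aspect = 1.0,
                         section_shape_coeffs = c(0.05, 0.02, 0.00),
                         suture_lobe_amplitude = 0.16,
                         n_chambers = 27L,
                         hatching_chamber = 7L,
                         angle_pre = 38,
                         angle_mid = 25,
                         angle_band = c(20, 30),
                         crowding_chambers = 3L,
                         angle_noise_sd = 1.2,
                         initial_diameter = 17.5) {
  p <- list(whorl_expansion_rate = whorl_expansion_rate,
            umbilical_ratio = umbilical_ratio,
            section_aspect = section_aspect,
            section_shape_coeffs = {
              sc <- as.numeric(section_shape_coeffs)
              if (length(sc) == 2L) sc <- c(sc, 0)
              if (length(sc) != 3L) stop("section_shape_coeffs must have length 2 or 3")
              sc
            },
            suture_lobe_amplitude = suture_lobe_amplitude,
            n_chambers = as.integer(n_chambers),
            hatching_chamber = as.integer(hatching_chamber),
            angle_pre = angle_pre, angle_mid = angle_mid,
            angle_band = as.numeric(angle_band),
            crowding_chambers = as.integer(crowding_chambers),
            angle_noise_sd = angle_noise_sd,
            initial_diameter = initial_diameter)
  class(p) <- "shell_params"
  validate_shell_params(p)
  p
}

validate_shell_params <- function(p) {
  stopifnot(inherits(p, "shell_params"))
  if (!(p$whorl_expansion_rate > 1)) stop("whorl_expansion_rate must be > 1")
  if (p$umbilical_ratio < 0 || p$umbilical_ratio >= 1)
    stop("umbilical_ratio must lie in [0, 1)")
  if (!(p$section_aspect > 0)) stop("section_aspect must be > 0")
  if (p$suture_lobe_amplitude < 0) stop("suture_lobe_amplitude must be >= 0")
  if (p$hatching_chamber < 3L) stop("hatching_chamber must be >= 3")
  if (p$n_chambers <= p$hatching_chamber + p$crowding_chambers)
    stop("n_chambers must exceed hatching_chamber + crowding_chambers")
  if (p$angle_mid < p$angle_band[1L] || p$angle_mid > p$angle_band[2L])
    stop("angle_mid lies outside the configured band")
  if (p$angle_mid > 0.8 * p$angle_pre)
    stop("angle_mid must be <= 0.8 * angle_pre (post-hatching drop >= 20%)")
  if (p$angle_noise_sd < 0 || p$initial_diameter <= 0)
    stop("angle_noise_sd must be >= 0 and initial_diameter > 0")
  invisible(p)
}

#' Septal-spacing schedule
#'
#' Generates the series of rotational angles between successive septa
#' (degrees; length `n_chambers - 1`, the angle at position i separating
#' septum i from septum i + 1 and hence associated with chamber i + 1; chamber
#' 1 itself carries no angle). The series rises monotonically to a maximum at
#' chamber `hatching_chamber - 1`, drops by at least 20 percent at the
#' hatching chamber, fluctuates about `angle_mid` through mid-ontogeny, and
#' decreases strictly over the last `crowding_chambers` angles.
#'
#' @param params a [shell_params()] object.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param noise_sd noise level, degrees; defaults to `params$angle_noise_sd`.
#' @return numeric vector of septal angles, degrees.
#' @export
septal_schedule <- function(params, seed = NULL, noise_sd = params$angle_noise_sd) {
  validate_shell_params(params)
  with_seed(seed, {
    m <- params$n_chambers - 1L
    h <- params$hatching_chamber
    cc <- params$crowding_chambers
    p <- h - 2L                      # peak position: chamber h - 1
    if (m - cc < h) stop("no room for a mid-ontogeny plateau")
    rise <- seq(0.45 * params$angle_pre, params$angle_pre, length.out = p)
    rise <- sort(rise + stats::rnorm(p, 0, 0.5 * noise_sd))
    peak <- rise[p]
    cap <- 0.8 * peak - 1e-3         # everything after the peak stays below this
    n_mid <- (m - cc) - p
    mid <- params$angle_mid + stats::rnorm(n_mid, 0, noise_sd)
    mid <- pmin(pmax(mid, 0.5 * params$angle_mid), cap)
    tail_base <- params$angle_mid * seq(0.85, 0.45, length.out = cc)
    tl <- tail_base + stats::rnorm(cc, 0, 0.4 * noise_sd)
    tl <- pmin(pmax(tl, 1), cap)
    if (cc > 1L) {                   # enforce strict terminal decrease
      step <- max(0.2, 0.02 * params$angle_mid)
      for (j in 2:cc) tl[j] <- min(tl[j], tl[j - 1L] - step)
      tl <- pmax(tl, 0.5)
    }
    c(rise, mid, tl)
  })
}

#' Species specification for the generator
#'
#' A species (or geographic population) is a mean [shell_params()] plus
#' intraspecific variation: a per-parameter coefficient of variation applied
#' on each parameter's natural scale when specimen-level parameters are
#' drawn, and isotropic coordinate noise added to every generated curve
#' point.
#'
#' @param name species name.
#' @param region geographic population label.
#' @param mean_params a [shell_params()] object.
#' @param intraspecific_cv coefficient of variation (>= 0) for specimen-level
#'   parameter draws.
#' @param landmark_noise_sd isotropic coordinate noise, mm (>= 0).
#' @param label short unique label; defaults to `name_region`.
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(name, region = "unknown", mean_params = shell_params(),
                         intraspecific_cv = 0.015, landmark_noise_sd = 0.05,
                         label = NULL) {
  if (intraspecific_cv < 0) stop("intraspecific_cv must be >= 0")
  if (landmark_noise_sd < 0) stop("landmark_noise_sd must be >= 0")
  validate_shell_params(mean_params)
  if (is.null(label)) label <- gsub("[^A-Za-z0-9]+", "_", paste(name, region, sep = "_"))
  structure(list(name = name, region = region, mean_params = mean_params,
                 intraspecific_cv = intraspecific_cv,
                 landmark_noise_sd = landmark_noise_sd, label = label),
            class = "species_spec")
}

# draw specimen-level parameters: mean params perturbed on natural scales
draw_specimen_params <- function(spec) {
  p <- spec$mean_params
  cv <- spec$intraspecific_cv
  if (cv > 0) {
    z <- stats::rnorm(10L)
    p$whorl_expansion_rate <- p$whorl_expansion_rate * (1 + cv * z[1L])
    p$umbilical_ratio <- max(0, p$umbilical_ratio * (1 + cv * z[2L]))
    p$section_aspect <- p$section_aspect + cv * z[3L]
    p$section_shape_coeffs <- p$section_shape_coeffs + 0.5 * cv * z[4:6]
    p$suture_lobe_amplitude <- max(0, p$suture_lobe_amplitude + 0.5 * cv * z[7L])
    p$angle_pre <- p$angle_pre * (1 + cv * z[9L])
    p$angle_mid <- min(max(p$angle_mid + 40 * cv * z[8L], p$angle_band[1L]),
                       min(p$angle_band[2L], 0.8 * p$angle_pre))
    p$initial_diameter <- p$initial_diameter * (1 + cv * z[10L])
  }
  validate_shell_params(p)
  p
}

# conch diameter along the spiral: d(theta) = d0 * W^(theta/360)
spiral_diameter <- function(params, theta_deg) {
  params$initial_diameter * params$whorl_expansion_rate^(theta_deg / 360)
}

# ontogenetic shape program. Species-level deviations from the genus base
# (the shell_params() defaults) are expressed progressively through ontogeny
# (ramp g(d), saturating around 40 mm), which is what makes species separate
# in middle ontogeny but not before hatching. A sharp logistic switch at the
# specimen's hatching diameter moves the outline from the inflated embryonic
# shape (high aspect, negative cos 2phi) to the adult shape, and switches the
# suture from nearly lobeless to fully lobed. Smooth post-hatching drift also
# saturates around 40 mm, after which shape is ontogenetically stable.
shape_at_diameter <- function(p, d, hatch_mid) {
  base <- shell_params()
  s <- as.numeric(d >= hatch_mid)  # hatching modifies the aperture abruptly
  r40 <- pmin(1, d / 40)
  g <- 0.25 + 0.75 * stats::plogis((d - 33) / 2.5)
  aspect <- base$section_aspect * (1 + 0.50 * (1 - s)) - 0.05 * r40 +
    g * (p$section_aspect - base$section_aspect)
  c2 <- 0.20 * (1 - s) + base$section_shape_coeffs[1L] * s + 0.03 * r40 * s +
    g * (p$section_shape_coeffs[1L] - base$section_shape_coeffs[1L])
  c3 <- base$section_shape_coeffs[2L] +
    g * (p$section_shape_coeffs[2L] - base$section_shape_coeffs[2L])
  c4 <- base$section_shape_coeffs[3L] +
    g * (p$section_shape_coeffs[3L] - base$section_shape_coeffs[3L])
  lobe <- 0.03 * (1 - s) + base$suture_lobe_amplitude * s * (1 + 0.25 * r40) +
    g * s * (p$suture_lobe_amplitude - base$suture_lobe_amplitude)
  list(aspect = aspect, c2 = c2, c3 = c3, c4 = c4, lobe = max(0.005, lobe))
}

# whorl outline in the section plane at diameter d. Returns list(a, b, H, c0):
# a radial offset, b lateral coordinate, H whorl height, c0 center radius.
whorl_outline <- function(p, d, hatch_mid, n_points) {
  sh <- shape_at_diameter(p, d, hatch_mid)
  W <- p$whorl_expansion_rate
  R <- d / (1 + W^(-0.5))                    # outer spiral radius
  H <- R * (1 - p$umbilical_ratio)           # whorl height
  wd <- H / sh$aspect                        # whorl width
  phi <- 2 * pi * (0:(n_points - 1L)) / n_points
  m <- 1 + sh$c2 * cos(2 * phi) + sh$c3 * cos(3 * phi) + sh$c4 * cos(4 * phi)
  if (min(m) < 0.15)
    stop("section_shape_coeffs produce a self-intersecting whorl outline")
  list(a = (H / 2) * cos(phi) * m, b = (wd / 2) * sin(phi) * m,
       phi = phi, H = H, c0 = R * (1 + p$umbilical_ratio) / 2, lobe = sh$lobe)
}

# 2D cross-section outline curve (radial offset, lateral) at azimuth theta
section_curve <- function(p, theta, hatch_mid, n_points, noise_sd, label) {
  d <- spiral_diameter(p, theta)
  o <- whorl_outline(p, d, hatch_mid, n_points)
  pts <- cbind(o$a, o$b)
  if (noise_sd > 0) pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd),
                                        ncol = 2L)
  conch_curve(pts, closed = TRUE, label = label)
}

# closed 3D suture curve at cumulative rotational angle theta (degrees).
# The outline is displaced adapically (against growth) by one shallow lateral
# lobe per flank: arc displacement lobe * H * sin(phi)^2, zero at venter and
# dorsum. Coiling axis = y; median plane = x-z.
suture_curve <- function(p, theta, hatch_mid, n_points, noise_sd, label) {
  d <- spiral_diameter(p, theta)
  o <- whorl_outline(p, d, hatch_mid, n_points)
  rho <- o$c0 + o$a
  dtheta <- (o$lobe * o$H * sin(o$phi)^2 / o$c0) * (180 / pi)
  th <- (theta - dtheta) * pi / 180
  pts <- cbind(rho * cos(th), o$b, rho * sin(th))
  if (noise_sd > 0) pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd),
                                        ncol = 3L)
  conch_curve(pts, closed = TRUE, label = label)
}

#' Generate one synthetic specimen
#'
#' Draws specimen-level parameters from the species spec, generates the septal
#' schedule, and builds per-chamber 3D suture curves (chambers numbered from
#' 2; chamber 1 is excluded as in CT work, where its resolution is unreliable)
#' and 2D whorl cross-section outlines every `section_step` degrees from the
#' aperture.
#'
#' @param spec a [species_spec()].
#' @param specimen_id specimen label.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param n_points dense sampling of each generated curve.
#' @param section_step rotational step between cross-sections, degrees.
#' @return an object of class `specimen_record` with fields `suture_curves`,
#'   `section_outlines`, `septal_angles`, `diameters_at_chamber`,
#'   `diameters_at_section`, `max_diameter`, `hatching_diameter`.
#' @export
generate_shell <- function(spec, specimen_id, seed = NULL, n_points = 512L,
                           section_step = 45) {
  stopifnot(inherits(spec, "species_spec"))
  with_seed(seed, {
    p <- draw_specimen_params(spec)
    ang <- septal_schedule(p)
    pos <- cumsum(c(0, ang))                 # septa 1..n_chambers
    n <- p$n_chambers
    h <- p$hatching_chamber
    hatch_mid <- sqrt(spiral_diameter(p, pos[h]) * spiral_diameter(p, pos[h + 1L]))
    noise <- spec$landmark_noise_sd
    sut <- lapply(2:n, function(j)
      suture_curve(p, pos[j], hatch_mid, n_points, noise,
                   label = sprintf("%s|c%02d", specimen_id, j)))
    names(sut) <- sprintf("chamber_%02d", 2:n)
    d_ch <- spiral_diameter(p, pos[2:n])
    names(d_ch) <- sprintf("chamber_%02d", 2:n)
    theta_ap <- pos[n] + 90                  # aperture: 90 deg of body chamber
    k_max <- floor(theta_ap / section_step)
    thetas <- theta_ap - section_step * (k_max:0)   # ascending, ends at aperture
    thetas <- thetas[thetas >= 0]
    sec <- lapply(seq_along(thetas), function(j)
      section_curve(p, thetas[j], hatch_mid, n_points, noise,
                    label = sprintf("%s|s%02d", specimen_id, j)))
    names(sec) <- sprintf("section_%02d", seq_along(thetas))
    d_sec <- spiral_diameter(p, thetas)
    names(d_sec) <- names(sec)
    structure(list(specimen_id = specimen_id, species = spec$name,
                   region = spec$region, group = spec$label, params = p,
                   suture_curves = sut, section_outlines = sec,
                   septal_positions = pos, septal_angles = ang,
                   diameters_at_chamber = d_ch, diameters_at_section = d_sec,
                   section_azimuths = thetas,
                   max_diameter = unname(d_sec[length(d_sec)]),
                   hatching_diameter = hatch_mid,
                   hatching_chamber = h),
              class = "specimen_record")
  })
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("<specimen_record> %s (%s, %s): %d chambers, %d sections, max diameter %.1f mm\n",
              x$specimen_id, x$species, x$region,
              length(x$suture_curves) + 1L, length(x$section_outlines),
              x$max_diameter))
  invisible(x)
}

#' Default species specifications
#'
#' Nine species/population specifications mirroring a study design of eight
#' modern nautilid species with one species split into two geographic
#' populations (2 specimens each gives 18 specimens). Between-group parameter
#' deviations are small, comparable in size across groups, and closely spaced
#' for the two *Allonautilus* species and the two *N. pompilius* populations.
#'
#' @param intraspecific_cv coefficient of variation shared by all specs.
#' @param landmark_noise_sd coordinate noise (mm) shared by all specs.
#' @return list of [species_spec()] objects.
#' @export
default_species_specs <- function(intraspecific_cv = 0.015,
                                  landmark_noise_sd = 0.05) {
  tab <- data.frame(
    name   = c("N_pompilius", "N_pompilius", "N_stenomphalus", "N_belauensis",
               "N_macromphalus", "N_repertus", "N_vitiensis",
               "A_scrobiculatus", "A_perforatus"),
    region = c("Philippines", "Fiji", "Australia", "Palau", "New_Caledonia",
               "Australia", "Fiji", "PNG", "Indonesia"),
    aspect = c(1.05, 1.10, 0.90, 0.95, 0.90, 1.10, 0.95, 1.10, 1.05),
    c2     = c(0.080, 0.110, -0.010, 0.020, -0.010, 0.110, 0.020, 0.110, 0.080),
    c3     = c(0.020, -0.035, 0.020, 0.075, 0.020, -0.035, -0.035, 0.075, 0.075),
    c4     = c(0.050, 0.050, -0.050, -0.050, 0.050, -0.050, 0.050, 0.000, -0.050),
    lobe   = c(0.160, 0.175, 0.130, 0.200, 0.220, 0.110, 0.180, 0.235, 0.225),
    W      = c(3.00, 3.02, 2.95, 3.10, 2.90, 3.15, 3.00, 2.85, 2.88),
    umb    = c(0.10, 0.11, 0.08, 0.12, 0.16, 0.11, 0.09, 0.18, 0.17),
    amid   = c(25.0, 24.0, 27.0, 22.0, 29.0, 21.0, 26.0, 23.5, 28.0)
  )
  lapply(seq_len(nrow(tab)), function(i) {
    species_spec(
      name = tab$name[i], region = tab$region[i],
      mean_params = shell_params(
        whorl_expansion_rate = tab$W[i], umbilical_ratio = tab$umb[i],
        section_aspect = tab$aspect[i],
        section_shape_coeffs = c(tab$c2[i], tab$c3[i], tab$c4[i]),
        suture_lobe_amplitude = tab$lobe[i], angle_mid = tab$amid[i]),
      intraspecific_cv = intraspecific_cv,
      landmark_noise_sd = landmark_noise_sd)
  })
}

#' Generate a synthetic dataset
#'
#' @param specs list of [species_spec()]; labels must be unique.
#' @param n_per_species specimens per spec (>= 1).
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   `(specs, n_per_species, seed)`.
#' @param n_points dense curve sampling, passed to [generate_shell()].
#' @return an object of class `conch_dataset`.
#' @export
generate_dataset <- function(specs = default_species_specs(), n_per_species = 2L,
                             seed = 1L, n_points = 512L) {
  if (n_per_species < 1L) stop("n_per_species must be >= 1")
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate species labels in specs")
  with_seed(seed, {
    specimens <- list()
    for (sp in specs) {
      for (i in seq_len(n_per_species)) {
        id <- sprintf("%s_%d", sp$label, i)
        specimens[[id]] <- generate_shell(sp, id, seed = NULL,
                                          n_points = n_points)
      }
    }
    structure(list(specimens = specimens, species_specs = specs,
                   seed = seed, generator_version = "1.0"),
              class = "conch_dataset")
  })
}

#' @export
print.conch_dataset <- function(x, ...) {
  cat(sprintf("<conch_dataset> %d specimens from %d species specs (seed %d, generator %s)\n",
              length(x$specimens), length(x$species_specs), x$seed,
              x$generator_version))
  invisible(x)
}

#' Write septal angles and diameters to CSV
#'
#' One row per chamber (from chamber 2): specimen_id, species, region,
#' chamber, angle_deg, diameter_mm.
#'
#' @param dataset a `conch_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_septal_csv <- function(dataset, path) {
  rows <- lapply(dataset$specimens, function(r) {
    n <- length(r$septal_angles)
    data.frame(specimen_id = r$specimen_id, species = r$species,
               region = r$region, group = r$group, chamber = 2:(n + 1L),
               angle_deg = r$septal_angles,
               diameter_mm = unname(r$diameters_at_chamber))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a synthetic shell surface to PLY
#'
#' Sweeps the (noise-free) whorl outline along the spiral and writes an ASCII
#' PLY triangle mesh for visual inspection.
#'
#' @param record a `specimen_record`.
#' @param path output `.ply` path.
#' @param theta_step azimuthal step, degrees.
#' @param n_phi points around the outline.
#' @return `path`, invisibly.
#' @export
write_ply <- function(record, path, theta_step = 7.5, n_phi = 48L) {
  p <- record$params
  thetas <- seq(0, max(record$section_azimuths), by = theta_step)
  verts <- do.call(rbind, lapply(thetas, function(th) {
    d <- spiral_diameter(p, th)
    o <- whorl_outline(p, d, record$hatching_diameter, n_phi)
    rho <- o$c0 + o$a
    cbind(rho * cos(th * pi / 180), o$b, rho * sin(th * pi / 180))
  }))
  nt <- length(thetas)
  faces <- list()
  for (i in seq_len(nt - 1L)) {
    for (j in seq_len(n_phi)) {
      j2 <- if (j == n_phi) 1L else j + 1L
      a <- (i - 1L) * n_phi + j;  b <- (i - 1L) * n_phi + j2
      cc <- i * n_phi + j;        dd <- i * n_phi + j2
      faces[[length(faces) + 1L]] <- c(a, b, cc)
      faces[[length(faces) + 1L]] <- c(b, dd, cc)
    }
  }
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(verts)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", length(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(verts, 1L, function(v) paste(sprintf("%.4f", v), collapse = " ")), con)
  writeLines(vapply(faces, function(f) paste(c(3L, f - 1L), collapse = " "), ""), con)
  invisible(path)
}
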