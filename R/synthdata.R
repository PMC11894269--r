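#' Ground truth for a synthetic dentition
#'
#' Bundles the sphere parameters and noise settings from which synthetic
#' landmark sets and meshes are generated, so recovery tests can compare
#' fitted values against a known truth.
#'
#' @param center Sphere centre (x, y, z) in mm. The default places the
#'   centre 100 mm above the occlusal table, cranially, so cusp tips sit
#'   on the lower spherical cap.
#' @param radius Sphere radius in mm (> 0); the default 77.35 mm is a
#'   typical adult mean occlusal-sphere radius.
#' @param noise_sd Isotropic Gaussian landmark noise SD in mm (>= 0);
#'   the default 0.1 mm brackets reported intraoral-scanner trueness.
#' @param seed Integer RNG seed; all generated randomness is a pure
#'   function of the spec plus this seed.
#' @param layout Arch-layout name; `"arch35"` is the built-in bilateral
#'   canine-to-second-molar footprint spanning a spherical cap of
#'   half-angle about 35 degrees.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(center = c(0, 0, 100), radius = 77.35,
                            noise_sd = 0.1, seed = 1L, layout = "arch35") {
  if (radius <= 0) ms_validation_error("radius must be positive")
  if (noise_sd < 0) ms_validation_error("noise_sd must be non-negative")
  if (length(center) != 3 || any(!is.finite(center))) {
    ms_validation_error("center must be a finite length-3 vector")
  }
  structure(
    list(center = as.numeric(center), radius = radius, noise_sd = noise_sd,
         seed = as.integer(seed), layout = layout),
    class = "synthetic_truth"
  )
}

# The "arch35" footprint: occlusal-table (x, y) positions in mm of the 26
# cusp tips at the reference radius 77.35 mm, right side listed; the left
# side is the mirror image x -> -x. The arch is a canine-to-second-molar
# horseshoe (buccal rows outward, lingual rows inward, molar cusps at the
# four corners of each occlusal table) spanning a spherical cap of
# half-angle about 35 deg around the cap pole: that angular extent is what
# keeps the radius well conditioned at realistic landmark noise, and it
# stretches the footprint somewhat beyond a typical dentition. All
# coordinates are multiples of 0.25 mm so the synthetic mesh grid can
# carry exact apex vertices.
.arch35_right <- local({
  m <- rbind(
    Pt1  = c(23.75, 38.50),   # canine tip
    Pt3  = c(31.75, 29.50),   # first premolar buccal
    Pt4  = c(25.50, 25.25),   # first premolar lingual
    Pt7  = c(35.75, 16.75),   # second premolar buccal
    Pt8  = c(28.75, 14.00),   # second premolar lingual
    Pt11 = c(38.25, 6.75),    # first molar mesio-buccal
    Pt12 = c(39.25, 0.25),    # first molar disto-buccal
    Pt13 = c(30.75, 5.25),    # first molar mesio-lingual
    Pt14 = c(31.75, -1.00),   # first molar disto-lingual
    Pt19 = c(40.25, -8.00),   # second molar mesio-buccal
    Pt20 = c(40.25, -14.25),  # second molar disto-buccal
    Pt21 = c(32.50, -8.00),   # second molar mesio-lingual
    Pt22 = c(32.50, -14.25)   # second molar disto-lingual
  )
  colnames(m) <- c("x", "y")
  m
})

.arch35_reference_radius <- 77.35

# Mirror label mapping right -> left for the Pt scheme.
.arch35_left_of <- c(Pt1 = "Pt2", Pt3 = "Pt5", Pt4 = "Pt6", Pt7 = "Pt9",
                     Pt8 = "Pt10", Pt11 = "Pt15", Pt12 = "Pt16",
                     Pt13 = "Pt17", Pt14 = "Pt18", Pt19 = "Pt23",
                     Pt20 = "Pt24", Pt21 = "Pt25", Pt22 = "Pt26")

#' Occlusal-table footprint of an arch layout
#'
#' @param layout Layout name; only `"arch35"` is built in.
#' @return A 26 x 2 matrix of (x, y) footprint coordinates in mm at the
#'   layout's reference radius (77.35 mm), rownames `Pt1`..`Pt26`.
#' @export
arch_layout <- function(layout = "arch35") {
  if (!identical(layout, "arch35")) {
    ms_validation_error(paste0("unknown arch layout: ", layout))
  }
  left <- .arch35_right
  left[, "x"] <- -left[, "x"]
  rownames(left) <- .arch35_left_of[rownames(.arch35_right)]
  m <- rbind(.arch35_right, left)
  m[order(match(rownames(m), .all_landmark_codes)), ]
}

# Unit directions from the sphere centre to each landmark, fixed angular
# positions defined at the layout's reference radius (so the footprint
# scales with the generated radius).
arch_directions <- function(layout = "arch35") {
  fp <- arch_layout(layout)
  r0 <- .arch35_reference_radius
  dz <- -sqrt(r0^2 - rowSums(fp^2))
  u <- cbind(fp, z = dz) / r0
  u
}

#' Generate a synthetic landmark set near a known sphere
#'
#' Places the 26 cusp tips at the fixed, bilaterally symmetric angular
#' positions of the requested arch layout (a spherical cap below the
#' centre, buccal rows outward and lingual rows inward), projects them
#' exactly onto the truth sphere, then adds isotropic Gaussian noise with
#' SD `noise_sd`. Deterministic given `(layout, seed)`.
#'
#' @param truth A [synthetic_truth()].
#' @param subject_id Identifier for the generated set.
#' @return A list with `landmarks` (a [landmark_set()]) and `truth`.
#' @examples
#' g <- generate_landmarks(synthetic_truth(seed = 7))
#' fit_sphere(g$landmarks)
#' @export
generate_landmarks <- function(truth, subject_id = "synthetic") {
  if (!inherits(truth, "synthetic_truth")) {
    ms_validation_error("truth must be a synthetic_truth")
  }
  u <- arch_directions(truth$layout)
  pts <- sweep(u * truth$radius, 2, truth$center, "+")
  if (truth$noise_sd > 0) {
    noise <- with_seed(truth$seed, matrix(
      stats::rnorm(length(pts), sd = truth$noise_sd), ncol = 3))
    pts <- pts + noise
  }
  colnames(pts) <- c("x", "y", "z")
  list(landmarks = landmark_set(pts, subject_id = subject_id), truth = truth)
}

#' Cohort simulation parameters
#'
#' Sex-specific normal distributions of Monson-sphere radii. The defaults
#' are the study conditions the cohort analysis targets: 32 males at
#' 83.57 +/- 13.12 mm and 32 females at 71.13 +/- 10.59 mm.
#'
#' @param n_male,n_female Group sizes.
#' @param mean_male,sd_male,mean_female,sd_female Group parameters (mm).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_male = 32, n_female = 32,
                        mean_male = 83.57, sd_male = 13.12,
                        mean_female = 71.13, sd_female = 10.59,
                        seed = 1L) {
  if (sd_male < 0 || sd_female < 0) ms_validation_error("sds must be >= 0")
  if (n_male < 0 || n_female < 0) ms_validation_error("ns must be >= 0")
  structure(
    list(n_male = as.integer(n_male), n_female = as.integer(n_female),
         mean_male = mean_male, sd_male = sd_male,
         mean_female = mean_female, sd_female = sd_female,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort of radii
#'
#' Draws per-subject radii from the sex-specific normal distributions of
#' the spec, truncated at 0 (redrawn; practically never triggered at the
#' default parameters). Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns `subject_id`, `sex` (`"M"`/`"F"`),
#'   `radius_mm`, males first.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    ms_validation_error("spec must be a cohort_spec")
  }
  draw <- function(n, mean, sd) {
    if (n == 0) return(numeric())
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) {
      x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    }
    x
  }
  with_seed(spec$seed, {
    males <- draw(spec$n_male, spec$mean_male, spec$sd_male)
    females <- draw(spec$n_female, spec$mean_female, spec$sd_female)
    data.frame(
      subject_id = c(sprintf("M%03d", seq_len(spec$n_male)),
                     sprintf("F%03d", seq_len(spec$n_female))),
      sex = rep(c("M", "F"), c(spec$n_male, spec$n_female)),
      radius_mm = c(males, females),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic dentition surface mesh
#'
#' Builds a triangulated occlusal surface consisting of a flat base band
#' plus one smooth convex (paraboloid-capped) bump per landmark of the
#' truth's arch layout. Each bump's apex lies exactly at the noiseless
#' landmark position on the truth sphere: the regular grid is locally
#' snapped so an apex vertex exists at every true cusp tip. The mesh is
#' the fixture for cusp-tip detection ([extract_tip_candidates()]).
#'
#' @param truth A [synthetic_truth()] (its `noise_sd` is ignored; the
#'   mesh is built from the noiseless landmark positions).
#' @param cusp_height Height in mm of the lowest cusp above the base
#'   band (> 0).
#' @param step Grid spacing in mm (default 0.25).
#' @param bump_slope Paraboloid curvature in mm^-1: a bump of height h
#'   has footprint radius `sqrt(h / bump_slope)`. The default keeps
#'   neighbouring cusp bumps (closest pair about 4.5 mm apart) from
#'   overlapping above the base band, so each cusp is its own region.
#' @param margin Flat border around the arch footprint, mm.
#' @return A list with `mesh` (a `tri_mesh`: `vertices` n x 3,
#'   `triangles` m x 3 vertex indices) and `apices` (a [landmark_set()]
#'   of the 26 true cusp tips).
#' @export
generate_dentition_mesh <- function(truth, cusp_height = 6, step = 0.25,
                                    bump_slope = 2, margin = 4) {
  if (!inherits(truth, "synthetic_truth")) {
    ms_validation_error("truth must be a synthetic_truth")
  }
  if (cusp_height <= 0) ms_validation_error("cusp_height must be positive")
  noiseless <- synthetic_truth(center = truth$center, radius = truth$radius,
                               noise_sd = 0, seed = truth$seed,
                               layout = truth$layout)
  apices <- generate_landmarks(noiseless, subject_id = "mesh_truth")$landmarks
  ap <- as_point_matrix(apices)
  base_z <- min(ap[, 3]) - cusp_height

  xs <- seq(min(ap[, 1]) - margin, max(ap[, 1]) + margin, by = step)
  ys <- seq(min(ap[, 2]) - margin, max(ap[, 2]) + margin, by = step)
  nx <- length(xs); ny <- length(ys)
  gx <- rep(xs, times = ny)
  gy <- rep(ys, each = nx)

  # snap the nearest grid node to each apex so the apex is an exact vertex
  for (i in seq_len(nrow(ap))) {
    ix <- which.min(abs(xs - ap[i, 1]))
    iy <- which.min(abs(ys - ap[i, 2]))
    idx <- (iy - 1) * nx + ix
    gx[idx] <- ap[i, 1]
    gy[idx] <- ap[i, 2]
  }

  gz <- rep(base_z, nx * ny)
  for (i in seq_len(nrow(ap))) {
    d2 <- (gx - ap[i, 1])^2 + (gy - ap[i, 2])^2
    gz <- pmax(gz, ap[i, 3] - bump_slope * d2)
  }

  vertices <- cbind(x = gx, y = gy, z = gz)
  # two triangles per grid cell
  ix <- rep(seq_len(nx - 1), times = ny - 1)
  iy <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (iy - 1) * nx + ix
  v10 <- v00 + 1
  v01 <- v00 + nx
  v11 <- v01 + 1
  triangles <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  mesh <- tri_mesh(vertices, triangles)
  list(mesh = mesh, apices = apices)
}
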