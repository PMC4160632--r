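#' Parameters of the synthetic two-layer skull surrogate
#'
#' The surrogate emulates a dry cranium prepared for bone-conduction
#' experiments: a closed bone shell lined on the inside with a layer of
#' poured polyurethane damping material, suspended freely. Geometrically it
#' is a pair of concentric spherical shells (bone outside, polyurethane
#' lining inside, hollow core) built by radially extruding a subdivided
#' icosahedron into prisms, each split into three tetrahedra.
#'
#' The default outer radius of 80 mm gives, after mass calibration against
#' the component densities, a bone shell about 6.8 mm thick and a lining
#' close to the nominal 5 mm.
#'
#' Probe geometry: the stimulation site sits on the outer surface at azimuth
#' `probe_angles["stim"]` in the x-y plane (x is the medial-lateral axis);
#' the ipsilateral cochlea probe patch is centred at azimuth
#' `probe_angles["ipsi"]` and the contralateral patch is its mirror image
#' through the mid-sagittal plane (x negated). With the defaults the
#' stim-to-probe great-circle distance is about 35 mm, matching a
#' retro-auricular stimulation site.
#'
#' @param outer_radius outer radius of the bone shell, metres.
#' @param bone_thickness bone layer thickness, metres.
#' @param lining_thickness polyurethane layer thickness, metres (nominally
#'   about 5 mm).
#' @param refinement_level icosphere subdivision level (>= 1); level L has
#'   `20 * 4^L` surface triangles.
#' @param layers_bone,layers_lining number of radial element layers.
#' @param target_bone_mass,target_lining_mass calibration targets in kg.
#' @param probe_angles named numeric, azimuths in degrees: `stim`, `ipsi`.
#' @param patch_radius_deg angular radius of the probe patches, degrees.
#' @return an object of class `shell_spec`.
#' @seealso [generate_shell()], [calibrate_masses()]
#' @export
shell_spec <- function(outer_radius = 0.08,
                       bone_thickness = 6.8e-3,
                       lining_thickness = 5e-3,
                       refinement_level = 3L,
                       layers_bone = 3L,
                       layers_lining = 2L,
                       target_bone_mass = 0.470,
                       target_lining_mass = 0.340,
                       probe_angles = c(stim = 0, ipsi = 25),
                       patch_radius_deg = 8) {
  probe_angles <- unlist(probe_angles)
  spec <- structure(
    list(outer_radius = outer_radius,
         bone_thickness = bone_thickness,
         lining_thickness = lining_thickness,
         refinement_level = as.integer(refinement_level),
         layers_bone = as.integer(layers_bone),
         layers_lining = as.integer(layers_lining),
         target_bone_mass = target_bone_mass,
         target_lining_mass = target_lining_mass,
         probe_angles = probe_angles,
         patch_radius_deg = patch_radius_deg),
    class = "shell_spec")
  validate_shell_spec(spec)
  spec
}

validate_shell_spec <- function(spec) {
  with(spec, {
    if (outer_radius <= 0 || bone_thickness <= 0 || lining_thickness <= 0)
      stop("radius and thicknesses must be positive")
    if (bone_thickness + lining_thickness >= outer_radius)
      stop("layer thicknesses exceed the outer radius: lining must lie ",
           "strictly inside the bone shell")
    if (refinement_level < 1L) stop("refinement_level must be >= 1")
    if (layers_bone < 1L || layers_lining < 1L)
      stop("each layer needs at least one radial element layer")
    if (!all(c("stim", "ipsi") %in% names(probe_angles)))
      stop("probe_angles must name 'stim' and 'ipsi'")
  })
  invisible(spec)
}

# Unit icosphere: subdivided icosahedron with vertices projected onto the
# unit sphere. The base solid's vertex set is symmetric under negation of
# any single coordinate, and midpoint subdivision preserves that symmetry,
# so probe patches mirror exactly through the mid-sagittal plane.
icosphere <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0,  1, t), c(0, -1, -t), c(0,  1, -t),
    c(t,  0, -1), c(t,  0, 1), c(-t,  0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (lev in seq_len(level)) {
    memo <- new.env(parent = emptyenv())
    verts <- v
    nv <- nrow(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- memo[[key]]
      if (!is.null(got)) return(got)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      idx <- nrow(verts)
      memo[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c_ <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * k - 3L, ] <- c(a, ab, ca)
      newf[4L * k - 2L, ] <- c(b, bc, ab)
      newf[4L * k - 1L, ] <- c(c_, ca, bc)
      newf[4L * k, ]      <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  list(verts = v, faces = f)
}

# Volume of the faceted unit icosphere divided by the exact sphere volume.
# A radially extruded layer of the faceted sphere has volume
# factor * (4/3) pi (R^3 - r^3) exactly (frusta of the cone decomposition),
# so mass calibration can target mesh volumes analytically.
icosphere_volume_factor <- function(level) {
  ico <- icosphere(level)
  a <- ico$verts[ico$faces[, 1L], , drop = FALSE]
  b <- ico$verts[ico$faces[, 2L], , drop = FALSE]
  c_ <- ico$verts[ico$faces[, 3L], , drop = FALSE]
  vol <- abs(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
             a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
             a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  sum(vol) / (4 * pi / 3)
}

# Split the prism between a surface triangle at two radii into 3 tets.
# Diagonal of each quad face runs from its lowest-indexed bottom vertex,
# which is consistent across neighbouring prisms and across radial layers
# (top indices are bottom + nv, preserving the ordering).
prism_tets <- function(tri, off_bot, off_top) {
  rot <- which.min(tri)
  tri <- tri[((rot - 1L + 0:2) %% 3L) + 1L]
  a <- tri[1L]; b <- tri[2L]; c_ <- tri[3L]
  ab <- off_bot + a; bb <- off_bot + b; cb <- off_bot + c_
  at <- off_top + a; bt <- off_top + b; ct <- off_top + c_
  if (b < c_) {
    rbind(c(ab, bb, cb, ct),
          c(ab, bb, ct, bt),
          c(ab, bt, ct, at))
  } else {
    rbind(c(ab, bb, cb, bt),
          c(ab, cb, bt, ct),
          c(ab, bt, ct, at))
  }
}

#' Generate the two-layer spherical skull surrogate
#'
#' Builds a watertight tetrahedral mesh of two concentric spherical shells:
#' an outer `"bone"` layer and an inner `"polyurethane"` lining, with node
#' sets `"stim_site"` (a single outer-surface node), `"ipsi_cochlea"` and
#' `"contra_cochlea"` (small outer-surface patches, mirror-symmetric about
#' the mid-sagittal plane).
#'
#' @param spec a [shell_spec()].
#' @return a [tet4_mesh()].
#' @examples
#' m <- generate_shell(shell_spec(refinement_level = 1))
#' region_volume(m, "bone")
#' @export
generate_shell <- function(spec) {
  validate_shell_spec(spec)
  ico <- icosphere(spec$refinement_level)
  nv <- nrow(ico$verts)
  r_out <- spec$outer_radius
  r_mid <- r_out - spec$bone_thickness
  r_in <- r_mid - spec$lining_thickness
  nl <- spec$layers_lining; nb <- spec$layers_bone
  radii <- c(seq(r_in, r_mid, length.out = nl + 1L),
             seq(r_mid, r_out, length.out = nb + 1L)[-1L])
  n_lay <- length(radii)

  nodes <- do.call(rbind, lapply(radii, function(r) r * ico$verts))

  per_layer <- 3L * nrow(ico$faces)
  elements <- matrix(0L, per_layer * (n_lay - 1L), 4L)
  region <- character(nrow(elements))
  row <- 0L
  for (k in seq_len(n_lay - 1L)) {
    off_bot <- (k - 1L) * nv
    off_top <- k * nv
    lab <- if (k <= nl) "polyurethane" else "bone"
    for (fk in seq_len(nrow(ico$faces))) {
      elements[row + 1:3, ] <- prism_tets(ico$faces[fk, ], off_bot, off_top)
      region[row + 1:3] <- lab
      row <- row + 3L
    }
  }

  outer <- (n_lay - 1L) * nv + seq_len(nv)
  unit <- ico$verts
  az <- spec$probe_angles * pi / 180
  dir_stim <- c(cos(az[["stim"]]), sin(az[["stim"]]), 0)
  dir_ipsi <- c(cos(az[["ipsi"]]), sin(az[["ipsi"]]), 0)
  dir_contra <- dir_ipsi * c(-1, 1, 1)

  stim <- outer[which.max(unit %*% dir_stim)]
  cosr <- cos(spec$patch_radius_deg * pi / 180)
  patch <- function(d) {
    sel <- which(unit %*% d >= cosr)
    if (!length(sel)) sel <- which.max(unit %*% d)
    outer[sel]
  }

  tet4_mesh(nodes, elements, region,
            node_sets = list(stim_site = stim,
                             ipsi_cochlea = patch(dir_ipsi),
                             contra_cochlea = patch(dir_contra)))
}

#' Calibrate layer thicknesses to target masses
#'
#' Adjusts the bone and lining thicknesses of a [shell_spec()] (at fixed
#' outer radius) so that `density x mesh layer volume` equals each target
#' mass. The faceted-sphere volume factor of the chosen refinement level is
#' accounted for analytically, so the calibrated mesh masses are exact to
#' round-off, well within the 1 % contract.
#'
#' @param spec a [shell_spec()] carrying the target masses.
#' @param densities named numeric, kg/m^3, with entries `bone` and
#'   `polyurethane` (or a [material_set()] whose materials carry `rho`).
#' @return the calibrated `shell_spec`.
#' @examples
#' sp <- calibrate_masses(shell_spec(refinement_level = 2),
#'                        c(bone = 870.23, polyurethane = 997.40))
#' sp$bone_thickness
#' @export
calibrate_masses <- function(spec, densities) {
  validate_shell_spec(spec)
  if (inherits(densities, "material_set"))
    densities <- vapply(densities, function(m) m$rho, numeric(1))
  if (!all(c("bone", "polyurethane") %in% names(densities)))
    stop("`densities` must name 'bone' and 'polyurethane'")
  if (any(densities <= 0)) stop("densities must be positive")
  if (spec$target_bone_mass <= 0 || spec$target_lining_mass <= 0)
    stop("target masses must be positive")

  fac <- icosphere_volume_factor(spec$refinement_level)
  shell_inner_radius <- function(r_outer, target_volume) {
    cube <- r_outer^3 - target_volume / (4 * pi / 3 * fac)
    if (cube <= 0)
      stop("mass target unreachable: required layer volume exceeds the ",
           "sphere of radius ", format(r_outer), " m")
    cube^(1 / 3)
  }
  v_bone <- spec$target_bone_mass / densities[["bone"]]
  v_lining <- spec$target_lining_mass / densities[["polyurethane"]]
  r_mid <- shell_inner_radius(spec$outer_radius, v_bone)
  r_in <- shell_inner_radius(r_mid, v_lining)

  spec$bone_thickness <- spec$outer_radius - r_mid
  spec$lining_thickness <- r_mid - r_in
  validate_shell_spec(spec)
  spec
}
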