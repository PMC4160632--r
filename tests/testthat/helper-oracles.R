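# Shared fixtures and independent oracles. Expensive fixtures (the
# calibrated test surrogate and its baseline sweep) are built lazily once
# per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

table1_densities <- c(bone = 870.23, polyurethane = 997.40)

unit_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

# two tets sharing the face (2,3,4)
two_tet_mesh <- function(regions = c("bone", "bone")) {
  tet4_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(1, 1, 1)),
            rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)),
            regions)
}

# unit cube split into 6 tetrahedra around the main diagonal (Kuhn)
cube_mesh <- function(region = "bone") {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  idx <- function(x, y, z) 1L + x + 2L * y + 4L * z
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  els <- t(apply(perms, 1L, function(p) {
    steps <- diag(3)[p, , drop = FALSE]
    pts <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    apply(pts, 1L, function(q) idx(q[1], q[2], q[3]))
  }))
  tet4_mesh(v, els, region)
}

# random well-shaped tetrahedron (unit tet perturbed, positive volume)
random_tet <- function() {
  repeat {
    coords <- unit_tet + matrix(stats::runif(12, -0.15, 0.15), 4L, 3L)
    v <- vibroskull:::tet_signed_volumes(coords, matrix(1:4, 1L))
    if (v > 0.02) return(coords)
  }
}

# Independent quadrature oracle for the tet4 stiffness: 4-point Gauss rule
# on the reference tetrahedron mapped to the element, with B assembled
# from finite-difference-free closed-form shape gradients recomputed here.
tet4_stiffness_quadrature <- function(coords, D) {
  a <- 0.5854101966249685; b <- 0.1381966011250105
  bary <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  A <- cbind(coords[2, ] - coords[1, ], coords[3, ] - coords[1, ],
             coords[4, ] - coords[1, ])
  V <- det(A) / 6
  Ainv <- solve(A)
  G <- rbind(-colSums(Ainv), Ainv)   # constant over the element
  Bm <- matrix(0, 6, 12)
  for (nd in 1:4) {
    c0 <- 3 * (nd - 1)
    Bm[1, c0 + 1] <- G[nd, 1]; Bm[2, c0 + 2] <- G[nd, 2]
    Bm[3, c0 + 3] <- G[nd, 3]
    Bm[4, c0 + 2] <- G[nd, 3]; Bm[4, c0 + 3] <- G[nd, 2]
    Bm[5, c0 + 1] <- G[nd, 3]; Bm[5, c0 + 3] <- G[nd, 1]
    Bm[6, c0 + 1] <- G[nd, 2]; Bm[6, c0 + 2] <- G[nd, 1]
  }
  Ke <- matrix(0, 12, 12)
  for (q in 1:4) Ke <- Ke + (V / 4) * t(Bm) %*% D %*% Bm  # 4-pt Gauss, w = V/4
  Ke
}

# dense scatter-add assembly oracle
dense_assembly_oracle <- function(mesh, materials) {
  n <- 3L * n_nodes(mesh)
  K <- matrix(0, n, n); M <- matrix(0, n, n)
  for (e in seq_len(n_elements(mesh))) {
    mat <- materials[[mesh$region[e]]]
    D <- constitutive_matrix(mat$E1, mat$nu)
    nd <- mesh$elements[e, ]
    coords <- mesh$nodes[nd, , drop = FALSE]
    Ke <- tet4_stiffness(coords, D)
    Me <- tet4_mass(coords, mat$rho)
    dofs <- rep(3L * nd, each = 3L) + c(-2L, -1L, 0L)
    K[dofs, dofs] <- K[dofs, dofs] + Ke
    M[dofs, dofs] <- M[dofs, dofs] + Me
  }
  list(K = K, M = M)
}

# closed-form transfer of a grounded 2-dof chain with hysteretic damping:
# ground -k1- m1 -k2- m2, force F on mass 1
two_dof_transfer <- function(m1, m2, k1, k2, eta, f, F = 1) {
  w <- 2 * pi * f
  kk1 <- k1 * (1 + 1i * eta); kk2 <- k2 * (1 + 1i * eta)
  a11 <- kk1 + kk2 - w^2 * m1
  a12 <- -kk2
  a22 <- kk2 - w^2 * m2
  det <- a11 * a22 - a12 * a12
  c(x1 = (a22 * F) / det, x2 = (-a12 * F) / det)
}

two_dof_system <- function(m1, m2, k1, k2, eta) {
  K1 <- matrix(c(k1 + k2, -k2, -k2, k2), 2, 2)
  harmonic_system(M = diag(c(m1, m2)), K1 = K1, K2 = eta * K1)
}

# single grounded mass-spring resonator; |Z| dips at sqrt(k/m)/(2 pi)
sdof_system <- function(m, k, eta) {
  harmonic_system(M = matrix(m), K1 = matrix(k), K2 = matrix(eta * k))
}

# the standard small surrogate used by sweep-based tests
test_surrogate <- function() {
  cached("surrogate", {
    sp <- calibrate_masses(
      shell_spec(refinement_level = 2, layers_bone = 2, layers_lining = 2),
      table1_densities)
    mesh <- generate_shell(sp)
    sys <- assemble_system(mesh, material_preset())
    load <- point_load(mesh, node_set = "stim_site", direction = c(1, 0, 0))
    list(spec = sp, mesh = mesh, sys = sys, load = load)
  })
}

test_surrogate_sweep <- function() {
  cached("surrogate_sweep", {
    su <- test_surrogate()
    solve_sweep(su$sys, su$load, frequency_grid(60))
  })
}

first_resonance <- function(imp) {
  ex <- find_extrema(imp)
  ex <- ex[ex$type == "resonance", , drop = FALSE]
  if (!nrow(ex)) return(NULL)
  ex[1L, ]
}
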