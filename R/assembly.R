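# Element kernels for the 4-node constant-strain tetrahedron and the
# global sparse assembly. Damping enters only through the imaginary part
# of the stiffness: K(f) = K1 + 1i * K2(f), with K2(f) the sum of the
# per-region elastic stiffnesses scaled by their loss factors. There is no
# separate viscous damping matrix, and no essential boundary conditions
# are applied (free-free structure).

# Shape-function gradients of the linear tet: rows of G are grad N_a.
tet4_gradients <- function(coords) {
  A <- cbind(coords[2L, ] - coords[1L, ],
             coords[3L, ] - coords[1L, ],
             coords[4L, ] - coords[1L, ])
  V <- det(A) / 6
  if (!is.finite(V) || abs(V) <= 1e-14 * max(abs(A))^3 || V == 0)
    stop("degenerate (zero-volume) tetrahedron")
  Ainv <- solve(A)          # row i of Ainv is grad N_{i+1}
  G <- rbind(-colSums(Ainv), Ainv)
  list(V = V, G = G)
}

# Strain-displacement matrix B (6 x 12), Voigt order
# (exx, eyy, ezz, gyz, gxz, gxy), engineering shear, dofs grouped per node.
tet4_b_matrix <- function(G) {
  B <- matrix(0, 6L, 12L)
  for (a in 1:4) {
    col <- 3L * (a - 1L)
    gx <- G[a, 1L]; gy <- G[a, 2L]; gz <- G[a, 3L]
    B[1L, col + 1L] <- gx
    B[2L, col + 2L] <- gy
    B[3L, col + 3L] <- gz
    B[4L, col + 2L] <- gz; B[4L, col + 3L] <- gy
    B[5L, col + 1L] <- gz; B[5L, col + 3L] <- gx
    B[6L, col + 1L] <- gy; B[6L, col + 2L] <- gx
  }
  B
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' Computes `Ke = V * t(B) %*% D %*% B` with the constant-strain B of the
#' 4-node tetrahedron. One-point integration is exact here because B is
#' constant over the element. The result is symmetric and its nullspace
#' contains the three rigid translations and three infinitesimal rotations.
#' A complex constitutive matrix scales Ke entrywise.
#'
#' @param coords 4 x 3 matrix of node positions (element must have positive
#'   signed volume; a degenerate element is an error).
#' @param D 6 x 6 constitutive matrix from [constitutive_matrix()].
#' @return 12 x 12 (possibly complex) symmetric matrix; dofs are grouped
#'   per node as (x, y, z).
#' @export
tet4_stiffness <- function(coords, D) {
  g <- tet4_gradients(coords)
  if (g$V < 0) stop("element has negative orientation; reorder its nodes")
  B <- tet4_b_matrix(g$G)
  Ke <- g$V * crossprod(B, D %*% B)
  (Ke + t(Ke)) / 2
}

#' Element mass matrix of a linear tetrahedron
#'
#' The consistent mass matrix: per axis, diagonal blocks `rho V / 10` and
#' off-diagonal blocks `rho V / 20`; each axis row-sums to `rho V`.
#' With `lumped = TRUE` the row-sum diagonal lumping `rho V / 4` per node
#' is returned instead.
#'
#' @param coords 4 x 3 matrix of node positions.
#' @param rho density in kg/m^3 (>= 0).
#' @param lumped use row-sum lumping.
#' @return 12 x 12 real positive-semidefinite matrix.
#' @export
tet4_mass <- function(coords, rho, lumped = FALSE) {
  g <- tet4_gradients(coords)
  V <- abs(g$V)
  if (rho < 0) stop("rho must be >= 0")
  if (lumped) return(diag(rep(rho * V / 4, 12L)))
  M4 <- matrix(1, 4L, 4L) + diag(4L)
  (rho * V / 20) * (M4 %x% diag(3L))
}

#' Assemble the global mass and stiffness structure of a mesh
#'
#' Scatter-adds every element's consistent mass and elastic stiffness into
#' global sparse matrices. The stiffness is kept per region so that the
#' frequency-dependent complex stiffness
#' `K(f) = K1 + 1i * sum_r eta_r(f) * K_r` can be formed at any frequency
#' without re-assembly (the storage moduli are frequency-independent).
#' The dof of node `n`, axis `a` (1 = x, 2 = y, 3 = z) is `3 (n - 1) + a`.
#'
#' @param mesh a [tet4_mesh()].
#' @param materials a [material_set()] covering every region of the mesh.
#' @param lumped use lumped element mass matrices.
#' @return an object of class `assembled_system` with fields `M` (real
#'   sparse symmetric), `K_regions` (per-region real sparse stiffness),
#'   `K1` (their sum), `M_regions`, `materials`, `n_dof`, `node_sets`,
#'   `nodes`.
#' @export
assemble_system <- function(mesh, materials, lumped = FALSE) {
  stopifnot(inherits(mesh, "tet4_mesh"))
  materials <- material_set(materials)
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop("no material for region(s): ", paste(missing, collapse = ", "))

  n_dof <- 3L * n_nodes(mesh)
  K_regions <- list()
  M_regions <- list()
  for (r in regions) {
    mat <- materials[[r]]
    D <- constitutive_matrix(mat$E1, mat$nu)
    els <- which(mesh$region == r)
    ne <- length(els)
    iidx <- integer(144L * ne); jidx <- integer(144L * ne)
    kx <- numeric(144L * ne); mx <- numeric(144L * ne)
    pos <- 0L
    for (e in els) {
      nd <- mesh$elements[e, ]
      coords <- mesh$nodes[nd, , drop = FALSE]
      Ke <- tet4_stiffness(coords, D)
      Me <- tet4_mass(coords, mat$rho, lumped = lumped)
      dofs <- rep(3L * nd, each = 3L) + c(-2L, -1L, 0L)
      idx <- pos + 1:144
      iidx[idx] <- rep(dofs, times = 12L)
      jidx[idx] <- rep(dofs, each = 12L)
      kx[idx] <- as.vector(Ke)
      mx[idx] <- as.vector(Me)
      pos <- pos + 144L
    }
    K_regions[[r]] <- Matrix::sparseMatrix(i = iidx, j = jidx, x = kx,
                                           dims = c(n_dof, n_dof))
    M_regions[[r]] <- Matrix::sparseMatrix(i = iidx, j = jidx, x = mx,
                                           dims = c(n_dof, n_dof))
  }

  harmonic_system(M = Reduce(`+`, M_regions),
                  K1 = Reduce(`+`, K_regions),
                  K_regions = K_regions,
                  M_regions = M_regions,
                  materials = materials,
                  node_sets = mesh$node_sets,
                  nodes = mesh$nodes)
}

#' Low-level constructor for an assembled system
#'
#' Wraps explicit global matrices as a system the harmonic solver accepts;
#' useful for lumped-parameter oracles (spring-mass chains) and tests.
#' Supply either `K_regions` + `materials` (loss models drive `K2(f)`) or
#' a fixed `K2` matrix (or `NULL` for an undamped system).
#'
#' @param M real sparse (or dense) symmetric mass matrix.
#' @param K1 real sparse symmetric elastic stiffness.
#' @param K_regions optional named list of per-region stiffness matrices.
#' @param M_regions optional named list of per-region mass matrices.
#' @param materials optional [material_set()] (required with `K_regions`).
#' @param K2 optional fixed imaginary stiffness part.
#' @param node_sets,nodes optional mesh metadata carried through to probes.
#' @return an `assembled_system`.
#' @export
harmonic_system <- function(M, K1, K_regions = NULL, M_regions = NULL,
                            materials = NULL, K2 = NULL,
                            node_sets = list(), nodes = NULL) {
  M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
  K1 <- methods::as(methods::as(K1, "generalMatrix"), "CsparseMatrix")
  if (!is.null(K2))
    K2 <- methods::as(methods::as(K2, "generalMatrix"), "CsparseMatrix")
  structure(
    list(M = M, K1 = K1, K_regions = K_regions, M_regions = M_regions,
         materials = materials, K2_fixed = K2,
         n_dof = nrow(M), node_sets = node_sets, nodes = nodes),
    class = "assembled_system")
}

#' Complex stiffness at a frequency
#'
#' Returns `K(f) = K1 + 1i K2(f)` as its real and imaginary parts. With
#' all loss factors zero (or no damping information) `K2` is the zero
#' matrix.
#'
#' @param system an [assemble_system()] result.
#' @param f frequency in Hz (> 0).
#' @return list with sparse real matrices `K1` and `K2`.
#' @export
stiffness_at <- function(system, f) {
  stopifnot(inherits(system, "assembled_system"))
  if (f <= 0) stop("frequency must be positive")
  if (!is.null(system$K2_fixed))
    return(list(K1 = system$K1, K2 = system$K2_fixed))
  if (is.null(system$K_regions))
    return(list(K1 = system$K1, K2 = system$K1 * 0))
  K2 <- NULL
  for (r in names(system$K_regions)) {
    eta <- loss_factor(system$materials[[r]]$loss, f)
    term <- eta * system$K_regions[[r]]
    K2 <- if (is.null(K2)) term else K2 + term
  }
  list(K1 = system$K1, K2 = K2)
}

#' Total mass of the assembled system or one region
#'
#' Integrates the consistent mass matrix: one third of the sum of all
#' entries of the (region-restricted) mass matrix, i.e. the x-axis row sum
#' `1' M 1`, which equals `sum(rho_e V_e)` exactly.
#'
#' @param system an [assemble_system()] result.
#' @param region region label or `"all"`.
#' @return mass in kg.
#' @export
total_mass <- function(system, region = "all") {
  stopifnot(inherits(system, "assembled_system"))
  if (identical(region, "all")) return(sum(system$M) / 3)
  if (is.null(system$M_regions) || !region %in% names(system$M_regions))
    stop("unknown region '", region, "'")
  sum(system$M_regions[[region]]) / 3
}

#' @export
print.assembled_system <- function(x, ...) {
  cat("<assembled_system> ", x$n_dof, " dofs",
      if (!is.null(x$K_regions))
        paste0(", regions: ", paste(names(x$K_regions), collapse = ", ")),
      "\n", sep = "")
  cat("  total mass: ", format(total_mass(x)), " kg\n", sep = "")
  invisible(x)
}
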