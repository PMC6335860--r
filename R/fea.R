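# Voxel-based linear elastic FEA: one trilinear 8-node hexahedron per bone
# voxel, shared nodes between face-adjacent voxels, 2x2x2 Gauss integration.
# Units are mm / N / MPa throughout, so energies come out in N*mm = mJ and
# strain energy density in mJ/mm3 (reported as uJ/mm3, x1000).

dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  if (d[1] > 1L) {
    out[-d[1], , ] <- out[-d[1], , ] | m[-1L, , ]
    out[-1L, , ] <- out[-1L, , ] | m[-d[1], , ]
  }
  if (d[2] > 1L) {
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1L, ]
    out[, -1L, ] <- out[, -1L, ] | m[, -d[2], ]
  }
  if (d[3] > 1L) {
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1L]
    out[, , -1L] <- out[, , -1L] | m[, , -d[3]]
  }
  out
}

largest_component3d <- function(mask) {
  remaining <- mask
  best <- NULL
  n_comp <- 0L
  while (any(remaining)) {
    n_comp <- n_comp + 1L
    cur <- array(FALSE, dim = dim(mask))
    cur[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- dilate6(cur) & remaining
      if (sum(grown) == sum(cur)) break
      cur <- grown
    }
    if (is.null(best) || sum(cur) > sum(best)) best <- cur
    remaining <- remaining & !cur
  }
  list(mask = best, n_components = n_comp)
}

# local node order: standard trilinear hexahedron, bottom face counter-
# clockwise then top face; offsets in (x, y, z)
hex_offsets <- cbind(x = c(0, 1, 1, 0, 0, 1, 1, 0),
                     y = c(0, 0, 1, 1, 0, 0, 1, 1),
                     z = c(0, 0, 0, 0, 1, 1, 1, 1))

#' Build a hexahedral mesh from a voxel mask
#'
#' Each masked voxel becomes one 8-node solid element with physical edge
#' lengths equal to the voxel spacing; face-adjacent voxels share nodes.
#' When the mask has several 6-connected components, only the largest is
#' kept and a warning reports the removed fragment count (floating fragments
#' would make the system singular).
#'
#' @param mask 3-D logical array (`[y, x, z]`).
#' @param spacing `(dx, dy, dz)` voxel spacing, mm.
#' @return An object of class `fe_model` with fields `elements` (ne x 8
#'   node ids), `nodes` (n x 3 coordinates, mm), `voxel_index` (linear index
#'   of each element's voxel in the original array), `spacing`, `dims`.
#' @export
build_mesh <- function(mask, spacing) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-D logical array")
  if (!any(mask)) stop("empty mask: no voxels to mesh")
  if (any(spacing <= 0)) stop("spacing must be positive")
  comp <- largest_component3d(mask)
  if (comp$n_components > 1L) {
    warning(sprintf("mask has %d disconnected components; %d floating fragment(s) (%d voxels) removed",
                    comp$n_components, comp$n_components - 1L,
                    sum(mask) - sum(comp$mask)))
    mask <- comp$mask
  }
  d <- dim(mask)
  vox_lin <- which(mask)
  vox <- arrayInd(vox_lin, d)  # (iy, ix, iz), 1-based
  nxp <- d[2] + 1L; nyp <- d[1] + 1L
  # lattice node key, lexicographic (z, y, x): x fastest
  node_key <- function(ix, iy, iz) ((iz - 1L) * nyp + (iy - 1L)) * nxp + ix
  keys <- matrix(0, nrow(vox), 8L)
  for (k in 1:8)
    keys[, k] <- node_key(vox[, 2] + hex_offsets[k, "x"],
                          vox[, 1] + hex_offsets[k, "y"],
                          vox[, 3] + hex_offsets[k, "z"])
  uk <- sort(unique(as.vector(keys)))
  elements <- matrix(match(keys, uk), nrow(vox), 8L)
  k0 <- uk - 1
  ix <- k0 %% nxp
  iy <- (k0 %/% nxp) %% nyp
  iz <- k0 %/% (nxp * nyp)
  nodes <- cbind(x = ix * spacing[1], y = iy * spacing[2], z = iz * spacing[3])
  structure(list(elements = elements, nodes = nodes,
                 voxel_index = vox_lin, dims = d,
                 spacing = as.numeric(spacing), poisson = 0.3,
                 moduli = NULL, fixed_dofs = NULL, load = NULL,
                 site = NULL, total_force = NULL),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %d elements, %d nodes, spacing %.3g x %.3g x %.3g mm\n",
              nrow(x$elements), nrow(x$nodes),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Trilinear hexahedron stiffness matrix
#'
#' Full 2x2x2 Gauss integration of `B' D B` over a rectangular 8-node
#' element of edge lengths `spacing`; isotropic elasticity. Degrees of
#' freedom are node-major: `(ux1, uy1, uz1, ux2, ...)`.
#'
#' @param e Young's modulus, MPa.
#' @param poisson Poisson's ratio, `[0, 0.5)`.
#' @param spacing `(dx, dy, dz)` edge lengths, mm.
#' @return Symmetric 24 x 24 matrix, N/mm.
#' @export
hex_stiffness <- function(e, poisson, spacing) {
  if (e <= 0) stop("modulus must be positive")
  if (poisson < 0 || poisson >= 0.5)
    stop("poisson must lie in [0, 0.5): incompressible limit not supported")
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  lam <- e * poisson / ((1 + poisson) * (1 - 2 * poisson))
  mu <- e / (2 * (1 + poisson))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  s <- 2 * hex_offsets - 1  # corner signs in (x, y, z)
  g <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- dx * dy * dz / 8
  for (gx in c(-g, g)) for (gy in c(-g, g)) for (gz in c(-g, g)) {
    dN <- matrix(0, 8, 3)
    for (i in 1:8) {
      dN[i, 1] <- s[i, 1] * (1 + s[i, 2] * gy) * (1 + s[i, 3] * gz) / 8 * (2 / dx)
      dN[i, 2] <- s[i, 2] * (1 + s[i, 1] * gx) * (1 + s[i, 3] * gz) / 8 * (2 / dy)
      dN[i, 3] <- s[i, 3] * (1 + s[i, 1] * gx) * (1 + s[i, 2] * gy) / 8 * (2 / dz)
    }
    B <- matrix(0, 6, 24)
    for (i in 1:8) {
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- dN[i, 1]
      B[2, c0 + 2] <- dN[i, 2]
      B[3, c0 + 3] <- dN[i, 3]
      B[4, c0 + 1] <- dN[i, 2]; B[4, c0 + 2] <- dN[i, 1]
      B[5, c0 + 2] <- dN[i, 3]; B[5, c0 + 3] <- dN[i, 2]
      B[6, c0 + 1] <- dN[i, 3]; B[6, c0 + 3] <- dN[i, 1]
    }
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

#' Assign per-element moduli to a mesh
#'
#' @param model an `fe_model`.
#' @param field an `element_field` from [map_materials()], or a numeric
#'   vector with one modulus (MPa) per element, in element order.
#' @return The model with moduli attached.
#' @export
set_materials <- function(model, field) {
  stopifnot(inherits(model, "fe_model"))
  field <- as.numeric(field)
  if (length(field) == 1L) field <- rep(field, nrow(model$elements))
  if (length(field) != nrow(model$elements))
    stop("one modulus per element is required")
  if (any(!is.finite(field)) || any(field <= 0))
    stop("element moduli must be finite and positive")
  model$moduli <- field
  model
}

top_layer_nodes <- function(model) {
  zt <- max(model$nodes[, "z"])
  which(model$nodes[, "z"] > zt - model$spacing[3] / 2)
}

bottom_layer_nodes <- function(model) {
  zb <- min(model$nodes[, "z"])
  which(model$nodes[, "z"] < zb + model$spacing[3] / 2)
}

#' Apply loads and constraints for the standard load cases
#'
#' Spine (pure compression): the superior endplate nodes carry the total
#' force vertically downward -- equal nodal shares by default, or
#' area-consistent ("tributary") shares that reproduce a uniform pressure
#' exactly -- while the inferior surface is constrained. Hip (sideways-fall
#' style): nodes on the superior head patch are loaded with equal-magnitude
#' forces pointing at the head centre (scaled so the resultant magnitude
#' equals the total force) and the distal node layer is fully fixed.
#'
#' @param model an `fe_model`.
#' @param site `"spine"` or `"hip"`.
#' @param total_force resultant force in N; defaults 2000 N (spine),
#'   1000 N (hip).
#' @param constraint `"fixed"` (all base dofs, the pipeline default) or
#'   `"roller"` (vertical fixity plus minimal lateral constraints, used for
#'   uniaxial verification where free lateral expansion is required).
#' @param load_distribution `"uniform_nodal"` or `"tributary"` (spine only).
#' @param patch_fraction hip only: radius of the loaded head patch as a
#'   fraction of the top-surface radius.
#' @return The model with `load` (3n vector, N) and `fixed_dofs` attached.
#' @export
apply_boundary_conditions <- function(model, site,
                                      total_force = NULL,
                                      constraint = c("fixed", "roller"),
                                      load_distribution = c("uniform_nodal", "tributary"),
                                      patch_fraction = 0.6) {
  stopifnot(inherits(model, "fe_model"))
  site <- match_site(site)
  constraint <- match.arg(constraint)
  load_distribution <- match.arg(load_distribution)
  if (is.null(total_force)) total_force <- if (site == "spine") 2000 else 1000
  n <- nrow(model$nodes)
  f <- numeric(3L * n)
  bot <- bottom_layer_nodes(model)
  top <- top_layer_nodes(model)
  if (!length(top) || !length(bot)) stop("no surface nodes found for the load patch")

  if (site == "spine") {
    if (load_distribution == "uniform_nodal") {
      w <- rep(1, length(top))
    } else {
      # tributary: 1/4 share per adjacent top element face
      zt <- max(model$nodes[, "z"])
      elem_top_z <- model$nodes[model$elements[, 5], "z"] + model$spacing[3] / 2
      top_elems <- which(model$nodes[model$elements[, 5], "z"] > zt - model$spacing[3])
      w <- numeric(n)
      for (k in 5:8) {
        tab <- tabulate(model$elements[top_elems, k], nbins = n)
        w <- w + tab / 4
      }
      w <- w[top]
      if (!any(w > 0)) stop("no surface nodes found for the load patch")
    }
    f[3 * top] <- -total_force * w / sum(w)
  } else {
    zr <- range(model$nodes[, "z"])
    ez <- model$nodes[model$elements[, 1], "z"] + model$spacing[3] / 2
    head_sel <- ez >= zr[1] + 0.7 * diff(zr)
    if (!any(head_sel)) head_sel <- rep(TRUE, nrow(model$elements))
    centers <- (model$nodes[model$elements[, 1], , drop = FALSE] +
                model$nodes[model$elements[, 7], , drop = FALSE]) / 2
    head_center <- colMeans(centers[head_sel, , drop = FALSE])
    tc <- colMeans(model$nodes[top, , drop = FALSE])
    rad <- sqrt((model$nodes[top, "x"] - tc["x"])^2 +
                (model$nodes[top, "y"] - tc["y"])^2)
    patch <- top[rad <= patch_fraction * max(max(rad), model$spacing[1])]
    if (!length(patch)) stop("no surface nodes found for the load patch")
    dirs <- t(apply(model$nodes[patch, , drop = FALSE], 1,
                    function(p) {
                      v <- head_center - p
                      nv <- sqrt(sum(v^2))
                      if (nv == 0) c(0, 0, -1) else v / nv
                    }))
    resultant_dir <- colSums(dirs)
    mag <- total_force / sqrt(sum(resultant_dir^2))
    for (ax in 1:3) f[3 * (patch - 1L) + ax] <- mag * dirs[, ax]
  }

  if (constraint == "fixed" || site == "hip") {
    fixed <- as.vector(outer(c(-2L, -1L, 0L), 3L * bot, `+`))
  } else {
    fixed <- 3L * bot  # vertical rollers
    a_node <- bot[order(model$nodes[bot, "x"], model$nodes[bot, "y"])][1]
    b_node <- bot[order(-model$nodes[bot, "x"], model$nodes[bot, "y"])][1]
    fixed <- c(fixed, 3L * a_node - 2L, 3L * a_node - 1L)
    fixed <- c(fixed, if (model$nodes[b_node, "x"] != model$nodes[a_node, "x"])
      3L * b_node - 1L else 3L * b_node - 2L)
  }
  model$fixed_dofs <- sort(unique(fixed))
  model$load <- f
  model$site <- site
  model$total_force <- total_force
  resultant <- sqrt(sum(c(sum(f[seq(1, 3 * n, 3)]), sum(f[seq(2, 3 * n, 3)]),
                          sum(f[seq(3, 3 * n, 3)]))^2))
  stopifnot(abs(resultant - total_force) < 1e-6)
  model
}

assemble_stiffness <- function(model) {
  K0 <- hex_stiffness(1, model$poisson, model$spacing)
  edof <- matrix(0L, nrow(model$elements), 24L)
  for (k in 1:8) {
    edof[, 3 * k - 2] <- 3L * model$elements[, k] - 2L
    edof[, 3 * k - 1] <- 3L * model$elements[, k] - 1L
    edof[, 3 * k] <- 3L * model$elements[, k]
  }
  idx_r <- rep(1:24, times = 24)
  idx_c <- rep(1:24, each = 24)
  k0vec <- K0[cbind(idx_r, idx_c)]
  ndof <- 3L * nrow(model$nodes)
  K <- Matrix::sparseMatrix(
    i = as.vector(edof[, idx_r]),
    j = as.vector(edof[, idx_c]),
    x = as.vector(model$moduli %o% k0vec),
    dims = c(ndof, ndof))
  list(K = K, K0 = K0, edof = edof)
}

jacobi_pcg <- function(K, b, tol, max_iter) {
  d <- Matrix::diag(K)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    Kp <- as.vector(K %*% p)
    alpha <- rz / sum(p * Kp)
    x <- x + alpha * p
    r <- r - alpha * Kp
    res <- sqrt(sum(r^2)) / b_norm
    history[it] <- res
    if (res <= tol) return(list(x = x, iterations = it, history = history))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("CG failed to converge in %d iterations (final relative residual %.3e)",
               max_iter, history[length(history)]))
}

#' Solve the constrained linear elastic system
#'
#' Assembles the global sparse stiffness matrix, eliminates the Dirichlet
#' dofs, and solves `K u = f`. The default direct sparse Cholesky route is
#' checked against a relative residual of `tol`; a Jacobi-preconditioned
#' conjugate-gradient solver is available as `method = "cg"`.
#'
#' @param model an `fe_model` with materials and boundary conditions set.
#' @param method `"direct"` or `"cg"`.
#' @param tol relative residual tolerance.
#' @param max_iter CG iteration cap; default `10 * ndof`.
#' @return An object of class `fea_result`: `displacements` (n x 3, mm),
#'   `element_energy` (mJ), `sed` (uJ/mm3), `total_energy` (mJ),
#'   `average_sed` (uJ/mm3), `external_work` (mJ), `residual`.
#' @export
solve_fea <- function(model, method = c("direct", "cg"), tol = 1e-8,
                      max_iter = NULL) {
  stopifnot(inherits(model, "fe_model"))
  method <- match.arg(method)
  if (is.null(model$moduli)) stop("set_materials() must be called before solving")
  if (is.null(model$load) || is.null(model$fixed_dofs) || !length(model$fixed_dofs))
    stop("unconstrained system: apply_boundary_conditions() must fix at least one dof")
  asm <- assemble_stiffness(model)
  ndof <- 3L * nrow(model$nodes)
  free <- setdiff(seq_len(ndof), model$fixed_dofs)
  Kff <- asm$K[free, free, drop = FALSE]
  ff <- model$load[free]
  u <- numeric(ndof)
  if (all(ff == 0)) {
    residual <- 0
  } else if (method == "direct") {
    uf <- as.vector(Matrix::solve(Matrix::forceSymmetric(Kff), ff))
    residual <- sqrt(sum((as.vector(Kff %*% uf) - ff)^2)) / sqrt(sum(ff^2))
    if (residual > tol)
      warning(sprintf("direct solve residual %.3e exceeds tol %.1e", residual, tol))
    u[free] <- uf
  } else {
    if (is.null(max_iter)) max_iter <- 10L * length(free)
    sol <- jacobi_pcg(Kff, ff, tol, max_iter)
    u[free] <- sol$x
    residual <- sol$history[sol$iterations]
  }
  U <- matrix(u[t(asm$edof)], ncol = 24, byrow = TRUE)
  en <- 0.5 * model$moduli * rowSums((U %*% asm$K0) * U)  # mJ per element
  v_elem <- prod(model$spacing)
  total <- sum(en)
  structure(list(
    displacements = matrix(u, ncol = 3, byrow = TRUE,
                           dimnames = list(NULL, c("ux", "uy", "uz"))),
    element_energy = en,
    sed = en / v_elem * 1000,
    total_energy = total,
    average_sed = total / (length(en) * v_elem) * 1000,
    external_work = 0.5 * sum(model$load * u),
    residual = residual,
    method = method), class = "fea_result")
}

#' @export
print.fea_result <- function(x, ...) {
  cat(sprintf("<fea_result> total strain energy %.6g mJ, average SED %.6g uJ/mm3 (residual %.2e)\n",
              x$total_energy, x$average_sed, x$residual))
  invisible(x)
}

#' Strain energy summaries of a solved model
#'
#' @param result an `fea_result`.
#' @param model the solved `fe_model`.
#' @return List with `average_sed` (volume-weighted mean, uJ/mm3),
#'   `total_energy` (mJ), and the per-element `sed` field (uJ/mm3).
#' @export
energy_metrics <- function(result, model) {
  stopifnot(inherits(result, "fea_result"), inherits(model, "fe_model"))
  list(average_sed = result$average_sed,
       total_energy = result$total_energy,
       sed = result$sed)
}

#' Export mesh and results as legacy VTK
#'
#' Unstructured-grid ASCII VTK with hexahedral cells, point displacements,
#' and cell strain energy density -- loadable in ParaView.
#'
#' @param model an `fe_model`.
#' @param path output `.vtk` path.
#' @param result optional `fea_result` to attach fields from.
#' @export
write_vtk <- function(model, path, result = NULL) {
  stopifnot(inherits(model, "fe_model"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(model$nodes); ne <- nrow(model$elements)
  writeLines(c("# vtk DataFile Version 3.0", "voxel FE model", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  utils::write.table(model$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  utils::write.table(cbind(8L, model$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  if (!is.null(result)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    utils::write.table(result$displacements, con, row.names = FALSE,
                       col.names = FALSE)
    writeLines(c(sprintf("CELL_DATA %d", ne),
                 "SCALARS sed double 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(result$sed), con)
  }
  invisible(path)
}
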