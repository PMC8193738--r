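# per-element material arrays for the assembly kernel
build_material_arrays <- function(mesh, materials) {
  ne <- nrow(mesh$elems)
  mtype <- integer(ne)
  mpar <- matrix(0, ne, 4)
  mfib <- mesh$fibres %||% matrix(0, ne, 6)
  rg <- mesh$region
  bone <- rg %in% c(REGION[["bone_caudal"]], REGION[["bone_cranial"]])
  ec <- rg %in% c(REGION[["endcap_bottom"]], REGION[["endcap_top"]])
  af <- rg == REGION[["af"]]
  np <- rg == REGION[["np"]]
  # linear elastic (St. Venant-Kirchhoff in total-Lagrangian form)
  mtype[bone] <- 0L
  mpar[bone, 1] <- mesh$bone_E[bone]
  mpar[bone, 2] <- materials$bone_nu
  mtype[ec] <- 0L
  mpar[ec, 1] <- materials$pmma_E
  mpar[ec, 2] <- materials$pmma_nu
  mtype[af] <- 2L
  mpar[af, 1] <- materials$af_c10
  mpar[af, 2] <- materials$af_k1
  mpar[af, 3] <- materials$af_k2
  mpar[af, 4] <- materials$K_af
  mtype[np] <- 1L
  mpar[np, 1] <- materials$np_c10
  mpar[np, 2] <- materials$np_c01
  mpar[np, 3] <- materials$K_np
  if (any(bone & is.na(mesh$bone_E %||% NA)))
    stop("bone elements without assigned modulus")
  list(mtype = mtype, mpar = mpar, mfib = mfib,
       volform = volform_code(materials$volumetric_form))
}

newton_solve <- function(mesh, mats, fixed_dofs, fixed_vals, u0 = NULL,
                         tol = 1e-6, etol = 1e-8, max_iter = 30) {
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  free <- setdiff(seq_len(ndof), fixed_dofs)
  u <- u0 %||% matrix(0, nn, 3)
  uv <- as.vector(t(u))  # dof order: 3(node-1)+comp
  uv[fixed_dofs] <- fixed_vals
  iters <- 0L
  res_hist <- numeric(0)
  repeat {
    iters <- iters + 1L
    um <- matrix(uv, nn, 3, byrow = TRUE)
    asm <- cpp_assemble(mesh$nodes, mesh$elems - 1L, um, mats$mtype,
                        mats$mpar, mats$mfib, mats$volform, TRUE)
    if (!isTRUE(asm$ok))
      return(list(converged = FALSE, reason = "inverted element",
                  u = um, iters = iters, res_hist = res_hist))
    asm$fint <- as.numeric(asm$fint)
    r <- asm$fint[free]
    ref <- max(sqrt(sum(asm$fint[fixed_dofs]^2)), 1e-6)
    rn <- sqrt(sum(r^2))
    if (!is.finite(rn) || !is.finite(ref))
      return(list(converged = FALSE, reason = "non-finite residual",
                  u = um, iters = iters, res_hist = res_hist))
    res_hist <- c(res_hist, rn / ref)
    if (rn / ref < tol)
      return(list(converged = TRUE, u = um, fint = asm$fint,
                  energy = asm$energy, iters = iters, res_hist = res_hist))
    if (iters > max_iter)
      return(list(converged = FALSE, reason = "max Newton iterations",
                  u = um, iters = iters, res_hist = res_hist))
    K <- Matrix::sparseMatrix(i = as.integer(asm$Ki), j = as.integer(asm$Kj),
                              x = as.numeric(asm$Kx), dims = c(ndof, ndof))
    du <- tryCatch(
      as.numeric(Matrix::solve(K[free, free, drop = FALSE], -r)),
      error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du)))
      return(list(converged = FALSE, reason = "singular tangent",
                  u = um, iters = iters, res_hist = res_hist))
    # energy-criterion early exit: negligible incremental work
    if (abs(sum(du * r)) < etol * max(abs(asm$energy), 1e-12) && iters > 1)
      return(list(converged = TRUE, u = um, fint = asm$fint,
                  energy = asm$energy, iters = iters, res_hist = res_hist))
    uv[free] <- uv[free] + du
  }
}

#' Solve one axial-compression displacement step
#'
#' Quasi-static total-Lagrangian solution of the specimen model under a
#' prescribed platen displacement: the inferior endcap face is clamped, the
#' superior face is fixed transversely and driven axially. Newton-Raphson
#' with load substepping (adaptive halving on divergence) and a consistent
#' tangent from the constitutive models. Convergence when the free residual
#' norm falls below `tol` times the constraint-force norm, or when the
#' incremental energy criterion is met.
#'
#' @param model a `specimen_model` from [build_specimen_model()].
#' @param materials a [material_params()].
#' @param displacement platen displacement, mm (>= 0, compression).
#' @param warm_start optional nodal displacement matrix to start from.
#' @param n_substeps initial number of equal substeps.
#' @param max_halvings maximum adaptive halvings on divergence.
#' @param tol relative residual tolerance.
#' @return A `solve_result`: `u` (N x 3 nodal displacements, mm),
#'   `reaction_N` (axial compressive reaction at the top face),
#'   `convergence` log tibble, `model` reference.
#' @export
solve_step <- function(model, materials, displacement, warm_start = NULL,
                       n_substeps = 5, max_halvings = 8, tol = 1e-6) {
  stopifnot(inherits(model, "specimen_model"), displacement >= 0)
  mesh <- model$mesh
  mats <- build_material_arrays(mesh, materials)
  nn <- nrow(mesh$nodes)
  if (displacement == 0) {
    res <- list(u = matrix(0, nn, 3), reaction_N = 0,
                convergence = tibble::tibble(substep = integer(),
                                             target_mm = numeric(),
                                             iters = integer(),
                                             residual = numeric()),
                model = model)
    class(res) <- "solve_result"
    return(res)
  }
  u <- warm_start
  reached <- if (is.null(warm_start)) 0 else attr(warm_start, "displacement") %||% 0
  log <- list()
  dstep <- (displacement - reached) / n_substeps
  halvings <- 0L
  fint <- NULL
  while (reached < displacement - 1e-12) {
    target <- min(reached + dstep, displacement)
    bc <- build_bcs(mesh, target)
    sol <- newton_solve(mesh, mats, bc$fixed_dofs, bc$values, u0 = u,
                        tol = tol)
    if (!sol$converged) {
      halvings <- halvings + 1L
      if (halvings > max_halvings)
        stop("solver failed to converge at ", signif(target, 4),
             " mm after ", max_halvings, " halvings (", sol$reason,
             "; last residual ", signif(tail(sol$res_hist, 1), 3), ")")
      dstep <- dstep / 2
      next
    }
    u <- sol$u
    fint <- sol$fint
    reached <- target
    log[[length(log) + 1]] <- tibble::tibble(
      substep = length(log) + 1L, target_mm = target,
      iters = sol$iters, residual = tail(sol$res_hist, 1))
  }
  top_z <- 3 * (model$top_nodes - 1) + 3
  res <- list(u = u, reaction_N = -sum(fint[top_z]),
              convergence = dplyr::bind_rows(log), model = model)
  attr(res$u, "displacement") <- reached
  class(res) <- "solve_result"
  res
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("<solve_result> reaction %.2f N, %d substeps, max |u| %.3f mm\n",
              x$reaction_N, nrow(x$convergence), max(abs(x$u))))
  invisible(x)
}

#' Predicted marker bulge from a solved step
#'
#' Transverse-plane displacement norm of the surface node mapped to each
#' marker.
#'
#' @param result a `solve_result`.
#' @param model the `specimen_model` (defaults to the one in `result`).
#' @param specimen_id,step identifiers recorded in the output.
#' @return A bulge tibble as from [compute_bulge()].
#' @export
predict_bulge <- function(result, model = result$model,
                          specimen_id = "s1", step = 1L) {
  mm <- model$marker_map
  ux <- result$u[mm$node, 1]
  uy <- result$u[mm$node, 2]
  tibble::tibble(specimen_id = specimen_id, marker_id = mm$marker_id,
                 zone = mm$zone, step = as.integer(step),
                 bulge_mm = sqrt(ux^2 + uy^2))
}

#' Forward load--displacement curve
#'
#' Sequential warm-started solves at increasing platen displacements,
#' returning the axial reaction per step (the computational peak load).
#'
#' @param model a `specimen_model`.
#' @param materials a [material_params()].
#' @param displacements increasing cumulative displacements, mm.
#' @param keep_solutions if `TRUE`, attach the per-step `solve_result`s.
#' @return Tibble `(step, displacement_mm, load_N)`; attribute `solutions`
#'   when requested.
#' @export
forward_load_curve <- function(model, materials, displacements,
                               keep_solutions = FALSE) {
  stopifnot(all(diff(displacements) > 0))
  u <- NULL
  loads <- numeric(length(displacements))
  sols <- list()
  for (i in seq_along(displacements)) {
    res <- solve_step(model, materials, displacements[i], warm_start = u)
    u <- res$u
    loads[i] <- res$reaction_N
    if (keep_solutions) sols[[i]] <- res
  }
  out <- tibble::tibble(step = seq_along(displacements),
                        displacement_mm = displacements, load_N = loads)
  if (keep_solutions) attr(out, "solutions") <- sols
  out
}
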