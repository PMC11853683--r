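# Steady-state solution of the coupled reaction-diffusion system:
# external ADP/ATP fields (finite-volume grid, Dirichlet cytosolic boundary)
# coupled to a well-mixed matrix pool through membrane fluxes.
#
# The discrete steady equations per external cell i (mM/ms):
#   F_A = D_A (L A + b_A) + k_f T - k_r Pi_e A - c_i J_ANT(A_i, T_i; matrix)
#   F_T = D_T (L T + b_T) - k_f T + k_r Pi_e A + c_i J_ANT(A_i, T_i; matrix)
# where L is the grid Laplacian, b the Dirichlet contribution, and
# c_i = (membrane face area adjacent to i) / (cell volume * 602214)
# converts a flux density (molecules/ms/um^2) into mM/ms.
# The matrix pool closes the system: sum(J_ANT dS) = J_AS * S_IM at steady
# state, with ADP_m + ATP_m conserved.
#
# With equal diffusivities the sum field A + T obeys pure diffusion with
# uniform Dirichlet data (membrane exchange and the kinase are 1:1
# conversions), so its steady solution is the uniform boundary value; the
# system then reduces exactly to a single-species Newton iteration. The
# reported residuals are always those of the full, unreduced two-species
# equations. Lumens without a Dirichlet connection (detached cristae)
# conserve their own adenine total; it is fixed to the cytosolic total.

#' Dirichlet boundary conditions (cytosolic composition)
#'
#' @param ADP_cyt cytosolic ADP (mM). The standard workload sweep spans
#'   0.0185-0.074 mM.
#' @param ATP_cyt cytosolic ATP (mM)
#' @return object of class `boundary_conditions`
#' @export
boundary_conditions <- function(ADP_cyt, ATP_cyt = 4.0) {
  if (ADP_cyt <= 0 || ATP_cyt <= 0)
    stop("boundary_conditions: concentrations must be > 0", call. = FALSE)
  structure(list(ADP_cyt = ADP_cyt, ATP_cyt = ATP_cyt),
            class = "boundary_conditions")
}

#' @keywords internal
.solver_setup <- function(model) {
  mask <- model$mask; region <- model$region
  dims <- dim(mask); nd <- length(dims)
  h <- model$h
  ext <- which(mask == 1L)
  n <- length(ext)
  if (n == 0L) stop("solver: model has no external solute cells", call. = FALSE)
  ext_rank <- integer(length(mask)); ext_rank[ext] <- seq_len(n)
  strides <- c(1L, dims[1], if (nd == 3L) dims[1] * dims[2])
  ia <- arrayInd(ext, dims)

  dir_count <- integer(n)
  cris_count <- integer(n); ibm_count <- integer(n)
  nbmat <- matrix(0L, n, 2L * nd)
  ip <- jp <- integer(0)
  col <- 0L
  for (d in seq_len(nd)) for (s in c(-1L, 1L)) {
    col <- col + 1L
    valid <- ia[, d] + s >= 1L & ia[, d] + s <= dims[d]
    nb <- ext + s * strides[d]
    nb_mask <- rep(0L, n)
    nb_mask[valid] <- mask[nb[valid]]
    dir_count <- dir_count + (nb_mask == 3L)
    reg <- region[ext]
    is_mem <- nb_mask == 2L
    cris_count <- cris_count + (is_mem & reg > 0L)
    ibm_count <- ibm_count + (is_mem & reg == -1L)
    is_ext <- nb_mask == 1L
    nbmat[is_ext, col] <- ext_rank[nb[is_ext]]
    if (s == 1L) {
      w <- which(is_ext)
      ip <- c(ip, w); jp <- c(jp, ext_rank[nb[w]])
    }
  }
  deg <- tabulate(c(ip, jp), nbins = n) + dir_count
  Lap <- Matrix::sparseMatrix(i = c(ip, jp, seq_len(n)),
                              j = c(jp, ip, seq_len(n)),
                              x = c(rep(1 / h^2, 2L * length(ip)), -deg / h^2),
                              dims = c(n, n))
  Lap <- methods::as(Matrix::forceSymmetric(Lap), "CsparseMatrix")

  # reachability from Dirichlet cells (frontier BFS over ext graph)
  reach <- dir_count > 0L
  frontier <- which(reach)
  while (length(frontier)) {
    nbs <- unique(as.vector(nbmat[frontier, , drop = FALSE]))
    nbs <- nbs[nbs > 0L]
    frontier <- nbs[!reach[nbs]]
    reach[frontier] <- TRUE
  }

  face_area <- if (model$dim == 2L) h * model$depth else h^2
  cellvol <- if (model$dim == 2L) h^2 * model$depth else h^3
  mem_faces <- cris_count + ibm_count
  mem_area <- mem_faces * face_area
  cmem <- mem_area / (cellvol * .MOLEC_PER_UM3_PER_MM)
  list(n = n, ext = ext, ext_rank = ext_rank, Lap = Lap,
       dir_count = dir_count, mem_area = mem_area, cmem = cmem,
       mem_idx = which(mem_faces > 0L), reach = reach,
       S_CRIS = sum(cris_count) * face_area,
       S_IBM = sum(ibm_count) * face_area + model$extra_ibm,
       face_area = face_area, cellvol = cellvol)
}

# Single-species Newton for the equal-diffusivity reduction.
# Returns list(A, J (full-length, 0 off-membrane), iters, ok)
#' @keywords internal
.solve_fields_eqD <- function(su, p, s, krP, b_A, adm, atm, A,
                              tol, max_iter) {
  D <- p$D_ADP
  mi <- su$mem_idx
  cm <- su$cmem[mi]
  J <- numeric(su$n)
  iters <- 0L; ok <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    A <- pmin(pmax(A, 1e-12), s - 1e-12)
    core <- .ant_flux_core(A[mi], s[mi] - A[mi], adm, atm, p, deriv = TRUE)
    FA <- D * (as.numeric(su$Lap %*% A) + b_A) + p$k_f * (s - A) - krP * A
    FA[mi] <- FA[mi] - cm * core$J
    dJ <- numeric(su$n)
    dJ[mi] <- cm * (core$dJ_dADPe - core$dJ_dATPe)   # both terms >= 0
    M <- -D * su$Lap + Matrix::Diagonal(su$n, p$k_f + krP + dJ)
    delta <- as.numeric(Matrix::solve(M, FA))
    A <- A + delta
    if (max(abs(delta)) < tol * max(s)) { ok <- TRUE; break }
  }
  A <- pmin(pmax(A, 1e-12), s - 1e-12)
  core <- .ant_flux_core(A[mi], s[mi] - A[mi], adm, atm, p, deriv = FALSE)
  J[mi] <- core
  list(A = A, J = J, iters = iters, ok = ok)
}

# Coupled two-species Newton (general diffusivities; Dirichlet-connected
# domains only).
#' @keywords internal
.solve_fields_coupled <- function(su, p, krP, b_A, b_T, adm, atm, A, T,
                                  tol, max_iter) {
  n <- su$n
  mi <- su$mem_idx
  cm_full <- su$cmem
  iters <- 0L; ok <- FALSE
  scl <- max(b_T, 1) # loose magnitude scale
  for (it in seq_len(max_iter)) {
    iters <- it
    A <- pmax(A, 1e-12); T <- pmax(T, 1e-12)
    core <- .ant_flux_core(A[mi], T[mi], adm, atm, p, deriv = TRUE)
    J <- dJA <- dJT <- numeric(n)
    J[mi] <- core$J; dJA[mi] <- core$dJ_dADPe; dJT[mi] <- core$dJ_dATPe
    FA <- p$D_ADP * (as.numeric(su$Lap %*% A) + b_A) + p$k_f * T - krP * A -
      cm_full * J
    FT <- p$D_ATP * (as.numeric(su$Lap %*% T) + b_T) - p$k_f * T + krP * A +
      cm_full * J
    MAA <- -p$D_ADP * su$Lap + Matrix::Diagonal(n, krP + cm_full * dJA)
    MTT <- -p$D_ATP * su$Lap + Matrix::Diagonal(n, p$k_f - cm_full * dJT)
    MAT <- Matrix::Diagonal(n, -p$k_f + cm_full * dJT)
    MTA <- Matrix::Diagonal(n, -krP - cm_full * dJA)
    M <- rbind(cbind(MAA, MAT), cbind(MTA, MTT))
    delta <- as.numeric(Matrix::solve(M, c(FA, FT)))
    A <- A + delta[seq_len(n)]
    T <- T + delta[n + seq_len(n)]
    if (max(abs(delta)) < tol * scl) { ok <- TRUE; break }
  }
  A <- pmax(A, 1e-12); T <- pmax(T, 1e-12)
  J <- numeric(n)
  J[mi] <- .ant_flux_core(A[mi], T[mi], adm, atm, p, deriv = FALSE)
  list(A = A, T = T, J = J, iters = iters, ok = ok)
}

#' Solve the reaction-diffusion system to steady state
#'
#' Computes the steady state of the external ADP/ATP fields and the
#' well-mixed matrix pool for a spatial model, parameter set and cytosolic
#' boundary composition. The matrix adenine total `ADP_m0 + ATP_m0` is
#' conserved; the steady matrix partitioning is found by a monotone scalar
#' root-find on the matrix flux balance (total ANT uptake = total synthase
#' flux), with the external fields re-solved by Newton iteration inside.
#'
#' @param model a `crista_model`
#' @param p a [kinetic_params()]
#' @param bc a [boundary_conditions()]
#' @param tol relative tolerance on the field Newton updates and on the
#'   matrix flux balance
#' @param max_iter maximum Newton iterations per field solve
#' @param ADP_m0,ATP_m0 initial (resting) matrix totals (mM); their sum is
#'   the conserved matrix adenine total
#' @return an object of class `crista_steady`
#' @examples
#' m <- build_uniform_2d(0.32, "one_end", domain_w = 0.04, h = 0.004)
#' st <- solve_steady_state(m, kinetic_params(), boundary_conditions(0.037))
#' st$ADP_m; st$J_AS
#' @export
solve_steady_state <- function(model, p, bc, tol = 1e-8, max_iter = 60,
                               ADP_m0 = 0.72, ATP_m0 = 0.44) {
  stopifnot(inherits(model, "crista_model"), inherits(p, "kinetic_params"),
            inherits(bc, "boundary_conditions"))
  su <- .solver_setup(model)
  krP <- p$k_r * .resolve_Pi_e(p, bc)
  h2 <- model$h^2
  b_A <- su$dir_count * bc$ADP_cyt / h2
  b_T <- su$dir_count * bc$ATP_cyt / h2
  s_tot <- bc$ADP_cyt + bc$ATP_cyt
  eqD <- isTRUE(all.equal(p$D_ADP, p$D_ATP))
  if (!eqD && any(!su$reach))
    stop("solver: detached lumens require equal ADP/ATP diffusivities",
         call. = FALSE)
  Atot <- ADP_m0 + ATP_m0
  S_IM <- su$S_CRIS + su$S_IBM
  ftol <- min(tol, 1e-9)

  env <- new.env()
  env$A <- rep(bc$ADP_cyt, su$n)
  env$T <- rep(bc$ATP_cyt, su$n)
  env$inner <- 0L; env$evals <- 0L; env$all_ok <- TRUE
  s_vec <- rep(s_tot, su$n)   # exact steady sum field (uniform Dirichlet data)

  field_solve <- function(adm, atm) {
    if (eqD) {
      fs <- .solve_fields_eqD(su, p, s_vec, krP, b_A, adm, atm, env$A,
                              ftol, max_iter)
      env$A <- fs$A
      fs$T <- s_vec - fs$A
    } else {
      fs <- .solve_fields_coupled(su, p, krP, b_A, b_T, adm, atm,
                                  env$A, env$T, ftol, max_iter)
      env$A <- fs$A; env$T <- fs$T
    }
    env$inner <- env$inner + fs$iters
    env$evals <- env$evals + 1L
    env$all_ok <- env$all_ok && fs$ok
    fs
  }

  bc_state_J <- function(adm, atm)
    .ant_flux_core(bc$ADP_cyt, bc$ATP_cyt, adm, atm, p)

  G <- function(adm) {
    atm <- Atot - adm
    fs <- field_solve(adm, atm)
    tot_ant <- sum(fs$J * su$mem_area) +
      model$extra_ibm * bc_state_J(adm, atm)
    tot_as <- .as_flux_core(adm, atm, p) * S_IM
    tot_ant - tot_as
  }

  eps <- 1e-6 * Atot
  root <- stats::uniroot(G, c(eps, Atot - eps), tol = 1e-11 * Atot,
                         maxiter = 200)
  adm <- root$root; atm <- Atot - adm
  fs <- field_solve(adm, atm)
  A <- fs$A; T <- fs$T

  # full unreduced residuals
  FA <- p$D_ADP * (as.numeric(su$Lap %*% A) + b_A) + p$k_f * T - krP * A -
    su$cmem * fs$J
  FT <- p$D_ATP * (as.numeric(su$Lap %*% T) + b_T) - p$k_f * T + krP * A +
    su$cmem * fs$J
  react_scale <- max(p$k_f * bc$ATP_cyt, krP * bc$ADP_cyt)
  field_res <- max(abs(c(FA, FT))) / react_scale
  tot_ant <- sum(fs$J * su$mem_area) + model$extra_ibm * bc_state_J(adm, atm)
  J_AS <- .as_flux_core(adm, atm, p)
  mat_scale <- max(abs(J_AS) * S_IM, abs(tot_ant), 1e-6 * p$V_AS * S_IM)
  mat_res <- abs(tot_ant - J_AS * S_IM) / mat_scale

  res <- list(model = model, params = p, bc = bc,
              Pi_e = .resolve_Pi_e(p, bc),
              ADP_m = adm, ATP_m = atm, adenine_total = Atot,
              ADP_e = A, ATP_e = T,
              J_ANT = fs$J, mem_area = su$mem_area,
              J_ANT_total = tot_ant,
              J_AS = J_AS, J_AS_total = J_AS * S_IM,
              S = list(S_IBM = su$S_IBM, S_CRIS = su$S_CRIS, S_IM = S_IM),
              ext = su$ext, ext_rank = su$ext_rank,
              residuals = list(field = field_res, matrix = mat_res),
              iterations = list(outer = env$evals, inner = env$inner),
              converged = env$all_ok && field_res < 1e-6 && mat_res < 1e-6)
  class(res) <- "crista_steady"
  if (!res$converged)
    warning("solve_steady_state: not fully converged (field residual ",
            format(field_res, digits = 3), ", matrix residual ",
            format(mat_res, digits = 3), ")", call. = FALSE)
  res
}

#' Extract a solute field as a grid array
#'
#' @param st a `crista_steady`
#' @param what `"ADP"`, `"ATP"` or `"J_ANT"` (flux density on
#'   membrane-adjacent cells)
#' @return array shaped like the model grid; `NA` outside the external domain
#' @export
field_array <- function(st, what = c("ADP", "ATP", "J_ANT")) {
  what <- match.arg(what)
  v <- switch(what, ADP = st$ADP_e, ATP = st$ATP_e, J_ANT = st$J_ANT)
  out <- array(NA_real_, dim(st$model$mask))
  out[st$ext] <- v
  out
}

#' @export
print.crista_steady <- function(x, ...) {
  cat("Steady state of the crista reaction-diffusion model\n")
  cat(sprintf("  ADP_cyt = %g mM; matrix ADP = %.4f, ATP = %.4f mM\n",
              x$bc$ADP_cyt, x$ADP_m, x$ATP_m))
  cat(sprintf("  J(AS) = %.3f molecules/ms/um^2 (total %.3f molecules/ms over %.4g um^2)\n",
              x$J_AS, x$J_AS_total, x$S$S_IM))
  cat(sprintf("  residuals: field %.2e, matrix balance %.2e; converged: %s\n",
              x$residuals$field, x$residuals$matrix, x$converged))
  invisible(x)
}

#' @export
summary.crista_steady <- function(object, ...) {
  rng <- range(object$ADP_e)
  cat("External ADP field: ", sprintf("%.5f - %.5f mM", rng[1], rng[2]), "\n")
  cat("Sum field spread (uniformity check): ",
      format(diff(range(object$ADP_e + object$ATP_e)), digits = 3), " mM\n")
  print(object)
  invisible(object)
}

#' @export
residuals.crista_steady <- function(object, ...) {
  unlist(object$residuals)
}

#' @export
plot.crista_steady <- function(x, what = "ADP", ...) {
  arr <- field_array(x, what)
  if (x$model$dim == 3L) arr <- arr[, , ceiling(dim(arr)[3] / 2)]
  graphics::image(seq_len(nrow(arr)) * x$model$h,
                  seq_len(ncol(arr)) * x$model$h,
                  arr, xlab = "x (um)", ylab = "y (um)",
                  main = paste0("[", what, "] field"), useRaster = TRUE, ...)
  invisible(x)
}
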