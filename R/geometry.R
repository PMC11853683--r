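# Discretized 2-D and 3-D spatial models of cristae.
#
# A `crista_model` is a cell-centered regular grid with an integer mask:
#   0 = void, 1 = external solute domain (intracristal space + boundary
#   layer), 2 = matrix, 3 = Dirichlet boundary cell.
# A parallel `region` array labels external cells: -1 = boundary layer,
# k > 0 = lumen of crista k. Membrane faces are faces between an external
# cell and a matrix cell; they carry ANT, and the whole inner membrane
# (IBM + crista) carries ATP synthase. Faces whose external cell is a lumen
# cell are crista membrane; faces whose external cell is boundary layer are
# inner boundary membrane (IBM).

.new_crista_model <- function(dim, h, depth, mask, region, cristae,
                              extra_ibm = 0, meta = list()) {
  m <- list(dim = dim, h = h, depth = depth, mask = mask, region = region,
            cristae = cristae, extra_ibm = extra_ibm, meta = meta)
  m$matrix_volume <- sum(mask == 2L) * if (dim == 2L) h^2 * depth else h^3
  class(m) <- "crista_model"
  m
}

#' @keywords internal
.snap <- function(x, h) {
  n <- as.integer(round(x / h))
  if (abs(n * h - x) > 1e-9 + 1e-6 * h)
    stop("geometry: length ", x, " um is not a multiple of the grid spacing h = ",
         h, " um", call. = FALSE)
  n
}

# Linear index helper for 2-D/3-D arrays
.lin_idx <- function(dims, i, j, k = NULL) {
  if (is.null(k)) (j - 1L) * dims[1] + i
  else ((k - 1L) * dims[2] + (j - 1L)) * dims[1] + i
}

#' Build a uniform 2-D crista array model
#'
#' Parallel unbranched cristae (lumen width 20 nm, spaced 20 nm apart by
#' default) run vertically across the domain, opening to a thin cytosolic
#' boundary layer through crista junctions (CJs) at one end, both ends, or
#' neither (detached). Dirichlet boundary cells carrying the cytosolic
#' composition form the outermost rows beyond the boundary layers; lateral
#' domain faces are no-flux (the array is periodic across its width, so a
#' one-crista unit cell `domain_w = 0.04` reproduces the infinite array).
#'
#' @param L_CRIS crista length (um); `0` builds the no-crista baseline model
#' @param cj_config `"one_end"`, `"both_ends"` or `"none"`
#' @param domain_w domain width (um); the model packs
#'   `floor(domain_w / (crista_w + spacing))` cristae
#' @param domain_h domain height (um) or `NULL` to auto-size to the crista
#'   plus boundary layers
#' @param h grid spacing (um)
#' @param crista_w lumen width (um)
#' @param spacing matrix gap between adjacent cristae (um)
#' @param blayer boundary-layer thickness between IBM and Dirichlet cells (um)
#' @param tip_gap matrix gap beyond a closed crista tip (um)
#' @return a `crista_model`
#' @examples
#' m <- build_uniform_2d(0.32, "one_end", domain_w = 0.04)
#' surface_ledger(m)
#' @export
build_uniform_2d <- function(L_CRIS,
                             cj_config = c("one_end", "both_ends", "none"),
                             domain_w = 0.76, domain_h = NULL, h = 0.002,
                             crista_w = 0.02, spacing = 0.02,
                             blayer = 0.02, tip_gap = 0.04) {
  cj_config <- match.arg(cj_config)
  if (L_CRIS < 0) stop("geometry: L_CRIS must be >= 0", call. = FALSE)
  nL <- as.integer(round(L_CRIS / h))
  nw <- .snap(crista_w, h); nsp <- .snap(spacing, h)
  nbl <- .snap(blayer, h); ntip <- .snap(tip_gap, h)
  pitch <- nw + nsp
  nx <- as.integer(floor(domain_w / h + 1e-9))
  n_cris <- if (nL > 0L) as.integer(floor(domain_w / ((crista_w + spacing)) + 1e-9)) else 0L
  if (nL > 0L && n_cris < 1L)
    stop("geometry: domain_w too small to hold a crista", call. = FALSE)

  n_int <- if (nL == 0L) ntip
  else switch(cj_config,
              both_ends = nL,
              one_end   = nL + ntip,
              none      = nL + 2L * ntip)
  nbl_bot <- nbl_top <- nbl
  needed <- (n_int + 2L * nbl + 2L) * h
  if (!is.null(domain_h)) {
    if (domain_h < needed - 1e-9)
      stop("geometry: crista of length ", L_CRIS,
           " um does not fit in domain_h = ", domain_h, " um (needs >= ",
           needed, " um)", call. = FALSE)
    extra <- as.integer(round(domain_h / h)) - (n_int + 2L * nbl + 2L)
    nbl_bot <- nbl + extra %/% 2L
    nbl_top <- nbl + extra - extra %/% 2L
  }
  ny <- 1L + nbl_bot + n_int + nbl_top + 1L

  mask <- matrix(2L, nx, ny)
  region <- matrix(0L, nx, ny)
  mask[, 1L] <- 3L; mask[, ny] <- 3L
  bl_rows <- c(seq_len(nbl_bot) + 1L, ny - 1L - seq_len(nbl_top) + 1L)
  mask[, bl_rows] <- 1L; region[, bl_rows] <- -1L
  j0 <- 1L + nbl_bot + 1L       # first interior row
  j1 <- j0 + n_int - 1L         # last interior row

  cristae <- list()
  if (nL > 0L) {
    lum_rows <- switch(cj_config,
                       both_ends = j0:j1,
                       one_end   = (j1 - nL + 1L):j1,     # attached at top
                       none      = (j0 + ntip):(j0 + ntip + nL - 1L))
    for (k in seq_len(n_cris)) {
      c0 <- (k - 1L) * pitch + nsp %/% 2L + 1L
      cols <- c0:(c0 + nw - 1L)
      mask[cols, lum_rows] <- 1L
      region[cols, lum_rows] <- k
      midc <- cols[c(nw %/% 2L, nw %/% 2L + 1L)]
      # stations ordered from the CJ opening (top for one_end, bottom CJ
      # for both_ends; proximal end for detached)
      rows_ord <- if (cj_config == "one_end") rev(lum_rows) else lum_rows
      mid_idx <- cbind(.lin_idx(c(nx, ny), midc[1], rows_ord),
                       .lin_idx(c(nx, ny), midc[2], rows_ord))
      cristae[[k]] <- list(id = k, L = nL * h, cj = cj_config,
                           x = (seq_len(nL) - 0.5) * h,
                           midline = mid_idx)
    }
  }
  .new_crista_model(2L, h, 1, mask, region, cristae,
                    meta = list(builder = "uniform_2d", L_CRIS = L_CRIS,
                                cj_config = cj_config, n_cristae = n_cris,
                                domain_w = nx * h, domain_h = ny * h))
}

#' Build the variable-topology 2-D model (branched crista)
#'
#' A trunk crista of length `L_CRIS` with CJs at both ends plus two side
#' branches of lengths `L_CRIS/3` and `L_CRIS/4`, drawn perpendicular to the
#' trunk; each branch runs from its own CJ on the side IBM to an opening in
#' the trunk wall. The Dirichlet boundary and boundary layer surround the
#' model on all four sides.
#'
#' @param L_CRIS trunk length (um)
#' @param h grid spacing (um)
#' @param crista_w lumen width (um)
#' @param blayer boundary-layer thickness (um)
#' @param attach trunk-relative attachment heights of the two branches
#' @return a `crista_model`; cristae 1, 2, 3 are the trunk, the `L/3`
#'   branch and the `L/4` branch
#' @export
build_variable_2d <- function(L_CRIS, h = 0.002, crista_w = 0.02,
                              blayer = 0.02, attach = c(0.40, 0.60)) {
  if (L_CRIS <= 0) stop("geometry: L_CRIS must be > 0", call. = FALSE)
  nL <- .snap(L_CRIS, h)
  nw <- .snap(crista_w, h); nbl <- .snap(blayer, h)
  nLA <- as.integer(round(nL / 3)); nLB <- as.integer(round(nL / 4))
  wint <- nLA + nw + nLB
  nx <- 1L + nbl + wint + nbl + 1L
  ny <- 1L + nbl + nL + nbl + 1L
  mask <- matrix(1L, nx, ny)      # start as boundary layer ring
  region <- matrix(-1L, nx, ny)
  mask[c(1L, nx), ] <- 3L; mask[, c(1L, ny)] <- 3L
  region[c(1L, nx), ] <- 0L; region[, c(1L, ny)] <- 0L
  ix0 <- 2L + nbl; ix1 <- ix0 + wint - 1L
  jy0 <- 2L + nbl; jy1 <- jy0 + nL - 1L
  mask[ix0:ix1, jy0:jy1] <- 2L    # interior matrix
  region[ix0:ix1, jy0:jy1] <- 0L

  tx0 <- ix0 + nLA; tx1 <- tx0 + nw - 1L
  mask[tx0:tx1, jy0:jy1] <- 1L; region[tx0:tx1, jy0:jy1] <- 1L  # trunk

  br_rows <- function(frac) {
    ctr <- jy0 + as.integer(round(frac * nL))
    r0 <- min(max(ctr - nw %/% 2L, jy0), jy1 - nw + 1L)
    r0:(r0 + nw - 1L)
  }
  ra <- br_rows(attach[1])
  mask[ix0:(tx0 - 1L), ra] <- 1L; region[ix0:(tx0 - 1L), ra] <- 2L
  rb <- br_rows(attach[2])
  mask[(tx1 + 1L):ix1, rb] <- 1L; region[(tx1 + 1L):ix1, rb] <- 3L

  midc <- function(v) v[c(length(v) %/% 2L, length(v) %/% 2L + 1L)]
  tm <- midc(tx0:tx1)
  cristae <- list(
    list(id = 1L, L = nL * h, cj = "both_ends",
         x = (seq_len(nL) - 0.5) * h,
         midline = cbind(.lin_idx(c(nx, ny), tm[1], jy0:jy1),
                         .lin_idx(c(nx, ny), tm[2], jy0:jy1))),
    list(id = 2L, L = nLA * h, cj = "branch",
         x = (seq_len(nLA) - 0.5) * h,
         midline = cbind(.lin_idx(c(nx, ny), ix0:(tx0 - 1L), midc(ra)[1]),
                         .lin_idx(c(nx, ny), ix0:(tx0 - 1L), midc(ra)[2]))),
    list(id = 3L, L = nLB * h, cj = "branch",
         x = (seq_len(nLB) - 0.5) * h,
         midline = cbind(.lin_idx(c(nx, ny), rev((tx1 + 1L):ix1), midc(rb)[1]),
                         .lin_idx(c(nx, ny), rev((tx1 + 1L):ix1), midc(rb)[2])))
  )
  .new_crista_model(2L, h, 1, mask, region, cristae,
                    meta = list(builder = "variable_2d", L_CRIS = L_CRIS,
                                attach = attach,
                                branch_L = c(nLA, nLB) * h))
}

#' Build a 3-D lamellar crista model
#'
#' A lamellar crista (150 nm wide, 20 nm lumen) attached to an IBM face via
#' no CJ (detached), one 20-nm tubular CJ (`"narrow"`), one slit CJ as wide
#' as the crista (`"wide"`), or `n_cj` equally spaced 20-nm CJs on the cis
#' side (`"n_cis"`). The simulated box holds the crista, a thin matrix
#' collar, and a cytosolic boundary-layer slab in front of the IBM plane;
#' IBM surface beyond the simulated patch is carried as an analytic area
#' term (`extra_ibm`, operating at boundary-layer composition) sized so that
#' S_CRIS/S_IBM follows the nominal schedule `1.0` at `L = 0.15` um to
#' `1.8` at `L = 0.9` um (override with `ibm_ratio`).
#'
#' @param L_CRIS crista length (um); `0` builds the no-crista baseline
#' @param cj_mode `"none"`, `"narrow"`, `"wide"` or `"n_cis"`
#' @param h grid spacing (um)
#' @param n_cj number of cis-side narrow CJs when `cj_mode = "n_cis"`
#' @param width,lumen_t crista width and lumen thickness (um)
#' @param blayer boundary-layer slab thickness (um)
#' @param ibm_ratio target S_CRIS/S_IBM, or `NULL` for the length schedule
#' @return a `crista_model`
#' @export
build_lamellar_3d <- function(L_CRIS,
                              cj_mode = c("none", "narrow", "wide", "n_cis"),
                              h = 0.005, n_cj = 1L,
                              width = 0.15, lumen_t = 0.02,
                              blayer = 0.02, ibm_ratio = NULL) {
  cj_mode <- match.arg(cj_mode)
  if (L_CRIS < 0) stop("geometry: L_CRIS must be >= 0", call. = FALSE)
  nL <- as.integer(round(L_CRIS / h))
  nwid <- .snap(width, h); nth <- .snap(lumen_t, h)
  nbl <- .snap(blayer, h)
  ncol_ <- 2L                      # matrix collar cells around the lumen
  nbase <- 2L; ntipc <- 2L         # matrix slabs at crista base and tip
  nneck <- .snap(0.02, h)          # narrow CJ width (0.02 um)

  nx <- 1L + nbl + nbase + nL + ntipc
  ny <- ncol_ + nwid + ncol_
  nz <- ncol_ + nth + ncol_
  dims <- c(nx, ny, nz)
  mask <- array(2L, dims); region <- array(0L, dims)
  mask[1L, , ] <- 3L
  mask[1L + seq_len(nbl), , ] <- 1L
  region[1L + seq_len(nbl), , ] <- -1L
  yl <- (ncol_ + 1L):(ncol_ + nwid)
  zl <- (ncol_ + 1L):(ncol_ + nth)

  cristae <- list()
  if (nL > 0L) {
    xl <- (1L + nbl + nbase + 1L):(1L + nbl + nbase + nL)
    mask[xl, yl, zl] <- 1L; region[xl, yl, zl] <- 1L
    # CJ necks through the base slab
    xneck <- (1L + nbl + 1L):(1L + nbl + nbase)
    neck_cols <- switch(cj_mode,
      none = integer(0),
      wide = yl,
      narrow = {
        c0 <- ncol_ + (nwid - nneck) %/% 2L
        (c0 + 1L):(c0 + nneck)
      },
      n_cis = {
        n_cj <- as.integer(n_cj)
        if (n_cj < 1L || n_cj * nneck > nwid)
          stop("geometry: n_cj narrow CJs do not fit across the crista width",
               call. = FALSE)
        centers <- ncol_ + round((seq_len(n_cj) - 0.5) / n_cj * nwid)
        unique(unlist(lapply(centers, function(cc) {
          c0 <- cc - nneck %/% 2L
          c0 <- min(max(c0, ncol_ + 1L), ncol_ + nwid - nneck + 1L)
          c0:(c0 + nneck - 1L)
        })))
      })
    if (length(neck_cols)) {
      mask[xneck, neck_cols, zl] <- 1L
      region[xneck, neck_cols, zl] <- 1L
    }
    ym <- yl[c(nwid %/% 2L, nwid %/% 2L + 1L)]
    zm <- zl[c(nth %/% 2L, nth %/% 2L + 1L)]
    combs <- expand.grid(y = ym, z = zm)
    mid <- sapply(seq_len(nrow(combs)), function(r)
      .lin_idx(dims, xl, combs$y[r], combs$z[r]))
    cristae[[1]] <- list(id = 1L, L = nL * h, cj = cj_mode,
                         x = (seq_len(nL) - 0.5) * h, midline = mid)
  }
  m <- .new_crista_model(3L, h, NA_real_, mask, region, cristae,
                         meta = list(builder = "lamellar_3d",
                                     L_CRIS = L_CRIS, cj_mode = cj_mode,
                                     n_cj = n_cj))
  if (nL > 0L) {
    led <- surface_ledger(m)
    r <- if (!is.null(ibm_ratio)) ibm_ratio
         else min(max(1.0 + 0.8 * (L_CRIS - 0.15) / 0.75, 1.0), 1.8)
    m$extra_ibm <- max(0, led$S_CRIS / r - led$S_IBM)
    m$meta$ibm_ratio <- r
  }
  m
}

# Face scan: for each grid axis and direction, classify faces of external
# cells. Returns per-external-cell membrane face counts by class.
#' @keywords internal
.membrane_faces <- function(model) {
  mask <- model$mask; region <- model$region
  dims <- dim(mask)
  nd <- length(dims)
  ext <- which(mask == 1L)
  n_cris_faces <- n_ibm_faces <- n_dir_faces <- integer(length(ext))
  ext_rank <- integer(length(mask)); ext_rank[ext] <- seq_along(ext)
  offs <- list()
  strides <- c(1L, dims[1], if (nd == 3L) dims[1] * dims[2])
  for (d in seq_len(nd)) for (s in c(-1L, 1L)) {
    # neighbor of cell along axis d, direction s; guard the array edge
    idxa <- arrayInd(ext, dims)
    valid <- idxa[, d] + s >= 1L & idxa[, d] + s <= dims[d]
    nb <- ext + s * strides[d]
    nb_mask <- rep(0L, length(ext))       # 0 => outside the box (no-flux)
    nb_mask[valid] <- mask[nb[valid]]
    is_mem <- nb_mask == 2L
    is_dir <- nb_mask == 3L
    reg <- region[ext]
    n_cris_faces <- n_cris_faces + (is_mem & reg > 0L)
    n_ibm_faces <- n_ibm_faces + (is_mem & reg == -1L)
    n_dir_faces <- n_dir_faces + is_dir
  }
  face_area <- if (model$dim == 2L) model$h * model$depth else model$h^2
  list(ext = ext, ext_rank = ext_rank,
       n_cris_faces = n_cris_faces, n_ibm_faces = n_ibm_faces,
       n_dir_faces = n_dir_faces, face_area = face_area)
}

#' Surface-area ledger of a spatial model
#'
#' Sums membrane face areas by class: crista membrane (faces between a
#' lumen cell and the matrix), inner boundary membrane (faces between a
#' boundary-layer cell and the matrix, plus any analytic `extra_ibm` area
#' the model carries), and their total. `S_IM = S_IBM + S_CRIS` exactly.
#'
#' @param model a `crista_model`
#' @return list with `S_IBM`, `S_CRIS`, `S_IM` (um^2)
#' @export
surface_ledger <- function(model) {
  stopifnot(inherits(model, "crista_model"))
  mf <- .membrane_faces(model)
  S_CRIS <- sum(mf$n_cris_faces) * mf$face_area
  S_IBM <- sum(mf$n_ibm_faces) * mf$face_area + model$extra_ibm
  list(S_IBM = S_IBM, S_CRIS = S_CRIS, S_IM = S_IBM + S_CRIS)
}

#' @export
print.crista_model <- function(x, ...) {
  led <- surface_ledger(x)
  cat(sprintf("crista_model (%d-D, h = %g um): %s\n", x$dim, x$h,
              x$meta$builder))
  cat(sprintf("  grid %s; %d external, %d matrix cells\n",
              paste(dim(x$mask), collapse = " x "),
              sum(x$mask == 1L), sum(x$mask == 2L)))
  cat(sprintf("  cristae: %d; S_CRIS = %.4g, S_IBM = %.4g um^2 (S_CRIS/S_IM = %.3f)\n",
              length(x$cristae), led$S_CRIS, led$S_IBM,
              if (led$S_IM > 0) led$S_CRIS / led$S_IM else NA))
  cat(sprintf("  matrix volume = %.4g um^3\n", x$matrix_volume))
  invisible(x)
}
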