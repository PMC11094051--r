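# Synthetic landscapes: spatially autocorrelated covariate layers on a
# regular grid, with focal (moving-window) means at the five radii used by
# multi-scale species distribution models.

FOCAL_RADII_M <- c(75, 165, 315, 615, 1215)

default_covariate_names <- function(n) {
  base <- c("canopy", "urban_hdmd", "urban_total", "d_river", "d_highway",
            "greenness")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("cov", seq_len(n - length(base))))
}

# Shift a matrix by (di, dj) cells, zero-padding; `valid` marks in-bounds cells.
shift_matrix <- function(mat, di, dj) {
  n <- nrow(mat); m <- ncol(mat)
  out <- matrix(0, n, m)
  valid <- matrix(FALSE, n, m)
  r_lo <- max(1L, 1L - di); r_hi <- min(n, n - di)   # destination rows
  c_lo <- max(1L, 1L - dj); c_hi <- min(m, m - dj)   # destination cols
  if (r_lo <= r_hi && c_lo <= c_hi) {
    ri <- r_lo:r_hi; cj <- c_lo:c_hi
    out[ri, cj] <- mat[ri + di, cj + dj]
    valid[ri, cj] <- TRUE
  }
  list(values = out, valid = valid)
}

# Weighted moving-window mean with edge renormalization.
window_mean <- function(mat, offsets, weights) {
  acc <- matrix(0, nrow(mat), ncol(mat))
  wsum <- matrix(0, nrow(mat), ncol(mat))
  for (k in seq_len(nrow(offsets))) {
    sh <- shift_matrix(mat, offsets[k, 1L], offsets[k, 2L])
    acc <- acc + weights[k] * sh$values
    wsum <- wsum + weights[k] * sh$valid
  }
  acc / wsum
}

disc_offsets <- function(radius_m, cell_m) {
  r_cells <- floor(radius_m / cell_m)
  g <- expand.grid(di = -r_cells:r_cells, dj = -r_cells:r_cells)
  keep <- sqrt(g$di^2 + g$dj^2) * cell_m <= radius_m
  as.matrix(g[keep, , drop = FALSE])
}

#' Focal mean of a gridded layer
#'
#' Averages the cells whose centers fall within `radius_m` of each cell
#' center; windows are clipped (renormalized) at the landscape edge.
#'
#' @param mat numeric matrix (rows = x index, cols = y index).
#' @param radius_m focal radius in meters.
#' @param cell_m cell side length in meters.
#' @return matrix of the same dimension.
#' @export
focal_mean <- function(mat, radius_m, cell_m) {
  assert_scalar_number(radius_m, "radius_m", positive = TRUE)
  assert_scalar_number(cell_m, "cell_m", positive = TRUE)
  offs <- disc_offsets(radius_m, cell_m)
  window_mean(mat, offs, rep(1, nrow(offs)))
}

gaussian_smooth <- function(mat, sigma_cells) {
  if (sigma_cells < 1e-8) return(mat)
  r <- max(1L, ceiling(3 * sigma_cells))
  g <- expand.grid(di = -r:r, dj = -r:r)
  d2 <- g$di^2 + g$dj^2
  keep <- sqrt(d2) <= 3 * sigma_cells
  offs <- as.matrix(g[keep, , drop = FALSE])
  w <- exp(-d2[keep] / (2 * sigma_cells^2))
  window_mean(mat, offs, w)
}

#' Generate a synthetic landscape
#'
#' Creates `n_covariates` spatially autocorrelated layers (white noise
#' convolved with an isotropic Gaussian kernel of scale `smoothness`), each
#' standardized to mean 0 and sd 1, together with focal means at the 75, 165,
#' 315, 615, and 1215 m radii. Cells are half-open squares
#' `[x, x + cell) x [y, y + cell)` with the origin at the landscape corner.
#'
#' @param n_x,n_y grid dimensions (cells); at least 8 each.
#' @param cell_m cell side length, meters.
#' @param n_covariates number of covariate layers.
#' @param smoothness kernel scale in meters (> 0); as it shrinks below the
#'   cell size the layers approach independent white noise.
#' @param seed integer seed; identical inputs reproduce the landscape
#'   bit-for-bit.
#' @param covariate_names optional character vector of layer names; defaults
#'   to canopy / urban / distance-surrogate names used by the detection
#'   model candidate sets.
#' @return an object of class `landscape`: grid metadata, raw layers, and a
#'   list of focal-mean layers per radius.
#' @export
generate_landscape <- function(n_x, n_y, cell_m, n_covariates = 6,
                               smoothness = 400, seed = 1,
                               covariate_names = NULL) {
  assert_scalar_number(n_x, "n_x"); assert_scalar_number(n_y, "n_y")
  if (n_x < 8 || n_y < 8) stop_invalid("grid must be at least 8 x 8 cells")
  assert_scalar_number(cell_m, "cell_m", positive = TRUE)
  assert_scalar_number(n_covariates, "n_covariates", positive = TRUE)
  assert_scalar_number(smoothness, "smoothness", positive = TRUE)
  nms <- covariate_names %||% default_covariate_names(n_covariates)
  if (length(nms) != n_covariates) stop_invalid("need one name per covariate")

  sigma_cells <- smoothness / cell_m
  raw <- withr::with_seed(as.integer(seed), {
    lapply(setNames(nms, nms), function(nm) {
      z <- matrix(rnorm(n_x * n_y), n_x, n_y)
      z <- gaussian_smooth(z, sigma_cells)
      (z - mean(z)) / sd(as.vector(z))
    })
  })
  focal <- lapply(raw, function(m) {
    lapply(setNames(FOCAL_RADII_M, paste0("f", FOCAL_RADII_M)),
           function(r) focal_mean(m, r, cell_m))
  })
  structure(list(
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    cell_m = cell_m, cell_area_ha = (cell_m / 100)^2,
    radii_m = FOCAL_RADII_M, covariate_names = nms,
    raw = raw, focal = focal
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d cells of %g m (%.0f ha), %d covariates\n",
              x$n_x, x$n_y, x$cell_m, x$n_x * x$n_y * x$cell_area_ha,
              length(x$covariate_names)))
  cat("covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

n_cells <- function(landscape) landscape$n_x * landscape$n_y

#' Map planar coordinates to cell indices
#'
#' Half-open convention: a point exactly on a cell boundary belongs to the
#' upper/right cell.
#'
#' @param landscape a `landscape`.
#' @param x_m,y_m coordinate vectors in meters from the landscape origin.
#' @return integer vector of cell ids (column-major over the grid), `NA` for
#'   points outside the landscape.
#' @export
cell_at <- function(landscape, x_m, y_m) {
  ix <- floor(x_m / landscape$cell_m) + 1
  iy <- floor(y_m / landscape$cell_m) + 1
  ok <- ix >= 1 & ix <= landscape$n_x & iy >= 1 & iy <= landscape$n_y
  out <- ifelse(ok, (iy - 1) * landscape$n_x + ix, NA_integer_)
  as.integer(out)
}

focal_column_names <- function(landscape) {
  as.vector(t(outer(landscape$covariate_names, paste0("f", landscape$radii_m),
                    paste, sep = "_")))
}

#' Per-cell covariate table
#'
#' One row per grid cell (column-major), with cell-center coordinates, raw
#' layer values, and all focal-mean columns named `<covariate>_f<radius>`.
#'
#' @param landscape a `landscape`.
#' @return data.frame with `n_x * n_y` rows.
#' @export
covariate_table <- function(landscape) {
  nx <- landscape$n_x; ny <- landscape$n_y
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  out <- data.frame(
    cell_id = seq_len(nx * ny),
    x_m = (ix - 0.5) * landscape$cell_m,
    y_m = (iy - 0.5) * landscape$cell_m
  )
  for (nm in landscape$covariate_names) {
    out[[nm]] <- as.vector(landscape$raw[[nm]])
    for (r in landscape$radii_m)
      out[[paste0(nm, "_f", r)]] <- as.vector(landscape$focal[[nm]][[paste0("f", r)]])
  }
  out
}

# Focal-covariate rows for arbitrary locations (by containing cell).
cell_covariates <- function(landscape, x_m, y_m,
                            table = covariate_table(landscape)) {
  id <- cell_at(landscape, x_m, y_m)
  if (anyNA(id)) stop_invalid("location outside the landscape")
  table[id, , drop = FALSE]
}

#' Detection-stage survey covariates
#'
#' Builds the covariate columns used by the distance-sampling candidate set:
#' 75-m focal means of canopy and urban covers plus strictly positive
#' distance-to-river / distance-to-highway surrogates (a lognormal-style
#' transform of the standardized `d_river` / `d_highway` layers, in meters,
#' so that log-transformed model forms are well defined).
#'
#' @param landscape a `landscape` whose covariates include `canopy`,
#'   `urban_hdmd`, `urban_total`, `d_river`, `d_highway`.
#' @param x_m,y_m survey coordinates.
#' @return data.frame with columns `d_river`, `d_highway`, `canopy_f75`,
#'   `urban_hdmd_f75`, `urban_total_f75`.
#' @export
detection_covariates <- function(landscape, x_m, y_m) {
  need <- c("canopy", "urban_hdmd", "urban_total", "d_river", "d_highway")
  missing <- setdiff(need, landscape$covariate_names)
  if (length(missing))
    stop_invalid("landscape lacks covariates: %s", paste(missing, collapse = ", "))
  cc <- cell_covariates(landscape, x_m, y_m)
  data.frame(
    d_river = 800 * exp(0.5 * cc$d_river),
    d_highway = 800 * exp(0.5 * cc$d_highway),
    canopy_f75 = cc$canopy_f75,
    urban_hdmd_f75 = cc$urban_hdmd_f75,
    urban_total_f75 = cc$urban_total_f75
  )
}
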