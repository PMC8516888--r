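#' Solve the steady-state potential between two needle electrodes
#'
#' Solves the Laplace equation for the electric potential on a rectangular
#' slice cross-section, with Dirichlet conditions on the two electrode disks
#' (`V0` on the driven electrode at `x = +d/2`, `0` on the grounded electrode
#' at `x = -d/2`) and an insulating (zero normal derivative, mirror) condition
#' on the outer rectangle. Constant conductivity is assumed, under which the
#' potential distribution is independent of the conductivity value.
#'
#' The 5-point stencil with mirror boundary closure is assembled as a sparse
#' symmetric positive-definite system (boundary rows scaled by their cell
#' volume fraction) and solved directly by sparse Cholesky factorization.
#' The interior 5-point residual is then verified against `tol`; a direct
#' solve normally achieves residuals near machine precision.
#'
#' @param config An [electrode_config()].
#' @param grid A [grid_spec()]; must enclose both electrodes with margin
#'   (width and height at least twice the electrode spacing).
#' @param tol Relative residual tolerance: the unscaled 5-point stencil
#'   residual `|phi_E + phi_W + phi_N + phi_S - 4 phi|` at every interior
#'   non-electrode node must not exceed `tol * V0`. Default `1e-6`.
#' @return An object of class `potential_field`: the grid, the potential
#'   matrix `phi` (volts, indexed `[ix, iy]`), logical `electrode_mask`
#'   (either electrode) and `pos_mask` (driven electrode), the achieved
#'   maximum interior residual, and the configuration.
#' @seealso [analytic_two_wire()] for the unbounded-medium closed form,
#'   [field_magnitude()] for the derived field map.
#' @examples
#' pf <- solve_laplace(electrode_config(applied_voltage_V0 = 1000),
#'                     grid_spec(spacing_h = 0.5))
#' pf$phi[(pf$grid$nx + 1) / 2, (pf$grid$ny + 1) / 2]  # ~ V0/2 at the midpoint
#' @export
solve_laplace <- function(config, grid = grid_spec(), tol = 1e-6) {
  stopifnot(inherits(config, "electrode_config"), inherits(grid, "grid_spec"),
            tol > 0)
  if (config$center_spacing_d / 2 + config$radius_a >= grid$width / 2 ||
      config$radius_a >= grid$height / 2)
    stop("electrodes overlap the domain boundary")
  if (grid$width < 2 * config$center_spacing_d ||
      grid$height < 2 * config$center_spacing_d)
    stop("grid must be at least twice the electrode spacing in each direction")

  V0 <- config$applied_voltage_V0
  nx <- grid$nx; ny <- grid$ny
  em <- electrode_masks(config, grid)
  elec <- em$pos | em$neg
  free <- !elec
  N <- sum(free)
  idx <- matrix(NA_integer_, nx, ny)
  idx[free] <- seq_len(N)

  ij <- which(free, arr.ind = TRUE)
  I <- ij[, 1L]; J <- ij[, 2L]
  # cell volume fractions: 1 interior, 1/2 edges, 1/4 corners (symmetrizes
  # the mirror-closure stencil)
  w <- ifelse(I == 1L | I == nx, 0.5, 1) * ifelse(J == 1L | J == ny, 0.5, 1)

  rows <- vector("list", 4L); cols <- vector("list", 4L); vals <- vector("list", 4L)
  b <- numeric(N); dg <- numeric(N)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  for (s in seq_along(shifts)) {
    di <- shifts[[s]][1L]; dj <- shifts[[s]][2L]
    Ii <- I + di; Jj <- J + dj
    outb <- Ii < 1L | Ii > nx | Jj < 1L | Jj > ny
    # mirror closure: an out-of-domain neighbour reflects onto the opposite
    # in-domain neighbour
    Im <- ifelse(outb, I - di, Ii)
    Jm <- ifelse(outb, J - dj, Jj)
    dg <- dg + w
    nb <- idx[cbind(Im, Jm)]
    isfree <- !is.na(nb)
    rows[[s]] <- which(isfree)
    cols[[s]] <- nb[isfree]
    vals[[s]] <- -w[isfree]
    dir <- which(!isfree)
    if (length(dir))
      b[dir] <- b[dir] + w[dir] * ifelse(em$pos[cbind(Im[dir], Jm[dir])], V0, 0)
  }
  A <- Matrix::sparseMatrix(i = c(unlist(rows), seq_len(N)),
                            j = c(unlist(cols), seq_len(N)),
                            x = c(unlist(vals), dg), dims = c(N, N))
  phi_free <- if (V0 == 0) numeric(N) else
    as.numeric(Matrix::solve(Matrix::forceSymmetric(A), b))

  phi <- matrix(0, nx, ny)
  phi[em$pos] <- V0
  phi[free] <- phi_free

  res <- interior_residual(phi, elec)
  if (V0 > 0 && res > tol * V0)
    stop(sprintf("solver failed to meet tolerance: achieved residual %.3e > %.3e",
                 res, tol * V0))

  structure(list(grid = grid, phi = phi, electrode_mask = elec,
                 pos_mask = em$pos, residual = res, config = config),
            class = "potential_field")
}

# max |phi_E + phi_W + phi_N + phi_S - 4 phi| over interior non-electrode nodes
interior_residual <- function(phi, elec) {
  nx <- nrow(phi); ny <- ncol(phi)
  ii <- 2:(nx - 1L); jj <- 2:(ny - 1L)
  r <- phi[ii - 1L, jj] + phi[ii + 1L, jj] + phi[ii, jj - 1L] +
    phi[ii, jj + 1L] - 4 * phi[ii, jj]
  r[elec[ii, jj]] <- 0
  max(abs(r))
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential field: %d x %d nodes, V0 = %g V, residual %.2e\n",
              x$grid$nx, x$grid$ny, x$config$applied_voltage_V0, x$residual))
  invisible(x)
}

#' Closed-form two-wire potential in an unbounded medium
#'
#' Image-line-charge solution for two parallel cylindrical conductors of
#' radius `a` with axis spacing `d` held at potentials `V0` and `0` in an
#' unbounded homogeneous medium. With `c = d/2`, the equivalent line charges
#' sit at `x = +-b`, `b = sqrt(c^2 - a^2)`, and
#' `phi(x, y) = V0/2 + K * log(r_minus / r_plus)` with
#' `K = V0 / (2 * acosh(c / a))`, where `r_plus`, `r_minus` are the distances
#' to the line charges at `(+b, 0)` and `(-b, 0)`. The electrode at `x = +c`
#' reads `V0`. This is the independent oracle used to validate the
#' finite-difference solver away from the insulating walls.
#'
#' @param config An [electrode_config()].
#' @param points Numeric matrix (or 2-column data frame) of `(x, y)`
#'   coordinates in mm; all points must lie outside both electrode disks.
#' @return Numeric vector of potentials in volts.
#' @examples
#' cfg <- electrode_config(applied_voltage_V0 = 1000)
#' analytic_two_wire(cfg, cbind(0, 0))  # exactly V0/2 at the midpoint
#' @export
analytic_two_wire <- function(config, points) {
  stopifnot(inherits(config, "electrode_config"))
  pts <- as.matrix(points)
  stopifnot(is.numeric(pts), ncol(pts) == 2L)
  a <- config$radius_a
  cc <- config$center_spacing_d / 2
  V0 <- config$applied_voltage_V0
  inside <- (pts[, 1L] - cc)^2 + pts[, 2L]^2 < a^2 |
    (pts[, 1L] + cc)^2 + pts[, 2L]^2 < a^2
  if (any(inside))
    stop("points inside an electrode are not admissible")
  b <- sqrt(cc^2 - a^2)
  K <- V0 / (2 * acosh(cc / a))
  rp <- sqrt((pts[, 1L] - b)^2 + pts[, 2L]^2)
  rm <- sqrt((pts[, 1L] + b)^2 + pts[, 2L]^2)
  V0 / 2 + K * log(rm / rp)
}
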