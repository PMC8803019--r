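#' PS-OCT data stack
#'
#' Co-registered intensity, retardation and optic-axis volumes from
#' polarization-sensitive OCT, plus the retinal layer boundaries needed to
#' restrict depth averaging to the polarization-preserving layers.  Volumes
#' are arrays indexed `[y, x, z]` (z = depth).  Boundaries are 2-D z-index
#' maps: `ilm` (inner limiting membrane), `rnfl_gcl` (RNFL / ganglion cell
#' layer boundary) and `opl_onl` (outer plexiform / outer nuclear layer
#' boundary), with `ilm <= rnfl_gcl <= opl_onl <= depth` everywhere.
#'
#' @param intensity,retardation,axis 3-D arrays of identical shape;
#'   retardation in radians `[0, pi/2]`, axis in radians (folded mod pi).
#' @param boundaries List with matrices `ilm`, `rnfl_gcl`, `opl_onl`.
#' @param spacing_x,spacing_y Lateral pixel pitch, micrometers.
#' @return An object of class `psoct_stack`.
#' @export
psoct_stack <- function(intensity, retardation, axis, boundaries,
                        spacing_x = 1, spacing_y = 1) {
  stopifnot(length(dim(retardation)) == 3,
            all(dim(intensity) == dim(retardation)),
            all(dim(axis) == dim(retardation)))
  b <- boundaries
  stopifnot(is.matrix(b$ilm), is.matrix(b$rnfl_gcl), is.matrix(b$opl_onl),
            all(dim(b$ilm) == dim(retardation)[1:2]))
  if (any(b$ilm > b$rnfl_gcl) || any(b$rnfl_gcl > b$opl_onl) ||
      any(b$opl_onl > dim(retardation)[3])) {
    stop("boundaries must satisfy ilm <= rnfl_gcl <= opl_onl <= depth")
  }
  if (any(retardation < -1e-9) || any(retardation > pi / 2 + 1e-9)) {
    stop("retardation must lie in [0, pi/2]")
  }
  structure(
    list(intensity = intensity, retardation = retardation,
         axis = fold_axial(axis), boundaries = b,
         spacing_x = spacing_x, spacing_y = spacing_y),
    class = "psoct_stack"
  )
}

#' Depth-averaged normalized Stokes vector
#'
#' For every lateral position, averages the normalized Stokes vector
#' \deqn{(\cos 2\delta,\; \sin 2\delta \cos(\pi - 2\theta),\;
#'        \sin 2\delta \sin(\pi - 2\theta))}
#' over the depth samples strictly below the RNFL/GCL boundary down to the
#' OPL/ONL boundary -- the polarization-preserving layers, where the state
#' set by the birefringent RNFL above is carried unchanged.  The average
#' runs over exactly `opl_onl - rnfl_gcl` samples; pixels where that count
#' is zero are invalid.
#'
#' @param stack A [psoct_stack()].
#' @return List of matrices `Q`, `U`, `V` (each in `[-1, 1]`, `NA` where
#'   invalid), `n` (sample count) and logical `valid`.
#' @export
average_stokes <- function(stack) {
  d <- dim(stack$retardation)
  nz <- d[3]
  bng <- stack$boundaries$rnfl_gcl
  boo <- stack$boundaries$opl_onl
  n <- boo - bng
  q <- u <- v <- matrix(0, d[1], d[2])
  for (i in seq_len(nz)) {
    inc <- i > bng & i <= boo
    if (!any(inc)) next
    del <- stack$retardation[, , i]
    th <- stack$axis[, , i]
    qi <- cos(2 * del)
    ui <- sin(2 * del) * cos(pi - 2 * th)
    vi <- sin(2 * del) * sin(pi - 2 * th)
    q[inc] <- q[inc] + qi[inc]
    u[inc] <- u[inc] + ui[inc]
    v[inc] <- v[inc] + vi[inc]
  }
  valid <- n > 0
  q[valid] <- q[valid] / n[valid]
  u[valid] <- u[valid] / n[valid]
  v[valid] <- v[valid] / n[valid]
  q[!valid] <- u[!valid] <- v[!valid] <- NA_real_
  list(Q = q, U = u, V = v, n = n, valid = valid)
}

#' RNFL retardation and axis orientation maps from a PS-OCT stack
#'
#' Re-normalizes the depth-averaged Stokes vector to unit length and reads
#' off the cumulative RNFL retardation
#' \eqn{\delta_P = \arccos(\langle Q\rangle_R)/2} and the optic-axis
#' orientation \eqn{\phi_P = \arctan2(-\langle V\rangle_R,
#' \langle U\rangle_R)/2}, folded into `[0, pi)`.  The two-argument
#' arctangent keeps the quadrant of \eqn{(-V, U)} before halving; a
#' single-argument arctan of the ratio would lose half the axis range.
#' Note the Stokes parameterization carries a fixed quarter-turn: for a
#' depth-constant input axis \eqn{\theta_0} the extracted \eqn{\phi_P}
#' equals \eqn{\theta_0 - 90} degrees (mod 180).  Since the optic axis from
#' PS-OCT is a relative quantity that is offset-calibrated downstream
#' anyway (see [find_axis_offset()]), the constant is left as the formula
#' produces it.
#'
#' Pixels whose averaged vector norm falls below `norm_threshold` carry
#' depth-inconsistent polarization (or none at all) and are marked invalid;
#' so are pixels with no in-plane component (`U = V = 0`, no birefringence,
#' hence no axis).
#'
#' @param stack A [psoct_stack()].
#' @param norm_threshold Minimum averaged-vector norm for a usable pixel
#'   (default 0.1).
#' @return List with `retardation` (matrix, radians, `NA` invalid) and
#'   `axis` (an [axial_map()]).
#' @export
extract_polarization_maps <- function(stack, norm_threshold = 0.1) {
  av <- average_stokes(stack)
  nrm <- sqrt(av$Q^2 + av$U^2 + av$V^2)
  ok <- av$valid & !is.na(nrm) & nrm > norm_threshold
  qr <- av$Q / nrm; ur <- av$U / nrm; vr <- av$V / nrm
  delta <- 0.5 * acos(pmin(pmax(qr, -1), 1))
  delta[!ok] <- NA_real_
  inplane <- sqrt(ur^2 + vr^2)
  ok_axis <- ok & inplane > 1e-9
  phi <- matrix(NA_real_, nrow(qr), ncol(qr))
  phi[ok_axis] <- fold_axial(0.5 * atan2(-vr[ok_axis], ur[ok_axis]))
  list(retardation = delta,
       axis = axial_map(phi, ok_axis, stack$spacing_x, stack$spacing_y))
}
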