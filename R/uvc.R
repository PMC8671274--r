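#' Universal ventricular coordinate (UVC) helpers
#'
#' A UVC coordinate is a length-4 numeric `(z, rho, phi, nu)`: apicobasal
#' `z` and transmural `rho` in \[0, 1\], rotational `phi` in (-pi, pi\]
#' (wrapped), ventricular `nu` exactly -1 (LV incl. septum) or +1 (RV free
#' wall).
#'
#' @param z,rho,phi,nu coordinate components.
#' @return numeric vector of class `uvc_coord`.
#' @export
uvc_coord <- function(z, rho, phi, nu) {
  if (z < 0 || z > 1 || rho < 0 || rho > 1)
    stop("uvc_coord: z and rho must lie in [0, 1]")
  if (!nu %in% c(-1, 1)) stop("uvc_coord: nu must be -1 or +1")
  structure(c(z = z, rho = rho, phi = wrap_angle(phi), nu = nu),
            class = "uvc_coord")
}

as_uvc <- function(b) {
  if (inherits(b, "uvc_coord")) return(b)
  stopifnot(is.numeric(b), length(b) == 4)
  uvc_coord(b[1], b[2], b[3], b[4])
}

## Weighted UVC distance used by the inverse mapping: nu must match exactly
## (lexicographic priority); within a ventricle the metric is Euclidean in
## (z, rho, phi/pi) with equal weights, phi measured on the circle.
uvc_metric <- function(uvc_mat, b) {
  dz <- uvc_mat[, "z"] - b[1]
  dr <- uvc_mat[, "rho"] - b[2]
  dp <- circ_dist(uvc_mat[, "phi"], b[3]) / pi
  d2 <- dz * dz + dr * dr + dp * dp
  d2[uvc_mat[, "nu"] != b[4]] <- Inf
  d2
}

#' Map a UVC coordinate to the nearest mesh node
#'
#' Returns the mesh node whose stored UVC minimizes the weighted UVC
#' distance to `b`: the ventricular component `nu` must match exactly, then
#' a Euclidean metric in `(z, rho, phi/pi)` (with the rotational distance
#' computed on the circle) is minimized. Ties break to the lowest node
#' index.
#'
#' @param frame a `uvc_frame`.
#' @param b UVC coordinate (length-4 numeric or [uvc_coord()]).
#' @return list with `index` (node index), `point` (Cartesian mm), `uvc`
#'   (the stored coordinate) and `dist` (metric value).
#' @export
uvc_to_cartesian <- function(frame, b) {
  stopifnot(inherits(frame, "uvc_frame"))
  if (nrow(frame$uvc) == 0) stop("uvc_to_cartesian: empty frame")
  b <- as_uvc(b)
  d2 <- uvc_metric(frame$uvc, b)
  i <- which.min(d2)   # which.min returns the first (lowest) index on ties
  if (!is.finite(d2[i]))
    stop("uvc_to_cartesian: no node with nu = ", b[4], " in frame")
  list(index = i, point = frame$nodes[i, ], uvc = frame$uvc[i, ],
       dist = sqrt(d2[i]))
}

#' Map a Cartesian point to UVC via the nearest mesh node
#'
#' Returns the stored UVC of the Euclidean-nearest mesh node. The result is
#' flagged `outside = TRUE` when the point lies further than twice the
#' target edge length from any node.
#'
#' @param frame a `uvc_frame`.
#' @param x Cartesian point (length-3, mm).
#' @return list with `uvc`, `index`, `dist` (mm) and logical `outside`.
#' @export
cartesian_to_uvc <- function(frame, x) {
  stopifnot(inherits(frame, "uvc_frame"), length(x) == 3)
  if (nrow(frame$uvc) == 0) stop("cartesian_to_uvc: empty frame")
  nn <- cpp_nn1(as.numeric(x), frame$nodes, logical(0))
  d <- sqrt(nn$dist2)
  list(uvc = frame$uvc[nn$index, ], index = nn$index, dist = d,
       outside = d > 2 * frame$edge_length)
}
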