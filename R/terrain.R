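#' Elevation grid container
#'
#' Holds corner altitudes on the `(n_qx+1) x (n_qy+1)` lattice of quadrat
#' corners (corner `(i, j)` sits at `(i*s, j*s)` metres) and, optionally,
#' measured altitudes of quadrat centre points.  Centre altitudes are what
#' the edge-quadrat convexity rule needs; a bilinear interpolation of the
#' four corners cannot supply them (it reproduces the corner mean, which
#' makes edge convexity identically zero), so they must be measured or
#' generated from the same analytic surface.
#'
#' @param corner numeric matrix `(n_qx+1) x (n_qy+1)` of corner altitudes
#'   (m a.s.l.), `corner[i+1, j+1]` at lattice node `(i, j)`.
#' @param grid a [plot_grid()].
#' @param center optional numeric matrix `n_qx x n_qy` of quadrat
#'   centre-point altitudes.
#' @return An object of class `elevation_grid`.
#' @export
elevation_grid <- function(corner, grid, center = NULL) {
  stopifnot(inherits(grid, "plot_grid"))
  corner <- as.matrix(corner)
  if (!all(dim(corner) == c(grid$n_qx + 1L, grid$n_qy + 1L)))
    stop("corner lattice must be (n_qx+1) x (n_qy+1) = ",
         grid$n_qx + 1L, " x ", grid$n_qy + 1L)
  if (any(!is.finite(corner))) stop("corner lattice has missing/non-finite altitudes")
  if (!is.null(center)) {
    center <- as.matrix(center)
    if (!all(dim(center) == c(grid$n_qx, grid$n_qy)))
      stop("center matrix must be n_qx x n_qy")
    if (any(!is.finite(center))) stop("center altitudes must be finite")
  }
  structure(list(corner = corner, center = center, grid = grid),
            class = "elevation_grid")
}

#' Read corner (and optional centre) elevations from CSV
#'
#' `corner_path` holds columns `i,j,altitude` with 0-based lattice indices;
#' `center_path` (optional) holds `qx,qy,altitude` with 0-based quadrat
#' indices.
#'
#' @param corner_path CSV of corner altitudes.
#' @param grid a [plot_grid()].
#' @param center_path optional CSV of quadrat centre altitudes.
#' @return An [elevation_grid()].
#' @export
read_elevation_grid <- function(corner_path, grid, center_path = NULL) {
  cc <- utils::read.csv(corner_path, stringsAsFactors = FALSE)
  if (!all(c("i", "j", "altitude") %in% names(cc)))
    stop("corner elevation file needs columns i,j,altitude")
  corner <- matrix(NA_real_, grid$n_qx + 1L, grid$n_qy + 1L)
  corner[cbind(cc$i + 1L, cc$j + 1L)] <- cc$altitude
  center <- NULL
  if (!is.null(center_path)) {
    ct <- utils::read.csv(center_path, stringsAsFactors = FALSE)
    if (!all(c("qx", "qy", "altitude") %in% names(ct)))
      stop("center elevation file needs columns qx,qy,altitude")
    center <- matrix(NA_real_, grid$n_qx, grid$n_qy)
    center[cbind(ct$qx + 1L, ct$qy + 1L)] <- ct$altitude
  }
  elevation_grid(corner, grid, center)
}

#' @rdname read_elevation_grid
#' @param egrid an [elevation_grid()].
#' @param corner_path,center_path output CSV paths (centre file written only
#'   when centre altitudes are present).
#' @export
write_elevation_grid <- function(egrid, corner_path, center_path = NULL) {
  g <- egrid$grid
  idx <- expand.grid(i = 0:g$n_qx, j = 0:g$n_qy)
  utils::write.csv(data.frame(idx, altitude = egrid$corner[cbind(idx$i + 1L, idx$j + 1L)]),
                   corner_path, row.names = FALSE, quote = FALSE)
  if (!is.null(egrid$center) && !is.null(center_path)) {
    idq <- expand.grid(qx = 0:(g$n_qx - 1L), qy = 0:(g$n_qy - 1L))
    utils::write.csv(data.frame(idq, altitude = egrid$center[cbind(idq$qx + 1L, idq$qy + 1L)]),
                     center_path, row.names = FALSE, quote = FALSE)
  }
  invisible(corner_path)
}

# quadrat altitudes as an n_qx x n_qy matrix (mean of the four corners)
.altitude_matrix <- function(egrid) {
  M <- egrid$corner
  nx <- egrid$grid$n_qx; ny <- egrid$grid$n_qy
  (M[1:nx, 1:ny] + M[2:(nx + 1), 1:ny] +
   M[1:nx, 2:(ny + 1)] + M[2:(nx + 1), 2:(ny + 1)]) / 4
}

#' Quadrat altitude
#'
#' Altitude of each quadrat = mean altitude of its four corners.
#'
#' @param egrid an [elevation_grid()].
#' @return data.frame `quadrat_id`, `altitude` in linear-id order.
#' @export
quadrat_altitude <- function(egrid) {
  stopifnot(inherits(egrid, "elevation_grid"))
  alt <- .altitude_matrix(egrid)
  data.frame(quadrat_id = seq_len(length(alt)) - 1L,
             altitude = as.vector(alt))
}

#' Terrain convexity per quadrat
#'
#' Interior quadrats: focal altitude minus the mean altitude of the eight
#' surrounding quadrats.  Edge and corner quadrats: centre-point altitude
#' minus the focal (four-corner-mean) altitude, when centre altitudes are
#' available; otherwise the documented fallback, focal altitude minus the
#' mean of the existing 3-5 neighbours.  Positive convexity indicates a
#' ridge or hilltop, negative a hollow.
#'
#' @param egrid an [elevation_grid()].
#' @return data.frame `quadrat_id`, `altitude`, `convexity`, `edge_rule`
#'   (one of `"interior"`, `"center_point"`, `"reduced_neighbors"`).
#' @export
convexity <- function(egrid) {
  stopifnot(inherits(egrid, "elevation_grid"))
  alt <- .altitude_matrix(egrid)
  nx <- nrow(alt); ny <- ncol(alt)
  # 8-neighbour mean via an NA-padded matrix
  pad <- matrix(NA_real_, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- alt
  nbr_sum <- matrix(0, nx, ny); nbr_n <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
    ok <- !is.na(sh)
    nbr_sum[ok] <- nbr_sum[ok] + sh[ok]
    nbr_n <- nbr_n + ok
  }
  interior <- nbr_n == 8L
  conv <- alt - nbr_sum / nbr_n          # reduced-neighbour value everywhere
  rule <- ifelse(interior, "interior", "reduced_neighbors")
  if (!is.null(egrid$center)) {
    edge <- !interior
    conv[edge] <- egrid$center[edge] - alt[edge]
    rule[!interior] <- "center_point"
  }
  data.frame(quadrat_id = seq_len(length(alt)) - 1L,
             altitude = as.vector(alt),
             convexity = as.vector(conv),
             edge_rule = as.vector(rule))
}
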