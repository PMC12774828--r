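## Equal Earth projection coefficients (Savric, Patterson & Jenny 2019)
.EE_A1 <- 1.340264
.EE_A2 <- -0.081106
.EE_A3 <- 0.000893
.EE_A4 <- 0.003796

#' Convert unit vectors to spherical longitude/latitude
#'
#' Convention: latitude phi = asin(z), longitude lambda = atan2(y, x), in
#' radians.
#'
#' @param xyz unit 3-vector or matrix with one unit vector per row
#' @return matrix with columns \code{lon}, \code{lat}
#' @export
toLonLat <- function(xyz) {
    xyz <- rbind(xyz)
    nrm <- sqrt(rowSums(xyz^2))
    if (any(nrm < 1e-9)) stop("zero vector has no spherical coordinates")
    if (any(abs(nrm - 1) > 1e-6))
        stop("input vectors must be unit length")
    out <- cbind(lon = atan2(xyz[, 2], xyz[, 1]),
                 lat = asin(pmin(pmax(xyz[, 3], -1), 1)))
    rownames(out) <- NULL
    out
}

#' Rotation matrix from Euler angles
#'
#' Composition Rz(yaw) Ry(pitch) Rx(roll), a convenient parameterization of
#' the arbitrary sphere rotation applied before projecting.
#'
#' @param yaw,pitch,roll angles in radians
#' @return 3 x 3 rotation matrix
#' @export
eulerRotation <- function(yaw = 0, pitch = 0, roll = 0) {
    Rz <- rbind(c(cos(yaw), -sin(yaw), 0), c(sin(yaw), cos(yaw), 0),
                c(0, 0, 1))
    Ry <- rbind(c(cos(pitch), 0, sin(pitch)), c(0, 1, 0),
                c(-sin(pitch), 0, cos(pitch)))
    Rx <- rbind(c(1, 0, 0), c(0, cos(roll), -sin(roll)),
                c(0, sin(roll), cos(roll)))
    Rz %*% Ry %*% Rx
}

#' Rotate points on the sphere
#'
#' @param xyz vector or matrix of 3D coordinates (rows)
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1)
#' @return rotated coordinates, same shape
#' @export
rotateSphere <- function(xyz, rotation) {
    rotation <- as.matrix(rotation)
    if (!isTRUE(all.equal(crossprod(rotation), diag(3),
                          tolerance = 1e-8)) ||
        abs(det(rotation) - 1) > 1e-8)
        stop("rotation must be orthogonal with determinant +1")
    single <- is.null(dim(xyz))
    out <- rbind(xyz) %*% t(rotation)
    if (single) drop(out) else out
}

#' Equal Earth map projection
#'
#' Projects spherical (longitude, latitude) to the plane with the Equal Earth
#' pseudocylindrical projection. On the unit sphere the projection is exactly
#' equal-area: planar area equals spherical area.
#'
#' @param lonlat matrix with columns longitude and latitude in radians (a
#'   length-2 vector is accepted)
#' @return matrix with columns \code{x}, \code{y}
#' @examples
#' equalEarth(c(0, 0))          # origin maps to (0, 0)
#' equalEarth(c(0, pi / 2))     # north pole, y ~ 1.3173
#' @export
equalEarth <- function(lonlat) {
    lonlat <- rbind(lonlat)
    lam <- lonlat[, 1]; phi <- lonlat[, 2]
    th <- asin(pmin(pmax(sqrt(3) / 2 * sin(phi), -1), 1))
    mp <- .EE_A1 + 3 * .EE_A2 * th^2 + 7 * .EE_A3 * th^6 + 9 * .EE_A4 * th^8
    out <- cbind(x = 2 * sqrt(3) / 3 * lam * cos(th) / mp,
                 y = .EE_A1 * th + .EE_A2 * th^3 + .EE_A3 * th^7 +
                     .EE_A4 * th^9)
    rownames(out) <- NULL
    out
}

#' Boundary outline of the Equal Earth projection
#'
#' The image of the antimeridian (lambda = +/- pi) and pole lines, useful as
#' the enveloping outline when plotting projected embeddings.
#'
#' @param n points per edge
#' @return matrix of boundary (x, y) coordinates, closed polygon
#' @export
equalEarthBoundary <- function(n = 181L) {
    lat <- seq(-pi / 2, pi / 2, length.out = n)
    right <- equalEarth(cbind(pi, lat))
    left <- equalEarth(cbind(-pi, rev(lat)))
    rbind(right, left, right[1, , drop = FALSE])
}

#' Project a spherical embedding to 2D
#'
#' Applies (optionally) a rotation of the sphere, converts to
#' longitude/latitude and projects with Equal Earth, filling the 2D
#' coordinate slot of the embedding.
#'
#' @param es a \linkS4class{SphereEmbedding}
#' @param rotation 3 x 3 rotation matrix (default identity), e.g. from
#'   \code{\link{eulerRotation}}
#' @return the embedding with 2D coordinates populated
#' @export
projectEmbedding <- function(es, rotation = diag(3)) {
    xyz <- rotateSphere(es@coords3, rotation)
    xy <- equalEarth(toLonLat(xyz))
    SphereEmbedding(es@coords3, sampleIds = es@sampleIds, coords2 = xy)
}
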