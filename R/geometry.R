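## Gas constant in kcal/(mol K) and the 1 M standard-state volume in A^3.
RGAS_KCAL <- 1.98720425864083e-3
STD_VOLUME_A3 <- 1661
DEFAULT_TEMPERATURE <- 298.15

#' Thermodynamic context
#'
#' Bundles the temperature, gas constant and standard concentration used
#' throughout cycle assembly and pose combination.
#'
#' @param T temperature in Kelvin.
#' @param R gas constant in kcal/(mol K).
#' @param conc standard concentration in molecules per A^3 (1 M by default).
#' @return An object of class `abfe_thermo` with elements `T`, `R`, `beta`
#'   (1/RT, mol/kcal) and `conc`.
#' @export
thermo_context <- function(T = DEFAULT_TEMPERATURE, R = RGAS_KCAL,
                           conc = 1 / STD_VOLUME_A3) {
  stopifnot(is.numeric(T), length(T) == 1, T > 0, R > 0, conc > 0)
  structure(list(T = T, R = R, beta = 1 / (R * T), conc = conc),
            class = "abfe_thermo")
}

vnorm <- function(v) sqrt(sum(v * v))

## Interior angle a-b-c in degrees.
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu == 0 || nv == 0)
    stop("undefined angle: coincident atoms")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

## Signed dihedral a-b-c-d in degrees, in (-180, 180].
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) == 0 || vnorm(n2) == 0)
    stop("undefined dihedral: collinear atoms")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  ang <- atan2(y, x) * 180 / pi
  wrap_deg(ang)
}

## Wrap an angular difference (degrees) into (-180, 180].
wrap_deg <- function(x) {
  w <- x - 360 * round(x / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

## Rotation matrix for an angle (radians) about the z axis.
rotz <- function(theta) {
  ct <- cos(theta)
  st <- sin(theta)
  matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), nrow = 3, byrow = TRUE)
}

## Random proper rotation (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
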