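#' Spherical conductor head model
#'
#' Head coordinate frame: origin at the sphere center, x right, y anterior,
#' z superior, millimetres.
#'
#' @param center sphere center (mm, length 3).
#' @param radius_mm conductor radius (mm).
#' @export
head_model <- function(center = c(0, 0, 0), radius_mm = 90) {
  structure(list(center = as.numeric(center), radius_mm = radius_mm),
            class = "assr_headmodel")
}

#' Synthetic axial-gradiometer helmet array
#'
#' 151 sensor positions on a helmet surface, with one disabled channel, so
#' 150 are usable. First-order axial gradiometers are modeled as the
#' difference of the radial field at two coaxial coils 50 mm apart along the
#' coil normal. Layouts: `"spiral"` (Fibonacci spiral on a spherical cap,
#' the default) or `"rings"` (latitude rings, mirror-symmetric about the
#' x = 0 plane; useful for symmetry checks).
#'
#' @param n_sensors total sensor count (default 151).
#' @param helmet_radius_mm distance of the inner coil from the head origin.
#' @param baseline_mm gradiometer baseline.
#' @param layout `"spiral"` or `"rings"`.
#' @param disabled index of the disabled channel (1 entry).
#' @return object of class `assr_array` with `pos` (n x 3 mm), `normal`
#'   (n x 3 unit outward), `baseline_mm`, `disabled`, `usable` (indices).
#' @export
sensor_array <- function(n_sensors = 151, helmet_radius_mm = 110,
                         baseline_mm = 50, layout = c("spiral", "rings"),
                         disabled = 42L) {
  layout <- match.arg(layout)
  if (layout == "spiral") {
    # Fibonacci spiral on a cap from the vertex down to ~115 degrees polar
    i <- seq_len(n_sensors) - 0.5
    cosmax <- cos(115 * pi / 180)
    z <- 1 - i / n_sensors * (1 - cosmax)
    theta <- pi * (1 + sqrt(5)) * i
    r <- sqrt(pmax(1 - z^2, 0))
    u <- cbind(r * cos(theta), r * sin(theta), z)
  } else {
    # vertex sensor plus latitude rings with even counts; the half-step
    # azimuth offset makes each ring symmetric under phi -> pi - phi
    # (mirror in the x = 0 plane)
    polar <- c(15, 32, 50, 70, 90, 110)
    counts <- c(8, 14, 22, 30, 36, 40)
    counts[6] <- counts[6] + (n_sensors - 1L - sum(counts))
    rows <- list(c(0, 0, 1))
    for (k in seq_along(polar)) {
      th <- polar[k] * pi / 180
      phi <- 2 * pi * (seq_len(counts[k]) - 0.5) / counts[k]
      rows[[k + 1]] <- cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                             rep(cos(th), counts[k]))
    }
    u <- do.call(rbind, rows)[seq_len(n_sensors), ]
  }
  structure(list(
    pos = u * helmet_radius_mm, normal = u,
    baseline_mm = baseline_mm, disabled = as.integer(disabled),
    usable = setdiff(seq_len(n_sensors), disabled)
  ), class = "assr_array")
}

#' A current dipole source
#'
#' @param position mm, head coordinates.
#' @param orientation 3-vector; normalized internally.
#' @param moment optional moment time series (nAm).
#' @export
dipole_source <- function(position, orientation, moment = NULL) {
  o <- as.numeric(orientation)
  no <- sqrt(sum(o^2))
  if (no == 0) stop("orientation must be non-zero")
  structure(list(position = as.numeric(position), orientation = o / no,
                 moment = moment), class = "assr_dipole")
}

# Magnetic field of a current dipole in a conducting sphere centered at the
# origin (Sarvas 1987). q: moment vector (A m), r0: dipole position (m),
# rs: n x 3 sensor positions (m). Returns n x 3 field (tesla).
sarvas_field <- function(q, r0, rs) {
  mu0_4pi <- 1e-7
  a_vec <- sweep(rs, 2, r0)            # r - r0
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(rs^2))
  adotr <- rowSums(a_vec * rs)
  r0dotr <- rowSums(sweep(rs, 2, r0, `*`))
  FF <- a * (r * a + r^2 - r0dotr)
  gF_r <- a^2 / r + adotr / a + 2 * a + 2 * r
  gF_r0 <- a + 2 * r + adotr / a
  gradF <- rs * gF_r - outer(gF_r0, r0)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  qxr0_dot_r <- rowSums(sweep(rs, 2, qxr0, `*`))
  num <- outer(FF, qxr0) - gradF * qxr0_dot_r
  mu0_4pi * num / FF^2
}

#' Lead field of a dipole position at the gradiometer array
#'
#' Returns the usable-channel gain matrix (tesla per nAm) for the three
#' Cartesian unit moments at `position_mm`. The gradiometer output is the
#' difference of the radial field between the inner coil and the outer coil
#' `baseline_mm` further out along the coil normal.
#'
#' @param position_mm dipole position (mm, head coordinates).
#' @param head a [head_model()].
#' @param array a [sensor_array()].
#' @return matrix `length(array$usable)` x 3, tesla per nAm.
#' @export
lead_field <- function(position_mm, head, array) {
  r0 <- (position_mm - head$center) / 1000
  if (sqrt(sum(r0^2)) >= head$radius_mm / 1000)
    stop("dipole outside the conductor sphere")
  rs1 <- sweep(array$pos, 2, head$center)[array$usable, , drop = FALSE] / 1000
  nrm <- array$normal[array$usable, , drop = FALSE]
  rs2 <- rs1 + nrm * (array$baseline_mm / 1000)
  L <- matrix(0, length(array$usable), 3)
  for (k in 1:3) {
    q <- c(0, 0, 0); q[k] <- 1e-9      # unit moment of 1 nAm
    B1 <- sarvas_field(q, r0, rs1)
    B2 <- sarvas_field(q, r0, rs2)
    L[, k] <- rowSums(B1 * nrm) - rowSums(B2 * nrm)
  }
  L
}

#' Forward field of a dipole (fixed orientation)
#'
#' @param dipole a [dipole_source()].
#' @param head a [head_model()].
#' @param array a [sensor_array()].
#' @return gain vector over usable channels, tesla per nAm of moment.
#' @export
forward_field <- function(dipole, head, array) {
  drop(lead_field(dipole$position, head, array) %*% dipole$orientation)
}

# Orthonormal tangential basis at a dipole position (radial dipoles are
# silent in a sphere, so the effective source space is 2-D).
tangential_basis <- function(position_mm, head) {
  r <- position_mm - head$center
  r <- r / sqrt(sum(r^2))
  a <- if (abs(r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- a - sum(a * r) * r
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(r[2] * t1[3] - r[3] * t1[2],
          r[3] * t1[1] - r[1] * t1[3],
          r[1] * t1[2] - r[2] * t1[1])
  cbind(t1, t2)
}
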