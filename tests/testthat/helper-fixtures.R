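# Shared helpers for the suite. Everything is generated in code; no stored
# fixtures.

# A seeded random rotation matrix (uniform via Shoemake quaternions).
random_rotation <- function() {
  q <- nanostargel:::random_quats(1)[1, ]
  nanostargel:::quat_to_matrix(q)
}

# Independent brute-force oracle for the planarity of three unit vectors:
# explicit plane fit through the tips (least assumptions, no shared code
# with compute_dp beyond base R).
oracle_dp <- function(e) {
  e <- e / sqrt(rowSums(e^2))
  p1 <- e[1, ]; p2 <- e[2, ]; p3 <- e[3, ]
  u <- p2 - p1; v <- p3 - p1
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  abs(sum(n * p1)) / sqrt(sum(n^2))
}

# Symmetric three-arm unit vectors at polar angle psi.
symmetric_axes <- function(psi) {
  az <- c(0, 2, 4) * pi / 3
  cbind(sin(psi) * cos(az), sin(psi) * sin(az), rep(cos(psi), 3))
}

# Central-difference force oracle at bead level, using the exported scalar
# energies only (independent of the compiled force kernel).
fd_forces <- function(frame, ff, h = 1e-6) {
  energy_of <- function(pos) {
    tot <- 0
    n <- nrow(pos)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (frame$mol[i] == frame$mol[j]) next
        ti <- frame$type_code[i]; tj <- frame$type_code[j]
        if (ti == 2L && tj == 2L) {
          d <- pos[i, ] - pos[j, ]
          d <- d - frame$box_L * round(d / frame$box_L)
          tot <- tot + morse_energy(sqrt(sum(d^2)), ff)
        } else if (ti != 2L && tj != 2L) {
          d <- pos[i, ] - pos[j, ]
          d <- d - frame$box_L * round(d / frame$box_L)
          tot <- tot + wca_energy(sqrt(sum(d^2)), ff)
        }
      }
    }
    tot
  }
  n <- nrow(frame$positions)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      p1 <- frame$positions; p1[i, k] <- p1[i, k] + h
      p2 <- frame$positions; p2[i, k] <- p2[i, k] - h
      out[i, k] <- -(energy_of(p1) - energy_of(p2)) / (2 * h)
    }
  }
  out
}

# A deterministic interacting configuration: two stretched patch bonds plus
# one WCA contact, so both interaction channels carry non-zero forces.
interacting_state <- function(d_p = 0, box_L = 16) {
  tpl <- ns_template(d_p)
  rotz <- function(a) nanostargel:::quat_from_axis_angle(c(0, 0, 1), a)
  a2 <- c(-0.5, sqrt(3) / 2, 0)          # planar arm-2 direction
  centers <- rbind(
    c(8, 8, 8),                          # A
    c(13.3, 8, 8),                       # B: bonded to A arm 1 (stretched)
    c(8, 8, 8) + 5.3 * a2,               # C: bonded to A arm 2
    c(10, 8, 9.05))                      # D: WCA contact with A's outer bead
  quats <- rbind(c(1, 0, 0, 0), rotz(pi), rotz(pi + 2 * pi / 3),
                 c(1, 0, 0, 0))
  sim_state(tpl, centers, quats, box_L = box_L, temperature = 1)
}
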