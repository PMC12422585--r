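#' Phase trajectory of a simulation
#'
#' Assigns each region an instantaneous phase over the steady-state window via
#' the four-quadrant arctangent of the (I, E) plane,
#' `phi_k(t) = atan2(I_k(t), E_k(t))`. Samples where both populations are
#' exactly zero have no defined angle; their phase is set to 0 and a warning
#' is issued (quiescent region).
#'
#' @param trajectory A `wc_trajectory` with a nonempty steady-state window.
#' @param center Subtract each region's window mean from E and I before the
#'   angle is taken (default `FALSE`: raw activities, the reference
#'   convention).
#' @return A `phase_trajectory`: list with `phi` (time x region, values in
#'   `(-pi, pi]`) and `times`.
#' @export
phase_trajectory <- function(trajectory, center = FALSE) {
  stopifnot(inherits(trajectory, "wc_trajectory"))
  sl <- trajectory$steady_slice
  if (length(sl) == 0) stop("steady-state window is empty")
  E <- trajectory$E[sl, , drop = FALSE]
  I <- trajectory$I[sl, , drop = FALSE]
  if (center) {
    E <- sweep(E, 2, colMeans(E))
    I <- sweep(I, 2, colMeans(I))
  }
  degenerate <- E == 0 & I == 0
  phi <- atan2(I, E)
  if (any(degenerate)) {
    warning("phase undefined at ", sum(degenerate),
            " samples with E = I = 0; set to 0 (quiescent region)")
    phi[degenerate] <- 0
  }
  structure(list(phi = phi, times = trajectory$times[sl]),
            class = "phase_trajectory")
}

#' Kuramoto order parameter of a region set
#'
#' Magnitude and mean phase of the complex order parameter
#' `rho e^{i Theta} = mean over members of e^{i phi}`. `rho = 1` for full
#' phase coherence, near 0 for incoherence.
#'
#' @param phi Numeric vector of phases (one time point) or a time x region
#'   matrix.
#' @param members Nonempty integer vector of region indices.
#' @return List with `rho` and `Theta` (scalars, or vectors over time).
#' @export
order_parameter <- function(phi, members) {
  if (length(members) == 0) stop("member set must be nonempty")
  if (is.matrix(phi)) {
    z <- rowMeans(exp(1i * phi[, members, drop = FALSE]))
  } else {
    z <- mean(exp(1i * phi[members]))
  }
  list(rho = Mod(z), Theta = Arg(z))
}

#' Region members of a cognitive-system pair
#'
#' For two distinct systems, the disjoint union of their member regions (so
#' the order-parameter normalization is `N_sj + N_sk`); for a system paired
#' with itself, its members once.
#'
#' @param parcellation A `cognitive_parcellation`.
#' @param s_j,s_k System labels.
#' @return Integer vector of region indices.
#' @export
pair_members <- function(parcellation, s_j, s_k) {
  m_j <- system_members(parcellation, s_j)
  if (s_j == s_k) return(m_j)
  m_k <- system_members(parcellation, s_k)
  stopifnot(length(intersect(m_j, m_k)) == 0)
  c(m_j, m_k)
}

#' Time-averaged synchrony
#'
#' The synchrony `R` is the time average of the order-parameter magnitude
#' `rho(t)` over the steady-state window; bounded in `[0, 1]`.
#'
#' @param rho Numeric vector of order-parameter magnitudes over time.
#' @return Scalar synchrony.
#' @export
synchrony <- function(rho) {
  if (length(rho) == 0) stop("empty synchrony window")
  mean(rho)
}

#' Pairwise cognitive-system synchrony matrix
#'
#' Computes the symmetric `n_systems x n_systems` matrix of time-averaged
#' synchrony for every pair of cognitive systems (diagonal: within-system
#' synchrony of each system's own order parameter).
#'
#' @param phases A [phase_trajectory()].
#' @param parcellation A `cognitive_parcellation` covering all regions.
#' @return A `synchrony_matrix`: symmetric numeric matrix in `[0, 1]` with
#'   system labels as dimnames.
#' @export
synchrony_matrix <- function(phases, parcellation) {
  stopifnot(inherits(phases, "phase_trajectory"),
            inherits(parcellation, "cognitive_parcellation"))
  if (ncol(phases$phi) != length(parcellation$membership)) {
    stop("parcellation covers ", length(parcellation$membership),
         " regions, phases have ", ncol(phases$phi))
  }
  systems <- parcellation$systems
  ns <- length(systems)
  Z <- exp(1i * phases$phi)
  # per-system complex sums over time
  sums <- vapply(systems, function(s) {
    m <- system_members(parcellation, s)
    rowSums(Z[, m, drop = FALSE])
  }, complex(nrow(Z)))
  sums <- matrix(sums, nrow = nrow(Z))
  counts <- vapply(systems, function(s) {
    length(system_members(parcellation, s))
  }, integer(1))
  R <- matrix(0, ns, ns, dimnames = list(systems, systems))
  for (j in seq_len(ns)) {
    for (k in j:ns) {
      if (j == k) {
        rho <- Mod(sums[, j]) / counts[j]
      } else {
        rho <- Mod(sums[, j] + sums[, k]) / (counts[j] + counts[k])
      }
      R[j, k] <- R[k, j] <- synchrony(rho)
    }
  }
  class(R) <- c("synchrony_matrix", class(R))
  R
}
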