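#' Wilson-Cowan model parameters
#'
#' Local and global parameters of the delay-coupled Wilson-Cowan neural mass
#' model. Defaults are the classical oscillation-capable parameter set
#' (local couplings 16/12/15/3, sigmoid growth rates 1.3 and 2, midpoints 4
#' and 3.7, time constant 8 ms, refractory constants 1). The inhibitory global
#' coupling is tied to the excitatory one as `C_I = C_E / 4`, reflecting the
#' roughly 4:1 ratio of excitatory to inhibitory neurons; it is re-derived
#' whenever `C_E` is set through this constructor or [set_global_coupling()].
#'
#' @param tau Time constant in ms.
#' @param r_E,r_I Refractory constants.
#' @param C_EE,C_EI,C_IE,C_II Local population couplings.
#' @param C_E Excitatory global (between-region) coupling.
#' @param a_E,a_I Sigmoid growth rates.
#' @param theta_E,theta_I Sigmoid midpoints.
#' @param sigma Noise intensity (variance parameter of the white-noise drive;
#'   default 1e-5).
#' @param v_d Conduction velocity in m/s (default 10).
#' @return A `wc_params` object.
#' @export
wc_params <- function(tau = 8, r_E = 1, r_I = 1,
                      C_EE = 16, C_EI = 12, C_IE = 15, C_II = 3,
                      C_E = 1, a_E = 1.3, theta_E = 4,
                      a_I = 2, theta_I = 3.7,
                      sigma = 1e-5, v_d = 10) {
  stopifnot(tau > 0, sigma >= 0, v_d > 0, a_E > 0, a_I > 0)
  structure(
    list(tau = tau, r_E = r_E, r_I = r_I, C_EE = C_EE, C_EI = C_EI,
         C_IE = C_IE, C_II = C_II, C_E = C_E, C_I = C_E / 4,
         a_E = a_E, theta_E = theta_E, a_I = a_I, theta_I = theta_I,
         sigma = sigma, v_d = v_d),
    class = "wc_params"
  )
}

#' Set the excitatory global coupling
#'
#' Updates `C_E` and re-derives `C_I = C_E / 4`.
#'
#' @param params A [wc_params()] object.
#' @param C_E New excitatory global coupling.
#' @return Updated `wc_params`.
#' @export
set_global_coupling <- function(params, C_E) {
  stopifnot(inherits(params, "wc_params"))
  params$C_E <- C_E
  params$C_I <- C_E / 4
  params
}

#' Wilson-Cowan sigmoid activation
#'
#' `S(x) = 1/(1 + exp(-a (x - theta))) - 1/(1 + exp(a theta))`. The subtracted
#' constant makes `S(0) = 0`, so the origin is a fixed point of the unforced
#' dynamics. Strictly increasing with supremum [sigmoid_max()].
#'
#' @param x Input (vectorized).
#' @param a Growth rate (> 0).
#' @param theta Midpoint.
#' @return Activation value(s).
#' @export
wc_sigmoid <- function(x, a, theta) {
  stopifnot(a > 0)
  stats::plogis(a * (x - theta)) - stats::plogis(-a * theta)
}

#' Supremum of the Wilson-Cowan sigmoid
#'
#' `S_max = 1 - 1/(1 + exp(a theta))`, the limit of [wc_sigmoid()] as
#' `x -> Inf`; lies in (0, 1).
#'
#' @inheritParams wc_sigmoid
#' @return Scalar supremum.
#' @export
wc_sigmoid_max <- function(a, theta) {
  stopifnot(a > 0)
  stats::plogis(a * theta)
}

#' Conduction delay matrix
#'
#' Pairwise signal travel times `d_jk = ||x_j - x_k|| / v_d`. With coordinates
#' in mm and velocity in m/s (= mm/ms) the delays are in ms.
#'
#' @param coordinates Numeric matrix (regions x 3) of coordinates in mm, or a
#'   `connectome` (whose region coordinates are used).
#' @param v_d Conduction velocity in m/s.
#' @return Symmetric nonnegative delay matrix in ms with zero diagonal.
#' @export
build_delay_matrix <- function(coordinates, v_d = 10) {
  stopifnot(v_d > 0)
  if (inherits(coordinates, "connectome")) {
    coordinates <- as.matrix(coordinates$regions[, c("x", "y", "z")])
  }
  coordinates <- as.matrix(coordinates)
  D <- as.matrix(stats::dist(coordinates)) / v_d
  dimnames(D) <- NULL
  diag(D) <- 0
  D
}

#' Single-region stimulus specification
#'
#' Constant stimulation of one region for the entire simulation; all other
#' regions receive zero input. The default amplitude 1.15 is strong enough to
#' push a critically tuned region across the Hopf bifurcation into sustained
#' oscillation without driving it to a new high-activity fixed point.
#'
#' @param target_region Region index (1-based), or `NULL` for no stimulus.
#' @param amplitude Stimulation strength `P` (>= 0).
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(target_region = NULL, amplitude = 1.15) {
  stopifnot(amplitude >= 0)
  structure(list(target_region = target_region, amplitude = amplitude),
            class = "stimulus_spec")
}

#' Simulation configuration
#'
#' Integration settings for [simulate_wc()]. Model time is in ms. The first
#' `transient` ms are treated as transient; the following `record_window` ms
#' form the steady-state analysis window. The state is recorded every
#' `record_dt` ms (the integration itself always proceeds at `dt`).
#'
#' @param dt Integration step in ms (default 1e-3).
#' @param transient Transient duration discarded from analysis (ms).
#' @param record_window Steady-state window length T (ms, default 500).
#' @param record_dt Sampling interval of the recorded trajectory (ms); rounded
#'   to a whole number of integration steps.
#' @param initial_value Initial condition `E(0) = I(0)` for all regions.
#' @param seed Integer RNG seed for the noise.
#' @return A `sim_config` object.
#' @export
sim_config <- function(dt = 1e-3, transient = 1000, record_window = 500,
                       record_dt = max(dt, 0.1), initial_value = 0.1,
                       seed = 1L) {
  stopifnot(dt > 0, record_window > 0, transient >= 0, record_dt >= dt)
  structure(
    list(dt = dt, transient = transient, record_window = record_window,
         record_dt = record_dt, initial_value = initial_value,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Desk-scale simulation configuration
#'
#' Coarser integration step and shorter transient than the reference settings,
#' keeping the 500 ms steady-state window. Suitable for small synthetic
#' cohorts on one CPU; see the methods vignette for the accuracy checks
#' backing these choices.
#'
#' @param seed Integer RNG seed.
#' @return A `sim_config`.
#' @export
demo_sim_config <- function(seed = 1L) {
  sim_config(dt = 0.02, transient = 150, record_window = 500,
             record_dt = 0.2, seed = seed)
}

#' Simulate the delay-coupled Wilson-Cowan network
#'
#' Euler-Maruyama integration of the two-population Wilson-Cowan equations on
#' a weighted connectome with per-edge conduction delays applied to both the
#' excitatory and inhibitory between-region inputs. History before t = 0 is
#' held constant at the initial value. With `sigma = 0` the integration is
#' deterministic and bit-reproducible.
#'
#' @param x A `connectome`, or a weight matrix (then `delays` is required
#'   unless zero delays are acceptable).
#' @param params A [wc_params()].
#' @param stim A [stimulus_spec()] or `NULL` for no stimulation.
#' @param config A [sim_config()].
#' @param delays Optional delay matrix in ms; defaults to
#'   [build_delay_matrix()] of the connectome coordinates at `params$v_d`, or
#'   zero delays for a plain matrix.
#' @return A `wc_trajectory`: list with `E`, `I` (time x region matrices),
#'   `times` (ms), `steady_slice` (indices of the steady-state window) and the
#'   configuration used.
#' @export
simulate_wc <- function(x, params = wc_params(), stim = NULL,
                        config = sim_config(), delays = NULL) {
  stopifnot(inherits(params, "wc_params"), inherits(config, "sim_config"))
  W <- weight_matrix(x)
  n <- nrow(W)
  if (is.null(delays)) {
    delays <- if (inherits(x, "connectome")) {
      build_delay_matrix(x, params$v_d)
    } else {
      matrix(0, n, n)
    }
  }
  if (any(dim(delays) != c(n, n))) stop("delay matrix dimension mismatch")
  P <- rep(0, n)
  if (!is.null(stim) && !is.null(stim$target_region)) {
    stopifnot(inherits(stim, "stimulus_spec"))
    if (stim$target_region < 1 || stim$target_region > n) {
      stop("stimulus target out of range: ", stim$target_region)
    }
    P[stim$target_region] <- stim$amplitude
  }
  dt <- config$dt
  delay_steps <- matrix(as.integer(round(delays / dt)), n, n)
  total <- config$transient + config$record_window
  if (max(delays) >= max(total, 1)) {
    stop("maximum delay exceeds the simulated duration")
  }
  n_steps <- as.integer(round(total / dt))
  record_every <- max(1L, as.integer(round(config$record_dt / dt)))
  set.seed(config$seed)
  raw <- wc_simulate_cpp(W, delay_steps, P, unclass(params), dt, n_steps,
                         record_every, config$initial_value, params$sigma)
  steady <- which(raw$times >= config$transient)
  structure(
    list(E = raw$E, I = raw$I, times = raw$times, steady_slice = steady,
         params = params, config = config, stim = stim),
    class = "wc_trajectory"
  )
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat("<wc_trajectory> ", ncol(x$E), " regions, ", nrow(x$E),
      " samples over ", max(x$times), " ms (steady window ",
      length(x$steady_slice), " samples)\n", sep = "")
  invisible(x)
}

#' Classify a noise-free trajectory as quiescent or active
#'
#' A network state is called active when the standard deviation of the mean
#' excitatory activity over the steady-state window exceeds `epsilon`
#' (sustained oscillation); otherwise it has settled to a fixed point and is
#' quiescent.
#'
#' @param trajectory A `wc_trajectory`.
#' @param epsilon Activity threshold on the standard deviation (default 1e-4).
#' @return `"active"` or `"quiescent"`.
#' @export
classify_activity <- function(trajectory, epsilon = 1e-4) {
  stopifnot(inherits(trajectory, "wc_trajectory"))
  if (length(trajectory$steady_slice) < 2) {
    stop("trajectory has no steady-state window beyond the transient")
  }
  mean_E <- rowMeans(trajectory$E[trajectory$steady_slice, , drop = FALSE])
  if (stats::sd(mean_E) > epsilon) "active" else "quiescent"
}

#' Tune the global coupling to the critical regime
#'
#' Finds the excitatory global coupling `C_E` at the boundary between the
#' quiescent fixed point and network-wide oscillation by bisection
#' (the midpoint method). Simulations are noise-free and stimulus-free with
#' all regions initialized at `config$initial_value`. The bracket is found by
#' doubling `C_E` from 1 until the network is active (cap `c_cap`); bisection
#' then narrows the interval to width `tol` and the midpoint is returned after
#' verifying that it classifies as quiescent (bisecting further if not, which
#' only shrinks the interval).
#'
#' @param x A `connectome` or weight matrix.
#' @param params A [wc_params()]; `sigma` is forced to 0 during tuning.
#' @param config A [sim_config()].
#' @param tol Final bracket width (default 1e-6).
#' @param epsilon Activity threshold passed to [classify_activity()].
#' @param departure_epsilon Threshold on the mean steady-state activity level
#'   beyond which the network is considered to have left the zero fixed point
#'   even without oscillating (guards the search against jumping straight onto
#'   a high-activity fixed point when the oscillatory window in `C_E` is
#'   narrow).
#' @param bracket Optional `c(lo, hi)` with quiescent/active endpoints,
#'   skipping the doubling search.
#' @param c_cap Upper cap of the doubling search (default 1e6).
#' @param delays Optional delay matrix (ms).
#' @return List with `C_E` (critical coupling, quiescent side), `bracket`
#'   (final `c(lo, hi)`), `width` and `n_sim` (simulations spent).
#' @export
tune_global_coupling <- function(x, params = wc_params(),
                                 config = sim_config(), tol = 1e-6,
                                 epsilon = 1e-4, departure_epsilon = 1e-3,
                                 bracket = NULL, c_cap = 1e6, delays = NULL) {
  W <- weight_matrix(x)
  if (is.null(delays)) {
    delays <- if (inherits(x, "connectome")) {
      build_delay_matrix(x, params$v_d)
    } else {
      matrix(0, nrow(W), ncol(W))
    }
  }
  quiet_params <- params
  quiet_params$sigma <- 0
  n_sim <- 0L
  departed_at <- function(C_E) {
    p <- set_global_coupling(quiet_params, C_E)
    tr <- simulate_wc(W, p, stim = NULL, config = config, delays = delays)
    n_sim <<- n_sim + 1L
    mean_E <- rowMeans(tr$E[tr$steady_slice, , drop = FALSE])
    stats::sd(mean_E) > epsilon || abs(mean(mean_E)) > departure_epsilon
  }
  if (is.null(bracket)) {
    lo <- 0
    hi <- 1
    while (!departed_at(hi)) {
      lo <- hi
      hi <- hi * 2
      if (hi > c_cap) stop("no bifurcation in range: network stays quiescent ",
                           "up to C_E = ", c_cap)
    }
  } else {
    lo <- bracket[1]
    hi <- bracket[2]
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (departed_at(mid)) hi <- mid else lo <- mid
  }
  mid <- (lo + hi) / 2
  while (departed_at(mid)) {
    hi <- mid
    mid <- (lo + hi) / 2
  }
  list(C_E = mid, bracket = c(lo, hi), width = hi - lo, n_sim = n_sim)
}

#' Stimulate each region of a connectome
#'
#' Runs the single-region stimulation protocol: one simulation per requested
#' region with constant stimulus `P_k = amplitude` on that region and 0
#' elsewhere. Per-run seeds are derived from the configuration seed as
#' `(seed + region index) mod (2^31 - 1)`.
#'
#' @param x A `connectome`.
#' @param params A [wc_params()] with `C_E` already tuned (see
#'   [tune_global_coupling()]).
#' @param config A [sim_config()].
#' @param regions Integer vector of regions to stimulate (default all).
#' @param amplitude Stimulus strength (default 1.15).
#' @param delays Optional precomputed delay matrix.
#' @return Named list of `wc_trajectory`, one per stimulated region.
#' @export
stimulate_each_region <- function(x, params, config = sim_config(),
                                  regions = NULL, amplitude = 1.15,
                                  delays = NULL) {
  W <- weight_matrix(x)
  n <- nrow(W)
  if (is.null(regions)) regions <- seq_len(n)
  if (is.null(delays)) {
    delays <- if (inherits(x, "connectome")) {
      build_delay_matrix(x, params$v_d)
    } else {
      matrix(0, n, n)
    }
  }
  out <- lapply(regions, function(r) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(config$seed) + r) %% 2147483647)
    simulate_wc(W, params, stim = stimulus_spec(r, amplitude), config = cfg,
                delays = delays)
  })
  names(out) <- if (inherits(x, "connectome")) {
    x$regions$name[regions]
  } else {
    as.character(regions)
  }
  out
}
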