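#' Default per-system region counts
#'
#' Total region counts per cognitive system summing to 128 regions. The
#' ventral-temporal system has 10 regions per hemisphere and the auditory
#' system 3 per hemisphere; the subcortical system has 14 regions in total;
#' the remaining cortical systems share the rest roughly evenly.
#'
#' @return Named integer vector over the nine cognitive systems.
#' @export
default_region_plan <- function() {
  c(Att = 14L, Aud = 6L, FP = 14L, CO = 14L, MS = 16L, DM = 16L,
    V = 14L, VT = 20L, SC = 14L)
}

# run expr under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# approximate per-hemisphere centroids (mm) of the cognitive systems,
# used only to lay out synthetic coordinates for conduction delays
system_centroids <- function() {
  rbind(
    Att = c(30, 15, 45), Aud = c(55, -20, 8), FP = c(40, 35, 28),
    CO = c(38, 5, 15), MS = c(40, -22, 50), DM = c(10, -50, 35),
    V = c(15, -80, 5), VT = c(35, -50, -15), SC = c(12, -5, 0)
  )
}

#' Generate a synthetic cognitive parcellation and region metadata
#'
#' Builds region metadata for a synthetic connectome cohort: regions are
#' assigned to cognitive systems per the plan, split as evenly as possible
#' between hemispheres, given log-normal volumes, and placed on a two-hemisphere
#' coordinate layout (Gaussian scatter around per-system centroids, mirrored in
#' x) so that inter-region Euclidean distances span roughly `dist_range`.
#' Deterministic for a given plan and seed.
#'
#' @param region_plan Named integer vector of per-system total region counts.
#' @param seed Integer seed (default 1; fixed so the layout is a deterministic
#'   function of the plan).
#' @param dist_range Target range of pairwise distances in mm
#'   (default `c(10, 170)`); the lower bound is enforced as a minimum
#'   separation, the upper bound by rescaling.
#' @param volume_meanlog,volume_sdlog Log-normal volume parameters
#'   (arbitrary volume units; defaults give typical region volumes of a few
#'   thousand units).
#' @return List with `parcellation` (a [cognitive_parcellation()]) and
#'   `regions` (data frame of name, hemisphere, system, volume, x, y, z).
#' @export
generate_parcellation <- function(region_plan = default_region_plan(),
                                  seed = 1L,
                                  dist_range = c(10, 170),
                                  volume_meanlog = log(3500),
                                  volume_sdlog = 0.35) {
  if (length(region_plan) == 0) stop("region plan must name at least 1 system")
  if (any(region_plan < 1)) stop("all per-system counts must be >= 1")
  systems <- names(region_plan)
  if (is.null(systems) || any(!nzchar(systems))) {
    stop("region plan must be a named vector")
  }
  with_seed(seed, {
    rows <- list()
    cents <- system_centroids()
    for (s in systems) {
      cnt <- region_plan[[s]]
      n_left <- ceiling(cnt / 2)
      hemi <- c(rep("left", n_left), rep("right", cnt - n_left))
      cent <- if (s %in% rownames(cents)) cents[s, ] else c(30, 0, 20)
      idx_in_hemi <- c(seq_len(n_left), seq_len(cnt - n_left))
      rows[[s]] <- data.frame(
        name = paste0(s, "_", ifelse(hemi == "left", "L", "R"), idx_in_hemi),
        hemisphere = hemi, system = s,
        volume = rlnorm(cnt, volume_meanlog, volume_sdlog),
        x = ifelse(hemi == "left", -1, 1) * abs(cent[1] + rnorm(cnt, 0, 10)),
        y = cent[2] + rnorm(cnt, 0, 12),
        z = cent[3] + rnorm(cnt, 0, 12),
        stringsAsFactors = FALSE
      )
    }
    regions <- do.call(rbind, rows)
    rownames(regions) <- NULL
    xyz <- as.matrix(regions[, c("x", "y", "z")])
    xyz <- enforce_min_separation(xyz, dist_range[1])
    # rescale about the centroid so the largest pairwise distance fits
    d <- as.matrix(stats::dist(xyz))
    dmax <- max(d)
    if (dmax > dist_range[2]) {
      ctr <- colMeans(xyz)
      xyz <- sweep(xyz, 2, ctr) * (dist_range[2] / dmax)
      xyz <- sweep(xyz, 2, ctr, `+`)
    }
    regions$x <- xyz[, 1]; regions$y <- xyz[, 2]; regions$z <- xyz[, 3]
    list(
      parcellation = cognitive_parcellation(regions$system, systems = systems),
      regions = regions
    )
  })
}

enforce_min_separation <- function(xyz, min_sep, max_tries = 200) {
  n <- nrow(xyz)
  for (i in seq_len(n)[-1]) {
    tries <- 0
    repeat {
      d <- sqrt(colSums((t(xyz[seq_len(i - 1), , drop = FALSE]) - xyz[i, ])^2))
      if (all(d >= min_sep) || tries >= max_tries) break
      xyz[i, ] <- xyz[i, ] + rnorm(3, 0, min_sep / 2)
      tries <- tries + 1
    }
  }
  xyz
}

#' Age trajectory specification
#'
#' Describes how a generator parameter scales with age. Kinds:
#' `"constant"` (always 1), `"linear"` (interpolates `from` to `to` across the
#' age range; increasing or decreasing depending on the endpoints),
#' `"decline"` (linear from `from` down to `to`, defaults 1.3 to 0.7), and
#' `"inverse_u"` (quadratic peak of height `peak_value` at age `peak`, falling
#' to `floor` at the age-range edge farthest from the peak).
#'
#' @param kind One of `"constant"`, `"linear"`, `"decline"`, `"inverse_u"`.
#' @param from,to Endpoints for linear kinds.
#' @param peak,peak_value,floor Inverse-U parameters.
#' @return An `age_trajectory` object.
#' @export
age_trajectory <- function(kind = c("constant", "linear", "decline",
                                    "inverse_u"),
                           from = 0.7, to = 1.3,
                           peak = 45, peak_value = 1.2, floor = 0.7) {
  kind <- match.arg(kind)
  if (kind == "decline" && from <= to) { tmp <- from; from <- to; to <- tmp }
  structure(list(kind = kind, from = from, to = to, peak = peak,
                 peak_value = peak_value, floor = floor),
            class = "age_trajectory")
}

#' Evaluate an age trajectory
#' @param traj An [age_trajectory()].
#' @param age Age in years.
#' @param age_range Ages over which the trajectory is defined.
#' @return Positive multiplicative factor.
#' @export
age_factor <- function(traj, age, age_range = c(5, 90)) {
  stopifnot(inherits(traj, "age_trajectory"))
  a <- pmin(pmax(age, age_range[1]), age_range[2])
  u <- (a - age_range[1]) / diff(age_range)
  switch(traj$kind,
    constant = rep(1, length(a)),
    linear = traj$from + u * (traj$to - traj$from),
    decline = traj$from + u * (traj$to - traj$from),
    inverse_u = {
      half <- max(abs(age_range - traj$peak))
      traj$peak_value -
        (traj$peak_value - traj$floor) * ((a - traj$peak) / half)^2
    }
  )
}

#' Synthetic cohort configuration
#'
#' Collects every knob of the synthetic connectome generator: the region plan,
#' block densities and streamline-count scales, the rich-club core, age
#' trajectories of the within- and between-system count scales, and the cohort
#' layout (age bins and individuals per bin).
#'
#' @param region_plan Named per-system region counts
#'   (default [default_region_plan()]).
#' @param n_per_bin Integer vector of individuals per age bin.
#' @param age_bins Matrix-like list of `c(lo, hi)` age bins in years.
#' @param density_within,density_between Edge probabilities within and between
#'   cognitive systems.
#' @param count_within,count_between Median streamline counts for within- and
#'   between-system edges (log-normal, `count_sdlog` spread).
#' @param count_sdlog Log-scale standard deviation of streamline counts (heavy
#'   tail).
#' @param core_size Number of rich-club core regions.
#' @param core_systems Systems from which core regions are drawn round-robin.
#' @param core_mult Weight multiplier for core-core edges.
#' @param hub_boost Multiplier applied to all edges incident to core regions.
#' @param traj_within,traj_between [age_trajectory()] of the within-/between-
#'   system count scales.
#' @param traj_density_between [age_trajectory()] multiplying the
#'   between-system edge density (clipped to `[0, 1]`); the main integration
#'   dial, since denser between-system wiring is what lets a stimulated
#'   region recruit other systems.
#' @param age_range Age span of the cohort in years.
#' @param dist_range Pairwise coordinate distance range in mm.
#' @param layout_seed Seed of the deterministic parcellation layout.
#' @param master_seed Master seed; per-individual seeds are derived from it.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(region_plan = default_region_plan(),
                          n_per_bin = c(8, 8, 8),
                          age_bins = list(c(5, 30), c(30, 60), c(60, 90)),
                          density_within = 0.85,
                          density_between = 0.20,
                          count_within = 600,
                          count_between = 90,
                          count_sdlog = 0.7,
                          core_size = 12L,
                          core_systems = c("SC", "DM", "Att"),
                          core_mult = 6,
                          hub_boost = 2,
                          traj_within = age_trajectory("inverse_u", peak = 40),
                          traj_between = age_trajectory("inverse_u", peak = 40),
                          traj_density_between = age_trajectory("constant"),
                          age_range = c(5, 90),
                          dist_range = c(10, 170),
                          layout_seed = 1L,
                          master_seed = 42L) {
  stopifnot(density_within >= 0, density_within <= 1,
            density_between >= 0, density_between <= 1,
            length(n_per_bin) == length(age_bins),
            all(n_per_bin >= 1), core_size >= 0)
  structure(
    list(region_plan = region_plan, n_per_bin = as.integer(n_per_bin),
         age_bins = age_bins, density_within = density_within,
         density_between = density_between, count_within = count_within,
         count_between = count_between, count_sdlog = count_sdlog,
         core_size = as.integer(core_size), core_systems = core_systems,
         core_mult = core_mult, hub_boost = hub_boost,
         traj_within = traj_within, traj_between = traj_between,
         traj_density_between = traj_density_between,
         age_range = age_range, dist_range = dist_range,
         layout_seed = as.integer(layout_seed),
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' Desk-scale demo cohort configuration
#'
#' A reduced cohort used by the examples and the end-to-end analysis at desk
#' scale: 27 regions (3 per cognitive system), 12 individuals (4 per coarse age
#' bin) and an age-increasing between-system coupling so that the planted
#' aging trend (rising integration) is recoverable from a small cohort.
#'
#' @param master_seed Master seed.
#' @return A `cohort_config`.
#' @export
demo_cohort_config <- function(master_seed = 42L) {
  plan <- setNames(rep(3L, 9), COGNITIVE_SYSTEMS)
  cohort_config(
    region_plan = plan,
    n_per_bin = c(4, 4, 4),
    core_size = 6L,
    traj_within = age_trajectory("constant"),
    traj_between = age_trajectory("constant"),
    traj_density_between = age_trajectory("linear", from = 0.4, to = 2.0),
    master_seed = master_seed
  )
}

core_regions <- function(parcellation, core_size, core_systems) {
  # deterministic round-robin draw of core regions from the core systems
  pools <- lapply(core_systems, function(s) system_members(parcellation, s))
  out <- integer(0)
  i <- 1
  while (length(out) < core_size) {
    pool <- pools[[(i - 1) %% length(pools) + 1]]
    take <- setdiff(pool, out)
    if (length(take) > 0) out <- c(out, take[1])
    i <- i + 1
    if (i > 10 * core_size + length(pools)) break
  }
  sort(out[seq_len(min(core_size, length(out)))])
}

#' Generate one synthetic connectome
#'
#' Draws a weighted stochastic block model over the cognitive systems:
#' within-system edges are denser and heavier than between-system edges,
#' a rich-club core of hub regions is planted (core-core edges always present
#' with boosted weights, all core-incident edges strengthened), streamline
#' counts follow truncated log-normal laws, and the within-/between-system
#' count scales are modulated by the configured age trajectories evaluated at
#' `age`. Counts are volume-normalized into weights via
#' [normalize_by_volume()].
#'
#' @param age Age in years (within the configured range).
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same `(age, config, seed)` reproduces the
#'   connectome bit-for-bit.
#' @param individual_id Label stored on the connectome.
#' @return A [connectome()] whose `regions` carry the system labels.
#' @export
generate_connectome <- function(age, config, seed,
                                individual_id = sprintf("synthetic_%06d",
                                                        seed %% 1000000L)) {
  stopifnot(inherits(config, "cohort_config"))
  if (age < config$age_range[1] || age > config$age_range[2]) {
    stop("age ", age, " outside configured range [",
         config$age_range[1], ", ", config$age_range[2], "]")
  }
  parc <- generate_parcellation(config$region_plan, seed = config$layout_seed,
                                dist_range = config$dist_range)
  n <- nrow(parc$regions)
  membership <- parc$parcellation$membership
  core <- core_regions(parc$parcellation, config$core_size,
                       config$core_systems)
  f_w <- age_factor(config$traj_within, age, config$age_range)
  f_b <- age_factor(config$traj_between, age, config$age_range)
  f_db <- age_factor(config$traj_density_between, age, config$age_range)
  with_seed(seed, {
    counts <- matrix(0, n, n)
    same <- outer(membership, membership, `==`)
    iu <- which(upper.tri(counts))
    is_within <- same[iu]
    p_edge <- ifelse(is_within, config$density_within,
                     pmin(1, config$density_between * f_db))
    mu <- ifelse(is_within, config$count_within * f_w,
                 config$count_between * f_b)
    present <- runif(length(iu)) < p_edge
    w <- numeric(length(iu))
    w[present] <- rlnorm(sum(present), meanlog = log(mu[present]),
                         sdlog = config$count_sdlog)
    counts[iu] <- w
    counts <- counts + t(counts)
    if (length(core) >= 2) {
      # plant the rich club: dense heavy core plus hub-strength boost;
      # core-core weights do not follow the age trajectories (hub wiring is
      # preserved across age, only peripheral connectivity drifts)
      cc <- as.matrix(expand.grid(core, core))
      cc <- cc[cc[, 1] < cc[, 2], , drop = FALSE]
      core_w <- rlnorm(nrow(cc),
                       meanlog = log(config$count_between * config$core_mult),
                       sdlog = config$count_sdlog)
      counts[cc] <- pmax(counts[cc], core_w)
      counts[cc[, 2:1, drop = FALSE]] <- counts[cc]
      counts[core, ] <- counts[core, ] * config$hub_boost
      counts[, core] <- t(counts[core, ])
    }
    counts <- round(counts)
    counts[counts < 0] <- 0
    diag(counts) <- 0
    weights <- normalize_by_volume(counts, parc$regions$volume)
    connectome(weights, parc$regions, age = age,
               individual_id = individual_id)
  })
}

#' Per-individual seed derivation
#'
#' Counter scheme deriving one RNG seed per individual from the master seed:
#' `seed_i = (master + 104729 * i) mod (2^31 - 1)` (104729 is the 10000th
#' prime; the modulus keeps seeds within R's integer range).
#'
#' @param master_seed Integer master seed.
#' @param i Individual counter (1-based).
#' @return Integer seed.
#' @export
individual_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(i)) %%
               2147483647)
}

#' Generate a synthetic cohort of connectomes
#'
#' Draws ages uniformly within each configured age bin (exactly `n_per_bin`
#' individuals per bin) and generates one connectome per individual with a
#' seed derived from the master seed via [individual_seed()].
#'
#' @param config A [cohort_config()].
#' @return List with `connectomes` (list of [connectome()]) and `manifest`
#'   (data frame: individual_id, age, seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ages <- with_seed(config$master_seed, {
    unlist(lapply(seq_along(config$age_bins), function(b) {
      lo <- config$age_bins[[b]][1]
      hi <- config$age_bins[[b]][2]
      runif(config$n_per_bin[b], lo, min(hi, config$age_range[2]))
    }))
  })
  n <- length(ages)
  ids <- sprintf("ind%03d", seq_len(n))
  seeds <- vapply(seq_len(n), function(i) individual_seed(config$master_seed, i),
                  integer(1))
  connectomes <- lapply(seq_len(n), function(i) {
    generate_connectome(ages[i], config, seed = seeds[i],
                        individual_id = ids[i])
  })
  manifest <- data.frame(individual_id = ids, age = ages, seed = seeds,
                         stringsAsFactors = FALSE)
  list(connectomes = connectomes, manifest = manifest)
}
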