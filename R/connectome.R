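#' Construct a structural connectome
#'
#' A connectome bundles a symmetric, nonnegative, zero-diagonal weight matrix
#' (volume-normalized streamline counts) with per-region metadata and the
#' individual's age. Weights that are symmetric only up to a small numerical
#' tolerance are symmetrized by averaging; anything worse is rejected.
#'
#' @param weights Square numeric matrix of nonnegative weights, zero diagonal.
#' @param regions Data frame with one row per region and columns
#'   `name`, `hemisphere` (`"left"`, `"right"` or `"none"`), `system`,
#'   `volume` (> 0) and coordinates `x`, `y`, `z` in mm.
#' @param age Age of the individual in years.
#' @param individual_id Opaque label for the individual.
#' @param sym_tol Tolerance on `max(abs(W - t(W)))` beyond which the matrix is
#'   rejected rather than symmetrized (default `1e-12`, scaled by the largest
#'   weight).
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, regions, age = NA_real_,
                       individual_id = "unknown", sym_tol = 1e-12) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("weights must be square, got ", nrow(weights), " x ", ncol(weights))
  }
  n <- nrow(weights)
  if (!is.data.frame(regions) || nrow(regions) != n) {
    stop("regions must be a data.frame with one row per region (", n, ")")
  }
  required <- c("name", "hemisphere", "system", "volume", "x", "y", "z")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("regions is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!regions$hemisphere %in% c("left", "right", "none"))) {
    stop("hemisphere must be one of 'left', 'right', 'none'")
  }
  bad_vol <- which(!is.finite(regions$volume) | regions$volume <= 0)
  if (length(bad_vol) > 0) {
    stop("non-positive volume at region index ", bad_vol[1])
  }
  if (any(!is.finite(weights))) stop("weights contain non-finite entries")
  neg <- which(weights < 0)
  if (length(neg) > 0) {
    idx <- arrayInd(neg[1], dim(weights))
    stop("negative weight at (", idx[1], ", ", idx[2], ")")
  }
  scale <- max(weights, 1)
  asym <- max(abs(weights - t(weights)))
  if (asym > sym_tol * scale) {
    idx <- arrayInd(which.max(abs(weights - t(weights))), dim(weights))
    stop("weights not symmetric: max asymmetry ", signif(asym, 3),
         " at (", idx[1], ", ", idx[2], ")")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(regions$name, regions$name)
  structure(
    list(weights = weights, regions = regions, age = as.numeric(age),
         individual_id = as.character(individual_id)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  cat("<connectome> ", x$individual_id, ": ", n, " regions, age ",
      x$age, "\n", sep = "")
  cat("  systems: ", paste(sort(unique(x$regions$system)), collapse = ", "),
      "\n", sep = "")
  cat("  edges (nonzero upper triangle): ",
      sum(x$weights[upper.tri(x$weights)] > 0), "\n", sep = "")
  invisible(x)
}

#' Number of regions in a connectome
#' @param x A `connectome`.
#' @return Integer region count.
#' @export
n_regions <- function(x) {
  stopifnot(inherits(x, "connectome"))
  nrow(x$weights)
}

#' Volume-normalize a streamline count matrix
#'
#' Converts raw streamline counts into connectome weights by dividing each
#' count by the sum of the two incident region volumes:
#' `W[j, k] = counts[j, k] / (volumes[j] + volumes[k])`.
#'
#' @param counts Square symmetric nonnegative matrix of streamline counts with
#'   zero diagonal.
#' @param volumes Strictly positive numeric vector, one entry per region.
#' @return Weight matrix of the same dimension; symmetric with zero diagonal.
#' @export
normalize_by_volume <- function(counts, volumes) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (ncol(counts) != n) stop("counts must be square")
  if (length(volumes) != n) {
    stop("volumes has length ", length(volumes), ", expected ", n)
  }
  bad <- which(!is.finite(volumes) | volumes <= 0)
  if (length(bad) > 0) stop("non-positive volume at index ", bad[1])
  neg <- which(counts < 0)
  if (length(neg) > 0) {
    idx <- arrayInd(neg[1], dim(counts))
    stop("negative count at (", idx[1], ", ", idx[2], ")")
  }
  asym <- which(counts != t(counts))
  if (length(asym) > 0) {
    idx <- arrayInd(asym[1], dim(counts))
    stop("counts not symmetric at (", idx[1], ", ", idx[2], ")")
  }
  if (any(diag(counts) != 0)) {
    stop("counts diagonal must be zero (index ",
         which(diag(counts) != 0)[1], ")")
  }
  denom <- outer(volumes, volumes, `+`)
  out <- counts / denom
  diag(out) <- 0
  out
}

#' Construct a cognitive parcellation
#'
#' Maps region indices to cognitive systems. The default parcellation has
#' nine systems; the auditory system is conventionally split by hemisphere at
#' the reporting (not classification) stage.
#'
#' @param membership Character vector, one system label per region.
#' @param systems Ordered vector of system labels (defaults to the sorted
#'   unique labels of `membership`, or [COGNITIVE_SYSTEMS] when all labels are
#'   canonical).
#' @param hemisphere_split Systems whose statistics are reported separately per
#'   hemisphere (default `"Aud"`).
#' @return An object of class `cognitive_parcellation`.
#' @export
cognitive_parcellation <- function(membership,
                                   systems = NULL,
                                   hemisphere_split = "Aud") {
  membership <- as.character(membership)
  if (length(membership) == 0) stop("membership must be nonempty")
  if (is.null(systems)) {
    u <- unique(membership)
    systems <- if (all(u %in% COGNITIVE_SYSTEMS)) {
      COGNITIVE_SYSTEMS[COGNITIVE_SYSTEMS %in% u]
    } else {
      sort(u)
    }
  }
  if (!all(membership %in% systems)) {
    stop("membership labels not in systems: ",
         paste(setdiff(membership, systems), collapse = ", "))
  }
  structure(
    list(systems = systems, membership = membership,
         hemisphere_split = hemisphere_split),
    class = "cognitive_parcellation"
  )
}

#' @export
print.cognitive_parcellation <- function(x, ...) {
  cat("<cognitive_parcellation> ", length(x$membership), " regions in ",
      length(x$systems), " systems\n", sep = "")
  print(table(factor(x$membership, levels = x$systems)))
  invisible(x)
}

#' Region indices belonging to a cognitive system
#' @param parcellation A `cognitive_parcellation`.
#' @param system System label.
#' @return Integer vector of region indices.
#' @export
system_members <- function(parcellation, system) {
  stopifnot(inherits(parcellation, "cognitive_parcellation"))
  if (!system %in% parcellation$systems) stop("unknown system: ", system)
  which(parcellation$membership == system)
}

#' Construct a module partition
#'
#' A partition of regions into modules, used by [module_strength()] and
#' [participation_coefficient()]. Module ids are recoded to be contiguous
#' starting at 1, preserving first-appearance order.
#'
#' @param labels Vector of module labels, one per region.
#' @return An object of class `module_partition` with elements `labels`
#'   (integer, contiguous from 1) and `n_modules`.
#' @export
module_partition <- function(labels) {
  if (length(labels) == 0) stop("labels must be nonempty")
  ids <- as.integer(factor(labels, levels = unique(labels)))
  structure(list(labels = ids, n_modules = max(ids)),
            class = "module_partition")
}

#' Module partition induced by a cognitive parcellation
#' @param parcellation A `cognitive_parcellation`.
#' @return A `module_partition` with one module per system.
#' @export
as_module_partition <- function(parcellation) {
  stopifnot(inherits(parcellation, "cognitive_parcellation"))
  module_partition(factor(parcellation$membership,
                          levels = parcellation$systems))
}
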