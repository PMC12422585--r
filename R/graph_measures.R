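#' Region strength
#'
#' Total weighted connectivity of each region, `S_k = sum_j A[j, k]`.
#'
#' @param x A `connectome` or a symmetric weight matrix.
#' @return Numeric vector of strengths, one per region.
#' @export
region_strength <- function(x) {
  W <- weight_matrix(x)
  colSums(W)
}

weight_matrix <- function(x) {
  if (inherits(x, "connectome")) x$weights else as.matrix(x)
}

#' Module strength of a region
#'
#' Connectivity of region `k` restricted to regions in module `m`:
#' `S_{k,m} = sum_{j in m} A[j, k]`. Summed over all modules this equals the
#' region strength.
#'
#' @param x A `connectome` or weight matrix.
#' @param partition A `module_partition`.
#' @param k Region index.
#' @param m Module id (1-based, contiguous).
#' @return Scalar module strength.
#' @export
module_strength <- function(x, partition, k, m) {
  W <- weight_matrix(x)
  stopifnot(inherits(partition, "module_partition"))
  if (k < 1 || k > nrow(W)) stop("region index out of range: ", k)
  if (!m %in% seq_len(partition$n_modules)) stop("unknown module id: ", m)
  sum(W[partition$labels == m, k])
}

module_strength_matrix <- function(W, partition) {
  # regions x modules matrix of S_{k,m}
  M <- outer(partition$labels, seq_len(partition$n_modules), `==`) * 1
  t(M) %*% W  # modules x regions
}

#' Participation coefficient
#'
#' Measures how evenly a region's strength is spread across modules:
#' `PC_k = 1 - sum_m (S_{k,m} / S_k)^2`. Zero-strength (isolated) regions are
#' assigned `PC = 0`: an isolated node participates in nothing.
#'
#' @param x A `connectome` or weight matrix.
#' @param partition A `module_partition`; for a connectome this defaults to
#'   the partition induced by its cognitive-system labels.
#' @return Numeric vector `PC_k` in `[0, 1 - 1/n_modules]`.
#' @export
participation_coefficient <- function(x, partition = NULL) {
  W <- weight_matrix(x)
  if (is.null(partition)) {
    if (!inherits(x, "connectome")) {
      stop("partition required when x is a plain matrix")
    }
    partition <- module_partition(x$regions$system)
  }
  stopifnot(inherits(partition, "module_partition"))
  if (length(partition$labels) != nrow(W)) {
    stop("partition covers ", length(partition$labels),
         " regions, matrix has ", nrow(W))
  }
  S <- colSums(W)
  Skm <- module_strength_matrix(W, partition)  # modules x regions
  pc <- rep(0, length(S))
  pos <- S > 0
  frac <- sweep(Skm[, pos, drop = FALSE], 2, S[pos], "/")
  pc[pos] <- 1 - colSums(frac^2)
  unname(pc)
}

#' Strength-preserving randomized null connectome
#'
#' Generates a null weight matrix that randomizes topology and weight placement
#' while preserving the degree sequence (via double-edge swaps) and the node
#' strength sequence (via symmetric iterative proportional fitting of the
#' rewired weights onto the original strengths).
#'
#' @param W Symmetric nonnegative weight matrix, zero diagonal.
#' @param n_swaps Number of attempted double-edge swaps (default `10 * edges`).
#' @param strength_tol Relative tolerance on the strength match (default 1e-8).
#' @param max_ipf Iteration cap for the strength-matching scaling.
#' @return A symmetric null weight matrix with (near-)identical strengths.
#' @export
strength_preserving_null <- function(W, n_swaps = NULL, strength_tol = 1e-8,
                                     max_ipf = 500) {
  W <- weight_matrix(W)
  n <- nrow(W)
  target <- colSums(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  if (is.null(n_swaps)) n_swaps <- 10L * igraph::ecount(g)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  igraph::E(g2)$weight <- sample(ew)
  Wn <- as.matrix(igraph::as_adjacency_matrix(g2, attr = "weight",
                                              sparse = FALSE))
  # symmetric IPF: scale W <- D W D until row sums match the target strengths
  for (it in seq_len(max_ipf)) {
    s <- colSums(Wn)
    if (all(s == 0)) break
    err <- max(abs(s - target) / pmax(target, .Machine$double.eps))
    if (err < strength_tol) break
    d <- sqrt(target / pmax(s, .Machine$double.eps))
    d[target == 0] <- 0
    Wn <- Wn * outer(d, d)
  }
  diag(Wn) <- 0
  Wn
}

#' Weighted rich-club detection
#'
#' Computes the weighted rich-club coefficient over strength-ranked cutoffs and
#' identifies the rich-club members. For each cutoff rank `r`, the coefficient
#' `phi(r)` is the total weight among the top-`r` strongest regions divided by
#' the sum of the same number of strongest edge weights anywhere in the network
#' (so `phi <= 1`). It is normalized by the mean coefficient of
#' `n_null` strength-preserving randomized nulls. Members are the top-ranked
#' regions over the widest contiguous run of cutoffs with normalized
#' coefficient `> 1` (the club is read off at the upper end of that run, so it
#' contains every cutoff set in the run).
#'
#' @param x A `connectome` or weight matrix (connected, >= 8 regions).
#' @param n_null Number of randomized nulls (default 100).
#' @param min_rank,max_rank Range of cutoff ranks scanned (defaults 2 to n-1).
#' @param seed Integer seed for null generation.
#' @return List with `members` (integer region indices, possibly empty),
#'   `ranks`, `phi`, `phi_null` (mean over nulls) and `phi_norm`.
#' @export
rich_club <- function(x, n_null = 100, min_rank = 2, max_rank = NULL,
                      seed = 1L) {
  W <- weight_matrix(x)
  n <- nrow(W)
  if (n < 8) stop("graph too small for rich-club null generation (< 8 nodes)")
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  if (igraph::components(g)$no > 1) {
    stop("rich_club requires a connected graph")
  }
  if (is.null(max_rank)) max_rank <- n - 1
  ranks <- seq.int(min_rank, max_rank)
  phi <- rich_club_curve(W, ranks)
  set.seed(seed)
  phi_null <- matrix(0, nrow = n_null, ncol = length(ranks))
  for (b in seq_len(n_null)) {
    phi_null[b, ] <- rich_club_curve(strength_preserving_null(W), ranks)
  }
  phi_null_mean <- colMeans(phi_null)
  phi_norm <- ifelse(phi_null_mean > 0, phi / phi_null_mean, NA_real_)
  above <- !is.na(phi_norm) & phi_norm > 1
  members <- integer(0)
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    keep <- which(runs$values)
    widest <- keep[which.max(runs$lengths[keep])]
    r_star <- ranks[ends[widest]]
    members <- order(colSums(W), decreasing = TRUE)[seq_len(r_star)]
  }
  list(members = sort(members), ranks = ranks, phi = phi,
       phi_null = phi_null_mean, phi_norm = phi_norm)
}

rich_club_curve <- function(W, ranks) {
  n <- nrow(W)
  S <- colSums(W)
  ord <- order(S, decreasing = TRUE)
  upper <- W[upper.tri(W)]
  wsorted <- sort(upper[upper > 0], decreasing = TRUE)
  vapply(ranks, function(r) {
    top <- ord[seq_len(r)]
    sub <- W[top, top]
    w_in <- sum(sub[upper.tri(sub)])
    e_in <- sum(sub[upper.tri(sub)] > 0)
    if (e_in == 0) return(0)
    w_in / sum(wsorted[seq_len(e_in)])
  }, numeric(1))
}

#' Shortest topological distance to the rich club
#'
#' Minimum hop count on the binary graph of nonzero edges from a region to any
#' rich-club member; 0 for members themselves and `Inf` for regions with no
#' path to the club. With `weighted = TRUE`, path lengths use `1/weight` edge
#' costs instead of hops.
#'
#' @param x A `connectome` or weight matrix.
#' @param members Nonempty integer vector of rich-club region indices.
#' @param k Optional region index; if `NULL` the full distance vector is
#'   returned.
#' @param weighted Use `1/weight` edge lengths instead of hop counts.
#' @return Distance(s); `Inf` marks disconnection from the club.
#' @export
distance_to_rich_club <- function(x, members, k = NULL, weighted = FALSE) {
  W <- weight_matrix(x)
  if (length(members) == 0) stop("rich club member set must be nonempty")
  if (weighted) {
    L <- ifelse(W > 0, 1 / W, 0)
    g <- igraph::graph_from_adjacency_matrix(L, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    D <- igraph::distances(g, v = members, weights = igraph::E(g)$weight)
  } else {
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    D <- igraph::distances(g, v = members)
  }
  d <- apply(D, 2, min)
  d[members] <- 0
  if (is.null(k)) unname(d) else unname(d[k])
}
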