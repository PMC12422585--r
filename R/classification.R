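#' Classifier configuration
#'
#' @param threshold Binarization threshold on the synchrony matrix; entries
#'   with `R >= threshold` count as synchronous (default 0.65, robust over
#'   roughly 0.55-0.80).
#' @param louvain_restarts Number of seeded Louvain restarts (best modularity
#'   kept).
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed Integer seed making the restarts deterministic.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(threshold = 0.65, louvain_restarts = 50L,
                              resolution = 1, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1, louvain_restarts >= 1)
  structure(
    list(threshold = threshold, louvain_restarts = as.integer(louvain_restarts),
         resolution = resolution, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Binarize a synchrony matrix
#'
#' Entries with `R >= threshold` (inclusive) become 1, all others 0.
#'
#' @param R Symmetric synchrony matrix.
#' @param threshold Threshold in (0, 1), default 0.65.
#' @return Symmetric binary matrix of the same dimension.
#' @export
binarize <- function(R, threshold = 0.65) {
  B <- (unclass(as.matrix(R)) >= threshold) * 1
  dimnames(B) <- dimnames(R)
  B
}

#' Louvain community detection on a binary synchrony graph
#'
#' Modularity maximization (Newman-Girvan null model, configurable resolution)
#' over the binary graph; the diagonal (self-synchrony) is ignored. Each
#' restart runs Louvain on a seeded random vertex permutation (the aggregation
#' itself is deterministic, so permuting is what diversifies restarts); two
#' further deterministic heuristics (greedy agglomeration and leading
#' eigenvector) seed additional candidates, guarding against the rare local
#' optima that vertex-order restarts alone do not escape on small graphs. The
#' best candidates are finished with a deterministic refinement pass
#' (strictly-improving single-node moves, then modularity-neutral merges that
#' realize the fewest-communities convention on degenerate optima) and the
#' highest-modularity result is returned, ties broken toward fewer
#' communities. Deterministic given the seed. An edgeless graph yields
#' all-singleton communities.
#'
#' @param B Square symmetric 0/1 matrix.
#' @param config A [classifier_config()] (threshold unused here).
#' @return Integer community labels, contiguous from 1.
#' @export
louvain_partition <- function(B, config = classifier_config()) {
  B <- as.matrix(B)
  stopifnot(nrow(B) == ncol(B), all(B %in% c(0, 1)),
            all(B == t(B)))
  diag(B) <- 0
  n <- nrow(B)
  if (sum(B) == 0) return(seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected",
                                           diag = FALSE)
  candidates <- lapply(seq_len(config$louvain_restarts), function(i) {
    with_seed(individual_seed(config$seed, i), {
      perm <- sample.int(n)
      gp <- igraph::graph_from_adjacency_matrix(B[perm, perm, drop = FALSE],
                                                mode = "undirected",
                                                diag = FALSE)
      mp <- igraph::membership(
        igraph::cluster_louvain(gp, resolution = config$resolution)
      )
      as.integer(mp)[match(seq_len(n), perm)]
    })
  })
  extra <- with_seed(config$seed, list(
    tryCatch(as.integer(igraph::membership(igraph::cluster_fast_greedy(g))),
             error = function(e) NULL),
    tryCatch(suppressWarnings(
      as.integer(igraph::membership(igraph::cluster_leading_eigen(g)))),
      error = function(e) NULL)
  ))
  extra <- Filter(Negate(is.null), extra)
  qs <- vapply(candidates, newman_modularity, numeric(1), B = B,
               resolution = config$resolution)
  finalists <- order(qs, decreasing = TRUE)[seq_len(min(3, length(qs)))]
  candidates <- c(candidates[finalists], extra)
  finalists <- seq_along(candidates)
  best <- NULL
  best_q <- -Inf
  for (i in finalists) {
    memb <- refine_partition(B, candidates[[i]], config$resolution)
    q <- newman_modularity(B, memb, resolution = config$resolution)
    better <- q > best_q + 1e-12 ||
      (abs(q - best_q) <= 1e-12 &&
         length(unique(memb)) < length(unique(best)))
    if (better) {
      best_q <- q
      best <- memb
    }
  }
  as.integer(factor(best, levels = unique(best)))
}

newman_modularity <- function(B, memb, resolution = 1) {
  m2 <- sum(B)
  if (m2 == 0) return(0)
  k <- colSums(B)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(B[idx, idx]) / m2 - resolution * (sum(k[idx]) / m2)^2
  }
  q
}

# deterministic refinement: greedy strictly-improving single-node moves, then
# modularity-neutral (or better) merges of communities that share at least one
# edge. The merge step realizes the fewest-communities convention on
# degenerate optima, where the same maximal modularity is attained both with
# and without singleton communities; requiring a connecting edge keeps
# entirely unconnected (zero-degree) systems in their own singleton
# communities, where a cost-free merge would otherwise fabricate synchrony.
refine_partition <- function(B, memb, resolution = 1) {
  n <- nrow(B)
  repeat {
    repeat {
      moved <- FALSE
      for (v in seq_len(n)) {
        q0 <- newman_modularity(B, memb, resolution)
        for (tcomm in setdiff(c(unique(memb), max(memb) + 1L), memb[v])) {
          cand <- memb
          cand[v] <- tcomm
          if (newman_modularity(B, cand, resolution) > q0 + 1e-12) {
            memb <- cand
            moved <- TRUE
            break
          }
        }
      }
      if (!moved) break
    }
    comms <- unique(memb)
    if (length(comms) < 2) break
    q0 <- newman_modularity(B, memb, resolution)
    best_dq <- -Inf
    best_pair <- NULL
    for (a in seq_along(comms)[-length(comms)]) {
      for (b in (a + 1):length(comms)) {
        if (sum(B[memb == comms[a], memb == comms[b]]) == 0) next
        cand <- memb
        cand[cand == comms[b]] <- comms[a]
        dq <- newman_modularity(B, cand, resolution) - q0
        if (dq > best_dq) {
          best_dq <- dq
          best_pair <- c(comms[a], comms[b])
        }
      }
    }
    if (is.null(best_pair)) break
    if (best_dq < -1e-12) break
    memb[memb == best_pair[2]] <- best_pair[1]
  }
  memb
}

# cache of set-partition enumerations keyed by n
.partition_cache <- new.env(parent = emptyenv())

# all set partitions of n elements as restricted growth strings
# (lexicographic), returned as an n-column integer matrix of 1-based labels
enumerate_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  parts <- list()
  rgs <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) {
      parts[[length(parts) + 1]] <<- rgs + 1L
      return(invisible())
    }
    for (lab in 0:maxlab) {
      rgs[i] <<- lab
      recurse(i + 1, max(maxlab, lab + 1))
    }
  }
  recurse(2L, 1L)  # rgs[1] = 0 fixed
  M <- do.call(rbind, parts)
  .partition_cache[[key]] <- M
  M
}

# upper-triangle pair co-membership matrix for all partitions of n nodes
pair_comembership <- function(n) {
  key <- paste0("D", n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  P <- enumerate_set_partitions(n)
  iu <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  D <- (P[, iu[, 1]] == P[, iu[, 2]]) * 1
  .partition_cache[[key]] <- D
  D
}

#' Exhaustive modularity-optimal partition (test oracle)
#'
#' Enumerates every set partition of the nodes (Bell(9) = 21147 for nine
#' nodes) and returns the one maximizing Newman-Girvan modularity. Among
#' tied optima, partitions in which some member of a multi-node community has
#' no edge into its own community are discarded (splitting such a member off
#' never lowers modularity, and a cost-free co-assignment would fabricate
#' community membership); remaining ties break toward fewer communities, then
#' lexicographically smallest labels. Refuses graphs with more than 10 nodes.
#'
#' @param B Square symmetric 0/1 matrix, diagonal ignored.
#' @return List with `membership` (integer labels from 1) and `modularity`.
#' @export
brute_force_partition <- function(B) {
  B <- as.matrix(B)
  n <- nrow(B)
  if (n > 10) stop("brute_force_partition refuses graphs with > 10 nodes")
  stopifnot(ncol(B) == n, all(B %in% c(0, 1)), all(B == t(B)))
  diag(B) <- 0
  if (sum(B) == 0) {
    return(list(membership = seq_len(n), modularity = 0))
  }
  m2 <- sum(B)
  k <- colSums(B)
  iu <- which(upper.tri(B), arr.ind = TRUE)
  b <- B[iu] - k[iu[, 1]] * k[iu[, 2]] / m2
  diag_term <- -sum(k^2) / m2
  D <- pair_comembership(n)
  Q <- as.numeric(2 * (D %*% b) + diag_term) / m2
  q_max <- max(Q)
  cand <- which(Q >= q_max - 1e-12)
  P <- enumerate_set_partitions(n)
  no_stray <- vapply(cand, function(ci) {
    memb <- P[ci, ]
    for (c in unique(memb)) {
      idx <- which(memb == c)
      if (length(idx) >= 2 &&
          any(colSums(B[idx, idx, drop = FALSE]) == 0)) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  if (any(no_stray)) cand <- cand[no_stray]
  n_comm <- apply(P[cand, , drop = FALSE], 1, max)
  cand <- cand[n_comm == min(n_comm)]
  best <- min(cand)  # enumeration is lexicographic in the growth string
  list(membership = as.integer(P[best, ]), modularity = Q[best])
}

#' Synchronization pattern from a community assignment
#'
#' Systems in any community with two or more members join the synchronous
#' group (label 1), including when several multi-member communities coexist;
#' singleton-community systems form the asynchronous group (label 0).
#'
#' @param assignment Integer community labels over the systems.
#' @return Binary integer vector of the same length (named if the assignment
#'   is named).
#' @export
pattern_from_partition <- function(assignment) {
  sizes <- table(assignment)
  labels <- as.integer(sizes[as.character(assignment)] >= 2)
  names(labels) <- names(assignment)
  labels
}

#' Three-way class of a synchronization pattern
#'
#' @param labels Binary vector over the cognitive systems (1 = synchronous
#'   group).
#' @return `"synchronous"` (all 1), `"asynchronous"` (all 0) or `"chimera"`.
#' @export
classify_pattern <- function(labels) {
  stopifnot(all(labels %in% c(0, 1)))
  if (all(labels == 1)) return("synchronous")
  if (all(labels == 0)) return("asynchronous")
  "chimera"
}

#' Classify a synchrony matrix into a synchronization pattern
#'
#' Full classification pipeline for one stimulated region: binarize the
#' synchrony matrix, detect communities among the cognitive systems with
#' seeded Louvain restarts, map multi-member communities to the synchronous
#' group, and assign the three-way class.
#'
#' @param R A `synchrony_matrix` (or plain symmetric matrix with system
#'   dimnames).
#' @param config A [classifier_config()].
#' @return A `synchronization_pattern`: list with `labels` (named binary
#'   vector), `class`, and `community_assignment`.
#' @export
classify_synchrony_matrix <- function(R, config = classifier_config()) {
  B <- binarize(R, config$threshold)
  memb <- louvain_partition(B, config)
  names(memb) <- rownames(B)
  labels <- pattern_from_partition(memb)
  structure(
    list(labels = labels, class = classify_pattern(labels),
         community_assignment = memb),
    class = "synchronization_pattern"
  )
}

#' @export
print.synchronization_pattern <- function(x, ...) {
  cat("<synchronization_pattern> class: ", x$class, "\n  ", sep = "")
  cat(paste0(names(x$labels), "=", x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Encode a pattern's labels as a bit string
#' @param labels Binary vector (or a `synchronization_pattern`).
#' @return Character scalar such as `"110100110"`.
#' @export
pattern_string <- function(labels) {
  if (inherits(labels, "synchronization_pattern")) labels <- labels$labels
  paste(as.integer(labels), collapse = "")
}
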