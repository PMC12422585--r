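# shared fixtures and independent oracles, built in code at test time

make_regions <- function(systems, hemisphere = NULL, volume = NULL,
                         coords = NULL) {
  n <- length(systems)
  if (is.null(hemisphere)) hemisphere <- rep(c("left", "right"), length.out = n)
  if (is.null(volume)) volume <- rep(1000, n)
  if (is.null(coords)) {
    coords <- cbind(x = seq_len(n) * 10, y = 0, z = 0)
  }
  data.frame(name = paste0("r", seq_len(n)), hemisphere = hemisphere,
             system = systems, volume = volume,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

toy_connectome <- function(W, systems = rep("A", nrow(W)), age = 30,
                           id = "toy", ...) {
  connectome(W, make_regions(systems, ...), age = age, individual_id = id)
}

random_symmetric_weights <- function(n, density = 0.5, wmax = 1) {
  W <- matrix(0, n, n)
  iu <- which(upper.tri(W))
  on <- runif(length(iu)) < density
  W[iu[on]] <- runif(sum(on), 0, wmax)
  W + t(W)
}

random_binary_graph <- function(n = 9, p = runif(1, 0.15, 0.85)) {
  B <- matrix(0, n, n)
  iu <- upper.tri(B)
  B[iu] <- rbinom(sum(iu), 1, p)
  B + t(B)
}

# brute-force per-edge tally for module strength (independent of the
# matrix-algebra implementation)
oracle_module_strength <- function(W, labels, k, m) {
  total <- 0
  for (j in seq_len(nrow(W))) {
    if (labels[j] == m) total <- total + W[j, k]
  }
  total
}

# direct double-loop evaluation of the pairwise cognitive-system synchrony
oracle_synchrony_matrix <- function(phi, membership, systems) {
  ns <- length(systems)
  R <- matrix(0, ns, ns, dimnames = list(systems, systems))
  for (j in seq_len(ns)) {
    for (k in j:ns) {
      members <- if (j == k) {
        which(membership == systems[j])
      } else {
        c(which(membership == systems[j]), which(membership == systems[k]))
      }
      rho <- vapply(seq_len(nrow(phi)), function(t) {
        Mod(sum(exp(1i * phi[t, members])) / length(members))
      }, numeric(1))
      R[j, k] <- R[k, j] <- mean(rho)
    }
  }
  R
}

# naive O(Np^2 * Ncs) pattern similarity
oracle_pattern_similarity <- function(M) {
  np <- nrow(M)
  acc <- 0
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (i == j) next
      acc <- acc + mean(M[i, ] == M[j, ])
    }
  }
  acc / (np * (np - 1))
}

as_matrix_bits <- function(bitstrings) {
  do.call(rbind, lapply(strsplit(bitstrings, ""), as.integer))
}

# synthetic trajectory wrapper for phase/classification tests
fake_trajectory <- function(E, I, dt = 1, transient = 0) {
  times <- (seq_len(nrow(E)) - 1) * dt
  structure(
    list(E = E, I = I, times = times,
         steady_slice = which(times >= transient),
         params = wc_params(), config = NULL, stim = NULL),
    class = "wc_trajectory"
  )
}
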