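test_that("strength is the weighted row sum", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2
  W[1, 3] <- W[3, 1] <- 3
  cn <- toy_connectome(W, c("A", "A", "B"))
  expect_equal(unname(region_strength(cn)), c(5, 2, 3))

  # isolated region and permutation equivariance
  W4 <- rbind(cbind(W, 0), 0)
  expect_equal(region_strength(W4)[4], 0)
  perm <- c(3, 1, 4, 2)
  expect_equal(region_strength(W4[perm, perm]), region_strength(W4)[perm])
})

test_that("module strength partitions the total strength", {
  set.seed(11)
  W <- random_symmetric_weights(4, density = 1)
  labels <- c(1, 1, 2, 2)
  mp <- module_partition(labels)
  for (k in 1:4) {
    parts <- vapply(1:2, function(m) module_strength(W, mp, k, m), numeric(1))
    expect_equal(sum(parts), region_strength(W)[k])
    for (m in 1:2) {
      expect_equal(parts[m], oracle_module_strength(W, labels, k, m))
    }
  }
  # all edges inside own module
  Wb <- matrix(0, 4, 4)
  Wb[1, 2] <- Wb[2, 1] <- 3
  expect_equal(module_strength(Wb, mp, 1, 1), region_strength(Wb)[1])
  expect_equal(module_strength(Wb, mp, 1, 2), 0)
  expect_error(module_strength(Wb, mp, 1, 9), "unknown module")
  expect_error(module_strength(Wb, mp, 9, 1), "out of range")
})

test_that("participation coefficient matches its closed forms", {
  # all edges within own module -> 0
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 2
  mp <- module_partition(c(1, 1, 2, 2))
  expect_equal(participation_coefficient(W, mp), rep(0, 4))

  # strength split evenly among 4 modules -> 1 - 1/4
  W2 <- matrix(0, 5, 5)
  W2[1, 2:5] <- W2[2:5, 1] <- 1
  mp2 <- module_partition(c(1, 1, 2, 3, 4))
  expect_equal(participation_coefficient(W2, mp2)[1], 0.75)

  # hand 5-node example against term-by-term evaluation
  set.seed(21)
  W3 <- random_symmetric_weights(5, density = 0.9)
  labels <- c(1, 2, 1, 2, 2)
  mp3 <- module_partition(labels)
  pc <- participation_coefficient(W3, mp3)
  S <- region_strength(W3)
  for (k in 1:5) {
    terms <- vapply(1:2, function(m) {
      (oracle_module_strength(W3, labels, k, m) / S[k])^2
    }, numeric(1))
    expect_equal(pc[k], 1 - sum(terms))
  }
  expect_true(all(pc >= 0 & pc <= 1 - 1 / 2 + 1e-12))

  # zero-strength region gets 0, and PC is scale invariant
  W4 <- rbind(cbind(W3, 0), 0)
  mp4 <- module_partition(c(labels, 1))
  pc4 <- participation_coefficient(W4, mp4)
  expect_identical(pc4[6], 0)
  expect_equal(participation_coefficient(W4 * 17.3, mp4), pc4)
})

test_that("graph measures agree with per-edge enumeration on random graphs", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    W <- random_symmetric_weights(n, density = 0.6)
    labels <- sample(1:3, n, replace = TRUE)
    labels[1:3] <- 1:3
    mp <- module_partition(labels)
    S_direct <- vapply(seq_len(n), function(k) sum(W[, k]), numeric(1))
    expect_equal(region_strength(W), S_direct)
    pc <- participation_coefficient(W, mp)
    for (k in seq_len(n)) {
      skm <- vapply(1:3, function(m) oracle_module_strength(W, labels, k, m),
                    numeric(1))
      expect_equal(sum(skm), S_direct[k])
      expected_pc <- if (S_direct[k] == 0) 0 else 1 - sum((skm / S_direct[k])^2)
      expect_equal(pc[k], expected_pc)
    }
  }
})

test_that("rich club is empty on a star and contains a planted core", {
  set.seed(44)
  n <- 10
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- runif(n - 1, 0.5, 1.5)
  rc <- rich_club(W, n_null = 30, seed = 1)
  expect_length(rc$members, 0)
  expect_true(all(rc$phi_norm <= 1 + 1e-9, na.rm = TRUE))
  expect_error(rich_club(matrix(0, 4, 4)), "too small")

  planted <- function(seed) {
    set.seed(seed)
    n <- 16
    W <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (i <= 6 && j <= 6) {
          W[i, j] <- W[j, i] <- 10 + runif(1)
        } else if (runif(1) < 0.3) {
          W[i, j] <- W[j, i] <- runif(1)
        }
      }
    }
    for (j in 7:n) {
      if (sum(W[, j]) == 0) {
        i <- sample(1:6, 1)
        W[i, j] <- W[j, i] <- runif(1)
      }
    }
    W
  }
  hits <- 0
  n_trials <- 25
  for (s in seq_len(n_trials)) {
    rc <- rich_club(planted(s), n_null = 30, seed = s)
    hits <- hits + all(1:6 %in% rc$members)
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("randomized null preserves the strength sequence", {
  set.seed(55)
  W <- random_symmetric_weights(12, density = 0.5)
  Wn <- strength_preserving_null(W)
  expect_equal(colSums(Wn), colSums(W), tolerance = 1e-6)
  expect_identical(unname(diag(Wn)), rep(0, 12))
  expect_equal(Wn, t(Wn))
})

test_that("distance to the rich club counts hops, Inf when unreachable", {
  # 7-node path graph, club = one endpoint
  n <- 7
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) W[i, i + 1] <- W[i + 1, i] <- runif(1, 0.5, 2)
  expect_equal(distance_to_rich_club(W, members = 1), 0:6)
  expect_equal(distance_to_rich_club(W, members = 1, k = 2), 1)
  expect_equal(distance_to_rich_club(W, members = c(1, 4), k = 6), 2)
  expect_error(distance_to_rich_club(W, members = integer(0)), "nonempty")

  W2 <- W
  W2[6, 7] <- W2[7, 6] <- 0 # disconnect node 7
  expect_identical(distance_to_rich_club(W2, members = 1, k = 7), Inf)

  # weighted option: strong edges are short
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 2   # length 1/2
  W3[2, 3] <- W3[3, 2] <- 0.5 # length 2
  expect_equal(distance_to_rich_club(W3, members = 1, k = 3, weighted = TRUE),
               2.5)
})
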