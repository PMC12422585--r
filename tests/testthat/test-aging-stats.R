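test_that("age bins follow the coarse and fine schemes", {
  expect_identical(assign_age_bin(c(29, 30, 59.9, 60, 85), "coarse"),
                   c("young", "middle", "middle", "old", "old"))
  expect_identical(assign_age_bin(72, "fine"), "65-75")
  expect_identical(assign_age_bin(83, "fine"), "75-90")
  expect_identical(assign_age_bin(12, "fine"), "10-15")
  expect_identical(assign_age_bin(67, "fine"), "65-75")
  expect_error(assign_age_bin(-1), "nonnegative")
  expect_identical(age_bin_levels(c(72, 12, 33), "fine"),
                   c("10-15", "30-35", "65-75"))
})

test_that("class proportions are exact and order independent", {
  df <- data.frame(
    class = c("asynchronous", "asynchronous", "chimera", "synchronous"),
    grp = c("a", "a", "a", "a"))
  cp <- class_proportions(df)
  expect_equal(cp$prop_async, 0.5)
  expect_equal(cp$prop_chimera, 0.25)
  expect_equal(cp$prop_sync, 0.25)
  expect_equal(cp$prop_async + cp$prop_chimera + cp$prop_sync, 1)

  all_chim <- data.frame(class = rep("chimera", 4))
  expect_equal(class_proportions(all_chim)$prop_chimera, 1)

  set.seed(3)
  big <- data.frame(
    class = sample(c("asynchronous", "chimera", "synchronous"), 60,
                   replace = TRUE),
    bin = sample(c("young", "old"), 60, replace = TRUE))
  batch <- class_proportions(big, by = "bin")
  shuffled <- class_proportions(big[sample(60), ], by = "bin")
  expect_equal(batch[order(batch$bin), ], shuffled[order(shuffled$bin), ],
               ignore_attr = TRUE)
  sums <- batch$prop_async + batch$prop_chimera + batch$prop_sync
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(class_proportions(big[0, ]), "empty")
})

test_that("net change is the signed difference summing to zero", {
  y <- c(prop_async = 0.5, prop_chimera = 0.5, prop_sync = 0)
  o <- c(prop_async = 0.2, prop_chimera = 0.6, prop_sync = 0.2)
  d <- net_change(y, o)
  expect_equal(unname(d), c(-0.3, 0.1, 0.2))
  expect_equal(sum(d), 0)
  expect_equal(unname(net_change(y, y)), c(0, 0, 0))
  expect_error(net_change(data.frame(prop_async = 1:2), o), "one group")
})

test_that("prevalence tiers use a closed 3-5% medium band", {
  # exactly 100 patterns: 6%, 4%, 3%, 5%, 2% and one filler at 80%
  df <- data.frame(pattern = c(rep("A", 6), rep("B", 4), rep("C", 3),
                               rep("D", 5), rep("E", 2), rep("F", 80)))
  tab <- prevalence_table(df)
  tier <- setNames(tab$tier, tab$pattern)
  expect_identical(unname(tier["A"]), "high")    # 6%
  expect_identical(unname(tier["B"]), "medium")  # 4%
  expect_identical(unname(tier["C"]), "medium")  # 3% boundary
  expect_identical(unname(tier["D"]), "medium")  # 5% boundary
  expect_identical(unname(tier["E"]), "low")     # 2%
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_equal(sum(tab$proportion), 1)
  expect_true(all(diff(tab$count) <= 0))
})

test_that("pattern similarity matches the pairwise oracle", {
  same <- matrix(1, 4, 9)
  expect_equal(pattern_similarity(same), 1)
  comp <- rbind(rep(0, 9), rep(1, 9))
  expect_equal(pattern_similarity(comp), 0)
  two <- rbind(c(1, 1, 1, 0, 0, 0, 1, 1, 1),
               c(0, 1, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(pattern_similarity(two), 6 / 9)
  expect_error(pattern_similarity(matrix(1, 1, 9)), "fewer than 2")

  set.seed(12)
  for (rep in 1:15) {
    np <- sample(2:50, 1)
    M <- matrix(rbinom(np * 9, 1, runif(1, 0.2, 0.8)), np, 9)
    expect_equal(pattern_similarity(M), oracle_pattern_similarity(M))
    expect_equal(pattern_similarity(M[sample(np), ]), pattern_similarity(M))
  }
  # accepts bit strings too
  expect_equal(pattern_similarity(c("111", "000", "111")),
               oracle_pattern_similarity(rbind(c(1, 1, 1), c(0, 0, 0),
                                               c(1, 1, 1))))
})

test_that("similarity decomposition averages over the right sets", {
  pats <- expand.grid(region = paste0("r", 1:3),
                      individual_id = paste0("i", 1:3),
                      stringsAsFactors = FALSE)
  set.seed(8)
  pats$pattern <- replicate(9, paste(rbinom(9, 1, 0.5), collapse = ""))
  pats$class <- "chimera"
  ind <- similarity_decomposition(pats, "individual")
  reg <- similarity_decomposition(pats, "region")
  # exhaustive recomputation
  by_region <- split(pats$pattern, pats$region)
  expect_equal(ind, mean(vapply(by_region, function(p) {
    oracle_pattern_similarity(as_matrix_bits(p))
  }, numeric(1))))
  by_ind <- split(pats$pattern, pats$individual_id)
  expect_equal(reg, mean(vapply(by_ind, function(p) {
    oracle_pattern_similarity(as_matrix_bits(p))
  }, numeric(1))))

  # identical patterns across individuals -> individual similarity 1
  pats2 <- pats
  pats2$pattern <- rep(c("111000111", "000111000", "101010101"), 3)
  expect_equal(similarity_decomposition(pats2, "individual"), 1)

  # groups with < 2 patterns are skipped with a warning
  single <- pats[pats$region == "r1" & pats$individual_id == "i1", ]
  expect_warning(out <- similarity_decomposition(single, "region"),
                 "skipped")
  expect_true(is.na(out))
  # chimera-only filter drops non-chimera rows before grouping
  pats3 <- pats
  pats3$class <- "synchronous"
  pats3$class[pats3$region == "r3"] <- "chimera"
  pats3$class[pats3$region == "r2" & pats3$individual_id == "i1"] <- "chimera"
  expect_warning(v <- similarity_decomposition(pats3, "individual",
                                               chimera_only = TRUE), "skipped")
  r3 <- pats3$pattern[pats3$region == "r3"]
  expect_equal(v, oracle_pattern_similarity(as_matrix_bits(r3)))
})

test_that("confidence interval uses the t critical value and covers", {
  expect_equal(confidence_interval(rep(0.4, 5))$half_width, 0)
  ci <- confidence_interval(c(0, 1))
  expect_equal(ci$mean, 0.5)
  expect_equal(ci$half_width, qt(0.975, 1) * sqrt(0.5) / sqrt(2))
  expect_error(confidence_interval(1), "at least 2")

  set.seed(123)
  hits <- vapply(1:2000, function(i) {
    x <- rnorm(30)
    ci <- confidence_interval(x)
    abs(ci$mean) <= ci$half_width
  }, logical(1))
  expect_gte(mean(hits), 0.94)
  expect_lte(mean(hits), 0.96)
})

test_that("strength stratification recovers a planted step function", {
  all_sync <- data.frame(strength = runif(40), class = "synchronous")
  s1 <- strength_class_stratification(all_sync, n_bins = 4)
  expect_true(all(s1$dominant == "synchronous"))
  sums <- s1$prop_async + s1$prop_chimera + s1$prop_sync
  expect_true(all(abs(sums - 1) < 1e-12))

  set.seed(31)
  strength <- runif(300)
  cls <- ifelse(strength < 0.3, "asynchronous",
                ifelse(strength < 0.7, "chimera", "synchronous"))
  step <- strength_class_stratification(
    data.frame(strength = strength, class = cls), n_bins = 10)
  doms <- step$dominant
  # recovered breakpoints within one bin of the planted ones
  expect_identical(doms[1:2], rep("asynchronous", 2))
  expect_identical(doms[5:6], rep("chimera", 2))
  expect_identical(doms[9:10], rep("synchronous", 2))
  # ties break toward chimera
  tie <- data.frame(strength = c(1, 2, 3, 4),
                    class = c("chimera", "synchronous", "chimera",
                              "synchronous"))
  expect_identical(strength_class_stratification(tie, n_bins = 1)$dominant,
                   "chimera")
})
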