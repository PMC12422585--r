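#' Assign an age to an age bin
#'
#' Coarse scheme: `young` (< 30), `middle` (>= 30 and < 60), `old` (>= 60).
#' Fine scheme: 5-year bins, with the oldest bins merged for robustness
#' (65-70 and 70-75 combine into 65-75; 75-80, 80-85 and 85-90 combine into
#' 75-90).
#'
#' @param age Age(s) in years, nonnegative.
#' @param scheme `"coarse"` or `"fine"`.
#' @return Character bin label(s).
#' @export
assign_age_bin <- function(age, scheme = c("coarse", "fine")) {
  scheme <- match.arg(scheme)
  if (any(age < 0)) stop("age must be nonnegative")
  if (scheme == "coarse") {
    ifelse(age < 30, "young", ifelse(age < 60, "middle", "old"))
  } else {
    lo <- floor(age / 5) * 5
    lab <- paste0(lo, "-", lo + 5)
    lab[age >= 65 & age < 75] <- "65-75"
    lab[age >= 75] <- "75-90"
    lab
  }
}

#' Ordered levels of an age-binning scheme over observed ages
#' @param ages Numeric ages.
#' @param scheme `"coarse"` or `"fine"`.
#' @return Character vector of bin labels in age order.
#' @export
age_bin_levels <- function(ages, scheme = c("coarse", "fine")) {
  scheme <- match.arg(scheme)
  if (scheme == "coarse") {
    intersect(c("young", "middle", "old"), assign_age_bin(ages, scheme))
  } else {
    labs <- assign_age_bin(ages, scheme)
    lows <- as.numeric(sub("-.*", "", labs))
    unique(labs[order(lows)])
  }
}

#' Class proportions per group
#'
#' Proportions of the three synchronization classes within each group of a
#' pattern table. Proportions are counts over the group size, so each triple
#' sums to 1 exactly.
#'
#' @param patterns Data frame with a `class` column
#'   (`asynchronous`/`chimera`/`synchronous`).
#' @param by Character vector of grouping columns (empty: one global group).
#' @return Data frame with the grouping columns, `n`, and
#'   `prop_async`, `prop_chimera`, `prop_sync`.
#' @export
class_proportions <- function(patterns, by = character(0)) {
  stopifnot(is.data.frame(patterns), "class" %in% names(patterns))
  if (nrow(patterns) == 0) stop("empty pattern table")
  key <- if (length(by) == 0) rep("all", nrow(patterns)) else {
    interaction(patterns[by], drop = TRUE, sep = "\r")
  }
  groups <- split(seq_len(nrow(patterns)), key)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    cls <- patterns$class[idx]
    n <- length(idx)
    out <- data.frame(
      n = n,
      prop_async = sum(cls == "asynchronous") / n,
      prop_chimera = sum(cls == "chimera") / n,
      prop_sync = sum(cls == "synchronous") / n
    )
    if (length(by) > 0) {
      keyvals <- strsplit(g, "\r", fixed = TRUE)[[1]]
      out <- cbind(setNames(as.data.frame(as.list(keyvals),
                                          stringsAsFactors = FALSE), by), out)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Net change in class proportions between two groups
#'
#' Signed difference (late minus early) of the three class proportions; the
#' differences sum to zero because both triples sum to one.
#'
#' @param props_young,props_old Single-row data frames (or named vectors) with
#'   `prop_async`, `prop_chimera`, `prop_sync`.
#' @return Named numeric vector of signed differences.
#' @export
net_change <- function(props_young, props_old) {
  cols <- c("prop_async", "prop_chimera", "prop_sync")
  pick <- function(p) {
    if (is.data.frame(p)) {
      if (nrow(p) != 1) stop("expected exactly one group, got ", nrow(p))
      unlist(p[1, cols])
    } else {
      if (!all(cols %in% names(p))) stop("missing proportion components")
      p[cols]
    }
  }
  pick(props_old) - pick(props_young)
}

#' Pattern prevalence table with tiers
#'
#' Ranks the distinct synchronization patterns of each group by frequency and
#' assigns prevalence tiers: `low` below 3%, `medium` from 3% to 5%
#' (inclusive on both boundaries) and `high` above 5%.
#'
#' @param patterns Data frame with a `pattern` column (bit strings, see
#'   [pattern_string()]).
#' @param by Character vector of grouping columns.
#' @param low,high Tier boundaries as proportions (defaults 0.03 and 0.05).
#' @return Data frame with grouping columns, `pattern`, `count`, `proportion`,
#'   `rank` and `tier`.
#' @export
prevalence_table <- function(patterns, by = character(0),
                             low = 0.03, high = 0.05) {
  stopifnot(is.data.frame(patterns), "pattern" %in% names(patterns))
  key <- if (length(by) == 0) rep("all", nrow(patterns)) else {
    interaction(patterns[by], drop = TRUE, sep = "\r")
  }
  groups <- split(seq_len(nrow(patterns)), key)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    tab <- sort(table(patterns$pattern[idx]), decreasing = TRUE)
    prop <- as.numeric(tab) / length(idx)
    tier <- ifelse(prop < low, "low", ifelse(prop > high, "high", "medium"))
    out <- data.frame(pattern = names(tab), count = as.integer(tab),
                      proportion = prop, rank = seq_along(tab), tier = tier,
                      stringsAsFactors = FALSE)
    if (length(by) > 0) {
      keyvals <- strsplit(g, "\r", fixed = TRUE)[[1]]
      out <- cbind(setNames(as.data.frame(as.list(keyvals),
                                          stringsAsFactors = FALSE), by),
                   out, row.names = NULL)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

as_pattern_matrix <- function(patterns) {
  if (is.matrix(patterns)) return(patterns)
  if (is.character(patterns)) {
    return(do.call(rbind, lapply(strsplit(patterns, ""), as.integer)))
  }
  if (is.list(patterns)) {
    return(do.call(rbind, lapply(patterns, function(p) {
      if (inherits(p, "synchronization_pattern")) p$labels else as.integer(p)
    })))
  }
  stop("cannot interpret patterns of class ", class(patterns)[1])
}

#' Pattern similarity
#'
#' Mean pairwise agreement between synchronization patterns: over all ordered
#' pairs of distinct patterns, the fraction of cognitive systems with the same
#' group label in both. Equals 1 for identical patterns and 0 for
#' complementary ones.
#'
#' @param patterns Binary matrix (patterns x systems), character vector of bit
#'   strings, or list of patterns/label vectors. At least two patterns.
#' @return Scalar similarity in `[0, 1]`.
#' @export
pattern_similarity <- function(patterns) {
  M <- as_pattern_matrix(patterns)
  np <- nrow(M)
  if (np < 2) stop("pattern similarity undefined for fewer than 2 patterns")
  n1 <- colSums(M)
  n0 <- np - n1
  agree <- sum(n1 * (n1 - 1) + n0 * (n0 - 1))  # over ordered pairs, per system
  agree / (np * (np - 1) * ncol(M))
}

#' Region/individual decomposition of pattern similarity
#'
#' Splits pattern variability into two modes. Individual similarity: for each
#' stimulated region, the similarity of the patterns it evokes across
#' individuals, averaged over regions (high when different individuals respond
#' alike). Region similarity: for each individual, the similarity across the
#' stimulated regions of the system, averaged over individuals (high when a
#' system's regions behave alike). Groups with fewer than two patterns (after
#' optional chimera-only filtering) are skipped with a warning.
#'
#' @param patterns Data frame with columns `pattern`, `region`,
#'   `individual_id` and `class`.
#' @param mode `"individual"` or `"region"`.
#' @param chimera_only Keep only chimera-class patterns before computing.
#' @return Scalar mean similarity, or `NA` if no group was computable.
#' @export
similarity_decomposition <- function(patterns,
                                     mode = c("individual", "region"),
                                     chimera_only = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(patterns),
            all(c("pattern", "region", "individual_id") %in% names(patterns)))
  if (chimera_only) {
    patterns <- patterns[patterns$class == "chimera", , drop = FALSE]
  }
  key <- if (mode == "individual") patterns$region else patterns$individual_id
  groups <- split(patterns$pattern, key)
  vals <- vapply(groups, function(p) {
    if (length(p) < 2) NA_real_ else pattern_similarity(p)
  }, numeric(1))
  skipped <- sum(is.na(vals))
  if (skipped > 0) {
    warning(skipped, " group(s) with < 2 patterns skipped")
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' t-based confidence interval
#'
#' Mean and half-width of the two-sided Student-t confidence interval
#' `mean +/- t * sd / sqrt(n)`.
#'
#' @param samples Numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return List with `mean` and `half_width`.
#' @export
confidence_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 2) stop("confidence interval requires at least 2 samples")
  tcrit <- qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = mean(samples), half_width = tcrit * sd(samples) / sqrt(n))
}

#' Class proportions stratified by stimulated-region strength
#'
#' Bins the stimulated regions' strengths into equal-count bins (deciles by
#' default; ties in the strength distribution can merge neighboring bins) and
#' reports per-bin class proportions and the dominant class; ties in the
#' argmax are broken toward chimera, the intermediate state.
#'
#' @param patterns Data frame with `strength` and `class` columns.
#' @param n_bins Number of quantile bins (default 10).
#' @return Data frame with bin boundaries, `n`, the three proportions and
#'   `dominant`.
#' @export
strength_class_stratification <- function(patterns, n_bins = 10) {
  stopifnot(is.data.frame(patterns),
            all(c("strength", "class") %in% names(patterns)))
  breaks <- unique(quantile(patterns$strength,
                            probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) breaks <- range(patterns$strength) + c(-1e-9, 1e-9)
  bin <- cut(patterns$strength, breaks = breaks, include.lowest = TRUE)
  rows <- lapply(split(seq_len(nrow(patterns)), bin), function(idx) {
    if (length(idx) == 0) return(NULL)
    cls <- patterns$class[idx]
    props <- c(asynchronous = mean(cls == "asynchronous"),
               chimera = mean(cls == "chimera"),
               synchronous = mean(cls == "synchronous"))
    top <- names(props)[props == max(props)]
    dominant <- if (length(top) > 1 && "chimera" %in% top) "chimera" else top[1]
    data.frame(lo = min(patterns$strength[idx]),
               hi = max(patterns$strength[idx]),
               n = length(idx),
               prop_async = props[["asynchronous"]],
               prop_chimera = props[["chimera"]],
               prop_sync = props[["synchronous"]],
               dominant = dominant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
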