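# Quantify how the naive estimators deviate from simulation ground truth:
# origin-age inflation, ancestral-state error and sampling sensitivity,
# and the downward rate bias toward the present.

#' Origin-age inflation under incomplete sampling
#'
#' Pairs each sampled tip's naive origin age (parent-node age in the
#' sampled tree) with its true origin age (parent-node age in the fully
#' sampled reconstructed tree) and summarizes the inflation two ways:
#' `mean_percent_older = 100 * mean(naive/true - 1)` (the mean of per-tip
#' ratios) and, because that aggregation is a choice, the alternative
#' `ratio-of-means` version `100 * (mean(naive)/mean(true) - 1)`; plus the
#' squared Pearson correlation of the log ages, `loglog_r2`. Pruning can
#' only promote older nodes to parents, so `mean_percent_older >= 0`
#' always.
#'
#' @param record A [simulate_record()] result with >= 2 sampled tips.
#' @return Object of class `bias_report`: list with `pairs` (data frame
#'   `tip`, `naive_age`, `true_age`), `mean_percent_older`,
#'   `mean_percent_older_ratio_of_means`, `loglog_r2`, `n`.
#' @export
origin_age_bias <- function(record) {
  stopifnot(inherits(record, "sim_record"))
  if (ape::Ntip(record$sampled_tree) < 2L) {
    stop("sampled tree has fewer than 2 tips", call. = FALSE)
  }
  naive <- tip_parent_ages(record$sampled_tree)
  true <- record$true_origin_age[names(naive)]
  if (anyNA(true)) {
    stop("true origin age missing for sampled tip(s): ",
         paste(names(naive)[is.na(true)], collapse = ", "), call. = FALSE)
  }
  if (any(true <= 0)) stop("true origin ages must be positive", call. = FALSE)
  r2 <- if (length(naive) >= 3L && stats::sd(log(naive)) > 0 && stats::sd(log(true)) > 0) {
    stats::cor(log(naive), log(true))^2
  } else if (length(naive) >= 2L && stats::sd(log(true)) == 0 && stats::sd(log(naive)) == 0) {
    1  # degenerate but informative: identical vectors
  } else {
    NA_real_
  }
  structure(
    list(pairs = data.frame(tip = names(naive), naive_age = unname(naive),
                            true_age = unname(true)),
         mean_percent_older = 100 * mean(naive / true - 1),
         mean_percent_older_ratio_of_means = 100 * (mean(naive) / mean(true) - 1),
         loglog_r2 = r2,
         n = length(naive)),
    class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report> n =", x$n, "tip pairs\n")
  cat("  mean percent older (mean of ratios): ",
      format(x$mean_percent_older, digits = 4), "%\n", sep = "")
  cat("  mean percent older (ratio of means): ",
      format(x$mean_percent_older_ratio_of_means, digits = 4), "%\n", sep = "")
  cat("  log-log r2: ", format(x$loglog_r2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' True per-interval lineage-mean trait
#'
#' The ground-truth counterpart of the interval-median series: for each
#' interval midpoint, the mean trait over all complete-tree branches alive
#' at that age, with each branch's state linearly interpolated between its
#' endpoint states (linear interpolation is the Brownian-bridge mean).
#' Intervals whose midpoint is older than the root, including the
#' open-ended final interval, are absent (`NA`).
#'
#' @param record A [simulate_record()] with `node_states` on the complete
#'   tree.
#' @param grid An [interval_grid()].
#' @return Data frame `interval`, `lo`, `hi`, `midpoint`, `n_lineages`,
#'   `true_mean`.
#' @export
true_lineage_means <- function(record, grid) {
  stopifnot(inherits(record, "sim_record"))
  tree <- record$complete_tree
  states <- record$node_states
  ages <- node_ages(tree)
  out <- interval_bounds(grid)
  out$midpoint <- ifelse(is.finite(out$hi), (out$lo + out$hi) / 2, NA_real_)
  root_age <- crown_age(tree)
  parent_age <- ages[tree$edge[, 1L]]
  child_age <- ages[tree$edge[, 2L]]
  # states indexed by ape node number (names follow c(tips, internals))
  st <- unname(states)
  res <- vapply(out$midpoint, function(m) {
    if (is.na(m) || m > root_age) return(c(NA_real_, NA_real_))
    # same crossing convention as lineage_count_at: a node exactly at m has
    # already split, so its daughter branches are the live lineages
    live <- which(parent_age >= m - AGE_TOL & child_age < m - AGE_TOL)
    if (!length(live)) return(c(NA_real_, NA_real_))
    w <- (m - child_age[live]) / (parent_age[live] - child_age[live])
    interp <- st[tree$edge[live, 2L]] * (1 - w) + st[tree$edge[live, 1L]] * w
    c(length(live), mean(interp))
  }, numeric(2L))
  out$n_lineages <- res[1L, ]
  out$true_mean <- res[2L, ]
  out
}

#' Ancestral-state bias and sampling sensitivity
#'
#' Compares the naive interval-median series computed on the sampled tree
#' with the true lineage-mean trait per interval, reporting the absolute
#' error where both are defined. Also reports the worked-example
#' sensitivity statistic: after dropping one random tip from the sampled
#' tree, the per-interval change in the naive medians.
#'
#' @param record A [simulate_record()].
#' @param grid An [interval_grid()].
#' @param drop_seed Seed for the random dropped tip (default 1).
#' @return Object of class `asr_bias_report`: list with `table` (per
#'   interval: naive median, true mean, `abs_error`) and `sensitivity`
#'   (per interval: median before/after the drop, plus the dropped tip).
#' @export
asr_bias <- function(record, grid, drop_seed = 1L) {
  stopifnot(inherits(record, "sim_record"))
  origins <- naive_origin_ages(record$sampled_tree, grid)
  naive <- interval_median_states(origins, record$tip_traits, grid)
  truth <- true_lineage_means(record, grid)
  tab <- naive[, c("interval", "lo", "hi", "count", "median")]
  names(tab)[names(tab) == "median"] <- "naive_median"
  tab$true_mean <- truth$true_mean
  tab$abs_error <- abs(tab$naive_median - tab$true_mean)
  sens <- NULL
  if (ape::Ntip(record$sampled_tree) >= 3L) {
    dropped <- withr::with_seed(drop_seed,
                                sample(record$sampled_tree$tip.label, 1L))
    reduced <- prune_to_tips(record$sampled_tree,
                             setdiff(record$sampled_tree$tip.label, dropped))
    naive2 <- interval_median_states(naive_origin_ages(reduced, grid),
                                     record$tip_traits, grid)
    sens <- data.frame(interval = naive$interval,
                       median_full = naive$median,
                       median_dropped = naive2$median,
                       change = naive2$median - naive$median)
    attr(sens, "dropped_tip") <- dropped
  }
  structure(list(table = tab, sensitivity = sens), class = "asr_bias_report")
}

#' Naive rate-through-time vs the true net rate
#'
#' Pairs the naive `log(n)/t` rate at each grid boundary (computed on the
#' sampled tree) with the constant simulation truth `lambda - mu`.
#'
#' @param record A [simulate_record()] (needs `params`).
#' @param grid An [interval_grid()]; boundaries must be younger than the
#'   stem age.
#' @return Data frame `boundary`, `n`, `t`, `naive_rate`, `true_rate`,
#'   youngest-first.
#' @export
rate_bias_curve <- function(record, grid) {
  stopifnot(inherits(record, "sim_record"))
  if (is.null(record$params)) stop("record carries no simulation parameters", call. = FALSE)
  rs <- naive_rate_through_time(record$sampled_tree, grid)
  data.frame(boundary = rs$boundary, n = rs$n, t = rs$t,
             naive_rate = rs$rate,
             true_rate = record$params$lambda - record$params$mu)
}

#' Sampling fraction as a percentage
#'
#' Exact rational arithmetic (`100 * sampled / total`) with a
#' two-significant-figure presentation alongside full precision.
#'
#' @param sampled Number of sampled species (> 0).
#' @param total Total described species (>= sampled).
#' @return List with `percent` (full precision) and `percent_2sf`.
#' @export
#' @examples
#' sampling_fraction(232, 359208)$percent_2sf    # 0.065
#' sampling_fraction(31389, 359208)$percent_2sf  # 8.7
sampling_fraction <- function(sampled, total) {
  stopifnot(is.numeric(sampled), length(sampled) == 1L,
            is.numeric(total), length(total) == 1L)
  if (sampled <= 0) stop("sampled must be > 0", call. = FALSE)
  if (sampled > total) stop("sampled exceeds total", call. = FALSE)
  pct <- 100 * sampled / total
  list(percent = pct, percent_2sf = signif(pct, 2))
}
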