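# The naive procedures under scrutiny, implemented exactly as described so
# their behaviour under incomplete sampling can be measured: parent-node
# "origin times", interval-median ancestral states, log(n)/t clade rates,
# and the Kendall-Moran speciation rate.

#' Naive per-tip origin ages
#'
#' Reads each species' "origin time" off the age of its parent node in the
#' analyzed tree -- the age at which it split from its apparent sister.
#' On an incompletely sampled tree this age is inflated: removing a tip's
#' true sister promotes an older node to parent.
#'
#' @param tree A `phylo` with at least 2 tips (a single tip has no parent
#'   split).
#' @param grid Optional [interval_grid()]; when given, each tip is also
#'   assigned the interval containing its origin age.
#' @return Data frame with columns `tip`, `origin_age`, and (with a grid)
#'   `interval`.
#' @export
#' @examples
#' tr <- make_four_taxon_fixture()
#' naive_origin_ages(tr$reconstructed_tree)  # all four tips: 2.5
#' naive_origin_ages(tr$sampled_tree)        # A, B: 2.5; C: 7.5
naive_origin_ages <- function(tree, grid = NULL) {
  oa <- tip_parent_ages(tree)
  out <- data.frame(tip = names(oa), origin_age = unname(oa))
  if (!is.null(grid)) out$interval <- interval_index(out$origin_age, grid)
  out
}

#' Interval-median ancestral trait series
#'
#' The naive ancestral-state series: for each time interval, the median
#' trait value over all extant species whose (naive) origin age falls in
#' that interval. Intervals with no contributing species are reported with
#' `median = NA` -- absent, never zero. Even contributor counts use the
#' mean of the two middle values ([stats::median()]).
#'
#' @param origins An origin table from [naive_origin_ages()].
#' @param traits Named numeric vector, tip label -> trait value; must cover
#'   every tip in `origins`.
#' @param grid An [interval_grid()].
#' @return Data frame with columns `interval`, `lo`, `hi`, `count`,
#'   `median`.
#' @export
interval_median_states <- function(origins, traits, grid) {
  stopifnot(is.data.frame(origins), all(c("tip", "origin_age") %in% names(origins)))
  missing_tips <- setdiff(origins$tip, names(traits))
  if (length(missing_tips)) {
    stop("no trait value for tip(s): ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  vals <- traits[origins$tip]
  if (anyNA(vals)) {
    stop("non-numeric trait for tip(s): ",
         paste(origins$tip[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  idx <- interval_index(origins$origin_age, grid)
  out <- interval_bounds(grid)
  out$count <- vapply(out$interval, function(k) sum(idx == k), integer(1L))
  out$median <- vapply(out$interval, function(k) {
    if (any(idx == k)) stats::median(vals[idx == k]) else NA_real_
  }, numeric(1L))
  out
}

#' Clade diversification rate from richness and age
#'
#' The crude richness-based estimator log(n)/t: natural log of the tip
#' count divided by the stem age. With incomplete sampling the apparent
#' `n` is a fraction of the true richness, so the statistic cannot recover
#' the true rate.
#'
#' @param n Tip count (>= 1).
#' @param t Stem age in My (> 0).
#' @return Rate per My.
#' @export
magallon_sanderson_rate <- function(n, t) {
  stopifnot(is.numeric(n), length(n) == 1L, is.numeric(t), length(t) == 1L)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (t <= 0) stop("t must be > 0", call. = FALSE)
  log(n) / t
}

#' Kendall-Moran speciation rate
#'
#' The pure-birth maximum-likelihood speciation rate for a completely
#' sampled, crown-conditioned ultrametric tree: `(n - 2) / S`, the number
#' of birth events since the crown divided by the total branch length
#' (lineage-My of exposure). Valid only without extinction and with
#' complete sampling; applying it to sparsely sampled trees understates
#' the rate.
#'
#' @param tree An ultrametric `phylo` with `n >= 3` tips and positive total
#'   branch length.
#' @return Speciation rate per My.
#' @export
kendall_moran_rate <- function(tree) {
  validate_phylo(tree)
  n <- ape::Ntip(tree)
  if (n < 3L) stop("Kendall-Moran rate needs at least 3 tips", call. = FALSE)
  if (!is_ultrametric(tree)) {
    stop("Kendall-Moran rate requires an ultrametric tree", call. = FALSE)
  }
  S <- total_branch_length(tree)
  if (S <= 0) stop("total branch length is zero", call. = FALSE)
  (n - 2) / S
}

#' Naive diversification rate through time
#'
#' Emulates estimating a rate per time interval by pruning all tips and
#' branches younger than the interval: at each grid boundary `T` the
#' lineages crossing age `T` become the counted units, and the rate is
#' `log(n_T) / (stem_age - T)`. Returned youngest-first. At `T = 0` this
#' reproduces [magallon_sanderson_rate()] of the whole tree.
#'
#' @param tree An ultrametric `phylo`.
#' @param grid An [interval_grid()]; every boundary must be younger than
#'   `stem_age`.
#' @param stem_age Stem age in My (defaults to the tree's recorded
#'   [stem_age()]); must be at least the crown age.
#' @return Data frame with columns `boundary`, `n`, `t`, `rate`,
#'   youngest boundary first.
#' @export
naive_rate_through_time <- function(tree, grid, stem_age = NULL) {
  validate_phylo(tree)
  stopifnot(inherits(grid, "interval_grid"))
  if (is.null(stem_age)) stem_age <- stem_age(tree)
  stopifnot(is.numeric(stem_age), length(stem_age) == 1L)
  if (stem_age < crown_age(tree) - AGE_TOL) {
    stop("stem_age is younger than the crown age", call. = FALSE)
  }
  boundaries <- as.numeric(unclass(grid))
  if (any(boundaries >= stem_age)) {
    stop("grid boundary at or beyond the stem age (", stem_age, ")", call. = FALSE)
  }
  n_T <- vapply(boundaries, function(T) lineage_count_at(tree, T), numeric(1L))
  t_T <- stem_age - boundaries
  data.frame(boundary = boundaries, n = n_T, t = t_T, rate = log(n_T) / t_T)
}
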