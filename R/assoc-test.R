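# Tip diversification rates (the DR / inverse-equal-splits statistic) and
# permutation tests of trait-rate association, with tip-level and
# regime-level (STRAPP-style) nulls.

#' DR tip-rate statistic (inverse equal splits)
#'
#' For tip `i` with root-ward branch lengths `l_1` (terminal), `l_2`, ...,
#' `l_N`, the equal-splits sum is `ES_i = sum_j l_j (1/2)^(j-1)` and the
#' tip rate is `DR_i = 1/ES_i`. A fast nonparametric proxy for the tip
#' speciation rate; used here in place of model-based (e.g. BAMM) rate
#' estimates.
#'
#' @param tree An ultrametric `phylo` with >= 2 tips.
#' @return Data frame with columns `tip`, `rate`, `method` (`"DR"`).
#' @export
#' @examples
#' fx <- make_four_taxon_fixture()
#' dr_statistic(fx$reconstructed_tree)  # tip A: ES = 2.5 + 5/2 = 5, DR = 0.2
dr_statistic <- function(tree) {
  validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("DR needs at least 2 tips", call. = FALSE)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  blen <- rep(NA_real_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen[tree$edge[, 2L]] <- tree$edge.length
  es <- vapply(seq_len(ntip), function(i) {
    v <- i; w <- 1; s <- 0
    while (!is.na(parent[[v]])) {
      s <- s + blen[[v]] * w
      w <- w / 2
      v <- parent[[v]]
    }
    s
  }, numeric(1L))
  if (any(es <= 0)) {
    stop("zero equal-splits sum for tip(s): ",
         paste(tree$tip.label[es <= 0], collapse = ", "), call. = FALSE)
  }
  data.frame(tip = tree$tip.label, rate = 1 / es, method = "DR")
}

# Normalize rates input (TipRates data frame or named vector) to a named
# numeric vector.
as_rate_vector <- function(rates) {
  if (is.data.frame(rates)) {
    stopifnot(all(c("tip", "rate") %in% names(rates)))
    stats::setNames(rates$rate, rates$tip)
  } else {
    stopifnot(is.numeric(rates), !is.null(names(rates)))
    rates
  }
}

#' Trait-rate correlation statistic
#'
#' Pearson correlation of log rates vs log traits (both must be positive;
#' matches analyses done on log-log axes) or Spearman rank correlation,
#' over the tips shared by both inputs, in deterministic (sorted-label)
#' order.
#'
#' @param rates Tip rates: a [dr_statistic()] data frame or named vector.
#' @param traits Named numeric vector of tip traits.
#' @param kind `"pearson_log"` (default) or `"spearman"`.
#' @return The correlation `r` in `[-1, 1]`.
#' @export
correlation_stat <- function(rates, traits, kind = c("pearson_log", "spearman")) {
  kind <- match.arg(kind)
  r <- as_rate_vector(rates)
  shared <- sort(intersect(names(r), names(traits)))
  if (length(shared) < 3L) stop("fewer than 3 shared tips", call. = FALSE)
  x <- r[shared]; y <- traits[shared]
  xy <- transform_xy(x, y, kind, shared)
  if (stats::sd(xy$x) == 0 || stats::sd(xy$y) == 0) {
    stop("zero variance in rates or traits: correlation undefined", call. = FALSE)
  }
  stats::cor(xy$x, xy$y)
}

transform_xy <- function(x, y, kind, shared) {
  if (kind == "pearson_log") {
    bad <- shared[x <= 0 | y <= 0]
    if (length(bad)) {
      stop("nonpositive rate or trait under log mode for tip(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    list(x = log(x), y = log(y))
  } else {
    list(x = rank(x), y = rank(y))
  }
}

#' Permutation test of trait-rate association
#'
#' Two-tailed (by default) permutation test of the [correlation_stat()]
#' between tip rates and traits. `tip_shuffle` permutes trait values
#' across tips -- simple but anticonservative when rates and traits share
#' phylogenetic signal. `regime_shuffle` is the STRAPP-style null: rates
#' are permuted at the level of rate regimes, and tips inherit their
#' regime's permuted rate; it requires a regime map. The p-value uses the
#' add-one rule `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + B)`, ties counted
#' as extreme, so `p >= 1/(B+1)` always.
#'
#' @param rates Tip rates ([dr_statistic()] data frame or named vector).
#'   Under `regime_shuffle`, per-regime rates are taken from
#'   `regimes$rate`.
#' @param traits Named numeric vector of tip traits.
#' @param scheme `"tip_shuffle"` or `"regime_shuffle"`.
#' @param B Number of permutations (>= 99).
#' @param seed Integer seed; required.
#' @param kind Correlation kind, see [correlation_stat()].
#' @param regimes For `regime_shuffle`: data frame with columns `tip`,
#'   `regime`, `rate` (one rate per regime; every tip mapped, every regime
#'   nonempty).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return Object of class `assoc_result`: list with `kind`, `scheme`,
#'   `r_obs`, `p`, `B`, `alternative`, `seed`.
#' @export
permutation_test <- function(rates, traits, scheme = c("tip_shuffle", "regime_shuffle"),
                             B = 999L, seed, kind = c("pearson_log", "spearman"),
                             regimes = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  scheme <- match.arg(scheme)
  kind <- match.arg(kind)
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(B), length(B) == 1L, B >= 99,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  B <- as.integer(B)

  if (scheme == "regime_shuffle") {
    if (is.null(regimes)) stop("regime_shuffle requires a 'regimes' map", call. = FALSE)
    stopifnot(is.data.frame(regimes), all(c("tip", "regime", "rate") %in% names(regimes)))
    regime_rate <- unique(regimes[, c("regime", "rate")])
    if (anyDuplicated(regime_rate$regime)) {
      stop("inconsistent rates within a regime", call. = FALSE)
    }
    unmapped <- setdiff(names(traits), regimes$tip)
    if (length(unmapped)) {
      stop("tip(s) missing from regime map: ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    r <- stats::setNames(regimes$rate, regimes$tip)
  } else {
    r <- as_rate_vector(rates)
  }

  shared <- sort(intersect(names(r), names(traits)))
  if (length(shared) < 3L) stop("fewer than 3 shared tips", call. = FALSE)
  xy <- transform_xy(r[shared], traits[shared], kind, shared)
  if (stats::sd(xy$x) == 0 || stats::sd(xy$y) == 0) {
    stop("zero variance in rates or traits: correlation undefined", call. = FALSE)
  }
  r_obs <- stats::cor(xy$x, xy$y)

  r_perm <- withr::with_seed(seed, {
    if (scheme == "tip_shuffle") {
      perm_cor_tip(xy$x, xy$y, B)
    } else {
      perm_cor_regime(regimes, regime_rate, traits, shared, kind, B)
    }
  })
  tol <- 1e-12
  n_extreme <- switch(alternative,
    two.sided = sum(abs(r_perm) >= abs(r_obs) - tol),
    greater = sum(r_perm >= r_obs - tol),
    less = sum(r_perm <= r_obs + tol))
  structure(
    list(kind = kind, scheme = scheme, r_obs = r_obs,
         p = (1 + n_extreme) / (1 + B), B = B,
         alternative = alternative, seed = as.integer(seed)),
    class = "assoc_result")
}

# Vectorized permutation correlations: shuffle y across tips.
perm_cor_tip <- function(x, y, B) {
  n <- length(x)
  xs <- (x - mean(x)) / stats::sd(x)
  Y <- matrix(y[sample_perms(n, B)], nrow = n)
  Ys <- scale(Y)
  as.numeric(crossprod(xs, Ys)) / (n - 1)
}

sample_perms <- function(n, B) {
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

# Regime-level null: permute the regime -> rate assignment; tips inherit
# their regime's permuted rate.
perm_cor_regime <- function(regimes, regime_rate, traits, shared, kind, B) {
  regime_of <- stats::setNames(regimes$regime, regimes$tip)[shared]
  y <- traits[shared]
  vapply(seq_len(B), function(b) {
    perm_rates <- stats::setNames(sample(regime_rate$rate), regime_rate$regime)
    x <- perm_rates[as.character(regime_of)]
    xy <- transform_xy(x, y, kind, shared)
    stats::cor(xy$x, xy$y)
  }, numeric(1L))
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> ", x$kind, ", ", x$scheme, " null\n", sep = "")
  cat("  r =", format(x$r_obs, digits = 4),
      " p =", format(x$p, digits = 4),
      " (", x$alternative, ", B =", x$B, ")\n")
  invisible(x)
}

#' Type-I error / power simulation for the permutation test
#'
#' For each effect size `beta`, repeatedly: simulate a birth-death tree,
#' reconstruct and subsample it, compute DR tip rates, draw traits with
#' `log(trait) = beta * log(DR) + Normal(0, noise_sd^2)` (so `beta = 0` is
#' an exchangeable null of i.i.d. log-normal traits), run the tip-shuffle
#' permutation test, and tabulate rejections at level `alpha`.
#'
#' @param lambda,mu,t_max Birth-death simulation settings.
#' @param f Uniform sampling fraction.
#' @param beta Vector of effect sizes (0 = null).
#' @param noise_sd Residual sd of log traits.
#' @param reps Replicates per condition (0 gives an empty table).
#' @param B Permutations per test.
#' @param alpha Rejection level.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return Data frame with one row per condition: `beta`, `reps`,
#'   `rejections`, `rate`, plus a `p_values` list-column of the raw
#'   p-values.
#' @export
type1_power_sim <- function(lambda = 0.1, mu = 0, t_max = 40, f = 1,
                            beta = 0, noise_sd = 1, reps = 100L, B = 999L,
                            alpha = 0.05, seed) {
  stopifnot(is.numeric(reps), length(reps) == 1L, reps >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  reps <- as.integer(reps)
  if (reps == 0L) {
    return(data.frame(beta = numeric(0), reps = integer(0),
                      rejections = integer(0), rate = numeric(0)))
  }
  sub_seeds <- withr::with_seed(seed, {
    matrix(sample.int(.Machine$integer.max, 3L * reps * length(beta)),
           ncol = 3L)
  })
  out <- data.frame(beta = beta, reps = reps, rejections = NA_integer_,
                    rate = NA_real_)
  out$p_values <- vector("list", length(beta))
  row <- 0L
  for (bi in seq_along(beta)) {
    p_vals <- numeric(reps)
    for (rep in seq_len(reps)) {
      row <- row + 1L
      s <- sub_seeds[row, ]
      repeat {
        tr <- simulate_birth_death(sim_params(lambda, mu, t_max = t_max, seed = s[[1L]]))
        if (!is_extinct(tr) && length(attr(tr, "extant_tips")) >= max(3L, ceiling(3 / f))) break
        s[[1L]] <- (s[[1L]] + 1L) %% .Machine$integer.max
      }
      rec_tree <- reconstruct_extant(tr)
      samp <- apply_sampling(rec_tree, sampling_scheme("uniform", f = f, seed = s[[2L]]))
      dr <- dr_statistic(samp$tree)
      n <- nrow(dr)
      log_tr <- withr::with_seed(s[[3L]], {
        beta[[bi]] * log(dr$rate) + stats::rnorm(n, 0, noise_sd)
      })
      traits <- stats::setNames(exp(log_tr), dr$tip)
      p_vals[[rep]] <- permutation_test(dr, traits, "tip_shuffle", B = B,
                                        seed = (s[[3L]] + 1) %% .Machine$integer.max)$p
    }
    out$rejections[[bi]] <- sum(p_vals <= alpha)
    out$rate[[bi]] <- mean(p_vals <= alpha)
    out$p_values[[bi]] <- p_vals
  }
  out
}
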