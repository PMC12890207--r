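# Birth-death simulation with ground truth: complete trees that retain
# extinct lineages, reconstructed (extant-only) trees, incomplete-sampling
# schemes, and Brownian trait evolution. Every downstream estimator is
# tested against the truth these generators record.

#' Birth-death simulation parameters
#'
#' @param lambda Speciation rate per lineage per My (> 0).
#' @param mu Extinction rate per lineage per My (>= 0).
#' @param t_max Simulation duration in My (crown age of the complete tree).
#'   Exactly one of `t_max` / `n_target` must be given.
#' @param n_target Stop when the extant lineage count first reaches this
#'   value (>= 2). Requires `mu < lambda`. First-passage stopping is simple
#'   but biases the tree-age distribution relative to generalized sampling;
#'   fixed-duration (`t_max`) simulation is the default mode for all
#'   calibration work in this package.
#' @param seed Integer seed; required, all draws are local to it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(lambda, mu = 0, t_max = NULL, n_target = NULL, seed) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(mu), length(mu) == 1L, mu >= 0)
  if (is.null(t_max) == is.null(n_target)) {
    stop("exactly one of 't_max' and 'n_target' must be set", call. = FALSE)
  }
  if (!is.null(t_max)) stopifnot(is.numeric(t_max), length(t_max) == 1L, t_max > 0)
  if (!is.null(n_target)) {
    stopifnot(is.numeric(n_target), length(n_target) == 1L, n_target >= 2)
    if (mu >= lambda) {
      stop("n_target mode requires mu < lambda (otherwise the process is ",
           "not guaranteed to reach the target)", call. = FALSE)
    }
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(lambda = lambda, mu = mu, t_max = t_max,
                 n_target = n_target, seed = as.integer(seed)),
            class = "sim_params")
}

#' Incomplete-sampling scheme
#'
#' @param kind `"uniform"` (keep a uniform random fraction `f` of tips,
#'   without replacement, exactly `max(1, round(f * n))` tips) or
#'   `"one_per_clade"` (keep one uniformly chosen tip from each maximal
#'   clade whose crown age is younger than `cutoff_age`, mimicking
#'   one-species-per-genus sampling of genus-level trees).
#' @param f Sampling fraction in (0, 1] (`uniform` only).
#' @param cutoff_age Clade-age cutoff in My (`one_per_clade` only).
#' @param seed Integer seed; required.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(kind = c("uniform", "one_per_clade"),
                            f = NULL, cutoff_age = NULL, seed) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    stopifnot(is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  } else {
    stopifnot(is.numeric(cutoff_age), length(cutoff_age) == 1L, cutoff_age > 0)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(kind = kind, f = f, cutoff_age = cutoff_age,
                 seed = as.integer(seed)),
            class = "sampling_scheme")
}

#' Brownian-motion trait model
#'
#' Anagenic change accumulates along branches as Brownian motion with rate
#' `sigma2`; optionally a cladogenetic jump of sd `cladogenetic_jump_sd` is
#' added to each daughter lineage at its origin (once per branch), so
#' `cladogenetic_jump_sd = 0` is pure anagenic change and `sigma2` near 0
#' with a positive jump sd approximates purely cladogenetic change.
#'
#' @param sigma2 BM rate, trait^2 per My (> 0).
#' @param root_state Trait value at the root.
#' @param cladogenetic_jump_sd Jump standard deviation (>= 0).
#' @param log_trait If `TRUE` the simulated states live on log scale and tip
#'   traits are exponentiated, producing positive Vcmax-like values.
#' @param seed Integer seed; required.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(sigma2, root_state = 0, cladogenetic_jump_sd = 0,
                        log_trait = FALSE, seed) {
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0,
            is.numeric(root_state), length(root_state) == 1L,
            is.numeric(cladogenetic_jump_sd), cladogenetic_jump_sd >= 0,
            is.logical(log_trait), length(log_trait) == 1L,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(sigma2 = sigma2, root_state = root_state,
                 cladogenetic_jump_sd = cladogenetic_jump_sd,
                 log_trait = log_trait, seed = as.integer(seed)),
            class = "trait_model")
}

#' Simulate a complete birth-death tree
#'
#' Exact Gillespie simulation from a crown pair (two lineages at the crown).
#' Extinct lineages are retained as tips at their death times, so the
#' returned tree is generally non-ultrametric; [reconstruct_extant()]
#' recovers the ultrametric extant-only tree. A stem age (crown age plus an
#' Exponential(lambda) stem branch) is drawn and stored in the `stem_age`
#' attribute. Deterministic given `params$seed`.
#'
#' In `t_max` mode, whole-clade extinction is a legitimate outcome and is
#' returned as an object of class `extinct_clade` (test with
#' [is_extinct()]), never raised as an error. In `n_target` mode the rare
#' pre-target extinction of the clade triggers a fresh attempt from the
#' same RNG stream (still deterministic given the seed).
#'
#' @param params A [sim_params()] object.
#' @return A `phylo` object with tips labelled `t1, t2, ...` in order of
#'   lineage origin, or an `extinct_clade` object.
#' @export
simulate_birth_death <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    if (is.null(params$n_target)) {
      bd_gillespie(params$lambda, params$mu, t_max = params$t_max)
    } else {
      for (attempt in seq_len(1000L)) {
        res <- bd_gillespie(params$lambda, params$mu, n_target = params$n_target)
        if (!is_extinct(res)) return(res)
      }
      stop("clade went extinct before reaching n_target in 1000 attempts",
           call. = FALSE)
    }
  })
}

#' @rdname simulate_birth_death
#' @param x Object to test.
#' @export
is_extinct <- function(x) inherits(x, "extinct_clade")

# Core Gillespie loop; runs inside an already-seeded RNG context.
bd_gillespie <- function(lambda, mu, t_max = NULL, n_target = NULL) {
  # per-lineage records; lineages 1 and 2 are the crown pair
  par <- c(0L, 0L); t0 <- c(0, 0); t1 <- c(NA_real_, NA_real_)
  fate <- c(NA_character_, NA_character_)
  alive <- c(1L, 2L)
  t <- 0
  repeat {
    n_alive <- length(alive)
    if (n_alive == 0L) {
      return(structure(list(extinction_time = t), class = "extinct_clade"))
    }
    if (!is.null(n_target) && n_alive >= n_target) break
    dt <- stats::rexp(1L, n_alive * (lambda + mu))
    if (!is.null(t_max) && t + dt > t_max) { t <- t_max; break }
    t <- t + dt
    i <- alive[[sample.int(n_alive, 1L)]]
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      t1[[i]] <- t; fate[[i]] <- "internal"
      k <- length(par)
      par <- c(par, i, i); t0 <- c(t0, t, t); t1 <- c(t1, NA, NA)
      fate <- c(fate, NA, NA)
      alive <- c(setdiff(alive, i), k + 1L, k + 2L)
    } else {
      t1[[i]] <- t; fate[[i]] <- "extinct"
      alive <- setdiff(alive, i)
    }
  }
  t1[alive] <- t
  fate[alive] <- "extant"
  tree <- bd_to_phylo(par, t0, t1, fate, height = t)
  attr(tree, "stem_age") <- t + stats::rexp(1L, lambda)
  tree
}

# Convert lineage records into an ape phylo. Terminal lineages (extant or
# extinct) become tips; speciating lineages and the crown vertex become
# internal nodes, with the crown vertex as the root (Ntip + 1).
bd_to_phylo <- function(par, t0, t1, fate, height) {
  terminal <- fate %in% c("extant", "extinct")
  tip_ids <- which(terminal)
  int_ids <- which(!terminal)   # lineages ending in a speciation
  ntip <- length(tip_ids)
  # vertex number for the end-vertex of each lineage
  vnum <- integer(length(par))
  vnum[tip_ids] <- seq_len(ntip)
  vnum[int_ids] <- ntip + 1L + seq_along(int_ids)
  root <- ntip + 1L
  parent_vertex <- ifelse(par == 0L, root, vnum[pmax(par, 1L)])
  edge <- cbind(parent_vertex, vnum)
  tree <- structure(
    list(edge = edge, edge.length = t1 - t0,
         tip.label = paste0("t", tip_ids),
         Nnode = length(int_ids) + 1L),
    class = "phylo")
  tree <- stats::reorder(tree, "cladewise")
  attr(tree, "extant_tips") <- paste0("t", which(fate == "extant"))
  tree
}

#' Prune extinct lineages from a complete tree
#'
#' Returns the reconstructed (extant-only) tree: extinct tips removed,
#' degree-2 nodes suppressed, ages of retained nodes unchanged. The result
#' is ultrametric.
#'
#' @param complete A `phylo` from [simulate_birth_death()] (or any tree in
#'   which extant tips sit at age 0 within tolerance).
#' @return An ultrametric `phylo`.
#' @export
reconstruct_extant <- function(complete) {
  validate_phylo(complete)
  ages <- node_ages(complete)
  tips <- seq_len(ape::Ntip(complete))
  extant <- complete$tip.label[ages[tips] <= AGE_TOL * max(1, crown_age(complete))]
  if (length(extant) == 0L) stop("tree has no extant (age-0) tips", call. = FALSE)
  prune_to_tips(complete, extant)
}

#' Apply an incomplete-sampling scheme
#'
#' Subsamples the tips of an ultrametric tree and prunes the tree to them.
#' Node ages of retained nodes are unchanged (sampling only removes tips),
#' which is precisely why apparent origin times inflate. Deterministic
#' given `scheme$seed`.
#'
#' @param tree An ultrametric `phylo`.
#' @param scheme A [sampling_scheme()].
#' @return List with `tree` (pruned `phylo`) and `kept` (character vector
#'   of retained tip labels).
#' @export
apply_sampling <- function(tree, scheme) {
  validate_phylo(tree)
  stopifnot(inherits(scheme, "sampling_scheme"))
  withr::with_seed(scheme$seed, {
    if (scheme$kind == "uniform") {
      n <- ape::Ntip(tree)
      m <- round(scheme$f * n)
      if (m < 1L) {
        warning("f * n rounds to 0; keeping 1 tip", call. = FALSE)
        m <- 1L
      }
      kept <- sample(tree$tip.label, m)
    } else {
      kept <- one_per_clade_sample(tree, scheme$cutoff_age)
    }
  })
  kept <- sort(kept)
  list(tree = prune_to_tips(tree, kept), kept = kept)
}

# One tip from each maximal clade whose crown age < cutoff. A node is
# maximal when its own (crown) age is below the cutoff but its parent's is
# not; a lone tip subtending an old branch forms its own clade.
one_per_clade_sample <- function(tree, cutoff_age) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  maximal <- which(vapply(seq_len(nn), function(v) {
    ages[[v]] < cutoff_age &&
      (is.na(parent[[v]]) || ages[[parent[[v]]]] >= cutoff_age)
  }, logical(1L)))
  vapply(maximal, function(v) {
    tips <- clade_tip_labels(tree, v)
    if (length(tips) == 1L) tips else sample(tips, 1L)
  }, character(1L))
}

# Tip labels descending from node v (v itself if a tip).
clade_tip_labels <- function(tree, v) {
  ntip <- ape::Ntip(tree)
  if (v <= ntip) return(tree$tip.label[[v]])
  stack <- v
  tips <- integer(0)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    tips <- c(tips, children[children <= ntip])
    stack <- c(stack, children[children > ntip])
  }
  tree$tip.label[tips]
}

#' Simulate trait evolution on a tree
#'
#' Brownian motion from the root: each child state is its parent's state
#' plus Normal(0, `sigma2` x branch length), plus (when
#' `cladogenetic_jump_sd > 0`) an independent Normal(0, jump_sd^2) jump at
#' the branching event that created the lineage. Deterministic given
#' `model$seed`.
#'
#' @param tree A `phylo`.
#' @param model A [trait_model()].
#' @return Named numeric vector of states for all `Ntip + Nnode` nodes
#'   (tips named by label, internal nodes `nd<number>`), with attribute
#'   `log_trait` copied from the model.
#' @export
simulate_traits <- function(tree, model) {
  validate_phylo(tree)
  stopifnot(inherits(model, "trait_model"))
  tr <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tr)
  nn <- ntip + tr$Nnode
  states <- numeric(nn)
  states[[ntip + 1L]] <- model$root_state
  nedge <- nrow(tr$edge)
  withr::with_seed(model$seed, {
    inc <- stats::rnorm(nedge, 0, sqrt(model$sigma2 * tr$edge.length))
    if (model$cladogenetic_jump_sd > 0) {
      inc <- inc + stats::rnorm(nedge, 0, model$cladogenetic_jump_sd)
    }
  })
  for (e in seq_len(nedge)) {
    states[[tr$edge[e, 2L]]] <- states[[tr$edge[e, 1L]]] + inc[[e]]
  }
  names(states) <- c(tr$tip.label, paste0("nd", (ntip + 1L):nn))
  attr(states, "log_trait") <- model$log_trait
  states
}

# Age of each tip's parent node, named by tip label.
tip_parent_ages <- function(tree) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("tree has fewer than 2 tips: no parent splits", call. = FALSE)
  parent <- integer(ntip)
  term <- tree$edge[, 2L] <= ntip
  parent[tree$edge[term, 2L]] <- tree$edge[term, 1L]
  stats::setNames(ages[parent], tree$tip.label)
}

#' Run a full simulation and package the ground truth
#'
#' Simulates a complete birth-death tree, reconstructs the extant tree,
#' applies the sampling scheme, simulates traits on the complete tree, and
#' records the true per-tip origin ages (each extant tip's parent-node age
#' in the fully sampled reconstructed tree) -- everything the bias analyses
#' need.
#'
#' @param params A [sim_params()].
#' @param scheme A [sampling_scheme()].
#' @param model A [trait_model()].
#' @return An object of class `sim_record`: list with `complete_tree`,
#'   `reconstructed_tree`, `sampled_tree`, `kept`, `true_origin_age`,
#'   `node_states`, `tip_traits`, `params`, `scheme`, `trait_model`.
#' @export
simulate_record <- function(params, scheme, model) {
  complete <- simulate_birth_death(params)
  if (is_extinct(complete)) {
    stop("clade went extinct before the end of the simulation; ",
         "choose another seed or lower mu", call. = FALSE)
  }
  reconstructed <- reconstruct_extant(complete)
  if (ape::Ntip(reconstructed) < 2L) {
    stop("fewer than 2 extant tips survived; choose another seed", call. = FALSE)
  }
  sampled <- apply_sampling(reconstructed, scheme)
  node_states <- simulate_traits(complete, model)
  tip_states <- node_states[reconstructed$tip.label]
  tip_traits <- if (model$log_trait) exp(tip_states) else tip_states
  attr(tip_traits, "log_trait") <- NULL
  structure(
    list(complete_tree = complete,
         reconstructed_tree = reconstructed,
         sampled_tree = sampled$tree,
         kept = sampled$kept,
         true_origin_age = tip_parent_ages(reconstructed),
         node_states = node_states,
         tip_traits = tip_traits,
         params = params, scheme = scheme, trait_model = model),
    class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat("<sim_record>\n")
  cat("  complete tree:     ", ape::Ntip(x$complete_tree), "tips\n")
  cat("  reconstructed tree:", ape::Ntip(x$reconstructed_tree), "extant tips\n")
  cat("  sampled tree:      ", ape::Ntip(x$sampled_tree), "sampled tips\n")
  invisible(x)
}

#' Four-taxon worked example
#'
#' The didactic four-species tree `((A:2.5,B:2.5):5.0,(C:2.5,D:2.5):5.0)`:
#' two cherries that split 2.5 My ago, their common ancestor 7.5 My ago,
#' stem age 10 My. Packaged as a `sim_record` with placeholder traits
#' A=1, B=2, C=3, D=4 (internal-node states set to child midpoints as a
#' deterministic placeholder) and the biased sampling variant with species
#' D removed as `sampled_tree`; the complete sampling variant is the
#' `reconstructed_tree` itself.
#'
#' Dropping D moves C's apparent origin from 2.5 to 7.5 My -- from the
#' 0-5 My interval to the 5-10 My interval -- while A and B are unchanged:
#' the sensitivity of interval-median ancestral states to a single
#' unsampled species.
#'
#' @return A `sim_record` (with `params`, `scheme`, `trait_model` set to
#'   `NULL`: the fixture is constructed, not simulated).
#' @export
make_four_taxon_fixture <- function() {
  tree <- parse_newick("((A:2.5,B:2.5):5.0,(C:2.5,D:2.5):5.0);", stem_age = 10)
  traits <- c(A = 1, B = 2, C = 3, D = 4)
  # ape numbering for this newick: tips A,B,C,D = 1..4; root = 5; AB = 6; CD = 7
  node_states <- c(traits, nd5 = 2.5, nd6 = 1.5, nd7 = 3.5)
  structure(
    list(complete_tree = tree,
         reconstructed_tree = tree,
         sampled_tree = prune_to_tips(tree, c("A", "B", "C")),
         kept = c("A", "B", "C"),
         true_origin_age = c(A = 2.5, B = 2.5, C = 2.5, D = 2.5),
         node_states = node_states,
         tip_traits = traits,
         params = NULL, scheme = NULL, trait_model = NULL),
    class = "sim_record")
}

#' Write a simulation record to disk
#'
#' Emits Newick files for the complete, reconstructed and sampled trees,
#' CSVs for tip traits (`tip,trait`) and node states
#' (`node_id,age,state`), and a `manifest.txt` of key=value pairs
#' recording parameters and seeds.
#'
#' @param record A [simulate_record()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_record <- function(record, dir) {
  stopifnot(inherits(record, "sim_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(name, writer) {
    p <- file.path(dir, name); writer(p); paths <<- c(paths, p)
  }
  wr("complete.nwk", function(p) writeLines(write_newick(record$complete_tree), p))
  wr("reconstructed.nwk", function(p) writeLines(write_newick(record$reconstructed_tree), p))
  wr("sampled.nwk", function(p) writeLines(write_newick(record$sampled_tree), p))
  wr("tip_traits.csv", function(p) {
    utils::write.csv(data.frame(tip = names(record$tip_traits),
                                trait = unname(record$tip_traits)),
                     p, row.names = FALSE, quote = FALSE)
  })
  wr("node_states.csv", function(p) {
    ages <- node_ages(record$complete_tree)
    utils::write.csv(data.frame(node_id = names(record$node_states),
                                age = unname(ages),
                                state = unname(record$node_states)),
                     p, row.names = FALSE, quote = FALSE)
  })
  wr("manifest.txt", function(p) {
    kv <- c(
      divbias_version = as.character(utils::packageVersion("divbias")),
      lambda = record$params$lambda %||% "", mu = record$params$mu %||% "",
      t_max = record$params$t_max %||% "", n_target = record$params$n_target %||% "",
      sim_seed = record$params$seed %||% "",
      sampling_kind = record$scheme$kind %||% "", f = record$scheme$f %||% "",
      cutoff_age = record$scheme$cutoff_age %||% "",
      sampling_seed = record$scheme$seed %||% "",
      sigma2 = record$trait_model$sigma2 %||% "",
      root_state = record$trait_model$root_state %||% "",
      cladogenetic_jump_sd = record$trait_model$cladogenetic_jump_sd %||% "",
      log_trait = record$trait_model$log_trait %||% "",
      trait_seed = record$trait_model$seed %||% "",
      log_base = "natural", kendall_moran = "(n-2)/S",
      interval_rule = "half-open [lo, hi) in age"
    )
    writeLines(paste0(names(kv), "=", unlist(kv)), p)
  })
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
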