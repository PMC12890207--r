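test_that("parameter constructors enforce their invariants", {
  expect_error(sim_params(0.1, 0, seed = 1), "exactly one")
  expect_error(sim_params(0.1, 0, t_max = 10, n_target = 10, seed = 1), "exactly one")
  expect_error(sim_params(0.1, 0.2, n_target = 10, seed = 1), "mu < lambda")
  expect_error(sampling_scheme("uniform", seed = 1))
  expect_error(sampling_scheme("one_per_clade", seed = 1))
  expect_error(trait_model(0, seed = 1))
})

test_that("birth-death simulation is deterministic given its seed", {
  p <- sim_params(0.1, 0, t_max = 10, seed = 1)
  expect_identical(write_newick(simulate_birth_death(p)),
                   write_newick(simulate_birth_death(p)))
  p2 <- sim_params(0.1, 0.04, t_max = 30, seed = 42)
  t1 <- simulate_birth_death(p2)
  t2 <- simulate_birth_death(p2)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(attr(t1, "stem_age"), attr(t2, "stem_age"))
  expect_gt(attr(t1, "stem_age"), crown_age(t1))
})

test_that("extant lineage counts match the Yule expectation from a crown pair", {
  # E[N(t)] = 2 exp(lambda t); moderate scale here, full scale in acceptance
  ns <- vapply(1:500, function(s) {
    length(attr(simulate_birth_death(sim_params(0.2, 0, t_max = 10, seed = s)),
                "extant_tips"))
  }, numeric(1))
  expected <- 2 * exp(0.2 * 10)
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected), 3 * se)
})

test_that("dominant extinction yields the explicit extinct outcome", {
  ext <- vapply(1:200, function(s) {
    is_extinct(simulate_birth_death(sim_params(0.1, 0.5, t_max = 50, seed = s)))
  }, logical(1))
  expect_gte(mean(ext), 0.95)
})

test_that("reconstruction prunes extinct lineages and preserves ages", {
  # pure birth: nothing to prune
  tr <- simulate_birth_death(sim_params(0.15, 0, t_max = 15, seed = 3))
  expect_tree_equal(reconstruct_extant(tr), tr)

  # hand-built: B dies at age 1 -> (A,C) cherry with summed branch
  mixed <- parse_newick("((A:2,B:1):1,C:3);")
  rec <- reconstruct_extant(mixed)
  expect_setequal(rec$tip.label, c("A", "C"))
  expect_true(is_ultrametric(rec))
  expect_equal(crown_age(rec), 3)

  # all but one extinct -> single-lineage tree
  lone <- reconstruct_extant(parse_newick("((A:1,B:0.5):1,C:0.7);"))
  expect_equal(ape::Ntip(lone), 1L)
  expect_equal(total_branch_length(lone), 2)

  # node ages of survivors unchanged on simulated trees
  bd <- simulate_birth_death(sim_params(0.12, 0.06, t_max = 30, seed = 8))
  rec2 <- reconstruct_extant(bd)
  full_ages <- internal_ages(bd)
  for (a in internal_ages(rec2)) {
    expect_lt(min(abs(full_ages - a)), 1e-9)
  }
})

test_that("uniform sampling keeps round(f*n) tips and replays under its seed", {
  tr <- reconstruct_extant(sim_yule_min_tips(0.12, 40, 100, seed = 5L))
  tr <- prune_to_tips(tr, tr$tip.label[1:100])
  s1 <- apply_sampling(tr, sampling_scheme("uniform", f = 0.5, seed = 9))
  expect_length(s1$kept, 50L)
  s2 <- apply_sampling(tr, sampling_scheme("uniform", f = 0.5, seed = 9))
  expect_identical(s1$kept, s2$kept)

  # f = 1 is the identity
  all_kept <- apply_sampling(tr, sampling_scheme("uniform", f = 1, seed = 1))
  expect_setequal(all_kept$kept, tr$tip.label)
  expect_tree_equal(all_kept$tree, tr)

  # f*n rounding to 0 keeps one tip with a warning
  small <- four_taxon_tree()
  expect_warning(
    s3 <- apply_sampling(small, sampling_scheme("uniform", f = 0.05, seed = 2)),
    "keeping 1 tip")
  expect_length(s3$kept, 1L)

  # sampling never changes a retained node's age
  ages_before <- node_ages(tr)
  sub <- apply_sampling(tr, sampling_scheme("uniform", f = 0.3, seed = 4))
  oa_sub <- naive_origin_ages(sub$tree)
  full_internal <- internal_ages(tr)
  for (a in oa_sub$origin_age) expect_lt(min(abs(full_internal - a)), 1e-9)
})

test_that("one-per-clade sampling keeps one tip per young clade", {
  s <- apply_sampling(four_taxon_tree(),
                      sampling_scheme("one_per_clade", cutoff_age = 5, seed = 1))
  expect_length(s$kept, 2L)
  expect_length(intersect(s$kept, c("A", "B")), 1L)
  expect_length(intersect(s$kept, c("C", "D")), 1L)

  # cutoff above the crown age: the whole tree is one clade
  s2 <- apply_sampling(four_taxon_tree(),
                       sampling_scheme("one_per_clade", cutoff_age = 8, seed = 1))
  expect_length(s2$kept, 1L)
})

test_that("trait simulation follows the Brownian variance-covariance structure", {
  fx <- make_four_taxon_fixture()
  tr <- fx$reconstructed_tree
  m <- trait_model(1, 0, seed = 1)
  expect_identical(simulate_traits(tr, m), simulate_traits(tr, m))

  # zero branch lengths: all states collapse to the root state
  flat <- tr
  flat$edge.length <- rep(0, nrow(flat$edge))
  st <- simulate_traits(flat, trait_model(5, root_state = 3, seed = 2))
  expect_equal(unname(st), rep(3, 7), ignore_attr = TRUE)

  # tip variance = sigma2 * depth; tip covariance = sigma2 * shared depth
  reps <- 2000
  ab <- vapply(1:reps, function(s) {
    st <- simulate_traits(tr, trait_model(1, 0, seed = s))
    c(st[["A"]], st[["B"]], st[["C"]])
  }, numeric(3))
  expect_lt(abs(var(ab[1, ]) - 7.5), 0.8)       # sd of var-hat ~ 0.24
  expect_lt(abs(cov(ab[1, ], ab[2, ]) - 5.0), 0.8)
  expect_lt(abs(cov(ab[1, ], ab[3, ]) - 0.0), 0.8)

  # cladogenetic jumps add per-branch variance on top of BM
  jmp <- vapply(1:reps, function(s) {
    simulate_traits(tr, trait_model(1, 0, cladogenetic_jump_sd = 2, seed = s))[["A"]]
  }, numeric(1))
  expect_gt(var(jmp), 7.5 + 2 * 4 - 1.5)  # two branching events on A's path
})

test_that("reconstructed trees show the pull of the present under extinction", {
  slopes <- function(tree) {
    D <- crown_age(tree)
    lc <- function(T) lineage_count_at(tree, T)
    c(young = (log(lc(0)) - log(lc(0.1 * D))) / (0.1 * D),
      old = (log(lc(0.4 * D)) - log(lc(0.5 * D))) / (0.1 * D))
  }
  set.seed(1)
  got <- matrix(NA_real_, 30, 2)
  s <- 0L
  for (i in 1:30) {
    repeat {
      s <- s + 1L
      tr <- simulate_birth_death(sim_params(0.12, 0.06, t_max = 40, seed = s))
      if (!is_extinct(tr) && length(attr(tr, "extant_tips")) >= 20) break
    }
    got[i, ] <- slopes(reconstruct_extant(tr))
  }
  expect_gt(mean(got[, 1]), mean(got[, 2]))
})

test_that("simulation records tie the three trees and the truth together", {
  rec <- simulate_record(
    sim_params(0.1, 0.02, t_max = 40, seed = 13),
    sampling_scheme("uniform", f = 0.5, seed = 14),
    trait_model(1, 0, log_trait = TRUE, seed = 15))
  expect_true(all(rec$sampled_tree$tip.label %in% rec$reconstructed_tree$tip.label))
  expect_true(all(rec$reconstructed_tree$tip.label %in% rec$complete_tree$tip.label))
  expect_setequal(names(rec$tip_traits), rec$reconstructed_tree$tip.label)
  expect_true(all(rec$tip_traits > 0))  # log-BM traits are positive
  expect_setequal(names(rec$true_origin_age), rec$reconstructed_tree$tip.label)
  expect_true(all(rec$true_origin_age > 0))
  # shared internal node ages agree across the three trees
  comp <- internal_ages(rec$complete_tree)
  for (a in internal_ages(rec$sampled_tree)) {
    expect_lt(min(abs(comp - a)), 1e-9)
  }
})

test_that("the four-taxon fixture encodes the worked example", {
  fx <- make_four_taxon_fixture()
  expect_equal(crown_age(fx$reconstructed_tree), 7.5)
  expect_equal(unname(fx$true_origin_age), rep(2.5, 4))
  oa <- naive_origin_ages(fx$sampled_tree)
  expect_equal(oa$origin_age[oa$tip == "C"], 7.5)
})

test_that("records round-trip to plain-text outputs", {
  rec <- simulate_record(
    sim_params(0.1, 0, t_max = 20, seed = 3),
    sampling_scheme("uniform", f = 0.5, seed = 4),
    trait_model(1, 0, seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_record(rec, dir)
  expect_true(all(file.exists(paths)))
  back <- parse_newick(paste(readLines(file.path(dir, "sampled.nwk")), collapse = ""))
  expect_tree_equal(back, rec$sampled_tree)
  traits <- load_traits(file.path(dir, "tip_traits.csv"))
  expect_equal(traits[names(rec$tip_traits)], rec$tip_traits, tolerance = 1e-9)
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^lambda=0.1$", manifest)))
  expect_true(any(grepl("^log_base=natural$", manifest)))
})
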