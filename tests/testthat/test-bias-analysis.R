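# Minimal hand-built record: a sampled tree plus true origin ages.
stub_record <- function(sampled_tree, true_origin_age, complete_tree = NULL,
                        node_states = NULL, tip_traits = NULL, params = NULL) {
  structure(list(sampled_tree = sampled_tree, true_origin_age = true_origin_age,
                 complete_tree = complete_tree, node_states = node_states,
                 tip_traits = tip_traits, params = params),
            class = "sim_record")
}

test_that("complete sampling shows zero inflation and perfect log-log fit", {
  rec <- simulate_record(sim_params(0.1, 0, t_max = 35, seed = 21),
                         sampling_scheme("uniform", f = 1, seed = 22),
                         trait_model(1, 0, seed = 23))
  b <- origin_age_bias(rec)
  expect_equal(b$mean_percent_older, 0)
  expect_equal(b$mean_percent_older_ratio_of_means, 0)
  expect_equal(b$loglog_r2, 1)
  expect_equal(b$n, ape::Ntip(rec$reconstructed_tree))
})

test_that("a constant naive/true ratio gives 100% inflation and r2 = 1", {
  tr <- four_taxon_tree()
  doubled <- tr
  doubled$edge.length <- 2 * tr$edge.length
  # jitter true ages so the log-log correlation is over a non-degenerate cloud
  chain <- parse_newick("(((A:1,B:1):1.5,C:2.5):5,D:7.5);")
  truth <- tip_parent_ages_of(chain)
  rec <- stub_record(scale_tree(chain, 2), truth)
  b <- origin_age_bias(rec)
  expect_equal(b$mean_percent_older, 100)
  expect_equal(b$mean_percent_older_ratio_of_means, 100)
  expect_equal(b$loglog_r2, 1)
})

test_that("uniform subsampling inflates origin ages in every replicate", {
  for (i in 1:20) {
    tr <- reconstruct_extant(sim_yule_min_tips(0.1, 40, 40, seed = 3000L + i * 11L))
    truth <- tip_parent_ages_of(tr)
    samp <- apply_sampling(tr, sampling_scheme("uniform", f = 0.05, seed = i))
    b <- origin_age_bias(stub_record(samp$tree, truth))
    expect_gte(b$mean_percent_older, -1e-9)
  }
})

test_that("log-log r2 degrades as sampling gets sparser", {
  r2 <- matrix(NA_real_, 40, 2)
  for (i in 1:40) {
    tr <- reconstruct_extant(sim_yule_min_tips(0.1, 40, 40, seed = 6000L + i * 11L))
    truth <- tip_parent_ages_of(tr)
    for (j in 1:2) {
      f <- c(0.2, 1)[j]
      samp <- apply_sampling(tr, sampling_scheme("uniform", f = f, seed = i))
      r2[i, j] <- origin_age_bias(stub_record(samp$tree, truth))$loglog_r2
    }
  }
  expect_equal(mean(r2[, 2]), 1)
  expect_lt(mean(r2[, 1]), 1)
})

test_that("true lineage means interpolate states along live branches", {
  # constant states: every defined interval mean is that constant
  fx <- make_four_taxon_fixture()
  fx$node_states[] <- 4.2
  g <- interval_grid(boundaries = c(0, 5, 10))
  tm <- true_lineage_means(fx, g)
  expect_equal(tm$true_mean[1:2], c(4.2, 4.2))
  expect_true(is.na(tm$true_mean[[3]]))  # open-ended interval has no midpoint

  # single branch, state 0 at age 10 down to 10 at age 0: midpoint 5 -> 5
  one <- parse_newick("(A:10);")
  rec <- stub_record(NULL, NULL, complete_tree = one,
                     node_states = c(A = 10, nd2 = 0))
  tm1 <- true_lineage_means(rec, interval_grid(boundaries = c(0, 10)))
  expect_equal(tm1$true_mean[[1]], 5)

  # exactly the two basal lineages are alive in [5, 10)
  tm2 <- true_lineage_means(make_four_taxon_fixture(), g)
  expect_equal(tm2$n_lineages[1:2], c(4, 2))
  expect_equal(tm2$true_mean[[2]], mean(c(
    # interpolation at age 7.5 midpoint between root (7.5) and cherries (2.5)
    2.5, 2.5)))
})

test_that("ancestral-state bias reacts to a single dropped species", {
  fx <- make_four_taxon_fixture()
  g <- interval_grid(boundaries = c(0, 5, 10))
  # with D dropped, the 5-10 My interval median appears as C's trait value
  ab <- asr_bias(fx, g)
  expect_equal(ab$table$naive_median[1:2], c(1.5, 3.0))
  expect_equal(ab$table$count, c(2L, 1L, 0L))

  # complete sampling of a 2-tip tree with equal traits: zero error
  cherry <- parse_newick("(A:4,B:4);")
  rec <- stub_record(cherry, c(A = 4, B = 4), complete_tree = cherry,
                     node_states = c(A = 1, B = 1, nd3 = 1),
                     tip_traits = c(A = 1, B = 1))
  ab2 <- asr_bias(rec, interval_grid(boundaries = c(0, 5)))
  expect_equal(ab2$table$abs_error[[1]], 0)
})

test_that("sparser sampling worsens the oldest-interval ancestral error", {
  errs <- matrix(NA_real_, 60, 2)
  g <- interval_grid(width = 5, max_age = 35)
  for (i in 1:60) {
    base <- 100000L + i * 17L
    rec_full <- simulate_record(sim_params(0.1, 0, t_max = 35, seed = base),
                                sampling_scheme("uniform", f = 1, seed = base + 1L),
                                trait_model(1, 0, seed = base + 2L))
    if (ape::Ntip(rec_full$reconstructed_tree) < 30) next
    rec_sparse <- rec_full
    samp <- apply_sampling(rec_full$reconstructed_tree,
                           sampling_scheme("uniform", f = 0.1, seed = base + 3L))
    rec_sparse$sampled_tree <- samp$tree
    t_full <- asr_bias(rec_full, g)$table
    t_sparse <- asr_bias(rec_sparse, g)$table
    ok <- which(!is.na(t_full$abs_error) & !is.na(t_sparse$abs_error))
    if (!length(ok)) next
    oldest <- max(ok)
    errs[i, ] <- c(t_sparse$abs_error[[oldest]], t_full$abs_error[[oldest]])
  }
  errs <- errs[stats::complete.cases(errs), , drop = FALSE]
  expect_gte(nrow(errs), 30)
  expect_gt(mean(errs[, 1]), mean(errs[, 2]))
})

test_that("naive rates sit near the truth only under complete Yule sampling", {
  g <- interval_grid(boundaries = c(0, 20))
  at0 <- numeric(25)
  for (i in 1:25) {
    rec <- simulate_record(sim_params(0.1, 0, t_max = 50, seed = 40000L + i * 7L),
                           sampling_scheme("uniform", f = 1, seed = i),
                           trait_model(1, 0, seed = i))
    rb <- rate_bias_curve(rec, g)
    expect_equal(rb$true_rate, rep(0.1, 2))
    at0[[i]] <- rb$naive_rate[[1]]
  }
  expect_lt(abs(mean(at0) - 0.1) / 0.1, 0.25)

  # a single sampled lineage has rate 0 at every boundary
  fx <- make_four_taxon_fixture()
  rec1 <- stub_record(prune_to_tips(fx$reconstructed_tree, "A"),
                      c(A = 2.5), params = list(lambda = 0.1, mu = 0))
  rb1 <- rate_bias_curve(rec1, interval_grid(boundaries = c(0, 5)))
  expect_equal(rb1$naive_rate, c(0, 0))
  expect_equal(rb1$true_rate, rep(0.1, 2))
})

test_that("sampling fractions are exact before 2-significant-figure formatting", {
  expect_equal(sampling_fraction(232, 359208)$percent_2sf, 0.065)
  expect_equal(sampling_fraction(31389, 359208)$percent_2sf, 8.7)
  expect_equal(sampling_fraction(123, 123)$percent, 100)
  expect_equal(sampling_fraction(1, 3)$percent, 100 / 3)
  expect_error(sampling_fraction(10, 5), "exceeds")
  expect_error(sampling_fraction(0, 5), "> 0")
})
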