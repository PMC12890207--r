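# Shared fixtures and simulation helpers, all built in code.

four_taxon_newick <- "((A:2.5,B:2.5):5.0,(C:2.5,D:2.5):5.0);"

four_taxon_tree <- function() parse_newick(four_taxon_newick, stem_age = 10)

four_taxon_traits <- c(A = 1, B = 2, C = 3, D = 4)

# Simulate a pure-birth tree conditioned on a minimum extant tip count by
# advancing the seed; returns the complete tree. Deterministic given seed.
sim_yule_min_tips <- function(lambda, t_max, min_tips, seed) {
  repeat {
    tr <- simulate_birth_death(sim_params(lambda, 0, t_max = t_max, seed = seed))
    if (ape::Ntip(tr) >= min_tips) return(tr)
    seed <- seed + 1L
  }
}

tip_parent_ages_of <- function(tree) {
  oa <- naive_origin_ages(tree)
  setNames(oa$origin_age, oa$tip)
}

scale_tree <- function(tree, k) {
  tree$edge.length <- tree$edge.length * k
  tree
}

# Internal-node ages of a tree, sorted (for topology-free comparisons).
internal_ages <- function(tree) {
  sort(node_ages(tree)[(ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)])
}

expect_tree_equal <- function(a, b, tol = 1e-9) {
  expect_setequal(a$tip.label, b$tip.label)
  da <- ape::cophenetic.phylo(a)[a$tip.label, a$tip.label]
  db <- ape::cophenetic.phylo(b)[a$tip.label, a$tip.label]
  expect_lt(max(abs(da - db)), tol)
}
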