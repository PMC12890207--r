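#' @importFrom ape read.tree write.tree keep.tip node.depth.edgelength Ntip Nnode is.ultrametric
#' @importFrom stats cor median rexp rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Tolerance (My) used throughout for ultrametricity and age tie-breaks.
AGE_TOL <- 1e-9

#' Parse a rooted Newick tree
#'
#' Reads a single rooted Newick string into an [ape::read.tree()] `phylo`
#' object and validates it for use in this package: unique nonempty tip
#' labels, a branch length on every non-root edge, all lengths finite and
#' non-negative. Time is measured backward from the present: the farthest
#' tip from the root sits at age 0 and ages increase into the past
#' (millions of years, My, throughout).
#'
#' @param text Newick string (terminating `;` optional for a single tree).
#' @param stem_age Optional known stem age (My) of the clade, i.e. the age
#'   at which its lineage split from its sister clade. Must be at least the
#'   crown (root) age. Stored as the `stem_age` attribute; estimators that
#'   need a stem age fall back to the crown age with a warning when absent.
#' @return A `phylo` object.
#' @export
#' @examples
#' tr <- parse_newick("((A:2.5,B:2.5):5.0,(C:2.5,D:2.5):5.0);")
#' crown_age(tr) # 7.5
parse_newick <- function(text, stem_age = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) text <- paste0(text, ";")
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick: could not parse a tree from the input", call. = FALSE)
  }
  validate_phylo(tr)
  if (!is.null(stem_age)) {
    stopifnot(is.numeric(stem_age), length(stem_age) == 1L, is.finite(stem_age))
    if (stem_age < crown_age(tr) - AGE_TOL) {
      stop("stem_age (", stem_age, ") is younger than the crown age (",
           crown_age(tr), ")", call. = FALSE)
    }
    attr(tr, "stem_age") <- stem_age
  }
  tr
}

#' Serialize a tree to Newick
#'
#' Writes the subset Newick dialect used by this package: unquoted labels,
#' decimal branch lengths, no comments or annotations. Round-trips through
#' [parse_newick()] with branch lengths preserved to well below 1e-9 My.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  validate_phylo(tree)
  ape::write.tree(tree, digits = 12)
}

# Structural validation shared by parse_newick and the operations below.
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  labs <- tree$tip.label
  if (any(is.na(labs) | !nzchar(labs))) {
    stop("parse error: empty tip label", call. = FALSE)
  }
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop("parse error: duplicate tip label '", dup[[1L]], "'", call. = FALSE)
  }
  el <- tree$edge.length
  if (is.null(el)) stop("parse error: tree has no branch lengths", call. = FALSE)
  if (anyNA(el) || any(!is.finite(el))) {
    stop("parse error: missing or non-finite branch length", call. = FALSE)
  }
  if (any(el < 0)) stop("parse error: negative branch length", call. = FALSE)
  invisible(tree)
}

#' Node ages
#'
#' Age of every node, measured backward from the present: the tree height
#' (maximum root-to-tip path) minus the node's depth from the root. For an
#' ultrametric tree all tip ages are 0 within 1e-9 My.
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `Ntip + Nnode`, indexed by ape node
#'   number (tips `1..Ntip` first), named by tip label for tips.
#' @export
node_ages <- function(tree) {
  validate_phylo(tree)
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  names(ages) <- c(tree$tip.label, rep("", tree$Nnode))
  ages
}

#' Crown (root) age of a tree
#'
#' @param tree A `phylo` object.
#' @return The root age in My (maximum root-to-tip path length).
#' @export
crown_age <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' Stem age of a tree
#'
#' Returns the recorded `stem_age` attribute (set by [parse_newick()] or the
#' simulator). When absent, falls back to the crown age with a warning,
#' since user-supplied Newick files rarely carry a stem age.
#'
#' @param tree A `phylo` object.
#' @return Stem age in My.
#' @export
stem_age <- function(tree) {
  s <- attr(tree, "stem_age")
  if (is.null(s)) {
    warning("no stem_age recorded; falling back to the crown age", call. = FALSE)
    s <- crown_age(tree)
  }
  s
}

#' Is a tree ultrametric (to package tolerance)?
#'
#' All tip ages within 1e-9 My of 0. Complete simulated trees that retain
#' extinct lineages are legitimately non-ultrametric.
#'
#' @param tree A `phylo` object.
#' @return Logical.
#' @export
is_ultrametric <- function(tree) {
  ages <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  all(abs(ages) <= AGE_TOL * max(1, crown_age(tree)))
}

#' Restrict a tree to a set of tips
#'
#' Drops all tips not in `keep`; degree-2 internal nodes created by the
#' pruning are suppressed with their incident branch lengths summed, so the
#' age of every retained node is unchanged. This is the operation that
#' inflates apparent tip "origin" ages under incomplete sampling: a tip
#' whose sister was removed inherits a strictly older parent node.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least one).
#' @return A `phylo` object containing exactly the kept tips. A single kept
#'   tip yields a one-tip tree whose branch is the tip's full root-to-tip
#'   path length. The `stem_age` attribute, if present, is carried over.
#' @export
prune_to_tips <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("'keep' must contain at least one tip label", call. = FALSE)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(keep) == 1L) {
    depth <- ape::node.depth.edgelength(tree)
    i <- match(keep, tree$tip.label)
    out <- structure(
      list(edge = matrix(c(2L, 1L), nrow = 1L),
           tip.label = keep, Nnode = 1L,
           edge.length = depth[i]),
      class = "phylo", order = "cladewise")
  } else {
    out <- ape::keep.tip(tree, keep)
  }
  attr(out, "stem_age") <- attr(tree, "stem_age")
  out
}

#' Number of lineages crossing a given age
#'
#' Counts the branches of an ultrametric tree alive at age `T`, i.e. the
#' units an interval-pruning analysis would treat as the lineages present
#' `T` My ago. A node exactly at age `T` counts as already split, so its
#' daughter branches are the ones counted. At `T = 0` this is the tip
#' count; just below the crown age it is 2 for a bifurcating root; between
#' the crown and stem ages there is a single stem lineage.
#'
#' @param tree An ultrametric `phylo` object.
#' @param T Age in My, `0 <= T <= stem age`.
#' @return Integer lineage count.
#' @export
lineage_count_at <- function(tree, T) {
  validate_phylo(tree)
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T), T >= 0)
  ca <- crown_age(tree)
  sa <- attr(tree, "stem_age")
  if (is.null(sa)) sa <- ca
  if (T > sa + AGE_TOL) {
    stop("T (", T, ") is older than the stem age (", sa, ")", call. = FALSE)
  }
  if (T <= AGE_TOL) return(ape::Ntip(tree))
  if (T > ca + AGE_TOL) return(1L)
  ages <- node_ages(tree)
  parent_age <- ages[tree$edge[, 1L]]
  child_age <- ages[tree$edge[, 2L]]
  sum(parent_age >= T - AGE_TOL & child_age < T - AGE_TOL)
}

#' Total branch length
#'
#' Sum of all branch lengths (My); the exposure term of the Kendall-Moran
#' speciation-rate estimator.
#'
#' @param tree A `phylo` object.
#' @return Non-negative numeric.
#' @export
total_branch_length <- function(tree) {
  validate_phylo(tree)
  sum(tree$edge.length)
}

#' Build a time-interval grid
#'
#' Ordered half-open intervals `[b_k, b_{k+1})` in age, measured backward
#' from the present, starting at 0. The final interval is open-ended
#' (`[b_K, Inf)`), so every age maps to exactly one interval; an age exactly
#' on a boundary belongs to the interval whose young edge it is.
#'
#' @param width Interval width in My (default 5, the conventional bin for
#'   Cenozoic-scale analyses).
#' @param max_age Oldest boundary to generate; boundaries run
#'   `0, width, ..., <= max_age`.
#' @param boundaries Alternatively, an explicit strictly increasing numeric
#'   vector of boundaries starting at 0 (overrides `width`/`max_age`).
#' @return An object of class `interval_grid`: the boundary vector.
#' @export
#' @examples
#' interval_grid(width = 5, max_age = 10) # boundaries 0, 5, 10
interval_grid <- function(width = 5, max_age = NULL, boundaries = NULL) {
  if (is.null(boundaries)) {
    stopifnot(is.numeric(width), length(width) == 1L, width > 0,
              is.numeric(max_age), length(max_age) == 1L, max_age > 0)
    boundaries <- seq(0, max_age, by = width)
  }
  boundaries <- as.numeric(boundaries)
  if (boundaries[[1L]] != 0) stop("first interval boundary must be 0", call. = FALSE)
  if (any(diff(boundaries) <= 0)) {
    stop("interval boundaries must be strictly increasing", call. = FALSE)
  }
  structure(boundaries, class = "interval_grid")
}

#' Map ages to interval indices
#'
#' @param age Numeric vector of ages (My), all `>= 0`.
#' @param grid An [interval_grid()].
#' @return Integer interval indices, 1 = youngest (`[0, b_2)`); ages at or
#'   beyond the last boundary fall in the open-ended final interval.
#' @export
interval_index <- function(age, grid) {
  stopifnot(inherits(grid, "interval_grid"), all(age >= -AGE_TOL))
  findInterval(pmax(age, 0), unclass(grid))
}

#' Interval bounds as a data frame
#'
#' @param grid An [interval_grid()].
#' @return Data frame with columns `interval`, `lo`, `hi` (`hi = Inf` for
#'   the final open-ended interval).
#' @export
interval_bounds <- function(grid) {
  stopifnot(inherits(grid, "interval_grid"))
  b <- unclass(grid)
  data.frame(interval = seq_along(b), lo = b, hi = c(b[-1L], Inf))
}
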