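#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation of the pure-birth process: starting from two lineages,
#' each of the current `k` lineages splits after an exponential waiting time
#' with total rate `k * birth_rate`; once `n_tips` lineages exist, all are
#' extended by a final Exp(`n_tips * birth_rate`) waiting time, so the tree
#' is ultrametric. Tips are labeled `t0001`, `t0002`, ... in order of birth.
#'
#' Under this construction the expected tree height is
#' `(1/birth_rate) * (sum_{k=2}^{n-1} 1/k + 1/n)`, which the test suite uses
#' as a closed-form oracle.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate lambda (> 0); branch lengths are in
#'   units of `1/birth_rate`.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` object with `n_tips` tips.
#' @examples
#' tr <- simulate_yule_tree(8, seed = 1)
#' ape::is.ultrametric(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2 || n_tips != round(n_tips))
    stop("n_tips must be an integer >= 2")
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be > 0")
  n <- as.integer(n_tips)
  if (!is.null(seed)) set.seed(seed)

  # lineage bookkeeping: parent lineage (0 = root), start time, end time
  max_lin <- 2L * n - 2L
  parent <- integer(max_lin); start <- numeric(max_lin); end <- numeric(max_lin)
  active <- c(1L, 2L)
  parent[1:2] <- 0L; start[1:2] <- 0
  n_lin <- 2L
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + stats::rexp(1L, rate = k * birth_rate)
    i <- active[sample.int(k, 1L)]
    end[i] <- t
    children <- c(n_lin + 1L, n_lin + 2L)
    parent[children] <- i; start[children] <- t
    n_lin <- n_lin + 2L
    active <- c(setdiff(active, i), children)
  }
  t <- t + stats::rexp(1L, rate = n * birth_rate)
  end[active] <- t

  # assemble the ape edge matrix: tips 1..n (in order of lineage creation),
  # internal nodes n+1..2n-1 with the root at n+1
  is_tip <- seq_len(n_lin) %in% active
  node_id <- integer(n_lin)
  node_id[is_tip] <- seq_len(n)
  node_id[!is_tip] <- n + 1L + seq_len(sum(!is_tip))
  ape_parent <- ifelse(parent[seq_len(n_lin)] == 0L, n + 1L,
                       node_id[pmax(parent[seq_len(n_lin)], 1L)])
  tr <- list(
    edge = cbind(ape_parent, node_id[seq_len(n_lin)]),
    edge.length = end[seq_len(n_lin)] - start[seq_len(n_lin)],
    tip.label = sprintf("t%04d", seq_len(n)),
    Nnode = n - 1L
  )
  dimnames(tr$edge) <- NULL
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "order") <- "cladewise"
  tr
}

#' Sample a community from a tree pool with known structure
#'
#' Draws `k` tips as one community, under one of three generating modes that
#' realize the alternatives the NRI/NTI are meant to distinguish:
#'
#' * `"null"`: `k` tips uniformly without replacement — no structure.
#' * `"clustered"`: tips drawn from inside a single clade. A non-root
#'   internal node with at least `k` descendant tips is chosen at random
#'   (preferring tight clades, at most `3 * k` tips, when any exist, so the
#'   planted signal is unambiguous); `round(strength * k)` members come from
#'   inside it and the rest are uniform top-ups.
#' * `"overdispersed"`: greedy max–min spread — start from the most distant
#'   pair, repeatedly add the tip maximizing the minimum patristic distance
#'   to the current set; `strength` interpolates toward uniform as above.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param k Community size, `2 <= k < Ntip(tree)`.
#' @param mode `"null"`, `"clustered"` or `"overdispersed"`.
#' @param strength In `[0, 1]`: fraction of members placed by the structured
#'   rule; 0 reduces every mode to `"null"`.
#' @param seed Optional integer seed.
#' @param dist Optional precomputed [patristic_distances()] matrix (saves
#'   recomputation in simulation loops).
#' @return Character vector of `k` tip labels.
#' @export
sample_community <- function(tree, k, mode = c("null", "clustered", "overdispersed"),
                             strength = 1, seed = NULL, dist = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (k < 2 || k >= n) stop("need 2 <= k < Ntip(tree); k = ", k, ", n = ", n)
  stopifnot(strength >= 0, strength <= 1)
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label

  m <- round(strength * k)
  core <- character(0)
  if (mode == "clustered" && m >= 1L) {
    clade_tips <- .clade_tip_sets(tree)
    sizes <- lengths(clade_tips)
    cand <- which(sizes >= k)
    if (length(cand)) {
      tight <- cand[sizes[cand] <= 3L * k]
      pick <- if (length(tight)) tight[sample.int(length(tight), 1L)]
              else cand[sample.int(length(cand), 1L)]
      core <- sample(clade_tips[[pick]], min(m, k))
    } else {
      # no non-root clade is large enough: take the largest whole, top up
      message("no clade of size >= ", k, "; using the largest (",
              max(sizes), " tips) plus uniform top-up")
      biggest <- clade_tips[[which.max(sizes)]]
      core <- biggest[seq_len(min(length(biggest), m))]
    }
  } else if (mode == "overdispersed" && m >= 2L) {
    if (is.null(dist)) dist <- patristic_distances(tree)
    core <- .maxmin_spread(dist, min(m, k))
  }
  rest <- sample(setdiff(tips, core), k - length(core))
  out <- c(core, rest)
  sample(out)  # shuffle so member order carries no information
}

# tip label sets of every non-root internal node
.clade_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  internal <- setdiff(unique(tree$edge[, 1L]), n + 1L)
  lapply(internal, function(nd) ape::extract.clade(tree, nd)$tip.label)
}

# greedy max-min diversification over a distance matrix
.maxmin_spread <- function(dist, m) {
  labs <- rownames(dist)
  far <- which(dist == max(dist), arr.ind = TRUE)[1L, ]
  sel <- c(far[[1L]], far[[2L]])
  while (length(sel) < m) {
    remaining <- setdiff(seq_along(labs), sel)
    mind <- apply(dist[remaining, sel, drop = FALSE], 1L, min)
    sel <- c(sel, remaining[which.max(mind)])
  }
  labs[sel[seq_len(m)]]
}

#' Simulation configuration for a synthetic efficacy study
#'
#' Defaults emulate the compiled Ranunculales ethnomedicinal data set: 551
#' medicinal species partitioned into five family-like clades with relative
#' sizes 300/69/42/14/126, and 15 therapeutic categories whose prevalences
#' are the published per-category species fractions (13.2% to 78.9%).
#'
#' @param n_tips Number of tips in the simulated pool.
#' @param n_clades Number of family-like clades to carve from the tree.
#' @param clade_weights Relative target sizes of the clades (normalized to
#'   sum to 1); realized sizes are emergent from the simulated topology and
#'   only approximate these weights.
#' @param birth_rate Yule speciation rate.
#' @param categories Category identifiers.
#' @param prevalence Per-category fraction of species positive, in (0, 1);
#'   recycled to `length(categories)`.
#' @param mode Per-category generating mode (`"null"`, `"clustered"`,
#'   `"overdispersed"`); recycled.
#' @param clustering_strength Strength passed to [sample_community()];
#'   recycled.
#' @param seed Integer seed recorded in the output metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 551,
                       n_clades = 5,
                       clade_weights = c(300, 69, 42, 14, 126) / 551,
                       birth_rate = 1,
                       categories = therapeutic_categories(),
                       prevalence = c(105, 80, 343, 78, 110, 435, 183, 389,
                                      132, 181, 73, 144, 239, 348, 124) / 551,
                       mode = "null",
                       clustering_strength = 1,
                       seed = 1L) {
  stopifnot(n_tips >= 4, n_clades >= 1, birth_rate > 0)
  clade_weights <- clade_weights / sum(clade_weights)
  if (length(clade_weights) != n_clades)
    stop("clade_weights must have length n_clades")
  ncat <- length(categories)
  prevalence <- rep_len(prevalence, ncat)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalences must lie strictly in (0, 1)")
  mode <- rep_len(mode, ncat)
  stopifnot(all(mode %in% c("null", "clustered", "overdispersed")))
  clustering_strength <- rep_len(clustering_strength, ncat)
  structure(list(
    n_tips = as.integer(n_tips), n_clades = as.integer(n_clades),
    clade_weights = clade_weights, birth_rate = birth_rate,
    categories = categories, prevalence = prevalence, mode = mode,
    clustering_strength = clustering_strength, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a complete synthetic efficacy study
#'
#' Simulates a Yule tree, carves it into family-like clades, and fills a
#' binary efficacy matrix by drawing each category's positive species with
#' [sample_community()] under that category's configured mode. A truth table
#' recording each category's generating mode, strength and community size is
#' returned alongside, so recovery tests can compare the pipeline's verdicts
#' with the planted structure. Species left all-zero after the draws are
#' given one positive category (chosen with probability proportional to
#' prevalence), mirroring the constraint that every recorded medicinal
#' species treats something.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_study` with elements `tree` (`phylo`),
#'   `matrix` (`efficacy_matrix` with family assignments), `truth`
#'   (data.frame: category, mode, strength, k) and `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_tips, config$birth_rate)
  fams <- .assign_families(tree, config$n_clades)
  dist <- patristic_distances(tree)

  n <- config$n_tips
  ncat <- length(config$categories)
  k <- round(config$prevalence * n)
  if (any(k < 2))
    stop("infeasible prevalence: category community size below 2 (k = ",
         paste(k[k < 2], collapse = ", "), ")")
  vals <- matrix(0L, n, ncat, dimnames = list(tree$tip.label, config$categories))
  for (j in seq_len(ncat)) {
    members <- sample_community(tree, k[j], mode = config$mode[j],
                                strength = config$clustering_strength[j],
                                dist = dist)
    vals[members, j] <- 1L
  }
  zero <- which(rowSums(vals) == 0L)
  for (i in zero)
    vals[i, sample.int(ncat, 1L, prob = config$prevalence)] <- 1L

  truth <- data.frame(category = config$categories, mode = config$mode,
                      strength = config$clustering_strength, k = k,
                      stringsAsFactors = FALSE)
  mat <- efficacy_matrix(vals, families = unname(fams[tree$tip.label]),
                         warn_all_zero = FALSE)
  structure(list(tree = tree, matrix = mat, truth = truth, config = config),
            class = "synthetic_study")
}

# Partition tips into n_clades monophyletic groups by repeatedly splitting
# the largest current clade at its root; family names are assigned largest
# to smallest so clade_weights order is respected by rank.
.assign_families <- function(tree, n_clades) {
  n <- ape::Ntip(tree)
  groups <- list(seq_len(n))
  roots <- (n + 1L)
  while (length(groups) < n_clades) {
    i <- which.max(lengths(groups))
    nd <- roots[i]
    children <- tree$edge[tree$edge[, 1L] == nd, 2L]
    if (length(children) < 2L) break
    sub <- lapply(children, function(ch) {
      if (ch <= n) ch else .descendant_tips(tree, ch)
    })
    groups <- c(groups[-i], sub)
    roots <- c(roots[-i], children)
  }
  ord <- order(lengths(groups), decreasing = TRUE)
  fams <- character(n)
  for (r in seq_along(ord))
    fams[groups[[ord[r]]]] <- sprintf("family%02d", r)
  stats::setNames(fams, tree$tip.label)
}

.descendant_tips <- function(tree, node) {
  n <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= n) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == nd, 2L])
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: ", ape::Ntip(x$tree), " tips, ",
      length(x$config$categories), " categories, seed ", x$config$seed,
      "\n", sep = "")
  print(table(mode = x$truth$mode))
  invisible(x)
}
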