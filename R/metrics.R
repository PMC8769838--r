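#' Mean pairwise distance (MPD)
#'
#' Mean patristic distance over all unordered pairs of distinct community
#' members. Large communities confined to one clade have small MPD relative
#' to random draws from the pool; the (sign-flipped) standardized version is
#' the net relatedness index, see [ses_metric()].
#'
#' @param dist A patristic distance matrix over the pool
#'   ([patristic_distances()]).
#' @param members Character vector of community member labels (>= 2, all
#'   present in `dist`).
#' @return The mean pairwise distance (nonnegative scalar).
#' @examples
#' d <- patristic_distances(parse_newick("((a:1,b:1):1,(c:1,d:1):1);"))
#' mpd(d, c("a", "b", "c"))  # (2 + 4 + 4) / 3
#' @export
mpd <- function(dist, members) {
  idx <- .member_index(dist, members)
  .mpd_idx(dist, idx)
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean, over community members, of each member's patristic distance to its
#' nearest other member. Sensitive to clustering near the tips of the tree;
#' its standardized version is the nearest taxon index.
#'
#' @inheritParams mpd
#' @return The mean nearest-taxon distance (nonnegative scalar).
#' @examples
#' d <- patristic_distances(parse_newick("((a:1,b:1):1,(c:1,d:1):1);"))
#' mntd(d, c("a", "b", "c"))  # (2 + 2 + 4) / 3
#' @export
mntd <- function(dist, members) {
  idx <- .member_index(dist, members)
  .mntd_idx(dist, idx)
}

.member_index <- function(dist, members) {
  stopifnot(is.matrix(dist), !is.null(rownames(dist)))
  if (length(members) < 2L)
    stop("a community needs at least 2 members, got ", length(members))
  if (anyDuplicated(members))
    stop("duplicate community members")
  idx <- match(members, rownames(dist))
  if (anyNA(idx))
    stop("member(s) not in the distance matrix: ",
         paste(utils::head(members[is.na(idx)], 5L), collapse = ", "))
  idx
}

.mpd_idx <- function(dist, idx) {
  s <- dist[idx, idx]
  sum(s) / (length(idx) * (length(idx) - 1L))
}

.mntd_idx <- function(dist, idx) {
  s <- dist[idx, idx]
  diag(s) <- Inf
  mean(apply(s, 1L, min))
}

#' Standardized effect size of MPD or MNTD (NRI / NTI)
#'
#' Compares the observed metric for a community against its distribution
#' under the taxa-label null model: the tip labels of the pool's distance
#' matrix are shuffled uniformly at random while the community's size is held
#' fixed (equivalent to drawing `k` labels from the pool without replacement
#' in each run). The standardized effect size is sign-flipped,
#'
#' \deqn{SES = -1 \times (obs - mean(null)) / sd(null),}
#'
#' so positive values mean the observed distance is *smaller* than expected —
#' phylogenetic clustering — and negative values mean overdispersion. With
#' `metric = "mpd"` this is the net relatedness index (NRI); with
#' `metric = "mntd"` it is the nearest taxon index (NTI).
#'
#' The p-value is one-tailed (lower): the midrank of the observed value among
#' observed-plus-null values, divided by `runs + 1`. Small p flags
#' significant clustering; overdispersed communities show p near 1.
#'
#' @param dist Patristic distance matrix over the pool.
#' @param members Community member labels (>= 2). A community equal to the
#'   whole pool has a degenerate null (every shuffle reproduces the observed
#'   value); the result is returned with `degenerate = TRUE` and `ses = NA`.
#' @param metric `"mpd"` (NRI) or `"mntd"` (NTI).
#' @param runs Number of null permutations (default 999).
#' @param seed Optional integer seed; identical seeds give identical results.
#' @return An object of class `ses_result`: a list with `metric`, `obs`,
#'   `null_mean`, `null_sd`, `ses`, `rank`, `p_value`, `runs`, `n_community`,
#'   `n_pool`, `degenerate`, `seed`, and the raw `null` values.
#' @examples
#' d <- patristic_distances(parse_newick(
#'   "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);"))
#' ses_metric(d, c("a", "b"), metric = "mpd", runs = 199, seed = 1)
#' @export
ses_metric <- function(dist, members, metric = c("mpd", "mntd"),
                       runs = 999L, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(runs >= 1L)
  idx <- .member_index(dist, members)
  k <- length(idx)
  n <- nrow(dist)
  fun <- if (metric == "mpd") .mpd_idx else .mntd_idx
  obs <- fun(dist, idx)

  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(runs),
                 function(i) fun(dist, sample.int(n, k)),
                 numeric(1L))
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  degenerate <- !is.finite(null_sd) || null_sd < .Machine$double.eps^0.5
  ses <- if (degenerate) NA_real_ else -1 * (obs - null_mean) / null_sd
  pr <- p_from_rank(obs, null)

  structure(list(
    metric = metric, obs = obs, null_mean = null_mean, null_sd = null_sd,
    ses = ses, rank = pr$rank, p_value = pr$p_value, runs = runs,
    n_community = k, n_pool = n, degenerate = degenerate,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    null = null
  ), class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  index <- if (x$metric == "mpd") "NRI" else "NTI"
  cat(sprintf("%s (ses of %s): obs = %.4f, null = %.4f +/- %.4f\n",
              index, toupper(x$metric), x$obs, x$null_mean, x$null_sd))
  if (x$degenerate) {
    cat("degenerate null (sd = 0): ses undefined\n")
  } else {
    cat(sprintf("%s = %.4f, rank = %.1f of %d, p = %.4g%s\n", index, x$ses,
                x$rank, x$runs + 1L, x$p_value,
                if (x$p_value < 0.05) " *" else ""))
  }
  cat(sprintf("community %d of pool %d, %d runs\n",
              x$n_community, x$n_pool, x$runs))
  invisible(x)
}

#' Rank-based one-tailed p-value
#'
#' Position of the observed value among the observed-plus-null values, in
#' ascending order with ties resolved by midrank; the p-value is
#' `rank / (runs + 1)`. The lower tail is reported: small p means the
#' observed distance is unusually small, i.e. phylogenetic clustering. The
#' smallest attainable p is `1 / (runs + 1)`.
#'
#' @param obs Observed metric value.
#' @param null Numeric vector of null metric values (length = runs).
#' @return A list with `rank` and `p_value`.
#' @examples
#' p_from_rank(0.5, c(1, 2, 3))  # rank 1, p = 0.25
#' @export
p_from_rank <- function(obs, null) {
  stopifnot(is.numeric(null), length(null) >= 1L, is.finite(obs))
  r <- rank(c(obs, null), ties.method = "average")[1L]
  list(rank = unname(r), p_value = unname(r) / (length(null) + 1L))
}
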