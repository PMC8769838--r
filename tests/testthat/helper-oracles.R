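# Independent brute-force oracles, deliberately not sharing code paths with
# the implementation: patristic distances by explicit root-path enumeration,
# MPD/MNTD by naive double loops.

oracle_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  nmax <- max(tree$edge)
  parent <- integer(nmax); elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n + 1L
  path_to_root <- function(i) {
    nodes <- integer(0); dists <- numeric(0); d <- 0; cur <- i
    while (cur != root) {
      d <- d + elen[cur]; cur <- parent[cur]
      nodes <- c(nodes, cur); dists <- c(dists, d)
    }
    stats::setNames(dists, nodes)
  }
  paths <- lapply(seq_len(n), path_to_root)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    common <- intersect(names(paths[[i]]), names(paths[[j]]))
    d[i, j] <- d[j, i] <- min(paths[[i]][common] + paths[[j]][common])
  }
  d
}

oracle_mpd <- function(d, members) {
  tot <- 0; np <- 0L
  for (a in seq_along(members)) for (b in seq_along(members)) if (a < b) {
    tot <- tot + d[members[a], members[b]]; np <- np + 1L
  }
  tot / np
}

oracle_mntd <- function(d, members) {
  mins <- vapply(members, function(a) {
    min(vapply(setdiff(members, a), function(b) d[a, b], numeric(1)))
  }, numeric(1))
  mean(mins)
}

# all size-k communities of a pool: exact taxa-label null distribution
oracle_exact_null <- function(d, k, fun) {
  combos <- utils::combn(rownames(d), k, simplify = FALSE)
  vapply(combos, function(m) fun(d, m), numeric(1))
}

balanced8 <- function() {
  parse_newick(paste0("(((a:1,b:1):1,(c:1,d:1):1):1,",
                      "((e:1,f:1):1,(g:1,h:1):1):1);"))
}

balanced4 <- function() parse_newick("((a:1,b:1):1,(c:1,d:1):1);")

# small efficacy CSV written on the fly
write_toy_efficacy <- function(path, extra_rows = NULL) {
  cats <- therapeutic_categories()
  hdr <- paste(c("species", "family", cats), collapse = ",")
  row1 <- paste(c("Aconitum alpha", "Ranunculaceae", rep(1, 15)), collapse = ",")
  row2 <- paste(c("Berberis beta", "Berberidaceae", c(1, rep(0, 14))), collapse = ",")
  writeLines(c(hdr, row1, row2, extra_rows), path)
  path
}
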