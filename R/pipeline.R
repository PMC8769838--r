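#' Score every therapeutic category within one analysis scope
#'
#' For a scope (the whole order, or one family), prunes the tree to the
#' scope's pool, computes the patristic distance matrix once, and evaluates
#' each category's species set with [ses_metric()]: the NRI (standardized
#' MPD) and NTI (standardized MNTD) with one-tailed rank p-values. Categories
#' with fewer than 2 member species in the scope get a row of `NA` metrics
#' with the true count, so every summary table has one row per category.
#'
#' @param tree A `phylo` object whose tips cover the matrix species (run
#'   [match_taxa()] first).
#' @param matrix An `efficacy_matrix` restricted to tree tips.
#' @param scope_species Optional character vector restricting the analysis to
#'   these species (e.g. one family); default uses every matrix species.
#' @param scope_name Name recorded on the result.
#' @param pool_policy `"all_tree_tips"`: the null draws from every tip of the
#'   (scope-pruned) tree, medicinal or not; `"medicinal_only"`: the pool is
#'   restricted to species present in the matrix. With a tree already pruned
#'   to the medicinal species the two coincide.
#' @param runs Null permutations per test (default 999).
#' @param seed Integer seed; category-level seeds are derived from it so the
#'   whole table is reproducible and independent of evaluation order.
#' @return A data.frame of class `ses_summary` with columns `category`,
#'   `NRI`, `p_NRI`, `NTI`, `p_NTI`, `n_species`, `sig_NRI`, `sig_NTI`
#'   (significance at p < 0.05, uncorrected).
#' @export
run_scope <- function(tree, matrix, scope_species = NULL, scope_name = "order",
                      pool_policy = c("all_tree_tips", "medicinal_only"),
                      runs = 999L, seed = 1L) {
  pool_policy <- match.arg(pool_policy)
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "efficacy_matrix"))
  sp <- rownames(matrix)
  if (is.null(scope_species)) scope_species <- sp
  scope_species <- intersect(scope_species, sp)
  if (!length(scope_species)) stop("empty scope: no matrix species in scope")
  scope_species <- intersect(scope_species, tree$tip.label)
  if (length(scope_species) < 2L)
    stop("scope '", scope_name, "' has fewer than 2 species on the tree")

  pool_tips <- switch(pool_policy,
    all_tree_tips = .scope_pool_tips(tree, scope_species),
    medicinal_only = scope_species)
  pruned <- if (length(pool_tips) < ape::Ntip(tree))
    prune_to_taxa(tree, pool_tips) else tree
  dist <- patristic_distances(pruned)

  categories <- colnames(matrix)
  n_cat <- length(categories)
  if (all(colSums(matrix[scope_species, , drop = FALSE]) < 2L))
    stop("every category has fewer than 2 species in scope '", scope_name, "'")

  out <- data.frame(category = categories, NRI = NA_real_, p_NRI = NA_real_,
                    NTI = NA_real_, p_NTI = NA_real_, n_species = NA_integer_,
                    sig_NRI = NA, sig_NTI = NA, stringsAsFactors = FALSE)
  for (j in seq_len(n_cat)) {
    members <- scope_species[matrix[scope_species, j] == 1L]
    members <- intersect(members, rownames(dist))
    out$n_species[j] <- length(members)
    if (length(members) < 2L) next
    r_mpd <- ses_metric(dist, members, "mpd", runs = runs,
                        seed = .derive_seed(seed, 2L * j))
    r_mntd <- ses_metric(dist, members, "mntd", runs = runs,
                         seed = .derive_seed(seed, 2L * j + 1L))
    out$NRI[j] <- r_mpd$ses;  out$p_NRI[j] <- r_mpd$p_value
    out$NTI[j] <- r_mntd$ses; out$p_NTI[j] <- r_mntd$p_value
    out$sig_NRI[j] <- !r_mpd$degenerate && r_mpd$p_value < 0.05
    out$sig_NTI[j] <- !r_mntd$degenerate && r_mntd$p_value < 0.05
    if (r_mpd$degenerate) out$NRI[j] <- NA_real_
    if (r_mntd$degenerate) out$NTI[j] <- NA_real_
  }
  attr(out, "scope") <- scope_name
  attr(out, "pool_policy") <- pool_policy
  attr(out, "n_pool") <- nrow(dist)
  attr(out, "runs") <- as.integer(runs)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ses_summary", "data.frame")
  out
}

# under all_tree_tips the pool is every tip of the scope's subtree: the
# smallest clade spanning the scope species (the whole tree for the order)
.scope_pool_tips <- function(tree, scope_species) {
  if (length(scope_species) == ape::Ntip(tree)) return(tree$tip.label)
  mrca <- ape::getMRCA(tree, scope_species)
  if (is.null(mrca) || mrca == ape::Ntip(tree) + 1L) return(tree$tip.label)
  ape::extract.clade(tree, mrca)$tip.label
}

# deterministic per-test seed stream, kept inside 32-bit integer range
.derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
}

#' @export
print.ses_summary <- function(x, digits = 4, ...) {
  cat("SES summary for scope '", attr(x, "scope"), "' (pool: ",
      attr(x, "pool_policy"), ", ", attr(x, "n_pool"), " tips, ",
      attr(x, "runs"), " runs)\n", sep = "")
  df <- as.data.frame(x)
  df$NRI <- round(df$NRI, digits); df$NTI <- round(df$NTI, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Species counts and percentages per category
#'
#' Column sums of the efficacy matrix over the scope's species, with the
#' percentage of scope species positive for each category (one decimal).
#'
#' @inheritParams run_scope
#' @return A data.frame with `category`, `count`, `percent`.
#' @export
count_species_per_category <- function(matrix, scope_species = NULL) {
  stopifnot(inherits(matrix, "efficacy_matrix"))
  sp <- rownames(matrix)
  if (is.null(scope_species)) scope_species <- sp
  scope_species <- intersect(scope_species, sp)
  m <- unclass(matrix)[scope_species, , drop = FALSE]
  counts <- colSums(m)
  data.frame(category = colnames(matrix),
             count = as.integer(counts),
             percent = round(100 * counts / length(scope_species), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multipurpose species: broad-spectrum medicinal taxa
#'
#' Species whose efficacy vector covers at least `threshold` of the
#' categories, sorted by breadth (descending) then name — the
#' "top-credit" taxa whose chemistry serves many organ systems.
#'
#' @param matrix A deduplicated `efficacy_matrix`.
#' @param threshold Minimum number of positive categories (1 to the number of
#'   category columns).
#' @return A data.frame with `species`, optional `family`, and
#'   `n_categories`.
#' @export
find_multipurpose <- function(matrix, threshold = 10L) {
  stopifnot(inherits(matrix, "efficacy_matrix"))
  ncat <- ncol(matrix)
  if (threshold < 1L || threshold > ncat)
    stop("threshold must be between 1 and ", ncat, ", got ", threshold)
  nn <- rowSums(unclass(matrix))
  keep <- which(nn >= threshold)
  keep <- keep[order(-nn[keep], rownames(matrix)[keep])]
  out <- data.frame(species = rownames(matrix)[keep],
                    n_categories = as.integer(nn[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  fams <- species_families(matrix)
  if (!is.null(fams))
    out <- data.frame(species = out$species,
                      family = unname(fams[out$species]),
                      n_categories = out$n_categories,
                      stringsAsFactors = FALSE)
  out
}

#' Run the full study: order-level plus per-family analyses
#'
#' Reconciles the matrix with the tree, scores every category at the order
#' (whole-matrix) scope and within each family, and collects species counts,
#' multipurpose species and a run manifest. Reruns with the same inputs and
#' seed reproduce the outputs exactly.
#'
#' @param tree A `phylo` object.
#' @param matrix An `efficacy_matrix`; its `families` attribute (not the
#'   tree) defines the family scopes.
#' @param runs Null permutations per test.
#' @param seed Integer base seed.
#' @param pool_policy See [run_scope()].
#' @param threshold Multipurpose-species threshold.
#' @param fallback_to_species Passed to [match_taxa()].
#' @param min_family_size Families with fewer matched species are reported in
#'   counts but not scored.
#' @return A list of class `study_result`: `summaries` (named list of
#'   `ses_summary`, first element the order scope), `counts`, `multipurpose`,
#'   `match_report`, `manifest`.
#' @export
run_study <- function(tree, matrix, runs = 999L, seed = 20220112L,
                      pool_policy = "all_tree_tips", threshold = 10L,
                      fallback_to_species = FALSE, min_family_size = 3L) {
  mt <- match_taxa(matrix, tree, fallback_to_species = fallback_to_species)
  mat <- mt$matrix
  fams <- species_families(mat)

  scopes <- list(order = rownames(mat))
  if (!is.null(fams)) {
    fam_names <- sort(unique(fams[!is.na(fams)]))
    for (f in fam_names) {
      members <- names(fams)[!is.na(fams) & fams == f]
      if (length(members) >= min_family_size) scopes[[f]] <- members
    }
  }
  summaries <- vector("list", length(scopes))
  names(summaries) <- names(scopes)
  for (i in seq_along(scopes)) {
    summaries[[i]] <- run_scope(tree, mat, scope_species = scopes[[i]],
                                scope_name = names(scopes)[i],
                                pool_policy = pool_policy, runs = runs,
                                seed = .derive_seed(seed, 1000L * i))
  }
  counts <- lapply(scopes, function(s) count_species_per_category(mat, s))

  manifest <- list(
    package = "ethnophylo",
    version = as.character(utils::packageVersion("ethnophylo")),
    seed = as.integer(seed), runs = as.integer(runs),
    pool_policy = pool_policy, threshold = as.integer(threshold),
    n_tree_tips = ape::Ntip(tree), n_species = nrow(mat),
    n_categories = ncol(mat), scopes = names(scopes),
    tree_digest = .object_digest(tree),
    matrix_digest = .object_digest(unclass(mat))
  )
  structure(list(summaries = summaries, counts = counts,
                 multipurpose = find_multipurpose(mat, threshold),
                 match_report = mt$report, manifest = manifest),
            class = "study_result")
}

# md5 of a canonical serialization; identifies inputs in the manifest
.object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.study_result <- function(x, ...) {
  m <- x$manifest
  cat("study_result: ", m$n_species, " species x ", m$n_categories,
      " categories on ", m$n_tree_tips, " tips; scopes: ",
      paste(m$scopes, collapse = ", "), "\n",
      "runs = ", m$runs, ", seed = ", m$seed, ", pool = ", m$pool_policy,
      "\n\n", sep = "")
  print(x$summaries[[1L]])
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits one CSV summary table per scope, a per-scope counts CSV, the
#' multipurpose-species CSV, the name-match report and a JSON manifest. File
#' contents carry no timestamps, so identical runs produce identical bytes.
#'
#' @param result A `study_result` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$summaries)) {
    utils::write.csv(as.data.frame(result$summaries[[nm]]),
                     file.path(dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$counts[[nm]],
                     file.path(dir, paste0("counts_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(result$multipurpose, file.path(dir, "multipurpose.csv"),
                   row.names = FALSE)
  rep <- result$match_report
  writeLines(c(
    paste("input species:", rep$n_input),
    paste("matched:", rep$n_matched),
    paste("unmatched:", rep$n_unmatched),
    paste("remapped:", rep$n_remapped),
    paste("tips retained:", rep$n_tips_retained),
    if (rep$n_unmatched) paste("unmatched names:",
                               paste(rep$unmatched, collapse = ", "))
  ), file.path(dir, "name_match_report.txt"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
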