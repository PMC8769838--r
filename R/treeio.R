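#' Parse a rooted phylogeny from a Newick string
#'
#' Reads a Newick-format tree into an [ape::phylo] object, validating the
#' properties every downstream analysis relies on: balanced parentheses,
#' unique tip labels, and non-negative branch lengths. Tip labels are stored
#' in underscore normal form (spaces become underscores), so binomials match
#' regardless of which separator the source file used.
#'
#' Trees without branch lengths parse successfully; whether lengths are
#' present is a declared state queried by downstream code (see
#' [patristic_distances()]), never silently coerced to zero.
#'
#' @param text A Newick string (must end in `;`). Quoted labels and internal
#'   node labels are supported.
#' @return A rooted `phylo` object.
#' @seealso [read_phylogeny()] to read from a file, [write_newick()] for the
#'   inverse operation.
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,c:2);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  .check_parens(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, got ", length(tr))
  .validate_phylogeny(tr)
}

#' Read a phylogeny from a Newick file
#'
#' @param path Path to a Newick file containing a single tree.
#' @return A rooted `phylo` object (validated as in [parse_newick()]).
#' @export
read_phylogeny <- function(path) {
  stopifnot(file.exists(path))
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# Balanced-parenthesis scan with position of the first offender, so the
# parse error names a token rather than echoing ape's internal message.
.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop("unbalanced parentheses: ", depth, " '(' never closed")
  invisible(TRUE)
}

.validate_phylogeny <- function(tr) {
  # strip surrounding quotes, then space -> underscore normal form
  tr$tip.label <- gsub("^['\"]|['\"]$", "", tr$tip.label)
  tr$tip.label <- gsub(" ", "_", tr$tip.label, fixed = TRUE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length(s) present")
  tr
}

#' Does a tree carry branch lengths?
#'
#' @param tree A `phylo` object.
#' @return `TRUE` if every edge has a length.
#' @export
has_branch_lengths <- function(tree) {
  !is.null(tree$edge.length) && !anyNA(tree$edge.length)
}

#' Prune a phylogeny to a set of tips
#'
#' Drops all tips not in `keep`, suppressing the resulting unary internal
#' nodes and summing their branch lengths, so the patristic distance between
#' any two surviving tips is exactly what it was in the full tree.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return The pruned `phylo` object.
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
#' prune_to_taxa(tr, c("a", "c", "d"))
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"), is.character(keep))
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("tip label(s) not in tree: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) sprintf(" (and %d more)", length(missing) - 10L))
  if (length(keep) < 2L)
    stop("need at least 2 tips to keep, got ", length(keep))
  ape::keep.tip(tree, keep)
}

#' Patristic distance matrix
#'
#' Tip-to-tip distances: the sum of branch lengths along the unique path
#' connecting each pair of tips. This matrix is the substrate for MPD/MNTD
#' and all NRI/NTI calculations.
#'
#' @param tree A `phylo` object with branch lengths on every edge.
#' @param unit_branch_lengths If `TRUE` and the tree carries no branch
#'   lengths, every edge is assigned length 1 (announced via a message).
#'   Trees without lengths are otherwise an error, never a silent zero.
#' @return A symmetric numeric matrix with tip labels as dimnames and a zero
#'   diagonal.
#' @examples
#' d <- patristic_distances(parse_newick("((a:1,b:1):1,(c:1,d:1):1);"))
#' d["a", "c"]  # 4
#' @export
patristic_distances <- function(tree, unit_branch_lengths = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!has_branch_lengths(tree)) {
    if (!unit_branch_lengths)
      stop("tree has missing branch lengths; pass unit_branch_lengths = TRUE ",
           "to assign length 1 to every edge")
    message("assigning unit length to all ", nrow(tree$edge), " edges")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  d <- ape::cophenetic.phylo(tree)
  # cophenetic returns tips in tree traversal order; keep that order but
  # guarantee exact symmetry and zero diagonal against FP noise
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}
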