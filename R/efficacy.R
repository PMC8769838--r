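#' The 15 canonical therapeutic disease categories
#'
#' Ethnomedicinal therapeutic uses are coded into 15 organ-system categories.
#' The order is fixed: it drives column order in every table and the
#' inner-to-outer ring order of the iTOL export.
#'
#' @param labels If `TRUE`, return the human-readable category names instead
#'   of the short machine identifiers.
#' @return A character vector of length 15.
#' @examples
#' therapeutic_categories()
#' @export
therapeutic_categories <- function(labels = FALSE) {
  if (labels) .category_table$label else .category_table$id
}

.category_table <- data.frame(
  id = c("poisoning", "circulatory", "gastrointestinal", "nervous", "eye",
         "general", "hepatobiliary", "musculoskeletal", "oral", "ent",
         "pediatric", "reproductive", "respiratory", "skin", "urinary"),
  label = c("Poisoning/intoxication", "Circulatory disease",
            "Gastrointestinal disease", "Nervous system disease",
            "Eye disease", "Other/general disease", "Hepatobiliary disease",
            "Musculoskeletal disease", "Oral disease",
            "Ear/nose/throat disease", "Pediatric disease",
            "Reproductive system disease", "Respiratory disease",
            "Skin disease", "Urinary disease"),
  stringsAsFactors = FALSE
)

#' Construct a binary efficacy matrix
#'
#' An `efficacy_matrix` is a species-by-category 0/1 integer matrix with
#' species names as row names and category identifiers as column names, plus
#' an optional per-species family assignment kept in the `"families"`
#' attribute. Each category column defines one "community": the set of
#' species recorded as treating that disease category.
#'
#' @param values Numeric/integer matrix of 0/1 values; row names are species.
#' @param families Optional character vector (one per species) of family
#'   assignments, or `NULL`.
#' @param categories Category identifiers; defaults to the column names of
#'   `values` or, failing that, [therapeutic_categories()].
#' @param warn_all_zero Flag all-zero rows with a warning (a recorded
#'   medicinal species must treat something). The rows are kept.
#' @return An object of class `efficacy_matrix`.
#' @export
efficacy_matrix <- function(values, families = NULL, categories = NULL,
                            warn_all_zero = TRUE) {
  values <- as.matrix(values)
  if (is.null(categories))
    categories <- if (!is.null(colnames(values))) colnames(values)
                  else therapeutic_categories()
  if (ncol(values) != length(categories))
    stop("matrix has ", ncol(values), " columns but ", length(categories),
         " categories were given")
  if (is.null(rownames(values)) || anyNA(rownames(values)))
    stop("species names (row names) are required")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop("non-binary cell at row ", rownames(values)[rc[1L]],
         ", column ", categories[rc[2L]], ": ", values[bad[1L]])
  }
  storage.mode(values) <- "integer"
  colnames(values) <- categories
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate species after construction: ", paste(dup, collapse = ", "),
         " (use read_efficacy_table() or or_merge_rows() to merge)")
  if (!is.null(families)) {
    if (length(families) != nrow(values))
      stop("families must have one entry per species")
    families <- as.character(families)
    names(families) <- rownames(values)
  }
  if (warn_all_zero) {
    z <- rownames(values)[rowSums(values) == 0L]
    if (length(z))
      warning("all-zero efficacy row(s): ", paste(utils::head(z, 5L), collapse = ", "),
              " - a recorded medicinal species should treat at least one category")
  }
  structure(values, families = families, class = c("efficacy_matrix", "matrix", "array"))
}

#' @export
print.efficacy_matrix <- function(x, ...) {
  cat("efficacy_matrix: ", nrow(x), " species x ", ncol(x), " categories\n", sep = "")
  fams <- attr(x, "families")
  if (!is.null(fams)) {
    tb <- sort(table(fams), decreasing = TRUE)
    cat("families: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("species per category:\n")
  print(colSums(unclass(x)))
  invisible(x)
}

#' @export
`[.efficacy_matrix` <- function(x, i, j, ..., drop = FALSE) {
  fams <- attr(x, "families")
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && !is.null(rownames(out))) {
    attr(out, "families") <- if (is.null(fams)) NULL else fams[rownames(out)]
    class(out) <- class(x)
  }
  out
}

#' Family assignments of an efficacy matrix
#'
#' @param matrix An `efficacy_matrix`.
#' @return Named character vector of families, or `NULL` if unset.
#' @export
species_families <- function(matrix) attr(matrix, "families")

#' Read a species x category table from delimited text
#'
#' Expects a header row with a species column, an optional family column, and
#' one column per therapeutic category. Duplicate species rows (the same name
#' recorded under several sources) are merged by elementwise OR with a
#' warning, so a species is positive for a category if any record says so.
#'
#' @param path Path to a CSV (`,`) or TSV (`\t`, chosen by file extension or
#'   `sep`) file, UTF-8, header required.
#' @param categories Category columns expected in the file; defaults to
#'   [therapeutic_categories()]. Columns in the file but not in this set (and
#'   not species/family) are an error.
#' @param species_col,family_col Column names holding species and family.
#'   `family_col` may be absent from the file.
#' @param sep Field separator; `NULL` picks `\t` for `.tsv`/`.txt`, else `,`.
#' @param truthy Tokens read as 1. The default enforces strict 0/1 coding;
#'   pass e.g. `c("1", "TRUE", "yes")` to relax.
#' @param genus_family_map Optional named character vector mapping genus to
#'   family, used to fill families when `family_col` is absent.
#' @return An `efficacy_matrix`.
#' @export
read_efficacy_table <- function(path, categories = therapeutic_categories(),
                                species_col = "species", family_col = "family",
                                sep = NULL, truthy = "1",
                                genus_family_map = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  if (!species_col %in% names(df))
    stop("no '", species_col, "' column in ", path)
  extra <- setdiff(names(df), c(species_col, family_col, categories))
  if (length(extra))
    stop("unknown category column(s): ", paste(extra, collapse = ", "))
  missing_cat <- setdiff(categories, names(df))
  if (length(missing_cat))
    stop("missing category column(s): ", paste(missing_cat, collapse = ", "))

  species <- vapply(df[[species_col]], normalize_name, character(1L),
                    USE.NAMES = FALSE)
  vals <- matrix(0L, nrow(df), length(categories),
                 dimnames = list(NULL, categories))
  falsy <- c("0", "FALSE", "false", "no", "")
  for (cc in categories) {
    tok <- trimws(as.character(df[[cc]]))
    v <- ifelse(tok %in% truthy, 1L, ifelse(tok %in% falsy, 0L, NA_integer_))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-binary cell at row ", i, " (", species[i], "), column ", cc,
           ": '", tok[i], "'")
    }
    vals[, cc] <- v
  }
  rownames(vals) <- species
  fams <- if (family_col %in% names(df)) as.character(df[[family_col]]) else
    .families_from_map(species, genus_family_map)

  merged <- or_merge_rows(vals, fams)
  if (nrow(merged$values) < nrow(vals))
    warning(nrow(vals) - nrow(merged$values),
            " duplicate species row(s) merged by elementwise OR")
  efficacy_matrix(merged$values, families = merged$families)
}

.families_from_map <- function(species, genus_family_map) {
  if (is.null(genus_family_map)) return(NULL)
  genus <- sub("_.*$", "", species)
  unname(genus_family_map[genus])
}

#' Merge duplicate species rows by elementwise OR
#'
#' OR-merging is commutative and associative, so the result never depends on
#' the row order of the input.
#'
#' @param values 0/1 matrix with species row names (duplicates allowed).
#' @param families Optional family per row; on conflict among duplicates the
#'   first non-missing value wins.
#' @return A list with `values` (unique rows, in first-appearance order) and
#'   `families`.
#' @export
or_merge_rows <- function(values, families = NULL) {
  sp <- rownames(values)
  uniq <- unique(sp)
  out <- matrix(0L, length(uniq), ncol(values),
                dimnames = list(uniq, colnames(values)))
  for (s in uniq) {
    rows <- values[sp == s, , drop = FALSE]
    out[s, ] <- as.integer(colSums(rows) > 0L)
  }
  fams <- NULL
  if (!is.null(families)) {
    fams <- vapply(uniq, function(s) {
      f <- families[sp == s]
      f <- f[!is.na(f) & nzchar(f)]
      if (length(f)) f[1L] else NA_character_
    }, character(1L))
  }
  list(values = out, families = fams)
}

#' Write an efficacy matrix to delimited text
#'
#' @param matrix An `efficacy_matrix`.
#' @param path Output path (`.tsv`/`.txt` writes tab-separated, else CSV).
#' @return `path`, invisibly.
#' @export
write_efficacy_table <- function(matrix, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  fams <- species_families(matrix)
  df <- data.frame(species = rownames(matrix), stringsAsFactors = FALSE)
  if (!is.null(fams)) df$family <- unname(fams)
  df <- cbind(df, as.data.frame(unclass(matrix), check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize a species name to tree-tip form
#'
#' Canonical form: `Genus_epithet` with underscores, genus capitalized,
#' epithets lower-case (hyphens preserved), infraspecific rank tokens
#' (`var.`, `subsp.`, `ssp.`, `f.`) kept with their epithet, and authority
#' strings (trailing capitalized tokens, e.g. "Franch.") stripped. The
#' operation is idempotent.
#'
#' @param raw A nonempty species name, spaces or underscores as separators.
#' @return The canonical name.
#' @examples
#' normalize_name("anemone rivularis var. flore-minore")
#' normalize_name("Coptis chinensis Franch.")
#' @export
normalize_name <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- trimws(gsub("_", " ", raw))
  if (!nzchar(s)) stop("empty species name")
  tokens <- strsplit(gsub("\\s+", " ", s), " ", fixed = TRUE)[[1L]]
  rank_tokens <- c("var.", "subsp.", "ssp.", "f.", "var", "subsp", "ssp")
  cap <- function(x) paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
  out <- cap(tokens[1L])
  i <- 2L
  expect_epithet <- TRUE
  while (i <= length(tokens)) {
    tok <- tokens[i]
    low <- tolower(tok)
    if (low %in% rank_tokens) {
      out <- c(out, sub("\\.?$", ".", low))  # normalize "var" -> "var."
      expect_epithet <- TRUE
    } else if (expect_epithet && grepl("^[a-zA-Z][a-z-]*$", tok) &&
               tok == tolower(tok)) {
      out <- c(out, tolower(tok))
      expect_epithet <- FALSE
    } else {
      break  # authority (capitalized / punctuated token): strip the rest
    }
    i <- i + 1L
  }
  paste(out, collapse = "_")
}

#' Reconcile efficacy-matrix species with tree tips
#'
#' Restricts the matrix to species that are tips of the tree and reports the
#' reconciliation. By default unmatched species are dropped (conservative: a
#' dropped name can never double-count a tip). With
#' `fallback_to_species = TRUE`, an unmatched infraspecific taxon
#' (`Genus_species_var._x`) whose parent binomial is a tip is OR-merged into
#' that tip's row.
#'
#' @param matrix An `efficacy_matrix` with normalized names.
#' @param tree A `phylo` object.
#' @param fallback_to_species Map unmatched infraspecific taxa to their
#'   parent binomial when present in the tree.
#' @return A list of class `taxa_match` with `matrix` (restricted) and
#'   `report` (counts + name lists; matched + unmatched = input species).
#' @export
match_taxa <- function(matrix, tree, fallback_to_species = FALSE) {
  stopifnot(inherits(matrix, "efficacy_matrix"), inherits(tree, "phylo"))
  sp <- rownames(matrix)
  tips <- tree$tip.label
  matched <- sp[sp %in% tips]
  unmatched <- setdiff(sp, tips)
  remapped <- character(0)

  vals <- unclass(matrix)[, , drop = FALSE]
  fams <- species_families(matrix)
  keep_vals <- vals[matched, , drop = FALSE]
  if (fallback_to_species && length(unmatched)) {
    parent <- .parent_binomial(unmatched)
    ok <- !is.na(parent) & parent %in% tips
    for (i in which(ok)) {
      tgt <- parent[i]
      row <- vals[unmatched[i], ]
      if (tgt %in% rownames(keep_vals)) {
        keep_vals[tgt, ] <- as.integer(keep_vals[tgt, ] | row)
      } else {
        keep_vals <- rbind(keep_vals, row)
        rownames(keep_vals)[nrow(keep_vals)] <- tgt
        if (!is.null(fams)) fams[tgt] <- fams[unmatched[i]]
        matched <- c(matched, tgt)
      }
    }
    remapped <- unmatched[ok]
    unmatched <- unmatched[!ok]
  }
  if (nrow(keep_vals) == 0L)
    stop("no species matched any tree tip - wrong tree or wrong name normalization?")

  restricted <- efficacy_matrix(
    keep_vals,
    families = if (is.null(fams)) NULL else unname(fams[rownames(keep_vals)]),
    warn_all_zero = FALSE
  )
  # every input species is accounted for: directly matched or remapped
  # species count as matched, so n_matched + n_unmatched = n_input
  report <- list(
    n_input = length(sp),
    n_matched = length(sp) - length(unmatched),
    n_unmatched = length(unmatched),
    n_remapped = length(remapped),
    n_tips_retained = nrow(keep_vals),
    matched = rownames(keep_vals), unmatched = unmatched, remapped = remapped
  )
  class(report) <- "name_match_report"
  structure(list(matrix = restricted, report = report), class = "taxa_match")
}

# parent binomial of an infraspecific name, NA when the name has no rank token
.parent_binomial <- function(x) {
  has_rank <- grepl("_(var\\.|subsp\\.|ssp\\.|f\\.)_", x)
  out <- rep(NA_character_, length(x))
  parts <- strsplit(x[has_rank], "_", fixed = TRUE)
  out[has_rank] <- vapply(parts, function(p) paste(p[1:2], collapse = "_"),
                          character(1L))
  out
}

#' @export
print.name_match_report <- function(x, ...) {
  cat("name match report: ", x$n_input, " input species; ",
      x$n_matched, " matched (", x$n_tips_retained, " tips retained), ",
      x$n_unmatched, " unmatched",
      if (x$n_remapped) paste0(", ", x$n_remapped, " infraspecific remapped"),
      "\n", sep = "")
  if (x$n_unmatched)
    cat("unmatched: ", paste(utils::head(x$unmatched, 10L), collapse = ", "),
        if (x$n_unmatched > 10L) " ...", "\n", sep = "")
  invisible(x)
}
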