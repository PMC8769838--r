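#' Default family color palette for clade ranges
#'
#' Hues follow the conventional ring-figure presentation of the five
#' species-rich Ranunculales families; other family names cycle through a
#' fixed auxiliary palette so assignments are stable across runs.
#' @keywords internal
.family_palette <- c(
  Ranunculaceae  = "#FFD700",  # yellow
  Berberidaceae  = "#228B22",  # green
  Menispermaceae = "#1E90FF",  # blue
  Lardizabalaceae = "#DC143C", # red
  Papaveraceae   = "#8A2BE2"   # purple
)

.aux_palette <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                  "#D55E00", "#CC79A7", "#999999")

# deterministic color per field index (15 distinct hues for the rings)
.field_colors <- function(n) {
  base <- grDevices::hcl(h = seq(15, 375, length.out = n + 1L)[seq_len(n)],
                         c = 80, l = 55)
  toupper(substr(base, 1L, 7L))
}

#' Write an iTOL DATASET_BINARY annotation of the efficacy matrix
#'
#' Produces one binary-symbol ring per therapeutic category, in the
#' canonical category order (inner to outer). Present efficacy is encoded
#' `1`; absent efficacy is encoded `-1` (symbol hidden) by default so the
#' rings read as filled-vs-empty, or `0` (empty outline) with
#' `absent_as_zero = TRUE`.
#'
#' @param matrix An `efficacy_matrix` already matched to the tree tips.
#' @param path Output file path.
#' @param label Dataset label shown in the iTOL legend.
#' @param shape iTOL symbol code used for every field (2 = circle).
#' @param absent_as_zero Encode absence as `0` (empty shape) instead of `-1`
#'   (hidden).
#' @return `path`, invisibly.
#' @export
write_binary_dataset <- function(matrix, path, label = "Therapeutic efficacy",
                                 shape = 2L, absent_as_zero = FALSE) {
  stopifnot(inherits(matrix, "efficacy_matrix"))
  categories <- colnames(matrix)
  n <- length(categories)
  absent <- if (absent_as_zero) 0L else -1L
  vals <- unclass(matrix)
  lines <- c(
    "DATASET_BINARY",
    "SEPARATOR COMMA",
    paste0("DATASET_LABEL,", label),
    "COLOR,#555555",
    paste0("FIELD_SHAPES,", paste(rep(shape, n), collapse = ",")),
    paste0("FIELD_LABELS,", paste(categories, collapse = ",")),
    paste0("FIELD_COLORS,", paste(.field_colors(n), collapse = ",")),
    "DATA",
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i],
              ifelse(vals[i, ] == 1L, 1L, absent)), collapse = ",")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse an iTOL DATASET_BINARY file back into a binary matrix
#'
#' Inverse of [write_binary_dataset()]; used to verify that exports are
#' lossless. Hidden (`-1`) and empty (`0`) field states both read as 0.
#'
#' @param path A DATASET_BINARY annotation file.
#' @return An integer 0/1 matrix, species x field labels.
#' @export
read_binary_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sep_line <- grep("^SEPARATOR", lines, value = TRUE)[1L]
  sep <- switch(sub("^SEPARATOR +", "", sep_line),
                COMMA = ",", TAB = "\t", SPACE = " ", ",")
  labels <- strsplit(sub("^FIELD_LABELS.", "",
                         grep("^FIELD_LABELS", lines, value = TRUE)[1L]),
                     sep, fixed = TRUE)[[1L]]
  data_start <- which(lines == "DATA")[1L]
  rows <- strsplit(lines[(data_start + 1L):length(lines)], sep, fixed = TRUE)
  rows <- rows[lengths(rows) == length(labels) + 1L]
  out <- t(vapply(rows, function(r) as.integer(r[-1L]) == 1L,
                  logical(length(labels))))
  storage.mode(out) <- "integer"
  dimnames(out) <- list(vapply(rows, `[[`, character(1L), 1L), labels)
  out
}

#' Write an iTOL TREE_COLORS file of family clade ranges
#'
#' One `range` line per family spanning its most recent common ancestor
#' (given as a `tipA|tipB` node specifier). A family whose tips are not
#' monophyletic in the tree cannot be painted as a single clade; it falls
#' back to one range line per tip, announced via a message.
#'
#' @param tree A `phylo` object.
#' @param family_map Named character vector: tip label -> family. Tips
#'   missing from the map are left uncolored.
#' @param path Output file path.
#' @param palette Named colors per family; unnamed families cycle a fixed
#'   auxiliary palette.
#' @return `path`, invisibly.
#' @export
write_clade_colors <- function(tree, family_map, path,
                               palette = .family_palette) {
  stopifnot(inherits(tree, "phylo"))
  family_map <- family_map[names(family_map) %in% tree$tip.label]
  family_map <- family_map[!is.na(family_map)]
  if (!length(family_map)) stop("family_map covers no tip of the tree")
  fams <- sort(unique(family_map))
  missing_col <- setdiff(fams, names(palette))
  if (length(missing_col)) {
    extra <- stats::setNames(rep_len(.aux_palette, length(missing_col)),
                             missing_col)
    palette <- c(palette, extra)
  }
  body <- character(0)
  for (f in fams) {
    tips <- names(family_map)[family_map == f]
    col <- unname(palette[f])
    if (length(tips) == 1L) {
      body <- c(body, paste(tips, "range", col, f, sep = ","))
    } else if (ape::is.monophyletic(tree, tips)) {
      clade <- ape::extract.clade(tree, ape::getMRCA(tree, tips))$tip.label
      body <- c(body, paste(paste0(clade[1L], "|", clade[length(clade)]),
                            "range", col, f, sep = ","))
    } else {
      message("family '", f, "' is not monophyletic; writing ",
              length(tips), " per-tip range lines")
      body <- c(body, paste(tips, "range", col, f, sep = ","))
    }
  }
  writeLines(c("TREE_COLORS", "SEPARATOR COMMA", "DATA", body), path)
  invisible(path)
}
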