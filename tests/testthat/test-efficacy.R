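test_that("normalize_name applies the canonical rules", {
  expect_equal(normalize_name("anemone rivularis var. flore-minore"),
               "Anemone_rivularis_var._flore-minore")
  expect_equal(normalize_name("Coptis chinensis Franch."), "Coptis_chinensis")
  expect_equal(normalize_name("MAHONIA eurybracteata"), "Mahonia_eurybracteata")
  expect_equal(normalize_name("Akebia trifoliata subsp australis"),
               "Akebia_trifoliata_subsp._australis")
  expect_error(normalize_name("   "), "empty")
})

test_that("normalize_name is idempotent on fuzzed inputs", {
  set.seed(11)
  pieces <- c("aconitum", "Clematis", "THALICTRUM", "rivularis", "alba",
              "flore-minore", "var.", "subsp.", "Franch.", "L.", "Hook.f.")
  for (i in 1:200) {
    raw <- paste(c(sample(pieces[1:3], 1L), sample(pieces[4:6], 1L),
                   sample(pieces, sample(0:3, 1L))), collapse = " ")
    once <- normalize_name(raw)
    expect_equal(normalize_name(once), once, label = raw)
  }
})

test_that("read_efficacy_table enforces binary coding and OR-merges duplicates", {
  cats <- therapeutic_categories()
  path <- withr::local_tempfile(fileext = ".csv")

  # duplicate species with complementary rows collapse to their OR
  dup1 <- paste(c("Coptis gamma", "Ranunculaceae", 1, 0, rep(0, 13)), collapse = ",")
  dup2 <- paste(c("Coptis gamma", "Ranunculaceae", 0, 1, rep(0, 13)), collapse = ",")
  write_toy_efficacy(path, extra_rows = c(dup1, dup2))
  expect_warning(mat <- read_efficacy_table(path), "merged by elementwise OR")
  expect_equal(nrow(mat), 3L)
  expect_equal(unname(unclass(mat)["Coptis_gamma", 1:2]), c(1L, 1L))
  expect_equal(sum(mat["Aconitum_alpha", ]), 15L)
  expect_equal(unname(species_families(mat)["Berberis_beta"]), "Berberidaceae")

  # non-binary cell names its row and column
  bad <- paste(c("Anemone delta", "Ranunculaceae", 2, rep(0, 14)), collapse = ",")
  write_toy_efficacy(path, extra_rows = bad)
  expect_error(read_efficacy_table(path), "non-binary cell.*poisoning")

  # unknown category column is an error
  writeLines(c(paste(c("species", "family", cats, "bogus"), collapse = ","),
               paste(c("A b", "F", rep(0, 15), 1), collapse = ",")), path)
  expect_error(read_efficacy_table(path), "unknown category column.*bogus")

  # missing category column is an error
  writeLines(c(paste(c("species", "family", cats[-1]), collapse = ","),
               paste(c("A b", "F", rep(1, 14)), collapse = ",")), path)
  expect_error(read_efficacy_table(path), "missing category column.*poisoning")
})

test_that("all-zero efficacy rows are flagged", {
  vals <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
                 dimnames = list(c("A_a", "B_b"), c("skin", "oral")))
  expect_warning(efficacy_matrix(vals, categories = c("skin", "oral")),
                 "all-zero.*B_b")
})

test_that("OR-merge is order-invariant and column sums survive round-trip", {
  set.seed(22)
  cats <- therapeutic_categories()
  n <- 30L
  sp <- sample(paste0("Genus_", c("alba", "bella", "cana", "densa", "erecta",
                                  "flava", "glabra", "hirta", "incana",
                                  "juncea", "laxa", "minor")),
               n, replace = TRUE)
  vals <- matrix(rbinom(n * 15, 1, 0.4), n, 15, dimnames = list(sp, cats))
  m1 <- or_merge_rows(vals)$values
  for (i in 1:5) {
    perm <- sample(n)
    m2 <- or_merge_rows(vals[perm, , drop = FALSE])$values
    expect_equal(m2[rownames(m1), ], m1)
  }
  # write -> read preserves per-category species counts
  mat <- efficacy_matrix(m1, warn_all_zero = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_efficacy_table(mat, path)
  back <- suppressWarnings(read_efficacy_table(path))
  expect_equal(colSums(unclass(back)), colSums(unclass(mat)))
})

test_that("match_taxa reconciles matrix species with tree tips", {
  tr <- balanced8()
  cats <- c("skin", "oral")
  vals <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), cats))
  mat <- efficacy_matrix(vals, categories = cats)

  # matrix subset of tips: identity mapping
  mt <- match_taxa(mat, tr)
  expect_equal(mt$report$n_matched, 3L)
  expect_equal(mt$report$n_unmatched, 0L)
  expect_setequal(rownames(mt$matrix), c("a", "b", "c"))

  # infraspecific fallback maps X_y_var._z onto tip X_y and OR-merges
  vals2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                  dimnames = list(c("a", "a_x_var._z"), cats))
  tr2 <- parse_newick("((a:1,a_x:1):1,(c:1,d:1):1);")
  mat2 <- efficacy_matrix(vals2, categories = cats, warn_all_zero = FALSE)
  dropped <- match_taxa(mat2, tr2)
  expect_equal(dropped$report$n_unmatched, 1L)
  mapped <- match_taxa(mat2, tr2, fallback_to_species = TRUE)
  expect_equal(mapped$report$n_unmatched, 0L)
  expect_equal(mapped$report$n_remapped, 1L)
  expect_true("a_x" %in% rownames(mapped$matrix))
  expect_equal(unname(unclass(mapped$matrix)["a_x", ]), c(0L, 1L))

  # conservation: matched + unmatched = input species
  set.seed(33)
  tr3 <- simulate_yule_tree(40)
  sp <- c(sample(tr3$tip.label, 25), sprintf("Missing_sp%02d", 1:25))
  vals3 <- matrix(rbinom(50 * 2, 1, 0.6), 50, 2, dimnames = list(sp, cats))
  mat3 <- efficacy_matrix(vals3, categories = cats, warn_all_zero = FALSE)
  mt3 <- match_taxa(mat3, tr3)
  expect_equal(mt3$report$n_matched + mt3$report$n_unmatched, 50L)
  expect_lte(nrow(mt3$matrix), 40L)

  # zero matches is an error, not an empty result
  vals4 <- matrix(1L, 2, 2, dimnames = list(c("X_x", "Y_y"), cats))
  mat4 <- efficacy_matrix(vals4, categories = cats)
  expect_error(match_taxa(mat4, tr), "no species matched")
})

test_that("the canonical category set has 15 stable entries", {
  cats <- therapeutic_categories()
  expect_length(cats, 15L)
  expect_equal(cats[1], "poisoning")   # innermost iTOL ring
  expect_equal(cats[15], "urinary")    # outermost
  expect_length(therapeutic_categories(labels = TRUE), 15L)
  # the bundled definition file agrees with the in-code set
  def <- read.delim(system.file("extdata", "therapeutic_categories.tsv",
                                package = "ethnophylo"))
  expect_equal(def$id, cats)
})
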