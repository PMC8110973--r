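test_that("occurrence tables round-trip through the reader with validation", {
  df <- data.frame(taxon = c("t1", "t2", "t3"), A = c(1, 0, 1), B = c(1, 1, 0))
  path <- write_temp_csv(df)
  m <- read_occurrence_table(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(m), 4L)
  expect_equal(faunas_of <- colnames(m), c("A", "B"))
  expect_equal(rownames(m), c("t1", "t2", "t3"))

  bad <- df; bad$A[2] <- 2
  expect_error(read_occurrence_table(write_temp_csv(bad)),
               "non-binary.*t2.*A")
  dup <- df; dup$taxon[2] <- "t1"
  expect_error(read_occurrence_table(write_temp_csv(dup)), "duplicate")
})

test_that("singleton removal keeps multi-fauna taxa and the fauna set", {
  m <- occurrence_matrix(rbind(only_b = c(0L, 1L, 0L),
                               wide = c(1L, 0L, 1L),
                               both = c(1L, 1L, 0L)),
                         faunas = c("A", "B", "C"))
  out <- drop_singletons(m)
  expect_setequal(rownames(out), c("wide", "both"))
  expect_equal(colnames(out), c("A", "B", "C"))
  allsing <- occurrence_matrix(diag(3L), taxa = paste0("t", 1:3),
                               faunas = paste0("F", 1:3))
  expect_error(drop_singletons(allsing), "singleton")
})

test_that("range-through filling closes Lazarus gaps and only those", {
  m <- occurrence_matrix(rbind(laz = c(1L, 0L, 1L, 0L),
                               solid = c(0L, 1L, 1L, 0L),
                               once = c(0L, 0L, 0L, 1L)),
                         faunas = paste0("F", 1:4))
  out <- range_through_fill(m)
  expect_equal(unname(unclass(out)["laz", ]), c(1L, 1L, 1L, 0L))
  expect_equal(unclass(out)["solid", ], unclass(m)["solid", ])
  expect_equal(unclass(out)["once", ], unclass(m)["once", ])
  expect_error(range_through_fill(m, order = c("F1", "F2")), "permutation")
})

test_that("range-through filling is idempotent and monotone", {
  for (seed in 1:5) {
    m <- random_matrix(12, 6, seed = seed)
    f1 <- range_through_fill(m)
    expect_true(all(unclass(f1) >= unclass(m)))           # monotone
    expect_equal(unclass(range_through_fill(f1)), unclass(f1)) # idempotent
  }
})

test_that("singleton removal then filling never recreates a dropped taxon", {
  for (seed in 1:5) {
    m <- random_matrix(15, 6, p = 0.25, seed = seed)
    kept <- drop_singletons(m)
    filled <- range_through_fill(kept)
    expect_setequal(rownames(filled), rownames(kept))
  }
})

test_that("fauna merging ORs columns and preserves the taxon pool", {
  m <- occurrence_matrix(rbind(a = c(1L, 0L, 0L), b = c(0L, 1L, 1L),
                               c = c(1L, 1L, 0L)),
                         faunas = c("MH", "QSUp", "Chas"))
  out <- merge_faunas(m, list(`MH+QSUp` = c("MH", "QSUp")))
  expect_equal(colnames(out), c("MH+QSUp", "Chas"))
  expect_equal(unname(unclass(out)[, "MH+QSUp"]), c(1L, 1L, 1L))
  expect_setequal(rownames(out), rownames(m))
  expect_error(merge_faunas(m, list(c("MH", "nope"))), "unknown fauna")

  # the study's four pairings reduce 19 faunas to 15
  m19 <- random_matrix(40, 19, seed = 3)
  pairs <- list(c("F01", "F02"), c("F03", "F04"), c("F05", "F06"),
                c("F07", "F08"))
  expect_equal(ncol(merge_faunas(m19, pairs)), 15L)
})

test_that("merged columns equal brute-force set union on random matrices", {
  for (seed in 1:4) {
    m <- random_matrix(20, 6, seed = seed)
    out <- merge_faunas(m, list(mrg = c("F02", "F05")))
    u <- union(rownames(m)[unclass(m)[, "F02"] == 1L],
               rownames(m)[unclass(m)[, "F05"] == 1L])
    expect_setequal(rownames(out)[unclass(out)[, "mrg"] == 1L], u)
  }
})

test_that("merged metadata age is the midpoint of member midpoints", {
  meta <- fauna_metadata(data.frame(
    fauna = c("A", "B", "C"), latitude = c(-38, -36, -37),
    longitude = c(-60, -62, -64),
    age_point = c(NA, 6, 3), age_max = c(9, 7, 4), age_min = c(8, 5, 2)))
  out <- merge_fauna_metadata(meta, list(AB = c("A", "B")))
  expect_equal(out$age_point[out$fauna == "AB"], (8.5 + 6) / 2)
  expect_equal(out$age_max[out$fauna == "AB"], 9)
  expect_equal(out$age_min[out$fauna == "AB"], 5)
})

test_that("boundary composites are flagged and excluded from richness", {
  m <- nested_matrix(4)
  out <- add_boundary_composites(m, older_taxa = c("t01", "t02"),
                                 younger_taxa = "t05")
  expect_equal(ncol(out), 6L)
  expect_equal(unname(unclass(out)[c("t01", "t02"), "OLDER"]), c(1L, 1L))
  expect_equal(sum(unclass(out)[, "YOUNGER"]), 1L)
  # empty sets give all-zero flanking columns
  z <- add_boundary_composites(m)
  expect_equal(sum(unclass(z)[, c("OLDER", "YOUNGER")]), 0L)
  # downstream richness for real faunas is unchanged by the composites
  bc_with <- bin_crossings(out, approach = "range_through")
  bc_without <- bin_crossings(m, approach = "range_through")
  expect_true(all(is.na(bc_with$richness[bc_with$composite])))
  expect_equal(bc_with$richness[!bc_with$composite], bc_without$richness)
  expect_error(add_boundary_composites(m, older_taxa = "ghost"),
               "unknown taxon")
})

test_that("character-matrix export round-trips in both dialects", {
  m <- random_matrix(6, 4, seed = 9)
  for (dialect in c("nexus", "tnt")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_character_matrix(m, path, dialect)
    back <- read_character_matrix(path, dialect)
    expect_equal(unname(unclass(back)), unname(unclass(m)), info = dialect)
    expect_equal(colnames(back), colnames(m), info = dialect)
  }
  # NEXUS carries character (taxon) labels through the round trip
  path <- withr::local_tempfile(fileext = ".nex")
  write_character_matrix(m, path, "nexus")
  expect_equal(rownames(read_character_matrix(path, "nexus")), rownames(m))
  txt <- export_character_matrix(tiny_matrix(), "nexus")
  expect_match(txt, "NTAX=2 NCHAR=3")
})

test_that("identifiers illegal in a dialect are sanitised with a mapping", {
  m <- occurrence_matrix(rbind(x = c(1L, 1L)), faunas = c("Fauna A", "B(1)"))
  txt <- export_character_matrix(m, "tnt")
  map <- attr(txt, "sanitized")
  expect_equal(unname(map["Fauna A"]), "Fauna_A")
  expect_false(grepl("\\(", strsplit(txt, "\n")[[1]][4]))
})

test_that("metadata validation enforces coordinate and age-bound sanity", {
  good <- data.frame(fauna = "X", latitude = -38, longitude = -60,
                     age_point = 4, age_max = 5, age_min = 3)
  expect_s3_class(fauna_metadata(good), "fauna_metadata")
  bad <- good; bad$age_min <- 6
  expect_error(fauna_metadata(bad), "age_max >= age_point >= age_min")
  bad2 <- good; bad2$latitude <- 95
  expect_error(fauna_metadata(bad2), "latitude")
})

test_that("trait tables reject labels outside the fixed vocabularies", {
  good <- data.frame(taxon = "t1", group = "Carnivora",
                     diet = "carnivorous", size = "IV")
  expect_s3_class(taxon_traits(good), "taxon_traits")
  bad <- good; bad$diet <- "piscivorous"
  expect_error(taxon_traits(bad), "unknown diet")
})

test_that("genus expansion adds OR rows only for multi-species genera", {
  m <- occurrence_matrix(rbind(`Canis a` = c(1L, 0L), `Canis b` = c(0L, 1L),
                               `Felis x` = c(1L, 1L)),
                         faunas = c("A", "B"))
  out <- expand_genus_entries(m)
  expect_true("Canis (genus)" %in% rownames(out))
  expect_false("Felis (genus)" %in% rownames(out))
  expect_equal(unname(unclass(out)["Canis (genus)", ]), c(1L, 1L))
})
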