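overlap_fixture <- function() {
  list(make_dataset("s1", "MS", c("A", "B")),
       make_dataset("s2", "MS", c("B", "C")),
       make_dataset("s3", "Olink", c("B")))
}

test_that("count_study_overlap enumerates recurrence correctly", {
  rec <- count_study_overlap(overlap_fixture())
  expect_equal(rec$symbol, c("B", "A", "C"))
  expect_equal(rec$n_studies_significant, c(3L, 1L, 1L))
  expect_equal(rec$significant_in[rec$symbol == "B"], "s1;s2;s3")
  expect_equal(rec$platforms[rec$symbol == "B"], "MS;Olink")
  # total distinct symbols equals union of dep sets
  expect_equal(nrow(rec), 3L)

  none <- list(make_dataset("s1", "MS", c("A"), significant = FALSE))
  expect_equal(nrow(count_study_overlap(none)), 0L)
})

test_that("select_top_deps thresholds and is monotone", {
  rec <- count_study_overlap(overlap_fixture())
  expect_equal(select_top_deps(rec, 2), "B")
  expect_setequal(select_top_deps(rec, 1), c("A", "B", "C"))
  expect_equal(select_top_deps(rec, 99), character(0))
  expect_error(select_top_deps(rec, 0), "min_studies")
  sizes <- vapply(1:4, function(k) length(select_top_deps(rec, k)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("upset_intersections groups exact membership patterns", {
  two <- list(make_dataset("s1", "MS", c("A", "B")),
              make_dataset("s2", "MS", "B"))
  up <- upset_intersections(count_study_overlap(two), top_n = 10)
  expect_setequal(up$pattern, c("s1", "s1&s2"))
  expect_equal(sum(up$count), 2L)
  expect_equal(up$count[up$pattern == "s1&s2"], 1L)

  disjoint <- list(make_dataset("s1", "MS", "A"),
                   make_dataset("s2", "MS", "B"))
  up2 <- upset_intersections(count_study_overlap(disjoint))
  expect_true(all(up2$degree == 1L))

  identical_sets <- list(make_dataset("s1", "MS", c("A", "B")),
                         make_dataset("s2", "MS", c("A", "B")))
  up3 <- upset_intersections(count_study_overlap(identical_sets))
  expect_equal(nrow(up3), 1L)
  expect_equal(up3$pattern, "s1&s2")
  expect_equal(up3$count, 2L)

  expect_error(upset_intersections(count_study_overlap(two), top_n = 0),
               "top_n")
})

test_that("upset membership matrix is written consumable", {
  rec <- count_study_overlap(overlap_fixture())
  path <- tempfile(fileext = ".tsv")
  write_upset_matrix(rec, path)
  mat <- read.delim(path)
  expect_equal(names(mat), c("symbol", "s1", "s2", "s3"))
  expect_equal(mat$s2[mat$symbol == "B"], 1L)
  expect_equal(rowSums(mat[, -1]), rec$n_studies_significant,
               ignore_attr = TRUE)
})

test_that("platform_partition splits MS vs affinity correctly", {
  rec <- count_study_overlap(overlap_fixture())
  part <- platform_partition(rec)
  expect_equal(part, c(ms_only = 2L, affinity_only = 0L, both = 1L))
  expect_equal(sum(part), nrow(rec))

  all_ms <- count_study_overlap(list(make_dataset("s1", "MS", c("A", "B"))))
  expect_equal(platform_partition(all_ms)[["affinity_only"]], 0L)
  expect_equal(platform_partition(all_ms)[["both"]], 0L)
})

test_that("direction consistency follows the sign rule", {
  ds <- list(
    make_dataset("s1", "MS", c("U", "D", "M", "Z"),
                 log2fc = c(0.5, -0.5, 0.5, 0)),
    make_dataset("s2", "MS", c("U", "D", "M"),
                 log2fc = c(0.2, -0.1, -0.2)),
    make_dataset("s3", "MS", "U", log2fc = 0.9))
  cls <- classify_direction_consistency(c("U", "D", "M", "Z", "ABSENT"), ds)
  expect_equal(cls$category[cls$symbol == "U"], "consistent_up")
  expect_equal(cls$category[cls$symbol == "D"], "consistent_down")
  expect_equal(cls$category[cls$symbol == "M"], "inconsistent")
  # zero fold-changes count toward neither direction
  expect_equal(cls$category[cls$symbol == "Z"], "unclassifiable")
  expect_equal(cls$n_zero[cls$symbol == "Z"], 1L)
  expect_equal(cls$category[cls$symbol == "ABSENT"], "unclassifiable")

  # affinity-only evidence is not classifiable (no comparable fold-change)
  aff <- list(make_dataset("o1", "Olink", "X"))
  expect_equal(classify_direction_consistency("X", aff)$category,
               "unclassifiable")
})

test_that("platform proportions count measured and directional DEPs", {
  ds <- make_dataset("s1", "MS", sprintf("P%02d", 1:10),
                     log2fc = c(1, 1, 1, -1, rep(0.5, 6)),
                     significant = c(rep(TRUE, 4), rep(FALSE, 6)))
  pp <- platform_proportions(list(ds))
  expect_equal(pp$n_measured, 10L)
  expect_equal(pp$n_up, 3L)
  expect_equal(pp$n_down, 1L)
  expect_equal(pp$prop_up, 0.3)
  expect_equal(pp$prop_down, 0.1)
  expect_true(pp$n_up + pp$n_down <= pp$n_measured)

  empty <- make_dataset("s2", "Olink", c("A", "B"), significant = FALSE)
  pp2 <- platform_proportions(list(empty))
  expect_equal(pp2$prop_up + pp2$prop_down, 0)
})

test_that("recurrence bins partition the DEP universe", {
  cfg <- sim_config(n_studies = 9,
                    platform_assignment = rep(c("MS", "Olink", "SomaScan"),
                                              c(6, 2, 1)),
                    n_proteins_universe = 500, panel_size = 250,
                    n_planted_top = 30, planted_min_recurrence = 5,
                    seed = 21)
  sim <- generate_studies(cfg)
  rec <- count_study_overlap(sim$datasets)
  s <- compile_summary(sim$datasets, min_studies = 5)
  expect_equal(s$n_single_study + s$n_mid + s$n_top, s$n_deps_total)
  expect_equal(s$n_single_study + s$n_multi_study, s$n_deps_total)
  expect_equal(sum(platform_partition(rec)), nrow(rec))
  # consistency categories partition the classifiable top set
  expect_equal(s$n_top_consistent_up + s$n_top_consistent_down +
                 s$n_top_inconsistent + s$n_top_unclassifiable, s$n_top)
})
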