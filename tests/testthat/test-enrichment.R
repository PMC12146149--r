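test_that("GMT files round-trip", {
  ann <- list(list(term_id = "T1", term_name = "first", members = c("A", "B")),
              list(term_id = "T2", term_name = "second",
                   members = c("B", "C", "D")))
  path <- tempfile(fileext = ".gmt")
  write_gmt(ann, path)
  back <- read_gmt(path)
  expect_equal(back, ann)
  writeLines("T1\tonly-two-fields", path)
  expect_error(read_gmt(path), "malformed")
})

test_that("background is the union of MS-measured symbols only", {
  ds <- list(make_dataset("m1", "MS", c("A", "B"), significant = FALSE),
             make_dataset("m2", "MS", c("B", "C"), significant = FALSE),
             make_dataset("o1", "Olink", c("D"), significant = FALSE))
  expect_equal(build_background(ds), c("A", "B", "C"))
  # union is idempotent over identical panels
  twice <- list(make_dataset("m1", "MS", c("A", "B")),
                make_dataset("m2", "MS", c("A", "B")))
  expect_equal(build_background(twice), c("A", "B"))
  expect_error(build_background(list(make_dataset("o1", "Olink", "A"))),
               "MS")
})

test_that("hypergeometric p-values match closed form and filters apply", {
  bg <- paste0("P", 1:10)
  ann <- list(list(term_id = "T1", term_name = "hit", members = bg[1:5]),
              list(term_id = "T0", term_name = "miss", members = bg[6:7]))
  res <- hypergeometric_enrichment(bg[1:5], bg, ann, filter = FALSE)
  expect_equal(res$p_value[res$term_id == "T1"], 1 / choose(10, 5),
               tolerance = 1e-12)  # C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(res$p_value[res$term_id == "T0"], 1)  # k = 0
  filt <- hypergeometric_enrichment(bg[1:5], bg, ann)
  expect_equal(filt$term_id, "T1")  # k=0 term never passes

  expect_warning(
    out <- hypergeometric_enrichment(c(bg[1], "OUTSIDE"), bg, ann,
                                     filter = FALSE),
    "outside background")
  expect_equal(unique(out$n_query), 1L)
  # both the drop and the resulting empty query warn
  expect_warning(expect_warning(
    empty <- hypergeometric_enrichment("OUTSIDE", bg, ann),
    "empty query"), "outside background")
  expect_equal(nrow(empty), 0L)
})

test_that("hypergeometric tail equals brute-force enumeration for N <= 8", {
  for (N in 3:8) {
    bg <- paste0("G", seq_len(N))
    for (K in 2:N) {
      for (n in 1:N) {
        query <- bg[seq_len(n)]
        ann <- list(list(term_id = "T", term_name = "t",
                         members = bg[seq_len(K)]))
        res <- hypergeometric_enrichment(query, bg, ann, filter = FALSE)
        k <- res$k_hits
        expect_equal(res$p_value, hyper_oracle(k, K, n, N),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric pmf sums to one and p decreases-free grows with N", {
  # oracle self-check: total mass over all achievable k equals 1
  for (case in list(c(K = 3, n = 4, N = 7), c(K = 5, n = 2, N = 8))) {
    K <- case[["K"]]; n <- case[["n"]]; N <- case[["N"]]
    ks <- max(0, n + K - N):min(K, n)
    expect_equal(sum(dhyper(ks, K, N - K, n)), 1, tolerance = 1e-12)
  }
  # with fixed k, K, n, growing the background with unannotated proteins
  # makes the full-hit query rarer: p shrinks monotonically in N
  bg8 <- paste0("G", 1:8)
  ann <- list(list(term_id = "T", term_name = "t", members = bg8[1:3]))
  q <- bg8[1:3]
  ps <- vapply(3:8, function(N)
    hypergeometric_enrichment(q, bg8[1:N], ann, filter = FALSE)$p_value,
    numeric(1))
  expect_true(all(diff(ps) <= 1e-15))  # p shrinks as unannotated N grows
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("BH-FDR across terms dominates raw p and respects term universe", {
  set.seed(77)
  bg <- paste0("B", 1:40)
  ann <- lapply(1:12, function(i)
    list(term_id = paste0("T", i), term_name = "r",
         members = sample(bg, sample(2:10, 1))))
  ann <- c(ann, list(list(term_id = "TINY", term_name = "singleton",
                          members = bg[1])))
  res <- hypergeometric_enrichment(sample(bg, 8), bg, ann, filter = FALSE)
  expect_false("TINY" %in% res$term_id)  # K < 2 excluded from universe
  expect_true(all(res$fdr >= res$p_value - 1e-15))
  expect_equal(res$fdr, bh_adjust(res$p_value), tolerance = 1e-12)
})

test_that("cluster_query separates disjoint profiles and is deterministic", {
  q <- c(paste0("A", 1:4), paste0("B", 1:4), "LONER")
  ann <- list(list(term_id = "TA", term_name = "a", members = paste0("A", 1:4)),
              list(term_id = "TB", term_name = "b", members = paste0("B", 1:4)))
  lab <- cluster_query(q, ann, k_clusters = 2, seed = 7)
  expect_equal(lab[["LONER"]], "unclustered")
  expect_equal(length(unique(lab[paste0("A", 1:4)])), 1L)
  expect_equal(length(unique(lab[paste0("B", 1:4)])), 1L)
  expect_false(lab[["A1"]] == lab[["B1"]])

  expect_equal(cluster_query(q, ann, k_clusters = 2, seed = 7), lab)
  one <- cluster_query(q, ann, k_clusters = 1, seed = 7)
  expect_equal(length(unique(one[setdiff(q, "LONER")])), 1L)
  expect_error(cluster_query(q, ann, k_clusters = 0), "k_clusters")
  expect_error(cluster_query(q, ann, k_clusters = 50), "exceeds")
})

test_that("planted annotation term attains the minimum p over the query", {
  set.seed(15)
  universe <- sprintf("U%03d", 1:200)
  planted <- universe[1:12]
  ann <- generate_annotations(universe, n_terms = 25, planted_term = planted,
                              seed = 4)
  expect_equal(ann[[1]]$members, sort(planted))
  res <- hypergeometric_enrichment(planted, universe, ann, filter = FALSE)
  expect_equal(res$term_id[which.min(res$p_value)], "TERM_PLANTED")
  # a term disjoint from the query has p = 1
  ann2 <- list(list(term_id = "D", term_name = "d",
                    members = universe[100:110]))
  expect_equal(hypergeometric_enrichment(planted, universe, ann2,
                                         filter = FALSE)$p_value, 1)
  # reproducible given seed
  expect_equal(generate_annotations(universe, 25, planted, seed = 4), ann)
})
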