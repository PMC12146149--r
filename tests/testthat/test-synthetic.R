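small_cfg <- function(...) {
  args <- list(n_studies = 8,
               platform_assignment = rep(c("MS", "Olink"), c(6, 2)),
               n_proteins_universe = 400, panel_size = 200,
               n_planted_top = 20, planted_min_recurrence = 4, seed = 7)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("generation is reproducible and respects the stated invariants", {
  cfg <- small_cfg()
  a <- generate_studies(cfg)
  b <- generate_studies(cfg)
  expect_identical(lapply(a$datasets, `[[`, "measurements"),
                   lapply(b$datasets, `[[`, "measurements"))
  expect_identical(a$truth, b$truth)

  expect_equal(length(a$truth$true_top_set), cfg$n_planted_top)
  expect_equal(rowSums(a$truth$membership),
               rep(cfg$planted_min_recurrence, cfg$n_planted_top),
               ignore_attr = TRUE)
  # planted proteins are measured wherever assigned
  for (s in seq_len(cfg$n_studies)) {
    assigned <- rownames(a$truth$membership)[a$truth$membership[, s]]
    expect_true(all(assigned %in% a$datasets[[s]]$measurements$symbol))
  }
  # affinity studies emit flags but no comparable fold-change
  plat <- vapply(a$datasets, function(d) d$meta$platform, character(1))
  for (d in a$datasets[plat != "MS"]) {
    expect_true(all(is.na(d$measurements$log2fc)))
    expect_equal(d$meta$fc_scale, "none")
  }
})

test_that("infeasible configurations are rejected up front", {
  expect_error(small_cfg(planted_min_recurrence = 9), "infeasible")
  expect_error(small_cfg(n_planted_top = 500), "infeasible")
  expect_error(sim_config(n_studies = 2, platform_assignment = "MS"),
               "length n_studies")
  expect_error(small_cfg(panel_overlap_fraction = 1.2), "\\[0, 1\\]")
})

test_that("noiseless regime recovers the planted truth exactly end to end", {
  cfg <- small_cfg(effect_sd = 0, deterministic_sig = TRUE)
  sim <- generate_studies(cfg)
  rec <- count_study_overlap(sim$datasets)
  top <- select_top_deps(rec, cfg$planted_min_recurrence)
  expect_identical(top, sim$truth$true_top_set)

  cls <- classify_direction_consistency(top, sim$datasets)
  got <- ifelse(cls$category == "consistent_up", "up",
                ifelse(cls$category == "consistent_down", "down", "?"))
  expect_identical(got, unname(sim$truth$true_direction_map[cls$symbol]))

  # forest mean signs match planted directions (a planted protein may also
  # be quantified at exactly 0 in non-assigned studies, shrinking the mean
  # toward 0 but never flipping its sign in the noiseless regime)
  ft <- forest_table(top, sim$datasets)
  expect_identical(ifelse(ft$mean_log2fc > 0, "up", "down"),
                   unname(sim$truth$true_direction_map[ft$symbol]))
})

test_that("frac_down = 0 plants no downregulated proteins", {
  cfg <- small_cfg(frac_down = 0, effect_sd = 0, deterministic_sig = TRUE)
  sim <- generate_studies(cfg)
  expect_true(all(sim$truth$true_direction_map == "up"))
  cls <- classify_direction_consistency(sim$truth$true_top_set, sim$datasets)
  expect_equal(sum(cls$category == "consistent_down"), 0L)
})

test_that("top-DEP recovery power is non-decreasing in effect size", {
  grid <- c(0.05, 0.3, 1.0)
  power <- vapply(seq_along(grid), function(gi) {
    recovered <- vapply(1:100, function(rep) {
      cfg <- sim_config(n_studies = 4, platform_assignment = rep("MS", 4),
                        n_proteins_universe = 60, panel_size = 40,
                        n_planted_top = 6, planted_min_recurrence = 3,
                        effect_size_log2 = grid[gi], effect_sd = 0.1,
                        n_case = 10, n_control = 10,
                        seed = 1000 * gi + rep)
      sim <- generate_studies(cfg)
      top <- select_top_deps(count_study_overlap(sim$datasets), 3)
      length(intersect(top, sim$truth$true_top_set)) / 6
    }, numeric(1))
    mean(recovered)
  }, numeric(1))
  expect_true(all(diff(power) >= -0.02))  # non-decreasing up to MC noise
  expect_gt(power[3], power[1])
})

test_that("generate_raw_matrix approaches planted effects as noise vanishes", {
  ab <- generate_raw_matrix(10, 10, c(A = 1, B = 0), noise_sd = 1e-6,
                            seed = 2)
  expect_equal(compute_log2fc(ab$case_values[1, ], ab$control_values[1, ],
                              "log2"), 1, tolerance = 1e-4)
  expect_identical(generate_raw_matrix(5, 5, c(A = 1), 0.5, seed = 3),
                   generate_raw_matrix(5, 5, c(A = 1), 0.5, seed = 3))
  expect_error(generate_raw_matrix(1, 5, c(A = 1), 0.5), "n_case")
})

test_that("simulation CLI writes a consumable bundle", {
  dir <- file.path(tempdir(), "clisim")
  cfgfile <- file.path(tempdir(), "simcfg.json")
  jsonlite::write_json(
    list(n_studies = 3, platform_assignment = c("MS", "MS", "Olink"),
         n_proteins_universe = 100, panel_size = 50, n_planted_top = 5,
         planted_min_recurrence = 2, effect_size_log2 = 2, effect_sd = 0.1,
         seed = 12),
    cfgfile, auto_unbox = TRUE)
  expect_message(csf_cli(c("simulate", "--config", cfgfile, "--out", dir)),
                 "wrote simulation")
  expect_true(file.exists(file.path(dir, "registry.json")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  outdir <- file.path(tempdir(), "cliover")
  expect_message(csf_cli(c("overlap", "--registry",
                           file.path(dir, "registry.json"),
                           "--min-studies", "2", "--out", outdir)),
                 "top DEPs")
  expect_true(file.exists(file.path(outdir, "overlap_table.tsv")))
  expect_true(file.exists(file.path(outdir, "upset_matrix.tsv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  top <- readLines(file.path(outdir, "top_deps.txt"))
  expect_true(all(truth$true_top_set %in% top))
  unlink(c(dir, outdir), recursive = TRUE)
})
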