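test_that("generation is deterministic and stable under experiment count growth", {
  g <- synthetic_grid()
  sp <- preset("differential_only", seed = 81)
  d1 <- generate_dataset(sp, "A", g)
  d2 <- generate_dataset(sp, "A", g)
  expect_identical(d1, d2)

  # hierarchical seeding: adding experiments does not perturb earlier ones
  sp_more <- sp
  sp_more$n_experiments_a <- sp$n_experiments_a + 5L
  d3 <- generate_dataset(sp_more, "A", g)
  expect_identical(d3$experiments[seq_along(d1$experiments)], d1$experiments)

  # different conditions draw from different streams
  db <- generate_dataset(sp, "B", g)
  expect_false(identical(lapply(d1$experiments, `[[`, "foci"),
                         lapply(db$experiments, `[[`, "foci")))
})

test_that("hit rate 1 with no noise yields exactly one focus per centre, near it", {
  g <- synthetic_grid()
  centres <- list(ground_truth_centre(c(0, 16, 8), hit_rate_a = 1,
                                      jitter_sd_mm = 5),
                  ground_truth_centre(c(-20, -20, 0), hit_rate_a = 1,
                                      jitter_sd_mm = 5))
  sp <- scenario_spec(centres, n_experiments_a = 10L,
                      noise_foci_range = c(0L, 0L), seed = 82)
  ds <- generate_dataset(sp, "A", g)
  for (e in ds$experiments) {
    expect_equal(nrow(e$foci), 2L)
    for (j in 1:2) {
      d <- sqrt(sum((e$foci[j, ] - centres[[j]]$centre_mm)^2))
      expect_lt(d, 4 * 5 + 1e-9)  # within 4 jitter sd (clipped to mask)
    }
  }
})

test_that("generated datasets satisfy all structural invariants as built", {
  g <- synthetic_grid()
  for (name in c("differential_only", "shared_activation", "null")) {
    sp <- preset(name, seed = 83)
    for (cond in c("A", "B", "diff")) {
      ds <- generate_dataset(sp, cond, g)
      ns <- vapply(ds$experiments, `[[`, integer(1), "n_subjects")
      expect_true(all(ns >= sp$n_subjects_range[1] &
                        ns <= sp$n_subjects_range[2]))
      for (e in ds$experiments) {
        expect_gt(nrow(e$foci), 0)
        expect_true(all(is.finite(e$foci)))
        expect_equal(anyDuplicated(apply(e$foci, 1, paste, collapse = ",")),
                     0L)
        # all foci inside the mask (jittered ones are resampled into it,
        # noise foci are drawn from it)
        lin <- alecontrast:::voxel_to_linear(g, mm_to_voxel(g, e$foci))
        expect_true(all(!is.na(lin) & g$mask[lin]))
      }
    }
  }
})

test_that("per-centre contributions are Binomial(n_experiments, hit_rate)", {
  g <- synthetic_grid()
  centre <- ground_truth_centre(c(0, 16, 8), hit_rate_a = 0.6)
  lo <- qbinom(0.005, 30, 0.6)
  hi <- qbinom(0.995, 30, 0.6)
  inside <- vapply(1:200, function(s) {
    sp <- scenario_spec(list(centre), n_experiments_a = 30L,
                        noise_foci_range = c(2L, 2L), seed = s)
    ds <- generate_dataset(sp, "A", g)
    hits <- sum(vapply(ds$experiments, function(e) nrow(e$foci), integer(1))
                == 3L)  # 2 noise foci + 1 centre focus when hit
    hits >= lo && hits <= hi
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})

test_that("null-preset foci are uniform over the mask (octant chi-square)", {
  g <- synthetic_grid()
  mask_mm <- voxel_to_mm(g, linear_to_voxel_r(g, g$mask_idx))
  octant <- function(mm) {
    1 + (mm[, 1] > 0) + 2 * (mm[, 2] > 0) + 4 * (mm[, 3] > 0)
  }
  expected <- tabulate(octant(mask_mm), 8) / nrow(mask_mm)
  not_rejected <- vapply(1:10, function(s) {
    sp <- preset("null", seed = 900 + s)
    ds <- generate_dataset(sp, "A", g)
    foci <- do.call(rbind, lapply(ds$experiments, `[[`, "foci"))
    counts <- tabulate(octant(foci), 8)
    suppressWarnings(stats::chisq.test(counts, p = expected)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(not_rejected), 0.9)
})

test_that("degenerate scenarios and unknown presets are rejected", {
  g <- synthetic_grid()
  sp <- scenario_spec(list(), noise_foci_range = c(0L, 0L), seed = 1)
  expect_error(generate_dataset(sp, "A", g), "empty experiments")
  outside <- scenario_spec(list(ground_truth_centre(c(500, 0, 0),
                                                    hit_rate_a = 1)),
                           seed = 1)
  expect_error(generate_dataset(outside, "A", g), "outside the mask")
  expect_error(preset("nope"), "arg")
  expect_error(scenario_spec(list(), n_experiments_a = 0), ">= 1")
})

test_that("scenario ground truth serializes to JSON", {
  sp <- preset("shared_activation", seed = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario_truth(sp, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$seed, 5L)
  expect_equal(back$centres$hit_rate_a, 0.6)
  expect_equal(back$n_experiments$A, 30L)
})
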