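test_that("default recipes carry the reference parameters", {
  r <- default_recipe("adni_like")
  expect_equal(r$n_ad, 263L); expect_equal(r$n_nc, 263L)
  expect_equal(r$seed, 42L)   # documented default seed
  hip <- r$params[r$params$region == "hippocampus" & r$params$group == "AD", ]
  expect_equal(hip$mean_left, 2933.4)
  expect_equal(hip$mean_right, 3030.7)
  expect_equal(hip$lr_correlation, 0.798)

  # implied bilateral MTL mean reproduces the reference total
  ad <- r$params[r$params$group == "AD", ]
  expect_lt(abs(sum(ad$mean_left + ad$mean_right) - 14697.2), 1.0)

  # bilateral SD of the 50/50-split regions inverts to the reference SD
  amy <- r$params[r$params$region == "amygdala" & r$params$group == "AD", ]
  bil_sd <- sqrt(amy$sd_left^2 + amy$sd_right^2 +
                 2 * amy$lr_correlation * amy$sd_left * amy$sd_right)
  expect_equal(bil_sd, 548.1, tolerance = 1e-10)

  m <- default_recipe("miriad_like")
  expect_equal(m$n_ad, 46L); expect_equal(m$n_nc, 23L)
})

test_that("calibrated between-region correlation hits the MTL total SD", {
  rho <- calibrate_region_correlation(adni_reference_params())
  expect_true(all(rho > 0 & rho < 1))
  co <- generate_cohort(cohort_recipe(20000, 20000, seed = 67,
                                      label = "cal"))
  mv <- measure_values(co, mtl_measure())
  expect_lt(abs(sd(mv$value[mv$group == "AD"]) - 2511.1) / 2511.1, 0.03)
  expect_lt(abs(sd(mv$value[mv$group == "NC"]) - 2052.8) / 2052.8, 0.03)
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  r <- cohort_recipe(5, 4, seed = 71, label = "det")
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- generate_cohort(r)
  mid <- runif(1)            # must continue the caller's stream
  b <- generate_cohort(r)
  expect_identical(a, b)
  expect_identical(mid, before)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, p1); write_cohort_csv(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- generate_cohort(cohort_recipe(0, 0, seed = 1, label = "none"))
  expect_equal(nrow(empty), 0L)
  expect_equal(n_subjects(empty), 0L)
})

test_that("a construction-sized cohort recovers the bilateral parameters", {
  co <- generate_cohort(default_recipe("adni_like", seed = 73))
  hv <- measure_values(co, region_measure("hippocampus"))
  fit_ad <- fit_gaussian(hv$value[hv$group == "AD"])
  fit_nc <- fit_gaussian(hv$value[hv$group == "NC"])
  expect_lt(abs(fit_ad$mu - 5962.1), 3 * 1025.3 / sqrt(263))
  expect_lt(abs(fit_ad$sigma - 1025.3) / 1025.3, 0.15)
  expect_lt(abs(fit_nc$mu - 7238.4), 3 * 870.0 / sqrt(263))
  expect_lt(abs(fit_nc$sigma - 870.0) / 870.0, 0.15)
})

test_that("generated left/right correlation converges to the recipe value", {
  co <- generate_cohort(cohort_recipe(10000, 0, seed = 79, label = "corr"))
  for (reg in c("hippocampus", "entorhinal")) {
    sub <- co[co$region == reg, ]
    ids <- unique(sub$subject_id)
    l <- sub$volume_mm3[match(paste(ids, "left"),
                              paste(sub$subject_id, sub$hemisphere))]
    r <- sub$volume_mm3[match(paste(ids, "right"),
                              paste(sub$subject_id, sub$hemisphere))]
    target <- adni_reference_params()[
      adni_reference_params()$region == reg &
      adni_reference_params()$group == "AD", "lr_correlation"]
    expect_lt(abs(cor(l, r) - target), 0.03)
  }
})

test_that("positivity rejection is inert at reference parameters", {
  # no draw is rejected at reference scale, so moments are untouched:
  # the generated volumes are identical to unconstrained normal draws
  # reconstructed from the same seed
  recipe <- cohort_recipe(5000, 0, seed = 83, label = "rej")
  co <- generate_cohort(recipe)
  expect_true(all(co$volume_mm3 > 0))
  hl <- co$volume_mm3[co$region == "hippocampus" & co$hemisphere == "left"]
  expect_lt(abs(mean(hl) - 2933.4) / 2933.4, 5e-3)

  # aggressive truncation still yields positive volumes (rejection path)
  params <- adni_reference_params()
  params$mean_left <- 40; params$mean_right <- 40
  params$sd_left <- 30; params$sd_right <- 30
  tight <- cohort_recipe(200, 0, params, seed = 89, label = "trunc",
                         region_correlation = c(AD = 0, NC = 0))
  expect_true(all(generate_cohort(tight)$volume_mm3 > 0))

  # hopeless parameters error out instead of looping
  params$mean_left <- -5000; params$mean_right <- -5000
  params$sd_left <- 1; params$sd_right <- 1
  broken <- cohort_recipe(3, 0, params, seed = 97, label = "bad",
                          region_correlation = c(AD = 0, NC = 0))
  expect_error(generate_cohort(broken), "rejection sampling failed")
})

test_that("invalid recipe parameters are rejected", {
  params <- adni_reference_params()
  params$lr_correlation[1] <- 1.0
  expect_error(cohort_recipe(5, 5, params), "lr_correlation")
  params <- adni_reference_params()
  params <- params[params$region != "amygdala" | params$group != "AD", ]
  expect_error(cohort_recipe(5, 5, params), "every \\(region, group\\)")
  expect_error(cohort_recipe(5, 5, region_correlation = c(AD = 2, NC = 0)),
               "region_correlation")
})

test_that("end-to-end AUC matches the fitted binormal Az at large n", {
  res <- end_to_end_power_check(default_recipe("adni_like", seed = 101),
                                cohort_recipe(5000, 5000, seed = 103,
                                              label = "big-test"))
  # reference binormal Az from the published MTL parameters (~0.842)
  ref_az <- binormal_az(gaussian_density(17943.8, 2052.8),
                        gaussian_density(14697.2, 2511.1))
  expect_lt(abs(res$auc - ref_az), 0.01)
  expect_gt(res$auc, 0.80)   # MTL-scale separation
  expect_lt(res$auc, 0.90)
})

test_that("identical class parameters drive performance to chance", {
  params <- adni_reference_params()
  nc_rows <- params$group == "NC"
  for (col in c("mean_left", "mean_right", "sd_left", "sd_right",
                "lr_correlation"))
    params[nc_rows, col] <- params[!nc_rows, col]
  res <- end_to_end_power_check(
    cohort_recipe(2000, 2000, params, seed = 107, label = "null-train",
                  region_correlation = c(AD = 0.5, NC = 0.5)),
    cohort_recipe(2000, 2000, params, seed = 109, label = "null-test",
                  region_correlation = c(AD = 0.5, NC = 0.5)))
  expect_lt(abs(res$auc - 0.5), 0.02)
  expect_lt(abs(res$report$balanced_accuracy - 0.5), 0.03)
})

test_that("extreme separation saturates sensitivity and specificity", {
  params <- adni_reference_params()
  nc_rows <- params$group == "NC"
  params[nc_rows, "mean_left"] <- params[nc_rows, "mean_left"] +
    10 * params[nc_rows, "sd_left"] * 2
  params[nc_rows, "mean_right"] <- params[nc_rows, "mean_right"] +
    10 * params[nc_rows, "sd_right"] * 2
  res <- end_to_end_power_check(
    cohort_recipe(500, 500, params, seed = 113, label = "sep-train",
                  region_correlation = c(AD = 0.5, NC = 0.5)),
    cohort_recipe(500, 500, params, seed = 127, label = "sep-test",
                  region_correlation = c(AD = 0.5, NC = 0.5)))
  expect_gt(res$report$sensitivity, 0.999)
  expect_gt(res$report$specificity, 0.999)
  expect_equal(res$auc, 1.0)
})

test_that("widening the class separation never hurts the AUC", {
  base <- adni_reference_params()
  aucs <- vapply(seq(0, 2, by = 0.5), function(k) {
    params <- base
    nc_rows <- params$group == "NC"
    params[nc_rows, "mean_left"] <- params[nc_rows, "mean_left"] * (1 + 0.05 * k)
    params[nc_rows, "mean_right"] <- params[nc_rows, "mean_right"] * (1 + 0.05 * k)
    end_to_end_power_check(
      cohort_recipe(1500, 1500, params, seed = 131, label = "grid-train",
                    region_correlation = c(AD = 0.5, NC = 0.5)),
      cohort_recipe(1500, 1500, params, seed = 137, label = "grid-test",
                    region_correlation = c(AD = 0.5, NC = 0.5)))$auc
  }, numeric(1L))
  expect_true(all(diff(aucs) > -0.005))
})
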