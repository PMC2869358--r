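test_that("population presets carry the stated ranges and ratio property", {
  r6 <- population_ranges(6)
  r10 <- population_ranges(10)
  r20 <- population_ranges(20)
  expect_equal(r6$normal_prolif, c(0.05, 0.15))
  expect_equal(r10$normal_prolif, c(0.03, 0.09))
  expect_equal(r20$normal_prolif, c(0.015, 0.045))
  for (r in list(r6, r10, r20)) {
    expect_equal(r$tumor_prolif, c(0.3, 0.9))
    expect_equal(r$normal_death, c(0.0024, 0.0048))
    expect_equal(r$tumor_death, c(0.0001, 0.0002))
    # quotient of range midpoints reproduces the ratio label
    expect_equal(mean(r$tumor_prolif) / mean(r$normal_prolif),
                 r$ratio_label)
  }
  expect_error(population_ranges(7), "6, 10, 20")
})

test_that("sampled parameters stay inside the population ranges", {
  set.seed(1)
  r <- population_ranges(10)
  for (i in 1:500) {
    pn <- sample_population_params(r, "normal")
    expect_gte(pn$prolif_prob, 0.03); expect_lte(pn$prolif_prob, 0.09)
    expect_gte(pn$death_prob, 0.0024); expect_lte(pn$death_prob, 0.0048)
    pt <- sample_population_params(r, "tumor")
    expect_gte(pt$prolif_prob, 0.3); expect_lte(pt$prolif_prob, 0.9)
  }
  expect_equal(sample_population_params(r, "normal",
                                        50L)$generation_potential, 50L)
  expect_equal(sample_population_params(r, "tumor")$generation_potential, -1L)
})

test_that("inheritance skews symmetrically, clips, and decrements potential", {
  r <- population_ranges(6)
  set.seed(2)
  parent <- sample_population_params(r, "normal")

  d0 <- inherit_params(parent, r, skew_frac = 0)
  expect_equal(d0$prolif_prob, parent$prolif_prob)
  expect_equal(d0$death_prob, parent$death_prob)
  expect_equal(d0$generation_potential, parent$generation_potential - 1L)

  top <- parent; top$prolif_prob <- 0.15
  for (i in 1:50) {
    expect_lte(inherit_params(top, r, skew_frac = 0.5)$prolif_prob, 0.15)
  }

  # Monte-Carlo: symmetric skew leaves the mean within 1% of the parent
  mid <- parent; mid$prolif_prob <- 0.10; mid$death_prob <- 0.0036
  set.seed(3)
  draws <- replicate(10000, inherit_params(mid, r, 0.1)$prolif_prob)
  expect_lt(abs(mean(draws) - 0.10) / 0.10, 0.01)
})

test_that("intrinsic death follows its probability and senescence rule", {
  p1 <- list(death_prob = 1, generation_potential = 10L)
  p0 <- list(death_prob = 0, generation_potential = 10L)
  expect_true(all(replicate(20, intrinsic_death(p1))))
  expect_false(any(replicate(20, intrinsic_death(p0))))

  spent <- list(death_prob = 0, generation_potential = 0L)
  expect_true(intrinsic_death(spent, age = 101L, senescence_age = 100L))
  expect_false(intrinsic_death(spent, age = 50L, senescence_age = 100L))

  set.seed(4)
  p <- list(death_prob = 0.003, generation_potential = 10L)
  hits <- sum(stats::runif(100000) < p$death_prob)  # same Bernoulli model
  rate <- mean(replicate(20000, intrinsic_death(p)))
  se <- sqrt(0.003 * 0.997 / 20000)
  expect_lt(abs(rate - 0.003), 3 * se)
  expect_lt(abs(hits / 100000 - 0.003), 3 * sqrt(0.003 * 0.997 / 100000))
})

test_that("tumorigenesis requires losing repair first and is irreversible", {
  r <- population_ranges(6)
  cell <- sample_population_params(r, "normal")

  expect_identical(mutate_step(cell, 0, r)$protocols_intact,
                   cell$protocols_intact)

  # while repair survives the checkpoint, every other loss is repaired
  set.seed(5)
  kept <- replicate(200, {
    out <- mutate_step(cell, 0.5, r)
    !out$protocols_intact[["repair"]] ||
      all(out$protocols_intact[c("apoptosis", "proliferation_suppression",
                                 "distance_regulation")])
  })
  expect_true(all(kept))

  # all four lost -> tumor with resampled tumor-range parameters
  gone <- cell
  gone$protocols_intact[] <- c(FALSE, TRUE, TRUE, TRUE)
  gone$protocols_intact[["repair"]] <- FALSE
  set.seed(6)
  became <- replicate(500, {
    out <- mutate_step(gone, 0.9, r)
    if (identical(out$phenotype, "tumor")) out$prolif_prob else NA_real_
  })
  became <- became[!is.na(became)]
  expect_gt(length(became), 0)
  expect_true(all(became >= 0.3 & became <= 0.9))

  tum <- sample_population_params(r, "tumor")
  expect_error(mutate_step(tum, 0.1, r), "back-mutation")
})

test_that("division respects space rules for normal and tumor cells", {
  cfg <- test_config(extents = c(5L, 5L, 5L))

  st <- full_state(c(5L, 5L, 5L), prolif_n = 0)
  expect_null(attempt_division(st, c(2L, 2L, 2L), cfg)$daughter)

  # normal with certain division but no free radius-1 site: no division
  st2 <- full_state(c(5L, 5L, 5L))
  i <- site_index(st2, c(2L, 2L, 2L))
  st2$prolif[i] <- 1
  expect_null(attempt_division(st2, c(2L, 2L, 2L), cfg)$daughter)

  # tumor with full radius 1 but a free radius-2 site divides there
  st3 <- full_state(c(5L, 5L, 5L), tumor_radius = 0L, prolif_t = 1)
  hole <- c(0L, 2L, 2L)  # Chebyshev distance 2 from the center
  st3$phen[site_index(st3, hole)] <- 0L
  set.seed(7)
  out <- attempt_division(st3, c(2L, 2L, 2L), cfg)
  expect_equal(out$daughter, hole)
  expect_equal(sum(out$state$phen == 2L), 2L)

  # exhausted generation potential blocks normal division
  st4 <- sim_state(c(5L, 5L, 5L))
  st4 <- place_cell(st4, c(2L, 2L, 2L), "normal", prolif = 1, genpot = 0L)
  expect_null(attempt_division(st4, c(2L, 2L, 2L), cfg)$daughter)
})

test_that("planting swaps exactly one cell for a tumor cell", {
  cfg <- test_config(extents = c(6L, 6L, 6L))
  st <- full_state(c(6L, 6L, 6L))
  set.seed(8)
  planted <- plant_tumor(st, cfg)
  expect_equal(state_counts(planted)[["tumor"]], 1L)
  expect_equal(occupancy(planted, "any"), 1)  # membrane still full
  ctr <- site_index(st, c(3L, 3L, 3L))
  expect_equal(planted$phen[ctr], 2L)
  expect_gte(planted$prolif[ctr], 0.3)
  expect_error(plant_tumor(sim_state(c(4L, 4L, 4L)), cfg), "empty")
})
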