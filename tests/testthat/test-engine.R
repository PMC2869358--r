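test_that("a single founder fills a small membrane to confluence", {
  cfg <- test_config(extents = c(5L, 5L, 5L))
  g <- grow_to_confluence(cfg, seed = 1, record = TRUE)
  expect_true(g$confluent)
  expect_equal(state_counts(g$state)[["normal"]], 125L)
  expect_equal(occupancy(g$state), 1)

  # occupancy is (nearly always) non-decreasing on the way up
  ups <- sapply(1:20, function(s) {
    gg <- grow_to_confluence(cfg, seed = 100 + s, record = TRUE)
    n <- gg$series[, "n_normal"]
    mean(diff(n) >= 0)
  })
  expect_gte(mean(ups), 0.95)
})

test_that("zero proliferation hits the growth cap with a warning", {
  cfg <- test_config(extents = c(4L, 4L, 4L),
                     ranges = list(normal_prolif = c(0, 0),
                                   tumor_prolif = c(0.3, 0.9),
                                   normal_death = c(0, 0),
                                   tumor_death = c(0.0001, 0.0002)),
                     growth_cap = 50L)
  expect_warning(g <- grow_to_confluence(cfg, seed = 2), "cap")
  expect_false(g$confluent)
  expect_equal(state_counts(g$state)[["normal"]], 1L)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- test_config(extents = c(10L, 10L, 10L))
  a <- sim_run(cfg, seed = 11, record = TRUE)
  b <- sim_run(cfg, seed = 11, record = TRUE)
  expect_identical(a$series, b$series)
  expect_identical(a$state, b$state)
  expect_identical(a$outcome, b$outcome)
})

test_that("the confluent all-normal system is homeostatic", {
  cfg <- test_config(extents = c(10L, 10L, 10L))
  g <- grow_to_confluence(cfg, seed = 12)
  set.seed(12)
  h <- sim_step(g$state, cfg, steps = 200, rescue = TRUE)
  n <- h$series[, "n_normal"]
  expect_gte(min(n), 0.97 * 1000)       # stable within turnover noise
  expect_equal(sum(h$series[, "n_tumor"]), 0)
  expect_equal(sum(h$series[, "deaths_signal_normal"]), 0)  # no signaling
})

test_that("with rescue off a planted tumor takes over", {
  cfg <- test_config(extents = c(10L, 10L, 10L), please_die = FALSE,
                     im_dying = FALSE, max_steps = 150L)
  r <- sim_run(cfg, seed = 13, record = TRUE)
  expect_identical(r$outcome, "timeout")
  tum <- r$series$battle[, "n_tumor"]
  expect_gt(r$final_tumor_frac, 0.05)
  expect_gt(tum[length(tum)], tum[1L])

  # tumor occupancy grows in expectation across seeded runs
  finals <- sapply(1:20, function(s) {
    sim_run(cfg, seed = 200 + s)$final_tumor_frac
  })
  expect_gt(mean(finals), 0.05)
  expect_gte(mean(finals > 1 / 1000), 0.95)
})

test_that("no cell ever reverts from tumor to normal along a trajectory", {
  cfg <- test_config(extents = c(8L, 8L, 8L), please_die = FALSE,
                     im_dying = FALSE)
  g <- grow_to_confluence(cfg, seed = 14)
  set.seed(14)
  st <- plant_tumor(g$state, cfg)
  seen_tumor <- integer(0)
  for (k in 1:40) {
    out <- sim_step(st, cfg, steps = 1L, rescue = FALSE, record = FALSE)
    st <- out$state
    now_tumor <- st$id[st$phen == 2L]
    now_normal <- st$id[st$phen == 1L]
    expect_length(intersect(seen_tumor, now_normal), 0L)
    seen_tumor <- union(seen_tumor, now_tumor)
  }
  expect_gt(length(seen_tumor), 1L)
})

test_that("site exclusivity and count bookkeeping hold after stepping", {
  cfg <- test_config(extents = c(8L, 8L, 8L))
  r <- sim_run(cfg, seed = 15, record = TRUE)
  st <- r$state
  expect_true(all(st$phen %in% 0:2))
  occ <- st$phen != 0L
  expect_true(all(st$id[occ] > 0L))
  expect_false(any(duplicated(st$id[occ])))
  s <- r$series$battle
  expect_true(all(s[, "n_normal"] + s[, "n_tumor"] + s[, "n_free"] == 512))
})

test_that("outcome classification matches the success definition", {
  classify <- rescuesim:::classify_outcome
  expect_equal(classify(0L, 800L, 1000L, 0.5, FALSE), "success")
  expect_equal(classify(0L, 400L, 1000L, 0.5, FALSE), "collapse")
  expect_equal(classify(5L, 900L, 1000L, 0.5, TRUE), "timeout")
  expect_equal(classify(5L, 0L, 1000L, 0.5, FALSE), "collapse")
  expect_equal(classify(0L, 500L, 1000L, 0.5, TRUE), "success")  # boundary
})

test_that("please-die alone only reaches the tumor periphery", {
  # two-shell tumor: a 7-cube blob whose core is 3 Chebyshev shells from any
  # normal cell; with death reports disabled the please-die field (radius 1)
  # can never touch cells deeper than one shell past the boundary
  cfg <- test_config(extents = c(11L, 11L, 11L), im_dying = FALSE)
  st <- full_state(c(11L, 11L, 11L), tumor_radius = 3L)
  set.seed(16)
  out <- sim_step(st, cfg, steps = 6L, rescue = TRUE)
  s <- out$state
  r_pd <- cfg$signals$normal_please_die[1L]
  tumors <- which(s$phen == 2L)
  expect_gt(length(tumors), 0L)
  dist_to_normal <- min_cheb_dist(s, 2L, 1L)
  deep <- dist_to_normal > r_pd + 1L
  expect_true(any(deep))
  expect_true(all(s$acc_a[tumors][deep] == 0))
  # and the periphery is being removed
  expect_gt(sum(out$series[, "deaths_signal_tumor"]), 0)
  expect_equal(sum(out$series[, "emissions_im_dying"]), 0)
})

test_that("fully non-compliant tumors make the rescue inert", {
  cfg <- test_config(extents = c(10L, 10L, 10L), ignore_prob = 1,
                     fail_emit_prob = 1, max_steps = 100L)
  r <- sim_run(cfg, seed = 17, record = TRUE)
  expect_false(r$success)
  expect_equal(sum(r$series$battle[, "deaths_signal_tumor"]), 0)
  expect_gt(r$final_tumor_frac, 0)
})

test_that("the combined protocol removes a young tumor and spares tissue", {
  cfg <- test_config(extents = c(12L, 12L, 12L))
  runs <- lapply(1:10, function(s) sim_run(cfg, seed = 300 + s))
  succ <- vapply(runs, `[[`, logical(1L), "success")
  expect_gte(mean(succ), 0.7)
  fin <- vapply(runs, `[[`, numeric(1L), "final_normal_frac")
  expect_true(all(fin[succ] >= 0.5 * vapply(runs, `[[`, numeric(1L),
                                            "baseline_normal")[succ] / 12^3))
})
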