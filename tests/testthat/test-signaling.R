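test_that("received strength decays linearly and vanishes beyond the radius", {
  expect_equal(received_strength(2, 1, 0), 2)
  expect_equal(received_strength(5, 3, 4), 0)  # d = r + 1 -> zero
  expect_equal(received_strength(3, 2, 1), 2)
  expect_equal(received_strength(1, 1, 1), 0.5)

  # monotonicity against a brute-force table over many configurations
  for (s in c(1, 2, 3)) {
    for (r in 0:3) {
      v <- received_strength(s, r, 0:(r + 2))
      expect_true(all(diff(v) <= 0))
      expect_equal(v[1L], s)
      expect_true(all(v[(r + 2):(r + 3)] == 0))
      ve <- received_strength(s, r, 0:(r + 2), decay = "exponential")
      expect_true(all(diff(ve) <= 0))
      expect_true(all(ve[(r + 2):(r + 3)] == 0))
    }
  }
  expect_error(received_strength(1, 1, -1), "non-negative")
})

test_that("spatial violation detects adjacent tumors only", {
  st <- full_state(c(7L, 7L, 7L), tumor_radius = 0L)  # tumor at center (3,3,3)
  expect_true(detect_spatial_violation(st, c(2L, 3L, 3L)))
  expect_false(detect_spatial_violation(st, c(0L, 3L, 3L)))  # distance 3
  expect_error(detect_spatial_violation(st, c(3L, 3L, 3L)), "normal")
  allnorm <- full_state(c(5L, 5L, 5L))
  expect_false(detect_spatial_violation(allnorm, c(2L, 2L, 2L)))
})

test_that("please-die deposits land on occupied neighbors with decay", {
  cfg <- test_config(signal_set = 2L)  # please die radius 1, strength 1
  st <- full_state(c(5L, 5L, 5L), tumor_radius = 0L)
  dep <- emit_please_die(st, c(2L, 2L, 3L), cfg)
  expect_equal(nrow(dep), 26L)
  expect_true(all(dep$amount == 0.5))  # d = 1 under linear decay
  expect_false(site_index(st, c(2L, 2L, 3L)) %in% dep$site)  # emitter excluded

  lone <- place_cell(sim_state(c(5L, 5L, 5L)), c(2L, 2L, 2L), "normal")
  expect_equal(nrow(emit_please_die(lone, c(2L, 2L, 2L), cfg)), 0L)
  expect_error(emit_please_die(st, c(2L, 2L, 2L), cfg), "normal")
})

test_that("death reports use phenotype-specific parameters and can fail", {
  st <- full_state(c(7L, 7L, 7L), tumor_radius = 1L)
  cfg5 <- test_config(signal_set = 5L)

  # dying tumor, set 5: radius 2 strength 3
  set.seed(9)
  dep_t <- emit_im_dying(st, c(3L, 3L, 3L), cfg5)
  d <- pmax(abs(dep_t$x - 3), pmax(abs(dep_t$y - 3), abs(dep_t$z - 3)))
  expect_equal(sort(unique(d)), c(1, 2))
  expect_equal(unique(dep_t$amount[d == 1]), 2)  # 3 * (1 - 1/3)
  expect_equal(unique(dep_t$amount[d == 2]), 1)

  # dying normal, set 5: radius 1 strength 2
  dep_n <- emit_im_dying(st, c(0L, 0L, 0L), cfg5)
  expect_equal(nrow(dep_n), 7L)
  expect_equal(unique(dep_n$amount), 1)

  cfg_f <- test_config(signal_set = 5L, fail_emit_prob = 1)
  for (i in 1:10) {
    expect_equal(nrow(emit_im_dying(st, c(3L, 3L, 3L), cfg_f)), 0L)
  }
  # normals always report, whatever f
  expect_gt(nrow(emit_im_dying(st, c(0L, 0L, 0L), cfg_f)), 0L)
})

test_that("signal totals per emission are bounded by strength times receivers", {
  cfg <- test_config(signal_set = 4L)  # all signals 1/3
  st <- full_state(c(5L, 5L, 5L), tumor_radius = 0L)
  dep <- emit_please_die(st, c(2L, 2L, 3L), cfg)
  expect_lte(sum(dep$amount), 3 * nrow(dep))
})

test_that("accumulator fold matches an independent recursive oracle", {
  expect_equal(apply_deposits(3, c(2, 1), rho = 1), 6)
  expect_equal(apply_deposits(100, 2, rho = 0), 2)

  set.seed(10)
  deposits <- replicate(50, stats::runif(sample(0:3, 1), 0, 2),
                        simplify = FALSE)
  oracle <- function(seq, rho) {
    if (length(seq) == 0L) return(0)
    rho * oracle(seq[-length(seq)], rho) + sum(seq[[length(seq)]])
  }
  for (rho in c(0, 0.5, 0.9, 1)) {
    acc <- 0
    for (d in deposits) acc <- apply_deposits(acc, d, rho)
    expect_equal(acc, oracle(deposits, rho))
  }
  expect_error(apply_deposits(0, 1, rho = 1.5), "rho")
})

test_that("responses pick the single highest-priority action", {
  cfg <- test_config()  # high_tumor 1, high_normal 4, lows 0.5, counts 1/1
  expect_equal(respond("tumor", 1.2, requests = 1L, config = cfg), "apoptose")
  expect_equal(respond("tumor", 1.2, requests = 0L, config = cfg), "none")
  expect_equal(respond("tumor", 0.9, requests = 5L, config = cfg), "none")
  expect_equal(respond("normal", 4.5, requests = 2L, config = cfg),
               "apoptose")
  expect_equal(respond("normal", 0.2, acc_repop = 0.7, config = cfg),
               "accelerate")
  expect_equal(respond("normal", 0.7, acc_repop = 0, config = cfg),
               "emit_early")
  expect_equal(respond("normal", 0.7, acc_repop = 0.7, config = cfg),
               "accelerate")  # acceleration shadows priming
  expect_equal(respond("normal", 0.1, config = cfg), "none")

  # deterministic resistance: six distinct requests needed at pair 6/16
  cfg6 <- test_config(det_counts = c(tumor = 6L, normal = 16L))
  expect_equal(respond("tumor", 10, requests = 5L, config = cfg6), "none")
  expect_equal(respond("tumor", 10, requests = 6L, config = cfg6),
               "apoptose")
})
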