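test_that("metabolic rate: baseline, cold elevation, speed response", {
  m <- metabolic_model()
  # at the reference temperature and the speed floor the exponential is 1
  expect_equal(as.numeric(metabolic_rate(m$u_min, m$T_ref, m)),
               m$R0 + m$c_speed * m$u_min^m$p)
  # colder at depth costs more (coldest vs warmest biome minimum temps)
  expect_gt(metabolic_rate(1.2, 7.4, m), metabolic_rate(1.2, 10.7, m))
  # increasing in speed, non-increasing in temperature below T_ref
  expect_gt(metabolic_rate(2, 12, m), metabolic_rate(1, 12, m))
  expect_gt(metabolic_rate(1, 6, m), metabolic_rate(1, 12, m))
  # formula self-consistency on random inputs
  set.seed(3)
  u <- stats::runif(50, 0, 3); tt <- stats::runif(50, 2, 25)
  manual <- (m$R0 + m$c_speed * pmax(u, m$u_min)^m$p) *
    exp(m$beta * pmax(0, m$T_ref - tt))
  expect_equal(as.numeric(metabolic_rate(u, tt, m)), manual,
               tolerance = 1e-12)
  expect_error(metabolic_rate(NA, 10, m), "non-finite")
  # clamping outside the valid range is flagged
  expect_true(attr(metabolic_rate(10, 10, m), "clamped"))
})

test_that("constant-rate dive cost is a pure unit conversion", {
  m300 <- metabolic_model(R0 = 300, c_speed = 0, u_min = 0)
  # 40 samples at 30 s = 20 min; bottom phase 24 samples = 12 min
  depth <- c(seq(40, 180, length.out = 8), rep(200, 24),
             seq(180, 40, length.out = 8))
  s <- make_series(depth = depth, temp = rep(18, 40))
  dv <- data.frame(dive_id = 1L, start_idx = 1L, end_idx = 40L,
                   total_duration_min = 20, bottom_duration_min = 12)
  en <- dive_energetics(dv, s, m300)
  expect_equal(en$cost_mgO2kg, 100)
  expect_equal(en$cost_rate, 5)
  expect_equal(en$profitability, 12 / 100)
})

test_that("cost, rate and profitability identities hold on pipeline dives", {
  s <- simulate_tag_series(cold_scenario(), cold_behavior(6))
  res <- run_dive_pipeline(s)
  dv <- res$dives
  expect_gt(nrow(dv), 10)
  expect_true(all(dv$cost_mgO2kg > 0))
  expect_equal(dv$cost_rate * dv$total_duration_min, dv$cost_mgO2kg,
               tolerance = 1e-12)
  expect_equal(dv$profitability * dv$cost_mgO2kg, dv$bottom_duration_min,
               tolerance = 1e-12)
})

test_that("phase costs are exactly additive", {
  m <- metabolic_model()
  s <- simulate_tag_series(cold_scenario(), cold_behavior(8))
  mld <- estimate_mld_daily(s)
  dv <- segment_dives(extract_dives(s, mld), s)[1:5, ]
  en <- dive_energetics(dv, s, m)
  for (i in 1:5) {
    idx <- dv$start_idx[i]:dv$end_idx[i]
    z <- s$records$depth_m[idx]; tt <- s$records$temp_c[idx]
    n <- length(z); dt <- s$interval_s
    v <- numeric(n)
    v[1] <- abs(z[2] - z[1]) / dt; v[n] <- abs(z[n] - z[n - 1]) / dt
    if (n > 2) v[2:(n - 1)] <- abs(z[3:n] - z[1:(n - 2)]) / (2 * dt)
    mr <- metabolic_rate(v / s$fish_length, tt, m)
    ph <- rep("bottom", n)
    rel_bs <- dv$bot_start_idx[i] - dv$start_idx[i] + 1
    rel_be <- dv$bot_end_idx[i] - dv$start_idx[i] + 1
    if (rel_bs > 1) ph[1:(rel_bs - 1)] <- "descent"
    if (rel_be < n) ph[(rel_be + 1):n] <- "ascent"
    phase_sum <- sum(tapply(mr, ph, sum)) * dt / 3600
    expect_equal(phase_sum, en$cost_mgO2kg[i], tolerance = 1e-12)
  }
})

test_that("cold water makes a geometrically matched dive costlier", {
  depth <- c(seq(40, 200, length.out = 9), rep(210, 20),
             seq(200, 40, length.out = 9))
  m <- metabolic_model()
  mk <- function(sc) {
    s <- make_series(depth = depth,
                     temp = scenario_temperature(sc, depth),
                     lat = sc$latitude, lon = sc$longitude)
    dv <- data.frame(dive_id = 1L, start_idx = 1L, end_idx = 38L,
                     total_duration_min = 19, bottom_duration_min = 10)
    dive_energetics(dv, s, m)
  }
  cold <- mk(cold_scenario())
  warm <- mk(warm_scenario())
  expect_gt(cold$cost_rate, warm$cost_rate)
  expect_gt(warm$profitability, cold$profitability)
})

test_that("hypothetical dive to the observed depth is the identity", {
  m <- metabolic_model()
  tp <- function(z) scenario_temperature(cold_scenario(), z)
  obs <- list(start_depth = 39, max_depth = 210, descent_rate = 1,
              ascent_rate = 1, bottom_duration_min = 10)
  h <- hypothetical_dive_comparison(obs, 210, tp, m, 0.8)
  expect_equal(h$rate_ratio, 1, tolerance = 1e-9)
  expect_equal(h$cost_ratio, 1, tolerance = 1e-9)
  expect_equal(h$equivalent_bottom_fraction, 1, tolerance = 1e-9)
  expect_false(h$infeasible)
  expect_error(hypothetical_dive_comparison(obs, 100, tp, m, 0.8), ">=")
  expect_error(hypothetical_dive_comparison(
    obs, 400, function(z) ifelse(z > 300, NA_real_, 10), m, 0.8),
    "undefined")
})

test_that("deeper targets in a cold-at-depth column cost more", {
  m <- metabolic_model()
  tp <- function(z) scenario_temperature(cold_scenario(), z)
  obs <- list(start_depth = 39, max_depth = 210, descent_rate = 1,
              ascent_rate = 1, bottom_duration_min = 10)
  h4 <- hypothetical_dive_comparison(obs, 400, tp, m, 0.8)
  expect_gt(h4$cost_ratio, 1)
  expect_gt(h4$rate_ratio, 1)
  # cost_ratio strictly increasing, equivalent fraction strictly
  # decreasing, until the travel alone exceeds the observed cost
  targets <- c(250, 300, 350, 400, 450, 500, 600)
  hh <- lapply(targets, function(td)
    hypothetical_dive_comparison(obs, td, tp, m, 0.8))
  cr <- vapply(hh, `[[`, numeric(1), "cost_ratio")
  expect_true(all(diff(cr) > 0))
  fr <- vapply(hh, `[[`, numeric(1), "equivalent_bottom_fraction")
  inf <- vapply(hh, `[[`, logical(1), "infeasible")
  feas <- which(!inf)
  expect_true(all(diff(fr[feas]) < 0))
  expect_true(any(inf))
  expect_true(all(inf[seq_along(inf) >= min(which(inf))])) # once infeasible, stays
})

test_that("two-layer piecewise-constant costs match the closed form", {
  m <- metabolic_model()
  tp_step <- function(z) ifelse(z < 100, 16, 8)
  obs <- list(start_depth = 40, max_depth = 200, descent_rate = 1,
              ascent_rate = 1, bottom_duration_min = 10)
  h <- hypothetical_dive_comparison(obs, 400, tp_step, m, 0.8)
  mr_warm <- as.numeric(metabolic_rate(1 / 0.8, 16, m))
  mr_cold <- as.numeric(metabolic_rate(1 / 0.8, 8, m))
  mr_bot <- as.numeric(metabolic_rate(m$u_min, 8, m)) / 60
  cost_of <- function(D)
    2 * (mr_warm * 60 + mr_cold * (D - 100)) / 3600 + mr_bot * 10
  expect_equal(h$cost_ratio, cost_of(400) / cost_of(200), tolerance = 1e-6)
})

test_that("closed-form cost-equivalent duration matches bisection", {
  m <- metabolic_model()
  tp <- function(z) scenario_temperature(cold_scenario(), z)
  obs <- list(start_depth = 39, max_depth = 210, descent_rate = 1,
              ascent_rate = 1, bottom_duration_min = 10)
  for (td in c(250, 300, 350, 420)) {
    h <- hypothetical_dive_comparison(obs, td, tp, m, 0.8)
    o <- seatag:::idealized_dive_cost(39, 210, 1, 1, 10, tp, m, 0.8)
    hy <- seatag:::idealized_dive_cost(39, td, 1, 1, 10, tp, m, 0.8)
    b_oracle <- oracle_bisect_bottom(o$total_cost, hy$travel_cost,
                                     hy$bottom_rate_per_min)
    if (is.na(b_oracle)) {
      expect_true(h$infeasible)
    } else {
      expect_lte(abs(h$equivalent_bottom_fraction * 10 - b_oracle), 1 / 60)
    }
  }
  # travel alone exceeding the observed cost is infeasible
  eq <- cost_equivalent_duration(50, 80, 5, 10)
  expect_true(eq$infeasible)
})
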