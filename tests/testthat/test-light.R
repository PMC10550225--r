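# crafted fish-day: repeated vertical sweeps through the midday window with
# light evaluated from the scenario's noiseless Beer-Lambert model at the
# actual timestamps
sweep_series <- function(scenario, z_max = 300, rate = 0.35,
                         interval = 30) {
  date <- as.Date("2004-06-15")
  one_leg <- seq(2, z_max, by = rate * interval)
  depth <- rep(c(one_leg, rev(one_leg)), length.out = 240)
  s <- make_series(depth = depth, lat = scenario$latitude,
                   lon = scenario$longitude, date = date,
                   interval = interval)
  s$records$temp_c <- scenario_temperature(scenario, depth)
  s$records$light <- scenario_light(scenario, depth, s$records$timestamp)
  s
}

test_that("a constant-K water column is recovered in every bin", {
  sc <- build_scenario(k0 = 0.041, latitude = 45, longitude = 230)
  s <- sweep_series(sc)
  prof <- build_attenuation_profile(s, as.Date("2004-06-15"))
  expect_true(all(abs(prof$bins$k_per_m - 0.041) < 1e-3))
  expect_equal(prof$epipelagic_mean_k, 0.041, tolerance = 1e-2)
})

test_that("an e-fold drop over a 25-m step gives k = 0.04 exactly", {
  depth <- rep(seq(0, 250, by = 25), 10)
  s <- make_series(depth = depth, light = 18 - 0.04 * depth)
  prof <- build_attenuation_profile(s, as.Date("2004-06-15"))
  expect_true(all(abs(prof$bins$k_per_m - 0.04) < 1e-12))
})

test_that("DCM and scattering-layer maxima appear at their true depths", {
  sc <- build_scenario(k0 = 0.03, latitude = 30, longitude = 210,
    components = list(
      attenuation_component("dcm", peak_k = 0.03, width = 20,
                            center_depth = 90),
      attenuation_component("scattering_layer", peak_k = 0.02, width = 30,
                            center_depth = 250)))
  prof <- build_attenuation_profile(sweep_series(sc), as.Date("2004-06-15"))
  b <- prof$bins
  shallow <- b[b$depth_m >= 40 & b$depth_m <= 150, ]
  deep <- b[b$depth_m >= 180 & b$depth_m <= 290, ]
  expect_lte(abs(shallow$depth_m[which.max(shallow$k_per_m)] - 90), 10)
  expect_lte(abs(deep$depth_m[which.max(deep$k_per_m)] - 250), 10)
})

test_that("profile preconditions raise informative errors", {
  s <- make_series(depth = rep(c(5, 25), 60))
  expect_error(build_attenuation_profile(s, as.Date("2004-06-15")),
               "depth span")
  s2 <- make_series(depth = rep(c(5, 100), 60), light = rep(0, 120))
  expect_error(build_attenuation_profile(s2, as.Date("2004-06-15")),
               "all-dark")
  s3 <- sweep_series(build_scenario())
  expect_error(build_attenuation_profile(s3, as.Date("2004-07-01")),
               "no position")
})

test_that("QC flags bad profiles and passes clean ones", {
  # 60% negative-k bins fail the negative-k rule
  p_bad <- make_profile(seq(25, 205, by = 10),
                        c(rep(-0.01, 11), rep(0.03, 8)))
  expect_false(qc_profile(p_bad)$qc_pass)
  expect_true("negative-k" %in% qc_profile(p_bad)$qc_fail)

  p_good <- make_profile(seq(25, 205, by = 10), rep(0.035, 19))
  expect_true(qc_profile(p_good)$qc_pass)

  p_few <- make_profile(c(25, 35, 45), rep(0.03, 3))
  expect_true("too-few-bins" %in% qc_profile(p_few)$qc_fail)

  p_jump <- make_profile(seq(25, 205, by = 10),
                         c(rep(0.035, 10), 0.2, rep(0.035, 8)))
  expect_true("jump" %in% qc_profile(p_jump)$qc_fail)
})

test_that("QC pass rate on simulated days is high", {
  pass <- vapply(1:20, function(seed) {
    s <- simulate_tag_series(warm_scenario(), warm_behavior(seed))
    qc_profile(build_attenuation_profile(s, s$positions$date[1],
                                         dcm_table = default_dcm_table())
    )$qc_pass
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("detector semantics: monotone profiles, short profiles, cutoffs", {
  # monotonically decreasing k below the cutoff: no detection
  p1 <- qc_profile(make_profile(seq(25, 255, by = 10),
                                seq(0.05, 0.027, length.out = 24)))
  d1 <- detect_scattering_overlap(p1)
  expect_true(d1$evaluated)
  expect_false(d1$overlap)

  # profile not reaching the cutoff: not evaluated (distinct from FALSE)
  p2 <- qc_profile(make_profile(seq(25, 155, by = 10), rep(0.035, 14)))
  d2 <- detect_scattering_overlap(p2)
  expect_false(d2$evaluated)
  expect_true(is.na(d2$overlap))

  # QC failure also yields not-evaluated
  p3 <- make_profile(seq(25, 255, by = 10), rep(0.035, 24))
  p3$qc_pass <- FALSE
  expect_false(detect_scattering_overlap(p3)$evaluated)

  # a clear deep bump is found, never shallower than the cutoff
  k <- 0.035 + 0.02 * exp(-(seq(25, 255, by = 10) - 230)^2 / (2 * 25^2))
  p4 <- qc_profile(make_profile(seq(25, 255, by = 10), k))
  d4 <- detect_scattering_overlap(p4)
  expect_true(d4$overlap)
  expect_true(all(d4$peak_depths > d4$cutoff))
  expect_lte(abs(d4$peak_depths[1] - 230), 10)
})

test_that("detection is invariant to rescaling irradiance", {
  s <- simulate_tag_series(warm_scenario(), warm_behavior(4))
  p1 <- qc_profile(build_attenuation_profile(s, s$positions$date[1],
                                             dcm_table = default_dcm_table()))
  s2 <- s
  s2$records$light <- s$records$light + log(37) # 37x brighter sensor
  p2 <- qc_profile(build_attenuation_profile(s2, s2$positions$date[1],
                                             dcm_table = default_dcm_table()))
  expect_equal(p1$bins$k_per_m, p2$bins$k_per_m, tolerance = 1e-12)
  d1 <- detect_scattering_overlap(p1)
  d2 <- detect_scattering_overlap(p2)
  expect_identical(d1$overlap, d2$overlap)
  expect_identical(d1$peak_depths, d2$peak_depths)
})

test_that("detection sensitivity is non-decreasing in layer strength", {
  sens_at <- function(peak_k) {
    hits <- vapply(1:10, function(seed) {
      sc <- build_scenario(surface_temp = 17, deep_temp = 10.5, mld = 55,
        thermocline_width = 40, latitude = 30, longitude = 210, k0 = 0.035,
        components = list(
          attenuation_component("dcm", peak_k = 0.02, width = 20,
                                center_depth = 120),
          attenuation_component("scattering_layer", peak_k = peak_k,
                                width = 30, noon_depth = 250,
                                midnight_depth = 120)))
      s <- simulate_tag_series(sc, warm_behavior(seed))
      d <- detect_scattering_overlap(qc_profile(build_attenuation_profile(
        s, s$positions$date[1], dcm_table = default_dcm_table())))
      isTRUE(d$overlap)
    }, logical(1))
    mean(hits)
  }
  sens <- vapply(c(0.004, 0.012, 0.024), sens_at, numeric(1))
  expect_true(all(diff(sens) >= -0.1))
  expect_gte(sens[3], sens[1])
})

test_that("profile clustering composites behave like means", {
  # identical profiles in one cluster: zero-width confidence interval
  profs <- replicate(5, make_profile(seq(25, 255, by = 10),
                                     rep(0.035, 24)),
                     simplify = FALSE)
  cl1 <- cluster_profiles(profs, 1)
  expect_true(all(cl1$clusters[[1]]$composite$ci95_hi ==
                    cl1$clusters[[1]]$composite$ci95_lo))

  # two synthetic families recovered and composite = arithmetic mean
  set.seed(9)
  mk <- function(center) {
    z <- seq(25, 255, by = 10)
    make_profile(z, 0.03 + 0.03 * exp(-(z - center)^2 / (2 * 20^2)) +
                   stats::rnorm(length(z), 0, 0.001))
  }
  fam <- c(replicate(8, mk(60), simplify = FALSE),
           replicate(8, mk(140), simplify = FALSE))
  cl2 <- cluster_profiles(fam, 2, seed = 1)
  truth <- rep(1:2, each = 8)
  agree <- max(mean(cl2$assignment == truth),
               mean(cl2$assignment == 3 - truth))
  expect_gte(agree, 0.95)
  g1 <- cl2$clusters[[1]]
  manual <- rowMeans(vapply(g1$members,
                            function(i) fam[[i]]$bins$k_per_m,
                            numeric(24)))
  expect_equal(g1$composite$mean_k, manual, tolerance = 1e-12)
  # clusters ordered by shallow mean attenuation
  expect_lte(cl2$clusters[[1]]$shallow_mean_k,
             cl2$clusters[[2]]$shallow_mean_k)

  expect_error(cluster_profiles(profs, 7), "too few")
})
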