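#' Surrogate metabolic model (speed x temperature)
#'
#' A parametric stand-in for an experimentally calibrated total metabolic
#' rate surface for tunas: `MR = (R0 + c * max(u, u_min)^p) *
#' exp(beta * max(0, T_ref - T))` in mg O2 kg^-1 h^-1, with swimming speed
#' `u` in body lengths per second and temperature `T` in deg C. Metabolic
#' rate increases with speed and is elevated in cold water below the
#' reference temperature (cold-elevated metabolism of a warm-bodied
#' predator), the two qualitative features the cost analyses rely on. The
#' defaults put typical deep foraging dives in the 4-6 mg O2 kg^-1 min^-1
#' cost-rate range. All parameters are configuration; a tabulated response
#' surface can replace the parametric form via `kind = "tabulated_surface"`
#' and a `predict_fn`.
#'
#' @param R0 baseline rate at the reference temperature and zero excess
#'   speed, mg O2 kg^-1 h^-1.
#' @param c_speed speed coefficient, mg O2 kg^-1 h^-1 per (BL/s)^p.
#' @param p speed exponent.
#' @param beta cold-elevation rate, per deg C below `T_ref`.
#' @param T_ref reference temperature, deg C.
#' @param u_min speed floor, BL s^-1 (a fish is never gliding at zero cost;
#'   horizontal swimming is absorbed here and in `R0`).
#' @param temp_range,speed_range validity ranges; inputs outside are
#'   clamped with a flag.
#' @param kind `"surrogate_parametric"` or `"tabulated_surface"`.
#' @param predict_fn for a tabulated surface: `function(speed, temp)` in
#'   the same units.
#' @return a `metabolic_model` object.
#' @export
metabolic_model <- function(R0 = 175, c_speed = 70, p = 2, beta = 0.035,
                            T_ref = 18, u_min = 0.8,
                            temp_range = c(0, 30), speed_range = c(0, 5),
                            kind = c("surrogate_parametric",
                                     "tabulated_surface"),
                            predict_fn = NULL) {
  kind <- match.arg(kind)
  stopifnot(R0 > 0, c_speed >= 0, p > 0, beta >= 0, u_min >= 0)
  if (kind == "tabulated_surface" && !is.function(predict_fn))
    stop("tabulated_surface requires a predict_fn(speed, temp)")
  structure(list(R0 = R0, c_speed = c_speed, p = p, beta = beta,
                 T_ref = T_ref, u_min = u_min, temp_range = temp_range,
                 speed_range = speed_range, kind = kind,
                 predict_fn = predict_fn),
            class = "metabolic_model")
}

#' Metabolic rate at a swimming speed and temperature
#'
#' @param speed swimming speed, body lengths s^-1 (vectorized).
#' @param temp water temperature, deg C (vectorized).
#' @param model a [metabolic_model()].
#' @return metabolic rate, mg O2 kg^-1 h^-1, with attribute `clamped`
#'   (TRUE if any input was outside the model's valid range).
#' @export
metabolic_rate <- function(speed, temp, model) {
  if (any(!is.finite(speed)) || any(!is.finite(temp)))
    stop("non-finite speed or temperature")
  clamped <- any(speed < model$speed_range[1] | speed > model$speed_range[2] |
                 temp < model$temp_range[1] | temp > model$temp_range[2])
  speed <- pmin(pmax(speed, model$speed_range[1]), model$speed_range[2])
  temp <- pmin(pmax(temp, model$temp_range[1]), model$temp_range[2])
  mr <- if (model$kind == "tabulated_surface") {
    model$predict_fn(speed, temp)
  } else {
    u <- pmax(speed, model$u_min)
    (model$R0 + model$c_speed * u^model$p) *
      exp(model$beta * pmax(0, model$T_ref - temp))
  }
  attr(mr, "clamped") <- clamped
  mr
}

#' Per-dive metabolic cost, cost rate, and potential profitability
#'
#' Vertical speed at each sample (central differences on the depth series,
#' in body lengths per second, floored at the model's `u_min`) and the
#' in situ temperature give a metabolic rate per sample; the dive cost is
#' the sample-wise integral (each sample owns one sampling interval), which
#' makes phase costs exactly additive. Cost rate is cost over total
#' duration (mg O2 kg^-1 min^-1); potential profitability is bottom time
#' (available foraging time) per unit cost (min mg O2^-1 kg).
#'
#' @param dives segmented dive table.
#' @param series the `tag_series`.
#' @param model a [metabolic_model()].
#' @param fish_length fork length, m (default from the series).
#' @return data.frame `dive_id`, `cost_mgO2kg`, `cost_rate`,
#'   `profitability`.
#' @export
dive_energetics <- function(dives, series, model,
                            fish_length = series$fish_length) {
  recs <- series$records
  dt <- series$interval_s
  out <- lapply(seq_len(nrow(dives)), function(i) {
    idx <- dives$start_idx[i]:dives$end_idx[i]
    if (length(idx) < 2L || dives$total_duration_min[i] <= 0)
      stop("zero-duration dive ", dives$dive_id[i])
    z <- recs$depth_m[idx]
    tmp <- recs$temp_c[idx]
    n <- length(z)
    v <- numeric(n)
    v[1] <- abs(z[2] - z[1]) / dt
    v[n] <- abs(z[n] - z[n - 1]) / dt
    if (n > 2L) v[2:(n - 1)] <- abs(z[3:n] - z[1:(n - 2)]) / (2 * dt)
    mr <- metabolic_rate(v / fish_length, tmp, model)
    cost <- sum(mr) * dt / 3600
    data.frame(dive_id = dives$dive_id[i], cost_mgO2kg = cost,
               cost_rate = cost / dives$total_duration_min[i],
               profitability = dives$bottom_duration_min[i] / cost)
  })
  do.call(rbind, out)
}

# travel cost (mg O2 kg^-1) of a monotone transit between two depths at a
# constant vertical rate, integrating the metabolic rate over the
# temperature profile (adaptive quadrature, so stratified and even
# discontinuous profiles integrate accurately)
travel_cost <- function(z0, z1, rate_ms, temp_profile, model, fish_length) {
  if (z1 == z0) return(0)
  f <- function(z) metabolic_rate(rep(rate_ms / fish_length, length(z)),
                                  temp_profile(z), model)
  stats::integrate(f, min(z0, z1), max(z0, z1), rel.tol = 1e-10,
                   subdivisions = 2000L)$value / (rate_ms * 3600)
}

# idealized dive: transit z0 -> D at the descent rate, hold bottom at D,
# transit back at the ascent rate
idealized_dive_cost <- function(start_depth, max_depth, descent_rate,
                                ascent_rate, bottom_duration_min,
                                temp_profile, model, fish_length) {
  travel <- travel_cost(start_depth, max_depth, descent_rate, temp_profile,
                        model, fish_length) +
    travel_cost(start_depth, max_depth, ascent_rate, temp_profile,
                model, fish_length)
  mr_bottom <- metabolic_rate(model$u_min, temp_profile(max_depth), model) / 60
  dur <- (max_depth - start_depth) / descent_rate / 60 +
    (max_depth - start_depth) / ascent_rate / 60 + bottom_duration_min
  list(travel_cost = travel,
       bottom_rate_per_min = as.numeric(mr_bottom),
       total_cost = travel + as.numeric(mr_bottom) * bottom_duration_min,
       duration_min = dur)
}

#' Compare an observed dive against a hypothetical deeper dive
#'
#' The hypothetical dive keeps the observed dive's start depth, descent and
#' ascent rates and bottom duration, but extends travel to `target_depth`,
#' taking its bottom temperature from the water-column profile at the
#' target and travel temperatures along the profile. Both the observed and
#' hypothetical dives are evaluated as idealized dives (same geometry
#' model), so `target_depth == max_depth` gives ratios of exactly 1.
#'
#' @param observed list or one-row data.frame with `start_depth`,
#'   `max_depth`, `descent_rate` (m/s), `ascent_rate` (m/s),
#'   `bottom_duration_min`.
#' @param target_depth hypothetical maximum depth, m (>= observed
#'   `max_depth`).
#' @param temp_profile `function(depth) -> deg C`, defined to
#'   `target_depth`.
#' @param model a [metabolic_model()].
#' @param fish_length fork length, m.
#' @return list: `target_depth`, `rate_ratio` (hypothetical / observed mean
#'   metabolic rate), `cost_ratio` (total cost ratio),
#'   `equivalent_bottom_fraction` (share of the observed foraging-depth
#'   duration retainable at equal total cost), `infeasible` (TRUE when the
#'   hypothetical travel alone exceeds the observed total cost).
#' @export
hypothetical_dive_comparison <- function(observed, target_depth,
                                         temp_profile, model, fish_length) {
  ob <- as.list(observed)
  if (target_depth < ob$max_depth)
    stop("target_depth must be >= the observed max_depth")
  tt <- temp_profile(target_depth)
  if (!is.finite(tt))
    stop("temperature profile undefined at target depth ", target_depth)
  o <- idealized_dive_cost(ob$start_depth, ob$max_depth, ob$descent_rate,
                           ob$ascent_rate, ob$bottom_duration_min,
                           temp_profile, model, fish_length)
  h <- idealized_dive_cost(ob$start_depth, target_depth, ob$descent_rate,
                           ob$ascent_rate, ob$bottom_duration_min,
                           temp_profile, model, fish_length)
  eq <- cost_equivalent_duration(o$total_cost, h$travel_cost,
                                 h$bottom_rate_per_min,
                                 ob$bottom_duration_min)
  list(target_depth = target_depth,
       rate_ratio = (h$total_cost / h$duration_min) /
                    (o$total_cost / o$duration_min),
       cost_ratio = h$total_cost / o$total_cost,
       equivalent_bottom_fraction = eq$fraction,
       infeasible = eq$infeasible,
       observed_cost = o$total_cost, hypothetical_cost = h$total_cost)
}

#' Bottom duration making a hypothetical dive cost-equivalent
#'
#' Solves `travel_cost_h + bottom_rate_h * b = observed_cost` for the
#' hypothetical bottom duration `b` in closed form. If even zero bottom
#' time exceeds the observed cost (travel alone costs more), the dive
#' cannot be made energetically equivalent by shortening its foraging
#' phase and the result is flagged infeasible.
#'
#' @param observed_cost observed total dive cost, mg O2 kg^-1.
#' @param hyp_travel_cost hypothetical travel (descent + ascent) cost.
#' @param hyp_bottom_rate_per_min hypothetical bottom-phase metabolic rate,
#'   mg O2 kg^-1 min^-1.
#' @param observed_bottom_min observed bottom duration, min.
#' @return list `fraction` (b / observed bottom duration; `NA` when
#'   infeasible), `bottom_min`, `infeasible`.
#' @export
cost_equivalent_duration <- function(observed_cost, hyp_travel_cost,
                                     hyp_bottom_rate_per_min,
                                     observed_bottom_min) {
  b <- (observed_cost - hyp_travel_cost) / hyp_bottom_rate_per_min
  if (!is.finite(b) || b <= 0)
    return(list(fraction = NA_real_, bottom_min = NA_real_,
                infeasible = TRUE))
  list(fraction = b / observed_bottom_min, bottom_min = b,
       infeasible = FALSE)
}
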