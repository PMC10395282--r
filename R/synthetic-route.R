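# Synthetic driving route and telemetry with known route-demand profile.

#' Simulate a driving route with a scripted demand profile
#'
#' Builds a route of freeway, rural, city, fog and construction sections.
#' Each section carries a baseline attentional demand in `[0, 1]`; within a
#' section the demand wanders smoothly, and section transitions are blended
#' over ~100 m so the profile is continuous. Known-position trigger points
#' are placed on an even grid along the track.
#'
#' The default desk-scale route is 5 km; the full-study scale (50 km,
#' 85 triggers) is available by configuration.
#'
#' @param total_distance Track length in meters (> 0).
#' @param n_triggers Number of known-position trigger points (> 0).
#' @param seed Integer seed; the profile is deterministic given the seed.
#' @param wiggle Amplitude of smooth within-section demand variation.
#' @return A `RouteProfile`: list with `total_distance`, `demand`
#'   (function distance -> `[0,1]`), `demand_grid` (1-m grid), `sections`
#'   (start/end/tag/base demand), `trigger_points` (m).
#' @export
simulate_route <- function(total_distance = 5000, n_triggers = 10, seed = 1,
                           wiggle = 0.08) {
  if (!is.numeric(total_distance) || total_distance <= 0)
    stop("total_distance must be positive")
  if (n_triggers < 1) stop("need at least one trigger point")
  set.seed(seed)
  prop <- c(freeway = 0.22, rural = 0.18, freeway = 0.12, rural = 0.13,
            city = 0.20, fog = 0.07, construction = 0.08)
  prop <- prop / sum(prop)
  base <- c(freeway = 0.15, rural = 0.45, city = 0.75, fog = 0.85,
            construction = 0.90)
  edges <- cumsum(c(0, prop)) * total_distance
  tags <- names(prop)
  sections <- data.frame(start_m = edges[-length(edges)],
                         end_m = edges[-1], tag = tags,
                         base_demand = base[tags], row.names = NULL)
  d <- seq(0, total_distance, by = 1)
  # piecewise-constant base, blended with a logistic ramp of ~100 m
  u <- numeric(length(d))
  blend <- 50  # m, logistic scale; full transition ~ 4*blend
  u <- u + sections$base_demand[1]
  for (k in seq_len(nrow(sections))[-1]) {
    step <- sections$base_demand[k] - sections$base_demand[k - 1]
    u <- u + step * stats::plogis((d - sections$start_m[k]) / blend)
  }
  # smooth within-section wander: two random-phase long-wave sinusoids
  wl <- total_distance / c(7, 13)
  ph <- runif(2, 0, 2 * pi)
  u <- u + wiggle * (sin(2 * pi * d / wl[1] + ph[1]) +
                     0.6 * sin(2 * pi * d / wl[2] + ph[2]))
  u <- pmin(1, pmax(0, u))
  triggers <- (seq_len(n_triggers) - 0.5) * total_distance / n_triggers
  structure(list(total_distance = total_distance,
                 demand = approxfun(d, u, rule = 2),
                 demand_grid = data.frame(distance_m = d, demand = u),
                 sections = sections, trigger_points = triggers,
                 seed = seed),
            class = "RouteProfile")
}

#' @export
print.RouteProfile <- function(x, ...) {
  cat(sprintf("<RouteProfile> %.1f km, %d sections, %d triggers\n",
              x$total_distance / 1000, nrow(x$sections),
              length(x$trigger_points)))
  invisible(x)
}

#' Simulate driving telemetry along a route
#'
#' Velocity tracks a demand-dependent target (high demand -> low speed)
#' through a first-order lag; steering angle is smooth colored noise whose
#' amplitude grows with demand. Telemetry is produced at the simulator
#' transcription rate (100 Hz). The integral of velocity over time equals
#' the track length to within 0.1%.
#'
#' @param route A [simulate_route()] profile.
#' @param seed Integer seed.
#' @param rate Telemetry sampling rate, Hz.
#' @param v_max,v_min Velocity targets (km/h) at demand 0 and 1.
#' @param tau_s Velocity lag time constant, seconds.
#' @param steering_sd_base,steering_sd_gain Steering-angle SD (deg) at
#'   demand 0 and its increase to demand 1.
#' @return data.frame of class `drive_telemetry` with columns `time_s`,
#'   `velocity_kmh`, `steering_deg`, `distance_m` (true simulator distance),
#'   plus attributes `trigger_table` (time/sample/distance of each trigger)
#'   and `route`.
#' @export
simulate_telemetry <- function(route, seed = 1, rate = 100,
                               v_max = 108, v_min = 40, tau_s = 3,
                               steering_sd_base = 2, steering_sd_gain = 6) {
  stopifnot(inherits(route, "RouteProfile"))
  set.seed(seed + 1000L)
  dt <- 1 / rate
  n_guess <- ceiling(route$total_distance / (v_min / 3.6) / dt) + rate
  v <- numeric(n_guess); dist <- numeric(n_guess)
  # smooth multiplicative velocity noise (~1 km/h, 0.1 Hz bandwidth)
  noise <- stats::filter(rnorm(n_guess), rep(1, rate) / rate, sides = 1)
  noise[is.na(noise)] <- 0
  v_cur <- v_max - (v_max - v_min) * route$demand(0)
  d_cur <- 0
  i <- 0L
  while (d_cur < route$total_distance && i < n_guess) {
    i <- i + 1L
    u <- route$demand(d_cur)
    v_target <- v_max - (v_max - v_min) * u + 3 * noise[i]
    v_cur <- v_cur + (v_target - v_cur) * dt / tau_s
    v[i] <- v_cur
    dist[i] <- d_cur
    d_cur <- d_cur + v_cur / 3.6 * dt
  }
  n <- i
  v <- v[seq_len(n)]; dist <- dist[seq_len(n)]
  time_s <- (seq_len(n) - 1) * dt
  u_t <- route$demand(dist)
  # steering: low-pass filtered white noise, SD modulated by demand
  bf <- signal::butter(2, 1.6 / (rate / 2), type = "low")
  raw <- signal::filtfilt(bf, rnorm(n))
  raw <- raw / sd(raw)
  steering <- raw * (steering_sd_base + steering_sd_gain * u_t)
  trig_idx <- findInterval(route$trigger_points, dist) + 1L
  trig_idx <- pmin(trig_idx, n)
  trig <- data.frame(sample = trig_idx - 1L,
                     time_s = time_s[trig_idx],
                     distance_m = route$trigger_points)
  out <- data.frame(time_s = time_s, velocity_kmh = v,
                    steering_deg = steering, distance_m = dist)
  attr(out, "trigger_table") <- trig
  attr(out, "route") <- route
  attr(out, "rate") <- rate
  class(out) <- c("drive_telemetry", "data.frame")
  out
}
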