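#' Inverted-pendulum walking-model parameters
#'
#' Parameters of the compass-gait inverted-pendulum model used to study
#' how the arch spring shapes walking dynamics: during single support the
#' centre of mass (CoM) vaults over the stance foot as an inverted
#' pendulum; at each step transition the foot-ground collision is an
#' impulsive event governed by the impulse theorem (the time integral of
#' the collision force equals the change in body momentum).
#'
#' @param body_mass Body mass, kg (default 54, the reference subject).
#' @param leg_length Effective leg length, m.
#' @param step_angle Half-angle swept each side of vertical, rad; the
#'   inter-leg angle at the transition is twice this.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param arch_spring Optional [spring_spec()]: a lumped arch compliance
#'   in series with the stance leg (rate converted from N/mm to N/m).
#' @param collision_model `"plastic_impulse"` (the CoM velocity component
#'   along the new leg is removed, dissipating energy) or `"none"`
#'   (conservative limit: speed carried through the transition).
#' @param init_angular_velocity Angular velocity at the start of the first
#'   step, rad/s; `NULL` picks 1.5 times the minimum needed to vault the
#'   pendulum over vertical. Note that a passive walker with plastic
#'   collisions loses a fixed speed fraction `1 - cos(2 * step_angle)`
#'   per step, so on level ground only a finite number of steps can be
#'   sustained from any initial speed.
#' @return List of class `pendulum_params`.
#' @export
pendulum_params <- function(body_mass = 54, leg_length = 0.9,
                            step_angle = 0.2, gravity = 9.81,
                            arch_spring = NULL,
                            collision_model = c("plastic_impulse", "none"),
                            init_angular_velocity = NULL) {
  collision_model <- match.arg(collision_model)
  stopifnot(body_mass > 0, leg_length > 0, gravity > 0,
            step_angle > 0, step_angle < pi / 2)
  if (!is.null(arch_spring)) stopifnot(inherits(arch_spring, "spring_spec"))
  structure(list(
    body_mass = body_mass, leg_length = leg_length,
    step_angle = step_angle, gravity = gravity,
    arch_spring = arch_spring, collision_model = collision_model,
    init_angular_velocity = init_angular_velocity
  ), class = "pendulum_params")
}

# mechanical energy of the (possibly compliant) pendulum state
pend_energy <- function(p, theta, omega, r, rdot, k_nm) {
  ke <- 0.5 * p$body_mass * (rdot^2 + (r * omega)^2)
  pe <- p$body_mass * p$gravity * r * cos(theta)
  se <- if (k_nm > 0) 0.5 * k_nm * (p$leg_length - r)^2 else 0
  ke + pe + se
}

#' Simulate inverted-pendulum walking
#'
#' Integrates single-support dynamics step by step. With a rigid leg the
#' equation of motion is `theta'' = (g/L) sin(theta)`; with an arch spring
#' the leg length becomes a dynamic coordinate with radial compliance
#' `m r'' = m r theta'^2 - m g cos(theta) + k (L - r)` and
#' `theta'' = (g sin(theta) - 2 r' theta') / r`. Each step runs from
#' `-step_angle` to `+step_angle` of lean; at the transition the collision
#' model redirects the CoM velocity (plastic impulse: the component along
#' the new leg is removed). A per-step energy ledger records integration
#' drift and collision loss.
#'
#' @param params A [pendulum_params()].
#' @param n_steps Number of steps to simulate (>= 1).
#' @param dt Output time resolution, s.
#' @param max_step_time Abort threshold: a step not completing within this
#'   many seconds raises an error with diagnostics.
#' @return Object of class `pendulum_trajectory`: `series` (data frame
#'   with time, step index, step phase, lean angle, angular velocity, leg
#'   length and rate, CoM position/velocity/speed/acceleration and arch
#'   spring force) and `steps` (per-step energy ledger with columns
#'   `energy_start`, `energy_end`, `drift`, `collision_loss`,
#'   `speed_pre`, `speed_post`).
#' @export
simulate_pendulum <- function(params, n_steps = 5L, dt = 0.002,
                              max_step_time = 3) {
  stopifnot(inherits(params, "pendulum_params"), n_steps >= 1)
  p <- params
  alpha <- p$step_angle
  L <- p$leg_length
  k_nm <- if (is.null(p$arch_spring)) 0 else p$arch_spring$stiffness * 1000

  omega0 <- p$init_angular_velocity
  if (is.null(omega0))
    omega0 <- 1.5 * sqrt(2 * p$gravity / L * (1 - cos(alpha)))

  deriv <- function(t, y, parms) {
    th <- y[1]; om <- y[2]; r <- y[3]; rd <- y[4]
    if (k_nm > 0) {
      list(c(om,
             (p$gravity * sin(th) - 2 * rd * om) / r,
             rd,
             r * om^2 - p$gravity * cos(th) + k_nm * (L - r) / p$body_mass))
    } else {
      list(c(om, (p$gravity / L) * sin(th), 0, 0))
    }
  }
  rootfun <- function(t, y, parms) y[1] - alpha

  state <- c(theta = -alpha, omega = omega0, r = L, rdot = 0)
  series <- list()
  ledger <- list()
  t_global <- 0
  foot_x <- 0

  for (s in seq_len(n_steps)) {
    e_start <- pend_energy(p, state[1], state[2], state[3], state[4], k_nm)
    sol <- deSolve::lsodar(
      y = state, times = seq(0, max_step_time, by = dt), func = deriv,
      parms = NULL, rootfunc = rootfun, rtol = 1e-10, atol = 1e-10
    )
    t_root <- attr(sol, "troot")
    if (is.null(t_root) || !length(t_root))
      stop(sprintf(
        "pendulum step %d did not reach +step_angle within %g s ",
        s, max_step_time),
        sprintf("(theta ended at %.3f rad, omega %.3f rad/s); ",
                sol[nrow(sol), "theta"], sol[nrow(sol), "omega"]),
        "increase init_angular_velocity or reduce step_angle")
    sol <- as.data.frame(sol)

    th <- sol$theta; om <- sol$omega
    r <- if (k_nm > 0) sol$r else rep(L, nrow(sol))
    rd <- if (k_nm > 0) sol$rdot else rep(0, nrow(sol))
    vx <- rd * sin(th) + r * om * cos(th)
    vy <- rd * cos(th) - r * om * sin(th)
    th_dd <- (p$gravity * sin(th) - 2 * rd * om) / r
    r_dd <- if (k_nm > 0)
      r * om^2 - p$gravity * cos(th) + k_nm * (L - r) / p$body_mass
    else rep(0, nrow(sol))
    # CoM acceleration magnitude in polar coordinates
    a_rad <- r_dd - r * om^2
    a_tan <- r * th_dd + 2 * rd * om
    series[[s]] <- data.frame(
      time = t_global + sol$time, step = s,
      phase = sol$time / max(sol$time),
      theta = th, omega = om, r = r, rdot = rd,
      com_x = foot_x + r * sin(th), com_y = r * cos(th),
      vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
      accel = sqrt(a_rad^2 + a_tan^2),
      spring_force = k_nm * (L - r)
    )
    last <- series[[s]][nrow(series[[s]]), ]
    e_end <- pend_energy(p, last$theta, last$omega, last$r, last$rdot, k_nm)

    # step transition
    v_pre <- c(last$vx, last$vy)
    speed_pre <- sqrt(sum(v_pre^2))
    if (p$collision_model == "plastic_impulse") {
      u_new <- c(sin(-alpha), cos(-alpha))  # unit vector along new leg
      v_post <- v_pre - sum(v_pre * u_new) * u_new
      speed_post <- sqrt(sum(v_post^2))
      # decompose post-collision velocity in the new leg's polar frame
      t_new <- c(cos(-alpha), -sin(-alpha))
      omega_new <- sum(v_post * t_new) / L
      state <- c(theta = -alpha, omega = omega_new, r = L, rdot = 0)
    } else {
      speed_post <- speed_pre
      state <- c(theta = -alpha, omega = unname(last$omega),
                 r = unname(last$r), rdot = unname(last$rdot))
    }
    e_post <- pend_energy(p, state[1], state[2], state[3], state[4], k_nm)
    ledger[[s]] <- data.frame(
      step = s, energy_start = e_start, energy_end = e_end,
      drift = e_end - e_start, collision_loss = e_end - e_post,
      speed_pre = speed_pre, speed_post = speed_post
    )
    t_global <- t_global + last$time - series[[s]]$time[1] + dt
    foot_x <- foot_x + last$r * sin(alpha) + L * sin(alpha)
  }
  structure(list(
    series = do.call(rbind, series),
    steps = do.call(rbind, ledger),
    params = params
  ), class = "pendulum_trajectory")
}

#' @export
print.pendulum_trajectory <- function(x, ...) {
  cat(sprintf(
    "<pendulum_trajectory> %d steps, %.2f s; mean collision loss %.3g J\n",
    nrow(x$steps), max(x$series$time), mean(x$steps$collision_loss)))
  invisible(x)
}

#' Validation-mode pendulum period
#'
#' Flips the sign of gravity's torque (a hanging pendulum about the stable
#' equilibrium) and measures the oscillation period from successive
#' same-direction zero crossings, for validating the integrator against
#' the closed-form small-amplitude period `2 pi sqrt(L / g)`.
#'
#' @param params A [pendulum_params()] (only `leg_length` and `gravity`
#'   are used).
#' @param amplitude Initial angle, rad (small; default 0.05).
#' @param n_periods Number of periods to average over.
#' @return Measured period, s.
#' @export
pendulum_validation_period <- function(params, amplitude = 0.05,
                                       n_periods = 5L) {
  stopifnot(inherits(params, "pendulum_params"), amplitude > 0)
  L <- params$leg_length; g <- params$gravity
  t_guess <- 2 * pi * sqrt(L / g)
  deriv <- function(t, y, parms) list(c(y[2], -(g / L) * sin(y[1])))
  sol <- deSolve::ode(
    y = c(theta = amplitude, omega = 0),
    times = seq(0, (n_periods + 1) * t_guess, by = t_guess / 2000),
    func = deriv, parms = NULL, rtol = 1e-10, atol = 1e-10
  )
  th <- sol[, "theta"]; tt <- sol[, "time"]
  # downward zero crossings, linearly interpolated
  idx <- which(th[-length(th)] > 0 & th[-1] <= 0)
  cross <- tt[idx] + (tt[idx + 1] - tt[idx]) * th[idx] / (th[idx] - th[idx + 1])
  if (length(cross) < 2) stop("not enough oscillations to measure a period")
  mean(diff(cross))
}
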