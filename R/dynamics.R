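# Velocity-Verlet molecular dynamics with optional Berendsen
# thermostat, plus the randomized quick optimizer (heated dynamics
# bursts alternating with conjugate-gradient minimization, keeping the
# best conformation seen).
#
# Internal units: Angstrom, fs, amu, kcal/mol. Acceleration converts
# via 1 kcal/mol/A/amu = 4.184e-4 A/fs^2.

#' Molecular dynamics options
#'
#' @param timestep integration step, fs.
#' @param steps number of steps.
#' @param temperature target / initial-velocity temperature, K.
#' @param thermostat `"none"` or `"berendsen"`.
#' @param tau Berendsen coupling time, ps.
#' @param seed integer seed for the Maxwell-Boltzmann draw.
#' @param sample_every record energies every this many steps.
#' @return an options list.
#' @export
md_options <- function(timestep = 1.0, steps = 100, temperature = 300,
                       thermostat = c("none", "berendsen"), tau = 0.1,
                       seed = 1L, sample_every = 10L) {
  stopifnot(timestep > 0, temperature >= 0, steps >= 0)
  list(timestep = timestep, steps = as.integer(steps),
       temperature = temperature, thermostat = match.arg(thermostat),
       tau = tau, seed = as.integer(seed),
       sample_every = as.integer(sample_every))
}

#' Kinetic temperature of a set of velocities
#'
#' T = 2 KE / (3 N k_B) over the movable atoms.
#'
#' @param masses amu, per movable atom.
#' @param velocities matrix (n x 3), Angstrom/fs.
#' @return temperature, K.
#' @export
compute_temperature <- function(masses, velocities) {
  n <- length(masses)
  if (!n) stop("zero movable atoms")
  ke <- 0.5 * sum(masses * rowSums(velocities^2)) / ACC_CONV  # kcal/mol
  2 * ke / (3 * n * KB_KCAL)
}

## Maxwell-Boltzmann velocities (A/fs) from a private RNG stream.
mb_velocities <- function(masses, temperature, rng) {
  sd <- sqrt(KB_KCAL * temperature * ACC_CONV / masses)
  matrix(rng(length(masses) * 3), ncol = 3) * sd
}

#' Run velocity-Verlet dynamics
#'
#' Integrates the movable atoms; frozen atoms contribute to the energy
#' but never move. Initial velocities are Maxwell-Boltzmann at
#' `opts$temperature` from `opts$seed`; with the Berendsen thermostat,
#' velocities are rescaled toward the target temperature each step.
#' Identical seeds give bit-identical trajectories.
#'
#' @param sys a `molsys` (coordinates updated in place).
#' @param ff a `forcefield`.
#' @param opts see [md_options()].
#' @param velocities optional n_movable x 3 initial velocities
#'   (Angstrom/fs) overriding the Maxwell-Boltzmann draw.
#' @return a trajectory summary: sampled step indices, potential /
#'   kinetic / total energies (kcal/mol), temperatures (K).
#' @export
run_md <- function(sys, ff, opts = md_options(), velocities = NULL) {
  movable <- which(ff$movable)
  if (!length(movable)) stop("no movable atoms")
  masses <- ff$lists$masses[movable]
  xyz <- coords(sys)
  if (is.null(velocities)) {
    v <- with_seed(opts$seed,
                   mb_velocities(masses, opts$temperature, stats::rnorm))
  } else v <- velocities
  grad <- compute_gradient(ff, xyz)
  a <- -grad[movable, , drop = FALSE] / masses * ACC_CONV
  dt <- opts$timestep
  sample_steps <- integer(); epot <- ekin <- temps <- numeric()
  record <- function(step) {
    e <- compute_energy(ff, xyz)$total
    ke <- 0.5 * sum(masses * rowSums(v^2)) / ACC_CONV
    sample_steps <<- c(sample_steps, step)
    epot <<- c(epot, e); ekin <<- c(ekin, ke)
    temps <<- c(temps, 2 * ke / (3 * length(masses) * KB_KCAL))
  }
  record(0L)
  for (step in seq_len(opts$steps)) {
    xyz[movable, ] <- xyz[movable, ] + v * dt + 0.5 * a * dt^2
    grad <- compute_gradient(ff, xyz)
    a_new <- -grad[movable, , drop = FALSE] / masses * ACC_CONV
    v <- v + 0.5 * (a + a_new) * dt
    a <- a_new
    if (opts$thermostat == "berendsen" && opts$temperature > 0) {
      tcur <- compute_temperature(masses, v)
      if (tcur > 0) {
        lambda <- sqrt(1 + dt / (opts$tau * 1000) *
                         (opts$temperature / tcur - 1))
        v <- v * lambda
      }
    }
    if (step %% opts$sample_every == 0 || step == opts$steps) {
      e <- compute_energy(ff, xyz)$total
      if (!is.finite(e)) stop("nonfinite energy at MD step ", step)
      record(step)
    }
  }
  set_coords(sys, xyz)
  list(steps = sample_steps, potential = epot, kinetic = ekin,
       total = epot + ekin, temperature = temps,
       velocities = v)
}

#' Randomized quick optimization
#'
#' Repeats `rounds` times: draw random velocities at 300 K (seeded),
#' run 100 MD steps of 1 fs, then conjugate-gradient minimize; the
#' lowest-energy conformation encountered is kept. `rounds = 0` is a
#' plain conjugate-gradient minimization.
#'
#' @param sys a `molsys` (updated in place to the best conformation).
#' @param ff a `forcefield`.
#' @param rounds number of heating/minimization rounds.
#' @param seed integer seed.
#' @param opts minimizer options for the inner minimizations.
#' @return the `minimizer_result` of the best conformation, with
#'   element `best_energy`.
#' @export
quick_optimize <- function(sys, ff, rounds = 3, seed = 1L,
                           opts = minimizer_options()) {
  best <- minimize_conjugate_gradient(sys, ff, opts)
  best_xyz <- coords(sys)
  for (r in seq_len(rounds)) {
    mdo <- md_options(timestep = 1.0, steps = 100, temperature = 300,
                      seed = seed + r)
    run_md(sys, ff, mdo)
    res <- minimize_conjugate_gradient(sys, ff, opts)
    if (res$final_energy < best$final_energy) {
      best <- res
      best_xyz <- coords(sys)
    } else {
      set_coords(sys, best_xyz)
    }
  }
  set_coords(sys, best_xyz)
  best$best_energy <- best$final_energy
  best
}
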