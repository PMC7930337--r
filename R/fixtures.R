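#' Synthetic traveling-wave kymograph
#'
#' Deterministic curvature wave for testing the kinematic estimators:
#' `k(u, t) = amp(u) * sin(2*pi*(u/wavelength - freq*t))`, a
#' posterior-traveling wave for positive `freq`, with an optional linear
#' amplitude gradient head to tail.
#'
#' @param wavelength spatial wavelength in body lengths.
#' @param freq temporal frequency, Hz.
#' @param duration,dt window and sampling, s.
#' @param n_body body points.
#' @param amplitude curvature amplitude at the head, 1/mm.
#' @param amp_slope linear change of amplitude over the body (negative =
#'   decaying towards the tail).
#' @return a `wcpg_kymograph`.
#' @export
synthetic_kymograph <- function(wavelength, freq = 0.44, duration = 10,
                                dt = 0.05, n_body = 49, amplitude = 4,
                                amp_slope = 0) {
  u <- seq(0, 1, length.out = n_body)
  t <- seq(dt, duration, by = dt)
  amp <- pmax(0, amplitude + amp_slope * u)
  curv <- outer(t, u, function(tt, uu)
    sin(2 * pi * (uu / wavelength - freq * tt))) *
    matrix(amp, length(t), n_body, byrow = TRUE)
  structure(list(curvature = curv, body_coord = u, time = t),
            class = c("wcpg_kymograph", "list"))
}

#' Synthetic center-of-mass paths
#'
#' @param type `"straight"` or `"circle"`.
#' @param radius circle radius, mm.
#' @param speed path speed, mm/s.
#' @param duration,dt window and sampling, s.
#' @return matrix (samples x 2), mm.
#' @export
synthetic_com_path <- function(type = c("straight", "circle"), radius = 1,
                               speed = 0.22, duration = 30, dt = 0.05) {
  type <- match.arg(type)
  t <- seq(0, duration, by = dt)
  if (type == "straight")
    return(cbind(x = speed * t, y = rep(0, length(t))))
  omega <- speed / radius
  cbind(x = radius * cos(omega * t), y = radius * sin(omega * t))
}

#' Load a demo genotype
#'
#' Committed products of the two-stage evolutionary search, regenerable with
#' [evolve_stage1()]/[evolve_stage2()]: `"oscillator"` is a stage-1 isolated
#' unit with F1 > 0.99; `"locomotor"` is a stage-2 worm that crawls forward
#' with a posterior-traveling wave.
#'
#' @param name `"oscillator"` or `"locomotor"`.
#' @return a [genotype()].
#' @export
demo_genotype <- function(name = c("locomotor", "oscillator")) {
  name <- match.arg(name)
  f <- system.file("extdata", "genotypes", paste0("demo_", name, ".json"),
                   package = "wormCPG", mustWork = TRUE)
  read_genotype(f)
}

#' Generate the test fixture set
#'
#' Deterministic synthetic inputs for the analysis operators plus the
#' committed demo genotypes. With the same seed the result is identical.
#'
#' @param seed RNG seed (the synthetic inputs are analytic; the seed fixes
#'   the jittered variants).
#' @param dir if non-`NULL`, also write the fixtures to this directory
#'   (kymographs and paths as CSV, genotypes as JSON).
#' @return list with kymographs, paths and genotypes.
#' @export
generate_fixtures <- function(seed = 1, dir = NULL) {
  set.seed(seed)
  fx <- list(
    kym_pass = synthetic_kymograph(wavelength = 0.6, amp_slope = -2),
    kym_long = synthetic_kymograph(wavelength = 1.5, amp_slope = -2),
    kym_flat = synthetic_kymograph(wavelength = 0.6, amp_slope = 0),
    path_straight = synthetic_com_path("straight"),
    path_small_circle = synthetic_com_path("circle", radius = 0.5),
    path_big_circle = synthetic_com_path("circle", radius = 2),
    oscillator = demo_genotype("oscillator"),
    locomotor = demo_genotype("locomotor"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in grep("^kym", names(fx), value = TRUE))
      write.csv(fx[[nm]]$curvature, file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    for (nm in grep("^path", names(fx), value = TRUE))
      write.csv(fx[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    write_genotype(fx$oscillator, file.path(dir, "demo_oscillator.json"))
    write_genotype(fx$locomotor, file.path(dir, "demo_locomotor.json"))
  }
  fx
}
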