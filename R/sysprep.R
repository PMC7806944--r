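## System-preparation numerics: the z-padding solver for the solvation
## box, the equilibration restraint-release schedule, and protocol time
## budgeting.

## Water number densities (molecules/A^3) by model; configurable, the
## 0.0329 default reflects typical TIP3P-like packing.
WATER_DENSITY <- c(TIP3P = 0.0329, TIP4PEW = 0.0332, SPCE = 0.0333)

#' Solvation-box specification
#'
#' The water-count model is `N(buffer_z) = density * (A * (z_extent + 2 *
#' buffer_z) - v_excluded)` with cross-section `A = (x_extent + 2 *
#' buffer_x) * (y_extent + 2 * buffer_y)`.
#'
#' @param num_waters target water count (> 0).
#' @param buffer_x,buffer_y water padding in x and y (Angstrom).
#' @param x_extent,y_extent,z_extent solute extents (Angstrom).
#' @param density water number density (molecules/A^3) or a water-model
#'   name (`"TIP3P"`, `"TIP4PEW"`, `"SPCE"`).
#' @param v_excluded solute excluded volume (A^3).
#' @return Object of class `abfe_box`.
#' @export
box_spec <- function(num_waters, buffer_x, buffer_y, x_extent = 0,
                     y_extent = 0, z_extent = 0, density = "TIP3P",
                     v_excluded = 0) {
  if (is.character(density)) {
    density <- WATER_DENSITY[toupper(density)]
    if (is.na(density)) stop("unknown water model")
  }
  if (num_waters <= 0) stop("num_waters must be positive")
  if (density <= 0) stop("density must be positive")
  structure(list(num_waters = num_waters, buffer_x = buffer_x,
                 buffer_y = buffer_y, x_extent = x_extent,
                 y_extent = y_extent, z_extent = z_extent,
                 density = unname(density), v_excluded = v_excluded),
            class = "abfe_box")
}

#' Solve the z water padding for a target water count
#'
#' Damped (relaxed) Newton iteration with relaxation factor 0.5 on
#' `N(buffer_z) - num_waters`, with a bisection fallback; converged when
#' the water count is within 0.5 of the target (rounds to it).
#'
#' @param spec an [box_spec()].
#' @return `buffer_z` in Angstrom.
#' @export
solve_z_buffer <- function(spec) {
  A <- (spec$x_extent + 2 * spec$buffer_x) *
    (spec$y_extent + 2 * spec$buffer_y)
  nw <- function(bz) spec$density *
    (A * (spec$z_extent + 2 * bz) - spec$v_excluded)
  target <- spec$num_waters
  if (nw(0) > target + 0.5)
    stop("target water count unreachable with non-negative z buffer")
  ## bracket the root
  hi <- 1
  while (nw(hi) < target && hi < 1e6) hi <- hi * 2
  if (nw(hi) < target) stop("target water count unreachable")
  lo <- 0
  bz <- hi / 2
  h <- 1e-4
  for (i in 1:200) {
    fx <- nw(bz) - target
    ## iterate well past the 0.5-water contract so the returned buffer is
    ## effectively the exact root of the count model
    if (abs(fx) <= 1e-7) return(bz)
    if (fx > 0) hi <- bz else lo <- bz
    dfx <- (nw(bz + h) - nw(bz - h)) / (2 * h)
    step <- if (dfx > 0) 0.5 * fx / dfx else NA   # relaxation 0.5
    cand <- bz - step
    if (is.na(cand) || cand <= lo || cand >= hi)
      cand <- (lo + hi) / 2                       # bisection fallback
    bz <- cand
  }
  if (abs(nw(bz) - target) <= 0.5) return(bz)
  stop("z-buffer solver did not converge")
}

#' Equilibration restraint-release schedule
#'
#' A sequence of stages with progressively weaker ligand TR restraints,
#' ending with the ligand free. Protein TR restraints and the protein
#' anchor distance restraints are maintained throughout.
#'
#' @param release_eq non-increasing percentages ending at 0.
#' @param eq_steps1,eq_steps2 MD steps for the first and the remaining
#'   stages (recorded as metadata).
#' @return data.frame: `stage`, `attach_pct`, `k_factor` (the pct/100
#'   spring multiplier), `steps`, `maintain_protein_tr`.
#' @export
equilibration_schedule <- function(release_eq, eq_steps1 = 0,
                                   eq_steps2 = 0) {
  if (length(release_eq) == 0) stop("release_eq is empty")
  if (is.unsorted(rev(release_eq)))
    stop("release_eq must be non-increasing")
  if (release_eq[length(release_eq)] != 0)
    stop("release_eq must end at 0 (ligand free)")
  data.frame(stage = seq_along(release_eq),
             attach_pct = release_eq,
             k_factor = release_eq / 100,
             steps = c(eq_steps1,
                       rep(eq_steps2, length(release_eq) - 1)),
             maintain_protein_tr = TRUE)
}

#' Protocol specification
#'
#' @param components data.frame with columns `component`, `windows`,
#'   `ns_per_window` (simulation time per window, ns).
#' @param equil_ns equilibration/preparation simulation time (ns).
#' @return Object of class `abfe_protocol`.
#' @export
protocol_spec <- function(components, equil_ns = 0) {
  stopifnot(all(c("component", "windows", "ns_per_window") %in%
                  names(components)))
  if (any(components$windows < 0) || any(components$ns_per_window < 0) ||
      equil_ns < 0)
    stop("negative simulation time")
  structure(list(components = components, equil_ns = equil_ns),
            class = "abfe_protocol")
}

#' Total simulated-time budget of a protocol
#'
#' @param spec an [protocol_spec()].
#' @return List: `per_component` (data.frame with an `ns` column),
#'   `equil_ns`, `total_ns` and `total_us`.
#' @export
protocol_budget <- function(spec) {
  comp <- spec$components
  comp$ns <- comp$windows * comp$ns_per_window
  total <- sum(comp$ns) + spec$equil_ns
  list(per_component = comp, equil_ns = spec$equil_ns,
       total_ns = total, total_us = total / 1000)
}

#' Default DD protocol budget
#'
#' Loads the packaged per-component window counts and per-window
#' simulation times of the reference double-decoupling protocol.
#'
#' @return An [protocol_spec()].
#' @export
default_dd_protocol <- function() {
  path <- system.file("extdata", "protocol-dd-default.tsv",
                      package = "abfekit")
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  equil <- d$component == "equilibration"
  protocol_spec(d[!equil, , drop = FALSE],
                equil_ns = sum(d$windows[equil] * d$ns_per_window[equil]))
}
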