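## Synthetic Boltzmann samplers with closed-form reference free energies.
##
## These replace molecular dynamics in tests and demonstrations: every
## sampler draws from the exact target density, so any discrepancy between
## an estimator and the analytic answer is attributable to the estimator
## (or to finite sampling), never to the data source. All samplers take an
## explicit seed and touch no global random state beyond their own
## set.seed scope.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a 1-D restrained harmonic system
#'
#' Intrinsic potential `k_sys (x - x_sys)^2` plus a window restraint
#' `k_win (x - x0)^2` (both with the no-1/2 convention). The Boltzmann
#' density is Gaussian with mean `(k_sys x_sys + k_win x0) / (k_sys +
#' k_win)` and variance `kT / (2 (k_sys + k_win))`.
#'
#' @param k_sys intrinsic spring (kcal/mol/unit^2), > 0.
#' @param x_sys intrinsic centre.
#' @param k_win full window restraint spring.
#' @param x0 restraint centre.
#' @param T temperature (K).
#' @param n_samples samples per window.
#' @return Object of class `abfe_harmspec`.
#' @export
harmonic_system_spec <- function(k_sys, x_sys = 0, k_win = 10, x0 = 0,
                                 T = DEFAULT_TEMPERATURE,
                                 n_samples = 1000) {
  stopifnot(k_sys > 0, k_win >= 0, n_samples >= 1)
  structure(list(k_sys = k_sys, x_sys = x_sys, k_win = k_win, x0 = x0,
                 T = T, n_samples = n_samples), class = "abfe_harmspec")
}

harm_window_moments <- function(spec, attach_pct) {
  kw <- scale_window(spec$k_win, attach_pct)
  ktot <- spec$k_sys + kw
  kT <- RGAS_KCAL * spec$T
  mu <- (spec$k_sys * spec$x_sys + kw * spec$x0) / ktot
  list(mean = mu, sd = sqrt(kT / (2 * ktot)), ktot = ktot, kw = kw)
}

#' Draw Boltzmann samples from a restrained harmonic window
#'
#' Direct (i.i.d.) sampling from the exact Gaussian Boltzmann density of
#' the window.
#'
#' @param spec an [harmonic_system_spec()].
#' @param attach_pct restraint scaling percentage of this window.
#' @param seed integer seed.
#' @return Numeric vector of `spec$n_samples` draws.
#' @export
sample_harmonic_window <- function(spec, attach_pct, seed) {
  m <- harm_window_moments(spec, attach_pct)
  with_seed(seed, stats::rnorm(spec$n_samples, m$mean, m$sd))
}

## log of the Gaussian partition function of a window (up to the constant
## sqrt(pi kT) factors that cancel in differences).
harm_log_z <- function(spec, attach_pct) {
  m <- harm_window_moments(spec, attach_pct)
  kT <- RGAS_KCAL * spec$T
  kw <- m$kw
  ## completing the square: Z = sqrt(pi kT / ktot) *
  ##   exp(-beta k_sys kw (x0 - x_sys)^2 / ktot)
  0.5 * log(pi * kT / m$ktot) -
    (spec$k_sys * kw * (spec$x0 - spec$x_sys)^2 / m$ktot) / kT
}

#' Closed-form window free-energy difference
#'
#' `-kT ln(Z_b / Z_a)` from the Gaussian partition functions of two
#' restraint windows of the same system.
#'
#' @param spec an [harmonic_system_spec()].
#' @param pct_a,pct_b attach percentages of the two windows.
#' @return Free energy (kcal/mol) of going from window a to window b.
#' @export
analytic_window_dg <- function(spec, pct_a, pct_b) {
  kT <- RGAS_KCAL * spec$T
  -kT * (harm_log_z(spec, pct_b) - harm_log_z(spec, pct_a))
}

#' Full attach leg for a harmonic system: samples plus reduced potentials
#'
#' Samples every window of the schedule and assembles the reduced-potential
#' matrix for the restraint energy `(pct/100) k_win (x - x0)^2`, ready for
#' [mbar_free_energies()].
#'
#' @param spec an [harmonic_system_spec()].
#' @param attach_rest window percentages (0 ... 100).
#' @param seed integer seed (per-window seeds are derived from it).
#' @return List: `samples` (list per window), `rpm` (an `abfe_rpm`),
#'   `exact_dg` (closed-form attach free energy, kcal/mol).
#' @export
sample_harmonic_attach <- function(spec, attach_rest, seed) {
  nw <- length(attach_rest)
  samples <- lapply(seq_len(nw), function(i)
    sample_harmonic_window(spec, attach_rest[i], seed + i - 1))
  x <- unlist(samples)
  beta <- 1 / (RGAS_KCAL * spec$T)
  base <- spec$k_win * (x - spec$x0)^2 * beta
  u <- outer(attach_rest / 100, base)
  rpm <- reduced_potential_matrix(u, vapply(samples, length, integer(1)),
                                  spec$T)
  list(samples = samples, rpm = rpm,
       exact_dg = analytic_window_dg(spec, attach_rest[1],
                                     attach_rest[nw]))
}

#' Specification of the 1-D toy alchemical system
#'
#' `U(x; lambda) = (1 - lambda) k_A (x - a)^2 + lambda k_B (x - b)^2`,
#' harmonic at every lambda, with an exactly integrable partition function.
#'
#' @param k_A,k_B end-state springs (> 0).
#' @param a,b end-state centres.
#' @param T temperature (K).
#' @param n_samples samples per window.
#' @return Object of class `abfe_toyspec`.
#' @export
toy_alchemical_spec <- function(k_A = 5, k_B = 25, a = 0, b = 1,
                                T = DEFAULT_TEMPERATURE, n_samples = 1000) {
  stopifnot(k_A > 0, k_B > 0, n_samples >= 1)
  structure(list(k_A = k_A, k_B = k_B, a = a, b = b, T = T,
                 n_samples = n_samples), class = "abfe_toyspec")
}

toy_params <- function(spec, lambda) {
  k <- (1 - lambda) * spec$k_A + lambda * spec$k_B
  m <- ((1 - lambda) * spec$k_A * spec$a + lambda * spec$k_B * spec$b) / k
  c0 <- (1 - lambda) * spec$k_A * spec$a^2 + lambda * spec$k_B * spec$b^2 -
    k * m^2
  list(k = k, m = m, c0 = c0)
}

toy_log_z <- function(spec, lambda) {
  p <- toy_params(spec, lambda)
  kT <- RGAS_KCAL * spec$T
  0.5 * log(pi * kT / p$k) - p$c0 / kT
}

#' Exact free-energy change of the toy alchemical transformation
#'
#' `-kT ln(Z(1) / Z(0))` in closed form.
#'
#' @param spec a [toy_alchemical_spec()].
#' @return kcal/mol.
#' @export
toy_exact_dg <- function(spec) {
  kT <- RGAS_KCAL * spec$T
  -kT * (toy_log_z(spec, 1) - toy_log_z(spec, 0))
}

#' Generate samples for the toy alchemical model
#'
#' Draws i.i.d. Boltzmann samples at each lambda, returning per-window
#' dU/dlambda samples (for TI) and the reduced-potential matrix over all
#' lambda states (for MBAR), together with the exact free energy.
#'
#' @param spec a [toy_alchemical_spec()].
#' @param lambdas window lambda values.
#' @param seed integer seed.
#' @return List: `lambdas`, `x` (list of coordinate samples), `dudl` (list
#'   of dU/dlambda samples), `rpm` (an `abfe_rpm`), `exact_dg` (kcal/mol).
#' @export
generate_toy_alchemical <- function(spec, lambdas, seed) {
  kT <- RGAS_KCAL * spec$T
  x <- lapply(seq_along(lambdas), function(i) {
    p <- toy_params(spec, lambdas[i])
    with_seed(seed + i - 1,
              stats::rnorm(spec$n_samples, p$m, sqrt(kT / (2 * p$k))))
  })
  dudl <- lapply(x, function(xi)
    spec$k_B * (xi - spec$b)^2 - spec$k_A * (xi - spec$a)^2)
  xa <- unlist(x)
  u <- matrix(0, length(lambdas), length(xa))
  uA <- spec$k_A * (xa - spec$a)^2
  uB <- spec$k_B * (xa - spec$b)^2
  for (i in seq_along(lambdas))
    u[i, ] <- ((1 - lambdas[i]) * uA + lambdas[i] * uB) / kT
  rpm <- reduced_potential_matrix(u, vapply(x, length, integer(1)), spec$T)
  list(lambdas = lambdas, x = x, dudl = dudl, rpm = rpm,
       exact_dg = toy_exact_dg(spec))
}

#' Metropolis samples of the restrained TR coordinates
#'
#' Samples `(r, theta, phi, Theta, Phi, Psi)` from the density proportional
#' to `r^2 sin(theta) sin(Theta) exp(-beta sum u)` of the ligand TR
#' restraints, for Monte-Carlo cross-checks of the analytic release term.
#' Angles are returned in degrees.
#'
#' @param spec an [tr_release_spec()].
#' @param n number of samples retained (after thinning).
#' @param seed integer seed.
#' @param thin keep every `thin`-th sweep.
#' @return Matrix n x 6 (columns r, theta, phi, Theta, Phi, Psi);
#'   attribute `acceptance` gives the move acceptance rate.
#' @export
sample_tr_coordinates <- function(spec, n, seed, thin = 5) {
  kT <- RGAS_KCAL * spec$T
  beta <- 1 / kT
  d2r <- pi / 180
  x0 <- c(spec$r0, spec$theta0 * d2r, spec$phi0 * d2r,
          spec$Theta0 * d2r, spec$Phi0 * d2r, spec$Psi0 * d2r)
  ks <- c(spec$k_d, rep(spec$k_a, 5))
  step <- sqrt(kT / (2 * ks)) * 2.4 / sqrt(6)   # 6-D random-walk scaling
  wrapd <- function(d) d - 2 * pi * round(d / (2 * pi))
  logdens <- function(v) {
    if (v[1] <= 0 || v[2] <= 0 || v[2] >= pi || v[4] <= 0 || v[4] >= pi)
      return(-Inf)
    dif <- v - x0
    dif[c(3, 5, 6)] <- wrapd(dif[c(3, 5, 6)])
    2 * log(v[1]) + log(sin(v[2])) + log(sin(v[4])) -
      beta * sum(ks * dif^2)
  }
  with_seed(seed, {
    cur <- x0
    lp <- logdens(cur)
    out <- matrix(0, n, 6)
    acc <- 0
    tot <- 0
    for (i in seq_len(n * thin)) {
      prop <- cur + stats::rnorm(6, 0, step)
      prop[c(3, 5, 6)] <- prop[c(3, 5, 6)] %% (2 * pi)
      lpp <- logdens(prop)
      tot <- tot + 1
      if (log(stats::runif(1)) < lpp - lp) {
        cur <- prop
        lp <- lpp
        acc <- acc + 1
      }
      if (i %% thin == 0) out[i %/% thin, ] <- cur
    }
    out[, 2:6] <- out[, 2:6] / d2r
    colnames(out) <- c("r", "theta", "phi", "Theta", "Phi", "Psi")
    attr(out, "acceptance") <- acc / tot
    out
  })
}

#' Synthetic protein-ligand complex for the anchor-geometry pipeline
#'
#' Builds a rigid 30-residue helical scaffold with backbone N/CA/C atoms, a
#' compact 12-heavy-atom ligand placed inside the default strike zone below
#' the P1 anchor, and a reference copy of the protein; the returned complex
#' is the reference-frame system under a random rigid transform, so the
#' alignment step is exercised. Entirely synthetic: it emulates the
#' geometry of a binding site, not the chemistry.
#'
#' @param seed integer seed (controls the sequence, ligand jitter and the
#'   rigid transform).
#' @param ligand_offset extra displacement (3-vector, Angstrom) applied to
#'   the ligand, e.g. to push it out of the strike zone.
#' @return List: `complex` (transformed structure), `reference` (protein
#'   only, reference frame), `graph` (ligand `abfe_graph`),
#'   `lig_resname`, `lig_serials` (graph order), anchors `P1`, `P2`, `P3`
#'   (selector strings) and `zone` (an `abfe_zone`).
#' @export
make_synthetic_complex <- function(seed = 1, ligand_offset = c(0, 0, 0)) {
  with_seed(seed, {
    nres <- 30
    aa3 <- names(AA3TO1)
    seq3 <- sample(aa3, nres, replace = TRUE)
    ## helical backbone: N, CA, C on a common helix with phase offsets
    mk <- function(i, phase, radius, rise_off) {
      t <- (i - 1) * 100 * pi / 180 + phase
      c(radius * cos(t), radius * sin(t), 1.5 * (i - 1) + rise_off)
    }
    rows <- list()
    serial <- 0
    for (i in seq_len(nres)) {
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1
        p <- switch(at,
                    N = mk(i, -0.55, 1.6, -0.5),
                    CA = mk(i, 0, 2.3, 0),
                    C = mk(i, 0.45, 1.7, 0.6))
        rows[[serial]] <- data.frame(
          serial = serial, name = at, element = substr(at, 1, 1),
          resid = seq3[i], chain = "A", resno = i,
          x = p[1], y = p[2], z = p[3], het = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    prot <- do.call(rbind, rows)
    ## ligand: fused 6-ring plus 6-atom tail, jittered, centred ~6 A below
    ## P1 (CA of residue 15) in z
    p1 <- prot[prot$resno == 15 & prot$name == "CA", ]
    ring <- t(vapply(0:5, function(k) {
      a <- k * pi / 3
      c(1.4 * cos(a), 1.4 * sin(a), 0)
    }, numeric(3)))
    tail_ <- t(vapply(1:6, function(k)
      c(1.4 + 1.25 * k, 0.35 * (-1)^k, 0.3 * k), numeric(3)))
    lig <- rbind(ring, tail_)
    lig <- lig + matrix(stats::rnorm(nrow(lig) * 3, 0, 0.05),
                        ncol = 3)
    lig <- sweep(lig, 2, colMeans(lig[1:6, , drop = FALSE]))
    lig <- sweep(lig, 2, c(p1$x, p1$y, p1$z - 6), `+`)
    lig <- sweep(lig, 2, as.numeric(ligand_offset), `+`)
    elements <- c(rep("C", 5), "N", "C", "O", rep("C", 4))
    bonds <- rbind(cbind(1:6, c(2:6, 1)),      # ring
                   c(1, 7), c(7, 8), c(8, 9), c(9, 10), c(10, 11),
                   c(11, 12))
    lrows <- lapply(seq_len(nrow(lig)), function(k)
      data.frame(serial = serial + k, name = paste0(elements[k], k),
                 element = elements[k], resid = "LIG", chain = "A",
                 resno = nres + 1, x = lig[k, 1], y = lig[k, 2],
                 z = lig[k, 3], het = TRUE, stringsAsFactors = FALSE))
    atoms <- rbind(prot, do.call(rbind, lrows))
    reference <- new_structure(prot, title = "synthetic reference")
    complex <- new_structure(atoms, title = "synthetic complex")
    ## random rigid transform of the complex away from the reference frame
    Rm <- random_rotation()
    tv <- stats::rnorm(3, 0, 8)
    xyz <- sweep(coords(complex) %*% t(Rm), 2, tv, `+`)
    complex <- set_coords(complex, xyz)
    list(complex = complex, reference = reference,
         graph = molecular_graph(elements, bonds),
         lig_resname = "LIG",
         lig_serials = serial + seq_len(nrow(lig)),
         P1 = ":15@CA", P2 = ":8@CA", P3 = ":22@CA",
         zone = strike_zone(l1_x = 0, l1_y = 0, l1_range = 4,
                            l1_z = 3, l1_zm = 9,
                            min_adis = 2, max_adis = 6))
  })
}
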