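## Free-energy estimators: MBAR, thermodynamic integration with Gaussian
## quadrature, the semi-analytic standard-state release of the ligand
## translational/rotational restraints, and block-based uncertainties.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Column-wise logsumexp of (a + M) where a is a vector added per row.
colLogSumExp <- function(M) {
  m <- apply(M, 2, max)
  m + log(colSums(exp(sweep(M, 2, m))))
}

#' Reduced-potential matrix from restraint-coordinate samples
#'
#' Builds the K x N matrix of dimensionless potentials `u[i, n] =
#' beta * sum_r k_ir (x_nr - x0_r)^2`, where `k_ir` is the window-i scaled
#' spring constant and the samples come from all windows pooled in order.
#'
#' @param windows list of per-window sample matrices (one row per frame,
#'   one column per restraint, in the order of `set$terms`; angular columns
#'   in degrees).
#' @param schedule an `abfe_schedule` with `attach_rest` of the same length
#'   as `windows`.
#' @param set an `abfe_restraints` with `x0` filled.
#' @param T temperature (K).
#' @return Object of class `abfe_rpm`: `u` (K x N matrix of beta*U),
#'   `counts` (samples per window), `T`.
#' @export
reduced_potentials <- function(windows, schedule, set,
                               T = DEFAULT_TEMPERATURE) {
  pct <- schedule$attach_rest
  if (length(windows) != length(pct))
    stop("number of sample sets does not match the schedule")
  t <- set$terms
  R <- nrow(t)
  sm <- lapply(windows, function(w) {
    w <- as.matrix(w)
    if (ncol(w) != R) stop("sample columns do not match restraint count")
    w
  })
  all_x <- do.call(rbind, sm)
  N <- nrow(all_x)
  beta <- 1 / (RGAS_KCAL * T)
  ## per-sample full-strength energy of each term, then scale per window
  eterm <- matrix(0, N, R)
  for (r in seq_len(R)) {
    eterm[, r] <- harmonic_term_energy(t$kind[r], t$k[r], all_x[, r], t$x0[r])
  }
  base <- rowSums(eterm)
  u <- outer(pct / 100, base * beta)
  structure(list(u = u, counts = vapply(sm, nrow, integer(1)), T = T),
            class = "abfe_rpm")
}

#' Reduced-potential matrix from raw dimensionless potentials
#'
#' @param u K x N matrix of beta*U values (windows by pooled samples).
#' @param counts samples contributed by each window (sums to N).
#' @param T temperature (K).
#' @return An `abfe_rpm`.
#' @export
reduced_potential_matrix <- function(u, counts, T = DEFAULT_TEMPERATURE) {
  u <- as.matrix(u)
  if (sum(counts) != ncol(u)) stop("counts do not sum to the sample total")
  if (any(!is.finite(u))) stop("non-finite reduced potential")
  structure(list(u = u, counts = as.integer(counts), T = T),
            class = "abfe_rpm")
}

#' MBAR free energies
#'
#' Solves the self-consistent multistate Bennett acceptance ratio equations
#' for the per-window free energies, gauge-fixed so the first window is
#' zero. Iteration starts self-consistently and switches to Newton steps on
#' the MBAR objective (with fallback to self-consistent iteration when a
#' Newton step does not reduce the residual); convergence when the largest
#' change is below `tol` (in kT).
#'
#' @param rpm an `abfe_rpm`.
#' @param tol convergence tolerance in kT.
#' @param max_iter maximum iterations.
#' @return Numeric vector of per-window free energies in kcal/mol
#'   (`G[1] = 0`); attribute `f` holds the dimensionless values,
#'   `iterations` the count used.
#' @export
mbar_free_energies <- function(rpm, tol = 1e-8, max_iter = 10000) {
  u <- rpm$u
  Nk <- rpm$counts
  K <- nrow(u)
  if (ncol(u) < 1) stop("no samples")
  f <- numeric(K)
  logNk <- log(Nk)
  sc_update <- function(f) {
    logden <- colLogSumExp(sweep(-u, 1, logNk + f, `+`))
    fnew <- -apply(sweep(-u, 2, logden, `-`), 1, logsumexp)
    fnew - fnew[1]
  }
  iter <- 0
  repeat {
    iter <- iter + 1
    fold <- f
    f <- sc_update(f)
    if (iter > 5 && K > 1) {
      ## Newton step on the convex MBAR objective (weights W as in the
      ## estimator); fall back to the self-consistent update if the step
      ## is ill-conditioned or implausibly large
      logden <- colLogSumExp(sweep(-u, 1, logNk + f, `+`))
      W <- exp(t(sweep(sweep(-u, 2, logden, `-`), 1, f, `+`)))
      colsum <- colSums(W)
      g <- Nk * colsum - Nk
      H <- -(t(W) %*% W) * outer(Nk, Nk)
      diag(H) <- diag(H) + Nk * colsum
      free <- 2:K
      step <- tryCatch(solve(H[free, free, drop = FALSE], g[free]),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step)) &&
          max(abs(step)) < 10 * (1 + max(abs(f)))) {
        f[free] <- f[free] - step
        f <- f - f[1]
      }
    }
    delta <- max(abs(f - fold))
    if (delta < tol) break
    if (iter >= max_iter)
      stop("MBAR failed to converge: residual ", signif(delta, 3),
           " after ", iter, " iterations")
  }
  G <- f * RGAS_KCAL * rpm$T
  attr(G, "f") <- f
  attr(G, "iterations") <- iter
  G
}

#' Free-energy change of a full attach (or release) leg from MBAR
#'
#' Convenience wrapper: `G[last] - G[first]` of [mbar_free_energies()].
#'
#' @inheritParams mbar_free_energies
#' @return Scalar kcal/mol.
#' @export
mbar_delta_g <- function(rpm, tol = 1e-8, max_iter = 10000) {
  G <- mbar_free_energies(rpm, tol = tol, max_iter = max_iter)
  unname(G[length(G)] - G[1])
}

#' Gauss-Legendre nodes and weights on [0, 1]
#'
#' @param n number of nodes (the 12-point rule is the usual default for
#'   the decoupling components).
#' @return List with `nodes` and `weights` (weights sum to 1).
#' @export
gauss_legendre_01 <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(nodes = gl$x, weights = gl$w)
}

#' Thermodynamic integration with Gaussian quadrature
#'
#' `dG = sum_i w_i <dU/dlambda>_i` over nodes on [0, 1].
#'
#' @param nodes lambda values.
#' @param weights quadrature weights (must sum to 1 over [0, 1]).
#' @param dudl_means mean dU/dlambda at each node (kcal/mol).
#' @return Scalar kcal/mol.
#' @export
ti_gauss_quadrature <- function(nodes, weights, dudl_means) {
  if (length(nodes) != length(weights) ||
      length(nodes) != length(dudl_means))
    stop("nodes, weights and dudl_means differ in length")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("quadrature weights must sum to 1 on [0, 1]")
  sum(weights * dudl_means)
}

#' Specification of the ligand TR release term
#'
#' @param k_d distance spring constant (kcal/mol/A^2, `lig_distance_force`).
#' @param k_a angular spring constant (kcal/mol/rad^2, `lig_angle_force`).
#' @param r0 reference D1 distance (A; 5.00 by construction).
#' @param theta0,phi0 reference A1 (deg) and T1 (deg).
#' @param Theta0,Phi0,Psi0 reference A2, T2, T3 (deg) - the Euler angles of
#'   the ligand orientation.
#' @param T temperature (K).
#' @param conc standard concentration (molecules/A^3; 1 M default).
#' @return Object of class `abfe_trspec`.
#' @export
tr_release_spec <- function(k_d, k_a, r0 = 5, theta0 = 90, phi0 = 0,
                            Theta0 = 90, Phi0 = 0, Psi0 = 0,
                            T = DEFAULT_TEMPERATURE,
                            conc = 1 / STD_VOLUME_A3) {
  if (k_d <= 0 || k_a <= 0)
    stop("force constants must be positive (integral diverges otherwise)")
  stopifnot(theta0 > 0, theta0 < 180, Theta0 > 0, Theta0 < 180, r0 > 0)
  structure(list(k_d = k_d, k_a = k_a, r0 = r0, theta0 = theta0,
                 phi0 = phi0, Theta0 = Theta0, Phi0 = Phi0, Psi0 = Psi0,
                 T = T, conc = conc), class = "abfe_trspec")
}

## 1-D Boltzmann integrals entering the TR release term. Angles in radians
## internally; dihedral potentials use the periodic (wrapped) difference.
tr_integrals <- function(spec) {
  kT <- RGAS_KCAL * spec$T
  beta <- 1 / kT
  d2r <- pi / 180
  reltol <- 1e-8
  ## radial: integrand r^2 exp(-beta k_d (r-r0)^2), truncated where it
  ## falls below 1e-16 of its peak
  half <- sqrt(log(1e16) * kT / spec$k_d)
  lo <- max(0, spec$r0 - half - 1)
  hi <- spec$r0 + half + 1
  I_r <- stats::integrate(function(r) r^2 * exp(-beta * spec$k_d *
                                                  (r - spec$r0)^2),
                          lo, hi, rel.tol = reltol)$value
  polar <- function(x0_deg) {
    x0 <- x0_deg * d2r
    stats::integrate(function(th) sin(th) *
                       exp(-beta * spec$k_a * (th - x0)^2),
                     0, pi, rel.tol = reltol)$value
  }
  azimuthal <- function(x0_deg) {
    x0 <- x0_deg * d2r
    f <- function(ph) {
      d <- ph - x0
      d <- d - 2 * pi * round(d / (2 * pi))
      exp(-beta * spec$k_a * d^2)
    }
    cut <- (x0 + pi) %% (2 * pi)   # split at the wrap point
    stats::integrate(f, 0, cut, rel.tol = reltol)$value +
      stats::integrate(f, cut, 2 * pi, rel.tol = reltol)$value
  }
  list(I_r = I_r,
       I_theta = polar(spec$theta0),
       I_phi = azimuthal(spec$phi0),
       I_Theta = polar(spec$Theta0),
       I_Phi = azimuthal(spec$Phi0),
       I_Psi = azimuthal(spec$Psi0))
}

#' Semi-analytic standard-state release of the ligand TR restraints
#'
#' Evaluates the Euler-angle/spherical-coordinate release free energy
#'
#' `dG = kT ln(C/8 pi^2) + kT ln(I_r I_theta I_phi) + kT ln(I_Theta I_Phi
#' I_Psi)`
#'
#' where the six one-dimensional Boltzmann integrals carry the r^2 sin
#' Jacobian of the translational part and the sin Jacobian of the
#' orientational part. Computed with adaptive quadrature (relative
#' tolerance 1e-8).
#'
#' @param spec an `abfe_trspec`.
#' @return Release free energy in kcal/mol.
#' @export
analytic_tr_release <- function(spec) {
  kT <- RGAS_KCAL * spec$T
  I <- tr_integrals(spec)
  kT * log(spec$conc / (8 * pi^2)) +
    kT * log(I$I_r * I$I_theta * I$I_phi) +
    kT * log(I$I_Theta * I$I_Phi * I$I_Psi)
}

#' Stiff-spring Gaussian closed form of the TR release term
#'
#' Limit of [analytic_tr_release()] for large force constants, where each
#' Boltzmann integral becomes Gaussian:
#' `kT ln[(C/8 pi^2) r0^2 sin(theta0) sin(Theta0) pi^3 (kT)^3 /
#' sqrt(k_d k_a^5)]`.
#'
#' @param spec an `abfe_trspec`.
#' @return kcal/mol.
#' @export
tr_release_stiff_limit <- function(spec) {
  kT <- RGAS_KCAL * spec$T
  d2r <- pi / 180
  kT * log(spec$conc / (8 * pi^2) * spec$r0^2 *
             sin(spec$theta0 * d2r) * sin(spec$Theta0 * d2r) *
             pi^3 * kT^3 / sqrt(spec$k_d * spec$k_a^5))
}

#' Split samples into contiguous blocks
#'
#' Order-preserving split into `n_blocks` contiguous pieces whose sizes
#' differ by at most one; any remainder goes to the last blocks.
#'
#' @param samples a vector, matrix or data.frame (rows are frames).
#' @param n_blocks number of blocks (>= 2).
#' @return List of blocks.
#' @export
split_blocks <- function(samples, n_blocks) {
  n <- if (is.null(dim(samples))) length(samples) else nrow(samples)
  if (n_blocks < 2) stop("need at least 2 blocks")
  if (n < n_blocks) stop("fewer samples than blocks")
  base <- n %/% n_blocks
  extra <- n %% n_blocks
  sizes <- rep(base, n_blocks)
  if (extra > 0)
    sizes[(n_blocks - extra + 1):n_blocks] <- base + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_len(n_blocks), function(i) {
    idx <- starts[i]:ends[i]
    if (is.null(dim(samples))) samples[idx] else
      samples[idx, , drop = FALSE]
  })
}

#' Block-based uncertainty
#'
#' `sigma = sqrt((1/N_b) sum_n (x_n - xbar)^2)` with `xbar` the estimate
#' from the whole trajectory (not the block mean) - a conservative spread
#' measure.
#'
#' @param full_estimate estimate from all samples.
#' @param block_estimates per-block estimates (length >= 2).
#' @return Object of class `abfe_blocks` with `sigma`, `x_bar`, `x_n`,
#'   `N_b`.
#' @export
block_sigma <- function(full_estimate, block_estimates) {
  nb <- length(block_estimates)
  if (nb < 2) stop("need at least 2 block estimates")
  sigma <- sqrt(mean((block_estimates - full_estimate)^2))
  structure(list(N_b = nb, x_bar = full_estimate, x_n = block_estimates,
                 sigma = sigma), class = "abfe_blocks")
}

#' Quadrature sum of independent uncertainties
#'
#' @param sigmas vector of non-negative standard deviations.
#' @return `sqrt(sum(sigmas^2))` (0 for an empty vector).
#' @export
combine_sigma_quadrature <- function(sigmas) {
  if (length(sigmas) == 0) return(0)
  if (any(sigmas < 0)) stop("negative sigma")
  sqrt(sum(sigmas^2))
}

#' Component free-energy estimate
#'
#' @param code component letter (a, l, t, e, v, w, f, b, c, r).
#' @param dG free energy of the named process (kcal/mol).
#' @param sigma uncertainty (kcal/mol).
#' @param method one of `"MBAR"`, `"TI-GQ"`, `"analytical"`.
#' @return Object of class `abfe_component`.
#' @export
component_estimate <- function(code, dG, sigma = 0, method = "MBAR") {
  code <- match.arg(code, c("a", "l", "t", "e", "v", "w", "f", "b",
                            "c", "r"))
  method <- match.arg(method, c("MBAR", "TI-GQ", "analytical"))
  allowed <- list(a = "MBAR", l = "MBAR", t = "MBAR",
                  e = c("MBAR", "TI-GQ"), v = c("MBAR", "TI-GQ"),
                  w = c("MBAR", "TI-GQ"), f = c("MBAR", "TI-GQ"),
                  b = "analytical", c = "MBAR", r = "MBAR")
  if (!method %in% allowed[[code]])
    stop("method ", method, " not permitted for component '", code, "'")
  if (sigma < 0) stop("negative sigma")
  structure(list(code = code, dG = dG, sigma = sigma, method = method),
            class = "abfe_component")
}

#' Read/write per-window sample tables
#'
#' TSV with a header naming the restraint labels (or `dudl` / `u_k`
#' columns) and one row per frame.
#'
#' @param path file path.
#' @return Numeric matrix of samples.
#' @export
read_window_samples <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  as.matrix(d)
}

#' @rdname read_window_samples
#' @param samples numeric matrix (one row per frame).
#' @export
write_window_samples <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
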