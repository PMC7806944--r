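kT298 <- R_KCAL_TEST * 298.15

test_that("reduced potentials reproduce the per-term harmonic sums", {
  set <- restraint_set(data.frame(label = "D", kind = "distance",
                                  a1 = "a", a2 = "b", a3 = NA, a4 = NA,
                                  k = 1, x0 = 0), "ligand_conf")
  Tbeta1 <- 1 / R_KCAL_TEST    # temperature at which beta = 1
  sched <- window_schedule(attach_rest = c(0, 100))
  rpm <- reduced_potentials(list(matrix(0.5, 3, 1), matrix(1, 2, 1)),
                            sched, set, T = Tbeta1)
  expect_equal(rpm$u[1, ], rep(0, 5))               # 0% window row
  expect_equal(rpm$u[2, 4], 1.0)                    # k=1, dx=1, beta=1
  expect_equal(rpm$counts, c(3L, 2L))

  # random multi-restraint case against a direct per-term oracle
  set.seed(3)
  terms <- data.frame(label = c("D", "A", "T"),
                      kind = c("distance", "angle", "dihedral"),
                      a1 = "a", a2 = "b", a3 = c(NA, "c", "c"),
                      a4 = c(NA, NA, "d"),
                      k = c(4, 30, 20), x0 = c(2, 95, 170))
  set3 <- restraint_set(terms, "ligand_conf")
  sched3 <- window_schedule(attach_rest = c(0, 25, 100))
  w <- lapply(1:3, function(i)
    cbind(runif(4, 1, 3), runif(4, 60, 130), runif(4, -180, 180)))
  rpm3 <- reduced_potentials(w, sched3, set3, T = 298.15)
  beta <- 1 / kT298
  for (i in 1:3) {
    xall <- do.call(rbind, w)
    for (n in seq_len(nrow(xall))) {
      e <- (sched3$attach_rest[i] / 100) *
        (4 * (xall[n, 1] - 2)^2 +
           30 * ((xall[n, 2] - 95) * pi / 180)^2 +
           20 * (abfekit:::wrap_deg(xall[n, 3] - 170) * pi / 180)^2)
      expect_equal(rpm3$u[i, n], beta * e, tolerance = 1e-12)
    }
  }

  expect_error(reduced_potentials(list(matrix(0, 2, 2)), sched, set),
               "number of sample sets|columns")
})

test_that("MBAR recovers closed-form harmonic attachment free energies", {
  # identical windows: zero free-energy difference
  spec0 <- harmonic_system_spec(k_sys = 8, k_win = 5, n_samples = 2000)
  s0 <- sample_harmonic_window(spec0, 100, 1)
  kT <- R_KCAL_TEST * spec0$T
  u0 <- (spec0$k_sys + spec0$k_win)   # same potential in both rows
  u <- rbind((u0 * (c(s0, s0) - 0)^2) / kT, (u0 * (c(s0, s0) - 0)^2) / kT)
  rpm0 <- reduced_potential_matrix(u, c(2000, 2000), spec0$T)
  expect_equal(mbar_delta_g(rpm0), 0, tolerance = 1e-8)

  # two-window attachment vs the Gaussian partition-function ratio
  spec <- harmonic_system_spec(k_sys = 10, x_sys = 0, k_win = 10, x0 = 0,
                               n_samples = 50000)
  sa <- sample_harmonic_attach(spec, c(0, 100), seed = 101)
  est <- mbar_delta_g(sa$rpm)
  exact <- (kT / 2) * log((spec$k_sys + spec$k_win) / spec$k_sys)
  expect_equal(sa$exact_dg, exact, tolerance = 1e-12)
  # block-based standard error of the pooled estimate
  nb <- 10
  blocks <- vapply(seq_len(nb), function(b) {
    wb <- lapply(sa$samples, function(x) split_blocks(x, nb)[[b]])
    xb <- unlist(wb)
    ub <- outer(c(0, 100) / 100,
                spec$k_win * (xb - spec$x0)^2 / kT)
    mbar_delta_g(reduced_potential_matrix(ub, lengths(wb), spec$T))
  }, numeric(1))
  se <- block_sigma(est, blocks)$sigma / sqrt(nb)
  expect_lt(abs(est - exact), 3 * se + 1e-4)
})

test_that("forward and backward exponential averages bracket the MBAR estimate", {
  spec <- harmonic_system_spec(k_sys = 6, x_sys = 0, k_win = 8, x0 = 0.4,
                               n_samples = 20000)
  sa <- sample_harmonic_attach(spec, c(0, 100), seed = 77)
  est <- mbar_delta_g(sa$rpm)
  kT <- R_KCAL_TEST * spec$T
  du0 <- spec$k_win * (sa$samples[[1]] - spec$x0)^2 / kT
  du1 <- spec$k_win * (sa$samples[[2]] - spec$x0)^2 / kT
  fwd <- -kT * (abfekit:::logsumexp(-du0) - log(length(du0)))
  bwd <- kT * (abfekit:::logsumexp(du1) - log(length(du1)))
  # EXP from the low side overestimates, from the high side
  # underestimates (in expectation); MBAR sits between them
  expect_lte(est, max(fwd, bwd) + 1e-6)
  expect_gte(est, min(fwd, bwd) - 1e-6)
  expect_lt(abs(est - sa$exact_dg), 0.05)
})

test_that("MBAR is gauge- and permutation-invariant", {
  spec <- harmonic_system_spec(k_sys = 5, k_win = 15, x0 = 0.3,
                               n_samples = 2000)
  sa <- sample_harmonic_attach(spec, c(0, 50, 100), seed = 5)
  base <- mbar_free_energies(sa$rpm)

  shifted <- sa$rpm
  shifted$u <- sa$rpm$u + 7.5          # constant added to every entry
  expect_equal(mbar_free_energies(shifted), base, tolerance = 1e-6,
               ignore_attr = TRUE)

  perm <- sample(ncol(sa$rpm$u))
  # permuting samples within the pooled set (keeping counts) only matters
  # through which window each sample is attributed to; a global
  # permutation that preserves the per-window sample blocks leaves the
  # estimate unchanged
  blocks <- split(seq_len(ncol(sa$rpm$u)),
                  rep(seq_along(sa$rpm$counts), sa$rpm$counts))
  perm2 <- unlist(lapply(blocks, sample))
  permuted <- sa$rpm
  permuted$u <- sa$rpm$u[, perm2]
  expect_equal(mbar_free_energies(permuted), base, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Gauss-Legendre TI integrates polynomials of degree 2n-1 exactly", {
  gl <- gauss_legendre_01(12)
  expect_length(gl$nodes, 12)
  expect_equal(sum(gl$weights), 1, tolerance = 1e-12)

  expect_equal(ti_gauss_quadrature(gl$nodes, gl$weights,
                                   rep(3.7, 12)), 3.7)

  # degree-23 polynomial: integral of sum c_k x^k over [0,1]
  set.seed(8)
  cf <- rnorm(24)
  vals <- vapply(gl$nodes, function(x) sum(cf * x^(0:23)), numeric(1))
  exact <- sum(cf / (1:24))
  expect_equal(ti_gauss_quadrature(gl$nodes, gl$weights, vals), exact,
               tolerance = 1e-10)

  expect_error(ti_gauss_quadrature(gl$nodes, gl$weights, rep(1, 3)),
               "length")
  expect_error(ti_gauss_quadrature(c(0, 1), c(0.7, 0.7), c(1, 1)),
               "sum to 1")
})

test_that("the TR release term matches a brute-force grid and the stiff-spring limit", {
  spec <- tr_release_spec(k_d = 10, k_a = 15, r0 = 5, theta0 = 80,
                          phi0 = 30, Theta0 = 100, Phi0 = -40, Psi0 = 120)
  kT <- R_KCAL_TEST * spec$T
  beta <- 1 / kT
  d2r <- pi / 180

  # brute-force trapezoid grids over (r, theta, phi) and (Theta, Phi, Psi)
  trap <- function(f, grid) {
    h <- diff(grid[1:2])
    w <- rep(h, length(grid)); w[c(1, length(grid))] <- h / 2
    sum(w * f(grid))
  }
  rg <- seq(3, 7, length.out = 400)
  tg <- seq(1e-6, pi, length.out = 400)
  pg <- seq(0, 2 * pi, length.out = 400)
  wrap <- function(d) d - 2 * pi * round(d / (2 * pi))
  I_r <- trap(function(r) r^2 * exp(-beta * spec$k_d * (r - 5)^2), rg)
  I_t <- trap(function(th) sin(th) *
                exp(-beta * spec$k_a * (th - 80 * d2r)^2), tg)
  I_p <- trap(function(ph) exp(-beta * spec$k_a * wrap(ph - 30 * d2r)^2),
              pg)
  I_T <- trap(function(th) sin(th) *
                exp(-beta * spec$k_a * (th - 100 * d2r)^2), tg)
  I_P <- trap(function(ph) exp(-beta * spec$k_a *
                                 wrap(ph + 40 * d2r)^2), pg)
  I_S <- trap(function(ph) exp(-beta * spec$k_a *
                                 wrap(ph - 120 * d2r)^2), pg)
  oracle <- kT * log(spec$conc / (8 * pi^2)) + kT * log(I_r * I_t * I_p) +
    kT * log(I_T * I_P * I_S)
  expect_equal(analytic_tr_release(spec), oracle, tolerance = 1e-3)

  # stiff-spring Gaussian closed form
  for (k in c(100, 200, 400)) {
    stiff <- tr_release_spec(k_d = k, k_a = k)
    expect_lt(abs(analytic_tr_release(stiff) -
                    tr_release_stiff_limit(stiff)), 0.01)
  }

  # doubling the standard concentration adds exactly kT ln 2
  twice <- spec
  twice$conc <- 2 * spec$conc
  expect_equal(analytic_tr_release(twice) - analytic_tr_release(spec),
               kT * log(2), tolerance = 1e-9)

  expect_error(tr_release_spec(k_d = -1, k_a = 10), "positive")
})

test_that("the TR release cost increases with restraint stiffness", {
  vals_kd <- vapply(c(2, 5, 10, 20, 50), function(k)
    analytic_tr_release(tr_release_spec(k_d = k, k_a = 100)), numeric(1))
  vals_ka <- vapply(c(20, 50, 100, 200), function(k)
    analytic_tr_release(tr_release_spec(k_d = 5, k_a = k)), numeric(1))
  # releasing tighter restraints into the standard-state volume costs
  # more, so the (negative) release term decreases
  expect_true(all(diff(vals_kd) < 0))
  expect_true(all(diff(vals_ka) < 0))
})

test_that("block splitting and the block sigma follow the declared conventions", {
  expect_equal(lengths(split_blocks(1:10, 5)), rep(2L, 5))
  expect_equal(lengths(split_blocks(1:11, 5)), c(2L, 2L, 2L, 2L, 3L))
  expect_equal(unlist(split_blocks(1:11, 5)), 1:11, ignore_attr = TRUE)
  expect_error(split_blocks(1:3, 5), "fewer samples")
  expect_error(split_blocks(1:10, 1), "at least 2")

  expect_equal(block_sigma(4, c(4, 4, 4))$sigma, 0)
  expect_equal(block_sigma(2, c(1, 3))$sigma, 1)
  set.seed(12)
  xb <- rnorm(7)
  xbar <- 0.3   # deliberately not the block mean: Eq-style centring
  expect_equal(block_sigma(xbar, xb)$sigma,
               sqrt(mean((xb - xbar)^2)))
  expect_error(block_sigma(1, 2), "at least 2")
})

test_that("uncertainties combine in quadrature", {
  expect_equal(combine_sigma_quadrature(c(3, 4)), 5)
  expect_equal(combine_sigma_quadrature(0.7), 0.7)
  expect_equal(combine_sigma_quadrature(numeric(0)), 0)
  expect_error(combine_sigma_quadrature(c(1, -1)), "negative")
})

test_that("window sample tables round-trip through TSV", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(NULL, c("D1", "A1", "T1")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_window_samples(m, p)
  back <- read_window_samples(p)
  expect_equal(back, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colnames(back), colnames(m))
})
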