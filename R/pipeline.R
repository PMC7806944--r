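## Pose pipeline orchestration: align -> anchors -> restraints ->
## per-window samples (file-based or synthetic) -> estimation -> cycle
## assembly -> pose combination, with structured logging.

#' Sample restraint-coordinate windows from the synthetic Boltzmann model
#'
#' Each restrained internal coordinate fluctuates in an intrinsic harmonic
#' well centred on its reference value with spring `k_sys_frac * k_full`;
#' window i adds the restraint scaled by `attach_rest[i]/100`. Draws are
#' i.i.d. Gaussian in the coordinate's energy-consistent unit (Angstrom,
#' or radians converted to degrees for storage). The exact attach free
#' energy of this model is `sum_r (kT/2) ln(1 + k_r / k_sys_r)`.
#'
#' @param set an `abfe_restraints` with `x0` filled.
#' @param attach_rest window percentages.
#' @param seed integer seed.
#' @param k_sys_frac intrinsic spring as a fraction of the full restraint
#'   spring.
#' @param T temperature (K).
#' @param n_samples frames per window.
#' @return List: `windows` (list of n x R matrices), `exact_dg` (kcal/mol).
#' @export
sample_restraint_windows <- function(set, attach_rest, seed,
                                     k_sys_frac = 1,
                                     T = DEFAULT_TEMPERATURE,
                                     n_samples = 1000) {
  t <- set$terms
  R <- nrow(t)
  kT <- RGAS_KCAL * T
  k_sys <- k_sys_frac * t$k
  windows <- lapply(seq_along(attach_rest), function(i) {
    kw <- scale_window(t$k, attach_rest[i])
    sd_nat <- sqrt(kT / (2 * (k_sys + kw)))     # A or rad
    sd_store <- ifelse(t$kind == "distance", sd_nat, sd_nat * 180 / pi)
    with_seed(seed + i - 1, {
      m <- matrix(stats::rnorm(n_samples * R), n_samples, R)
      sweep(m, 2, sd_store, `*`) +
        matrix(t$x0, n_samples, R, byrow = TRUE)
    })
  })
  exact <- sum(kT / 2 * log(1 + t$k / k_sys))
  list(windows = windows, exact_dg = exact)
}

## MBAR estimate + block sigma for a restraint attach leg.
estimate_attach_component <- function(code, set, cfg, seed) {
  ar <- cfg$attach_rest
  sw <- sample_restraint_windows(set, ar, seed,
                                 T = cfg$temperature,
                                 n_samples = cfg$n_samples)
  rpm <- reduced_potentials(sw$windows, window_schedule(attach_rest = ar),
                            set, T = cfg$temperature)
  full <- mbar_delta_g(rpm)
  nb <- cfg$blocks
  blocks <- vapply(seq_len(nb), function(b) {
    wb <- lapply(sw$windows, function(w) split_blocks(w, nb)[[b]])
    mbar_delta_g(reduced_potentials(wb,
                                    window_schedule(attach_rest = ar),
                                    set, T = cfg$temperature))
  }, numeric(1))
  component_estimate(code, full, block_sigma(full, blocks)$sigma, "MBAR")
}

## Toy alchemical stand-ins for the decoupling components. Fixed spring
## parameters per letter code so each component is a distinct, reproducible
## transformation.
TOY_DECOUPLING_SPECS <- list(
  e = list(k_A = 4, k_B = 18, a = 0.0, b = 0.8),
  v = list(k_A = 6, k_B = 12, a = 0.0, b = 1.2),
  w = list(k_A = 5, k_B = 10, a = 0.0, b = 0.9),
  f = list(k_A = 4, k_B = 20, a = 0.0, b = 0.7)
)

estimate_decoupling_component <- function(code, cfg, seed) {
  p <- TOY_DECOUPLING_SPECS[[code]]
  spec <- toy_alchemical_spec(p$k_A, p$k_B, p$a, p$b,
                              T = cfg$temperature,
                              n_samples = cfg$n_samples)
  nb <- cfg$blocks
  if (identical(cfg$dd_type, "MBAR")) {
    lambdas <- if (!is.null(cfg$lambdas)) cfg$lambdas else
      seq(0, 1, length.out = 23)
    gen <- generate_toy_alchemical(spec, lambdas, seed)
    full <- mbar_delta_g(gen$rpm)
    blocks <- vapply(seq_len(nb), function(b) {
      xb <- lapply(gen$x, function(xi) split_blocks(xi, nb)[[b]])
      ub <- make_toy_rpm(spec, lambdas, xb)
      mbar_delta_g(ub)
    }, numeric(1))
    method <- "MBAR"
  } else {
    if (!is.null(cfg$lambdas) && !is.null(cfg$weights)) {
      nodes <- cfg$lambdas
      weights <- cfg$weights
    } else {
      gl <- gauss_legendre_01(12)
      nodes <- gl$nodes
      weights <- gl$weights
    }
    gen <- generate_toy_alchemical(spec, nodes, seed)
    means <- vapply(gen$dudl, mean, numeric(1))
    full <- ti_gauss_quadrature(nodes, weights, means)
    blocks <- vapply(seq_len(nb), function(b) {
      mb <- vapply(gen$dudl, function(d) mean(split_blocks(d, nb)[[b]]),
                   numeric(1))
      ti_gauss_quadrature(nodes, weights, mb)
    }, numeric(1))
    method <- "TI-GQ"
  }
  component_estimate(code, full,
                     block_sigma(full, blocks)$sigma, method)
}

make_toy_rpm <- function(spec, lambdas, x) {
  kT <- RGAS_KCAL * spec$T
  xa <- unlist(x)
  uA <- spec$k_A * (xa - spec$a)^2
  uB <- spec$k_B * (xa - spec$b)^2
  u <- matrix(0, length(lambdas), length(xa))
  for (i in seq_along(lambdas))
    u[i, ] <- ((1 - lambdas[i]) * uA + lambdas[i] * uB) / kT
  reduced_potential_matrix(u, vapply(x, length, integer(1)), spec$T)
}

## Analytic release of the ligand TR restraints, referenced to the
## measured restraint values of this pose.
tr_release_from_set <- function(lig_tr, cfg) {
  t <- lig_tr$terms
  x0 <- function(lab) t$x0[t$label == lab]
  spec <- tr_release_spec(k_d = cfg$lig_distance_force,
                          k_a = cfg$lig_angle_force,
                          r0 = x0("D1"), theta0 = x0("A1"),
                          phi0 = x0("T1"), Theta0 = x0("A2"),
                          Phi0 = x0("T2"), Psi0 = x0("T3"),
                          T = cfg$temperature)
  component_estimate("b", analytic_tr_release(spec), 0, "analytical")
}

#' Run the full pose pipeline on synthetic samples
#'
#' For each pose: align to the reference, build the anchor set (an
#' unstable pose is flagged and skipped), build the restraint sets,
#' estimate every configured free-energy component from the synthetic
#' Boltzmann samplers, assemble the thermodynamic cycle, and finally
#' combine the stable poses by Boltzmann weighting. A failure in any pose
#' is logged and the run continues with the remaining poses.
#'
#' @param cfg an `abfe_config` (see [parse_input_file()]).
#' @param inputs list with elements `poses` (list of complex structures),
#'   `reference` (protein structure or `NULL`), `graph` (ligand
#'   `abfe_graph`), `lig_serials` (structure serials of the graph atoms,
#'   in graph order).
#' @param log an optional [run_log()] collector.
#' @return List: `poses` (per-pose list with `result` ([pose_result()])
#'   and `cycle`), `combined` (from [combine_poses()], or `NULL` if no
#'   stable pose).
#' @export
run_pose_pipeline <- function(cfg, inputs, log = run_log()) {
  ctx <- thermo_context(T = cfg$temperature)
  zone <- strike_zone(cfg$l1_x, cfg$l1_y, cfg$l1_range, cfg$l1_z,
                      cfg$l1_zm, cfg$min_adis, cfg$max_adis)
  comps_wanted <- config_components(cfg)
  out <- list()
  log_event(log, "run", "-", "start",
            paste0("method=", cfg$method, " dd_type=", cfg$dd_type,
                   " seed=", cfg$seed))
  for (ip in seq_along(inputs$poses)) {
    pid <- names(inputs$poses)[ip]
    if (is.null(pid) || !nzchar(pid)) pid <- paste0("pose", ip)
    seed_p <- as.integer(cfg$seed) + 1000L * ip
    res <- tryCatch({
      anchors <- build_anchor_set(inputs$poses[[ip]], inputs$reference,
                                  cfg$P1, cfg$P2, cfg$P3, zone,
                                  cfg$lig_resname)
      if (is.null(anchors)) {
        log_event(log, "anchors", pid, "unstable",
                  "no L1 in strike zone")
        list(result = pose_result(pid, stable = FALSE), cycle = NULL)
      } else {
        log_event(log, "anchors", pid, "ok",
                  paste0("L1=", anchors$L1$serial))
        lig_tr <- build_ligand_tr_restraints(anchors,
                                             cfg$lig_distance_force,
                                             cfg$lig_angle_force)
        anchor_idx <- match(c(anchors$L1$serial, anchors$L2$serial,
                              anchors$L3$serial), inputs$lig_serials)
        lig_xyz <- coords(anchors$structure)[
          as.character(inputs$lig_serials), , drop = FALSE]
        lig_conf <- assign_ligand_conformational_restraints(
          inputs$graph, lig_xyz, anchor_idx,
          cfg$lig_discf_force, cfg$lig_dihcf_force)
        bb <- if (!is.null(cfg$bb_start) && !is.null(cfg$bb_end))
          c(cfg$bb_start, cfg$bb_end) else NULL
        prot_conf <- build_protein_conf_restraints(anchors,
                                                   cfg$rec_discf_force,
                                                   cfg$rec_dihcf_force,
                                                   bb)
        log_event(log, "restraints", pid, "ok",
                  paste0(nrow(lig_conf$terms), " ligand conf terms"))
        sets <- list(a = prot_conf, l = lig_conf, t = lig_tr,
                     c = lig_conf, r = prot_conf)
        comps <- list()
        for (code in comps_wanted) {
          seed_c <- seed_p + match(code, DD_CODES)
          comps[[code]] <- if (code %in% names(sets)) {
            estimate_attach_component(code, sets[[code]], cfg, seed_c)
          } else if (code %in% c("e", "v", "w", "f")) {
            estimate_decoupling_component(code, cfg, seed_c)
          } else if (code == "b") {
            tr_release_from_set(lig_tr, cfg)
          } else stop("unknown component code: ", code)
        }
        log_event(log, "estimate", pid, "ok",
                  paste(names(comps), collapse = ","))
        cy <- if (cfg$method == "SDR")
          assemble_sdr(comps, ctx, dd_dist = cfg$dd_dist)
        else assemble_dd(comps, ctx)
        log_event(log, "assemble", pid, "ok",
                  sprintf("dG_bind=%.3f", cy$dG_bind))
        list(result = pose_result(pid, cy$dG_bind, cy$sigma, TRUE),
             cycle = cy)
      }
    }, error = function(e) {
      log_event(log, "pipeline", pid, "failed",
                paste0(class(e)[1], ": ", conditionMessage(e)))
      list(result = pose_result(pid, stable = FALSE), cycle = NULL)
    })
    out[[pid]] <- res
  }
  stable <- Filter(function(p) p$result$stable, out)
  combined <- if (length(stable)) {
    combine_poses(lapply(out, `[[`, "result"), ctx)
  } else NULL
  if (!is.null(combined))
    log_event(log, "combine", "-", "ok",
              sprintf("dG_bind=%.3f best=%s", combined$dG_bind,
                      combined$best_pose))
  list(poses = out, combined = combined, log = log)
}

#' Structured run log
#'
#' A line-delimited collector of timestamped stage records.
#'
#' @return An environment-backed log object of class `abfe_log`.
#' @export
run_log <- function() {
  e <- new.env(parent = emptyenv())
  e$records <- list()
  class(e) <- "abfe_log"
  e
}

#' @rdname run_log
#' @param log an `abfe_log`.
#' @param stage,pose,status,message record fields.
#' @export
log_event <- function(log, stage, pose, status, message = "") {
  log$records[[length(log$records) + 1]] <-
    list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         stage = stage, pose = pose, status = status,
         message = message)
  invisible(log)
}

#' @rdname run_log
#' @param path output path for the tab-separated log lines.
#' @export
write_log <- function(log, path) {
  lines <- vapply(log$records, function(r)
    paste(r$time, r$stage, r$pose, r$status, r$message, sep = "\t"),
    character(1))
  writeLines(c("time\tstage\tpose\tstatus\tmessage", lines), path)
  invisible(NULL)
}
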