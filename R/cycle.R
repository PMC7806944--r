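## Thermodynamic-cycle assembly: from component free energies to the
## standard binding free energy, pose combination, and Kd conversion.
##
## Components are stored as the free energy of the process named by their
## letter code (attachment of protein conformational restraints = a, ...,
## release of protein conformational restraints = r). The cycle identity
##
##   -dG_bind = dG_p,att + dG_l,conf,att + dG_l,TR,att + dG_trans
##              + dG_l,conf,rel + dG_l,TR,rel + dG_p,rel
##
## is applied literally, with dG_trans = (e + v) - (f + w) for double
## decoupling, or e + v for SDR where e and v are already bound-minus-bulk
## differences. dG_bind is reported negative-favourable.

DD_CODES <- c("a", "l", "t", "e", "v", "w", "f", "b", "c", "r")
SDR_CODES <- c("a", "l", "t", "e", "v", "b", "c", "r")

component_table <- function(components) {
  stopifnot(all(vapply(components, inherits, logical(1), "abfe_component")))
  codes <- vapply(components, `[[`, character(1), "code")
  names(components) <- codes
  components
}

#' Assemble a double-decoupling (DD) cycle
#'
#' Requires all ten component codes. The transfer term is
#' `(dG_elec,bound + dG_LJ,bound) - (dG_elec,unbound + dG_LJ,unbound)`,
#' i.e. `(e + v) - (f + w)`.
#'
#' @param components list of [component_estimate()] objects.
#' @param ctx a [thermo_context()].
#' @return Object of class `abfe_cycle` with `method`, `components`,
#'   `dG_bind` (kcal/mol, negative favourable), `sigma` (quadrature sum),
#'   and `transfer` (list with `dG_elec`, `dG_LJ`, `dG_trans`).
#' @export
assemble_dd <- function(components, ctx = thermo_context()) {
  comp <- component_table(components)
  missing <- setdiff(DD_CODES, names(comp))
  if (length(missing))
    stop("missing DD components: ", paste(missing, collapse = ", "))
  g <- function(code) comp[[code]]$dG
  dG_elec <- g("e") - g("f")
  dG_LJ <- g("v") - g("w")
  dG_trans <- dG_elec + dG_LJ
  minus_dg_bind <- g("a") + g("l") + g("t") + dG_trans +
    g("c") + g("b") + g("r")
  sigma <- combine_sigma_quadrature(
    vapply(comp[DD_CODES], `[[`, numeric(1), "sigma"))
  structure(list(method = "DD", components = comp,
                 dG_bind = -minus_dg_bind, sigma = sigma,
                 transfer = list(dG_elec = dG_elec, dG_LJ = dG_LJ,
                                 dG_trans = dG_trans),
                 ctx = ctx),
            class = "abfe_cycle")
}

#' Assemble a simultaneous decoupling-recoupling (SDR) cycle
#'
#' The `e` and `v` components must already be bound-minus-bulk differences
#' (both legs run in the same box); supplying `f` or `w` is an error since
#' SDR does not include them.
#'
#' @inheritParams assemble_dd
#' @param dd_dist z separation (Angstrom) between the bound ligand and its
#'   bulk counterpart; recorded as metadata.
#' @return An `abfe_cycle`.
#' @export
assemble_sdr <- function(components, ctx = thermo_context(),
                         dd_dist = NA_real_) {
  comp <- component_table(components)
  if (any(c("f", "w") %in% names(comp)))
    stop("components f/w are not part of the SDR method")
  missing <- setdiff(SDR_CODES, names(comp))
  if (length(missing))
    stop("missing SDR components: ", paste(missing, collapse = ", "))
  g <- function(code) comp[[code]]$dG
  dG_elec <- g("e")
  dG_LJ <- g("v")
  dG_trans <- dG_elec + dG_LJ
  minus_dg_bind <- g("a") + g("l") + g("t") + dG_trans +
    g("c") + g("b") + g("r")
  sigma <- combine_sigma_quadrature(
    vapply(comp[SDR_CODES], `[[`, numeric(1), "sigma"))
  structure(list(method = "SDR", components = comp,
                 dG_bind = -minus_dg_bind, sigma = sigma,
                 transfer = list(dG_elec = dG_elec, dG_LJ = dG_LJ,
                                 dG_trans = dG_trans),
                 dd_dist = dd_dist, ctx = ctx),
            class = "abfe_cycle")
}

#' @export
print.abfe_cycle <- function(x, ...) {
  cat("abfe_cycle [", x$method, "]\n", sep = "")
  for (c_ in x$components)
    cat(sprintf("  %s: %8.3f +/- %.3f kcal/mol (%s)\n",
                c_$code, c_$dG, c_$sigma, c_$method))
  cat(sprintf("  transfer: elec %.3f, LJ %.3f kcal/mol\n",
              x$transfer$dG_elec, x$transfer$dG_LJ))
  cat(sprintf("  dG_bind = %.3f +/- %.3f kcal/mol\n", x$dG_bind, x$sigma))
  invisible(x)
}

#' Pose result
#'
#' @param pose_id identifier.
#' @param dG binding free energy (kcal/mol); must be `NA` for unstable
#'   poses (no calculation is run for them).
#' @param sigma uncertainty.
#' @param stable logical pose-retention flag.
#' @return Object of class `abfe_pose`.
#' @export
pose_result <- function(pose_id, dG = NA_real_, sigma = NA_real_,
                        stable = TRUE) {
  if (!stable && !is.na(dG))
    stop("unstable poses carry no free energy")
  structure(list(pose_id = pose_id, dG = dG, sigma = sigma,
                 stable = stable), class = "abfe_pose")
}

#' Boltzmann combination of pose free energies
#'
#' `dG_bind = -RT ln sum_i exp(-dG_i / RT)` over the stable poses;
#' unstable poses are excluded rather than penalized. Also reports the
#' most favourable single pose, which is the predicted binding mode.
#'
#' @param poses list of [pose_result()] objects (or a data.frame with
#'   columns `pose_id`, `dG`, `sigma`, `stable`).
#' @param ctx a [thermo_context()].
#' @return List: `dG_bind` (kcal/mol), `best_pose` (id of the argmin),
#'   `best_dG`, `n_poses` used.
#' @export
combine_poses <- function(poses, ctx = thermo_context()) {
  if (is.data.frame(poses)) {
    df <- poses
  } else {
    df <- do.call(rbind, lapply(poses, function(p)
      data.frame(pose_id = p$pose_id, dG = p$dG, sigma = p$sigma,
                 stable = p$stable, stringsAsFactors = FALSE)))
  }
  df <- df[df$stable & !is.na(df$dG), , drop = FALSE]
  if (nrow(df) == 0) stop("no stable pose to combine")
  RT <- ctx$R * ctx$T
  lse <- logsumexp(-df$dG / RT)
  best <- which.min(df$dG)
  list(dG_bind = -RT * lse,
       best_pose = df$pose_id[best],
       best_dG = df$dG[best],
       n_poses = nrow(df))
}

#' Dissociation constant from the binding free energy
#'
#' `Kd = exp(dG_bind / RT)` in molar units (standard concentration 1 M).
#'
#' @param dG standard binding free energy (kcal/mol, negative favourable).
#' @param ctx a [thermo_context()].
#' @return Kd in M.
#' @export
kd_from_dg <- function(dG, ctx = thermo_context()) {
  exp(dG / (ctx$R * ctx$T))
}

#' Write a per-pose results table
#'
#' One TSV row per pose (pose_id, stable flag, per-component dG and sigma,
#' dG_bind and sigma) plus a final combined row from [combine_poses()].
#'
#' @param pose_cycles named list: for each pose either an `abfe_cycle` or
#'   `NULL` (unstable).
#' @param path output path.
#' @param ctx a [thermo_context()].
#' @return The table, invisibly.
#' @export
report_results <- function(pose_cycles, path, ctx = thermo_context()) {
  codes <- DD_CODES
  cols <- c("pose_id", "stable",
            as.vector(rbind(paste0("dG_", codes), paste0("sigma_", codes))),
            "dG_bind", "sigma")
  if (length(pose_cycles) == 0) {
    writeLines(paste(cols, collapse = "\t"), path)
    empty <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(empty) <- cols
    return(invisible(empty))
  }
  rows <- lapply(names(pose_cycles), function(id) {
    cy <- pose_cycles[[id]]
    row <- as.list(rep(NA_real_, length(cols)))
    names(row) <- cols
    row$pose_id <- id
    row$stable <- !is.null(cy)
    if (!is.null(cy)) {
      for (c_ in cy$components) {
        row[[paste0("dG_", c_$code)]] <- c_$dG
        row[[paste0("sigma_", c_$code)]] <- c_$sigma
      }
      row$dG_bind <- cy$dG_bind
      row$sigma <- cy$sigma
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  stable <- tab[tab$stable, , drop = FALSE]
  if (nrow(stable)) {
    comb <- combine_poses(data.frame(pose_id = stable$pose_id,
                                     dG = stable$dG_bind,
                                     sigma = stable$sigma,
                                     stable = TRUE), ctx)
    combined <- tab[1, , drop = FALSE]
    combined[1, ] <- NA
    combined$pose_id <- "combined"
    combined$stable <- TRUE
    combined$dG_bind <- comb$dG_bind
    combined$sigma <- combine_sigma_quadrature(stable$sigma)
    tab <- rbind(tab, combined)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(tab)
}
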