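## Loaders for the packaged reference fixtures.

#' The 89J ligand graph
#'
#' Heavy-atom molecular graph of
#' 2-methyl-5-(methylamino)-6-phenylpyridazin-3(2H)-one (PDB HETID 89J,
#' the BRD4 test ligand), with idealized planar 3D coordinates; the
#' connectivity follows the published chemical structure. Coordinates are
#' synthetic (idealized), intended for restraint-assignment counting and
#' geometry exercises, not for docking.
#'
#' @return An `abfe_graph` with a `coords` attribute.
#' @export
ligand_89j <- function() {
  read_molecule_graph(system.file("extdata", "ligand-89J-idealized.sdf",
                                  package = "abfekit"))
}

#' Reference decoupling/annihilation component values for BRD4
#'
#' Published per-component free energies (kcal/mol) of the BRD4 (5uf0)
#' double-decoupling calculation, for both the MBAR and the TI-GQ
#' estimates. Stored as the free energy of the named process (bulk terms
#' are often printed with the opposite sign).
#'
#' @param method `"TI-GQ"` or `"MBAR"`.
#' @return Named list of [component_estimate()] objects (codes e, v, w, f).
#' @export
brd4_dd_components <- function(method = c("TI-GQ", "MBAR")) {
  method <- match.arg(method)
  d <- utils::read.table(system.file("extdata", "brd4-dd-components.tsv",
                                     package = "abfekit"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d <- d[d$method == method, , drop = FALSE]
  out <- lapply(seq_len(nrow(d)), function(i)
    component_estimate(d$code[i], d$dG[i], d$sigma[i], method))
  names(out) <- d$code
  out
}

#' Reference per-pose binding free energies for BRD4
#'
#' Published pose table of the BRD4 (5uf0) system: ligand RMSDs before and
#' after equilibration and the computed `-dG_bind` per pose (kcal/mol).
#'
#' @return data.frame with columns `pose_id`, `initial_rmsd`,
#'   `equilibrated_rmsd`, `minus_dg_bind`, `sigma`, plus `dG` (signed).
#' @export
brd4_pose_table <- function() {
  d <- utils::read.table(system.file("extdata", "brd4-poses.tsv",
                                     package = "abfekit"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$dG <- -d$minus_dg_bind
  d
}
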