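## Harmonic restraint construction and evaluation.
##
## Every restraint is harmonic, U = k (x - x0)^2 (no 1/2 factor), with k in
## kcal/mol/A^2 for distances and kcal/mol/rad^2 for angles and dihedrals;
## x0 is stored in degrees for angular terms and converted to radians when
## energies are evaluated. Dihedral differences are wrapped to (-180, 180].

#' Construct a restraint set
#'
#' @param terms data.frame with columns `label`, `kind`
#'   (distance/angle/dihedral), `a1..a4` (atom ids; `NA` where unused),
#'   `k`, `x0`.
#' @param group one of `"protein_TR"`, `"protein_conf"`, `"ligand_TR"`,
#'   `"ligand_conf"`.
#' @return Object of class `abfe_restraints`.
#' @export
restraint_set <- function(terms, group) {
  group <- match.arg(group, c("protein_TR", "protein_conf",
                              "ligand_TR", "ligand_conf"))
  stopifnot(all(c("label", "kind", "a1", "a2", "k", "x0") %in% names(terms)))
  if (anyDuplicated(terms$label)) stop("restraint labels must be unique")
  if (any(terms$k < 0)) stop("negative force constant")
  bad <- terms$kind == "dihedral" &
    !(terms$x0 > -180 & terms$x0 <= 180) & !is.na(terms$x0)
  if (any(bad)) stop("dihedral x0 outside (-180, 180]")
  if (!"a3" %in% names(terms)) terms$a3 <- NA_character_
  if (!"a4" %in% names(terms)) terms$a4 <- NA_character_
  arity <- c(distance = 2, angle = 3, dihedral = 4)[terms$kind]
  natoms <- rowSums(!is.na(terms[, c("a1", "a2", "a3", "a4")]))
  if (any(natoms != arity)) stop("atom count does not match restraint kind")
  structure(list(terms = terms, group = group), class = "abfe_restraints")
}

#' @export
print.abfe_restraints <- function(x, ...) {
  cat("abfe_restraints [", x$group, "]: ", nrow(x$terms), " terms (",
      sum(x$terms$kind == "distance"), " distance, ",
      sum(x$terms$kind == "angle"), " angle, ",
      sum(x$terms$kind == "dihedral"), " dihedral)\n", sep = "")
  invisible(x)
}

term_row <- function(label, kind, atoms, k, x0 = NA_real_) {
  atoms <- c(atoms, rep(NA_character_, 4 - length(atoms)))
  data.frame(label = label, kind = kind, a1 = atoms[1], a2 = atoms[2],
             a3 = atoms[3], a4 = atoms[4], k = k, x0 = x0,
             stringsAsFactors = FALSE)
}

serial_id <- function(row) as.character(row$serial)

#' Coordinate lookup table for restraint evaluation
#'
#' @param s an `abfe_structure`.
#' @param anchors an `abfe_anchors` (contributes N1/N2/N3 rows), optional.
#' @return Matrix with one row per atom id (serials as character, plus
#'   `N1`, `N2`, `N3`).
#' @export
coord_map <- function(s, anchors = NULL) {
  m <- coords(s)
  if (!is.null(anchors))
    m <- rbind(m, N1 = anchors$N1, N2 = anchors$N2, N3 = anchors$N3)
  m
}

measure_term <- function(kind, ids, cm) {
  p <- lapply(ids[!is.na(ids)], function(id) {
    if (!id %in% rownames(cm)) stop("atom id not in coordinate map: ", id)
    cm[id, ]
  })
  switch(kind,
         distance = vnorm(p[[1]] - p[[2]]),
         angle = angle_deg(p[[1]], p[[2]], p[[3]]),
         dihedral = dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]]),
         stop("unknown restraint kind: ", kind))
}

#' Fill restraint reference values from a structure
#'
#' Sets each term's `x0` to the internal coordinate observed in the given
#' structure (for instance the final equilibrated one). Idempotent.
#'
#' @param set an `abfe_restraints`.
#' @param s an `abfe_structure`.
#' @param anchors an `abfe_anchors` supplying dummy coordinates, optional.
#' @return The set with `x0` filled.
#' @export
measure_reference_values <- function(set, s, anchors = NULL) {
  cm <- coord_map(s, anchors)
  t <- set$terms
  for (i in seq_len(nrow(t))) {
    t$x0[i] <- measure_term(t$kind[i],
                            unlist(t[i, c("a1", "a2", "a3", "a4")]), cm)
  }
  set$terms <- t
  set
}

#' Ligand translational/rotational restraints
#'
#' Six terms anchoring the ligand to the dummy frame: D1 = N1-L1,
#' A1 = N2-N1-L1, A2 = N1-L1-L2, T1 = N3-N2-N1-L1, T2 = N2-N1-L1-L2,
#' T3 = N1-L1-L2-L3. Reference values are measured from the anchor-set
#' structure, so D1 is 5.00 A and A1 is 90 degrees by construction.
#'
#' @param anchors an `abfe_anchors`.
#' @param k_dist spring constant for D1 (kcal/mol/A^2, the
#'   `lig_distance_force` input).
#' @param k_ang spring constant for angles/dihedrals (kcal/mol/rad^2, the
#'   `lig_angle_force` input).
#' @return An `abfe_restraints` (group `ligand_TR`).
#' @export
build_ligand_tr_restraints <- function(anchors, k_dist, k_ang) {
  L1 <- serial_id(anchors$L1)
  L2 <- serial_id(anchors$L2)
  L3 <- serial_id(anchors$L3)
  t <- rbind(
    term_row("D1", "distance", c("N1", L1), k_dist),
    term_row("A1", "angle", c("N2", "N1", L1), k_ang),
    term_row("A2", "angle", c("N1", L1, L2), k_ang),
    term_row("T1", "dihedral", c("N3", "N2", "N1", L1), k_ang),
    term_row("T2", "dihedral", c("N2", "N1", L1, L2), k_ang),
    term_row("T3", "dihedral", c("N1", L1, L2, L3), k_ang)
  )
  measure_reference_values(restraint_set(t, "ligand_TR"),
                           anchors$structure, anchors)
}

#' Protein translational/rotational restraints
#'
#' D2 = N1-P1, A3 = N2-N1-P1, A4 = N1-P1-P2, T4 = N3-N2-N1-P1,
#' T5 = N2-N1-P1-P2, T6 = N1-P1-P2-P3; x0 measured from the starting
#' coordinates.
#'
#' @param anchors an `abfe_anchors`.
#' @param k_dist `rec_distance_force` (kcal/mol/A^2).
#' @param k_ang `rec_angle_force` (kcal/mol/rad^2).
#' @return An `abfe_restraints` (group `protein_TR`).
#' @export
build_protein_tr_restraints <- function(anchors, k_dist, k_ang) {
  P1 <- serial_id(anchors$P1)
  P2 <- serial_id(anchors$P2)
  P3 <- serial_id(anchors$P3)
  t <- rbind(
    term_row("D2", "distance", c("N1", P1), k_dist),
    term_row("A3", "angle", c("N2", "N1", P1), k_ang),
    term_row("A4", "angle", c("N1", P1, P2), k_ang),
    term_row("T4", "dihedral", c("N3", "N2", "N1", P1), k_ang),
    term_row("T5", "dihedral", c("N2", "N1", P1, P2), k_ang),
    term_row("T6", "dihedral", c("N1", P1, P2, P3), k_ang)
  )
  measure_reference_values(restraint_set(t, "protein_TR"),
                           anchors$structure, anchors)
}

#' Protein conformational restraints
#'
#' Three distances among the protein anchors (P1-P2, P2-P3, P1-P3) plus,
#' optionally, backbone phi (C[i-1]-N[i]-CA[i]-C[i]) and psi
#' (N[i]-CA[i]-C[i]-N[i+1]) dihedrals for each residue in `bb_range` where
#' the flanking atoms exist. Omega angles are never restrained.
#'
#' @param anchors an `abfe_anchors`.
#' @param k_dist `rec_discf_force` (kcal/mol/A^2).
#' @param k_dih `rec_dihcf_force` (kcal/mol/rad^2).
#' @param bb_range integer vector `c(bb_start, bb_end)` of residue numbers,
#'   or `NULL` for no backbone restraints.
#' @return An `abfe_restraints` (group `protein_conf`).
#' @export
build_protein_conf_restraints <- function(anchors, k_dist, k_dih,
                                          bb_range = NULL) {
  s <- anchors$structure
  P1 <- serial_id(anchors$P1)
  P2 <- serial_id(anchors$P2)
  P3 <- serial_id(anchors$P3)
  t <- rbind(
    term_row("DP12", "distance", c(P1, P2), k_dist),
    term_row("DP23", "distance", c(P2, P3), k_dist),
    term_row("DP13", "distance", c(P1, P3), k_dist)
  )
  if (!is.null(bb_range)) {
    a <- s$atoms[!s$atoms$het, , drop = FALSE]
    bb_atom <- function(resno, name) {
      hit <- a[a$resno == resno & a$name == name, , drop = FALSE]
      if (nrow(hit)) as.character(hit$serial[1]) else NA_character_
    }
    res <- seq(bb_range[1], bb_range[2])
    if (!all(res %in% a$resno))
      stop("bb_range outside the protein chain")
    for (i in res) {
      Cprev <- bb_atom(i - 1, "C")
      Ni <- bb_atom(i, "N")
      CAi <- bb_atom(i, "CA")
      Ci <- bb_atom(i, "C")
      Nnext <- bb_atom(i + 1, "N")
      if (!any(is.na(c(Cprev, Ni, CAi, Ci))))
        t <- rbind(t, term_row(paste0("PHI", i), "dihedral",
                               c(Cprev, Ni, CAi, Ci), k_dih))
      if (!any(is.na(c(Ni, CAi, Ci, Nnext))))
        t <- rbind(t, term_row(paste0("PSI", i), "dihedral",
                               c(Ni, CAi, Ci, Nnext), k_dih))
    }
  }
  measure_reference_values(restraint_set(t, "protein_conf"), s, anchors)
}

heavy_adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (r in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[r, 1]
      j <- graph$bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Enumerate central bonds of a molecular graph
#'
#' A bond (b, c) between heavy atoms is central when b has at least one
#' heavy neighbour besides c and c has one besides b, i.e. a heavy-atom
#' proper dihedral runs through the bond. Ring bonds are included.
#'
#' @param graph an `abfe_graph`.
#' @return 2-column integer matrix of central bonds.
#' @export
enumerate_central_bonds <- function(graph) {
  heavy <- graph$elements != "H"
  adj <- heavy_adjacency(graph)
  out <- matrix(integer(0), ncol = 2)
  if (!nrow(graph$bonds)) return(out)
  for (r in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[r, 1]
    c_ <- graph$bonds[r, 2]
    if (!heavy[b] || !heavy[c_]) next
    nb <- setdiff(adj[[b]], c_)
    nc <- setdiff(adj[[c_]], b)
    if (any(heavy[nb]) && any(heavy[nc]))
      out <- rbind(out, c(b, c_))
  }
  out
}

#' Assign ligand conformational restraints
#'
#' Three distances among the ligand anchors (L1-L2, L2-L3, L1-L3) plus one
#' dihedral per heavy-atom central bond, making the ligand essentially
#' rigid. For each central bond the restrained quadruple is the
#' lexicographically smallest heavy (a, b, c, d) with a bonded to b and d
#' bonded to c, which makes the choice reproducible. Torsions within rings
#' are not excepted.
#'
#' @param graph `abfe_graph` of the ligand.
#' @param lig_coords n x 3 matrix of ligand coordinates in graph order.
#' @param anchor_idx integer vector: graph indices of L1, L2, L3.
#' @param k_dist `lig_discf_force` (kcal/mol/A^2).
#' @param k_dih `lig_dihcf_force` (kcal/mol/rad^2).
#' @param id_prefix prefix mapping graph indices to atom ids in the
#'   restraint table (default `"g"` gives ids `g1`, `g2`, ...).
#' @return An `abfe_restraints` (group `ligand_conf`).
#' @export
assign_ligand_conformational_restraints <- function(graph, lig_coords,
                                                    anchor_idx,
                                                    k_dist, k_dih,
                                                    id_prefix = "g") {
  n <- length(graph$elements)
  if (length(anchor_idx) != 3 || any(anchor_idx < 1 | anchor_idx > n))
    stop("anchor atoms absent from graph")
  gid <- function(i) paste0(id_prefix, i)
  t <- rbind(
    term_row("DL12", "distance", gid(anchor_idx[c(1, 2)]), k_dist),
    term_row("DL23", "distance", gid(anchor_idx[c(2, 3)]), k_dist),
    term_row("DL13", "distance", gid(anchor_idx[c(1, 3)]), k_dist)
  )
  cb <- enumerate_central_bonds(graph)
  heavy <- graph$elements != "H"
  adj <- heavy_adjacency(graph)
  if (nrow(cb)) {
    for (r in seq_len(nrow(cb))) {
      quad <- central_bond_quadruple(cb[r, 1], cb[r, 2], adj, heavy)
      t <- rbind(t, term_row(paste0("TL", r), "dihedral", gid(quad), k_dih))
    }
  }
  cm <- as.matrix(lig_coords)
  rownames(cm) <- gid(seq_len(n))
  measure_x0 <- restraint_set(t, "ligand_conf")
  tt <- measure_x0$terms
  for (i in seq_len(nrow(tt)))
    tt$x0[i] <- measure_term(tt$kind[i],
                             unlist(tt[i, c("a1", "a2", "a3", "a4")]), cm)
  measure_x0$terms <- tt
  measure_x0
}

## Smallest heavy quadruple (a,b,c,d) through central bond b-c, comparing
## both bond orientations.
central_bond_quadruple <- function(b, c_, adj, heavy) {
  pick <- function(bb, cc) {
    a <- sort(setdiff(adj[[bb]], cc))
    a <- a[heavy[a]][1]
    d <- sort(setdiff(adj[[cc]], bb))
    d <- d[heavy[d]][1]
    c(a, bb, cc, d)
  }
  q1 <- pick(b, c_)
  q2 <- pick(c_, b)
  if (paste(q1, collapse = ",") <= paste(q2, collapse = ","))
    q1 else q2
}

#' Evaluate the total restraint energy
#'
#' U = sum_r k_r (x_r - x0_r)^2, distances in Angstrom, angular terms
#' converted to radians, dihedral differences wrapped to (-180, 180].
#'
#' @param set an `abfe_restraints` with `x0` filled.
#' @param cm coordinate map (see [coord_map()]), or a structure (plus
#'   optional anchors) from which one is built.
#' @param anchors optional `abfe_anchors` when `cm` is a structure.
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(set, cm, anchors = NULL) {
  if (inherits(cm, "abfe_structure")) cm <- coord_map(cm, anchors)
  t <- set$terms
  if (any(is.na(t$x0))) stop("restraint set has unset reference values")
  u <- 0
  for (i in seq_len(nrow(t))) {
    x <- measure_term(t$kind[i], unlist(t[i, c("a1", "a2", "a3", "a4")]), cm)
    u <- u + harmonic_term_energy(t$kind[i], t$k[i], x, t$x0[i])
  }
  u
}

## Single-term energy with unit handling (x, x0 in A or degrees).
harmonic_term_energy <- function(kind, k, x, x0) {
  if (kind == "distance") return(k * (x - x0)^2)
  d <- x - x0
  if (kind == "dihedral") d <- wrap_deg(d)
  k * (d * pi / 180)^2
}

#' Scale a force constant for an attachment window
#'
#' `k = (attach_pct / 100) * k_full`.
#'
#' @param k_full full spring constant.
#' @param attach_pct window percentage in `[0, 100]`.
#' @return Scaled spring constant.
#' @export
scale_window <- function(k_full, attach_pct) {
  if (any(attach_pct < 0)) stop("negative attach percentage")
  (attach_pct / 100) * k_full
}

#' Window schedule for restraint attachment or alchemical paths
#'
#' @param attach_rest percentages in `[0, 100]`, non-decreasing, first 0
#'   and last 100 (used by restraint attach/release components).
#' @param lambdas coupling values in `[0, 1]` (alchemical components).
#' @param weights optional quadrature weights for `lambdas`, summing to 1.
#' @return Object of class `abfe_schedule`.
#' @export
window_schedule <- function(attach_rest = NULL, lambdas = NULL,
                            weights = NULL) {
  if (!is.null(attach_rest)) {
    if (is.unsorted(attach_rest)) stop("attach_rest must be non-decreasing")
    if (attach_rest[1] != 0 || attach_rest[length(attach_rest)] != 100)
      stop("attach_rest must start at 0 and end at 100")
    if (any(attach_rest < 0 | attach_rest > 100))
      stop("attach_rest outside [0, 100]")
  }
  if (!is.null(lambdas) && any(lambdas < 0 | lambdas > 1))
    stop("lambdas outside [0, 1]")
  if (!is.null(weights)) {
    if (length(weights) != length(lambdas))
      stop("weights and lambdas differ in length")
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  }
  structure(list(attach_rest = attach_rest, lambdas = lambdas,
                 weights = weights), class = "abfe_schedule")
}

#' Write a restraint set as TSV
#'
#' Columnar, engine-agnostic serialization: label, kind, atom ids, k, x0
#' and units.
#'
#' @param set an `abfe_restraints`.
#' @param path output path.
#' @export
write_restraints_tsv <- function(set, path) {
  t <- set$terms
  t$k_units <- ifelse(t$kind == "distance", "kcal/mol/A^2", "kcal/mol/rad^2")
  t$x0_units <- ifelse(t$kind == "distance", "A", "deg")
  t$group <- set$group
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
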