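## Ligand anchor selection, dummy-particle placement and the canonical
## yz-plane frame.
##
## The restraint frame is built on three protein anchors (P1-P3, chosen by
## the user), three ligand anchors (L1-L3, chosen automatically) and three
## lab-frame dummy particles (N1-N3) constructed so that |N1-L1| = 5 A and
## the N2-N1-L1 / N1-N2-P1 angles are exactly 90 degrees, which keeps the
## orientational dihedral restraints away from gimbal lock.

#' Strike-zone parameters for automatic L1 selection
#'
#' The strike zone is a square of side `2 * l1_range` perpendicular to the
#' z axis, centred at `(x_P1 + l1_x, y_P1 + l1_y)`. L1 is the ligand heavy
#' atom inside the square whose |z - z_P1| is smallest, subject to
#' `l1_z <= |z - z_P1| <= l1_zm`. All values in Angstrom.
#'
#' @param l1_x,l1_y offsets of the zone centre from P1.
#' @param l1_range half side-length of the square.
#' @param l1_z,l1_zm minimum and maximum |z| separation from P1.
#' @param min_adis,max_adis anchor-anchor distance window for L2/L3.
#' @return Object of class `abfe_zone`.
#' @export
strike_zone <- function(l1_x = 0, l1_y = 0, l1_range = 2.5,
                        l1_z = 3, l1_zm = 9, min_adis = 2, max_adis = 7) {
  stopifnot(l1_range > 0, l1_z > 0, l1_zm > l1_z,
            min_adis > 0, max_adis > min_adis)
  structure(list(l1_x = l1_x, l1_y = l1_y, l1_range = l1_range,
                 l1_z = l1_z, l1_zm = l1_zm,
                 min_adis = min_adis, max_adis = max_adis),
            class = "abfe_zone")
}

ligand_heavy_atoms <- function(s, lig_resname) {
  a <- s$atoms
  lig <- a[a$resid == lig_resname, , drop = FALSE]
  if (nrow(lig) == 0) stop("no ligand atoms with residue name ", lig_resname)
  lig[lig$element != "H", , drop = FALSE]
}

#' Select an atom by residue/atom selector
#'
#' Selectors use the `":<resno>@<atom name>"` form, e.g. `":84@CA"`.
#'
#' @param s an `abfe_structure`.
#' @param selector selector string.
#' @return One-row atom data.frame.
#' @export
select_atom <- function(s, selector) {
  m <- regmatches(selector, regexec("^:(-?[0-9]+)@(.+)$", selector))[[1]]
  if (length(m) != 3) stop("bad atom selector: ", selector)
  a <- s$atoms
  hit <- a[a$resno == as.integer(m[2]) & a$name == m[3], , drop = FALSE]
  if (nrow(hit) == 0) stop("selector matches no atom: ", selector)
  hit[1, , drop = FALSE]
}

atom_xyz <- function(row) as.numeric(row[1, c("x", "y", "z")])

#' Find the L1 ligand anchor inside the strike zone
#'
#' @param complex aligned `abfe_structure`.
#' @param P1 protein anchor as a one-row atom data.frame (from
#'   [select_atom()]) or a 3-vector of coordinates.
#' @param zone an `abfe_zone`.
#' @param lig_resname ligand residue name (HETATM).
#' @return One-row atom data.frame for L1, or `NULL` when no ligand atom
#'   qualifies (the pose-unstable signal). Zone boundaries are inclusive;
#'   ties break on the lowest atom serial.
#' @export
find_l1 <- function(complex, P1, zone, lig_resname = "LIG") {
  p1 <- if (is.data.frame(P1)) atom_xyz(P1) else as.numeric(P1)
  lig <- ligand_heavy_atoms(complex, lig_resname)
  inx <- abs(lig$x - (p1[1] + zone$l1_x)) <= zone$l1_range
  iny <- abs(lig$y - (p1[2] + zone$l1_y)) <= zone$l1_range
  dz <- abs(lig$z - p1[3])
  ok <- inx & iny & dz >= zone$l1_z & dz <= zone$l1_zm
  if (!any(ok)) return(NULL)
  cand <- lig[ok, , drop = FALSE]
  dzc <- dz[ok]
  best <- order(dzc, cand$serial)[1]
  cand[best, , drop = FALSE]
}

#' Place the N1 dummy particle
#'
#' N1 shares x and y with L1 and sits 5.0 A away along z, on the P1 side of
#' L1 (so it lies between P1 and L1 on the z axis).
#'
#' @param L1,P1 atom rows or 3-vectors.
#' @return 3-vector of N1 coordinates.
#' @export
place_n1 <- function(L1, P1) {
  l1 <- if (is.data.frame(L1)) atom_xyz(L1) else as.numeric(L1)
  p1 <- if (is.data.frame(P1)) atom_xyz(P1) else as.numeric(P1)
  dzsign <- sign(p1[3] - l1[3])
  if (dzsign == 0) stop("P1 and L1 have equal z; cannot place N1")
  c(l1[1], l1[2], l1[3] + 5.0 * dzsign)
}

#' Rotate the system about z into the canonical yz plane
#'
#' Finds the rotation about the z axis that gives P1, L1 and N1 equal x
#' coordinates, and applies it to the whole structure. Between the two
#' solutions the smaller-magnitude angle is chosen (positive on a tie). If
#' P1 lies directly above L1 any rotation works and the identity is applied.
#'
#' @param complex an `abfe_structure`.
#' @param P1,L1 atom rows or 3-vectors.
#' @param N1 3-vector (must share x,y with L1).
#' @return List: `structure` (rotated), `rotation` (3 x 3), `P1`, `L1`,
#'   `N1` (rotated coordinates).
#' @export
rotate_to_yz_plane <- function(complex, P1, L1, N1) {
  p1 <- if (is.data.frame(P1)) atom_xyz(P1) else as.numeric(P1)
  l1 <- if (is.data.frame(L1)) atom_xyz(L1) else as.numeric(L1)
  n1 <- as.numeric(N1)
  d <- p1[1:2] - l1[1:2]
  if (vnorm(d) < 1e-12) {
    Rm <- diag(3)
  } else {
    ## rotate the P1-L1 xy offset onto the y axis (zero x difference);
    ## the two solutions differ by 180 degrees - take the smaller |angle|
    phi <- atan2(d[1], d[2])
    cand <- atan2(sin(c(phi, phi + pi)), cos(c(phi, phi + pi)))
    theta <- cand[order(abs(cand), -cand)][1]
    Rm <- rotz(theta)
  }
  shift <- function(v) as.numeric(Rm %*% v)
  newxyz <- coords(complex) %*% t(Rm)
  list(structure = set_coords(complex, newxyz), rotation = Rm,
       P1 = shift(p1), L1 = shift(l1), N1 = shift(n1))
}

#' Place the N2 and N3 dummy particles
#'
#' In the canonical frame, N2 takes the x,y of P1 at the z of N1; N3 sits
#' above N2 (along +z) at a distance equal to |N1-N2|. This makes the
#' N1-N2-P1 and N3-N2-N1 angles exactly 90 degrees.
#'
#' @param P1 atom row or 3-vector (canonical frame).
#' @param N1 3-vector.
#' @return List with 3-vectors `N2` and `N3`.
#' @export
place_n2_n3 <- function(P1, N1) {
  p1 <- if (is.data.frame(P1)) atom_xyz(P1) else as.numeric(P1)
  n1 <- as.numeric(N1)
  n2 <- c(p1[1], p1[2], n1[3])
  d12 <- vnorm(n1 - n2)
  if (d12 == 0) stop("N1 and N2 coincide; degenerate frame")
  n3 <- c(n2[1], n2[2], n2[3] + d12)
  list(N2 = n2, N3 = n3)
}

find_l_next <- function(lig, ref_apex, ref_prev, zone, exclude_serials) {
  cand <- lig[!(lig$serial %in% exclude_serials), , drop = FALSE]
  if (nrow(cand) == 0) stop("no remaining ligand heavy atoms")
  d <- sqrt((cand$x - ref_apex[1])^2 + (cand$y - ref_apex[2])^2 +
              (cand$z - ref_apex[3])^2)
  ok <- d >= zone$min_adis & d <= zone$max_adis
  if (!any(ok))
    stop("no ligand atom within the anchor distance window [",
         zone$min_adis, ", ", zone$max_adis,
         "] A; adjust min_adis/max_adis")
  cand <- cand[ok, , drop = FALSE]
  dev <- vapply(seq_len(nrow(cand)), function(i) {
    abs(angle_deg(ref_prev, ref_apex, atom_xyz(cand[i, , drop = FALSE])) - 90)
  }, numeric(1))
  cand[order(dev, cand$serial)[1], , drop = FALSE]
}

#' Select the L2 ligand anchor
#'
#' L2 minimises |angle(N1, L1, L2) - 90 deg| among ligand heavy atoms with
#' |L1-L2| inside the `[min_adis, max_adis]` window.
#'
#' @param complex aligned, canonical-frame structure.
#' @param L1 atom row for L1.
#' @param N1 3-vector.
#' @param zone an `abfe_zone`.
#' @param lig_resname ligand residue name.
#' @return One-row atom data.frame.
#' @export
find_l2 <- function(complex, L1, N1, zone, lig_resname = "LIG") {
  lig <- ligand_heavy_atoms(complex, lig_resname)
  find_l_next(lig, atom_xyz(L1), as.numeric(N1), zone, L1$serial)
}

#' Select the L3 ligand anchor
#'
#' L3 minimises |angle(L1, L2, L3) - 90 deg| with |L2-L3| inside the
#' distance window.
#'
#' @inheritParams find_l2
#' @param L2 atom row for L2.
#' @return One-row atom data.frame.
#' @export
find_l3 <- function(complex, L1, L2, zone, lig_resname = "LIG") {
  lig <- ligand_heavy_atoms(complex, lig_resname)
  find_l_next(lig, atom_xyz(L2), atom_xyz(L1), zone, c(L1$serial, L2$serial))
}

#' Build the full anchor set for a pose
#'
#' Composite construction: align the complex to the reference, pick L1 in
#' the strike zone, place N1, rotate into the canonical yz plane, place
#' N2/N3, then pick L2 and L3. Returns `NULL` (pose-unstable) when no L1
#' can be found.
#'
#' @param complex pose structure (protein + ligand).
#' @param reference reference protein structure, or `NULL` if `complex` is
#'   already in the reference frame.
#' @param P1,P2,P3 protein anchor selectors (`":resno@name"`).
#' @param zone an `abfe_zone`.
#' @param lig_resname ligand residue name.
#' @return Object of class `abfe_anchors`: the rotated `structure`, atom
#'   rows `P1..P3`, `L1..L3`, dummy coordinates `N1..N3`, and the applied
#'   `rotation`; or `NULL` if the pose is unstable.
#' @export
build_anchor_set <- function(complex, reference, P1, P2, P3, zone,
                             lig_resname = "LIG") {
  s <- if (is.null(reference)) complex else
    align_complex_to_reference(complex, reference)
  p1 <- select_atom(s, P1)
  l1 <- find_l1(s, p1, zone, lig_resname)
  if (is.null(l1)) return(NULL)
  n1 <- place_n1(l1, p1)
  rot <- rotate_to_yz_plane(s, p1, l1, n1)
  s <- rot$structure
  p1 <- s$atoms[s$atoms$serial == p1$serial, , drop = FALSE]
  l1 <- s$atoms[s$atoms$serial == l1$serial, , drop = FALSE]
  n23 <- place_n2_n3(p1, rot$N1)
  l2 <- find_l2(s, l1, rot$N1, zone, lig_resname)
  l3 <- find_l3(s, l1, l2, zone, lig_resname)
  out <- list(structure = s,
              P1 = p1,
              P2 = s$atoms[s$atoms$serial == select_atom(s, P2)$serial, ,
                           drop = FALSE],
              P3 = s$atoms[s$atoms$serial == select_atom(s, P3)$serial, ,
                           drop = FALSE],
              L1 = l1, L2 = l2, L3 = l3,
              N1 = rot$N1, N2 = n23$N2, N3 = n23$N3,
              rotation = rot$rotation, lig_resname = lig_resname)
  serials <- c(out$P1$serial, out$P2$serial, out$P3$serial,
               out$L1$serial, out$L2$serial, out$L3$serial)
  if (anyDuplicated(serials)) stop("anchor atoms are not distinct")
  class(out) <- "abfe_anchors"
  out
}

#' @export
print.abfe_anchors <- function(x, ...) {
  fmt <- function(v) sprintf("(%.2f, %.2f, %.2f)", v[1], v[2], v[3])
  cat("abfe_anchors\n")
  for (nm in c("P1", "P2", "P3", "L1", "L2", "L3"))
    cat(sprintf("  %s: serial %d %s\n", nm, x[[nm]]$serial,
                fmt(atom_xyz(x[[nm]]))))
  for (nm in c("N1", "N2", "N3"))
    cat(sprintf("  %s: %s\n", nm, fmt(x[[nm]])))
  invisible(x)
}

#' Pose-retention check after equilibration
#'
#' A pose is retained (stable) iff an L1 anchor can still be found inside
#' the strike zone within `l1_zm` of P1 — otherwise the ligand is deemed to
#' have left the binding site. The `l1_zm` bound is inclusive.
#'
#' @param final_frame structure in the reference frame.
#' @param P1 protein anchor selector or atom row.
#' @param zone an `abfe_zone`.
#' @param lig_resname ligand residue name.
#' @return `TRUE` (stable) or `FALSE` (unstable).
#' @export
check_pose_retention <- function(final_frame, P1, zone, lig_resname = "LIG") {
  p1 <- if (is.character(P1)) select_atom(final_frame, P1) else P1
  !is.null(find_l1(final_frame, p1, zone, lig_resname))
}
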