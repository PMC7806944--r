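## Structure container and file I/O.
##
## A structure is a thin S3 wrapper around an atom table; PDB reading and
## writing are delegated to bio3d with a validation layer that enforces the
## contracts (line-numbered parse errors, single-character chain ids,
## 3-decimal coordinate precision).

DUMMY_RESNAME <- "DUM"

#' Create a structure from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (3-letter residue name), `chain`, `resno`, `x`, `y`, `z`,
#'   `het` (logical HETATM flag). Coordinates in Angstrom.
#' @param title optional title string.
#' @return Object of class `abfe_structure`.
#' @export
new_structure <- function(atoms, title = "") {
  req <- c("serial", "name", "element", "resid", "chain", "resno",
           "x", "y", "z", "het")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("structure must contain at least one atom")
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbol")
  atoms$chain <- as.character(atoms$chain)
  if (any(nchar(atoms$chain) > 1))
    stop("chain id must be a single character")
  structure(list(atoms = atoms, title = title), class = "abfe_structure")
}

#' @export
print.abfe_structure <- function(x, ...) {
  cat("abfe_structure:", nrow(x$atoms), "atoms")
  if (nzchar(x$title)) cat(" (", x$title, ")", sep = "")
  cat("\n  protein atoms:", sum(!x$atoms$het),
      " hetero atoms:", sum(x$atoms$het), "\n")
  invisible(x)
}

#' Coordinates of a structure as a matrix
#'
#' @param s an `abfe_structure`.
#' @return n x 3 numeric matrix (Angstrom), rownames = atom serials.
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  rownames(m) <- as.character(s$atoms$serial)
  m
}

set_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 columns) into a structure.
#' Alternate locations other than blank or 'A' are dropped with a warning.
#'
#' @param path path to a PDB file.
#' @return An `abfe_structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  ## validate coordinate fields up front so errors carry line numbers
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": bad coordinate field")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  if (any(!keep)) {
    warning(sum(!keep), " altloc record(s) dropped (altloc not blank/'A')")
    a <- a[keep, , drop = FALSE]
  }
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  ## fall back to the first letter of the atom name when the element
  ## column is absent (common in minimal hand-written files)
  elem[blank] <- substr(gsub("[^A-Za-z].*", "", trimws(a$elety[blank])), 1, 1)
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = trimws(elem),
    resid = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  new_structure(atoms, title = basename(path))
}

#' Write a structure to a PDB file
#'
#' Dummy particles (residue name `DUM`) are emitted as HETATM records.
#'
#' @param s an `abfe_structure`.
#' @param path output path.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "abfe_structure"))
  a <- s$atoms
  if (any(nchar(a$chain) > 1)) stop("chain id must be a single character")
  het <- a$het | a$resid == DUMMY_RESNAME
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(het, "HETATM", "ATOM"),
    resno = a$resno,
    resid = a$resid,
    eleno = a$serial,
    elety = a$name,
    chain = ifelse(nzchar(a$chain), a$chain, NA),
    elesy = a$element
  )
  invisible(NULL)
}

#' Add dummy particles to a structure
#'
#' Appends N1/N2/N3 dummy particles as HETATM records with the reserved
#' residue name `DUM`.
#'
#' @param s an `abfe_structure`.
#' @param dummies named list of 3-vectors (e.g. `list(N1 = ..., N2 = ...)`).
#' @return The augmented structure.
#' @export
add_dummy_atoms <- function(s, dummies) {
  a <- s$atoms
  serial0 <- max(a$serial)
  resno0 <- max(a$resno)
  rows <- do.call(rbind, lapply(seq_along(dummies), function(i) {
    p <- dummies[[i]]
    data.frame(serial = serial0 + i, name = names(dummies)[i],
               element = "Pb", resid = DUMMY_RESNAME, chain = "",
               resno = resno0 + i, x = p[1], y = p[2], z = p[3],
               het = TRUE, stringsAsFactors = FALSE)
  }))
  new_structure(rbind(a, rows), title = s$title)
}

#' Molecular graph
#'
#' @param elements character vector of element symbols (graph order).
#' @param bonds 2-column integer matrix of unordered bonded index pairs.
#' @param names optional atom names.
#' @return Object of class `abfe_graph`.
#' @export
molecular_graph <- function(elements, bonds, names = NULL) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- length(elements)
  if (nrow(bonds)) {
    if (any(bonds < 1 | bonds > n))
      stop("bond references nonexistent atom")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond not allowed")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond")
    bonds <- cbind(pmin(bonds[, 1], bonds[, 2]),
                   pmax(bonds[, 1], bonds[, 2]))
  }
  structure(list(elements = as.character(elements), bonds = bonds,
                 names = names), class = "abfe_graph")
}

#' Read a MOL/SDF (V2000) molecular graph
#'
#' @param path path to a MOL or SDF file (first record used).
#' @return An `abfe_graph` with a `coords` attribute (n x 3 matrix, Angstrom).
#' @export
read_molecule_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("not a V2000 MOL file: ", path)
  counts <- lines[4]
  natom <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbond <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natom) || is.na(nbond))
    stop("malformed V2000 counts line")
  body <- lines[-(1:4)]
  nrec <- sum(cumsum(grepl("^M  END|^\\$\\$\\$\\$", body)) == 0)
  if (nrec < natom + nbond)
    stop("V2000 counts line inconsistent with atom/bond blocks")
  sdf <- ChemmineR::read.SDFset(path)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  if (nrow(ab) != natom || nrow(bb) != nbond)
    stop("V2000 counts line inconsistent with atom/bond blocks")
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  if (nrow(bonds) && any(bonds < 1 | bonds > natom))
    stop("bond references nonexistent atom")
  g <- molecular_graph(elements, bonds)
  attr(g, "coords") <- unname(as.matrix(ab[, 1:3]))
  g
}

#' Decode heavy-atom proper dihedrals from AMBER prmtop dihedral entries
#'
#' Each dihedral term is five integers; the first four encode atom indices
#' as `index = |entry|/3 + 1`. A negative third entry marks a 1-4 exclusion
#' (still a proper torsion, retained); a negative fourth entry marks an
#' improper torsion (excluded). Duplicate terms on the same central bond are
#' retained; deduplication happens during restraint assignment.
#'
#' @param path text file containing `DIHEDRALS_WITHOUT_HYDROGEN` entries
#'   (whitespace-separated integers, 5 per term; a `%FLAG`/`%FORMAT` header
#'   is tolerated).
#' @return Integer matrix with 4 columns of 1-based atom indices.
#' @export
read_prmtop_dihedrals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  flag <- grep("DIHEDRALS_WITHOUT_HYDROGEN", lines)
  if (length(flag)) {
    lines <- lines[(flag[1] + 1):length(lines)]
    stopflag <- grep("^%FLAG", lines)
    if (length(stopflag)) lines <- lines[seq_len(stopflag[1] - 1)]
    lines <- lines[!grepl("^%", lines)]
  }
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) %% 5 != 0)
    stop("dihedral section length not a multiple of 5")
  m <- matrix(vals, ncol = 5, byrow = TRUE)
  decode_prmtop_dihedrals(m)
}

#' @rdname read_prmtop_dihedrals
#' @param entries numeric matrix with 5 columns of raw prmtop dihedral
#'   entries (coordinate-array pointers plus parameter index).
#' @export
decode_prmtop_dihedrals <- function(entries) {
  entries <- matrix(as.numeric(entries), ncol = 5)
  raw <- entries[, 1:4, drop = FALSE]
  if (any(abs(raw) %% 3 != 0))
    stop("prmtop dihedral entry not divisible by 3")
  proper <- entries[, 4] >= 0
  idx <- abs(raw[proper, , drop = FALSE]) / 3 + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Needleman-Wunsch global sequence alignment
#'
#' Global alignment with linear gap penalty. Ties in the traceback prefer
#' the diagonal move, then the vertical (gap in `seq_b`), then the
#' horizontal, so the returned pairing is deterministic.
#'
#' @param seq_a,seq_b residue code strings (one letter per residue).
#' @param match,mismatch,gap alignment scores (defaults +1/-1/-2).
#' @return 2-column integer matrix of matched (aligned, non-gap) positions;
#'   attribute `score` carries the optimal alignment score.
#' @export
global_sequence_align <- function(seq_a, seq_b, match = 1, mismatch = -1,
                                  gap = -2) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) stop("empty sequence")
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- gap * (0:n)
  F[1, ] <- gap * (0:m)
  for (i in 1:n) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in 1:m) {
      F[i + 1, j + 1] <- max(F[i, j] + sub[j], F[i, j + 1] + gap,
                             F[i + 1, j] + gap)
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  i <- n
  j <- m
  while (i > 0 && j > 0) {
    sub <- if (a[i] == b[j]) match else mismatch
    if (F[i + 1, j + 1] == F[i, j] + sub) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1
      j <- j - 1
    } else if (F[i + 1, j + 1] == F[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  colnames(pairs) <- c("a", "b")
  attr(pairs, "score") <- F[n + 1, m + 1]
  pairs
}

#' Kabsch least-squares rigid superposition
#'
#' @param mobile,ref paired n x 3 coordinate matrices (n >= 3,
#'   non-collinear).
#' @return List of class `abfe_alignment`: `rotation` (3 x 3 proper
#'   rotation), `translation` (3-vector), `rmsd` (post-fit, Angstrom). The
#'   fitted mobile coordinates are `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, ref) {
  mobile <- as.matrix(mobile)
  ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref)) stop("point sets differ in size")
  if (nrow(mobile) < 3) stop("need at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(ref, 2, cr)
  if (qr(X)$rank < 2 || qr(Y)$rank < 2)
    stop("collinear points: superposition is degenerate")
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- X %*% t(Rm)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  translation <- as.numeric(cr - Rm %*% cm)
  structure(list(rotation = Rm, translation = translation, rmsd = rmsd),
            class = "abfe_alignment")
}

apply_alignment <- function(xyz, aln) {
  sweep(as.matrix(xyz) %*% t(aln$rotation), 2, aln$translation, `+`)
}

## One-letter residue codes for sequence alignment.
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

protein_calpha <- function(s) {
  a <- s$atoms
  a[!a$het & a$name == "CA" & a$resid %in% names(AA3TO1), , drop = FALSE]
}

#' Align a complex into the frame of a reference protein
#'
#' The protein sequences (Calpha residues) are aligned globally, matched
#' Calpha pairs are superposed by the Kabsch algorithm, and the whole
#' complex (protein plus ligand and any dummies) is transformed into the
#' reference frame.
#'
#' @param complex an `abfe_structure` containing a protein and (typically) a
#'   ligand.
#' @param reference an `abfe_structure` of the reference protein.
#' @return The transformed complex; attributes `alignment` (the
#'   `abfe_alignment`) and `n_pairs`.
#' @export
align_complex_to_reference <- function(complex, reference) {
  ca_m <- protein_calpha(complex)
  ca_r <- protein_calpha(reference)
  if (nrow(ca_m) == 0 || nrow(ca_r) == 0)
    stop("no protein Calpha atoms found")
  seq_m <- paste(AA3TO1[ca_m$resid], collapse = "")
  seq_r <- paste(AA3TO1[ca_r$resid], collapse = "")
  pairs <- global_sequence_align(seq_m, seq_r)
  if (nrow(pairs) < 3)
    stop("fewer than 3 matched Calpha pairs; cannot superpose")
  aln <- kabsch_superpose(
    as.matrix(ca_m[pairs[, 1], c("x", "y", "z")]),
    as.matrix(ca_r[pairs[, 2], c("x", "y", "z")])
  )
  out <- set_coords(complex, apply_alignment(coords(complex), aln))
  attr(out, "alignment") <- aln
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Symmetry-aware RMSD
#'
#' Minimum plain RMSD over the identity and a set of automorphism
#' permutations of the second structure's atoms. No refitting is performed;
#' structures are assumed pre-aligned.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices.
#' @param automorphisms list of integer permutations of `1:n` (the identity
#'   is always included implicitly).
#' @return RMSD in Angstrom.
#' @export
symmetry_aware_rmsd <- function(coords_a, coords_b, automorphisms = list()) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  if (nrow(coords_b) != n) stop("coordinate sets differ in size")
  plain <- function(p) sqrt(mean(rowSums((coords_a - coords_b[p, , drop = FALSE])^2)))
  best <- plain(seq_len(n))
  for (p in automorphisms) {
    if (length(p) != n || !all(sort(p) == seq_len(n)))
      stop("automorphism is not a permutation of the atom indices")
    best <- min(best, plain(p))
  }
  best
}

#' Graph automorphisms of a small molecular fragment
#'
#' Exhaustive search for element-preserving, bond-preserving permutations.
#' Intended for small symmetric fragments (<= 12 atoms), e.g. a phenyl ring.
#'
#' @param graph an `abfe_graph`.
#' @return List of integer permutations (including the identity).
#' @export
graph_automorphisms <- function(graph) {
  n <- length(graph$elements)
  if (n > 12) stop("automorphism search limited to 12 atoms")
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$bonds)) {
    adj[graph$bonds] <- TRUE
    adj[graph$bonds[, c(2, 1), drop = FALSE]] <- TRUE
  }
  deg <- rowSums(adj)
  perms <- list()
  assign_next <- function(p, used) {
    i <- length(p) + 1
    if (i > n) {
      perms[[length(perms) + 1]] <<- as.integer(p)
      return(invisible(NULL))
    }
    for (cand in seq_len(n)[!used]) {
      if (graph$elements[cand] != graph$elements[i]) next
      if (deg[cand] != deg[i]) next
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (adj[i, j] != adj[cand, p[j]]) { ok <- FALSE; break }
      }
      if (ok) {
        used[cand] <- TRUE
        assign_next(c(p, cand), used)
        used[cand] <- FALSE
      }
    }
  }
  assign_next(integer(0), rep(FALSE, n))
  perms
}
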