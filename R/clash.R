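#' Standard van der Waals radii
#'
#' Bondi (1964) element radii in Angstrom for the elements that occur in
#' protein/nucleic structures; unknown elements fall back to 1.7 A
#' (carbon).
#'
#' @param element Character vector of element symbols.
#' @return Numeric radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73,
           "NA" = 2.27, K = 2.75, ZN = 1.39, MN = 1.73, FE = 1.94,
           CA = 2.31)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Construct an atom set
#'
#' The flat coordinate container used by the superposition and clash
#' operations: one row per atom with 3D coordinates (Angstrom), element,
#' chain id, residue number/name and atom name. A per-atom `radius`
#' column overrides the packaged element table when present.
#'
#' @param x,y,z Numeric coordinates (Angstrom, finite).
#' @param element Element symbols.
#' @param chain Chain ids.
#' @param resno Residue numbers.
#' @param resid Residue names (e.g. `"DA"`, `"DT"` for nucleotides).
#' @param atom_name Atom names (e.g. `"P"`, `"CA"`).
#' @param radius Optional per-atom vdW radius override.
#' @return An `atom_set` data.frame.
#' @export
atom_set <- function(x, y, z, element = "C", chain = "A", resno = NA,
                     resid = NA, atom_name = NA, radius = NULL) {
  n <- length(x)
  if (!all(is.finite(c(x, y, z)))) stop("coordinates must be finite")
  out <- data.frame(x = x, y = y, z = z,
                    element = rep_len(element, n),
                    chain = rep_len(chain, n),
                    resno = rep_len(resno, n),
                    resid = rep_len(as.character(resid), n),
                    atom_name = rep_len(as.character(atom_name), n),
                    stringsAsFactors = FALSE)
  out$radius <- if (is.null(radius)) vdw_radius(out$element)
                else rep_len(radius, n)
  class(out) <- c("atom_set", "data.frame")
  out
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# one-letter nucleotide code per residue of a chain, sorted by resno
.chain_residues <- function(atoms, chain) {
  a <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain '", chain, "' not found")
  res <- unique(a[, c("resno", "resid")])
  res <- res[order(res$resno), , drop = FALSE]
  letter <- toupper(sub("^D", "", res$resid))
  letter[!letter %in% c("A", "C", "G", "T", "U")] <- "N"
  list(resno = res$resno, letter = letter)
}

#' Pair backbone atoms of two nucleic chains by sequence alignment
#'
#' Globally aligns the residue sequences of a reference and a mobile DNA
#' chain (Needleman-Wunsch) and pairs one backbone atom per aligned,
#' non-gap residue column (phosphorus `"P"` by default). Gap columns are
#' excluded; mismatched but aligned residues are still paired, so a
#' single base substitution leaves the pairing unchanged.
#'
#' @param ref,mov `atom_set`s holding the reference and mobile
#'   structures.
#' @param ref_chain,mov_chain Chain ids of the DNA chains to align.
#' @param atom Backbone atom name used for pairing (default `"P"`).
#' @return data.frame `ref_idx`, `mov_idx`: row indices into `ref` and
#'   `mov` of the paired atoms.
#' @export
pair_chains <- function(ref, mov, ref_chain, mov_chain, atom = "P") {
  rr <- .chain_residues(ref, ref_chain)
  mm <- .chain_residues(mov, mov_chain)
  if (length(rr$resno) < 3L || length(mm$resno) < 3L)
    stop("chains must have at least 3 residues")
  aln <- Biostrings::pairwiseAlignment(
    paste(mm$letter, collapse = ""), paste(rr$letter, collapse = ""),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  pa <- .chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- .chars(as.character(Biostrings::alignedSubject(aln)))
  im <- ir <- 0L
  pairs <- list()
  for (k in seq_along(pa)) {
    if (pa[k] != "-") im <- im + 1L
    if (sa[k] != "-") ir <- ir + 1L
    if (pa[k] != "-" && sa[k] != "-")
      pairs[[length(pairs) + 1L]] <- c(ir, im)
  }
  find_atom <- function(atoms, chain, resno) {
    idx <- which(atoms$chain == chain & atoms$resno == resno &
                 atoms$atom_name == atom)
    if (length(idx)) idx[1L] else NA_integer_
  }
  out <- do.call(rbind, lapply(pairs, function(p) {
    ri <- find_atom(ref, ref_chain, rr$resno[p[1L]])
    mi <- find_atom(mov, mov_chain, mm$resno[p[2L]])
    c(ref_idx = ri, mov_idx = mi)
  }))
  out <- as.data.frame(out)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (nrow(out) < 3L)
    stop("fewer than 3 atom pairs; superposition underdetermined")
  rownames(out) <- NULL
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Computes the rotation and translation that minimise the RMSD between
#' paired atoms when applied to the mobile set, via the SVD solution of
#' the orthogonal Procrustes problem with a reflection guard
#' (determinant forced to +1).
#'
#' @param pairs data.frame `ref_idx`, `mov_idx` (from [pair_chains()]),
#'   or a 2-column matrix of indices.
#' @param ref,mov `atom_set`s.
#' @return A `superposition` list: `rotation` (3x3, orthonormal, det +1),
#'   `translation` (length 3), `rmsd` over the pairs after transform.
#'   The transform maps a mobile coordinate row-vector `v` to
#'   `v %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(pairs, ref, mov) {
  P <- .coords(ref)[pairs[[1L]], , drop = FALSE]
  Q <- .coords(mov)[pairs[[2L]], , drop = FALSE]
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 pairs")
  pc <- colMeans(P)
  qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc)
  Q0 <- sweep(Q, 2L, qc)
  s <- svd(crossprod(Q0, P0))          # t(Q0) %*% P0 = U D V'
  if (s$d[2L] < 1e-10)
    stop("degenerate (collinear) atom pairs; rotation underdetermined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- unname(pc - as.vector(R %*% qc))
  moved <- Q %*% t(R) + matrix(t_vec, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - P)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to an atom set
#'
#' @param atoms An `atom_set`.
#' @param sup A `superposition` from [kabsch_superpose()].
#' @return The transformed `atom_set`.
#' @export
apply_superposition <- function(atoms, sup) {
  xyz <- .coords(atoms) %*% t(sup$rotation) +
    matrix(sup$translation, nrow(atoms), 3L, byrow = TRUE)
  atoms$x <- xyz[, 1L]
  atoms$y <- xyz[, 2L]
  atoms$z <- xyz[, 3L]
  atoms
}

#' Count van der Waals clashes between two atom sets
#'
#' A clash is an unordered cross pair (a in A, b in B) whose vdW overlap
#' `r_a + r_b - d(a, b)` is at least `overlap_cutoff` (0.6 A, the common
#' default of structure-viewing clash detectors). Atoms of B can be
#' excluded beforehand with a caller-supplied predicate — e.g. dropping
#' the DNA duplex directly bound by the nuclease, or everything beyond a
#' chosen SHL; the module does not hard-code any nucleosome annotation.
#' Counting uses a uniform spatial grid so only nearby cells are
#' compared; results are identical to full pair enumeration.
#'
#' @param a,b `atom_set`s.
#' @param overlap_cutoff Minimum overlap in Angstrom (default 0.6).
#' @param exclude_b Optional predicate `function(atom_set) -> logical`
#'   returning `TRUE` for B atoms to drop before counting.
#' @return Integer clash count.
#' @export
count_clashes <- function(a, b, overlap_cutoff = 0.6, exclude_b = NULL) {
  if (!is.null(exclude_b)) {
    drop <- exclude_b(b)
    b <- b[!drop, , drop = FALSE]
  }
  na <- nrow(a)
  nb <- nrow(b)
  if (na == 0L || nb == 0L) return(0L)
  A <- .coords(a)
  B <- .coords(b)
  ra <- a$radius
  rb <- b$radius
  dmax <- max(ra) + max(rb) - overlap_cutoff
  if (dmax <= 0) return(0L)
  cell <- dmax
  keyB <- floor(B / cell)
  binB <- split(seq_len(nb),
                paste(keyB[, 1L], keyB[, 2L], keyB[, 3L], sep = ","))
  keyA <- floor(A / cell)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  total <- 0L
  for (i in seq_len(na)) {
    cand <- integer(0)
    for (o in seq_len(27L)) {
      key <- paste(keyA[i, 1L] + offs[o, 1L], keyA[i, 2L] + offs[o, 2L],
                   keyA[i, 3L] + offs[o, 3L], sep = ",")
      hit <- binB[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    d <- sqrt(colSums((t(B[cand, , drop = FALSE]) - A[i, ])^2))
    total <- total + sum(ra[i] + rb[cand] - d >= overlap_cutoff)
  }
  as.integer(total)
}

#' Load a PDB-format structure as an atom set
#'
#' Parses ATOM/HETATM records (via the standard `bio3d` reader) into an
#' `atom_set`. Records whose coordinate fields do not parse raise an
#' error naming the offending line.
#'
#' @param path PDB file path.
#' @return An `atom_set`.
#' @export
load_structure <- function(path) {
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (any(rec)) {
    coords_txt <- substr(lines[rec], 31L, 54L)
    ok <- grepl("^[ 0-9.+-]+$", coords_txt) & nchar(lines[rec]) >= 54L
    if (!all(ok))
      stop("malformed ATOM/HETATM record at line ",
           which(rec)[which(!ok)[1L]], " of ", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | elem == ""
  if (any(blank)) elem[blank] <- substr(trimws(at$elety[blank]), 1L, 1L)
  atom_set(at$x, at$y, at$z, element = elem, chain = at$chain,
           resno = at$resno, resid = at$resid, atom_name = trimws(at$elety))
}

#' Write an atom set as a PDB-format file
#'
#' Coordinates round-trip through [load_structure()] to 3 decimals (the
#' PDB fixed-column precision).
#'
#' @param atoms An `atom_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  resid <- ifelse(is.na(atoms$resid), "UNK", atoms$resid)
  aname <- ifelse(is.na(atoms$atom_name), atoms$element, atoms$atom_name)
  resno <- ifelse(is.na(atoms$resno), seq_len(nrow(atoms)), atoms$resno)
  bio3d::write.pdb(file = path, xyz = as.vector(t(.coords(atoms))),
                   type = rep("ATOM", nrow(atoms)),
                   resno = resno, resid = resid, chain = atoms$chain,
                   elety = aname, elesy = atoms$element)
  invisible(path)
}
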