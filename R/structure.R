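## Structure container and geometric primitives.
##
## A Structure is a data.frame of atom records (one row per atom) with columns
## chain, resno, resid, elety, element, x, y, z. Author residue numbering from
## the source PDB file is authoritative; no renumbering is ever performed.
## Hydrogens and waters are excluded on input and ignored everywhere.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_structure <- function(df) {
  required <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("structure table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("a Structure must contain at least one atom")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite atom coordinates")
  key <- paste(df$chain, df$resno, df$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) records: ",
         key[which(duplicated(key))[1]])
  df <- df[, required]
  rownames(df) <- NULL
  class(df) <- c("Structure", "data.frame")
  df
}

#' Build a Structure from an atom table
#'
#' @param df data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `x`, `y`, `z` (coordinates in Angstrom).
#' @return A `Structure` (a validated data.frame of atom records).
#' @export
as_structure <- function(df) new_structure(as.data.frame(df))

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              paste(sort(unique(x$chain)), collapse = ",")))
  invisible(x)
}

## derive the element from a protein atom name ("CA" is an alpha carbon, not
## calcium; "SE" in selenomethionine is the only two-letter case kept)
element_from_name <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", elety)))
  ifelse(e == "SE", "SE", substr(e, 1, 1))
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), resolving alternate locations to
#' the highest-occupancy conformer (ties broken by first encountered) and
#' dropping waters and hydrogens.
#'
#' @param path Path to a PDB-format file.
#' @param chains Optional character vector (or comma-separated string) of
#'   chain identifiers to retain.
#' @return A [as_structure()] `Structure`.
#' @export
read_pdb <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stop("unparseable PDB file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  ## element: trust the element column when present, else derive from name
  elesy <- trimws(as.character(at$elesy))
  elesy[is.na(elesy)] <- ""
  elem <- toupper(elesy)
  miss <- !nzchar(elem)
  elem[miss] <- element_from_name(at$elety[miss])
  keep <- elem != "H" & elem != "D" & at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  ## altloc: keep highest occupancy per (chain, resno, atom name), ties to
  ## the first conformer encountered
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]
  dup <- duplicated(paste(at$chain, at$resno, at$elety))
  at <- at[!dup, , drop = FALSE]
  elem <- elem[!dup]
  s <- data.frame(chain = as.character(at$chain), resno = at$resno,
                  resid = as.character(at$resid),
                  elety = as.character(at$elety), element = elem,
                  x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  if (!is.null(chains)) {
    chains <- trimws(unlist(strsplit(chains, ",")))
    s <- s[s$chain %in% chains, , drop = FALSE]
    if (nrow(s) == 0)
      stop("chain selection '", paste(chains, collapse = ","),
           "' matches no atoms in ", path)
  }
  ## restore file order within the deduplicated set
  s <- s[order(match(paste(s$chain, s$resno, s$elety), key)), , drop = FALSE]
  new_structure(s)
}

#' Write a Structure to a PDB file
#'
#' @param s A `Structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  s <- as_structure(s)
  xyz <- as.vector(t(as.matrix(s[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = s$resno, resid = s$resid,
                   chain = s$chain, elety = s$elety)
  invisible(path)
}

## Atom-class selection -------------------------------------------------------

select_atoms <- function(s, atom_class = c("heavy", "backbone", "calpha")) {
  atom_class <- match.arg(atom_class)
  switch(atom_class,
         heavy = s,
         backbone = s[s$elety %in% BACKBONE_ATOMS, , drop = FALSE],
         calpha = s[s$elety == "CA", , drop = FALSE])
}

#' Subset a Structure by chain
#' @param s A `Structure`.
#' @param chains Character vector of chain identifiers.
#' @return A `Structure` restricted to `chains`.
#' @export
structure_chains <- function(s, chains) {
  out <- s[s$chain %in% chains, , drop = FALSE]
  if (nrow(out) == 0) stop("no atoms in chain(s) ", paste(chains, collapse = ","))
  new_structure(out)
}

coord_matrix <- function(s) {
  m <- as.matrix(s[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

residue_key <- function(s) paste0(s$chain, ":", s$resno)

## Fetch coordinates of one atom per "chain:resno" selection string
anchor_coords <- function(s, selections, elety = "CA") {
  parts <- strsplit(selections, ":", fixed = TRUE)
  out <- matrix(NA_real_, length(selections), 3)
  for (i in seq_along(parts)) {
    ch <- parts[[i]][1]; rn <- as.integer(parts[[i]][2])
    hit <- which(s$chain == ch & s$resno == rn & s$elety == elety)
    if (length(hit) == 0)
      stop("selection '", selections[i], "' (", elety,
           ") resolves to no atom")
    out[i, ] <- c(s$x[hit[1]], s$y[hit[1]], s$z[hit[1]])
  }
  out
}

## Kabsch superposition -------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, mapping `mobile` onto `reference`.
#'
#' @param mobile,reference Numeric n-by-3 coordinate matrices, n >= 3, with
#'   row-wise correspondence.
#' @return List with `rotation` (3x3, determinant +1), `translation`
#'   (length-3), and `rmsd` (Angstrom) after the fit. The fitted coordinates
#'   are `mobile %*% t(rotation) + translation` (row-wise).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have the same dimensions")
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)            # covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile -> reference
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' RMSD between paired coordinate sets
#'
#' @param a,b n-by-3 matrices with row correspondence.
#' @param fit If `TRUE` (default), superpose `a` onto `b` first.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, fit = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  if (fit) return(superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

## Contacts -------------------------------------------------------------------

#' Inter-chain residue contacts
#'
#' A residue pair (r_a, r_b) is in contact when any selected atom of r_a lies
#' within `cutoff` of any selected atom of r_b.
#'
#' @param a,b `Structure`s (typically two chains of a complex).
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param atom_class `"heavy"`, `"backbone"`, or `"calpha"`.
#' @return data.frame with columns `res_a`, `res_b` ("chain:resno" keys), one
#'   row per contacting pair; zero rows when either side is empty.
#' @export
contacts <- function(a, b, cutoff = 5, atom_class = "heavy") {
  if (cutoff <= 0) stop("cutoff must be positive")
  sa <- select_atoms(a, atom_class); sb <- select_atoms(b, atom_class)
  empty <- data.frame(res_a = character(), res_b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sa) == 0 || nrow(sb) == 0) return(empty)
  ca <- coord_matrix(sa); cb <- coord_matrix(sb)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  pairs <- unique(data.frame(res_a = residue_key(sa)[hit[, 1]],
                             res_b = residue_key(sb)[hit[, 2]],
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}
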