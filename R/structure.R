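#' Load C-alpha coordinates from a PDB or mmCIF file
#'
#' Reads the file with bio3d, keeps C-alpha atoms of one protein chain
#' (first chain when unspecified), altloc blank or 'A' only, optionally
#' restricted to an inclusive residue-number range. Missing residues are
#' simply absent.
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain Chain identifier; default: first chain in the file.
#' @param residue_range Optional `c(first, last)` author residue numbers.
#' @return A `structure_model`: list with `entry_id`, `chain_id`, `resno`
#'   (strictly increasing) and `xyz` (n x 3 matrix, Angstrom).
#' @export
load_calpha <- function(path, chain = NULL, residue_range = NULL) {
  if (!file.exists(path)) stop("E_INPUT_NOT_FOUND: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("unparseable coordinate file: ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  sel <- at$elety == "CA" & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (is.null(chain)) chain <- at$chain[sel][1]
  sel <- sel & at$chain == chain
  if (!is.null(residue_range))
    sel <- sel & at$resno >= residue_range[1] & at$resno <= residue_range[2]
  at <- at[sel, , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]  # occupancy ties: first wins
  at <- at[order(at$resno), , drop = FALSE]
  if (nrow(at) == 0L)
    stop("empty C-alpha selection (chain '", chain, "')", call. = FALSE)
  structure(list(entry_id = sub("\\.[^.]*$", "", basename(path)),
                 chain_id = chain,
                 resno = at$resno,
                 xyz = unname(cbind(at$x, at$y, at$z))),
            class = "structure_model")
}

#' Construct a structure model from coordinates
#'
#' @param resno Strictly increasing residue numbers.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param entry_id,chain_id Labels.
#' @return A `structure_model`.
#' @export
structure_model <- function(resno, xyz, entry_id = "model", chain_id = "A") {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) == length(resno), ncol(xyz) == 3,
            all(is.finite(xyz)), all(diff(resno) > 0))
  structure(list(entry_id = entry_id, chain_id = chain_id,
                 resno = as.integer(resno), xyz = unname(xyz)),
            class = "structure_model")
}

#' @method print structure_model
#' @export
print.structure_model <- function(x, ...) {
  cat("Structure ", x$entry_id, " chain ", x$chain_id, ": ",
      length(x$resno), " C-alpha atoms, residues ", min(x$resno), "-",
      max(x$resno), "\n", sep = "")
  invisible(x)
}

# Kabsch: optimal proper rotation mapping centred mobile onto centred
# reference via SVD of the covariance, with reflection correction.
.kabsch_rotation <- function(P, Q) {
  # P, Q: n x 3, already centred; returns R with Q %*% R ~ P
  H <- crossprod(Q, P)               # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)             # applied as x %*% R
}

#' Optimal rigid superposition of two C-alpha sets
#'
#' Pairs residues by author residue number over the intersection of the two
#' selections, then computes the least-squares optimal proper rotation
#' (Kabsch, reflection-corrected) and translation of the mobile set onto
#' the reference, and the residual RMSD.
#'
#' @param reference,mobile `structure_model` objects (>= 3 shared,
#'   non-collinear residues).
#' @return A `superposition` object: `rotation` (3 x 3, det +1),
#'   `translation` (applied as `mobile %*% rotation + translation`),
#'   `rmsd_A`, `n_atoms`, `resno` (paired residues).
#' @export
kabsch_superpose <- function(reference, mobile) {
  stopifnot(inherits(reference, "structure_model"),
            inherits(mobile, "structure_model"))
  common <- intersect(reference$resno, mobile$resno)
  if (length(common) < 3L)
    stop("need at least 3 shared residues for superposition", call. = FALSE)
  P <- reference$xyz[match(common, reference$resno), , drop = FALSE]
  Q <- mobile$xyz[match(common, mobile$resno), , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (any(svd(Qc)$d[1:2] < 1e-8) || any(svd(Pc)$d[1:2] < 1e-8))
    stop("degenerate (collinear) geometry", call. = FALSE)
  R <- .kabsch_rotation(Pc, Qc)
  moved <- Qc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Pc)^2)))
  translation <- cp - as.numeric(cq %*% R)
  structure(list(rotation = R, translation = translation, rmsd_A = rmsd,
                 n_atoms = length(common), resno = common,
                 reference = reference$entry_id, mobile = mobile$entry_id),
            class = "superposition")
}

#' @method print superposition
#' @export
print.superposition <- function(x, ...) {
  cat("Kabsch superposition of ", x$mobile, " onto ", x$reference, ": ",
      x$n_atoms, " C-alpha pairs, RMSD = ", fmt6(x$rmsd_A), " A\n", sep = "")
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup A `superposition`.
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed coordinates.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(as.matrix(xyz) %*% sup$rotation, 2, sup$translation, `+`)
}

#' Plain RMSD of paired coordinate sets without superposition
#' @param a,b n x 3 matrices.
#' @return RMSD in the input units.
#' @export
rmsd_raw <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
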