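# Rigid-body structural comparison: PDB ATOM parsing, C-alpha pairing,
# Kabsch least-squares superposition and RMSD.

#' Read a PDB-format coordinate file
#'
#' Parses `ATOM` records (fixed-column PDB format). Alternate locations are
#' resolved per (chain, residue, insertion code, atom name) to the highest
#' occupancy, ties going to altloc `'A'` (then alphabetical). Insertion
#' codes are preserved in the residue key.
#'
#' @param path PDB file path.
#' @param label source label stored on the model (defaults to the file
#'   name).
#' @return a data frame of class `structure_model` with columns `chain`,
#'   `resseq`, `icode`, `resname`, `atom`, `altloc`, `x`, `y`, `z`,
#'   `occupancy`, `bfactor`.
#' @export
read_structure <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  atom <- lines[grepl("^ATOM  ", lines)]
  if (length(atom) == 0L) abort("no ATOM records in ", path)
  fld <- function(from, to) trimws(substr(atom, from, to))
  num <- function(from, to) as.numeric(fld(from, to))
  m <- data.frame(
    chain = substr(atom, 22, 22),
    resseq = as.integer(fld(23, 26)),
    icode = substr(atom, 27, 27),
    resname = fld(18, 20),
    atom = fld(13, 16),
    altloc = substr(atom, 17, 17),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = {
      occ <- suppressWarnings(num(55, 60)); occ[is.na(occ)] <- 1; occ
    },
    bfactor = suppressWarnings(num(61, 66)),
    stringsAsFactors = FALSE)
  if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z)))
    abort("non-finite coordinates in ", path)

  # altloc resolution: highest occupancy; ties -> 'A' (blank sorts first
  # among equals, then alphabetical)
  key <- paste(m$chain, m$resseq, m$icode, m$atom, sep = "\r")
  pick <- unlist(lapply(split(seq_len(nrow(m)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- m[idx, ]
    best <- idx[sub$occupancy == max(sub$occupancy)]
    if (length(best) == 1L) return(best)
    al <- m$altloc[best]
    best[order(al != "A", al)][1L]
  }), use.names = FALSE)
  m <- m[sort(pick), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("structure_model", "data.frame")
  attr(m, "label") <- label
  m
}

#' Write a structure model as a PDB file
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  name4 <- ifelse(nchar(model$atom) >= 4L, substr(model$atom, 1, 4),
                  sprintf(" %-3s", model$atom))
  lines <- sprintf(
    "ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(model)), name4, model$altloc, model$resname, model$chain,
    model$resseq, model$icode, model$x, model$y, model$z,
    model$occupancy, ifelse(is.na(model$bfactor), 0, model$bfactor))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Pair C-alpha atoms between two structure models
#'
#' Matches C-alpha atoms by (mapped chain, residue number + offset,
#' insertion code). Unpaired residue counts are attached as attributes.
#'
#' @param model_a,model_b `structure_model`s (reference, mobile).
#' @param chain_map named character vector mapping chains of `model_a` to
#'   chains of `model_b` (default: identity).
#' @param residue_offset added to `model_a` residue numbers before
#'   matching against `model_b`.
#' @return list with `x` (n x 3 matrix, model_a coords), `y` (model_b
#'   coords), `residues` (data frame of matched keys); at least 3 pairs
#'   are required.
#' @export
pair_calpha <- function(model_a, model_b, chain_map = NULL,
                        residue_offset = 0L) {
  ca_a <- model_a[model_a$atom == "CA", , drop = FALSE]
  ca_b <- model_b[model_b$atom == "CA", , drop = FALSE]
  mapped_chain <- if (is.null(chain_map)) ca_a$chain else {
    mc <- unname(chain_map[ca_a$chain])
    ifelse(is.na(mc), ca_a$chain, mc)
  }
  key_a <- paste(mapped_chain, ca_a$resseq + residue_offset, ca_a$icode)
  key_b <- paste(ca_b$chain, ca_b$resseq, ca_b$icode)
  j <- match(key_a, key_b)
  ok <- !is.na(j)
  if (sum(ok) < 3L)
    abort("fewer than 3 paired C-alpha atoms (", sum(ok), " found)")
  out <- list(
    x = as.matrix(ca_a[ok, c("x", "y", "z")]),
    y = as.matrix(ca_b[j[ok], c("x", "y", "z")]),
    residues = data.frame(chain = mapped_chain[ok],
                          resseq = ca_a$resseq[ok] + residue_offset,
                          icode = ca_a$icode[ok], stringsAsFactors = FALSE))
  attr(out, "unpaired_a") <- sum(!ok)
  attr(out, "unpaired_b") <- nrow(ca_b) - sum(ok)
  out
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' of `R y_i + t` against `x_i` (reflections excluded by determinant
#' correction). Coordinates are row vectors.
#'
#' @param coords_x reference coordinates, n x 3 matrix (n >= 3,
#'   non-collinear).
#' @param coords_y mobile coordinates, n x 3 matrix.
#' @return an object of class `superposition_result`: list with
#'   `rotation` (3 x 3, det = +1), `translation` (length-3), `rmsd`
#'   (Angstrom), `n_pairs`.
#' @export
kabsch_superpose <- function(coords_x, coords_y) {
  x <- as.matrix(coords_x); y <- as.matrix(coords_y)
  if (!all(dim(x) == dim(y)) || ncol(x) != 3L)
    abort("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(x)
  if (n < 3L) abort("need at least 3 point pairs")
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  for (m in list(x0, y0)) {
    sv <- svd(m)$d
    if (sv[2L] <= 1e-8 * max(sv[1L], 1e-12))
      abort("degenerate (collinear) coordinate configuration")
  }
  h <- crossprod(y0, x0)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cx - rot %*% cy)
  y_fit <- y %*% t(rot) + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((y_fit - x)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition of %d atom pairs: RMSD = %.4f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to a structure model
#'
#' @param model a `structure_model` (the mobile model).
#' @param sup a `superposition_result` from [kabsch_superpose()].
#' @return the transformed `structure_model`.
#' @export
apply_superposition <- function(model, sup) {
  stopifnot(inherits(model, "structure_model"),
            inherits(sup, "superposition_result"))
  xyz <- as.matrix(model[, c("x", "y", "z")])
  new <- xyz %*% t(sup$rotation) +
    matrix(sup$translation, nrow(xyz), 3, byrow = TRUE)
  model$x <- new[, 1L]; model$y <- new[, 2L]; model$z <- new[, 3L]
  model
}

#' Superpose two PDB files and report the RMSD
#'
#' Convenience wrapper: read both files, pair C-alpha atoms, run the
#' Kabsch superposition.
#'
#' @param ref_path,mobile_path PDB files (reference, mobile).
#' @inheritParams pair_calpha
#' @return a `superposition_result`.
#' @export
superpose_pdb <- function(ref_path, mobile_path, chain_map = NULL,
                          residue_offset = 0L) {
  a <- read_structure(ref_path)
  b <- read_structure(mobile_path)
  pr <- pair_calpha(a, b, chain_map, residue_offset)
  kabsch_superpose(pr$x, pr$y)
}
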