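# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of (parameters, seed).
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with call. = FALSE everywhere; keeps messages clean at the CLI
abort <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort(sprintf("'%s' must be > 0", name))
  invisible(x)
}

#' Read a single protein sequence from a FASTA file
#'
#' Minimal single-record FASTA reader (uppercase amino-acid letters). Only
#' the first record is returned; lines before the first header are ignored.
#'
#' @param path path to a plain-text FASTA file.
#' @return a single uppercase character string.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) abort("no FASTA header ('>') found in ", path)
  from <- hdr[1L] + 1L
  to <- if (length(hdr) > 1L) hdr[2L] - 1L else length(lines)
  seq <- toupper(gsub("[[:space:]]", "", paste(lines[from:to], collapse = "")))
  if (nchar(seq) == 0L) abort("empty sequence in ", path)
  seq
}

#' Write a protein sequence as FASTA
#' @param sequence amino-acid string.
#' @param path output path.
#' @param name header text (without '>').
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequence, path, name = "protein", width = 60L) {
  chunks <- substring(sequence, seq(1L, nchar(sequence), width),
                      pmin(seq(1L, nchar(sequence), width) + width - 1L,
                           nchar(sequence)))
  writeLines(c(paste0(">", name), chunks), path)
  invisible(path)
}

# monoisotopic residue masses (Da), used by the HX generator to build
# internally consistent peptide neutral masses
AA_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.00728
# mass increment per incorporated deuterium (H -> D)
MASS_D_INCREMENT <- 1.00628

peptide_neutral_mass <- function(sequence) {
  aa <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(aa, names(AA_MONO))
  if (length(bad))
    abort("non-standard residue letter(s): ", paste(unique(bad), collapse = ", "))
  sum(AA_MONO[aa]) + MASS_WATER
}
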