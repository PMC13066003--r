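# In-code fixtures (no binary files shipped).

write_psp_fixture <- function(rows, path = tempfile(fileext = ".gz"),
                              banner = TRUE) {
  header <- paste(c("GENE", "PROTEIN", "ACC_ID", "MOD_RSD", "ORGANISM",
                    "MS_LIT", "MS_CST", "LT_LIT"), collapse = "\t")
  lines <- c(if (banner) c("PhosphoSitePlus-style banner line", ""),
             header, rows)
  con <- gzfile(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

psp_row <- function(gene, acc, mod, org, ms_lit = "", ms_cst = "",
                    lt_lit = "") {
  paste(gene, gene, acc, mod, org, ms_lit, ms_cst, lt_lit, sep = "\t")
}

make_records <- function(ms_lit, ms_cst, lt_lit = 0,
                         acc = sprintf("P%05d", seq_along(ms_lit)),
                         position = seq_along(ms_lit)) {
  n <- length(ms_lit)
  data.frame(protein_accession = acc,
             gene_symbol = toupper(acc),
             residue = rep_len("Y", n), position = position,
             organism = rep_len("human", n),
             ms_lit = ms_lit, ms_cst = rep_len(ms_cst, n),
             lt_lit = rep_len(lt_lit, n),
             stringsAsFactors = FALSE)
}

write_pdb_fixture <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "HEADER    SYNTHETIC FIXTURE",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 11.00",
    "ATOM      3  CA  GLY A   2      13.478   7.500  -3.000  1.00 12.00",
    "ATOM      4  CA AVAL A   3      15.000   9.000  -1.000  0.60 13.00",
    "ATOM      5  CA BVAL A   3      15.100   9.100  -1.100  0.40 13.50",
    "ATOM      6  CA  LEU A   4      17.250  10.500   1.250  1.00 14.00",
    "ATOM      7  CA  SER A   5      19.000  12.000   3.500  1.00 15.00",
    "END")
  writeLines(lines, path)
  path
}

# protein sequence without prolines for clean exchange arithmetic
hx_test_sequence <- function(n = 100) {
  paste(rep_len(strsplit("GASTLVEKIR", "")[[1]], n), collapse = "")
}
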