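#' Read a PhosphoSitePlus-dialect phosphorylation site table
#'
#' Parses the tab-delimited `Phosphorylation_site_dataset` dialect: an
#' optional license banner precedes a header row containing at least the
#' columns `GENE`, `PROTEIN`, `ACC_ID`, `MOD_RSD`, `ORGANISM`, `MS_LIT`,
#' `MS_CST`, `LT_LIT`. The file may be gzipped (`.gz`). Only phosphorylation
#' records (modified-residue token of the form `"Y62-p"`) are returned;
#' malformed tokens are skipped with a warning. Blank count cells are read
#' as 0.
#'
#' @param path path to a (possibly gzipped) tab-delimited site table.
#' @param organism_filter if non-`NULL`, keep only records whose ORGANISM
#'   matches (case-insensitive exact match).
#' @return a data frame of class `phosphosite_table` with columns
#'   `protein_accession`, `gene_symbol`, `residue`, `position`, `organism`,
#'   `ms_lit`, `ms_cst`, `lt_lit`. The number of skipped malformed records
#'   is attached as attribute `n_skipped`.
#' @export
read_phosphosite_table <- function(path, organism_filter = NULL) {
  if (!file.exists(path)) abort("cannot read file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  required <- c("ACC_ID", "MOD_RSD", "ORGANISM")
  header_at <- NA_integer_
  for (i in seq_len(min(length(lines), 50L))) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (all(required %in% toupper(trimws(fields)))) { header_at <- i; break }
  }
  if (is.na(header_at))
    abort("no recognizable header row (need columns ",
          paste(required, collapse = ", "), ") in ", path)

  header <- toupper(trimws(strsplit(lines[header_at], "\t", fixed = TRUE)[[1L]]))
  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    return(empty_phosphosite_table())

  cells <- strsplit(body, "\t", fixed = TRUE)
  col <- function(nm) {
    j <- match(nm, header)
    if (is.na(j)) return(rep("", length(cells)))
    vapply(cells, function(r) if (length(r) >= j) r[j] else "", character(1))
  }
  count_col <- function(nm) {
    v <- suppressWarnings(as.numeric(col(nm)))
    v[is.na(v)] <- 0              # blank / missing cells -> 0
    as.integer(v)
  }

  mod <- trimws(col("MOD_RSD"))
  is_phos <- grepl("-p$", mod)
  m <- regmatches(mod, regexec("^([STY])([0-9]+)-p$", mod))
  ok <- is_phos & lengths(m) == 3L
  n_skipped <- sum(is_phos & !ok)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d record(s) with malformed modified-residue token",
                    n_skipped), call. = FALSE)

  res <- data.frame(
    protein_accession = trimws(col("ACC_ID"))[ok],
    gene_symbol = trimws(col("GENE"))[ok],
    residue = vapply(m[ok], `[`, character(1), 2L),
    position = as.integer(vapply(m[ok], `[`, character(1), 3L)),
    organism = trimws(col("ORGANISM"))[ok],
    ms_lit = count_col("MS_LIT")[ok],
    ms_cst = count_col("MS_CST")[ok],
    lt_lit = count_col("LT_LIT")[ok],
    stringsAsFactors = FALSE
  )
  if (!is.null(organism_filter))
    res <- res[tolower(res$organism) == tolower(organism_filter), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("phosphosite_table", "data.frame")
  attr(res, "n_skipped") <- n_skipped
  res
}

empty_phosphosite_table <- function() {
  res <- data.frame(
    protein_accession = character(0), gene_symbol = character(0),
    residue = character(0), position = integer(0), organism = character(0),
    ms_lit = integer(0), ms_cst = integer(0), lt_lit = integer(0),
    stringsAsFactors = FALSE)
  class(res) <- c("phosphosite_table", "data.frame")
  attr(res, "n_skipped") <- 0L
  res
}

#' Observation frequency of a phosphosite
#'
#' The number of mass-spectrometry observations supporting a site: the count
#' of published MS studies (`ms_lit`) plus the count of curated unpublished
#' MS experiments (`ms_cst`).
#'
#' @param records a `phosphosite_table` (or any data frame with `ms_lit`,
#'   `ms_cst` columns).
#' @return integer vector of frequencies, one per record.
#' @export
observation_frequency <- function(records) {
  stopifnot(all(c("ms_lit", "ms_cst") %in% names(records)))
  if (any(records$ms_lit < 0 | records$ms_cst < 0))
    abort("observation counts must be non-negative")
  as.integer(records$ms_lit + records$ms_cst)
}

#' Characterization ratio of a phosphosite
#'
#' Ratio of low-throughput literature support to MS observation frequency,
#' with a +1 pseudocount on the low-throughput count:
#' `(lt_lit + 1) / (ms_cst + ms_lit)`. Undefined (an error) when the
#' observation frequency is zero.
#'
#' @inheritParams observation_frequency
#' @return numeric vector of ratios (always > 0).
#' @export
characterization_ratio <- function(records) {
  freq <- observation_frequency(records)
  if (any(freq == 0))
    abort("characterization ratio undefined for records with zero observations")
  (records$lt_lit + 1) / freq
}

#' Rank phosphosites by observation frequency
#'
#' Sorts records by frequency (descending), breaking ties by accession then
#' position (ascending), and flags the top `ceiling(top_fraction * N)`
#' entries as hotspot candidates.
#'
#' @param records a `phosphosite_table`.
#' @param top_fraction fraction of sites to flag, in (0, 1].
#' @return a data frame of class `hotspot_scores`: the input columns plus
#'   `frequency`, `char_ratio` (`NA` where frequency is 0), `rank`
#'   (1 = most frequent) and `in_top_fraction`.
#' @export
rank_hotspots <- function(records, top_fraction = 0.01) {
  assert_scalar_number(top_fraction, "top_fraction")
  if (top_fraction <= 0 || top_fraction > 1)
    abort("'top_fraction' must be in (0, 1]")
  n <- nrow(records)
  if (n == 0L) {
    out <- cbind(as.data.frame(records),
                 frequency = integer(0), char_ratio = numeric(0),
                 rank = integer(0), in_top_fraction = logical(0))
    class(out) <- c("hotspot_scores", "data.frame")
    return(out)
  }
  freq <- observation_frequency(records)
  ord <- order(-freq, records$protein_accession, records$position,
               method = "radix")
  out <- as.data.frame(records)[ord, , drop = FALSE]
  out$frequency <- freq[ord]
  out$char_ratio <- ifelse(out$frequency > 0,
                           (out$lt_lit + 1) / out$frequency, NA_real_)
  out$rank <- seq_len(n)
  out$in_top_fraction <- out$rank <= ceiling(top_fraction * n)
  rownames(out) <- NULL
  class(out) <- c("hotspot_scores", "data.frame")
  out
}

#' Per-protein summary of hotspot sites
#'
#' Tallies, for each protein, how many of its sites fall in the flagged top
#' fraction, listing those sites in order of decreasing frequency. Proteins
#' are ordered by top-site count (descending), then by their maximum site
#' frequency (descending), then accession.
#'
#' @param scores output of [rank_hotspots()].
#' @return a data frame with columns `protein_accession`, `gene_symbol`,
#'   `n_top_sites`, `max_frequency`, `top_sites` (residue+position labels
#'   joined by ";").
#' @export
multisite_summary <- function(scores) {
  stopifnot(inherits(scores, "hotspot_scores"))
  top <- scores[scores$in_top_fraction, , drop = FALSE]
  accs <- unique(scores$protein_accession)
  rows <- lapply(accs, function(a) {
    sub_all <- scores[scores$protein_accession == a, , drop = FALSE]
    sub <- top[top$protein_accession == a, , drop = FALSE]
    sub <- sub[order(-sub$frequency, sub$position), , drop = FALSE]
    data.frame(
      protein_accession = a,
      gene_symbol = sub_all$gene_symbol[1L],
      n_top_sites = nrow(sub),
      max_frequency = max(sub_all$frequency),
      top_sites = paste0(sub$residue, sub$position, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_top_sites, -out$max_frequency,
                   out$protein_accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a hotspot table to CSV
#' @param scores output of [rank_hotspots()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hotspot_csv <- function(scores, path) {
  cols <- c("protein_accession", "gene_symbol", "residue", "position",
            "frequency", "char_ratio", "rank", "in_top_fraction")
  utils::write.csv(as.data.frame(scores)[, cols], path, row.names = FALSE)
  invisible(path)
}
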