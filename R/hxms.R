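# Hydrogen-deuterium exchange: peptide centroids -> back-exchange-corrected
# uptake fractions -> pseudo-residue differential deuteration (dD-bar) maps.

#' Number of exchangeable backbone amides in a peptide
#'
#' Standard HX convention: the first two residues of a peptide do not retain
#' label (N-terminal amine plus fast back-exchange of the second amide), and
#' proline has no backbone amide hydrogen. The count is therefore
#' `length - 2 - (# prolines at positions >= 3)`, floored at 0.
#'
#' @param sequence amino-acid string (standard 20 one-letter codes).
#' @return non-negative integer.
#' @export
exchangeable_count <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    abort("'sequence' must be a non-empty string")
  aa <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(aa, names(AA_MONO))
  if (length(bad))
    abort("non-standard residue letter(s): ", paste(unique(bad), collapse = ", "))
  n <- length(aa)
  if (n <= 2L) return(0L)
  as.integer(n - 2L - sum(aa[3:n] == "P"))
}

#' Peptide filter thresholds for HX-MS assignment tables
#'
#' Defaults follow the published PIGEON disambiguation settings: 30 ppm
#' initial and 7 ppm narrow mass cutoffs, 0.020 Da MS/MS error, score
#' cutoff 0.05, peptide length 3-15, charge cutoff 3, 0.1 D per
#' exchangeable residue and 0.5 min retention-time degeneracy cutoffs.
#' Only the length and charge rules act on an assigned peptide list; the
#' remaining thresholds are spectral-assignment settings carried as
#' metadata.
#'
#' @param min_length,max_length allowed peptide length range.
#' @param max_charge maximum precursor charge.
#' @param ppm_initial,ppm_narrow mass tolerances (ppm).
#' @param msms_error fragment mass error (Da).
#' @param score_cutoff assignment score cutoff.
#' @param de_cutoff deuterons per exchangeable residue cutoff.
#' @param rt_degeneracy_cutoff retention-time degeneracy cutoff (min).
#' @return a list of class `hx_filter_config`.
#' @export
hx_filter_config <- function(min_length = 3L, max_length = 15L,
                             max_charge = 3L, ppm_initial = 30,
                             ppm_narrow = 7, msms_error = 0.020,
                             score_cutoff = 0.05, de_cutoff = 0.1,
                             rt_degeneracy_cutoff = 0.5) {
  cfg <- list(min_length = as.integer(min_length),
              max_length = as.integer(max_length),
              max_charge = as.integer(max_charge),
              ppm_initial = ppm_initial, ppm_narrow = ppm_narrow,
              msms_error = msms_error, score_cutoff = score_cutoff,
              de_cutoff = de_cutoff,
              rt_degeneracy_cutoff = rt_degeneracy_cutoff)
  if (any(vapply(cfg, function(x) x <= 0, logical(1))))
    abort("all filter thresholds must be > 0")
  if (cfg$min_length > cfg$max_length)
    abort("min_length must be <= max_length")
  structure(cfg, class = "hx_filter_config")
}

#' Read an HX-MS peptide list from CSV
#'
#' Expected columns: `peptide_id`, `start`, `end` (1-based inclusive
#' protein coordinates), `sequence`, `charge`, and optionally `rt`
#' (retention time, minutes).
#'
#' @param path CSV path.
#' @param protein_sequence optional full protein sequence; when given, each
#'   peptide's sequence is checked against the corresponding slice.
#' @return a data frame of class `peptide_table`.
#' @export
read_peptides <- function(path, protein_sequence = NULL) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "start", "end", "sequence", "charge")
  if (!all(need %in% names(p)))
    abort("peptide CSV must contain columns: ", paste(need, collapse = ", "))
  if (!"rt" %in% names(p)) p$rt <- NA_real_
  as_peptide_table(p, protein_sequence)
}

as_peptide_table <- function(p, protein_sequence = NULL) {
  p$start <- as.integer(p$start); p$end <- as.integer(p$end)
  p$charge <- as.integer(p$charge)
  p$sequence <- toupper(p$sequence)
  bad <- p$end - p$start + 1L != nchar(p$sequence)
  if (any(bad))
    abort("peptide span inconsistent with sequence length: ",
          paste(p$peptide_id[bad], collapse = ", "))
  if (!is.null(protein_sequence)) {
    slice <- substring(protein_sequence, p$start, p$end)
    mism <- slice != p$sequence
    if (any(mism))
      abort("peptide sequence does not match protein slice: ",
            paste(p$peptide_id[mism], collapse = ", "))
  }
  class(p) <- c("peptide_table", "data.frame")
  p
}

#' Apply length/charge filters to an assigned peptide list
#'
#' @param peptides a `peptide_table`.
#' @param config an [hx_filter_config()].
#' @return list with elements `retained` (filtered `peptide_table`) and
#'   `rejections` (data frame `peptide_id`, `rule`).
#' @export
apply_peptide_filters <- function(peptides, config = hx_filter_config()) {
  stopifnot(inherits(config, "hx_filter_config"))
  len <- nchar(peptides$sequence)
  rule <- rep(NA_character_, nrow(peptides))
  rule[len < config$min_length | len > config$max_length] <- "length"
  rule[is.na(rule) & peptides$charge > config$max_charge] <- "charge"
  keep <- is.na(rule)
  list(
    retained = peptides[keep, , drop = FALSE],
    rejections = data.frame(peptide_id = peptides$peptide_id[!keep],
                            rule = rule[!keep], stringsAsFactors = FALSE))
}

#' Read HX-MS centroid measurements from CSV
#'
#' Expected columns: `peptide_id`, `variant`, `state` (one of
#' `undeuterated`, `deuterated`, `fully_deuterated`), `timepoint_s`
#' (seconds; 0 for undeuterated, -1 sentinel accepted for fully
#' deuterated), `replicate`, `centroid_mz`, `charge`. Centroid m/z values
#' are charge-deconvoluted to neutral masses:
#' `mass = (m/z - 1.00728) * z`.
#'
#' @param path CSV path.
#' @return a data frame of class `centroid_table` with a `centroid_mass`
#'   column (Da, neutral).
#' @export
read_centroids <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "variant", "state", "timepoint_s", "replicate",
            "centroid_mz", "charge")
  if (!all(need %in% names(d)))
    abort("centroid CSV must contain columns: ", paste(need, collapse = ", "))
  d$centroid_mass <- (d$centroid_mz - MASS_PROTON) * d$charge
  as_centroid_table(d)
}

as_centroid_table <- function(d) {
  states <- c("undeuterated", "deuterated", "fully_deuterated")
  bad <- setdiff(unique(d$state), states)
  if (length(bad)) abort("unknown labeling state(s): ", paste(bad, collapse = ", "))
  if (any(d$centroid_mass <= 0)) abort("centroid masses must be > 0")
  if (any(d$state == "deuterated" & d$timepoint_s <= 0))
    abort("deuterated measurements require timepoint_s > 0")
  class(d) <- c("centroid_table", "data.frame")
  d
}

# per-variant mean undeuterated centroid for one peptide
undeut_mean <- function(centroids, peptide_id) {
  u <- centroids[centroids$peptide_id == peptide_id &
                   centroids$state == "undeuterated", , drop = FALSE]
  if (nrow(u) == 0L)
    abort("no undeuterated reference for peptide ", peptide_id)
  tapply(u$centroid_mass, u$variant, mean)
}

#' Maximum labeling (back-exchange-corrected full-deuteration shift)
#'
#' If fully deuterated control spectra exist for the peptide, the maximum
#' labeling is the mean — pooled over all replicates and all variants — of
#' (full-D centroid minus that variant's mean undeuterated centroid).
#' Otherwise the theoretical maximum
#' `exchangeable_count * d2o_fraction * 1.00628` Da is used.
#'
#' @param peptide_id peptide identifier.
#' @param centroids a `centroid_table`.
#' @param d2o_fraction deuterium fraction of the labeling buffer
#'   (default 0.9, i.e. a tenfold dilution into deuterated buffer).
#' @param sequence peptide sequence; required when no full-D spectra exist.
#' @return maximum labeling in Da (> 0).
#' @export
max_labeling <- function(peptide_id, centroids, d2o_fraction = 0.9,
                         sequence = NULL) {
  stopifnot(inherits(centroids, "centroid_table"))
  fd <- centroids[centroids$peptide_id == peptide_id &
                    centroids$state == "fully_deuterated", , drop = FALSE]
  if (nrow(fd) > 0L) {
    u <- undeut_mean(centroids, peptide_id)
    miss <- setdiff(unique(fd$variant), names(u))
    if (length(miss))
      abort("no undeuterated reference for variant(s): ",
            paste(miss, collapse = ", "))
    shift <- mean(fd$centroid_mass - u[fd$variant])
  } else {
    if (is.null(sequence))
      abort("no full-D spectra for peptide ", peptide_id,
            "; supply 'sequence' for the theoretical maximum")
    shift <- exchangeable_count(sequence) * d2o_fraction * MASS_D_INCREMENT
  }
  if (shift <= 0)
    abort("maximum labeling <= 0 for peptide ", peptide_id,
          " (full-D below undeuterated)")
  shift
}

#' Deuterium uptake as a fraction of maximum labeling
#'
#' `(mean deuterated centroid - mean undeuterated centroid) / max_labeling`
#' for one (peptide, variant, timepoint). The replicate standard deviation
#' is computed from per-replicate fractions. Values slightly outside
#' \[0, 1\] are reported as-is with `out_of_range = TRUE`.
#'
#' @param peptide_id,variant,timepoint the measurement cell.
#' @param centroids a `centroid_table`.
#' @param max_labeling maximum labeling in Da (see [max_labeling()]).
#' @return a one-row data frame: `peptide_id`, `variant`, `timepoint`,
#'   `fraction_of_max`, `replicate_sd`, `n_replicates`, `out_of_range`.
#' @export
uptake_fraction <- function(peptide_id, variant, timepoint, centroids,
                            max_labeling) {
  stopifnot(inherits(centroids, "centroid_table"))
  assert_scalar_number(max_labeling, "max_labeling", positive = TRUE)
  d <- centroids[centroids$peptide_id == peptide_id &
                   centroids$variant == variant &
                   centroids$state == "deuterated" &
                   centroids$timepoint_s == timepoint, , drop = FALSE]
  if (nrow(d) == 0L)
    abort("no deuterated replicates for (", peptide_id, ", ", variant,
          ", t=", timepoint, ")")
  u <- undeut_mean(centroids, peptide_id)
  if (!variant %in% names(u))
    abort("no undeuterated reference for peptide ", peptide_id,
          " variant ", variant)
  fr <- (d$centroid_mass - u[[variant]]) / max_labeling
  frac <- mean(fr)
  oor <- frac < 0 || frac > 1
  if (frac < -0.05 || frac > 1.05)
    warning(sprintf("uptake fraction %.3f far outside [0, 1] for %s/%s t=%s",
                    frac, peptide_id, variant, format(timepoint)),
            call. = FALSE)
  data.frame(peptide_id = peptide_id, variant = variant,
             timepoint = timepoint, fraction_of_max = frac,
             replicate_sd = if (length(fr) > 1L) stats::sd(fr) else NA_real_,
             n_replicates = length(fr), out_of_range = oor,
             stringsAsFactors = FALSE)
}

#' Uptake fractions for every (peptide, variant, timepoint) cell
#'
#' Convenience driver over [max_labeling()] and [uptake_fraction()].
#'
#' @param peptides a `peptide_table` (used for sequences when theoretical
#'   maxima are needed).
#' @param centroids a `centroid_table`.
#' @param d2o_fraction labeling-buffer deuterium fraction.
#' @return a data frame of class `uptake_table` (columns as in
#'   [uptake_fraction()]).
#' @export
uptake_table <- function(peptides, centroids, d2o_fraction = 0.9) {
  stopifnot(inherits(centroids, "centroid_table"))
  dd <- centroids[centroids$state == "deuterated", , drop = FALSE]
  cells <- unique(dd[, c("peptide_id", "variant", "timepoint_s")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pid <- cells$peptide_id[i]
    seq_i <- peptides$sequence[match(pid, peptides$peptide_id)]
    ml <- max_labeling(pid, centroids, d2o_fraction,
                       sequence = if (is.na(seq_i)) NULL else seq_i)
    uptake_fraction(pid, cells$variant[i], cells$timepoint_s[i],
                    centroids, ml)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide_id, out$variant, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("uptake_table", "data.frame")
  out
}

#' Residue coverage map from a peptide list
#'
#' A peptide spanning `start..end` contributes coverage to residues
#' `(start+2)..end`: its first two residues carry no retained label, so no
#' information is attributed to them. Prolines remain in the map (they
#' carry information only through the peptide average). Residues covered
#' by no peptide are absent.
#'
#' @param peptides a `peptide_table`.
#' @param protein_length protein length (residues).
#' @return named list: residue index (as character) -> character vector of
#'   covering peptide ids.
#' @export
build_coverage <- function(peptides, protein_length) {
  assert_scalar_number(protein_length, "protein_length", positive = TRUE)
  if (any(peptides$end > protein_length))
    abort("peptide(s) exceed protein length: ",
          paste(peptides$peptide_id[peptides$end > protein_length],
                collapse = ", "))
  cov <- list()
  for (i in seq_len(nrow(peptides))) {
    lo <- peptides$start[i] + 2L
    hi <- peptides$end[i]
    if (lo > hi) next
    for (r in lo:hi) {
      key <- as.character(r)
      cov[[key]] <- c(cov[[key]], peptides$peptide_id[i])
    }
  }
  cov[order(as.integer(names(cov)))]
}

#' Pseudo-residue differential deuteration map (dD-bar)
#'
#' For each covered residue and each shared timepoint, the uptake fractions
#' of all covering peptides are averaged within each variant; the
#' difference (variant minus reference, in percentage points) is then
#' averaged over timepoints with equal weights. Positive values mean the
#' variant exchanges more (is more open) than the reference.
#'
#' Peptide sets and timepoints are intersected between the two inputs when
#' they differ (a message reports what was dropped).
#'
#' @param uptake_variant,uptake_reference `uptake_table`s each containing a
#'   single variant.
#' @param coverage output of [build_coverage()].
#' @param timepoints optional timepoint subset (seconds); default all
#'   shared timepoints.
#' @return a data frame of class `residue_uptake_map` with columns
#'   `residue`, `dD` (percentage points) and `coverage_count`.
#' @export
pseudo_residue_dD <- function(uptake_variant, uptake_reference, coverage,
                              timepoints = NULL) {
  for (u in list(uptake_variant, uptake_reference))
    if (length(unique(u$variant)) != 1L)
      abort("each uptake table must contain exactly one variant")
  peps <- intersect(unique(uptake_variant$peptide_id),
                    unique(uptake_reference$peptide_id))
  tps <- intersect(unique(uptake_variant$timepoint),
                   unique(uptake_reference$timepoint))
  if (!is.null(timepoints)) tps <- intersect(tps, timepoints)
  if (length(tps) == 0L) abort("no shared timepoints between variants")
  dropped <- length(unique(c(uptake_variant$peptide_id,
                             uptake_reference$peptide_id))) - length(peps)
  if (dropped > 0L)
    message(dropped, " peptide(s) not shared between variants; using the ",
            "intersection")

  mean_frac <- function(u, pid_set, tp)
    mean(u$fraction_of_max[u$peptide_id %in% pid_set & u$timepoint == tp])

  rows <- lapply(names(coverage), function(key) {
    pids <- intersect(coverage[[key]], peps)
    if (length(pids) == 0L) return(NULL)
    diffs <- vapply(tps, function(tp) {
      fv <- mean_frac(uptake_variant, pids, tp)
      fr <- mean_frac(uptake_reference, pids, tp)
      100 * (fv - fr)
    }, numeric(1))
    data.frame(residue = as.integer(key), dD = mean(diffs),
               coverage_count = length(pids))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(residue = integer(0), dD = numeric(0),
                      coverage_count = integer(0))
  rownames(out) <- NULL
  class(out) <- c("residue_uptake_map", "data.frame")
  attr(out, "timepoints") <- sort(tps)
  out
}

#' Export a residue dD-bar map to CSV or paint it onto a PDB file
#'
#' CSV output has columns `residue`, `dD`, `coverage_count`. PDB output
#' copies `pdb_path`, replacing the B-factor column of every ATOM record:
#' covered residues get their dD value (2 decimals), uncovered residues the
#' sentinel. Map residues absent from the PDB raise a warning and are
#' skipped.
#'
#' @param map a `residue_uptake_map`.
#' @param path output path.
#' @param format `"csv"` or `"pdb"`.
#' @param pdb_path template PDB (required for `format = "pdb"`).
#' @param sentinel B-factor for uncovered residues (default -99.0).
#' @return `path`, invisibly.
#' @export
export_residue_map <- function(map, path, format = c("csv", "pdb"),
                               pdb_path = NULL, sentinel = -99.0) {
  stopifnot(inherits(map, "residue_uptake_map"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(map), path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(pdb_path)) abort("'pdb_path' is required for PDB output")
  lines <- readLines(pdb_path, warn = FALSE)
  is_atom <- grepl("^ATOM  ", lines)
  resseq <- rep(NA_integer_, length(lines))
  resseq[is_atom] <- suppressWarnings(
    as.integer(trimws(substr(lines[is_atom], 23, 26))))
  pdb_res <- unique(resseq[is_atom])
  missing <- setdiff(map$residue, pdb_res)
  if (length(missing))
    warning("map residue(s) absent from PDB, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  bvals <- ifelse(resseq %in% map$residue,
                  map$dD[match(resseq, map$residue)], sentinel)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 66) ln <- formatC(ln, width = 66, flag = "-")
    substr(ln, 61, 66) <- sprintf("%6.2f", bvals[i])
    lines[i] <- ln
  }
  writeLines(lines, path)
  invisible(path)
}

#' End-to-end residue dD-bar map between two variants
#'
#' Runs filtering, uptake computation and residue averaging in one call.
#'
#' @param peptides a `peptide_table`.
#' @param centroids a `centroid_table` containing both variants.
#' @param reference,variant variant labels (e.g. `"WT"`, `"Y62D"`).
#' @param protein_length protein length in residues.
#' @param d2o_fraction labeling-buffer deuterium fraction.
#' @param config filter configuration; [hx_filter_config()] by default.
#' @return a `residue_uptake_map` (see [pseudo_residue_dD()]).
#' @export
hx_residue_map <- function(peptides, centroids, reference, variant,
                           protein_length, d2o_fraction = 0.9,
                           config = hx_filter_config()) {
  flt <- apply_peptide_filters(peptides, config)
  peps <- flt$retained
  cen <- centroids[centroids$peptide_id %in% peps$peptide_id, , drop = FALSE]
  class(cen) <- class(centroids)
  upt <- uptake_table(peps, cen, d2o_fraction)
  cov <- build_coverage(peps, protein_length)
  pseudo_residue_dD(upt[upt$variant == variant, , drop = FALSE],
                    upt[upt$variant == reference, , drop = FALSE],
                    cov)
}
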