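# Seeded synthetic-data generators. Each generator is a pure function of
# (parameters, seed), writes its ground truth as JSON next to any files it
# produces, and emits exactly the dialects the analysis modules read.

write_truth <- function(truth, path) {
  if (is.null(path)) return(invisible(NULL))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a PhosphoSitePlus-dialect phosphosite table
#'
#' Background observation counts are drawn from geometric (long-tailed)
#' distributions; `n_hotspots` designated rows receive frequencies above
#' every background site. `LT_LIT` is sparse. Zero counts are written as
#' blank cells, emulating the real table. A three-line license-style
#' banner precedes the header.
#'
#' @param n_sites number of site rows (>= 1).
#' @param hotspot_spec list with `n_hotspots` (default 5) and optionally
#'   `min_gap` (frequency margin above the background maximum, default 50).
#' @param seed integer seed.
#' @param path output path (`.gz` for gzipped); `NULL` for no file.
#' @param organism organism label (default `"human"`).
#' @return invisible list: `path`, `records` (data frame as written),
#'   `truth` (list incl. hotspot accessions/positions). Truth is also
#'   written to `<path>.truth.json` when a path is given.
#' @export
gen_phosphosite_table <- function(n_sites, hotspot_spec = list(), seed = 1L,
                                  path = NULL, organism = "human") {
  if (n_sites < 1L) abort("'n_sites' must be >= 1")
  n_hot <- hotspot_spec$n_hotspots %||% 5L
  min_gap <- hotspot_spec$min_gap %||% 50L
  if (n_hot > n_sites) abort("hotspot count exceeds n_sites")

  rec <- with_seed(seed, {
    n_prot <- max(1L, ceiling(n_sites / 4))   # ~4 sites per protein
    prot <- sprintf("P%05d", sample.int(99999L, n_prot))
    acc <- sample(prot, n_sites, replace = TRUE)
    gene <- toupper(substr(acc, 2, 6))
    residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                      prob = c(0.65, 0.2, 0.15))
    position <- sample.int(800L, n_sites, replace = TRUE)
    # keep (accession, position) unique
    key <- paste(acc, position)
    while (anyDuplicated(key)) {
      dup <- duplicated(key)
      position[dup] <- sample.int(800L, sum(dup), replace = TRUE)
      key <- paste(acc, position)
    }
    ms_lit <- stats::rgeom(n_sites, prob = 0.25)
    ms_cst <- stats::rgeom(n_sites, prob = 0.10)
    lt_lit <- stats::rgeom(n_sites, prob = 0.85)
    hot_idx <- sample.int(n_sites, n_hot)
    if (n_hot > 0L) {
      bg_max <- max((ms_lit + ms_cst)[-hot_idx], 0L)
      ms_cst[hot_idx] <- pmax(0L, bg_max + min_gap + n_hot:1L -
                                ms_lit[hot_idx])
    }
    data.frame(GENE = gene, PROTEIN = gene, ACC_ID = acc,
               MOD_RSD = paste0(residue, position, "-p"),
               ORGANISM = organism, MS_LIT = ms_lit, MS_CST = ms_cst,
               LT_LIT = lt_lit, hot = seq_len(n_sites) %in% hot_idx,
               stringsAsFactors = FALSE)
  })

  truth <- list(
    scenario = "hotspots", seed = seed, n_sites = n_sites,
    n_hotspots = n_hot,
    hotspot_accessions = rec$ACC_ID[rec$hot],
    hotspot_positions = as.integer(sub("-p$", "",
                                       substring(rec$MOD_RSD[rec$hot], 2))),
    hotspot_frequencies = as.integer((rec$MS_LIT + rec$MS_CST)[rec$hot]))

  if (!is.null(path)) {
    blank0 <- function(v) ifelse(v == 0L, "", as.character(v))
    body <- paste(rec$GENE, rec$PROTEIN, rec$ACC_ID, rec$MOD_RSD,
                  rec$ORGANISM, blank0(rec$MS_LIT), blank0(rec$MS_CST),
                  blank0(rec$LT_LIT), sep = "\t")
    lines <- c("Synthetic phosphosite dataset (not real data)",
               "For algorithm testing only.",
               "",
               paste(c("GENE", "PROTEIN", "ACC_ID", "MOD_RSD", "ORGANISM",
                       "MS_LIT", "MS_CST", "LT_LIT"), collapse = "\t"),
               body)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    writeLines(lines, con)
    close(con)
    write_truth(truth, paste0(path, ".truth.json"))
  }
  invisible(list(path = path, records = rec[, setdiff(names(rec), "hot")],
                 truth = truth))
}

#' Generate a site-by-sample log-abundance matrix with planted effects
#'
#' Gaussian log-abundances (site baselines around 20, noise `noise_sd`);
#' sites named in `effect_map` are shifted by their effect in the
#' `altered` group; entries are set missing completely at random at
#' `missing_rate`.
#'
#' @param n_sites number of sites.
#' @param n_per_group samples per group.
#' @param effect_map named numeric vector: site id (`"site<i>"`) -> shift.
#' @param noise_sd within-group standard deviation (default 1).
#' @param missing_rate missing-completely-at-random rate (default 0.1).
#' @param seed integer seed.
#' @param dir if non-`NULL`, write `matrix.csv`, `groups.csv` and
#'   `truth.json` into this directory.
#' @return invisible list: `matrix` (an [abundance_matrix()]), `truth`,
#'   and file paths when `dir` was given.
#' @export
gen_abundance_matrix <- function(n_sites, n_per_group = 8L,
                                 effect_map = numeric(0), noise_sd = 1,
                                 missing_rate = 0.1, seed = 1L, dir = NULL) {
  site_ids <- paste0("site", seq_len(n_sites))
  bad <- setdiff(names(effect_map), site_ids)
  if (length(bad)) abort("effect_map names not in site ids: ",
                         paste(bad, collapse = ", "))
  vals <- with_seed(seed, {
    base <- stats::rnorm(n_sites, mean = 20, sd = 2)
    m <- matrix(stats::rnorm(n_sites * 2L * n_per_group, mean = base,
                             sd = noise_sd),
                nrow = n_sites)
    if (length(effect_map)) {
      idx <- match(names(effect_map), site_ids)
      m[idx, seq_len(n_per_group)] <-
        m[idx, seq_len(n_per_group), drop = FALSE] + effect_map
    }
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- NA_real_
    m
  })
  rownames(vals) <- site_ids
  colnames(vals) <- c(paste0("alt", seq_len(n_per_group)),
                      paste0("wt", seq_len(n_per_group)))
  groups <- rep(c("altered", "wildtype"), each = n_per_group)
  am <- abundance_matrix(vals, groups)
  truth <- list(scenario = "diffphos", seed = seed, n_sites = n_sites,
                n_per_group = n_per_group, noise_sd = noise_sd,
                missing_rate = missing_rate,
                effect_sites = as.list(effect_map))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mp <- file.path(dir, "matrix.csv")
    gp <- file.path(dir, "groups.csv")
    utils::write.csv(data.frame(site_id = site_ids, vals,
                                check.names = FALSE),
                     mp, row.names = FALSE, na = "")
    utils::write.csv(data.frame(sample_id = colnames(vals), group = groups),
                     gp, row.names = FALSE)
    write_truth(truth, file.path(dir, "truth.json"))
    paths <- list(matrix_csv = mp, groups_csv = gp)
  }
  invisible(list(matrix = am, truth = truth, paths = paths))
}

#' Default tiling peptide map for a protein sequence
#'
#' Overlapping peptides of a fixed length tiled along the sequence; a
#' convenient input for [gen_hx_dataset()].
#'
#' @param sequence protein sequence.
#' @param length peptide length (default 10).
#' @param step tiling step (default 5).
#' @param charge precursor charge assigned to every peptide (default 2).
#' @return a `peptide_table`.
#' @export
tile_peptides <- function(sequence, length = 10L, step = 5L, charge = 2L) {
  n <- nchar(sequence)
  starts <- seq(1L, max(1L, n - length + 1L), by = step)
  p <- data.frame(
    peptide_id = sprintf("pep%03d", seq_along(starts)),
    start = starts, end = pmin(starts + length - 1L, n),
    sequence = substring(sequence, starts, pmin(starts + length - 1L, n)),
    charge = charge, rt = NA_real_, stringsAsFactors = FALSE)
  as_peptide_table(p, sequence)
}

# per-residue uptake under Linderstrom-Lang kinetics in the EX2 limit
ll_uptake <- function(k_int, pf, t) 1 - exp(-(k_int / pf) * t)

#' Generate an HX-MS centroid dataset from per-residue exchange kinetics
#'
#' Per-residue uptake follows `u_i(t) = 1 - exp(-(k_int_i / PF_i) t)`.
#' A peptide's deuterated centroid is its undeuterated neutral mass plus
#' `sum(u_i(t)) * d2o_fraction * retention * 1.00628` over its attributed
#' exchangeable residues (positions `start+2..end`, prolines excluded),
#' plus Gaussian centroid noise. Full-D controls carry the same
#' `retention`, so peptide-level back-exchange correction recovers the
#' true uptake fractions.
#'
#' @param sequence protein sequence.
#' @param peptides a `peptide_table` (see [tile_peptides()]).
#' @param variants named list: variant label -> numeric protection-factor
#'   vector (length = protein length, all > 0).
#' @param timepoints exchange timepoints (seconds, > 0).
#' @param d2o_fraction labeling-buffer deuterium fraction (default 0.9,
#'   tenfold dilution into deuterated buffer).
#' @param retention back-exchange retention factor in (0, 1] (default
#'   0.85).
#' @param noise_sd centroid noise standard deviation (Da; default 0).
#' @param k_int intrinsic exchange rate (1/s), a scalar or per-residue
#'   vector (default 1).
#' @param n_replicates replicates per state/timepoint (default 2).
#' @param with_full_d include fully deuterated control spectra
#'   (default TRUE).
#' @param seed integer seed.
#' @param dir if non-`NULL`, write `peptides.csv`, `centroids.csv`,
#'   `protein.fasta` and `truth.json` there.
#' @return invisible list: `centroids` (a `centroid_table`), `peptides`,
#'   `truth`, and `paths` when `dir` was given.
#' @export
gen_hx_dataset <- function(sequence, peptides, variants, timepoints,
                           d2o_fraction = 0.9, retention = 0.85,
                           noise_sd = 0, k_int = 1, n_replicates = 2L,
                           with_full_d = TRUE, seed = 1L, dir = NULL) {
  n <- nchar(sequence)
  aa <- strsplit(sequence, "")[[1L]]
  if (length(k_int) == 1L) k_int <- rep(k_int, n)
  if (length(k_int) != n) abort("'k_int' must be scalar or length(sequence)")
  for (v in names(variants)) {
    pf <- variants[[v]]
    if (length(pf) != n) abort("PF vector for ", v, " must have length ", n)
    if (any(pf <= 0)) abort("protection factors must be > 0")
  }
  if (any(timepoints <= 0)) abort("timepoints must be > 0")
  if (retention <= 0 || retention > 1) abort("'retention' must be in (0, 1]")

  # residues whose label is attributed to each peptide
  attributed <- lapply(seq_len(nrow(peptides)), function(i) {
    lo <- peptides$start[i] + 2L; hi <- peptides$end[i]
    if (lo > hi) return(integer(0))
    r <- lo:hi
    r[aa[r] != "P"]
  })
  undeut <- vapply(peptides$sequence, peptide_neutral_mass, numeric(1))

  rows <- list()
  add <- function(pid, var, state, tp, rep_, mass, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      peptide_id = pid, variant = var, state = state, timepoint_s = tp,
      replicate = rep_, centroid_mz = (mass + z * MASS_PROTON) / z,
      charge = z, stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    for (i in seq_len(nrow(peptides))) {
      pid <- peptides$peptide_id[i]; z <- peptides$charge[i]
      res <- attributed[[i]]
      for (v in names(variants)) {
        pf <- variants[[v]]
        for (r in seq_len(n_replicates))
          add(pid, v, "undeuterated", 0, r,
              undeut[i] + stats::rnorm(1, 0, noise_sd), z)
        for (tp in timepoints) {
          shift <- sum(ll_uptake(k_int[res], pf[res], tp)) *
            d2o_fraction * retention * MASS_D_INCREMENT
          for (r in seq_len(n_replicates))
            add(pid, v, "deuterated", tp, r,
                undeut[i] + shift + stats::rnorm(1, 0, noise_sd), z)
        }
        if (with_full_d) {
          fshift <- length(res) * d2o_fraction * retention * MASS_D_INCREMENT
          for (r in seq_len(n_replicates))
            add(pid, v, "fully_deuterated", -1, r,
                undeut[i] + fshift + stats::rnorm(1, 0, noise_sd), z)
        }
      }
    }
  })
  cen <- do.call(rbind, rows)
  cen$centroid_mass <- (cen$centroid_mz - MASS_PROTON) * cen$charge
  cen <- as_centroid_table(cen)

  truth <- list(
    scenario = "hxms", seed = seed, protein_length = n,
    variants = lapply(variants, as.numeric), k_int = as.numeric(k_int),
    timepoints = as.numeric(timepoints), d2o_fraction = d2o_fraction,
    retention = retention, noise_sd = noise_sd,
    n_replicates = n_replicates, with_full_d = with_full_d)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pp <- file.path(dir, "peptides.csv")
    cp <- file.path(dir, "centroids.csv")
    fp <- file.path(dir, "protein.fasta")
    utils::write.csv(as.data.frame(peptides), pp, row.names = FALSE)
    utils::write.csv(
      as.data.frame(cen)[, c("peptide_id", "variant", "state",
                             "timepoint_s", "replicate", "centroid_mz",
                             "charge")],
      cp, row.names = FALSE)
    write_protein_fasta(sequence, fp, "synthetic-protein")
    write_truth(truth, file.path(dir, "truth.json"))
    paths <- list(peptides_csv = pp, centroids_csv = cp, fasta = fp)
  }
  invisible(list(centroids = cen, peptides = peptides, truth = truth,
                 paths = paths))
}

#' Generate Michaelis-Menten kinetics measurements
#'
#' Mean curve `y = vmax x / (km + x)` with multiplicative Gaussian noise
#' of fractional standard deviation `noise_frac`.
#'
#' @param vmax,km true parameters (rate units, uM).
#' @param e_conc enzyme concentration (uM).
#' @param x_grid substrate concentrations (uM).
#' @param noise_frac fractional noise (default 0).
#' @param n_replicates replicates per concentration (default 3).
#' @param seed integer seed.
#' @return list: `data` (data frame `substrate`, `rate`, `replicate`),
#'   `truth`.
#' @export
gen_kinetics <- function(vmax, km, e_conc, x_grid, noise_frac = 0,
                         n_replicates = 3L, seed = 1L) {
  mu <- vmax * x_grid / (km + x_grid)
  dat <- with_seed(seed, {
    data.frame(
      substrate = rep(x_grid, each = n_replicates),
      rate = rep(mu, each = n_replicates) *
        (1 + stats::rnorm(length(x_grid) * n_replicates, 0, noise_frac)),
      replicate = rep(seq_len(n_replicates), times = length(x_grid)))
  })
  list(data = dat,
       truth = list(scenario = "kinetics", seed = seed, vmax = vmax,
                    km = km, e_conc = e_conc, kcat = vmax / e_conc,
                    noise_frac = noise_frac))
}

#' Generate 4PL inhibition (dose-response) measurements
#'
#' @param ic50,hill,top,bottom true 4PL parameters.
#' @param dose_grid doses (uM, > 0).
#' @param noise_frac fractional noise on the response (default 0).
#' @param n_replicates replicates per dose (default 3).
#' @param seed integer seed.
#' @return list: `data` (`dose`, `response`, `replicate`), `truth`.
#' @export
gen_inhibition <- function(ic50, hill, top, bottom, dose_grid,
                           noise_frac = 0, n_replicates = 3L, seed = 1L) {
  mu <- bottom + (top - bottom) / (1 + (dose_grid / ic50)^hill)
  dat <- with_seed(seed, {
    data.frame(
      dose = rep(dose_grid, each = n_replicates),
      response = rep(mu, each = n_replicates) *
        (1 + stats::rnorm(length(dose_grid) * n_replicates, 0, noise_frac)),
      replicate = rep(seq_len(n_replicates), times = length(dose_grid)))
  })
  list(data = dat,
       truth = list(scenario = "inhibition", seed = seed, ic50 = ic50,
                    hill = hill, top = top, bottom = bottom,
                    noise_frac = noise_frac))
}

#' Generate a two-state DSF melt trace
#'
#' Sigmoid `F(T) = baseline + amplitude / (1 + exp(-(T - tm) / slope))`
#' whose inflection point is exactly `tm`, plus Gaussian noise with
#' standard deviation `noise_frac * amplitude`.
#'
#' @param tm melting temperature (deg C).
#' @param slope transition width parameter (deg C, default 1.5).
#' @param amplitude transition amplitude (default 1000).
#' @param baseline pre-transition level (default 100).
#' @param grid temperature grid (default `seq(25, 99, by = 0.1)`).
#' @param noise_frac noise sd as a fraction of amplitude (default 0).
#' @param seed integer seed.
#' @return list: `data` (`temperature`, `fluorescence`), `truth`.
#' @export
gen_melt <- function(tm, slope = 1.5, amplitude = 1000, baseline = 100,
                     grid = seq(25, 99, by = 0.1), noise_frac = 0,
                     seed = 1L) {
  mu <- baseline + amplitude / (1 + exp(-(grid - tm) / slope))
  y <- with_seed(seed,
                 mu + stats::rnorm(length(grid), 0, noise_frac * amplitude))
  list(data = data.frame(temperature = grid, fluorescence = y),
       truth = list(scenario = "melt", seed = seed, tm = tm, slope = slope,
                    amplitude = amplitude, baseline = baseline,
                    noise_frac = noise_frac))
}

# random proper rotation via QR decomposition with sign fix
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Generate a pair of rigidly related synthetic structures
#'
#' Model A is a random non-degenerate C-alpha trace (3.8 A steps); model B
#' is a rigid transform of A plus optional isotropic per-residue Gaussian
#' displacements (expected RMSD `displacement_sd * sqrt(3)`).
#'
#' @param n_residues number of residues (>= 3 for a non-degenerate pair).
#' @param displacement_sd per-coordinate displacement sd (A, default 0).
#' @param seed integer seed.
#' @param dir if non-`NULL`, write `model_a.pdb`, `model_b.pdb`,
#'   `truth.json` there.
#' @return invisible list: `model_a`, `model_b` (`structure_model`s),
#'   `truth` (incl. the rotation and translation used), `paths`.
#' @export
gen_structure_pair <- function(n_residues, displacement_sd = 0, seed = 1L,
                               dir = NULL) {
  if (n_residues < 1L) abort("'n_residues' must be >= 1")
  out <- with_seed(seed, {
    step <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
    step <- step / pmax(sqrt(rowSums(step^2)), 1e-12) * 3.8
    xyz_a <- apply(step, 2, cumsum)
    if (n_residues == 1L) xyz_a <- matrix(xyz_a, 1, 3)
    rot <- random_rotation()
    trans <- stats::rnorm(3, 0, 20)
    xyz_b <- xyz_a %*% t(rot) + matrix(trans, n_residues, 3, byrow = TRUE)
    if (displacement_sd > 0)
      xyz_b <- xyz_b + matrix(stats::rnorm(3 * n_residues, 0,
                                           displacement_sd),
                              ncol = 3)
    list(xyz_a = xyz_a, xyz_b = xyz_b, rot = rot, trans = trans)
  })
  mk_model <- function(xyz, label) {
    m <- data.frame(
      chain = "A", resseq = seq_len(n_residues), icode = " ",
      resname = "ALA", atom = "CA", altloc = " ",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      occupancy = 1, bfactor = 0, stringsAsFactors = FALSE)
    class(m) <- c("structure_model", "data.frame")
    attr(m, "label") <- label
    m
  }
  a <- mk_model(out$xyz_a, "synthetic-A")
  b <- mk_model(out$xyz_b, "synthetic-B")
  truth <- list(scenario = "structures", seed = seed,
                n_residues = n_residues,
                rotation = out$rot, translation = out$trans,
                displacement_sd = displacement_sd,
                expected_rmsd = displacement_sd * sqrt(3))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pa <- file.path(dir, "model_a.pdb"); pb <- file.path(dir, "model_b.pdb")
    write_structure(a, pa); write_structure(b, pb)
    write_truth(truth, file.path(dir, "truth.json"))
    paths <- list(model_a = pa, model_b = pb)
  }
  invisible(list(model_a = a, model_b = b, truth = truth, paths = paths))
}
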