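test_that("exchangeable_count follows the HX convention", {
  expect_equal(exchangeable_count("GLSA"), 2L)    # 4 - 2, no prolines
  expect_equal(exchangeable_count("GAPAG"), 2L)   # 5 - 2 - 1 (P at pos 3)
  expect_equal(exchangeable_count("GG"), 0L)      # floored
  expect_equal(exchangeable_count("PPGLS"), 3L)   # leading prolines free
  expect_error(exchangeable_count("GLXZ"), "non-standard")
})

test_that("peptide filters retain/reject by length and charge with a log", {
  p <- as_pep <- data.frame(
    peptide_id = c("ok3", "long16", "z4", "ok15"),
    start = c(1, 1, 1, 1),
    end = c(3, 16, 5, 15),
    sequence = c("GLS", paste(rep("A", 16), collapse = ""), "GLSAV",
                 paste(rep("L", 15), collapse = "")),
    charge = c(3, 2, 4, 1), rt = NA_real_, stringsAsFactors = FALSE)
  class(p) <- c("peptide_table", "data.frame")
  flt <- apply_peptide_filters(p, hx_filter_config())
  expect_setequal(flt$retained$peptide_id, c("ok3", "ok15"))
  expect_equal(flt$rejections$rule[flt$rejections$peptide_id == "long16"],
               "length")
  expect_equal(flt$rejections$rule[flt$rejections$peptide_id == "z4"],
               "charge")
  expect_error(hx_filter_config(min_length = 10, max_length = 3))
})

test_that("max_labeling pools full-D shifts or falls back to theory", {
  cen <- data.frame(
    peptide_id = "p1",
    variant = c("WT", "WT", "WT", "WT", "Y62D", "Y62D"),
    state = c("undeuterated", "fully_deuterated", "fully_deuterated",
              "deuterated", "undeuterated", "fully_deuterated"),
    timepoint_s = c(0, -1, -1, 60, 0, -1),
    replicate = c(1, 1, 2, 1, 1, 1),
    centroid_mass = c(800, 803.0, 803.2, 801.5, 800.4, 803.5),
    stringsAsFactors = FALSE)
  cen <- phoshx:::as_centroid_table(cen)
  # mean over replicates AND variants of (fullD - that variant's undeut)
  expect_equal(max_labeling("p1", cen), mean(c(3.0, 3.2, 3.1)))

  # no full-D spectra -> theoretical maximum
  cen2 <- cen[cen$state != "fully_deuterated", ]
  class(cen2) <- class(cen)
  seq7 <- "GLSAVKE"                               # 5 exchangeable
  expect_equal(max_labeling("p1", cen2, d2o_fraction = 0.9,
                            sequence = seq7),
               5 * 0.9 * 1.00628)

  # full-D below undeuterated -> error
  cen3 <- cen
  cen3$centroid_mass[cen3$state == "fully_deuterated"] <- 799
  class(cen3) <- class(cen)
  expect_error(max_labeling("p1", cen3), "below undeuterated")
})

test_that("uptake_fraction is the back-exchange-corrected centroid shift", {
  cen <- phoshx:::as_centroid_table(data.frame(
    peptide_id = "p1", variant = "WT",
    state = c("undeuterated", "undeuterated", "deuterated", "deuterated"),
    timepoint_s = c(0, 0, 60, 60), replicate = c(1, 2, 1, 2),
    centroid_mass = c(799.9, 800.1, 801.9, 802.1),
    stringsAsFactors = FALSE))
  u <- uptake_fraction("p1", "WT", 60, cen, max_labeling = 4.0)
  expect_equal(u$fraction_of_max, 0.5)
  expect_equal(u$n_replicates, 2L)
  expect_false(u$out_of_range)
  # deut centroid equal to undeut -> 0; equal to undeut + max -> 1
  cen$centroid_mass[3:4] <- c(799.9, 800.1)
  u0 <- uptake_fraction("p1", "WT", 60, cen, 4.0)
  expect_equal(u0$fraction_of_max, 0)
  cen$centroid_mass[3:4] <- c(803.9, 804.1)
  u1 <- uptake_fraction("p1", "WT", 60, cen, 4.0)
  expect_equal(u1$fraction_of_max, 1)

  # unknown variant: no deuterated replicates to use
  expect_error(uptake_fraction("p1", "MUT", 60, cen, 4.0), "replicates")
  # deuterated data present but undeuterated reference missing
  cen_no_u <- cen[cen$state != "undeuterated", ]
  class(cen_no_u) <- class(cen)
  expect_error(uptake_fraction("p1", "WT", 60, cen_no_u, 4.0),
               "undeuterated")
})

test_that("build_coverage applies the start+2 convention", {
  p <- data.frame(peptide_id = c("a", "b"), start = c(10, 15),
                  end = c(19, 24),
                  sequence = c("AAAAAAAAAA", "AAAAAAAAAA"),
                  charge = 2, rt = NA_real_, stringsAsFactors = FALSE)
  class(p) <- c("peptide_table", "data.frame")
  cov <- build_coverage(p, protein_length = 30)
  expect_setequal(names(cov), as.character(c(12:19, 17:24)))
  expect_setequal(cov[["17"]], c("a", "b"))
  expect_false("1" %in% names(cov))
  expect_error(build_coverage(p, protein_length = 20), "exceed")
})

test_that("pseudo_residue_dD averages peptides then timepoints", {
  mk_upt <- function(var, fracs) {
    # fracs: named list peptide -> per-timepoint fractions (t = 60, 600)
    do.call(rbind, lapply(names(fracs), function(pid)
      data.frame(peptide_id = pid, variant = var, timepoint = c(60, 600),
                 fraction_of_max = fracs[[pid]], replicate_sd = NA,
                 n_replicates = 2, out_of_range = FALSE)))
  }
  cov <- list(`12` = c("a"), `13` = c("a", "b"))

  # one covering peptide: 60% vs 40% at both timepoints -> +20 points
  uv <- mk_upt("VAR", list(a = c(0.6, 0.6), b = c(0.7, 0.7)))
  ur <- mk_upt("WT", list(a = c(0.4, 0.4), b = c(0.6, 0.6)))
  map <- pseudo_residue_dD(uv, ur, cov)
  expect_equal(map$dD[map$residue == 12], 20)
  # two peptides: means (0.65 vs 0.5) -> +15 points; coverage count 2
  expect_equal(map$dD[map$residue == 13], 15)
  expect_equal(map$coverage_count[map$residue == 13], 2L)

  # identical datasets -> 0 everywhere
  map0 <- pseudo_residue_dD(mk_upt("A", list(a = c(0.3, 0.5))),
                            mk_upt("B", list(a = c(0.3, 0.5))),
                            list(`12` = "a"))
  expect_equal(map0$dD, 0)

  expect_error(pseudo_residue_dD(uv, ur, cov, timepoints = 999),
               "timepoints")
})

test_that("noiseless generator round-trips through uptake_fraction", {
  seq_ <- hx_test_sequence(60)
  peps <- tile_peptides(seq_, length = 10, step = 6)
  pf <- rep(300, 60)
  gen <- gen_hx_dataset(seq_, peps, list(WT = pf),
                        timepoints = c(30, 300), retention = 0.8,
                        noise_sd = 0, seed = 1)
  upt <- uptake_table(peps, gen$centroids)
  aa <- strsplit(seq_, "")[[1]]
  for (i in seq_len(nrow(upt))) {
    p <- peps[peps$peptide_id == upt$peptide_id[i], ]
    res <- (p$start + 2):p$end
    res <- res[aa[res] != "P"]
    truth <- mean(1 - exp(-(1 / 300) * upt$timepoint[i]))
    expect_equal(upt$fraction_of_max[i], truth, tolerance = 1e-9)
  }
})

test_that("back-exchange retention cancels when full-D shares it", {
  seq_ <- hx_test_sequence(40)
  peps <- tile_peptides(seq_, length = 8, step = 5)
  pf <- rep(100, 40)
  u <- lapply(c(1.0, 0.6), function(r) {
    g <- gen_hx_dataset(seq_, peps, list(WT = pf), timepoints = c(20, 200),
                        retention = r, noise_sd = 0, seed = 2)
    uptake_table(peps, g$centroids)$fraction_of_max
  })
  expect_equal(u[[1]], u[[2]], tolerance = 1e-9)
})

test_that("identical variants give dD-bar = 0 at machine precision", {
  seq_ <- hx_test_sequence(50)
  peps <- tile_peptides(seq_, length = 10, step = 5)
  pf <- rep(200, 50)
  g <- gen_hx_dataset(seq_, peps, list(WT = pf, TWIN = pf),
                      timepoints = c(15, 150, 1500), noise_sd = 0, seed = 3)
  map <- hx_residue_map(peps, g$centroids, "WT", "TWIN", 50)
  expect_true(all(abs(map$dD) < 1e-9))
})

test_that("pseudo_residue_dD matches the brute-force oracle on random data", {
  # smoke version; the 50-dataset acceptance criterion runs in
  # test-acceptance.R
  set.seed(44)
  for (k in 1:10) {
    n <- sample(30:60, 1)
    seq_ <- hx_test_sequence(n)
    peps <- tile_peptides(seq_, length = sample(6:12, 1),
                          step = sample(3:6, 1))
    pf_wt <- exp(runif(n, log(10), log(5000)))
    pf_v <- pf_wt * exp(rnorm(n, 0, 1))
    g <- gen_hx_dataset(seq_, peps, list(WT = pf_wt, V = pf_v),
                        timepoints = sort(sample(c(10, 60, 300, 1800), 2)),
                        noise_sd = 0.02, seed = 1000 + k)
    upt <- uptake_table(peps, g$centroids)
    cov <- build_coverage(peps, n)
    uv <- upt[upt$variant == "V", ]
    ur <- upt[upt$variant == "WT", ]
    map <- pseudo_residue_dD(uv, ur, cov)
    oracle <- brute_force_dD(uv, ur, cov)
    expect_equal(map$residue, as.integer(names(oracle)))
    expect_equal(map$dD, unname(unlist(oracle)), tolerance = 1e-10)
  }
})

test_that("a planted protection change localizes with the right sign", {
  # single-replicate smoke check; the 100-seed >= 95% acceptance criterion
  # runs in test-acceptance.R
  seq_ <- hx_test_sequence(100)
  peps <- tile_peptides(seq_, length = 10, step = 4)
  pf_wt <- rep(2000, 100)
  pf_v <- pf_wt
  pf_v[60:70] <- pf_v[60:70] / 10          # less protected -> more uptake
  g <- gen_hx_dataset(seq_, peps, list(WT = pf_wt, V = pf_v),
                      timepoints = c(60, 600, 3600), noise_sd = 0.05,
                      seed = 5001)
  map <- hx_residue_map(peps, g$centroids, "WT", "V", 100)
  peak <- map$residue[which.max(abs(map$dD))]
  expect_true(peak >= 58 && peak <= 72)
  expect_gt(map$dD[map$residue == peak], 0)
})

test_that("readers round-trip generated files without warnings", {
  seq_ <- hx_test_sequence(40)
  peps <- tile_peptides(seq_, length = 8, step = 6)
  dir <- tempfile()
  g <- gen_hx_dataset(seq_, peps, list(WT = rep(100, 40)),
                      timepoints = 60, noise_sd = 0, seed = 4, dir = dir)
  expect_no_warning({
    seq_in <- read_protein_fasta(g$paths$fasta)
    peps_in <- read_peptides(g$paths$peptides_csv, seq_in)
    cen_in <- read_centroids(g$paths$centroids_csv)
  })
  expect_equal(seq_in, seq_)
  expect_equal(peps_in$sequence, peps$sequence)
  expect_equal(cen_in$centroid_mass, g$centroids$centroid_mass,
               tolerance = 1e-9)
})

test_that("export_residue_map writes CSV and paints PDB B-factors", {
  map <- structure(
    data.frame(residue = c(2L, 3L, 99L), dD = c(12.34, -5.6, 1),
               coverage_count = c(1L, 2L, 1L)),
    class = c("residue_uptake_map", "data.frame"))
  csv <- tempfile(fileext = ".csv")
  export_residue_map(map, csv, "csv")
  expect_equal(nrow(read.csv(csv)), 3L)

  pdb <- write_pdb_fixture()
  out <- tempfile(fileext = ".pdb")
  expect_warning(export_residue_map(map, out, "pdb", pdb_path = pdb), "99")
  painted <- read_structure(out)
  ca2 <- painted[painted$atom == "CA" & painted$resseq == 2, ]
  expect_equal(ca2$bfactor, 12.34, tolerance = 1e-8)
  # uncovered residue gets the sentinel
  ca4 <- painted[painted$atom == "CA" & painted$resseq == 4, ]
  expect_equal(ca4$bfactor, -99.0)
  # round-trip: B-factors re-read identically (2 decimals)
  ca3 <- painted[painted$atom == "CA" & painted$resseq == 3, ]
  expect_equal(ca3$bfactor, -5.6)
})
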