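# CSV/YAML/JSON interchange and the end-to-end runner.
#
# CSV is the lone interchange format; unit-bearing columns embed their unit
# in the name (temperature_C, ligand_conc_uM, sat_time_s, wavenumber_cm1,
# ppm) so unit mistakes fail loudly at the schema check.

#' @importFrom utils read.csv write.csv packageVersion
NULL

.checkColumns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  .stopif(length(miss) > 0,
          sprintf("%s: missing column(s) %s", what,
                  paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Read DSF melt curves from long-format CSV
#'
#' Expected columns: \code{well}, \code{compound}, \code{replicate},
#' \code{temperature_C}, \code{fluorescence}. Each well's temperatures must
#' be strictly increasing.
#'
#' @param path CSV file.
#' @return list of \linkS4class{MeltCurve}.
#' @export
readMeltCurves <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("well", "compound", "replicate", "temperature_C",
                      "fluorescence"), basename(path))
  lapply(split(df, df$well), function(sub) {
    .checkStrictlyIncreasing(sub$temperature_C,
                             sprintf("well %s: temperature_C", sub$well[1]))
    MeltCurve(sub$temperature_C, sub$fluorescence, wellId = sub$well[1],
              compoundId = sub$compound[1],
              replicateIndex = sub$replicate[1])
  })
}

#' Write DSF melt curves to long-format CSV
#' @param curves list of \linkS4class{MeltCurve}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeMeltCurves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(well = cu@wellId, compound = cu@compoundId,
               replicate = cu@replicateIndex,
               temperature_C = cu@temperature,
               fluorescence = cu@fluorescence, stringsAsFactors = FALSE)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an STD integral table from CSV
#'
#' Expected columns: \code{epitope}, \code{ligand_conc_uM},
#' \code{sat_time_s}, \code{i_diff}, \code{i_ref}.
#'
#' @param path CSV file.
#' @param proteinConc protein concentration (uM); required, no default.
#' @return an \linkS4class{STDDataset}.
#' @export
readStdDataset <- function(path, proteinConc) {
  .stopif(missing(proteinConc), "proteinConc (uM) is a required input")
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("epitope", "ligand_conc_uM", "sat_time_s", "i_diff",
                      "i_ref"), basename(path))
  STDDataset(df, proteinConc = proteinConc)
}

#' Write an STD integral table to CSV
#' @param dataset an \linkS4class{STDDataset}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeStdDataset <- function(dataset, path) {
  write.csv(dataset@records[, c("epitope", "ligand_conc_uM", "sat_time_s",
                                "i_diff", "i_ref")], path, row.names = FALSE)
  invisible(path)
}

#' Read a 1D spectrum (ppm, intensity) from CSV
#' @param path CSV file with columns \code{ppm}, \code{intensity}.
#' @return data.frame with \code{ppm} and \code{intensity}.
#' @export
readSpectrum <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("ppm", "intensity"), basename(path))
  df
}

#' Read an IR thermal-ramp matrix from wide CSV
#'
#' First column \code{wavenumber_cm1}; each remaining column one ramp
#' temperature, header the temperature in degC (an optional leading
#' \code{T} or \code{X} prefix is tolerated).
#'
#' @param path CSV file.
#' @param sample,ligandId,ligandConc series metadata.
#' @return an \linkS4class{IRSpectrumSeries}.
#' @export
readIRSeries <- function(path, sample = basename(path),
                         ligandId = NA_character_, ligandConc = NA_real_) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .checkColumns(df, "wavenumber_cm1", basename(path))
  wn <- df$wavenumber_cm1
  .checkStrictlyIncreasing(wn, "wavenumber_cm1")
  tcols <- setdiff(names(df), "wavenumber_cm1")
  tt <- suppressWarnings(as.numeric(sub("^[TX]", "", tcols)))
  .stopif(anyNA(tt), sprintf("non-numeric temperature header(s): %s",
                             paste(tcols[is.na(tt)], collapse = ", ")))
  o <- order(tt)
  IRSpectrumSeries(wn, tt[o], as.matrix(df[, tcols[o], drop = FALSE]),
                   sample = sample, ligandId = ligandId,
                   ligandConc = ligandConc)
}

#' Write an IR thermal-ramp matrix to wide CSV
#' @param series an \linkS4class{IRSpectrumSeries}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeIRSeries <- function(series, path) {
  mat <- absorbance(series)
  df <- data.frame(wavenumber_cm1 = wavenumbers(series), mat,
                   check.names = FALSE)
  names(df)[-1] <- format(temperatures(series), trim = TRUE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a band model from YAML
#'
#' Expected structure: a \code{bands} list of mappings with \code{label},
#' \code{class}, \code{center}, and optionally \code{center_tol},
#' \code{width}, \code{width_lo}, \code{width_hi} (defaults 2, 6, 3, 12).
#'
#' @param path YAML file.
#' @return a \linkS4class{BandModel}.
#' @export
readBandModel <- function(path) {
  spec <- yaml::read_yaml(path)
  .stopif(is.null(spec$bands), "band YAML must contain a 'bands' list")
  rows <- lapply(spec$bands, function(b) {
    data.frame(label = b$label, class = b$class, center = b$center,
               center_tol = b$center_tol %||% 2,
               width = b$width %||% 6,
               width_lo = b$width_lo %||% 3,
               width_hi = b$width_hi %||% 12, stringsAsFactors = FALSE)
  })
  BandModel(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hit table to CSV
#' @param hits a \linkS4class{HitTable}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  write.csv(hitCalls(hits), path, row.names = FALSE)
  invisible(path)
}

# stable md5 of a config list via its canonical JSON serialization
.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the demo pipeline end to end on the packaged fixtures
#'
#' Executes the requested stages in campaign order — DSF screen with hit
#' calling, STD Kd estimation for the three characterized ligands, and the
#' apo-vs-bound MMS thermal ramp — entirely from the packaged synthetic
#' fixtures, and writes a JSON run report plus stage CSVs. All randomness
#' flows from the single \code{seed}; identical configs yield identical
#' report bodies.
#'
#' @param config list with optional elements \code{seed} (integer, default
#'   1), \code{stages} (subset of \code{c("dsf","std","mms")}),
#'   \code{std_noise_cv}, \code{dsf_noise_sd}, \code{out} (output
#'   directory). A YAML file path is also accepted.
#' @return the run report, invisibly (a list; also written as
#'   \code{report.json} when \code{out} is set).
#' @export
runEndToEnd <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("dsf", "std", "mms")
  out <- config$out
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  cfg <- list(seed = seed, stages = stages,
              std_noise_cv = config$std_noise_cv %||% 0.03,
              dsf_noise_sd = config$dsf_noise_sd)
  report <- list(package_version = as.character(packageVersion("stabscreen")),
                 config = cfg, config_hash = .configHash(cfg), stages = list())

  if ("dsf" %in% stages) {
    scr <- simulateScreen(screenFixture(seed = seed),
                          curveParams = dsfFixture("control",
                                                   noiseSd = cfg$dsf_noise_sd))
    hits <- callHits(fitScreen(scr$curves), controlId = "DMSO")
    report$stages$dsf <- list(
      threshold_C = hits@threshold, control_mean_C = hits@controlMean,
      compound_tm_sd_C = hits@tmSd, n_compounds = nrow(hitCalls(hits)),
      n_hits = sum(hitCalls(hits)$hit),
      n_discarded = sum(!is.na(hitCalls(hits)$discard_reason)))
    if (!is.null(out)) writeHitTable(hits, file.path(out, "hits.csv"))
  }
  if ("std" %in% stages) {
    kds <- lapply(c("KG-96", "KG-408", "KG-484"), function(nm) {
      ds <- simulateStdDataset(stdFixture(nm), noiseCv = cfg$std_noise_cv,
                               seed = .subSeed(seed, nm))
      est <- runStdPipeline(ds)
      if (!is.null(out))
        writeStdDataset(ds, file.path(out, sprintf("std_%s.csv", nm)))
      list(ligand = nm, kd_uM = est@kdCombined, kd_se_uM = est@kdCombinedSe,
           per_epitope = lapply(est@perEpitope, function(f)
             list(epitope = f@epitope, kd_uM = f@kd, kd_se_uM = f@kdSe)))
    })
    report$stages$std <- kds
  }
  if ("mms" %in% stages) {
    apo <- runMmsPipeline(simulateIRSeries(irFixture("apo"),
                                           seed = .subSeed(seed, "apo"),
                                           sample = "apo"))
    bound <- runMmsPipeline(simulateIRSeries(irFixture("bound"),
                                             seed = .subSeed(seed, "bound"),
                                             sample = "bound",
                                             ligandId = "KG-408",
                                             ligandConc = 1000))
    tmA <- meltTm(apo$thermal); tmB <- meltTm(bound$thermal)
    shared <- intersect(names(tmA), names(tmB))
    report$stages$mms <- list(
      apo_tm_C = as.list(tmA), bound_tm_C = as.list(tmB),
      delta_tm_C = as.list(tmB[shared] - tmA[shared]))
    if (!is.null(out)) {
      write.csv(apo$fractions, file.path(out, "mms_apo_fractions.csv"),
                row.names = FALSE)
      write.csv(bound$fractions, file.path(out, "mms_bound_fractions.csv"),
                row.names = FALSE)
    }
  }
  if (!is.null(out)) {
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, na = "null")
    writeLines(json, file.path(out, "report.json"))
  }
  invisible(report)
}
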