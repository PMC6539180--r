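# Pipeline orchestration: reproducible subcommands over a single config,
# with a run manifest recording the config fingerprint and seed. Identical
# config + seed produce byte-identical outputs.

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML config schema. Sections: \code{simulate}
#' (trial design, timepoints, scene parameters), \code{extract} (canopy
#' threshold, VI soil-mask flag, NIRv variant), \code{model} (features, ADD
#' at which to fit, split/fold settings), \code{traits} (lodging timepoint
#' pair) and \code{qc} (GCP displacement SDs).
#'
#' @return a named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    simulate = list(
      n_entries = 20, n_reps = 3, plot_width = 1.5, plot_length = 5.0,
      alley = 0.5, timepoints = c(365, 784, 1268, 1725, 1948),
      gsd = 0.05, noise_sd = 0.01, elev_noise_sd = 0.005,
      lodging_fraction = 0.15),
    extract = list(canopy_threshold = 0.15, vi_mask = TRUE,
                   nirv_variant = "paper"),
    model = list(fit_add = 1268,
                 feature_names = c("GRVI_sum", "NDVI_sum", "NDRE_sum", "CC",
                                   "PV"),
                 train_frac = 0.85, folds = 5),
    traits = list(lodging_add1 = 1268, lodging_addk = 1725,
                  include_cc = TRUE),
    qc = list(n_gcps = 10, horizontal_sd = 0.02, vertical_sd = 0.03))
}

.mergeConfig <- function(def, usr) {
  for (nm in names(usr)) {
    if (is.list(def[[nm]]) && is.list(usr[[nm]]))
      def[[nm]] <- .mergeConfig(def[[nm]], usr[[nm]])
    else def[[nm]] <- usr[[nm]]
  }
  def
}

#' Read and validate a pipeline config
#'
#' Reads a YAML config, overlays it on \code{\link{defaultPipelineConfig}},
#' and validates ranges (naming the offending field).
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return validated config list with attribute \code{fingerprint}.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  txt <- ""
  if (!is.null(path)) {
    txt <- readLines(path)
    cfg <- .mergeConfig(cfg, yaml::yaml.load(paste(txt, collapse = "\n")))
  }
  tf <- cfg$model$train_frac
  if (!is.numeric(tf) || tf <= 0 || tf >= 1)
    stop("invalid config: train_frac must lie in (0, 1); got ", tf)
  if (cfg$extract$canopy_threshold < 0)
    stop("invalid config: canopy_threshold must be >= 0")
  if (cfg$simulate$gsd <= 0)
    stop("invalid config: gsd must be > 0")
  attr(cfg, "fingerprint") <- textFingerprint(c(txt, ""))
  cfg
}

.writeManifest <- function(outDir, subcommand, cfg, seed, files) {
  jsonlite::write_json(list(
    tool = "uasPheno", version = as.character(utils::packageVersion("uasPheno")),
    subcommand = subcommand, seed = seed,
    config_fingerprint = attr(cfg, "fingerprint"),
    files = files), file.path(outDir, paste0("manifest_", subcommand, ".json")),
    auto_unbox = TRUE, pretty = TRUE)
}

.truthSchema <- list(
  required = c("plot_id", "entry", "add", "height_m", "cover", "agbm"),
  numeric = c("replicate", "add", "height_m", "cover", "agbm",
              "lodging_ratio", "refl_B", "refl_G", "refl_R", "refl_RE",
              "refl_NIR", "soil_B", "soil_G", "soil_R", "soil_RE",
              "soil_NIR"),
  logical = "lodged")

.featureSchema <- list(
  required = c("plot_id", "add", "GRVI_sum", "NDVI_sum", "NDRE_sum",
               "CH_uas", "CC", "PV"),
  numeric = c("add", "GRVI_sum", "GRVI_mean", "NDVI_sum", "NDVI_mean",
              "NDRE_sum", "NDRE_mean", "NIRv", "CH_uas", "CC", "PV",
              "G_mean", "n_vi_pixels"))

#' Run a pipeline stage
#'
#' Subcommands: \code{"simulate"} renders a synthetic trial (layout GeoJSON,
#' truth CSV, per-timepoint band stacks and DSMs, GCP and transect tables);
#' \code{"extract"} radiometrically corrects the stacks, builds DTM/CSM and
#' writes the feature table and a trait correlation report;
#' \code{"qc"} writes HPE/VPE georeferencing metrics; \code{"traits"} writes
#' lodging scores and the leaf-type classifier; \code{"model"} fits the
#' Lasso AGBM model at the configured ADD and writes the model JSON and
#' entry-level predictions. Each stage writes a manifest with the config
#' fingerprint and seed; outputs are deterministic functions of both.
#'
#' @param subcommand one of "simulate", "extract", "qc", "traits", "model".
#' @param config a config list from \code{\link{readPipelineConfig}}, a YAML
#'   path, or NULL for defaults.
#' @param outDir run directory (created if needed; stages share it).
#' @param seed integer seed.
#' @return invisibly, a list of the files written (and stage summaries).
#' @export
runPipeline <- function(subcommand, config = NULL, outDir, seed = 1) {
  if (!subcommand %in% c("simulate", "extract", "qc", "traits", "model"))
    stop("unknown subcommand '", subcommand, "'")
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else if (is.null(config)) readPipelineConfig(NULL)
         else config
  if (is.null(attr(cfg, "fingerprint")))
    attr(cfg, "fingerprint") <- textFingerprint("in-memory-config")
  for (d in c("", "rasters", "tables", "models"))
    dir.create(file.path(outDir, d), showWarnings = FALSE, recursive = TRUE)
  res <- switch(subcommand,
                simulate = .stageSimulate(cfg, outDir, seed),
                extract = .stageExtract(cfg, outDir, seed),
                qc = .stageQc(cfg, outDir, seed),
                traits = .stageTraits(cfg, outDir, seed),
                model = .stageModel(cfg, outDir, seed))
  .writeManifest(outDir, subcommand, cfg, seed, res$files)
  invisible(res)
}

.stageSimulate <- function(cfg, outDir, seed) {
  sc <- cfg$simulate
  layout <- generateTrialLayout(sc$n_entries, sc$n_reps, sc$plot_width,
                                sc$plot_length, sc$alley, seed = seed)
  truth <- generateTruth(layout, sc$timepoints,
                         lodgingFraction = sc$lodging_fraction, seed = seed)
  spec <- SceneSpec(gsd = sc$gsd, noiseSd = sc$noise_sd,
                    elevNoiseSd = sc$elev_noise_sd)
  files <- character(0)
  panel <- NULL
  for (tp in sc$timepoints) {
    scene <- renderScene(truth, layout, spec, tp, seed = seed)
    panel <- scene$panel
    sp <- file.path(outDir, "rasters", sprintf("stack_%d.json", tp))
    dp <- file.path(outDir, "rasters", sprintf("dsm_%d.asc", tp))
    writeBandStack(scene$stack, sp)
    writeElevation(scene$dsm, dp)
    files <- c(files, sp, dp)
  }
  # layout + panel polygon in one layer
  polysAll <- c(layout@polygons, list(panel))
  metaAll <- rbind(plotMeta(layout),
                   data.frame(plot_id = "PANEL", entry = NA_character_,
                              replicate = NA_integer_, role = "panel",
                              stringsAsFactors = FALSE))
  lp <- file.path(outDir, "tables", "layout.geojson")
  writePlots(PlotSet(polysAll, metaAll), lp)
  tp <- file.path(outDir, "tables", "truth.csv")
  writeTable(truth, tp)
  gcps <- generateGcpErrors(cfg$qc$n_gcps, cfg$qc$horizontal_sd,
                            cfg$qc$vertical_sd, seed = seed)
  gp <- file.path(outDir, "tables", "gcps.csv")
  writeGCPs(gcps, gp)
  # elevation transect (5 points): rectified follows terrain, non-rectified
  # carries extra vertical wobble
  trn <- withSeed(deriveSeed(seed, "transect"), {
    base <- 100 + cumsum(stats::rnorm(5, 0, 0.01))
    data.frame(point = 1:5, rectified = base + stats::rnorm(5, 0, 0.005),
               non_rectified = base + stats::rnorm(5, 0, 0.05))
  })
  trp <- file.path(outDir, "tables", "transect.csv")
  writeTable(trn, trp)
  list(files = c(files, lp, tp, gp, trp), layout = layout, truth = truth)
}

.readRunLayout <- function(outDir) {
  readPlots(file.path(outDir, "tables", "layout.geojson"))
}

.stageExtract <- function(cfg, outDir, seed) {
  all <- .readRunLayout(outDir)
  m <- plotMeta(all)
  panelIdx <- which(m$role == "panel")
  if (!length(panelIdx)) stop("layout has no panel polygon (role = 'panel')")
  panel <- all@polygons[[panelIdx[1]]]
  plots <- PlotSet(all@polygons[m$role == "plot"],
                   m[m$role == "plot", , drop = FALSE])
  scenes <- list()
  for (tp in cfg$simulate$timepoints) {
    stack <- readBandStack(file.path(outDir, "rasters",
                                     sprintf("stack_%d.json", tp)))
    dsm <- readElevation(file.path(outDir, "rasters",
                                   sprintf("dsm_%d.asc", tp)), role = "DSM")
    stack <- panelCorrect(stack, panel)
    dtm <- buildDTM(dsm, plots = plots)
    csm <- computeCSM(dsm, dtm)
    scenes[[as.character(tp)]] <- list(stack = stack, csm = csm)
  }
  feats <- buildFeatureTable(scenes, plots, maskVI = cfg$extract$vi_mask,
                             canopyThreshold = cfg$extract$canopy_threshold,
                             nirvVariant = cfg$extract$nirv_variant)
  fp <- file.path(outDir, "tables", "features.csv")
  writeTable(feats, fp)
  # trait correlations at the model-fit timepoint, entry-mean protocol
  truth <- readTable(file.path(outDir, "tables", "truth.csv"), .truthSchema)
  addFit <- cfg$model$fit_add
  rep <- correlateTraits(feats[feats$add == addFit, ],
                         truth[truth$add == addFit,
                               c("plot_id", "entry", "agbm", "height_m", "cover")],
                         featureCols = c("GRVI_sum", "NDVI_sum", "NDRE_sum",
                                         "NIRv", "CH_uas", "CC", "PV"),
                         traitCols = c("agbm", "height_m", "cover"),
                         grouping = "by_entry_mean")
  cp <- file.path(outDir, "tables", "correlations.csv")
  writeTable(as.data.frame(rep), cp)
  list(files = c(fp, cp), features = feats, correlations = rep)
}

.stageQc <- function(cfg, outDir, seed) {
  gcps <- readGCPs(file.path(outDir, "tables", "gcps.csv"))
  trn <- readTable(file.path(outDir, "tables", "transect.csv"),
                   list(required = c("rectified", "non_rectified"),
                        numeric = c("rectified", "non_rectified")))
  vpe <- computeVPE(trn$rectified, trn$non_rectified)
  qc <- list(hpe_m = computeHPE(gcps), vpe_m = vpe$vpe,
             vpe_abs_m = vpe$vpe_abs, n_gcps = nrow(gcps),
             n_segments = vpe$n_segments)
  qp <- file.path(outDir, "tables", "qc_georef.json")
  jsonlite::write_json(qc, qp, auto_unbox = TRUE, digits = NA)
  list(files = qp, qc = qc)
}

.stageTraits <- function(cfg, outDir, seed) {
  feats <- readTable(file.path(outDir, "tables", "features.csv"),
                     .featureSchema)
  truth <- readTable(file.path(outDir, "tables", "truth.csv"), .truthSchema)
  t1 <- feats[feats$add == cfg$traits$lodging_add1, ]
  tk <- feats[feats$add == cfg$traits$lodging_addk, ]
  tk <- tk[match(t1$plot_id, tk$plot_id), ]
  lodge <- lodgingScore(t1, tk, includeCC = cfg$traits$include_cc)
  tr1 <- truth[truth$add == cfg$traits$lodging_addk, ]
  lodge$lodging_ratio <- tr1$lodging_ratio[match(lodge$plot_id, tr1$plot_id)]
  lp <- file.path(outDir, "tables", "lodging.csv")
  writeTable(lodge, lp)
  # leaf type from canopy-mean green at the model-fit timepoint
  tf <- feats[feats$add == cfg$model$fit_add, ]
  trf <- truth[truth$add == cfg$model$fit_add, ]
  lab <- trf$leaf_type[match(tf$plot_id, trf$plot_id)]
  ok <- is.finite(tf$G_mean) & !is.na(lab)
  ltm <- fitLeafType(tf$G_mean[ok], lab[ok])
  lj <- file.path(outDir, "models", "leaftype.json")
  jsonlite::write_json(list(threshold = ltm@threshold,
                            upper_class = ltm@upperClass,
                            lower_class = ltm@lowerClass,
                            accuracy = ltm@accuracy),
                       lj, auto_unbox = TRUE, digits = NA)
  list(files = c(lp, lj), lodging = lodge, leafType = ltm)
}

.stageModel <- function(cfg, outDir, seed) {
  feats <- readTable(file.path(outDir, "tables", "features.csv"),
                     .featureSchema)
  truth <- readTable(file.path(outDir, "tables", "truth.csv"), .truthSchema)
  addFit <- cfg$model$fit_add
  ff <- feats[feats$add == addFit, ]
  tt <- truth[truth$add == addFit, c("plot_id", "agbm")]
  fit <- fitLassoAGBM(ff, tt, cfg$model$feature_names,
                      trainFrac = cfg$model$train_frac,
                      nFolds = cfg$model$folds, seed = seed)
  mp <- file.path(outDir, "models", "agbm_model.json")
  writeAGBMModel(fit$model, mp)
  all <- .readRunLayout(outDir)
  m <- plotMeta(all)
  plots <- PlotSet(all@polygons[m$role == "plot"],
                   m[m$role == "plot", , drop = FALSE])
  ent <- predictEntries(fit$model, ff, plots)
  pp <- file.path(outDir, "tables", "entry_predictions.csv")
  writeTable(ent, pp)
  met <- list(validation_r = fit$validation_r, mae = fit$mae,
              train_r2 = fit$train_r2, lambda = fit$lambda, n = fit$n,
              fit_add = addFit)
  mj <- file.path(outDir, "models", "agbm_metrics.json")
  jsonlite::write_json(met, mj, auto_unbox = TRUE, digits = NA)
  list(files = c(mp, pp, mj), fit = fit, entries = ent, metrics = met)
}
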