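# End-to-end commands tying the stages together: simulate -> unmix ->
# quantify -> report, with YAML configuration and file conventions from io.R.
# A thin command-line front-end over these functions ships in
# inst/cli/spax.R.

.simulateKeys <- c("seed", "depth_px", "lateral_px", "pixel_size_mm",
                   "skin_depth_px", "noise_frac", "collagen_amp", "n_blobs",
                   "bmode_mean", "bmode_local_variance", "animals",
                   "labels", "collagen_scales")

readConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  config
}

#' Simulate a longitudinal phantom study from a config
#'
#' Reads a YAML (or list) configuration describing the phantom and the
#' timepoint series, simulates `animals x timepoints` stacks with
#' [liverPhantom()] and [simulateProgression()], and writes per acquisition:
#' the multispectral stack (TIFF + sidecar JSON + B-mode/ROI PNG, see
#' [writeStack()]), the true concentration maps and SO2 map, plus a
#' `manifest.json` and a `run.log` recording the config hash and seed.
#'
#' Config keys (all optional except `seed`): `depth_px`, `lateral_px`,
#' `pixel_size_mm`, `skin_depth_px`, `noise_frac`, `collagen_amp`, `n_blobs`,
#' `bmode_mean`, `bmode_local_variance`, `animals`, `labels`,
#' `collagen_scales`.
#'
#' @param config YAML file path or list.
#' @param outDir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
cmdSimulate <- function(config, outDir) {
  cfgPath <- if (is.character(config)) config else NULL
  cfg <- readConfig(config)
  bad <- setdiff(names(cfg), .simulateKeys)
  if (length(bad))
    stop("invalid config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must provide a seed")
  labels <- cfg$labels %||% c("baseline", "wk05", "wk10", "wk13")
  scales <- cfg$collagen_scales %||% c(1, 1.5, 2, 3)
  if (length(labels) != length(scales))
    stop("labels and collagen_scales must have equal length")
  nAnimals <- cfg$animals %||% 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lib <- defaultSpectraLibrary()
  entries <- list()
  for (a in seq_len(nAnimals)) {
    spec <- liverPhantom(
      depth = cfg$depth_px %||% 128L, lateral = cfg$lateral_px %||% 256L,
      lib = lib, collagenAmp = cfg$collagen_amp %||% 1.5,
      noiseFrac = cfg$noise_frac %||% 0.02,
      skinDepthPx = cfg$skin_depth_px %||% 8L,
      nBlobs = cfg$n_blobs %||% 6L,
      seed = deriveSeed(cfg$seed, a),
      pixelSizeMm = cfg$pixel_size_mm %||% 0.1,
      bmodeMean = cfg$bmode_mean %||% 103.4,
      bmodeLocalVar = cfg$bmode_local_variance %||% 135)
    series <- simulateProgression(spec, scales, lib)
    for (t in seq_along(series)) {
      id <- sprintf("a%02d_%s", a, labels[t])
      prefix <- file.path(outDir, paste0("stack_", id))
      writeStack(series[[t]]$stack, prefix)
      tr <- series[[t]]$truth
      for (ch in names(tr@spec@concMaps))
        writeMapTiff(tr@spec@concMaps[[ch]],
                     file.path(outDir, sprintf("truth_%s_%s", id, ch)))
      so2 <- tr@so2True
      so2[is.na(so2)] <- 0
      writeMapTiff(so2, file.path(outDir, sprintf("truth_%s_so2", id)))
      entries[[id]] <- list(animal = sprintf("a%02d", a),
                            label = labels[t],
                            collagen_scale = scales[t],
                            stack_prefix = paste0("stack_", id))
    }
  }
  manifest <- list(seed = cfg$seed, labels = labels,
                   collagen_scales = scales, animals = nAnimals,
                   entries = entries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  hash <- if (!is.null(cfgPath)) unname(tools::md5sum(cfgPath)) else {
    tmp <- tempfile(); yaml::write_yaml(cfg, tmp)
    on.exit(unlink(tmp), add = TRUE)
    unname(tools::md5sum(tmp))
  }
  writeLines(c(sprintf("config_md5: %s", hash),
               sprintf("seed: %s", cfg$seed),
               sprintf("spaxr_version: %s",
                       as.character(utils::packageVersion("spaxr")))),
             file.path(outDir, "run.log"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unmix every stack of a simulated (or imported) study directory
#'
#' For each manifest entry runs [spaxPipeline()] and writes
#' `endmembers_<id>.csv` (wavelength_nm + one column per component),
#' per-component abundance TIFFs, and `assignment_<id>.json` with the
#' component-to-chromophore assignment, rank and reconstruction error.
#'
#' @param simDir directory produced by [cmdSimulate()] (must contain
#'   `manifest.json`).
#' @param outDir output directory.
#' @param ... options passed to [spaxPipeline()] (e.g. `nSuperpixels`, `K`,
#'   `fluenceCorrection`, `band`).
#' @return invisibly, a named list of [UnmixingResult-class] objects.
#' @export
cmdUnmix <- function(simDir, outDir, ...) {
  manifest <- jsonlite::read_json(file.path(simDir, "manifest.json"),
                                  simplifyVector = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (id in names(manifest$entries)) {
    e <- manifest$entries[[id]]
    stack <- readStack(file.path(simDir, e$stack_prefix))
    pl <- spaxPipeline(stack, ...)
    res <- pl$result
    df <- data.frame(wavelength_nm = res@wavelengths, t(res@S))
    names(df) <- c("wavelength_nm",
                   sprintf("component_%d", seq_len(res@rank)))
    utils::write.csv(df, file.path(outDir, sprintf("endmembers_%s.csv", id)),
                     row.names = FALSE, quote = FALSE)
    for (k in seq_len(res@rank))
      writeMapTiff(res@abundances[, , k],
                   file.path(outDir, sprintf("abundance_%s_comp%d", id, k)))
    jsonlite::write_json(
      list(rank = res@rank, recon_error = res@reconError,
           singular_values = res@singularValues,
           assignment = res@assignment),
      file.path(outDir, sprintf("assignment_%s.json", id)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results[[id]] <- res
  }
  invisible(results)
}

#' Quantify a study directory into longitudinal metric tables
#'
#' Runs [timepointMetrics()] on every manifest entry and writes
#' `metrics_per_animal.csv` (one row per acquisition),
#' `metrics_longitudinal.csv` (mean +/- sd per timepoint label, via
#' [longitudinalTable()]), and a collagen abundance-map overlay PNG per
#' acquisition.
#'
#' @param simDir directory produced by [cmdSimulate()].
#' @param outDir output directory.
#' @param ... options passed to [timepointMetrics()].
#' @return invisibly, the per-animal metrics data.frame.
#' @export
cmdQuantify <- function(simDir, outDir, ...) {
  manifest <- jsonlite::read_json(file.path(simDir, "manifest.json"),
                                  simplifyVector = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  lib <- defaultSpectraLibrary()
  ents <- manifest$entries
  animals <- unique(vapply(ents, function(e) e$animal, character(1)))
  rows <- list()
  for (an in animals) {
    ids <- names(ents)[vapply(ents, function(e)
      identical(e$animal, an), logical(1))]
    stacks <- lapply(ids, function(id)
      readStack(file.path(simDir, ents[[id]]$stack_prefix)))
    labels <- vapply(ids, function(id) ents[[id]]$label, character(1))
    lm <- longitudinalMetrics(stacks, labels, animal = an, lib = lib, ...)
    rows[[an]] <- lm$metrics
    for (t in seq_along(ids)) {
      cmap <- chromophoreMap(lm$pipelines[[t]]$result, "collagen3")
      overlayPng(stacks[[t]]@bmode, cmap, lm$pipelines[[t]]$result@roi,
                 file.path(outDir,
                           sprintf("overlay_collagen_%s.png", ids[t])))
    }
  }
  metrics <- do.call(rbind, rows)
  labelOrder <- unlist(manifest$labels)
  utils::write.csv(metrics, file.path(outDir, "metrics_per_animal.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(longitudinalTable(metrics, labelOrder),
                   file.path(outDir, "metrics_longitudinal.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(metrics)
}

# B-mode grayscale with the abundance map alpha-blended in red, PNG output.
overlayPng <- function(bmode, map, roi, path) {
  g <- pmin(pmax(bmode / 255, 0), 1)
  m <- map
  if (max(m) > 0) m <- m / max(m)
  alpha <- 0.6 * m * roi
  rgb <- array(0, dim = c(nrow(g), ncol(g), 3L))
  rgb[, , 1L] <- g * (1 - alpha) + alpha
  rgb[, , 2L] <- g * (1 - alpha)
  rgb[, , 3L] <- g * (1 - alpha)
  png::writePNG(rgb, path)
  invisible(path)
}

#' Plot longitudinal metric trends
#'
#' Reads the longitudinal metrics CSV written by [cmdQuantify()] and writes
#' one PNG per trend: collagen reference correlation, collagen percent-area,
#' collagen/SO2 ratio, echogenicity and heterogeneity across timepoints
#' (mean with sd error bars).
#'
#' @param metricsCsv path to `metrics_longitudinal.csv`.
#' @param outDir output directory for the PNG plots.
#' @return invisibly, the vector of files written.
#' @export
cmdReport <- function(metricsCsv, outDir) {
  tab <- utils::read.csv(metricsCsv, check.names = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  trends <- c(collagen_ref_correlation = "Collagen reference correlation",
              collagen_percent_area = "Collagen percent area (%)",
              collagen_to_so2_ratio = "Collagen / SO2 ratio",
              echogenicity = "Echogenicity (mean gray level)",
              heterogeneity = "Heterogeneity (local variance)")
  files <- character(0)
  for (m in names(trends)) {
    mu <- tab[[paste0(m, "_mean")]]
    sdv <- tab[[paste0(m, "_sd")]]
    if (is.null(mu)) next
    f <- file.path(outDir, paste0("trend_", m, ".png"))
    grDevices::png(f, width = 640, height = 480)
    x <- seq_len(nrow(tab))
    ylim <- range(c(mu - sdv, mu + sdv, mu), na.rm = TRUE)
    graphics::plot(x, mu, type = "b", pch = 19, xaxt = "n",
                   xlab = "timepoint", ylab = trends[[m]],
                   main = trends[[m]], ylim = ylim)
    graphics::axis(1, at = x, labels = tab$label)
    ok <- !is.na(sdv)
    if (any(ok))
      graphics::arrows(x[ok], mu[ok] - sdv[ok], x[ok], mu[ok] + sdv[ok],
                       angle = 90, code = 3, length = 0.05)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
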