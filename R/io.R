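#' @section Coordinate and file conventions:
#' Pixel coordinates are row-major and 0-based with pixel centres at
#' integer coordinates. Stacks are multi-page TIFFs (page k = phase step
#' k) with a JSON sidecar (same path, `.json` extension) carrying the
#' acquisition, instrument and phase metadata; the sidecar phase list is
#' authoritative. Integer count data up to 65535 are stored as 16-bit
#' pages and round-trip bit-exactly; other data are stored as 32-bit
#' pages of value/scale with the scale recorded in the sidecar.
#' @name fdflim-io
#' @keywords internal
NULL

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

write_pages <- function(pages, path, mode, scale) {
  if (mode == "uint16") {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535),
                    path, bits.per.sample = 16L, compression = "none",
                    reduce = FALSE)
  } else {
    tiff::writeTIFF(lapply(pages, function(p) p / scale),
                    path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  }
  invisible(path)
}

read_pages <- function(path, mode, scale) {
  if (mode == "uint16") {
    lapply(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
           function(p) p + 0)  # integer counts -> double
  } else {
    lapply(tiff::readTIFF(path, all = TRUE), function(p) p * scale)
  }
}

#' Write a phase stack to TIFF + JSON sidecar
#'
#' @param stack a [phase_stack()].
#' @param path output TIFF path (`.tif`); the sidecar goes next to it
#'   with a `.json` extension, and ground-truth maps (if present) into a
#'   companion `<path>_truth.tif`.
#' @param mode "auto" (default: 16-bit for integer counts <= 65535,
#'   else 32-bit), "uint16" or "float32".
#' @return the TIFF path, invisibly.
#' @export
write_stack <- function(stack, path, mode = c("auto", "uint16", "float32")) {
  stopifnot(inherits(stack, "phase_stack"))
  mode <- match.arg(mode)
  fr <- stack$frames
  is_counts <- all(fr == round(fr)) && max(fr) <= 65535
  if (mode == "auto") mode <- if (is_counts) "uint16" else "float32"
  if (mode == "uint16" && !is_counts)
    stop("uint16 mode requires integer values <= 65535")
  scale <- if (mode == "float32") 2^ceiling(log2(max(fr, 1))) else 65535
  k <- dim(fr)[3]
  write_pages(lapply(seq_len(k), function(i) fr[, , i]), path, mode, scale)
  truth_path <- NULL
  if (!is.null(stack$truth)) {
    truth_path <- sub("\\.tiff?$", "_truth.tif", path)
    tm <- stack$truth
    planes <- list(tm$phase, tm$modulation, tm$tau_phi, tm$tau_mod, tm$dc,
                   tm$regions + 0)
    tscale <- 2^ceiling(log2(max(abs(unlist(planes)), 1)))
    # affine map into [0,1]: plane values may be signed (phase)
    write_pages(lapply(planes, function(p) (p / tscale + 1) / 2),
                truth_path, "float32", 1)
    attr(truth_path, "tscale") <- tscale
  }
  sidecar <- list(
    format = list(mode = mode, scale = scale, pages = k,
                  rows = dim(fr)[1], cols = dim(fr)[2]),
    acquisition = unclass(stack$acq),
    instrument = if (!is.null(stack$instrument)) unclass(stack$instrument),
    phase_offsets = stack$phases,
    pixel_size = stack$pixel_size,
    truth = if (!is.null(truth_path))
      list(file = basename(truth_path),
           planes = c("phase", "modulation", "tau_phi", "tau_mod", "dc",
                      "regions"),
           scale = attr(truth_path, "tscale")))
  # digits = I(17): doubles (notably the phase offsets) must survive the
  # JSON round trip exactly
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a phase stack from TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_stack()].
#' @return a [phase_stack()]; ground truth is restored when the
#'   companion truth TIFF is present.
#' @export
read_stack <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop(sprintf(
      "missing sidecar %s; stacks need a JSON sidecar with acquisition metadata (write_stack() creates it)",
      sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- read_pages(path, sc$format$mode, sc$format$scale)
  k <- length(sc$phase_offsets)
  if (length(pages) != k)
    stop(sprintf("TIFF has %d pages but sidecar lists K = %d phase offsets",
                 length(pages), k))
  fr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), k))
  for (i in seq_len(k)) fr[, , i] <- pages[[i]]
  acq <- do.call(flim_acquisition, sc$acquisition[
    c("frequency", "n_phases", "exposure_ms", "reference_lifetime",
      "channel")])
  inst <- if (!is.null(sc$instrument))
    do.call(flim_instrument, sc$instrument)
  truth <- NULL
  if (!is.null(sc$truth)) {
    tp <- file.path(dirname(path), sc$truth$file)
    tpl <- read_pages(tp, "float32", 1)
    tpl <- lapply(tpl, function(p) (p * 2 - 1) * sc$truth$scale)
    names(tpl) <- sc$truth$planes
    tpl$regions <- matrix(as.integer(round(tpl$regions)),
                          nrow(tpl$regions))
    truth <- tpl
  }
  phase_stack(fr, sc$phase_offsets, acq, instrument = inst,
              truth = truth, pixel_size = sc$pixel_size)
}

#' Write a single image as a TIFF map
#'
#' 32-bit page of value/scale; NA pixels are stored as the minimum
#' finite value and flagged in the companion validity mask written by
#' [run_pipeline()].
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return list with the path and the scale used, invisibly.
#' @keywords internal
write_map <- function(image, path) {
  v <- image
  lo <- suppressWarnings(min(v, na.rm = TRUE))
  if (!is.finite(lo)) lo <- 0
  v[!is.finite(v)] <- lo
  offset <- min(v)
  v <- v - offset
  scale <- 2^ceiling(log2(max(v, 1)))
  tiff::writeTIFF(v / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  invisible(list(path = path, offset = offset, scale = scale))
}

#' Pipeline run configuration
#'
#' Bundles the file paths and analysis options for [run_pipeline()].
#' Sample and reference sidecars must agree on modulation frequency,
#' phase count and reference lifetime; the pipeline refuses to run
#' otherwise.
#'
#' @param sample,reference paths to stack TIFFs (with sidecars).
#' @param out_dir output directory (created if needed).
#' @param reference_mode see [calibrate()].
#' @param dc_min DC validity threshold, see [demodulate()].
#' @param masking "otsu" (default) or "none" (all valid pixels, for
#'   uniform solution phantoms).
#' @param n_bins Otsu histogram bins.
#' @param seed RNG seed recorded in the provenance record (the analysis
#'   itself is deterministic).
#' @return an object of class `run_config`.
#' @export
run_config <- function(sample, reference, out_dir,
                       reference_mode = c("pixel", "global"),
                       dc_min = 10, masking = c("otsu", "none"),
                       n_bins = 256L, seed = NULL) {
  structure(
    list(sample = sample, reference = reference, out_dir = out_dir,
         reference_mode = match.arg(reference_mode), dc_min = dc_min,
         masking = match.arg(masking), n_bins = as.integer(n_bins),
         seed = seed),
    class = "run_config")
}

#' Run the reconstruction pipeline on stored stacks
#'
#' read -> demodulate -> calibrate -> flat-field -> lifetime maps ->
#' mask -> summary, with all products written under `out_dir`:
#' `tau_phi.tif`, `tau_mod.tif`, `norm_intensity.tif`, `valid_mask.tif`,
#' `mask.tif`, `summary.csv` and a `provenance.json` with the config,
#' its MD5 hash, the seed and the package version. Any stage failure
#' aborts with a stage-labelled message and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return list with the `reconstruction`, the `summary` row and the
#'   output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  smp <- stage("read", read_stack(config$sample))
  ref <- stage("read", read_stack(config$reference))
  stage("config", {
    a <- smp$acq; b <- ref$acq
    if (a$frequency != b$frequency)
      stop(sprintf("frequency mismatch (sample %g Hz, reference %g Hz)",
                   a$frequency, b$frequency))
    if (a$n_phases != b$n_phases)
      stop(sprintf("phase count mismatch (sample %d, reference %d)",
                   a$n_phases, b$n_phases))
    if (a$reference_lifetime != b$reference_lifetime)
      stop("reference lifetime mismatch")
  })
  rec <- stage("reconstruct",
               flim_reconstruct(smp, ref,
                                reference_mode = config$reference_mode,
                                dc_min = config$dc_min))
  lt <- rec$lifetime
  mask <- stage("mask", {
    if (config$masking == "otsu")
      otsu_mask(lt$norm_intensity, config$n_bins)
    else matrix(TRUE, nrow(lt$tau_phi), ncol(lt$tau_phi))
  })
  summ <- stage("summarize", summarize_masked(lt, mask))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage("write", {
    map_meta <- list()
    for (spec in list(list(lt$tau_phi, "tau_phi.tif"),
                      list(lt$tau_mod, "tau_mod.tif"),
                      list(lt$norm_intensity, "norm_intensity.tif"))) {
      map_meta[[spec[[2]]]] <- write_map(spec[[1]], out(spec[[2]]))
      written <<- c(written, out(spec[[2]]))
    }
    tiff::writeTIFF(lt$valid + 0, out("valid_mask.tif"),
                    bits.per.sample = 8L, compression = "none")
    tiff::writeTIFF(mask + 0, out("mask.tif"), bits.per.sample = 8L,
                    compression = "none")
    written <<- c(written, out("valid_mask.tif"), out("mask.tif"))
    sdf <- as.data.frame(summ)
    num <- vapply(sdf, is.numeric, TRUE)
    sdf[num] <- lapply(sdf[num], signif, digits = 6L)
    utils::write.csv(sdf, out("summary.csv"), row.names = FALSE)
    written <<- c(written, out("summary.csv"))
    cfg <- unclass(config)
    cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                 null = "null")
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    prov <- list(config = cfg,
                 config_md5 = unname(tools::md5sum(tmp)),
                 seed = config$seed,
                 package = "fdflim",
                 version = as.character(utils::packageVersion("fdflim")),
                 dc_min = config$dc_min, masking = config$masking,
                 n_bins = config$n_bins,
                 n_masked_pixels = summ$n_pixels,
                 maps = lapply(map_meta, function(m)
                   list(offset = m$offset, scale = m$scale)))
    unlink(tmp)
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    written <<- c(written, out("provenance.json"))
  })
  invisible(list(reconstruction = rec, summary = summ, files = written))
}
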