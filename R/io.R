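#' Read a grayscale image as a scalar field
#'
#' Reads a single-channel TIFF or PNG. Integer pixel values are cast to
#' floating point without rescaling (a 16-bit PNG yields values on 0..65535);
#' 32-bit float TIFFs are read as stored. Multi-channel and non-square images
#' are rejected rather than silently reduced.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size_um Physical pixel size to record, in micrometers.
#' @return A [scalar_field()].
#' @export
read_image <- function(path, pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    probe <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(probe, "bits.per.sample")
    # 32-bit samples are floats stored verbatim; integer depths are read
    # unscaled via as.is
    img <- if (identical(bits, 32L) || identical(bits, 32)) probe
           else tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (!is.null(depth)) img <- img * (2^depth - 1)
  } else {
    stop("unsupported image format '", ext, "': ", path)
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1)
      stop("multi-channel image (", dim(img)[3], " channels): ", path)
    img <- img[, , 1]
  }
  img <- matrix(as.numeric(img), nrow = dim(img)[1])
  if (nrow(img) != ncol(img))
    stop("non-square image (", nrow(img), " x ", ncol(img), "): ", path)
  scalar_field(img, pixel_size_um)
}

#' Write a scalar field to disk
#'
#' Both formats store the field affinely rescaled to the unit interval (the
#' downstream analysis is invariant to affine intensity maps): TIFF as 32-bit
#' floats, which round-trip at single precision, PNG as 8-bit integers. The
#' affine parameters (`offset`, `scale` such that
#' `original = offset + scale * stored`) are returned for callers that need
#' the raw values back.
#'
#' @param field A [scalar_field()].
#' @param path Output path; the extension (`.tif`/`.tiff` or `.png`) selects
#'   the format.
#' @return Invisibly, a list with `path`, `offset`, `scale`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  ext <- tolower(tools::file_ext(path))
  rng <- range(field$values)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  v01 <- (field$values - rng[1]) / scale
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v01, path, bits.per.sample = 32L, reduce = FALSE)
  } else if (ext == "png") {
    png::writePNG(v01, path)
  } else {
    stop("unsupported output format '", ext, "'")
  }
  invisible(list(path = path, offset = rng[1], scale = scale))
}

#' Configuration of a full pipeline run
#'
#' Describes one batch analysis: where the images come from (synthetic
#' ensembles or labelled files on disk), the scale ladder, the binning policy,
#' the white-noise normalization reference, and the output directory. All
#' randomness derives from `seed`.
#'
#' @param groups Named list; each element is either
#'   `list(kind = , n = , ...)` describing a synthetic ensemble (extra fields
#'   are passed to [field_spec()]), or `list(paths = c(...))` naming image
#'   files (validated at construction).
#' @param ladder A [scale_ladder()]; default [default_ladder()].
#' @param policy A [binning_policy()].
#' @param reference `"white_noise"` to generate a fresh white-noise reference
#'   ensemble, a data frame with `scale`/`median_fa` columns to reuse one, or
#'   `NULL` to skip normalization.
#' @param n_reference Size of the generated reference ensemble (default 30).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-image seeds are derived from it.
#' @param pixel_size_um Pixel size applied to images read from disk.
#' @param side Side length of synthetic images (default 512).
#' @return An object of class `run_config`.
#' @export
run_config <- function(groups, ladder = default_ladder(),
                       policy = binning_policy(), reference = "white_noise",
                       n_reference = 30L, out_dir = "wtmm_out", seed = 1L,
                       pixel_size_um = 180 / 512, side = 512L) {
  if (length(groups) == 0 || is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be a non-empty named list")
  for (g in names(groups)) {
    grp <- groups[[g]]
    if (!is.null(grp$paths)) {
      missing <- grp$paths[!file.exists(grp$paths)]
      if (length(missing))
        stop("group '", g, "' references missing file(s): ",
             paste(missing, collapse = ", "))
    } else if (is.null(grp$kind) || is.null(grp$n)) {
      stop("group '", g, "' needs either `paths` or a synthetic `kind` and `n`")
    } else if (grp$n < 1) {
      stop("group '", g, "' has an empty synthetic ensemble")
    }
  }
  structure(list(groups = groups, ladder = ladder, policy = policy,
                 reference = reference, n_reference = as.integer(n_reference),
                 out_dir = out_dir, seed = as.integer(seed),
                 pixel_size_um = pixel_size_um, side = as.integer(side)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads the batch settings (groups, ladder bounds, binning policy, reference,
#' seed) from YAML and builds a [run_config()].
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore the intended name
  y$groups <- lapply(y$groups, function(g) {
    names(g)[names(g) == "FALSE"] <- "n"
    g
  })
  px <- if (is.null(y$pixel_size_um)) 180 / 512 else y$pixel_size_um
  lad <- if (is.null(y$ladder)) default_ladder(px) else
    scale_ladder(y$ladder$min_scale, y$ladder$max_scale, y$ladder$n_scales, px)
  pol <- if (is.null(y$policy)) binning_policy() else
    do.call(binning_policy, y$policy)
  run_config(groups = y$groups, ladder = lad, policy = pol,
             reference = if (is.null(y$reference)) "white_noise" else y$reference,
             n_reference = if (is.null(y$n_reference)) 30L else y$n_reference,
             out_dir = if (is.null(out_dir)) {
               if (is.null(y$out_dir)) "wtmm_out" else y$out_dir
             } else out_dir,
             seed = if (is.null(y$seed)) 1L else y$seed,
             pixel_size_um = px,
             side = if (is.null(y$side)) 512L else y$side)
}

# Derived per-image seed, kept inside 32-bit signed range.
derive_seed <- function(master, stream, index) {
  as.integer((as.double(master) + 7919 * stream + 104729 * index) %% 2147483647)
}

pipeline_group_curves <- function(cfg, label, grp, stream) {
  if (!is.null(grp$paths)) {
    curves <- lapply(seq_along(grp$paths), function(i) {
      img <- read_image(grp$paths[i], cfg$pixel_size_um)
      multiscale_curve(img, cfg$ladder, cfg$policy,
                       image_id = basename(grp$paths[i]))
    })
  } else {
    curves <- lapply(seq_len(grp$n), function(i) {
      args <- grp[setdiff(names(grp), c("kind", "n"))]
      spec <- do.call(field_spec, c(list(side_length = cfg$side,
                                         kind = grp$kind,
                                         seed = derive_seed(cfg$seed, stream, i),
                                         pixel_size_um = cfg$pixel_size_um),
                                    args))
      multiscale_curve(generate_field(spec), cfg$ladder, cfg$policy,
                       image_id = sprintf("%s_%03d", label, i))
    })
  }
  group_curves(label, curves)
}

#' Run the full batch anisotropy pipeline
#'
#' Generates or reads every image, computes its anisotropy curve, normalizes
#' by the white-noise reference, aggregates group medians, and runs per-scale
#' rank-sum tests between every pair of groups. Writes `curves.csv` (one row
#' per image and scale), `medians.csv`, `ptrack.csv` (if two or more groups),
#' `reference.csv`, and `manifest.json` (config echo, package version,
#' per-stage counts) under `config$out_dir`. Deterministic: the same config
#' and seed yield byte-identical CSVs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the curve table, median table, p-value
#'   table, reference table and manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  reference_tab <- NULL
  if (identical(config$reference, "white_noise")) {
    say("generating white-noise reference ensemble (n = ",
        config$n_reference, ")")
    ref_curves <- lapply(seq_len(config$n_reference), function(i) {
      spec <- field_spec(config$side, "white_noise",
                         seed = derive_seed(config$seed, 0L, i),
                         pixel_size_um = config$pixel_size_um)
      multiscale_curve(generate_field(spec), config$ladder, config$policy,
                       image_id = sprintf("reference_%03d", i))
    })
    reference_tab <- median_curve(ref_curves)
  } else if (is.data.frame(config$reference)) {
    reference_tab <- config$reference
  }

  groups <- vector("list", length(config$groups))
  names(groups) <- names(config$groups)
  for (gi in seq_along(config$groups)) {
    label <- names(config$groups)[gi]
    say("analyzing group '", label, "'")
    groups[[gi]] <- pipeline_group_curves(config, label,
                                          config$groups[[gi]], gi)
  }

  curve_rows <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(g$curves, function(cv) {
      fa_norm <- if (is.null(reference_tab)) NA_real_ else
        normalize_by_reference(cv, reference_tab)$fa
      data.frame(group = g$label, image_id = attr(cv, "image_id"),
                 scale_px = cv$scale, scale_um = cv$scale_um,
                 n_maxima = cv$n_samples, n_bins = cv$n_bins, fa = cv$fa,
                 fa_normalized = fa_norm)
    }))
  }))
  rownames(curve_rows) <- NULL

  median_rows <- do.call(rbind, lapply(groups, function(g) {
    m <- median_curve(g)
    data.frame(group = g$label, scale_px = m$scale, scale_um = m$scale_um,
               median_fa = m$median_fa, n = m$n)
  }))
  rownames(median_rows) <- NULL

  ptrack <- NULL
  if (length(groups) >= 2 && all(vapply(groups, function(g)
      length(g$curves) >= 3, logical(1)))) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    ptrack <- do.call(rbind, lapply(pairs, function(pr) {
      t <- pairwise_scale_test(groups[[pr[1]]], groups[[pr[2]]])
      data.frame(group_a = pr[1], group_b = pr[2], scale_px = t$scale,
                 scale_um = t$scale_um, p_raw = t$p)
    }))
    rownames(ptrack) <- NULL
  }

  out <- function(name) file.path(config$out_dir, name)
  utils::write.csv(curve_rows, out("curves.csv"), row.names = FALSE)
  utils::write.csv(median_rows, out("medians.csv"), row.names = FALSE)
  if (!is.null(ptrack)) utils::write.csv(ptrack, out("ptrack.csv"),
                                         row.names = FALSE)
  if (!is.null(reference_tab))
    utils::write.csv(reference_tab, out("reference.csv"), row.names = FALSE)

  manifest <- list(
    package = "wtmmaniso",
    version = as.character(utils::packageVersion("wtmmaniso")),
    seed = config$seed,
    side = config$side,
    pixel_size_um = config$pixel_size_um,
    ladder = list(scales_px = config$ladder$scales,
                  pixel_size_um = config$ladder$pixel_size_um),
    policy = unclass(config$policy),
    reference = if (is.data.frame(config$reference)) "precomputed"
                else config$reference,
    n_reference = config$n_reference,
    groups = lapply(config$groups, function(g)
      if (!is.null(g$paths)) list(n = length(g$paths), source = "files")
      else list(n = g$n, source = "synthetic", kind = g$kind)),
    n_images = sum(vapply(groups, function(g) length(g$curves), integer(1)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(curves = curve_rows, medians = median_rows, ptrack = ptrack,
                 reference = reference_tab, manifest = manifest))
}
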