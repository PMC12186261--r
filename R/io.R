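#' Write a scan to a directory container
#'
#' Plain-text container for a raster scan: `positions.csv` (point, ix,
#' iy, x, y), shared axes `q.csv` and `chi.csv`, shared `mask.csv`
#' (0/1), per-point intensity arrays `patterns/point_<i>.csv` (q rows x
#' chi columns), and, for synthetic scans, the ground-truth table
#' `truth.csv`. Chosen over a monolithic blob for inspectability.
#'
#' @param scan a [simulate_scan()] result, or a list with `patterns` and
#'   `positions` (any source of patterns sharing one (q, chi) grid).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_container <- function(scan, dir) {
  dir.create(file.path(dir, "patterns"), recursive = TRUE,
             showWarnings = FALSE)
  lazy <- inherits(scan, "saxs_scan")
  n <- nrow(scan$positions)
  pos <- cbind(point = seq_len(n), scan$positions)
  utils::write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  if (!is.null(scan$truth))
    utils::write.csv(scan$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  p1 <- if (lazy) realize_pattern(scan, 1) else scan$patterns[[1]]
  utils::write.csv(data.frame(q = p1$q), file.path(dir, "q.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(chi = p1$chi), file.path(dir, "chi.csv"),
                   row.names = FALSE)
  utils::write.table(p1$mask * 1L, file.path(dir, "mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  for (i in seq_len(n)) {
    p <- if (lazy) realize_pattern(scan, i) else scan$patterns[[i]]
    utils::write.table(p$intensity,
                       file.path(dir, "patterns", sprintf("point_%05d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a scan container
#'
#' Validates every pattern on load (axis lengths, monotone grids,
#' non-negative valid intensities); a violation raises an error naming
#' the offending point. A point whose bins are all masked is loaded and
#' flagged in `fully_masked`, never dropped.
#'
#' @param path container directory written by [write_scan_container()].
#' @return A list with `patterns` (list of [scattering_pattern()]),
#'   `positions`, `truth` (or NULL) and logical `fully_masked`.
#' @export
read_scan_container <- function(path) {
  need <- c("positions.csv", "q.csv", "chi.csv", "mask.csv")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss))
    stop("missing container files: ", paste(miss, collapse = ", "))
  pos <- utils::read.csv(file.path(path, "positions.csv"))
  q <- utils::read.csv(file.path(path, "q.csv"))$q
  chi <- utils::read.csv(file.path(path, "chi.csv"))$chi
  mask <- as.matrix(utils::read.csv(file.path(path, "mask.csv"),
                                    header = FALSE)) == 1
  dimnames(mask) <- NULL
  truth <- if (file.exists(file.path(path, "truth.csv")))
    utils::read.csv(file.path(path, "truth.csv")) else NULL
  patterns <- lapply(seq_len(nrow(pos)), function(i) {
    f <- file.path(path, "patterns", sprintf("point_%05d.csv", i))
    if (!file.exists(f)) stop("missing pattern array for point ", i)
    I <- as.matrix(utils::read.csv(f, header = FALSE))
    dimnames(I) <- NULL
    if (nrow(I) != length(q) || ncol(I) != length(chi))
      stop(sprintf("point %d: array is %d x %d but axes are %d x %d",
                   i, nrow(I), ncol(I), length(q), length(chi)))
    p <- scattering_pattern(I, q, chi, mask = mask,
                            meta = list(position_mm = c(x = pos$x[i],
                                                        y = pos$y[i])))
    tryCatch(validate_pattern(p, id = i), error = function(e) stop(e))
    p
  })
  list(patterns = patterns, positions = pos, truth = truth,
       fully_masked = vapply(patterns, function(p) !any(p$mask), logical(1)))
}

#' Write / read a result table with units metadata
#'
#' CSV with one leading comment line documenting the units of each
#' column; the reader skips it.
#'
#' @param results data frame (e.g. from [reduce_scan()]).
#' @param path output CSV path.
#' @return `path` invisibly; for the reader, the data frame.
#' @export
write_result_table <- function(results, path) {
  units <- c(point = "index", x = "mm", y = "mm", intensity = "counts",
             of = "dimensionless", q_peak = "1/Angstrom",
             delta_q = "1/Angstrom", d = "Angstrom", xi = "Angstrom",
             converged = "flag", B = "counts*Angstrom^P",
             P = "dimensionless", D_s = "dimensionless",
             angle = "degrees", power = "fraction of total")
  u <- units[names(results)]
  u[is.na(u)] <- "unspecified"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ",
                    paste(names(results), u, sep = "=", collapse = "; ")),
             con)
  utils::write.csv(results, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read / write grayscale TIFF micrographs
#'
#' Thin wrappers over the tiff package. Pixel values are stored in
#' `[0, 1]`; color images are averaged to gray on load. The pixel size
#' is not carried by the file and must be supplied.
#'
#' @param path TIFF file path.
#' @param pixel_size um per pixel.
#' @return A [micrograph()] (reader); `path` invisibly (writer).
#' @export
read_micrograph <- function(path, pixel_size = 1) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  micrograph(px, pixel_size)
}

#' @rdname read_micrograph
#' @param img a [micrograph()]; values are clamped to `[0, 1]` on write.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  tiff::writeTIFF(pmin(pmax(img$pixels, 0), 1), path)
  invisible(path)
}

#' Export a scan map as CSV grid and TIFF heatmap
#'
#' The CSV grid holds the map matrix (x rows, y columns); the TIFF is
#' the map min-max normalized to `[0, 1]` with NA rendered as 0.
#'
#' @param map matrix or `scan_map` (its `intensity_map`).
#' @param csv_path,tiff_path output paths (either may be NULL to skip).
#' @return Invisibly, the matrix written.
#' @export
write_map <- function(map, csv_path = NULL, tiff_path = NULL) {
  m <- if (inherits(map, "scan_map")) map$intensity_map else map
  if (!is.null(csv_path))
    utils::write.table(m, csv_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(tiff_path)) {
    rng <- range(m, na.rm = TRUE)
    nm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    nm[is.na(nm)] <- 0
    tiff::writeTIFF(t(nm), tiff_path)
  }
  invisible(m)
}

# ---- run configuration -----------------------------------------------------

config_schema <- function() list(
  schema_version = 1L,
  seed = 1L,
  saxs = list(q_min = 0.005, q_max = 0.20, n_q = 150, chi_step = 5,
              q0 = 0.1308, delta_q = 0.0045, peak_amplitude = 1000,
              background_B = 5e-6, background_P = -3.5, kappa = 0,
              chi_pref = 0, gap_period = 25, gap_width = 10,
              shoulder_on = FALSE, noise = TRUE),
  scan = list(nx = 101, ny = 101, step = 0.020, band_period = 0.3,
              band_axis = "x", band_contrast = 0.5, of_in_band = 0.4,
              xi_in_band = 1850, xi_out_band = 1460),
  reduce = list(q_band = c(0.11, 0.15), peak_window = c(0.10, 0.16),
                power_range = c(0.005, 0.05), kernel_size = 30,
                what = c("intensity", "of", "peak", "powerlaw")),
  micrograph = list(width = 512, height = 512, pixel_size = 1,
                    band_period = 300, band_axis = 90, band_contrast = 0.3,
                    n_platelets = 150, platelet_length = 20,
                    platelet_width = 4, platelet_depth = 0.3, kappa = 3,
                    blur_sigma = 1, noise_sigma = 0.02),
  fft = list(f_low = 0.025, f_high = 0.25, sigma_frac = 0.25,
             sg_window = 15, sg_order = 3))

#' Read a run configuration
#'
#' YAML configuration covering every pipeline stage. Unknown keys (top
#' level or within a stage) are rejected; missing keys take the package
#' defaults, and the fully resolved configuration is returned (and is
#' written next to the outputs of every CLI run).
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return A nested list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  schema <- config_schema()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(user), names(schema))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(schema[[k]]) && !is.null(names(schema[[k]]))) {
      badk <- setdiff(names(user[[k]]), names(schema[[k]]))
      if (length(badk))
        stop(sprintf("unknown keys in '%s': %s", k,
                     paste(badk, collapse = ", ")))
      schema[[k]][names(user[[k]])] <- user[[k]]
    } else schema[[k]] <- user[[k]]
  }
  structure(schema, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Build module configs from a run_config.
saxs_cfg_from_run <- function(rc, seed = rc$seed) {
  s <- rc$saxs
  saxs_sim_config(
    q_grid = seq(s$q_min, s$q_max, length.out = s$n_q),
    chi_grid = seq(0, 360 - s$chi_step, by = s$chi_step),
    q0 = s$q0, delta_q = s$delta_q, peak_amplitude = s$peak_amplitude,
    background_B = s$background_B, background_P = s$background_P,
    kappa = s$kappa, chi_pref = s$chi_pref, gap_period = s$gap_period,
    gap_width = s$gap_width, shoulder_on = s$shoulder_on,
    noise = s$noise, seed = seed)
}

scan_cfg_from_run <- function(rc, seed = rc$seed) {
  s <- rc$scan
  scan_sim_config(nx = s$nx, ny = s$ny, step = s$step,
                  band_period = s$band_period, band_axis = s$band_axis,
                  band_contrast = s$band_contrast,
                  of_in_band = s$of_in_band, xi_in_band = s$xi_in_band,
                  xi_out_band = s$xi_out_band, seed = seed)
}

micro_cfg_from_run <- function(rc, seed = rc$seed) {
  m <- rc$micrograph
  micrograph_sim_config(
    width = m$width, height = m$height, pixel_size = m$pixel_size,
    band_period = m$band_period, band_axis = m$band_axis,
    band_contrast = m$band_contrast, n_platelets = m$n_platelets,
    platelet_length = m$platelet_length, platelet_width = m$platelet_width,
    platelet_depth = m$platelet_depth, kappa = m$kappa,
    blur_sigma = m$blur_sigma, noise_sigma = m$noise_sigma, seed = seed)
}
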