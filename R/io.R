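# Plain-text persistence. Images travel as 16-bit ASCII PGM (P2) with a
# JSON sidecar for physical metadata; transmission matrices as a directory
# container with `entries` (CSV of re/im parts), `z_planes` and `config`
# (JSON) -- the same keys the HDF5-style layout would use.

#' Write a matrix as 16-bit ASCII PGM (P2)
#'
#' Values are linearly mapped from `[0, max_value]` to `0..65535`;
#' `max_value` defaults to the image maximum and is recorded by
#' [write_scan_image()]'s sidecar for exact inversion.
#'
#' @param img non-negative numeric matrix.
#' @param path output file.
#' @param max_value value mapped to 65535.
#' @return invisibly, the scale used.
#' @export
write_pgm <- function(img, path, max_value = NULL) {
  stopifnot(all(img >= 0))
  if (is.null(max_value)) max_value <- max(img, 1e-300)
  q <- round(pmin(img / max_value, 1) * 65535)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "65535"), con)
  apply(q, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(max_value)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file path.
#' @param max_value physical value of the white level (default 1: returns
#'   values in `[0, 1]`).
#' @return numeric matrix.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop(sprintf("'%s' is not an ASCII PGM (P2)", path))
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop(sprintf("'%s': truncated pixel data", path))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxv
}

#' Write a scan image as PGM plus JSON sidecar
#'
#' @param img a `scan_image`.
#' @param prefix path prefix; writes `<prefix>.pgm` and `<prefix>.json`.
#' @return invisibly, the two file paths.
#' @export
write_scan_image <- function(img, prefix) {
  stopifnot(inherits(img, "scan_image"))
  pgm <- paste0(prefix, ".pgm"); js <- paste0(prefix, ".json")
  scale <- write_pgm(img$pixels, pgm)
  meta <- list(pixel_size_um = img$pixel_size_um, z_um = img$z,
               mask_radius_px = sqrt(sum(img$fov_mask) / pi),
               white_level = scale)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(pgm, js))
}

#' Read a scan image written by [write_scan_image()]
#'
#' @param prefix path prefix used at write time.
#' @return a `scan_image`.
#' @export
read_scan_image <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  px <- read_pgm(paste0(prefix, ".pgm")) * meta$white_level
  mask <- circular_mask(dim(px), meta$mask_radius_px)
  scan_image(px, meta$pixel_size_um, z = meta$z_um, mask = mask)
}

#' Save a depth series as a directory with an index CSV
#'
#' Writes one PGM+JSON pair per record and `index.csv` with columns
#' `z_um,filename`.
#'
#' @param series a `depth_series`.
#' @param dir output directory (created if missing).
#' @return invisibly, the index path.
#' @export
write_depth_series <- function(series, dir) {
  stopifnot(inherits(series, "depth_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(series$records, function(rec) {
    fn <- sprintf("depth_%07.2f", rec$z)
    write_scan_image(rec$image, file.path(dir, fn))
    data.frame(z_um = rec$z, filename = paste0(fn, ".pgm"))
  })
  idx <- file.path(dir, "index.csv")
  utils::write.csv(do.call(rbind, rows), idx, row.names = FALSE)
  invisible(idx)
}

#' Save a transmission matrix as a directory container
#'
#' Layout: `entries.csv` (columns `re`, `im`, column-major over the
#' pixel x mode matrix), `config.json` (optical configuration, seed,
#' mode count) and `z_planes.json` when present.
#'
#' @param tm a `transmission_matrix`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
save_tm <- function(tm, dir) {
  stopifnot(inherits(tm, "transmission_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(re = Re(tm$entries), im = Im(tm$entries)),
                   file.path(dir, "entries.csv"), row.names = FALSE)
  cfg <- tm$config
  jsonlite::write_json(
    list(wavelength_um = cfg$wavelength_um, na = cfg$na,
         core_diameter_um = cfg$core_diameter_um,
         pixel_size_um = cfg$pixel_size_um, grid_shape = cfg$grid_shape,
         n_modes = tm$n_modes, seed = tm$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(tm$z_planes)) {
    jsonlite::write_json(tm$z_planes, file.path(dir, "z_planes.json"),
                         digits = NA)
  }
  invisible(dir)
}

#' Load a transmission matrix saved by [save_tm()]
#'
#' @param dir container directory.
#' @return a `transmission_matrix`.
#' @export
load_tm <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- optical_config(meta$wavelength_um, meta$na, meta$core_diameter_um,
                        meta$pixel_size_um, meta$grid_shape)
  df <- utils::read.csv(file.path(dir, "entries.csv"))
  nm <- meta$n_modes
  e <- matrix(complex(real = as.matrix(df[, seq_len(nm), drop = FALSE]),
                      imaginary = as.matrix(df[, nm + seq_len(nm), drop = FALSE])),
              ncol = nm)
  zp <- NULL
  zf <- file.path(dir, "z_planes.json")
  if (file.exists(zf)) zp <- jsonlite::read_json(zf, simplifyVector = TRUE)
  structure(list(entries = e, config = cfg, seed = meta$seed,
                 n_modes = nm, z_planes = zp),
            class = "transmission_matrix")
}

#' Write a cohort to a directory (images + manifest)
#'
#' @param ch a `phantom_cohort`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ch$images)) {
    write_pgm(ch$images[[i]], file.path(dir, ch$manifest$filename[i]),
              max_value = max(ch$images[[i]]))
  }
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(ch$manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read images and labels from a directory with a label CSV
#'
#' @param dir image directory.
#' @param labels_csv CSV with columns `filename` and `label`; defaults to
#'   `manifest.csv` inside `dir`.
#' @return list with `images` (list of matrices) and `labels`.
#' @export
read_labeled_images <- function(dir, labels_csv = file.path(dir, "manifest.csv")) {
  mf <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
  imgs <- lapply(mf$filename, function(fn) read_pgm(file.path(dir, fn)))
  list(images = imgs, labels = mf$label)
}
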