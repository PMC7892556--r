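# Readers and writers for the package's on-disk formats. Stiffness maps are
# 32-bit float TIFFs scaled by a power-of-two full scale recorded in the JSON
# sidecar, so scaling adds no error beyond the float32 rounding inherent to
# the format; contours are two-column CSVs of 0-based pixel-center
# vertices; expression data travel as TSV plus an annotation TSV and a
# plain-text signature list with a '#anticorrelated' section marker.

KPA_FULL_SCALE <- 256  # kPa mapped to 1.0 in the float TIFF

#' Write a stiffness map (TIFF + JSON sidecar + contour CSV)
#'
#' @param map a `stiffness_map`.
#' @param roi a `tumor_roi` (its contour is written alongside).
#' @param prefix path prefix; writes `<prefix>.tif`, `<prefix>.json`,
#'   `<prefix>_contour.csv`.
#' @param meta named list merged into the sidecar (preset, timepoint_days,
#'   replicate, seed, ...).
#' @return invisibly, the three paths written.
#' @export
write_stiffness_map <- function(map, roi, prefix, meta = list()) {
  stopifnot(inherits(map, "stiffness_map"), inherits(roi, "tumor_roi"))
  if (max(map$values) > KPA_FULL_SCALE)
    stop("stiffness exceeds the ", KPA_FULL_SCALE, " kPa file full scale")
  paths <- paste0(prefix, c(".tif", ".json", "_contour.csv"))
  tiff::writeTIFF(map$values / KPA_FULL_SCALE, paths[1],
                  bits.per.sample = 32L, compression = "none")
  sidecar <- c(list(pixel_spacing_mm = map$pixel_spacing_mm,
                    scale_max_kpa = KPA_FULL_SCALE,
                    frame_id = map$frame_id), meta)
  jsonlite::write_json(sidecar, paths[2], auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(x_px = roi$contour[, 1],
                              y_px = roi$contour[, 2]),
                   paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a stiffness map written by [write_stiffness_map()]
#'
#' The same reader accepts user-supplied files in the documented layout.
#'
#' @param prefix path prefix used at write time.
#' @return list `map` (a `stiffness_map`), `roi` (a `tumor_roi`), `meta`.
#' @export
read_stiffness_map <- function(prefix) {
  vals <- tiff::readTIFF(paste0(prefix, ".tif"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  contour <- utils::read.csv(paste0(prefix, "_contour.csv"))
  values <- vals * (meta$scale_max_kpa %||% KPA_FULL_SCALE)
  map <- stiffness_map(values, meta$pixel_spacing_mm,
                       frame_id = meta$frame_id %||% NA_character_)
  list(map = map,
       roi = tumor_roi(cbind(contour$x_px, contour$y_px), dim(values)),
       meta = meta)
}

#' Write / read an SHG z-stack as a multi-page float TIFF
#'
#' Intensities are clamped to [0, 1] on write.
#'
#' @param stack rows x cols x slices array.
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
write_shg_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) pmin(pmax(stack[, , k], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname write_shg_stack
#' @export
read_shg_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write / read a trichrome RGB image as PNG
#'
#' PNG quantizes to 8 bits; exact float round trips are only available on
#' the in-memory arrays.
#'
#' @param rgb h x w x 3 array in [0, 255].
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
write_trichrome_png <- function(rgb, path) {
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' @rdname write_trichrome_png
#' @export
read_trichrome_png <- function(path) {
  png::readPNG(path) * 255
}

#' Write / read an expression dataset (TSV + annotation TSV)
#'
#' @param dataset an `expression_dataset`.
#' @param prefix path prefix; writes `<prefix>_expr.tsv` (first column
#'   `gene_id`) and `<prefix>_samples.tsv`.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "expression_dataset"))
  paths <- paste0(prefix, c("_expr.tsv", "_samples.tsv"))
  utils::write.table(data.frame(gene_id = rownames(dataset$mat),
                                dataset$mat, check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- dataset$annotations
  ann$scale <- dataset$scale
  utils::write.table(ann, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' @rdname write_expression
#' @export
read_expression <- function(prefix) {
  tab <- utils::read.delim(paste0(prefix, "_expr.tsv"), check.names = FALSE)
  ann <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$gene_id
  scale <- unique(ann$scale) %||% "linear"
  ann$scale <- NULL
  expression_dataset(mat, ann, scale = scale)
}

#' Write / read a signature list
#'
#' One gene id per line; ids after a `#anticorrelated` marker line form the
#' anti-correlated half.
#'
#' @param signature a `signature_set`.
#' @param path output text path.
#' @return invisibly, `path`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "signature_set"))
  writeLines(c(signature$correlated, "#anticorrelated",
               signature$anticorrelated), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  marker <- which(lines == "#anticorrelated")
  if (length(marker) != 1)
    stop("signature file needs exactly one '#anticorrelated' marker")
  signature_set(correlated = lines[seq_len(marker - 1)],
                anticorrelated = lines[-seq_len(marker)])
}

#' Read a 3 x 3 stain matrix from a small text config
#'
#' Three whitespace-separated rows of three optical-density components
#' (collagen, cytoplasm/nuclei, residual); `#` comment lines are ignored.
#'
#' @param path text file path.
#' @return a `stain_model`.
#' @export
read_stain_model <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  m <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stain_model(m)
}
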