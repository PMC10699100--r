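#' Write an image pair as two 16-bit grayscale TIFF files
#'
#' Writes `<basename>_ref.tif` and `<basename>_tag.tif` under `dir`.
#'
#' @param pair An `image_pair` (see [simulate_image_pair()]).
#' @param dir Output directory (created if missing).
#' @param basename File stem; defaults to the pair's `image_id`.
#' @return Invisibly, a named character vector with paths `ref` and `tag`.
#' @export
write_image_pair <- function(pair, dir, basename = pair$image_id) {
  stopifnot(inherits(pair, "image_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ceiling_val <- 2^pair$bit_depth - 1
  paths <- c(ref = file.path(dir, paste0(basename, "_ref.tif")),
             tag = file.path(dir, paste0(basename, "_tag.tif")))
  tiff::writeTIFF(pair$ref / ceiling_val, paths[["ref"]], bits.per.sample = 16L)
  tiff::writeTIFF(pair$tag / ceiling_val, paths[["tag"]], bits.per.sample = 16L)
  invisible(paths)
}

#' Read a two-channel image pair from single-channel TIFF files
#'
#' @param ref_path,tag_path Paths to 16-bit grayscale TIFFs of identical size.
#' @param image_id Label attached to the returned pair.
#' @param bit_depth Bits per pixel of the stored data.
#' @return An `image_pair` with integer intensity matrices.
#' @export
read_image_pair <- function(ref_path, tag_path, image_id = basename(ref_path),
                            bit_depth = 16L) {
  for (p in c(ref_path, tag_path))
    if (!file.exists(p)) stop("cannot read image: ", p, call. = FALSE)
  read_one <- function(p) {
    m <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # tolerate single-band planar files
    storage.mode(m) <- "integer"
    m
  }
  ref <- read_one(ref_path); tag <- read_one(tag_path)
  if (!identical(dim(ref), dim(tag)))
    stop("channel dimensions differ between ", ref_path, " and ", tag_path,
         call. = FALSE)
  structure(list(ref = ref, tag = tag, bit_depth = as.integer(bit_depth),
                 image_id = image_id),
            class = "image_pair")
}

#' Write a ground-truth JSON sidecar
#'
#' Stores the scalar ground truth of a simulated pair (seed, true rho,
#' gains, backgrounds, detection factors, expected slope) next to its TIFFs
#' so recovery analyses can run without the in-memory object.
#'
#' @param truth A `ground_truth` object.
#' @param path Output path, conventionally `<basename>.truth.json`.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  meta <- list(
    image_id = truth$image_id, antibody_id = truth$antibody_id,
    rho = truth$rho,
    gain_ref = truth$gain_ref, gain_tag = truth$gain_tag,
    background_ref = truth$background_ref, background_tag = truth$background_tag,
    d_ref = truth$d_ref, d_tag = truth$d_tag,
    expected_slope = expected_slope(truth),
    noise_factor = truth$noise_factor,
    n_cells = nrow(truth$cells),
    n_transfected = sum(truth$cells$transfected),
    seed = truth$seed,
    generator = paste0("tagquant ", as.character(utils::packageVersion("tagquant")))
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation configuration from a flat YAML file
#'
#' The file holds a flat mapping whose keys are the arguments of
#' [simulation_config()]; unknown keys are an error, missing keys take the
#' defaults. Explicit arguments in `...` override file values.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, ...) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(simulation_config, vals)
}
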