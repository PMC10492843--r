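#' Default configuration
#'
#' All tunable constants of the analysis in one versioned list: the image
#' pipeline settings, the simulation grid, the slab and blood model
#' constants, and the fitting defaults.
#'
#' @return Nested list of defaults.
#' @export
pel_defaults <- function() {
  list(
    pipeline = unclass(pipeline_config()),
    grid = list(musp_values = seq(10, 35, by = 5),
                sigma_values = seq(0.5, 8, by = 0.5),
                bvf_values = seq(0.004, 0.009, by = 0.001)),
    slab = list(tau = 20, n_inside = 1.35, n_outside = 1.0),
    tissue = list(g_transport = 0.9, hemoglobin_gdl = 15,
                  oxygen_saturation = 1, n_particle = 1.42, n_medium = 1.35,
                  reference_wavelength_nm = 550),
    monte_carlo = list(n_photons = 5e3, wavelengths = mc_wavelengths(),
                       weight_min = 1e-4, roulette_survival = 0.1),
    collagen = list(orientation_window = 5L, variance_window = 33L),
    version = as.character(utils::packageVersion("polgate")))
}

#' Run manifest for provenance
#'
#' Records what was run: command label, configuration snapshot, seeds,
#' package version, input/output file MD5 hashes and a timestamp. Two runs
#' with identical manifests produce identical outputs.
#'
#' @param command Label of the operation.
#' @param config Configuration list actually used.
#' @param seeds Named list/vector of seeds.
#' @param inputs,outputs Character vectors of file paths (hashed if present).
#' @param path Optional JSON output path.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(command, config = pel_defaults(), seeds = list(),
                         inputs = character(), outputs = character(),
                         path = NULL) {
  hash <- function(fs) {
    fs <- fs[file.exists(fs)]
    if (length(fs) == 0) return(NULL)
    as.list(tools::md5sum(fs))
  }
  m <- list(command = command,
            package = "polgate",
            version = as.character(utils::packageVersion("polgate")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            seeds = seeds,
            config = config,
            input_hashes = hash(inputs),
            output_hashes = hash(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(m))
  }
  m
}

#' Read a co/cross TIFF frame pair
#'
#' @param co_path,cross_path TIFF files (any bit depth; values are rescaled
#'   to the stated `bit_depth` digital-number range).
#' @param bit_depth Acquisition bit depth (default 12).
#' @return A [polarized_frame_pair()].
#' @export
read_frame_pair <- function(co_path, cross_path, bit_depth = 12) {
  rd <- function(p) {
    x <- tiff::readTIFF(p)
    if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3))
    x[, , 1:3, drop = FALSE] * (2^bit_depth - 1)
  }
  polarized_frame_pair(rd(co_path), rd(cross_path), bit_depth = bit_depth)
}
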