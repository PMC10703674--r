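#' Write a synthetic dataset to disk as standard-format fixtures
#'
#' The volume is written as two NIfTI files (`intensity.nii.gz` float,
#' `segmentation.nii.gz` integer) with the voxel size in nm carried in the
#' NIfTI pixdim; skeletons as one SWC file per segment; segment labels,
#' node labels and synapses as TSV tables with header rows; and a JSON
#' manifest recording paths, the generator seed and the voxel size.
#'
#' @param synth A `segclr_synth` from [generate_synthetic()].
#' @param dir Output directory (created if missing).
#' @return The manifest as a list, invisibly; also written to
#'   `manifest.json`.
#' @export
write_fixtures <- function(synth, dir) {
  stopifnot(inherits(synth, "segclr_synth"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir)
  }
  if (file.access(dir, mode = 2) != 0) stop("directory not writable: ", dir)
  vs <- synth$volume$voxel_size_nm

  intensity_path <- file.path(dir, "intensity.nii.gz")
  seg_path <- file.path(dir, "segmentation.nii.gz")
  RNifti::writeNifti(
    RNifti::asNifti(synth$volume$intensity, pixdim = vs), intensity_path)
  RNifti::writeNifti(
    RNifti::asNifti(synth$volume$segmentation, pixdim = vs,
                    datatype = "int32"), seg_path)

  skel_dir <- file.path(dir, "skeletons")
  dir.create(skel_dir, showWarnings = FALSE)
  skel_paths <- purrr::map_chr(synth$skeletons, function(s) {
    p <- file.path(skel_dir, sprintf("segment_%d.swc", s$segment_id))
    write_swc(s, p)
    p
  })

  labels_path <- file.path(dir, "labels.tsv")
  readr::write_tsv(synth$labels, labels_path)
  node_labels_path <- file.path(dir, "node_labels.tsv")
  readr::write_tsv(synth$node_labels, node_labels_path)
  synapses_path <- file.path(dir, "synapses.tsv")
  readr::write_tsv(synth$synapses, synapses_path)

  manifest <- list(
    seed = synth$config$seed,
    voxel_size_nm = vs,
    volume_shape = dim(synth$volume$intensity),
    intensity = basename(intensity_path),
    segmentation = basename(seg_path),
    skeletons = file.path("skeletons", basename(unname(skel_paths))),
    labels = basename(labels_path),
    node_labels = basename(node_labels_path),
    synapses = basename(synapses_path)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read fixtures written by [write_fixtures()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A list shaped like a `segclr_synth` (volume, skeletons, labels,
#'   node_labels, synapses, seed).
#' @export
read_fixtures <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  img <- RNifti::readNifti(file.path(dir, manifest$intensity))
  seg <- RNifti::readNifti(file.path(dir, manifest$segmentation))
  vs <- as.numeric(manifest$voxel_size_nm)
  vol <- segmented_volume(array(as.numeric(img), dim = dim(img)),
                          array(as.integer(seg), dim = dim(seg)), vs)
  skels <- purrr::map(manifest$skeletons,
                      function(p) read_swc(file.path(dir, p)))
  names(skels) <- purrr::map_chr(skels, function(s) as.character(s$segment_id))
  labels <- readr::read_tsv(file.path(dir, manifest$labels),
                            show_col_types = FALSE)
  node_labels <- readr::read_tsv(file.path(dir, manifest$node_labels),
                                 show_col_types = FALSE)
  synapses <- readr::read_tsv(file.path(dir, manifest$synapses),
                              show_col_types = FALSE)
  list(volume = vol, skeletons = skels, labels = labels,
       node_labels = node_labels, synapses = synapses,
       seed = manifest$seed)
}
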