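#' Write / read a parcel vector as TSV
#'
#' @param x named numeric vector (names = parcel ids).
#' @param path file path.
#' @param units free-text units recorded as a column.
#' @export
write_parcel_vector <- function(x, path, units = "") {
  utils::write.table(
    data.frame(parcel_id = names(x), value = as.numeric(x), units = units),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcel_vector
#' @export
read_parcel_vector <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(d$value, d$parcel_id)
}

#' Write a volume map to NIfTI
#'
#' @param map a [volume_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume_nifti <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param kind map kind for the reconstructed object.
#' @export
read_volume_nifti <- function(path, kind = "frequency_percent") {
  img <- RNifti::readNifti(path)
  volume_map(array(as.numeric(img), dim(img)),
             RNifti::pixdim(img)[1:3], kind = kind)
}

#' Write the parcel metadata table as TSV
#' @param parc a [make_parcellation()].
#' @param path file path.
#' @export
write_parcel_table <- function(parc, path) {
  utils::write.table(parc$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write plain-text gene sets (one identifier per line)
#' @param path file path.
#' @param name set name (defaults to the file name).
#' @export
read_gene_set <- function(path, name = basename(path)) {
  gene_set(name, readLines(path))
}

#' @rdname read_gene_set
#' @param set a [gene_set()].
#' @export
write_gene_set <- function(set, path) {
  writeLines(set$gene_ids, path)
  invisible(path)
}

#' Write a spin ensemble as a compact integer table
#'
#' One row per spin; columns are parcel positions; entries are donor
#' positions (1-based) within the ensemble scope.
#'
#' @param ens a [build_spin_ensemble()].
#' @param path file path (TSV).
#' @export
write_spin_ensemble <- function(ens, path) {
  utils::write.table(ens$permutations, path, sep = "\t",
                     row.names = FALSE, col.names = ens$parcel_ids)
  invisible(path)
}

#' Write a spin-test result as JSON
#' @param res a [spin_correlation_test()] result.
#' @param path file path.
#' @export
write_spin_result <- function(res, path) {
  jsonlite::write_json(
    list(rho = res$rho_observed, p_spin = res$p_spin,
         n_spins = res$n_spins, sidedness = res$sidedness,
         direction = res$direction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a bootstrap gene ranking as TSV
#'
#' Full ranked lists (gene_id, z and rank per component), suitable for
#' ranked-list gene-ontology tools.
#'
#' @param r a [bootstrap_gene_z()] ranking.
#' @param path file path.
#' @export
write_gene_ranking <- function(r, path) {
  utils::write.table(r[order(r$rank1), ], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
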