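#' Parcellation atlas
#'
#' Couples an integer label volume with a registry of volumes of interest
#' (VOIs). Label 0 is background and never contributes to any feature. Each
#' row of `voi_table` describes one VOI; left/right homologues are linked
#' through a shared `pair_id`, which is what defines the asymmetry features.
#'
#' @param label_volume 3D integer array; 0 = background, k > 0 = VOI id.
#' @param voi_table Data frame with columns `voi_id` (integer), `name`
#'   (character), `hemisphere` (one of `"left"`, `"right"`, `"midline"`) and
#'   `pair_id` (integer or `NA`; a pair id must link exactly one left VOI to
#'   exactly one right VOI).
#'
#' @return An object of class `parcellation_atlas`: a list with elements
#'   `label_volume`, `voi_table` (tibble) and `pairs` (tibble with columns
#'   `pair_id`, `left_voi`, `right_voi`, ordered by `pair_id`).
#' @export
#' @examples
#' lab <- array(0L, c(4, 2, 2))
#' lab[1, , ] <- 1L; lab[4, , ] <- 2L
#' atl <- parcellation_atlas(lab, data.frame(
#'   voi_id = 1:2, name = c("roi_L", "roi_R"),
#'   hemisphere = c("left", "right"), pair_id = c(1L, 1L)))
#' atl$pairs
parcellation_atlas <- function(label_volume, voi_table) {
  if (length(dim(label_volume)) != 3L)
    abort("`label_volume` must be a 3D array.")
  storage.mode(label_volume) <- "integer"
  voi_table <- tibble::as_tibble(voi_table)
  req <- c("voi_id", "name", "hemisphere")
  if (!all(req %in% names(voi_table)))
    abort(paste0("`voi_table` must have columns: ", paste(req, collapse = ", "), "."))
  if (!"pair_id" %in% names(voi_table)) voi_table$pair_id <- NA_integer_
  voi_table$voi_id <- as.integer(voi_table$voi_id)
  voi_table$pair_id <- as.integer(voi_table$pair_id)
  if (anyDuplicated(voi_table$voi_id))
    abort("Duplicate voi_id in `voi_table`.")
  if (nrow(voi_table) < 2L)
    abort("An atlas needs at least 2 VOIs.")
  bad_h <- setdiff(unique(voi_table$hemisphere), c("left", "right", "midline"))
  if (length(bad_h))
    abort(paste0("Unknown hemisphere value(s): ", paste(bad_h, collapse = ", "), "."))
  labs <- setdiff(unique(as.vector(label_volume)), 0L)
  missing <- setdiff(labs, voi_table$voi_id)
  if (length(missing))
    abort(paste0("Label(s) in volume absent from voi_table: ",
                 paste(sort(missing), collapse = ", "), "."))
  pairs <- build_pair_registry(voi_table)
  structure(list(label_volume = label_volume, voi_table = voi_table, pairs = pairs),
            class = "parcellation_atlas")
}

build_pair_registry <- function(voi_table) {
  pt <- voi_table[!is.na(voi_table$pair_id), , drop = FALSE]
  if (nrow(pt) == 0L)
    return(tibble::tibble(pair_id = integer(), left_voi = integer(),
                          right_voi = integer(), name = character()))
  out <- lapply(split(pt, pt$pair_id), function(g) {
    l <- g$voi_id[g$hemisphere == "left"]
    r <- g$voi_id[g$hemisphere == "right"]
    if (length(l) != 1L || length(r) != 1L)
      abort(paste0("pair_id ", g$pair_id[1],
                   " must link exactly one left VOI to exactly one right VOI."))
    tibble::tibble(pair_id = g$pair_id[1], left_voi = l, right_voi = r,
                   name = sub("_L$|_left$", "", g$name[g$hemisphere == "left"]))
  })
  out <- dplyr::bind_rows(out)
  dplyr::arrange(out, .data$pair_id)
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat("<parcellation_atlas> ", nrow(x$voi_table), " VOIs (",
      nrow(x$pairs), " left-right pairs), label volume ",
      paste(dim(x$label_volume), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Read an atlas from a NIfTI label volume and a VOI table
#'
#' @param label_path Path to a NIfTI (.nii / .nii.gz) integer label volume.
#' @param voi_table_path Path to a tab-separated VOI table with columns
#'   `voi_id`, `name`, `hemisphere`, `pair_id` (empty pair_id = unpaired).
#' @return A [parcellation_atlas()].
#' @export
read_atlas <- function(label_path, voi_table_path) {
  vol <- as.array(RNifti::readNifti(label_path))
  tab <- read.delim(voi_table_path, sep = "\t", stringsAsFactors = FALSE)
  parcellation_atlas(vol, tab)
}

#' Write an atlas to a NIfTI label volume and a TSV VOI table
#'
#' @param atlas A [parcellation_atlas()].
#' @param label_path,voi_table_path Output paths (.nii/.nii.gz and .tsv).
#' @return `atlas`, invisibly.
#' @export
write_atlas <- function(atlas, label_path, voi_table_path) {
  RNifti::writeNifti(RNifti::asNifti(atlas$label_volume), label_path)
  utils::write.table(atlas$voi_table, voi_table_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(atlas)
}
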