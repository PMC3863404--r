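#' Read a multiecho stack from NIfTI
#'
#' Reads a 3D NIfTI file whose third axis indexes echoes, together with an
#' echo-time sidecar: either a JSON file with an `EchoTimes` array (ms) or a
#' plain text file with one TE per line. If `te` is omitted, a sidecar next
#' to the image (`<stem>.json`, then `<stem>.te.txt`) is used. Frames are
#' reordered to ascending TE on read, so the returned stack always
#' satisfies the container's invariants regardless of storage order.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param te Echo times in ms: a numeric vector, a sidecar file path, or
#'   `NULL` to auto-locate the sidecar.
#' @return An [echo_stack()].
#' @export
read_echo_stack <- function(path, te = NULL) {
  if (!file.exists(path)) stop("cannot read `", path, "`", call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L)
    stop("`", path, "` is not a 3D image (got ",
         length(dim(arr)), " dimensions)", call. = FALSE)
  te_ms <- if (is.numeric(te)) as.double(te) else .read_te_sidecar(path, te)
  if (length(te_ms) != dim(arr)[3])
    stop("TE count (", length(te_ms), ") does not match echo frames (",
         dim(arr)[3], ")", call. = FALSE)
  ord <- order(te_ms)
  if (anyDuplicated(te_ms))
    stop("echo times contain duplicates; ordering is unresolvable",
         call. = FALSE)
  echo_stack(arr[, , ord, drop = FALSE], te_ms[ord])
}

.read_te_sidecar <- function(image_path, te_path) {
  if (is.null(te_path)) {
    stem <- sub("\\.nii(\\.gz)?$", "", image_path)
    cand <- c(paste0(stem, ".json"), paste0(stem, ".te.txt"))
    te_path <- cand[file.exists(cand)][1]
    if (is.na(te_path))
      stop("no TE sidecar found next to `", image_path,
           "` (looked for ", paste(basename(cand), collapse = ", "), ")",
           call. = FALSE)
  }
  if (!file.exists(te_path))
    stop("cannot read TE sidecar `", te_path, "`", call. = FALSE)
  if (grepl("\\.json$", te_path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(te_path, simplifyVector = TRUE)
    te <- j[["EchoTimes"]]
    if (is.null(te))
      stop("TE sidecar `", te_path, "` has no `EchoTimes` array",
           call. = FALSE)
    as.double(te)
  } else {
    as.double(utils::read.table(te_path)[[1]])
  }
}

#' Write a multiecho stack to NIfTI with a TE sidecar
#'
#' Writes the intensities as a 3D NIfTI (float64, so values round-trip
#' exactly) and the echo times as a JSON sidecar `<stem>.json` with an
#' `EchoTimes` array in ms.
#'
#' @param stack An [echo_stack()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_echo_stack <- function(stack, path) {
  stopifnot(inherits(stack, "echo_stack"))
  img <- RNifti::asNifti(stack$intensities, datatype = "double")
  RNifti::writeNifti(img, path)
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  # 17 significant digits: IEEE doubles round-trip exactly through text
  jsonlite::write_json(list(EchoTimes = stack$te_ms), sidecar,
                       auto_unbox = FALSE, digits = I(17))
  invisible(path)
}

#' Write a parametric map to NIfTI
#'
#' Writes the map as a single-slice float64 NIfTI. Invalid pixels are
#' written as NaN and the map kind is recorded in the NIfTI `descrip`
#' header field (`kind=SSM` etc.), from where [read_map()] restores it.
#'
#' @param map A [parametric_map()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "parametric_map"))
  v <- unclass(map)
  attr(v, "kind") <- NULL
  v[is.na(v)] <- NaN
  img <- RNifti::asNifti(v, datatype = "double")
  img$descrip <- paste0("kind=", map_kind(map))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read `", path, "`", call. = FALSE)
  img <- RNifti::readNifti(path)
  descrip <- RNifti::niftiHeader(img)$descrip
  kind <- sub("^kind=", "", descrip)
  if (!kind %in% c("SSM", "FMM", "SCM", "T2STAR", "W"))
    stop("`", path, "` has no recognised map kind in its descrip field",
         call. = FALSE)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) dim(arr) <- dim(arr)[1:2]
  parametric_map(arr, kind)
}

#' Read a phantom specification from a YAML config
#'
#' Plain key-value format: top-level `shape`, `te_ms` (optional),
#' `noise: {model, sigma}`, `seed`, and a `regions` list whose entries have
#' a `type` (`disk` / `rect` / `line`), geometry fields matching the
#' [phantom_regions] constructors, `w` and `t2star_ms`. The bundled
#' example is at `system.file("extdata", "vein_phantom.yaml", package =
#' "echomap")`.
#'
#' @param path YAML file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_config <- function(path) {
  if (!file.exists(path)) stop("cannot read `", path, "`", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  regions <- lapply(cfg$regions, function(r) {
    switch(as.character(r$type),
      disk = region_disk(unlist(r$center), r$radius, r$w, r$t2star_ms),
      rect = region_rect(unlist(r$row_range), unlist(r$col_range),
                         r$w, r$t2star_ms),
      line = region_line(unlist(r$from), unlist(r$to),
                         thickness = if (is.null(r$thickness)) 1 else r$thickness,
                         w = r$w, t2star_ms = r$t2star_ms),
      stop("unknown region type `", r$type, "`", call. = FALSE))
  })
  phantom_spec(shape = unlist(cfg$shape), regions = regions,
               te_ms = if (is.null(cfg$te_ms)) te_schedule()
                       else unlist(cfg$te_ms),
               noise_model = if (is.null(cfg$noise$model)) "none"
                             else cfg$noise$model,
               noise_sigma = if (is.null(cfg$noise$sigma)) 0
                             else cfg$noise$sigma,
               seed = cfg$seed)
}

#' Write an optimization trace or contrast report to CSV
#'
#' `write_trace_csv()` writes the T2* sweep (columns `t2star_ms`,
#' `ci_ssm`, `ci_fmm`, `objective`). `write_contrast_csv()` writes the CI
#' table and the CII table stacked in one file with a `table` column.
#'
#' @param trace An `optimization_trace` from [optimize_reference()].
#' @param report A `contrast_report` from [contrast_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "optimization_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
write_contrast_csv <- function(report, path) {
  stopifnot(inherits(report, "contrast_report"))
  ci <- data.frame(table = "ci", label = report$ci$label,
                   original = NA_character_, value = report$ci$ci)
  cii <- data.frame(table = "cii", label = report$cii$map,
                    original = report$cii$original, value = report$cii$cii)
  mean_cii <- data.frame(table = "mean_cii", label = names(report$mean_cii),
                         original = NA_character_,
                         value = as.vector(report$mean_cii))
  utils::write.csv(rbind(ci, cii, mean_cii), path, row.names = FALSE)
  invisible(path)
}
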