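#' Read a diffusion-weighted dataset
#'
#' Loads a 4-D NIfTI diffusion series with FSL-convention bvals/bvecs text
#' files and a binary brain mask, and validates their mutual consistency.
#'
#' @param image_path path to the 4-D NIfTI image.
#' @param bval_path path to the FSL bvals file (one whitespace-delimited row).
#' @param bvec_path path to the FSL bvecs file (three rows: x, y, z).
#' @param mask_path path to a 3-D NIfTI mask (nonzero = included).
#' @return an object of class \code{dwi_dataset} with elements
#'   \code{volumes} (4-D array), \code{bvals}, \code{bvecs} (3 x n matrix)
#'   and \code{mask} (3-D logical array).
#' @export
read_dwi <- function(image_path, bval_path, bvec_path, mask_path) {
  for (p in c(image_path, bval_path, bvec_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  vols <- as.array(img)
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  # NIfTI readers drop trailing singleton dimensions; restore the 4-D
  # (x, y, z, volume) layout using the volume count from the bvals
  vols <- restore_dims(vols, 4L, n_last = length(bvals))
  if (length(dim(vols)) != 4L)
    stop("image is not a 4-D volume series: ", image_path)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3L)
    stop("bvec file must have three rows (x, y, z): ", bvec_path)
  mask <- restore_dims(as.array(RNifti::readNifti(mask_path)), 3L) != 0
  if (length(dim(mask)) != 3L)
    stop("mask is not a 3-D volume: ", mask_path)
  dwi_dataset(vols, bvals, bvecs, mask,
              sources = c(image = image_path, bval = bval_path,
                          bvec = bvec_path, mask = mask_path))
}

# re-insert singleton spatial dimensions dropped on disk round trips
restore_dims <- function(a, ndim, n_last = NULL) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  if (length(d) >= ndim) return(a)
  if (!is.null(n_last) && d[length(d)] == n_last && length(d) > 1L) {
    spatial <- d[-length(d)]
    d <- c(spatial, rep(1L, ndim - length(d)), n_last)
  } else {
    d <- c(d, rep(1L, ndim - length(d)))
  }
  dim(a) <- d
  a
}

#' Construct and validate a DWI dataset
#'
#' @param volumes 4-D numeric array (x, y, z, volume).
#' @param bvals per-volume b-values (s/mm^2).
#' @param bvecs 3 x n matrix of unit gradient directions (zero columns allowed
#'   for b=0 volumes).
#' @param mask 3-D logical array on the same spatial grid.
#' @param sources optional named character vector recording file provenance.
#' @return a \code{dwi_dataset} object.
#' @export
dwi_dataset <- function(volumes, bvals, bvecs, mask, sources = NULL) {
  dims <- dim(volumes)
  n_vol <- dims[4]
  if (length(bvals) != n_vol)
    stop(sprintf("bval count mismatch: %d b-values for %d volumes",
                 length(bvals), n_vol))
  if (ncol(bvecs) != n_vol)
    stop(sprintf("bvec count mismatch: %d directions for %d volumes",
                 ncol(bvecs), n_vol))
  if (any(!is.finite(volumes)))
    stop("non-finite voxel values in image data")
  if (any(bvals < 0)) stop("negative b-values")
  norms <- sqrt(colSums(bvecs^2))
  nonzero <- norms > 0
  if (any(abs(norms[nonzero] - 1) > 1e-3))
    stop("non-unit gradient directions (|norm - 1| > 1e-3)")
  if (!identical(dim(mask), dims[1:3]))
    stop("mask grid does not match image grid")
  structure(
    list(volumes = volumes, bvals = as.numeric(bvals),
         bvecs = bvecs, mask = array(as.logical(mask), dims[1:3]),
         sources = sources),
    class = "dwi_dataset"
  )
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("DWI dataset: %d x %d x %d grid, %d volumes, %d masked voxels\n",
              d[1], d[2], d[3], d[4], sum(x$mask)))
  print(group_shells(x$bvals)$scheme)
  invisible(x)
}

#' Per-shell mean signal matrix
#'
#' Averages the diffusion-weighted volumes of each shell at every masked
#' voxel, producing the N_s x N_v matrix that drives the basis decomposition.
#' Voxels are ordered by a row-major scan of the mask in image index order
#' (column-major in R's array storage, i.e. \code{which(mask)}), recorded so
#' weight maps can be re-embedded into image space.
#'
#' @param dataset a \code{dwi_dataset}.
#' @param scheme optionally a pre-computed [shell_scheme()] with matching
#'   per-volume assignment (as returned by [group_shells()]); by default
#'   shells are grouped from the dataset's bvals.
#' @param tolerance shell-grouping tolerance passed to [group_shells()].
#' @return a \code{mean_signal_matrix}: list with \code{D} (shells x voxels),
#'   \code{scheme}, \code{voxel_index} (linear indices into the image grid)
#'   and \code{provenance} (subject identifiers).
#' @export
shell_mean_signal <- function(dataset, scheme = NULL, tolerance = 50) {
  if (!inherits(dataset, "dwi_dataset")) stop("dataset must be a dwi_dataset")
  grp <- group_shells(dataset$bvals, tolerance)
  if (!is.null(scheme)) {
    if (!isTRUE(all.equal(scheme$bvalues, grp$scheme$bvalues)))
      stop("supplied scheme does not match the dataset's shell structure")
    grp$scheme <- scheme
  }
  idx <- which(dataset$mask)
  if (length(idx) == 0L) stop("empty mask: no voxels to average")
  d <- dim(dataset$volumes)
  flat <- matrix(dataset$volumes, nrow = prod(d[1:3]), ncol = d[4])
  vox <- flat[idx, , drop = FALSE]              # N_v x N_vol
  n_s <- length(grp$scheme$bvalues)
  D <- matrix(0, n_s, length(idx))
  for (s in seq_len(n_s)) {
    cols <- grp$shell_index == s
    D[s, ] <- rowMeans(vox[, cols, drop = FALSE])
  }
  mean_signal_matrix(D, grp$scheme,
                     provenance = list(subjects = "subject1",
                                       voxel_index = idx))
}

#' Construct a mean-signal matrix
#'
#' @param D numeric matrix, shells x voxels, of per-shell mean DW signal.
#' @param scheme the [shell_scheme()] the rows correspond to.
#' @param provenance list of metadata (subject identifiers, voxel ordering).
#' @return a \code{mean_signal_matrix} object.
#' @export
mean_signal_matrix <- function(D, scheme, provenance = list()) {
  D <- as.matrix(D)
  if (nrow(D) != length(scheme$bvalues))
    stop("row count of D must equal the number of shells in the scheme")
  if (any(!is.finite(D))) stop("non-finite entries in mean-signal matrix")
  if (any(D < 0)) stop("negative mean signals")
  structure(list(D = D, scheme = scheme, provenance = provenance),
            class = "mean_signal_matrix")
}

#' @export
print.mean_signal_matrix <- function(x, ...) {
  cat(sprintf("Mean DW signal matrix: %d shells x %d voxels\n",
              nrow(x$D), ncol(x$D)))
  cat("b-values:", paste(round(x$scheme$bvalues), collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' Pool mean-signal matrices across subjects
#'
#' Concatenates the voxel columns of several subjects' matrices, as in a
#' combined multi-subject analysis. All inputs must share identical shell
#' b-values.
#'
#' @param ... \code{mean_signal_matrix} objects, or a single list of them.
#' @return the pooled \code{mean_signal_matrix}; provenance records subject
#'   order and per-subject voxel counts.
#' @export
pool_subjects <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && !inherits(mats[[1]], "mean_signal_matrix"))
    mats <- mats[[1]]
  if (!all(vapply(mats, inherits, logical(1), "mean_signal_matrix")))
    stop("all inputs must be mean_signal_matrix objects")
  b0 <- mats[[1]]$scheme$bvalues
  for (m in mats[-1])
    if (!isTRUE(all.equal(m$scheme$bvalues, b0)))
      stop("mismatched shell schemes: all subjects must share the same b-values")
  D <- do.call(cbind, lapply(mats, `[[`, "D"))
  subj <- unlist(lapply(seq_along(mats), function(i) {
    s <- mats[[i]]$provenance$subjects
    if (is.null(s)) paste0("subject", i) else s
  }))
  mean_signal_matrix(D, mats[[1]]$scheme,
                     provenance = list(subjects = subj,
                                       n_voxels = vapply(mats, function(m)
                                         ncol(m$D), numeric(1))))
}

#' Write / read a mean-signal matrix as CSV
#'
#' The CSV holds one row per shell with a header row of b-values; a JSON
#' sidecar (\code{<path>.json}) carries the scheme counts and provenance.
#'
#' @param x a \code{mean_signal_matrix}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_mean_signal <- function(x, path) {
  tab <- as.data.frame(t(x$D))
  names(tab) <- paste0("b", format(x$scheme$bvalues, trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(bvalues = x$scheme$bvalues, counts = x$scheme$counts,
               subjects = x$provenance$subjects)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mean_signal
#' @param counts per-shell volume counts to attach when no JSON sidecar is
#'   present (defaults to 1 per shell).
#' @export
read_mean_signal <- function(path, counts = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  bvalues <- as.numeric(sub("^b", "", names(tab)))
  D <- t(as.matrix(tab))
  sidecar <- paste0(path, ".json")
  subjects <- NULL
  if (is.null(counts) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    counts <- meta$counts
    subjects <- meta$subjects
  }
  if (is.null(counts)) counts <- rep(1L, length(bvalues))
  mean_signal_matrix(D, shell_scheme(bvalues, counts),
                     provenance = list(subjects = subjects))
}
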