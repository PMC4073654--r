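#' Read a NIfTI image series into a response matrix
#'
#' Accepts one 4D NIfTI path (volumes = scans) or a character vector of 3D
#' paths, plus a 3D mask. Every image must match the mask's dimensions and
#' affine (tolerance 1e-4). Rows of the returned matrix are in scan order;
#' use [align_scans()] to permute them into a design's canonical order —
#' alignment must come from an explicit design-table row order, never from
#' file-system ordering.
#'
#' @param paths 4D NIfTI path or vector of 3D paths.
#' @param mask 3D NIfTI path (nonzero = in analysis).
#' @return list with `Y` (scans x in-mask voxels), `mask` (logical array),
#'   `idx` (in-mask linear indices), `dim`, and `ref` (the mask image, kept
#'   as geometry reference for writing maps).
#' @export
read_images <- function(paths, mask) {
  mimg <- RNifti::readNifti(mask)
  mdim <- dim(mimg)
  if (length(mdim) != 3) stop("mask must be a 3D image")
  maff <- RNifti::xform(mimg)
  keep <- as.array(mimg) != 0
  idx <- which(keep)
  if (!length(idx)) stop("empty mask")
  vols <- list()
  for (p in paths) {
    img <- RNifti::readNifti(p)
    d <- dim(img)
    if (!all(d[1:3] == mdim))
      stop("image ", p, " dimensions do not match the mask")
    if (max(abs(RNifti::xform(img) - maff)) > 1e-4)
      stop("image ", p, " affine does not match the mask")
    a <- as.array(img)
    if (length(d) == 4) {
      for (t in seq_len(d[4])) vols[[length(vols) + 1L]] <- a[, , , t][idx]
    } else if (length(d) == 3) {
      vols[[length(vols) + 1L]] <- a[idx]
    } else stop("image ", p, " must be 3D or 4D")
  }
  Y <- do.call(rbind, vols)
  storage.mode(Y) <- "double"
  list(Y = Y, mask = keep, idx = idx, dim = mdim, ref = mimg)
}

#' Voxelwise sandwich-estimator analysis
#'
#' Runs the full pipeline — OLS fit, robust covariance, effective-df Wald
#' test — independently at every voxel, in batches of columns to bound
#' memory. Voxel-independent quantities (normal equations, leverages,
#' contrast projections) are computed once; results are identical for any
#' batch size. Per-voxel numerical failures become NaN with a logged count;
#' more than `max_fail_frac` failures aborts.
#'
#' @param design an `swe_design`.
#' @param Y n x V response matrix in design row order (see [align_scans()]),
#'   or the list returned by [read_images()] (assumed already aligned).
#' @param contrasts named list of contrasts (vectors/matrices or keywords,
#'   see [resolve_contrast()]).
#' @param variant,adjustment see [swe_fit()].
#' @param dof "effective" or "naive".
#' @param batch_size voxels per batch.
#' @param max_fail_frac failure fraction triggering an abort.
#' @return list: `beta` (p x V), and per contrast a list with `stat`, `p`,
#'   `nu`, `df1` vectors (and `t` for rank-1 contrasts); plus `n_failed`.
#' @export
run_voxelwise <- function(design, Y, contrasts,
                          variant = c("hom", "het"),
                          adjustment = c("S3", "S0", "S1", "S2"),
                          dof = c("effective", "naive"),
                          batch_size = 5000L, max_fail_frac = 0.01) {
  variant <- match.arg(variant)
  adjustment <- match.arg(adjustment)
  dof <- match.arg(dof)
  if (is.list(Y) && !is.null(Y$Y)) Y <- Y$Y
  Y <- .as_response(design, Y)
  V <- ncol(Y)
  if (is.null(names(contrasts)))
    names(contrasts) <- paste0("c", seq_along(contrasts))
  Cs <- lapply(contrasts, function(k)
    .as_contrast(resolve_contrast(design, k), design$p))

  beta <- matrix(NA_real_, design$p, V)
  res <- lapply(Cs, function(C) {
    q <- nrow(C)
    r <- list(stat = rep(NaN, V), p = rep(NaN, V), nu = rep(NaN, V),
              df1 = q)
    if (q == 1) r$t <- rep(NaN, V)
    r
  })
  n_failed <- 0L
  starts <- seq(1L, V, by = batch_size)
  for (s in starts) {
    cols <- s:min(s + batch_size - 1L, V)
    fit <- swe_fit(design, Y[, cols, drop = FALSE], variant = variant,
                   adjustment = adjustment)
    beta[, cols] <- fit$beta
    for (cn in names(Cs)) {
      C <- Cs[[cn]]
      q <- nrow(C)
      nu <- if (dof == "naive") rep(naive_dof(design)$nu, length(cols))
        else suppressWarnings(estimate_dof(fit, C)$nu)
      cb <- C %*% fit$beta
      CSC <- .contrast_cov(fit, C)
      if (q == 1) {
        csc <- as.numeric(CSC)
        ok <- is.finite(csc) & csc > 0 & is.finite(nu)
        tt <- ifelse(ok, as.numeric(cb) / sqrt(csc), NaN)
        res[[cn]]$t[cols] <- tt
        res[[cn]]$stat[cols] <- tt^2
        res[[cn]]$nu[cols] <- nu
        res[[cn]]$p[cols] <- ifelse(ok, 2 * stats::pt(-abs(tt), df = nu), NaN)
        n_failed <- n_failed + sum(!ok)
      } else {
        for (j in seq_along(cols)) {
          W <- matrix(CSC[, j], q, q)
          ok <- all(is.finite(W)) && rcond(W) > 1e-14 && is.finite(nu[j]) &&
            nu[j] - q + 1 > 0
          if (!ok) { n_failed <- n_failed + 1L; next }
          Fv <- ((nu[j] - q + 1) / (nu[j] * q)) *
            sum(cb[, j] * solve(W, cb[, j]))
          res[[cn]]$stat[cols[j]] <- Fv
          res[[cn]]$nu[cols[j]] <- nu[j]
          res[[cn]]$p[cols[j]] <-
            stats::pf(Fv, q, nu[j] - q + 1, lower.tail = FALSE)
        }
      }
    }
  }
  if (n_failed > 0)
    message("voxelwise analysis: ", n_failed, " voxel-contrast failure(s)")
  if (n_failed > max_fail_frac * V * length(Cs))
    stop("more than ", 100 * max_fail_frac,
         "% of voxels failed; check design and data (failures: ", n_failed,
         ")")
  c(list(beta = beta, n_failed = n_failed, contrasts = Cs), results = list(res))
}

#' Write voxelwise results as NIfTI maps
#'
#' One volume per contrast and quantity, named
#' `<prefix>_<contrast>_{tstat|fstat|p|nu}.nii.gz`, using the mask image as
#' geometry reference. Out-of-mask voxels are 0.
#'
#' @param vox result of [run_voxelwise()].
#' @param geom the list returned by [read_images()] (for `mask`/`ref`).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param float32 write single-precision volumes.
#' @return invisibly, the written paths.
#' @export
write_stat_maps <- function(vox, geom, dir, prefix = "swe",
                            float32 = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(values, name) {
    a <- array(0, dim = geom$dim)
    a[geom$idx] <- ifelse(is.finite(values), values, 0)
    f <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    img <- RNifti::asNifti(a, reference = geom$ref)
    RNifti::writeNifti(img, f,
                       datatype = if (float32) "float" else "double")
    paths <<- c(paths, f)
  }
  for (cn in names(vox$results)) {
    r <- vox$results[[cn]]
    if (!is.null(r$t)) put(r$t, paste0(cn, "_tstat"))
    put(r$stat, paste0(cn, "_fstat"))
    put(r$p, paste0(cn, "_p"))
    put(r$nu, paste0(cn, "_nu"))
  }
  invisible(paths)
}
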