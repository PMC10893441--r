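#' Classical calibration-transfer maps
#'
#' `fit_ds()`, `fit_pds()` and `fit_sst()` relate a set of transfer standards
#' measured on both instruments. All three return a `"transfer_map"` object:
#' an affine operator taking slave-instrument spectra to the master-instrument
#' channel space, applied with [predict.transfer_map()] (or the
#' [apply_transfer()] alias). The standards must be physically paired (row i
#' of `master_std` and `slave_std` is the same sample) but may live on grids
#' of different channel counts — DS and SST fit the rectangular slave-to-master
#' map directly; PDS matches windows by nearest wavelength.
#'
#' Direct standardization solves `slave %*% F ~ master` by ridge-regularized
#' least squares, one global linear map. The ridge default
#' `1e-8 * mean diagonal of the slave cross-product` keeps the solve
#' well-posed when there are fewer standards than channels.
#'
#' @param master_std,slave_std paired [spectra_set()]s of transfer standards.
#' @param ridge non-negative ridge penalty added to the normal equations;
#'   `NULL` uses the trace-scaled default (suited to noiseless standards),
#'   `"gcv"` selects the penalty by generalized cross-validation on the
#'   standards — the right choice for noisy standards, where an
#'   under-regularized map develops a variance peak as the standard count
#'   approaches the channel count.
#' @return A `"transfer_map"` object.
#' @rdname transfer_map
#' @export
fit_ds <- function(master_std, slave_std, ridge = NULL) {
  check_standards(master_std, slave_std)
  X <- slave_std$absorbance
  Y <- master_std$absorbance
  G <- crossprod(X)
  if (identical(ridge, "gcv")) {
    ridge <- gcv_ridge(X, Y)
  } else if (is.null(ridge)) {
    ridge <- 1e-8 * mean(diag(G))
  }
  Fmat <- solve(G + diag(ridge, ncol(X)), crossprod(X, Y))
  new_transfer_map("DS", Fmat, intercept = rep(0, ncol(Y)),
                   slave_grid = slave_std$grid, master_grid = master_std$grid,
                   meta = list(n_standards = nrow(X), ridge = ridge))
}

# Generalized cross-validation for the ridge penalty of a multiresponse
# least-squares map Y ~ X F: GCV(lambda) = n * ||Y - Hat Y||_F^2 /
# (n - tr(Hat))^2 with Hat the ridge hat matrix, evaluated over a log grid
# scaled by the spectrum of X'X.
gcv_ridge <- function(X, Y) {
  n <- nrow(X)
  sv <- svd(X, nu = min(n, ncol(X)), nv = 0)
  d2 <- sv$d^2
  UY <- crossprod(sv$u, Y)           # projections of Y on left singular vectors
  ss_tot <- sum(Y^2)
  grid <- mean(d2) * 10^seq(-10, 0, length.out = 25)
  best <- Inf; best_l <- grid[1]
  for (l in grid) {
    shrink <- d2 / (d2 + l)
    # residual sum of squares: components along U shrink, the rest untouched
    rss <- sum((1 - shrink)^2 * rowSums(UY^2)) + (ss_tot - sum(UY^2))
    df <- sum(shrink)
    g <- n * rss / (n - df)^2
    if (is.finite(g) && g < best) {
      best <- g; best_l <- l
    }
  }
  best_l
}

#' @param half_window PDS half-window in slave channels: master channel j is
#'   regressed on the slave channels within `half_window` of its nearest
#'   slave wavelength. `0` gives per-channel slope correction.
#' @rdname transfer_map
#' @export
fit_pds <- function(master_std, slave_std, half_window = 5L, ridge = NULL) {
  check_standards(master_std, slave_std)
  X <- slave_std$absorbance
  Y <- master_std$absorbance
  p_s <- ncol(X)
  if (!is.numeric(half_window) || half_window < 0 || half_window != round(half_window)) {
    stop_nirshift("half_window must be a non-negative integer", "nirshift_argument_error")
  }
  if (half_window >= p_s) {
    stop_nirshift("half_window must be smaller than the slave channel count",
                  "nirshift_argument_error")
  }
  Fmat <- matrix(0, p_s, ncol(Y))
  intercept <- numeric(ncol(Y))
  slave_wl <- as.numeric(slave_std$grid)
  master_wl <- as.numeric(master_std$grid)
  for (j in seq_len(ncol(Y))) {
    centre <- which.min(abs(slave_wl - master_wl[j]))
    win <- max(1L, centre - half_window):min(p_s, centre + half_window)
    Xw <- X[, win, drop = FALSE]
    G <- crossprod(Xw)
    rj <- if (is.null(ridge)) 1e-8 * mean(diag(G)) else ridge
    Fmat[win, j] <- solve(G + diag(rj, length(win)), crossprod(Xw, Y[, j]))
  }
  new_transfer_map("PDS", Fmat, intercept = intercept,
                   slave_grid = slave_std$grid, master_grid = master_std$grid,
                   meta = list(n_standards = nrow(X), half_window = as.integer(half_window),
                               ridge = ridge))
}

#' @param n_components size of the joint singular subspace SST retains;
#'   between 1 and `n_standards - 1`.
#' @details
#' Spectral space transformation centres the paired standards, concatenates
#' them along channels, and takes the top `n_components` left-singular
#' subspace of the combined matrix. Splitting the corresponding right-singular
#' loadings into slave and master blocks `(P_s, P_m)` yields the corrector
#' `F = pinv(P_s') %*% P_m'` acting on centred slave spectra, with the master
#' column means as intercept.
#' @rdname transfer_map
#' @export
fit_sst <- function(master_std, slave_std, n_components) {
  check_standards(master_std, slave_std)
  n <- nrow(master_std$absorbance)
  if (!.is_count(n_components) || n_components > n - 1L) {
    stop_nirshift("n_components must be an integer in [1, n_standards - 1]",
                  "nirshift_argument_error")
  }
  mu_s <- colMeans(slave_std$absorbance)
  mu_m <- colMeans(master_std$absorbance)
  Xs <- sweep(slave_std$absorbance, 2L, mu_s)
  Xm <- sweep(master_std$absorbance, 2L, mu_m)
  comb <- cbind(Xs, Xm)
  sv <- svd(comb, nu = n_components, nv = n_components)
  keep <- seq_len(n_components)
  V <- sv$v                                  # (p_s + p_m) x k loadings
  Ps <- V[seq_len(ncol(Xs)), keep, drop = FALSE]
  Pm <- V[ncol(Xs) + seq_len(ncol(Xm)), keep, drop = FALSE]
  # scores of a centred slave spectrum x: t = x %*% Ps %*% solve(Ps'Ps);
  # reconstruction on the master side: t %*% Pm'
  Fmat <- Ps %*% solve(crossprod(Ps), t(Pm))
  new_transfer_map("SST", Fmat, intercept = mu_m, center = mu_s,
                   slave_grid = slave_std$grid, master_grid = master_std$grid,
                   meta = list(n_standards = n, n_components = as.integer(n_components)))
}

check_standards <- function(master_std, slave_std) {
  stopifnot(inherits(master_std, "spectra_set"), inherits(slave_std, "spectra_set"))
  if (nrow(master_std$absorbance) != nrow(slave_std$absorbance)) {
    stop_nirshift("master and slave standards must have equal, paired sample counts",
                  "nirshift_argument_error")
  }
  invisible(TRUE)
}

new_transfer_map <- function(kind, Fmat, intercept, slave_grid, master_grid,
                             center = NULL, meta = list()) {
  structure(
    list(kind = kind, F = Fmat, intercept = intercept, center = center,
         slave_grid = slave_grid, master_grid = master_grid, meta = meta),
    class = "transfer_map"
  )
}

#' @export
print.transfer_map <- function(x, ...) {
  extra <- switch(x$kind,
    PDS = sprintf(", half_window %d", x$meta$half_window),
    SST = sprintf(", %d components", x$meta$n_components),
    "")
  cat(sprintf("<transfer_map %s> %d slave -> %d master channels, %d standards%s\n",
              x$kind, nrow(x$F), ncol(x$F), x$meta$n_standards, extra))
  invisible(x)
}

#' Apply a transfer map to slave spectra
#'
#' @param object a `"transfer_map"`.
#' @param slave a [spectra_set()] on the grid the map was fit on.
#' @param ... unused.
#' @return A [spectra_set()] on the master grid; labels carried through.
#' @export
predict.transfer_map <- function(object, slave, ...) {
  stopifnot(inherits(slave, "spectra_set"))
  if (length(slave$grid) != nrow(object$F) ||
      max(abs(as.numeric(slave$grid) - as.numeric(object$slave_grid))) > 1e-9) {
    stop_nirshift("slave grid does not match the grid the map was fit on",
                  "nirshift_argument_error")
  }
  X <- slave$absorbance
  if (!is.null(object$center)) X <- sweep(X, 2L, object$center)
  out <- X %*% object$F
  out <- sweep(out, 2L, object$intercept, "+")
  spectra_set(object$master_grid, out, labels = slave$labels,
              instrument_id = paste0(slave$instrument_id, "->master"))
}

#' @rdname predict.transfer_map
#' @param map a `"transfer_map"`.
#' @export
apply_transfer <- function(map, slave) predict.transfer_map(map, slave)

#' Serialize / read a transfer map
#'
#' The dense map is written as CSV with a YAML header block (prefixed `#`)
#' recording kind, grids, intercept and fit metadata.
#'
#' @param map a `"transfer_map"`.
#' @param path output path.
#' @return `write_transfer_map`: invisibly `path`; `read_transfer_map`: the map.
#' @export
write_transfer_map <- function(map, path) {
  hdr <- yaml::as.yaml(list(
    kind = map$kind, meta = map$meta,
    intercept = as.numeric(map$intercept),
    center = if (is.null(map$center)) NULL else as.numeric(map$center),
    slave_grid = as.numeric(map$slave_grid),
    master_grid = as.numeric(map$master_grid)), precision = 15)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(hdr, "\n")[[1]]), con)
  utils::write.table(map$F, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_transfer_map
#' @export
read_transfer_map <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^# ", lines)
  meta <- yaml::yaml.load(paste(sub("^# ", "", lines[hdr_idx]), collapse = "\n"))
  Fmat <- as.matrix(utils::read.csv(text = lines[-hdr_idx], header = FALSE))
  dimnames(Fmat) <- NULL
  new_transfer_map(meta$kind, Fmat, intercept = meta$intercept,
                   slave_grid = wavelength_grid(meta$slave_grid),
                   master_grid = wavelength_grid(meta$master_grid),
                   center = meta$center, meta = meta$meta)
}
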