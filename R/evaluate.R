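# Metrics and the two experiment designs: the split-ratio sweep for the
# adaptation networks and the transfer-sample-size sweep for the classical
# standardization methods.

#' Coefficient of determination, in percent
#'
#' `100 * (1 - SS_res / SS_tot)` with the total sum of squares about the
#' observed mean. Can be negative for models worse than the mean predictor;
#' never exceeds 100.
#'
#' @param pred,obs equal-length numeric vectors (length >= 2); `obs` must be
#'   non-constant.
#' @return Scalar percentage.
#' @export
r_squared_percent <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 2L) {
    stop_nirshift("pred and obs must be equal-length with at least 2 values",
                  "nirshift_argument_error")
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    stop_nirshift("R is undefined for constant observations", "nirshift_metric_error")
  }
  100 * (1 - sum((pred - obs)^2) / ss_tot)
}

#' Root mean square error
#'
#' @param pred,obs equal-length numeric vectors.
#' @return Scalar RMSE.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) == 0L || length(pred) != length(obs)) {
    stop_nirshift("pred and obs must be equal-length, non-empty", "nirshift_argument_error")
  }
  sqrt(mean((pred - obs)^2))
}

#' Root mean square error of prediction
#'
#' RMSE of a fitted model on a held-out labelled test set.
#'
#' @param model anything with a `predict(model, test, ...)` method returning
#'   label units.
#' @param test a labelled [spectra_set()].
#' @param ... passed to `predict` (e.g. `domain`).
#' @return Scalar RMSEP.
#' @export
rmsep <- function(model, test, ...) {
  stopifnot(inherits(test, "spectra_set"))
  if (is.null(test$labels)) {
    stop_nirshift("test set must be labelled for RMSEP", "nirshift_argument_error")
  }
  rmse(predict(model, test, ...), test$labels)
}

#' Root mean square error of cross-validation
#'
#' k-fold cross-validation with seeded fold assignment; each fold's model is
#' trained from scratch by the supplied factory and the squared errors are
#' pooled over all folds before the root.
#'
#' @param model_factory function(train_set) returning an object predictable
#'   with `predict(object, test_set, ...)`.
#' @param data a labelled [spectra_set()].
#' @param k fold count (>= 2, <= n).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to `predict`.
#' @return Scalar RMSECV.
#' @export
rmsecv <- function(model_factory, data, k = 10L, seed = 1L, ...) {
  stopifnot(inherits(data, "spectra_set"))
  n <- nrow(data$absorbance)
  if (!.is_count(k) || k < 2L) {
    stop_nirshift("k must be an integer >= 2", "nirshift_argument_error")
  }
  if (k > n) stop_nirshift("k must not exceed the sample count", "nirshift_argument_error")
  set.seed(derive_seed(seed, "rmsecv_folds"))
  fold <- sample(rep_len(seq_len(k), n))
  sq <- numeric(0)
  for (f in seq_len(k)) {
    hold <- which(fold == f)
    fit <- model_factory(subset_spectra(data, -hold))
    pred <- predict(fit, subset_spectra(data, hold), ...)
    sq <- c(sq, (pred - data$labels[hold])^2)
  }
  sqrt(mean(sq))
}

#' Split-ratio sweep for the adaptation networks
#'
#' For each (method, ratio, rep): split the labelled source set by the
#' ratio, train the network on the training part with the full unlabelled
#' target set, and score the target-domain predictions against the held-out
#' truth labels. Default ratios are the ten-point grid from 25% to 70% in
#' 5% steps.
#'
#' @param methods character vector of method names.
#' @param dataset a [generate_paired()] result (truth labels are used for
#'   scoring only).
#' @param ratios training fractions inside (0, 1).
#' @param reps repetitions per cell (fresh split + training seeds).
#' @param seed integer sweep seed.
#' @param config an [adapt_config()] template; its seed is re-derived per cell.
#' @return An object of class `"eval_report"`: `$results` (one row per run)
#'   and `$summary` (mean and sd of R per cell).
#' @export
split_ratio_sweep <- function(methods, dataset, ratios = seq(0.25, 0.70, by = 0.05),
                              reps = 1L, seed = 1L, config = adapt_config()) {
  stopifnot(inherits(dataset, "paired_nir"))
  if (any(ratios <= 0 | ratios >= 1)) {
    stop_nirshift("ratios must lie strictly inside (0, 1)", "nirshift_argument_error")
  }
  rows <- list()
  tgt <- dataset$target
  truth <- dataset$truth$target_labels
  for (method in methods) {
    for (ratio in ratios) {
      for (rep in seq_len(reps)) {
        cell_seed <- derive_seed(seed, sprintf("sweep_%s_%g_%d", method, ratio, rep))
        sp <- random_split(dataset$source, ratio, cell_seed)
        cfg <- config
        cfg$seed <- cell_seed
        fit <- nir_adapt(sp$train, tgt, method = method, config = cfg)
        pred <- predict(fit, tgt, domain = "target")
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, split_ratio = ratio, seed = cell_seed, rep = rep,
          R_percent = r_squared_percent(pred, truth),
          RMSEP = rmse(pred, truth))
      }
    }
  }
  new_eval_report(do.call(rbind, rows), by = "split_ratio")
}

#' Transfer-sample-size sweep for the classical methods
#'
#' For each fraction: take that share of the paired transfer standards
#' (seeded shuffle), fit the classical map, correct the slave test spectra
#' onto the master space, and score them with a fixed master-domain ridge
#' regression model. The scorer is trained once on all labelled master
#' spectra so the comparison across fractions isolates the transfer map.
#'
#' @param ct_methods subset of `c("DS", "PDS", "SST")`.
#' @param dataset a [generate_paired()] result.
#' @param fractions shares of the paired standards in (0, 1].
#' @param seed integer seed for the standard selection shuffles.
#' @param reps number of seeded selection shuffles per fraction; the summary
#'   averages over them, separating the standard-count effect from the luck
#'   of any single selection.
#' @param half_window PDS half-window.
#' @param n_components SST component count (capped at n_standards - 1).
#' @param ridge_label ridge penalty of the master-domain label model.
#' @return An `"eval_report"` with per-(method, fraction, rep) target R and
#'   RMSEP rows and a mean/sd summary per cell.
#' @export
transfer_sample_sweep <- function(ct_methods = c("DS", "PDS", "SST"), dataset,
                                  fractions = c(0.3, 0.5, 0.7), seed = 1L,
                                  reps = 1L, half_window = 5L, n_components = 6L,
                                  ridge_label = 1e-4) {
  stopifnot(inherits(dataset, "paired_nir"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop_nirshift("fractions must lie in (0, 1]", "nirshift_argument_error")
  }
  ct_methods <- match.arg(ct_methods, c("DS", "PDS", "SST"), several.ok = TRUE)
  n_pair <- dataset$n_paired
  scorer <- fit_ridge_labels(dataset$source, ridge_label)
  truth <- dataset$truth$target_labels
  rows <- list()
  for (rep in seq_len(reps)) {
    set.seed(derive_seed(seed, paste0("transfer_standards_", rep)))
    shuffle <- sample.int(n_pair)
    for (frac in fractions) {
      k <- floor(frac * n_pair)
      if (k < 2L) {
        stop_nirshift(sprintf("fraction %.2f yields fewer than 2 standards", frac),
                      "nirshift_argument_error")
      }
      std_idx <- shuffle[seq_len(k)]
      m_std <- subset_spectra(dataset$source, std_idx)
      s_std <- subset_spectra(dataset$target, std_idx)
      for (method in ct_methods) {
        map <- switch(method,
          DS = fit_ds(m_std, s_std, ridge = "gcv"),
          PDS = fit_pds(m_std, s_std, half_window = half_window),
          SST = fit_sst(m_std, s_std, n_components = min(n_components, k - 1L)))
        corrected <- predict(map, dataset$target)
        pred <- predict_ridge_labels(scorer, corrected)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, transfer_fraction = frac, seed = as.integer(seed),
          rep = rep, R_percent = r_squared_percent(pred, truth),
          RMSEP = rmse(pred, truth))
      }
    }
  }
  new_eval_report(do.call(rbind, rows), by = "transfer_fraction")
}

# Master-domain calibration model the classical maps feed: ridge regression
# of labels on centred master spectra, closed form.
fit_ridge_labels <- function(master, ridge = 1e-4) {
  stopifnot(!is.null(master$labels))
  X <- master$absorbance
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  y <- master$labels
  G <- crossprod(Xc)
  beta <- solve(G + diag(ridge * mean(diag(G)), ncol(X)), crossprod(Xc, y - mean(y)))
  structure(list(beta = beta, mu = mu, y_bar = mean(y), grid = master$grid),
            class = "ridge_labels")
}

predict_ridge_labels <- function(object, set) {
  drop(sweep(set$absorbance, 2L, object$mu) %*% object$beta) + object$y_bar
}

#' @export
predict.ridge_labels <- function(object, set, ...) predict_ridge_labels(object, set)

new_eval_report <- function(results, by) {
  agg <- stats::aggregate(results[c("R_percent", "RMSEP")],
                          by = results[c("method", by)],
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  structure(list(results = results, summary = agg, by = by),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d runs, grouped by %s\n", nrow(x$results), x$by))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    r <- s$R_percent[i, ]
    cat(sprintf("  %-5s %s=%.2f  R = %6.2f +/- %5.2f  RMSEP = %.3f\n",
                s$method[i], x$by, s[[x$by]][i], r["mean"],
                ifelse(is.na(r["sd"]), 0, r["sd"]),
                s$RMSEP[i, "mean"]))
  }
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' @param report an `"eval_report"`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(report$results, path, row.names = FALSE)
  invisible(path)
}
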