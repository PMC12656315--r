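#' Score an indicator onto \[0, 1\]
#'
#' Linear min-max scoring. For `more_is_better` the maximum scores 1;
#' for `less_is_better` the minimum scores 1. A sigmoidal curve
#' (logistic around the midrange) is available as an alternative.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param polarity `"more_is_better"` or `"less_is_better"`.
#' @param method `"linear"` (default) or `"sigmoid"`.
#' @return scores in \[0, 1\].
#' @export
score_indicator <- function(values, polarity = "more_is_better",
                            method = c("linear", "sigmoid")) {
  method <- match.arg(method)
  rng <- range(values)
  if (diff(rng) == 0) stop("constant indicator: scoring undefined")
  s <- (values - rng[1]) / diff(rng)
  if (method == "sigmoid") {
    # logistic centred on the midrange, slope chosen so the extremes map
    # to ~0.01/0.99, then rescaled to exactly [0, 1]
    z <- 1 / (1 + exp(-9.19 * (s - 0.5)))
    s <- (z - min(z)) / (max(z) - min(z))
  }
  if (polarity == "less_is_better") s <- 1 - s
  s
}

#' Principal component analysis of an indicator matrix
#'
#' Eigen-decomposition of the correlation matrix. Loadings are
#' correlation loadings (eigenvector times sqrt eigenvalue), each
#' component sign-oriented so its largest-magnitude loading is positive.
#'
#' @param x numeric matrix or data.frame, samples x indicators.
#' @return list with `eigenvalues`, `loadings` (indicators x components),
#'   `scores`, `prop_var` (variance explained per component).
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 samples")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant indicator column: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  e <- eigen(cor(x), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  load <- e$vectors %*% diag(sqrt(ev), nrow = length(ev))
  for (k in seq_len(ncol(load))) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) load[, k] <- -load[, k]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  # scores in the same orientation as the loadings
  scores <- z %*% sweep(load, 2, sqrt(pmax(ev, .Machine$double.eps)), "/")
  list(eigenvalues = ev, loadings = load, scores = scores,
       prop_var = ev / sum(ev))
}

#' Select the minimum data set from a PCA
#'
#' Components with eigenvalue >= `eigen_min` are retained (with a 1e-9
#' tolerance at the boundary). Within each retained component the
#' candidates are the indicators whose absolute loading is within
#' `loading_window` (fraction) of that component's maximum absolute
#' loading. When a component yields several candidates, candidates whose
#' pairwise correlation is at least `corr_redundancy` are collapsed to
#' the one with the highest norm value
#' sqrt(sum over retained PCs of loading^2 * eigenvalue); uncorrelated
#' candidates are all kept.
#'
#' @param pca result of [run_pca()].
#' @param x the indicator matrix the PCA was run on (for redundancy
#'   correlations).
#' @param eigen_min eigenvalue retention threshold (default 1).
#' @param loading_window within-component candidate window (default 0.1,
#'   i.e. within 10 percent of the maximum absolute loading).
#' @param corr_redundancy correlation above which two candidates are
#'   considered redundant (default 0.5).
#' @return list with `mds` (indicator names), `component` (source
#'   component per MDS indicator), `retained` (retained component
#'   indices).
#' @export
select_mds <- function(pca, x, eigen_min = 1, loading_window = 0.1,
                       corr_redundancy = 0.5) {
  x <- as.matrix(x)
  retained <- which(pca$eigenvalues >= eigen_min - 1e-9)
  if (length(retained) == 0) {
    warning("no component reaches the eigenvalue threshold; using PC1")
    retained <- 1L
  }
  cx <- cor(x)
  norm_value <- sqrt(rowSums(
    (pca$loadings[, retained, drop = FALSE]^2) %*%
      diag(pca$eigenvalues[retained], nrow = length(retained))))
  mds <- character()
  comp <- integer()
  for (k in retained) {
    lk <- setNames(abs(pca$loadings[, k]), rownames(pca$loadings))
    cand <- names(lk)[lk >= (1 - loading_window) * max(lk)]
    keep <- cand
    if (length(cand) > 1) {
      keep <- character()
      pool <- cand[order(-norm_value[cand])]
      while (length(pool) > 0) {
        top <- pool[1]
        keep <- c(keep, top)
        red <- pool[-1][abs(cx[top, pool[-1]]) >= corr_redundancy]
        pool <- setdiff(pool[-1], red)
      }
    }
    new <- setdiff(keep, mds)
    mds <- c(mds, new)
    comp <- c(comp, rep(k, length(new)))
  }
  list(mds = mds, component = setNames(comp, mds), retained = retained)
}

#' PCA-variance weights for the minimum data set
#'
#' Each MDS indicator inherits the proportion of variance explained by
#' its source component; weights are normalised to sum one.
#'
#' @param pca result of [run_pca()].
#' @param mds result of [select_mds()].
#' @return named weight vector summing to 1.
#' @export
compute_weights <- function(pca, mds) {
  w <- pca$prop_var[mds$component]
  w <- w / sum(w)
  setNames(w, mds$mds)
}

#' Weighted soil quality index
#'
#' SQI = sum over MDS indicators of weight times score, per sample.
#'
#' @param scores samples x indicators matrix of \[0, 1\] scores.
#' @param weights named weights over the same indicators.
#' @return per-sample SQI in \[0, 1\].
#' @export
compute_sqi <- function(scores, weights) {
  scores <- as.matrix(scores)
  if (!setequal(colnames(scores), names(weights))) {
    stop("score columns and weight names do not match")
  }
  drop(scores[, names(weights), drop = FALSE] %*% weights)
}

#' Percent change of a treated group mean against a control mean
#' @param treated treated-group values.
#' @param control control-group values.
#' @return percent change (mean(treated) - mean(control)) / mean(control) * 100.
#' @export
percent_change <- function(treated, control) {
  mc <- mean(control)
  if (mc == 0) stop("control mean is zero: percent change undefined")
  (mean(treated) - mc) / mc * 100
}

#' Soil quality index for a soil table
#'
#' Runs scoring, PCA, minimum-data-set selection and weighting within
#' each crop season separately (scoring ranges and PCA per season), or
#' globally with `by_season = FALSE`.
#'
#' @param tab validated `soil_table`.
#' @param polarity named polarity vector; defaults to the table's
#'   `polarity` attribute, else [default_polarity()].
#' @param by_season compute per crop season (default TRUE).
#' @param method scoring curve, see [score_indicator()].
#' @param eigen_min,loading_window,corr_redundancy passed to
#'   [select_mds()].
#' @return list with per-season elements each holding `mds`, `weights`,
#'   `scores`, `sqi` (named by plot_id), and `pca` diagnostics; plus a
#'   combined `table` (plot_id, crop_season, treatment, SQI).
#' @export
soil_quality_index <- function(tab, polarity = NULL, by_season = TRUE,
                               method = "linear", eigen_min = 1,
                               loading_window = 0.1,
                               corr_redundancy = 0.5) {
  if (is.null(polarity)) polarity <- attr(tab, "polarity")
  if (is.null(polarity)) polarity <- default_polarity()
  ind <- intersect(setdiff(names(tab), design_columns()), names(polarity))
  groups <- if (by_season) split(seq_len(nrow(tab)), tab$crop_season) else
    list(all = seq_len(nrow(tab)))
  per <- lapply(groups, function(idx) {
    x <- as.matrix(tab[idx, ind, drop = FALSE])
    keep <- apply(x, 2, function(v) diff(range(v)) > 0)
    x <- x[, keep, drop = FALSE]
    sc <- sapply(colnames(x), function(cn)
      score_indicator(x[, cn], polarity[[cn]], method = method))
    rownames(sc) <- tab$plot_id[idx]
    pca <- run_pca(x)
    mds <- select_mds(pca, x, eigen_min, loading_window, corr_redundancy)
    w <- compute_weights(pca, mds)
    sqi <- compute_sqi(sc[, mds$mds, drop = FALSE], w)
    list(mds = mds$mds, weights = w,
         scores = sc[, mds$mds, drop = FALSE], sqi = sqi, pca = pca,
         rows = idx)
  })
  table <- do.call(rbind, lapply(names(per), function(g) {
    idx <- per[[g]]$rows
    data.frame(plot_id = tab$plot_id[idx], crop_season = tab$crop_season[idx],
               treatment = tab$treatment[idx], SQI = unname(per[[g]]$sqi),
               stringsAsFactors = FALSE)
  }))
  rownames(table) <- NULL
  list(seasons = per, table = table)
}
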