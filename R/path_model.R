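#' Specify a PLS path model
#'
#' @param blocks named list; each element is a character vector of
#'   indicator (column) names forming one reflective latent block.
#' @param paths two-column matrix or data.frame of latent names
#'   (source, target); must describe an acyclic directed inner model.
#' @return object of class `plspm_spec`.
#' @export
plspm_spec <- function(blocks, paths) {
  paths <- as.matrix(paths)
  if (ncol(paths) != 2) stop("paths needs two columns: source, target")
  lat <- names(blocks)
  if (is.null(lat) || anyDuplicated(lat)) stop("blocks must be uniquely named")
  unknown <- setdiff(c(paths), lat)
  if (length(unknown) > 0) {
    stop("path references unknown latent(s): ", paste(unknown, collapse = ", "))
  }
  ind <- unlist(blocks)
  if (anyDuplicated(ind)) {
    stop("indicator in more than one block: ", ind[duplicated(ind)][1])
  }
  # acyclicity via topological elimination
  remaining <- lat
  edges <- paths
  repeat {
    sinkless <- setdiff(remaining, edges[, 1])
    if (length(sinkless) == length(remaining)) break
    if (length(sinkless) == 0) stop("inner model contains a cycle")
    remaining <- setdiff(remaining, sinkless)
    edges <- edges[!(edges[, 2] %in% sinkless), , drop = FALSE]
    if (length(remaining) == 0 || nrow(edges) == 0) break
  }
  if (nrow(paths) > 0 && length(remaining) > 0 && nrow(edges) > 0) {
    stop("inner model contains a cycle")
  }
  structure(list(blocks = blocks, paths = paths), class = "plspm_spec")
}

pop_scale <- function(x) {
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sdv == 0)) {
    stop("constant indicator: ", paste(colnames(x)[sdv == 0], collapse = ", "))
  }
  sweep(sweep(x, 2, mu), 2, sdv, "/")
}

#' Fit a PLS path model
#'
#' Reflective (mode A) outer model with the centroid inner scheme:
#' latent scores are alternately updated from outer weights
#' (proportional to indicator-latent-proxy covariance) and inner proxies
#' (sign-weighted sums of adjacent latents) until the maximum outer
#' weight change drops below `tol`. Indicators and latent scores are
#' standardised with population variance. Path coefficients come from
#' least squares of each endogenous latent on its predecessors;
#' loadings are indicator-latent correlations.
#'
#' @param data data.frame or matrix holding every indicator column.
#' @param spec `plspm_spec`.
#' @param tol convergence tolerance on outer weights (default 1e-7).
#' @param max_iter maximum iterations (default 300).
#' @return object of class `plspm_fit`: `loadings`, `scores`,
#'   `path_coefficients` (data.frame source, target, estimate),
#'   `r_squared` per endogenous latent, `communality` per block,
#'   `gof`, `iterations`, `spec`.
#' @export
fit_plspm <- function(data, spec, tol = 1e-7, max_iter = 300) {
  stopifnot(inherits(spec, "plspm_spec"))
  ind <- unlist(spec$blocks)
  miss <- setdiff(ind, colnames(data))
  if (length(miss) > 0) {
    stop("indicator column(s) missing from data: ", paste(miss, collapse = ", "))
  }
  x <- pop_scale(as.matrix(data[, ind, drop = FALSE]))
  n <- nrow(x)
  lat <- names(spec$blocks)
  npred <- if (nrow(spec$paths) > 0) max(table(spec$paths[, 2])) else 0
  if (n <= npred + 1) stop("too few samples for the inner model")
  # adjacency (undirected for the centroid scheme)
  adj <- matrix(FALSE, length(lat), length(lat), dimnames = list(lat, lat))
  for (i in seq_len(nrow(spec$paths))) {
    adj[spec$paths[i, 1], spec$paths[i, 2]] <- TRUE
    adj[spec$paths[i, 2], spec$paths[i, 1]] <- TRUE
  }
  w <- lapply(spec$blocks, function(b) rep(1, length(b)))
  unit <- function(v) v / sqrt(mean(v^2))    # population unit variance
  scores <- sapply(lat, function(l)
    unit(x[, spec$blocks[[l]], drop = FALSE] %*% w[[l]]))
  colnames(scores) <- lat
  it <- 0
  repeat {
    it <- it + 1
    # inner approximation: centroid scheme
    inner <- sapply(lat, function(l) {
      nb <- lat[adj[l, ]]
      if (length(nb) == 0) return(scores[, l])
      e <- sign(cor(scores[, l], scores[, nb, drop = FALSE]))
      drop(scores[, nb, drop = FALSE] %*% as.numeric(e))
    })
    # outer approximation: mode A weights = cov(indicator, inner proxy)
    w_new <- lapply(lat, function(l) {
      xb <- x[, spec$blocks[[l]], drop = FALSE]
      drop(crossprod(xb, unit(inner[, l])) / n)
    })
    names(w_new) <- lat
    scores_new <- sapply(lat, function(l)
      unit(x[, spec$blocks[[l]], drop = FALSE] %*% w_new[[l]]))
    colnames(scores_new) <- lat
    # compare normalised weight vectors (scale-free convergence)
    nw <- unlist(lapply(w_new, function(v) v / sqrt(sum(v^2))))
    ow <- unlist(lapply(w, function(v) v / sqrt(sum(v^2))))
    delta <- max(abs(abs(nw) - abs(ow)))
    w <- w_new
    scores <- scores_new
    if (delta < tol) break
    if (it >= max_iter) {
      stop("PLS-PM did not converge in ", max_iter,
           " iterations (last delta ", format(delta), ")")
    }
  }
  loadings <- lapply(lat, function(l)
    setNames(drop(cor(x[, spec$blocks[[l]], drop = FALSE], scores[, l])),
             spec$blocks[[l]]))
  names(loadings) <- lat
  endo <- unique(spec$paths[, 2])
  path_df <- NULL
  r2 <- setNames(numeric(length(endo)), endo)
  for (l in endo) {
    preds <- spec$paths[spec$paths[, 2] == l, 1]
    b <- coef(lm(scores[, l] ~ scores[, preds, drop = FALSE]))[-1]
    if (anyNA(b)) stop("singular inner regression for latent '", l, "'")
    path_df <- rbind(path_df,
                     data.frame(source = preds, target = l,
                                estimate = unname(b),
                                stringsAsFactors = FALSE))
    pred_mat <- scores[, preds, drop = FALSE]
    fitted <- drop(pred_mat %*% b)
    r2[l] <- 1 - mean((scores[, l] - mean(scores[, l]) -
                         (fitted - mean(fitted)))^2) / mean(
                           (scores[, l] - mean(scores[, l]))^2)
  }
  communality <- sapply(loadings, function(v) mean(v^2))
  all_load <- unlist(loadings)
  gof_val <- sqrt(mean(all_load^2) * mean(r2))
  structure(list(loadings = loadings, scores = scores,
                 path_coefficients = path_df, r_squared = r2,
                 communality = communality, gof = gof_val,
                 iterations = it, spec = spec, data = data,
                 tol = tol, max_iter = max_iter),
            class = "plspm_fit")
}

#' Goodness of fit of a PLS path model
#'
#' GOF = sqrt(mean squared loading over all reflective indicators times
#' mean R-squared over endogenous latents). Values in (0.40, 1.00] are
#' conventionally considered acceptable.
#'
#' @param fit `plspm_fit`.
#' @return GOF in \[0, 1\].
#' @export
gof <- function(fit) {
  stopifnot(inherits(fit, "plspm_fit"))
  if (length(fit$r_squared) == 0) stop("no endogenous latent: GOF undefined")
  fit$gof
}

#' Is a GOF value acceptable?
#'
#' Applies the conventional acceptance band 0.40 < GOF <= 1.00
#' (strict at 0.40: a GOF of exactly 0.4 is not acceptable).
#'
#' @param g GOF value.
#' @return logical.
#' @export
gof_acceptable <- function(g) g > 0.4 & g <= 1

#' Prune weak indicators from a fitted model
#'
#' Removes indicators whose absolute loading is below `threshold`
#' (strictly below: a loading of exactly `threshold` is retained) and
#' returns the reduced spec for refitting.
#'
#' @param fit `plspm_fit`.
#' @param threshold loading cut (default 0.5).
#' @return reduced `plspm_spec`.
#' @export
prune_loadings <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "plspm_fit"))
  blocks <- lapply(names(fit$loadings), function(l) {
    v <- fit$loadings[[l]]
    keep <- names(v)[abs(v) >= threshold]
    if (length(keep) == 0) {
      stop("pruning empties block '", l, "'")
    }
    keep
  })
  names(blocks) <- names(fit$loadings)
  plspm_spec(blocks, fit$spec$paths)
}

#' Bootstrap path coefficients
#'
#' Percentile confidence intervals and two-sided p-values from row
#' resampling. Resamples in which an indicator becomes constant are
#' dropped (with a warning reporting the count). Deterministic under
#' `seed`.
#'
#' @param data,spec,tol,max_iter as in [fit_plspm()].
#' @param n_boot number of bootstrap resamples; 0 returns point
#'   estimates only.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame source, target, estimate, lower, upper, p_value,
#'   with attribute `n_dropped`.
#' @export
bootstrap_paths <- function(data, spec, n_boot = 200, seed = 1,
                            conf = 0.95, tol = 1e-7, max_iter = 300) {
  fit <- fit_plspm(data, spec, tol, max_iter)
  est <- fit$path_coefficients
  if (n_boot == 0) return(est)
  local_seed(seed)
  n <- nrow(data)
  boots <- matrix(NA_real_, n_boot, nrow(est))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    fb <- tryCatch(fit_plspm(data[idx, , drop = FALSE], spec, tol, max_iter),
                   error = function(e) NULL)
    if (is.null(fb)) { dropped <- dropped + 1L; next }
    boots[b, ] <- fb$path_coefficients$estimate
  }
  if (dropped > 0) warning(dropped, " degenerate resample(s) dropped")
  a <- (1 - conf) / 2
  ok <- complete.cases(boots)
  est$lower <- apply(boots[ok, , drop = FALSE], 2, quantile, probs = a)
  est$upper <- apply(boots[ok, , drop = FALSE], 2, quantile, probs = 1 - a)
  est$p_value <- vapply(seq_len(nrow(est)), function(j) {
    bj <- boots[ok, j]
    2 * min(mean(bj <= 0), mean(bj >= 0))
  }, numeric(1))
  attr(est, "n_dropped") <- dropped
  est
}

#' Default inner structure for amendment trials
#'
#' Amendment dose (single indicator) feeds the physical, chemical and
#' biological property latents; chemical also feeds biological; all
#' three feed soil quality, which feeds yield.
#'
#' @param blocks named list of indicator vectors for latents `dose`,
#'   `physical`, `chemical`, `biological`, `quality`, `yield`.
#' @return `plspm_spec`.
#' @export
default_path_spec <- function(blocks) {
  paths <- rbind(c("dose", "physical"), c("dose", "chemical"),
                 c("dose", "biological"), c("chemical", "biological"),
                 c("physical", "quality"), c("chemical", "quality"),
                 c("biological", "quality"), c("quality", "yield"))
  plspm_spec(blocks, paths)
}
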