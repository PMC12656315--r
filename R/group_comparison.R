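#' Balanced two-way ANOVA with interaction
#'
#' Standard balanced two-factor decomposition (main effects, interaction,
#' residual), F tested against the residual mean square. Unbalanced
#' layouts are rejected. A constant response yields all-zero sums of
#' squares with F reported as 0 and a `degenerate` flag.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factor labels (e.g. treatment and cropping
#'   system), equal cell sizes >= 2.
#' @return data.frame with rows A, B, A:B, Residuals and columns term,
#'   df, sum_sq, mean_sq, f_value, p_value; attribute `degenerate`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (length(values) != length(a) || length(values) != length(b)) {
    stop("values and factors must have equal length")
  }
  cells <- table(a, b)
  if (any(cells < 2)) stop("every cell needs at least 2 replicates")
  if (length(unique(as.vector(cells))) != 1) {
    stop("unbalanced design: equal cell sizes required")
  }
  degenerate <- diff(range(values)) == 0
  if (degenerate) {
    out <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                      df = c(nlevels(a) - 1, nlevels(b) - 1,
                             (nlevels(a) - 1) * (nlevels(b) - 1),
                             length(values) - nlevels(a) * nlevels(b)),
                      sum_sq = 0, mean_sq = 0,
                      f_value = c(0, 0, 0, NA), p_value = NA,
                      stringsAsFactors = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tab <- anova(aov(values ~ a * b))
  out <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                    df = tab$Df, sum_sq = tab$`Sum Sq`,
                    mean_sq = tab$`Mean Sq`, f_value = tab$`F value`,
                    p_value = tab$`Pr(>F)`, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- FALSE
  out
}

# critical range for a span of p means at joint protection level
duncan_range <- function(p, df_err, mse, n, alpha) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  qtukey(1 - alpha_p, nmeans = p, df = df_err) * sqrt(mse / n)
}

# Piepho-style insert-and-absorb compact letter display from a logical
# "different" matrix over groups sorted by decreasing mean
insert_absorb <- function(different, labels) {
  cols <- list(seq_along(labels))
  k <- length(labels)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!different[i, j]) next
      for (ci in seq_along(cols)) {
        cl <- cols[[ci]]
        if (i %in% cl && j %in% cl) {
          cols[[ci]] <- setdiff(cl, j)
          cols[[length(cols) + 1]] <- setdiff(cl, i)
        }
      }
      # absorb columns fully contained in another
      drop <- rep(FALSE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && !drop[cj] &&
              all(cols[[ci]] %in% cols[[cj]]) &&
              length(cols[[ci]]) < length(cols[[cj]])) {
            drop[ci] <- TRUE
            break
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  # deduplicate identical columns
  cols <- cols[!duplicated(lapply(cols, sort))]
  # order letters by the best (highest-mean) group they contain
  cols <- cols[order(sapply(cols, min))]
  letters_out <- rep("", k)
  for (ci in seq_along(cols)) {
    letters_out[cols[[ci]]] <- paste0(letters_out[cols[[ci]]],
                                      letters[ci])
  }
  setNames(letters_out, labels)
}

#' Duncan's multiple range test with compact letter display
#'
#' Groups are sorted by mean; for a span of p consecutive means the
#' critical range is R_p = q(alpha_p, p, df) sqrt(MS_err / n) with the
#' protection level alpha_p = 1 - (1 - alpha)^(p - 1) and q the
#' studentized-range quantile. A pair is declared different when its
#' mean difference exceeds the critical range of its span and every
#' enclosing range of means is itself significant (multiple-range
#' protection). Letters are assembled by the insert-and-absorb
#' procedure; groups share a letter iff they are not declared different.
#'
#' @param values numeric response.
#' @param groups group labels, equal group sizes.
#' @param alpha significance level (default 0.05).
#' @param mse residual mean square from the surrounding ANOVA; defaults
#'   to the one-way within-group mean square of `values ~ groups`.
#' @param df_err residual degrees of freedom matching `mse`.
#' @return data.frame with group, n, mean, letters; sorted by decreasing
#'   mean. Ties in means are broken by group label order.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05, mse = NULL,
                       df_err = NULL) {
  g <- as.character(groups)
  sizes <- table(g)
  if (length(unique(as.vector(sizes))) != 1) {
    stop("unequal group sizes: Duncan's test requires equal n")
  }
  n <- as.vector(sizes)[1]
  if (is.null(mse) || is.null(df_err)) {
    f <- factor(g)
    fit <- anova(aov(values ~ f))
    mse <- fit$`Mean Sq`[2]
    df_err <- fit$Df[2]
  }
  if (df_err < 1) stop("residual degrees of freedom below 1")
  means <- tapply(values, g, mean)
  ord <- order(-means, names(means))
  means <- means[ord]
  k <- length(means)
  different <- matrix(FALSE, k, k)
  if (mse > 0) {
    # multiple-range protection: a pair differs only if every range
    # containing it exceeds its own critical range
    exceeds <- matrix(TRUE, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        rp <- duncan_range(j - i + 1, df_err, mse, n, alpha)
        exceeds[i, j] <- (means[i] - means[j]) > rp
      }
    }
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        ok <- TRUE
        for (a in seq_len(i)) {
          for (b in j:k) {
            if (!exceeds[a, b]) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        different[i, j] <- different[j, i] <- ok
      }
    }
  } else {
    different[] <- outer(means, means, "!=")
  }
  lets <- insert_absorb(different, names(means))
  data.frame(group = names(means), n = n, mean = unname(means),
             letters = unname(lets), stringsAsFactors = FALSE,
             row.names = NULL)
}
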