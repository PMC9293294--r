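#' Fit a one-way mixed model of the emission factor for one controlling factor
#'
#' Fits `ef ~ 0 + class + (1 | location)` by REML: the factor classes enter
#' as fixed effects and the experimental location as a random intercept, so
#' repeated observations from one site are not treated as independent.
#' Classes with a sample size at or below `min_class_n` are dropped with a
#' warning before fitting (small classes bias fixed-effect estimates and
#' their errors); if fewer than two classes remain the factor is
#' unanalyzable.
#'
#' Per-class 95 % confidence intervals are `mean +/- t(df, 0.975) * SE` on
#' the marginal (fixed-effect) class means, with a containment-style residual
#' degrees of freedom `df = n_obs - n_classes - (n_locations - 1)`. The
#' overall p-value is a Wald F test of equal class means on the same df. AIC
#' comes from a maximum-likelihood refit so models with different fixed
#' effects are comparable; R^2 is the squared Pearson correlation between
#' observed EF and fitted values including the predicted random intercepts.
#'
#' @param observations Classified data frame with columns `ef`, `location`
#'   and the factor column (see [classify_dataset()]).
#' @param factor_name Name of the factor column, e.g. `"climate"`.
#' @param min_class_n Classes with `n <= min_class_n` are dropped (default
#'   20, i.e. the analysis is limited to sample sizes > 20).
#' @param var_location `NULL` (default) to estimate the location variance by
#'   REML, or `0` to fix it at zero, in which case the fit reduces to
#'   ordinary least squares on the class means.
#' @param alpha Significance level for the LSD letters.
#' @return An object of class `factor_model`: class means, CIs, LSD letters,
#'   pairwise p-values, variance components, p, R^2 and AIC.
#' @export
fit_factor_model <- function(observations, factor_name, min_class_n = 20,
                             var_location = NULL, alpha = 0.05) {
  if (!factor_name %in% names(observations)) {
    stop("no column `", factor_name, "` in the observations; classify first",
         call. = FALSE)
  }
  d <- observations[!is.na(observations[[factor_name]]) & !is.na(observations$ef), ,
                    drop = FALSE]
  if (nrow(d) == 0L) stop("no classified observations for factor `",
                          factor_name, "`", call. = FALSE)
  if (is.null(d$location)) stop("observations carry no `location` column",
                                call. = FALSE)
  cls_n <- table(d[[factor_name]])
  small <- names(cls_n)[cls_n <= min_class_n]
  if (length(small)) {
    warning("factor `", factor_name, "`: dropping class(es) with n <= ",
            min_class_n, ": ", paste(small, collapse = ", "), call. = FALSE)
    d <- d[!d[[factor_name]] %in% small, , drop = FALSE]
    cls_n <- cls_n[setdiff(names(cls_n), small)]
  }
  if (length(cls_n) < 2L) {
    stop("factor `", factor_name, "` is unanalyzable: fewer than 2 classes ",
         "with n > ", min_class_n, call. = FALSE)
  }
  d$.class <- factor(d[[factor_name]])
  d$.loc <- factor(d$location)
  classes <- levels(d$.class)
  n_obs <- nrow(d)
  n_loc <- nlevels(d$.loc)

  if (!is.null(var_location)) {
    if (!identical(as.numeric(var_location), 0)) {
      stop("`var_location` can only be fixed at 0 (or NULL to estimate)",
           call. = FALSE)
    }
    fit <- stats::lm(ef ~ 0 + .class, data = d)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    vl <- 0
    vr <- summary(fit)$sigma^2
    fitted_vals <- stats::fitted(fit)
    aic <- stats::AIC(fit)
  } else {
    fit <- lme4::lmer(ef ~ 0 + .class + (1 | .loc), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    vl <- vc$vcov[vc$grp == ".loc"]
    vr <- vc$vcov[vc$grp == "Residual"]
    if (vr <= 0) stop("singular fit: zero residual variance", call. = FALSE)
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    fitted_vals <- stats::fitted(fit)  # includes predicted random intercepts
    aic <- stats::AIC(stats::update(fit, REML = FALSE))
  }
  names(beta) <- classes
  dimnames(V) <- list(classes, classes)

  df_resid <- n_obs - length(classes) - (n_loc - 1)
  if (df_resid < 1) {
    warning("containment residual df < 1; clamped to 1", call. = FALSE)
    df_resid <- 1
  }
  se <- sqrt(diag(V))
  tq <- stats::qt(0.975, df_resid)
  ci <- cbind(low = beta - tq * se, high = beta + tq * se)

  ## Wald F test of equal class means
  k <- length(classes)
  L <- cbind(-1, diag(k - 1))
  Lb <- L %*% beta
  Fstat <- drop(t(Lb) %*% solve(L %*% V %*% t(L)) %*% Lb) / (k - 1)
  model_p <- stats::pf(Fstat, k - 1, df_resid, lower.tail = FALSE)

  r2 <- if (stats::sd(fitted_vals) == 0) {
    message("constant fitted values: R^2 undefined")
    NA_real_
  } else {
    stats::cor(d$ef, fitted_vals)^2
  }

  m <- structure(list(
    factor_name = factor_name,
    classes = classes,
    n_per_class = as.integer(cls_n[classes]),
    class_means = beta,
    se = se,
    ci95 = ci,
    vcov_fixed = V,
    df_residual = df_resid,
    model_p = model_p,
    f_statistic = Fstat,
    r2 = r2,
    aic = aic,
    var_location = vl,
    var_residual = vr,
    n_obs = n_obs,
    n_locations = n_loc,
    alpha = alpha,
    fit = fit
  ), class = "factor_model")
  lsd <- lsd_fisher(m, alpha = alpha)
  m$lsd_pairwise <- lsd$pairwise
  m$lsd_letters <- lsd$letters
  m
}

#' @export
print.factor_model <- function(x, ...) {
  cat("One-way mixed model of EF1, factor:", x$factor_name, "\n")
  cat(sprintf("  n = %d observations, %d locations; var(location) = %.3g, var(residual) = %.3g\n",
              x$n_obs, x$n_locations, x$var_location, x$var_residual))
  tab <- data.frame(class = x$classes, n = x$n_per_class,
                    mean = round(x$class_means, 4),
                    ci_low = round(x$ci95[, "low"], 4),
                    ci_high = round(x$ci95[, "high"], 4),
                    letters = x$lsd_letters[x$classes])
  print(tab, row.names = FALSE)
  cat(sprintf("  p = %.4g%s, R2 = %.3g, AIC = %.1f\n", x$model_p,
              if (x$model_p >= 0.05) " (non-significant)" else "",
              x$r2, x$aic))
  invisible(x)
}

#' LSD Fisher pairwise comparisons and letter display
#'
#' Unadjusted pairwise t tests on the differences of estimated class means,
#' using the model's fixed-effect covariance and the containment residual
#' degrees of freedom. Letters are assigned by the insert-and-absorb
#' algorithm: two classes share at least one letter exactly when their
#' pairwise difference is not significant at `alpha`. When pairwise
#' significance is intransitive a class may carry several letters. Letters
#' are ordered by ascending class mean (A = lowest).
#'
#' @param model A `factor_model` from [fit_factor_model()].
#' @param alpha Significance level (default 0.05).
#' @return List with `pairwise` (data frame: class pair, estimated
#'   difference, SE, t, df, p) and `letters` (named character vector).
#' @export
lsd_fisher <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "factor_model"))
  k <- length(model$classes)
  if (k < 2L) stop("LSD comparison needs at least 2 classes", call. = FALSE)
  b <- model$class_means
  V <- model$vcov_fixed
  pairs <- utils::combn(k, 2)
  est <- se <- tval <- pval <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est[j] <- b[i1] - b[i2]
    se[j] <- sqrt(V[i1, i1] + V[i2, i2] - 2 * V[i1, i2])
    tval[j] <- est[j] / se[j]
    pval[j] <- 2 * stats::pt(-abs(tval[j]), model$df_residual)
  }
  pw <- data.frame(class1 = model$classes[pairs[1, ]],
                   class2 = model$classes[pairs[2, ]],
                   estimate = est, se = se, t = tval,
                   df = model$df_residual, p = pval,
                   stringsAsFactors = FALSE)
  pmat <- matrix(1, k, k, dimnames = list(model$classes, model$classes))
  for (j in seq_len(ncol(pairs))) {
    pmat[pairs[1, j], pairs[2, j]] <- pmat[pairs[2, j], pairs[1, j]] <- pval[j]
  }
  letters <- lsd_letters(pmat, means = b, alpha = alpha)
  list(pairwise = pw, letters = letters)
}

## Insert-and-absorb letter display from a symmetric pairwise p matrix.
## Invariant: classes share a letter iff pmat >= alpha for the pair.
lsd_letters <- function(pmat, means, alpha = 0.05) {
  classes <- rownames(pmat)
  k <- length(classes)
  ## columns = letter groups, start with one group holding everything
  groups <- list(rep(TRUE, k))
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig)) {
    ## process pairs deterministically
    ord <- order(sig[, 1], sig[, 2])
    for (r in ord) {
      i <- sig[r, 1]; j <- sig[r, 2]
      new_groups <- list()
      for (g in groups) {
        if (g[i] && g[j]) {
          g1 <- g; g1[i] <- FALSE
          g2 <- g; g2[j] <- FALSE
          new_groups <- c(new_groups, list(g1, g2))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      ## absorb: drop groups contained in another group
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_groups[[a]] <= new_groups[[b]]) &&
              !identical(new_groups[[a]], new_groups[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      ## drop exact duplicates too
      groups <- unique(new_groups[keep])
    }
  }
  ## order letter groups by the mean of their lowest-mean member (A = lowest)
  g_rank <- vapply(groups, function(g) min(means[g]), numeric(1))
  groups <- groups[order(g_rank)]
  out <- vapply(seq_len(k), function(i) {
    paste0(LETTERS[which(vapply(groups, function(g) g[i], logical(1)))],
           collapse = "")
  }, character(1))
  stats::setNames(out, classes)
}

#' Merge factor classes whose means are statistically indistinguishable
#'
#' Refits the factor model and merges the candidate classes if and only if
#' every pairwise LSD comparison among them is non-significant
#' (`p >= alpha`). Returns the (possibly) relabelled observations together
#' with an auditable decision record. Re-running on already-merged output is
#' a no-op.
#'
#' @param observations Classified data frame.
#' @param factor_name Factor column name.
#' @param candidate Character vector (>= 2) of class labels to consider
#'   merging.
#' @param merged_label Label for the merged class; defaults to the candidates
#'   joined with `"+"` in sorted order.
#' @param alpha Significance threshold.
#' @inheritParams fit_factor_model
#' @return List with `observations` (factor column updated when merged),
#'   `merged` (logical), `merge_map` (named old -> new labels) and
#'   `decision` (data frame of the pairwise tests backing the call).
#' @export
merge_classes <- function(observations, factor_name, candidate,
                          merged_label = NULL, alpha = 0.05, min_class_n = 20) {
  cls <- observations[[factor_name]]
  if (is.null(cls)) stop("no column `", factor_name, "`", call. = FALSE)
  if (length(candidate) < 2L) stop("need at least 2 candidate classes", call. = FALSE)
  if (is.null(merged_label)) {
    merged_label <- paste(sort(candidate), collapse = "+")
  }
  present <- unique(stats::na.omit(cls))
  if (!all(candidate %in% present)) {
    if (merged_label %in% present && !any(candidate %in% present)) {
      ## already merged: idempotent no-op
      return(list(observations = observations, merged = TRUE,
                  merge_map = stats::setNames(rep(merged_label, length(candidate)),
                                              candidate),
                  decision = data.frame()))
    }
    stop("unknown class label(s) for factor `", factor_name, "`: ",
         paste(setdiff(candidate, present), collapse = ", "), call. = FALSE)
  }
  model <- fit_factor_model(observations, factor_name, min_class_n = min_class_n,
                            alpha = alpha)
  pw <- model$lsd_pairwise
  rel <- pw[pw$class1 %in% candidate & pw$class2 %in% candidate, , drop = FALSE]
  do_merge <- nrow(rel) > 0L && all(rel$p >= alpha)
  decision <- cbind(rel, merged = do_merge)
  if (do_merge) {
    cls[cls %in% candidate] <- merged_label
    observations[[factor_name]] <- cls
    merge_map <- stats::setNames(rep(merged_label, length(candidate)), candidate)
  } else {
    merge_map <- stats::setNames(candidate, candidate)
  }
  list(observations = observations, merged = do_merge,
       merge_map = merge_map, decision = decision)
}

#' Extract the fit statistics of a factor model
#'
#' @param model A `factor_model`.
#' @return List with `p` (Wald F test of equal class means), `r2` (squared
#'   correlation of observed and fitted EF, random intercepts included),
#'   `aic` (ML refit) and `significant` (`p < 0.05`, mirroring the bold-face
#'   convention used to flag non-significant models in summary tables).
#' @export
model_metrics <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  list(p = model$model_p, r2 = model$r2, aic = model$aic,
       significant = is.finite(model$model_p) && model$model_p < 0.05)
}

#' Summarize fitted factor models as a results table
#'
#' One row per class, mirroring the usual presentation of disaggregated EF1
#' tables: factor, class, n, mean, 95 % CI, LSD letters, and the model-level
#' p, R^2 and AIC repeated on each row of its factor.
#'
#' @param models A `factor_model` or list of them.
#' @return Data frame ready for [write_ef_csv()].
#' @export
factor_results_table <- function(models) {
  if (inherits(models, "factor_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    data.frame(factor = m$factor_name,
               class = m$classes,
               n = m$n_per_class,
               mean = unname(m$class_means),
               ci_low = unname(m$ci95[, "low"]),
               ci_high = unname(m$ci95[, "high"]),
               letters = unname(m$lsd_letters[m$classes]),
               p = m$model_p,
               r2 = m$r2,
               aic = m$aic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
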