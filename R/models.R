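#' Rank features by random-forest Gini importance
#'
#' Fits a seeded random forest and ranks features by mean decrease in node
#' impurity (Gini importance), normalized to sum to 1. Ties are broken by
#' feature-name order so the ranking is fully deterministic given the seed.
#'
#' @param table feature `data.frame` containing `label` plus the candidate
#'   feature columns.
#' @param features candidate feature names (default: all numeric columns
#'   except identifiers).
#' @param n_trees number of trees.
#' @param k number of top features to mark selected.
#' @param seed integer seed.
#' @return list of class `ranked_features`: `importance` (named, sorted,
#'   sums to 1), `ranking`, `selected` (top k), `k`.
#' @export
rank_features_gini <- function(table, features = NULL, n_trees = 500,
                               k = 5, seed = 1L) {
  lab <- droplevels(factor(table$label))
  if (nlevels(lab) < 2) stop("need at least 2 classes in labels")
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c("age"))
  x <- table[, features, drop = FALSE]
  if (anyNA(x)) stop("missing values in feature table")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = lab, ntree = n_trees)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  k <- min(k, length(imp))
  structure(list(importance = imp, ranking = names(imp),
                 selected = names(imp)[seq_len(k)], k = k),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat("Gini feature ranking (importances sum to 1):\n")
  for (i in seq_along(x$importance))
    cat(sprintf("  %2d. %-18s %.4f%s\n", i, x$ranking[i], x$importance[i],
                if (i <= x$k) "  *" else ""))
  invisible(x)
}

#' Fit the texture-analysis random-forest model
#'
#' Random-forest classifier on the selected texture features; predicted
#' probability of nonresponse is the fraction of trees voting for that
#' class (soft voting). Defaults mirror common radiomics practice: 500
#' trees, unrestricted depth, sqrt(p) candidate features per split, no
#' class weighting.
#'
#' @param table training feature table with a `label` column.
#' @param features feature names to use; the conventional five-feature
#'   texture signature by default.
#' @param n_trees,mtry,max_nodes forest hyperparameters (`NULL` = package
#'   defaults).
#' @param seed integer seed.
#' @return Object of class `ta_model`.
#' @export
fit_ta_model <- function(table,
                         features = c("post_mean", "mean_change",
                                      "post_skewness", "post_entropy",
                                      "entropy_change"),
                         n_trees = 500, mtry = NULL, max_nodes = NULL,
                         seed = 1L) {
  missing_f <- setdiff(features, names(table))
  if (length(missing_f))
    stop("features absent from table: ", paste(missing_f, collapse = ", "))
  lab <- factor(as.character(table$label),
                levels = c("response", "nonresponse"))
  x <- table[, features, drop = FALSE]
  set.seed(seed)
  args <- list(x = x, y = lab, ntree = n_trees)
  if (!is.null(mtry)) args$mtry <- mtry
  if (!is.null(max_nodes)) args$maxnodes <- max_nodes
  rf <- do.call(randomForest::randomForest, args)
  structure(list(forest = rf, features = features, n_trees = n_trees,
                 seed = seed),
            class = "ta_model")
}

#' @param object a `ta_model`.
#' @param newdata feature table to score.
#' @param ... unused.
#' @return Numeric vector of nonresponse probabilities in \[0, 1\].
#' @rdname fit_ta_model
#' @export
predict.ta_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f))
    stop("unseen feature names at predict: ",
         paste(missing_f, collapse = ", "))
  pr <- stats::predict(object$forest,
                       newdata = newdata[, object$features, drop = FALSE],
                       type = "prob")
  as.numeric(pr[, "nonresponse"])
}

#' Screen ADC candidates by group difference
#'
#' Returns the subset of the three manual ADC quantities whose two-group
#' comparison (test chosen by the normality rule of
#' [compare_groups_numeric()]) is significant at `alpha`.
#'
#' @param table feature table with `label` and the ADC columns.
#' @param candidates columns to screen.
#' @param alpha significance level.
#' @return Character vector of significant candidates (with per-candidate
#'   p-values as an attribute `p_values`).
#' @export
select_significant_adc_candidates <- function(
    table, candidates = c("pre_ADC", "post_ADC", "ADC_change"),
    alpha = 0.05) {
  p <- vapply(candidates, function(f)
    compare_groups_numeric(table[[f]], table$label)$p_value, numeric(1))
  out <- candidates[p < alpha]
  attr(out, "p_values") <- p
  out
}

#' Forward likelihood-ratio stepwise logistic regression
#'
#' Builds a binary logistic model by forward selection on likelihood-ratio
#' tests: at each step the candidate with the smallest LR-test p-value
#' enters if p < `p_enter`; entered terms are then re-tested and removed if
#' their removal p-value exceeds `p_remove`; iteration stops when nothing
#' changes. If a fit shows quasi-complete separation, coefficients for that
#' model are taken from a lightly ridge-penalized fit (the LR deviances,
#' which remain finite, still drive selection) and a warning is issued.
#'
#' @param table data with outcome and candidates.
#' @param candidates candidate predictor names (numeric).
#' @param p_enter,p_remove entry and removal thresholds.
#' @return Object of class `adc_logistic_model`: `entered`, `coefficients`
#'   table, `fit` (the final `glm`), `steps` log, `separation` flag.
#' @export
forward_lr_logistic <- function(table, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  y <- as_binary_labels(table$label)
  dat <- data.frame(.y = y, table[, candidates, drop = FALSE],
                    check.names = FALSE)
  separation <- FALSE
  fit_glm <- function(terms) {
    fml <- if (length(terms))
      stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    else stats::as.formula(".y ~ 1")
    withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  entered <- character(0)
  steps <- list()
  seen <- character(0)   # visited model signatures; stepwise can cycle
  repeat {
    sig <- paste(sort(entered), collapse = "+")
    if (sig %in% seen) break
    seen <- c(seen, sig)
    changed <- FALSE
    base_fit <- fit_glm(entered)
    pool <- setdiff(candidates, entered)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        if (stats::var(dat[[cand]]) == 0) return(1)
        f1 <- fit_glm(c(entered, cand))
        stats::pchisq(base_fit$deviance - f1$deviance, df = 1,
                      lower.tail = FALSE)
      }, numeric(1))
      best <- which.min(pvals)
      if (pvals[best] < p_enter) {
        entered <- c(entered, pool[best])
        steps[[length(steps) + 1]] <- list(action = "enter",
                                           term = pool[best],
                                           p = unname(pvals[best]))
        changed <- TRUE
      }
    }
    if (length(entered) > 1) {
      full_fit <- fit_glm(entered)
      prem <- vapply(entered, function(term) {
        f0 <- fit_glm(setdiff(entered, term))
        stats::pchisq(f0$deviance - full_fit$deviance, df = 1,
                      lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(prem)
      if (prem[worst] > p_remove) {
        steps[[length(steps) + 1]] <- list(action = "remove",
                                           term = entered[worst],
                                           p = unname(prem[worst]))
        entered <- entered[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- fit_glm(entered)
  coef_tab <- summary(fit)$coefficients
  if (separation && length(entered)) {
    warning("quasi-complete separation detected; reporting ridge-penalized coefficients")
    xm <- as.matrix(dat[, entered, drop = FALSE])
    if (ncol(xm) == 1) xm <- cbind(xm, 0)   # glmnet needs >= 2 columns
    rg <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    b <- as.numeric(stats::coef(rg))[seq_len(length(entered) + 1)]
    coef_tab <- cbind(Estimate = b,
                      `Std. Error` = NA_real_, `z value` = NA_real_,
                      `Pr(>|z|)` = NA_real_)
    rownames(coef_tab) <- c("(Intercept)", entered)
  }
  structure(list(entered = entered, coefficients = coef_tab, fit = fit,
                 candidates = candidates, steps = steps,
                 p_enter = p_enter, p_remove = p_remove,
                 separation = separation),
            class = "adc_logistic_model")
}

#' @param object an `adc_logistic_model`.
#' @param newdata data containing the entered terms.
#' @param ... unused.
#' @return Predicted nonresponse probabilities.
#' @rdname forward_lr_logistic
#' @export
predict.adc_logistic_model <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit, newdata = newdata,
                            type = "response"))
}

#' @export
print.adc_logistic_model <- function(x, ...) {
  cat("Forward-LR logistic model\n")
  cat("  entered terms:",
      if (length(x$entered)) paste(x$entered, collapse = ", ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}
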