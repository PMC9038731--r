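# Plot-level additive growth models: penalized-spline GAMs of ln growth,
# variance partitioning for the fungal predictor, collinearity screening,
# partial-residual back-transformation, and group contrasts.

# Covariates entering linearly; stand age and density get smooths.
linear_covariates <- c("MAT", "MAP", "N_deposition", "soil_pH",
                       "inorganic_N", "leaf_type")
smooth_covariates <- c("stand_age_class", "stem_density")

#' Fit the additive growth model
#'
#' Models ln(mean tree growth, kg C yr^-1) at the plot level with
#' penalized-regression-spline smooths for stand age class and stem density
#' (basis dimension `k_basis`), linear terms for the remaining covariates,
#' and optionally a linear fungal predictor (community axis, CWM trait or
#' exploration-type abundance; fungal predictors enter without smoothing).
#' Smoothing parameters are estimated by restricted maximum likelihood.
#' Only complete cases are fitted; dropped rows are recorded.
#'
#' @param frame data.frame with column `ln_growth`, the covariates in
#'   [linear_covariates] and [smooth_covariates], and (optionally) the
#'   fungal predictor column.
#' @param fungal name of the fungal predictor column, or `NULL` for the
#'   reduced (environment-only) model.
#' @param k_basis smooth basis dimension (default 5).
#' @param linear,smooth covariate sets entering linearly and as
#'   penalized-spline smooths; the defaults are the full covariate set the
#'   analysis uses.
#' @return object of class `growth_model`: the `mgcv::gam` fit plus
#'   `r_squared` (1 - RSS/TSS on the ln scale), `frame`, `fungal`,
#'   `n_dropped`.
#' @export
fit_growth_model <- function(frame, fungal = NULL, k_basis = 5,
                             linear = linear_covariates,
                             smooth = smooth_covariates) {
  vars <- c("ln_growth", linear, smooth, fungal)
  missing_cols <- setdiff(vars, names(frame))
  assert_that(length(missing_cols) == 0,
              "model frame lacks columns: ",
              paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(frame[vars])
  data <- frame[cc, , drop = FALSE]
  assert_that(nrow(data) >= length(vars) + 10,
              "too few complete plots for the model")
  if ("leaf_type" %in% vars) data$leaf_type <- factor(data$leaf_type)
  rhs <- c(
    if (length(smooth)) sprintf("s(%s, k = %d)", smooth, k_basis),
    linear,
    fungal
  )
  form <- stats::as.formula(paste("ln_growth ~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(form, data = data, method = "REML")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((data$ln_growth - mean(data$ln_growth))^2)
  structure(list(fit = fit, r_squared = 1 - rss / tss, frame = data,
                 fungal = fungal, n_dropped = sum(!cc)),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Additive growth model on ln(kg C yr^-1); n =", nrow(x$frame),
      if (x$n_dropped) paste0("(", x$n_dropped, " incomplete dropped)"),
      "\n  fungal predictor:", if (is.null(x$fungal)) "none" else x$fungal,
      "\n  R^2 =", round(x$r_squared, 3), "\n")
  invisible(x)
}

#' Variance explained by adding the fungal predictor
#'
#' R^2 difference between a full model and a reduced model nested within it,
#' both fitted to the same plots.
#'
#' @param full,reduced `growth_model` fits.
#' @return numeric Delta R^2.
#' @export
delta_r_squared <- function(full, reduced) {
  assert_that(nrow(full$frame) == nrow(reduced$frame) &&
                all(full$frame$plot_id == reduced$frame$plot_id),
              "models must be fitted to the same plots")
  full$r_squared - reduced$r_squared
}

#' Variance inflation factors for the linear predictors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the other linear
#' predictors; factors are coded as indicators.
#'
#' @param frame model frame.
#' @param predictors columns to screen (default: the linear covariates plus
#'   smooth covariates treated linearly).
#' @return named numeric vector of VIFs.
#' @export
vif_report <- function(frame,
                       predictors = c(linear_covariates, smooth_covariates)) {
  assert_that(length(predictors) >= 2, "need >= 2 predictors")
  data <- as.data.frame(frame)[predictors]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  X <- stats::model.matrix(~ ., data = data)[, -1, drop = FALSE]
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop_invalid("perfectly collinear predictors: VIF is infinite")
  }
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Partial residuals for one model term
#'
#' y_i = f(x_i^focal) + sum_{j != focal} f_j(xbar_j) + eps_i on the ln scale:
#' the focal term's fitted contribution at each observation, plus every
#' other term evaluated at the covariate means (factors at their first
#' fitted level), plus the model residuals. With `back_transform = TRUE`
#' the result is exponentiated to kg C yr^-1 so partial effects read on the
#' original growth scale.
#'
#' @param model a `growth_model`.
#' @param focal term label: a linear covariate name or a smooth covariate
#'   name (matched to its smooth).
#' @param back_transform exponentiate to the response scale (default TRUE).
#' @return data.frame with `plot_id`, `focal_value`, `partial_residual`.
#' @export
partial_residuals <- function(model, focal, back_transform = TRUE) {
  fit <- model$fit
  tm <- stats::predict(fit, type = "terms")
  labels <- colnames(tm)
  hit <- which(labels == focal | labels == sprintf("s(%s)", focal))
  if (length(hit) != 1) {
    stop_invalid("focal term not in model: ", focal,
                 " (terms: ", paste(labels, collapse = ", "), ")")
  }
  data <- model$frame
  means <- data[1, , drop = FALSE]
  for (v in names(means)) {
    if (is.numeric(data[[v]])) means[[v]] <- mean(data[[v]])
    else means[[v]] <- sort(unique(data[[v]]))[1]
  }
  tmbar <- stats::predict(fit, newdata = means, type = "terms")
  const <- attr(tm, "constant") + sum(tmbar[1, -hit])
  y <- tm[, hit] + const + stats::residuals(fit)
  if (back_transform) y <- exp(y)
  data.frame(plot_id = data$plot_id,
             focal_value = data[[focal]],
             partial_residual = unname(y),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch's heteroscedastic t-test
#'
#' Two-sided t-test with unequal variances and Welch-Satterthwaite degrees
#' of freedom.
#'
#' @param x,y numeric samples with >= 2 finite values each.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  assert_that(length(x) >= 2 && length(y) >= 2,
              "both samples need >= 2 finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      stop_invalid("degenerate input: both samples constant and equal")
    }
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Compare stand growth between slow and fast community classes
#'
#' Within each leaf type, contrasts mean stand growth of plots whose
#' community cluster was classified slow versus fast, using Welch's t-test.
#' Leaf types missing either class are reported as untestable rather than
#' raising an error.
#'
#' @param stand stand growth table with `plot_id` and `mean_growth`
#'   (Mg C ha^-1 yr^-1).
#' @param classification output of [anom_classify()] (columns `cluster`,
#'   `class`), or a list of such tables keyed by leaf type when
#'   classification was run per leaf type.
#' @param labels named vector mapping plot id to cluster.
#' @param leaf_type named vector mapping plot id to leaf type; use a single
#'   constant to pool all plots.
#' @return data.frame with one row per leaf type: `leaf_type`, `n_slow`,
#'   `n_fast`, `slow_mean`, `fast_mean`, `ratio` (fast/slow), `t`, `df`,
#'   `p`, `testable`.
#' @export
compare_growth_classes <- function(stand, classification, labels, leaf_type) {
  plots <- intersect(stand$plot_id, names(labels))
  growth <- stats::setNames(stand$mean_growth,
                            stand$plot_id)[plots]
  lt <- leaf_type[plots]
  per_leaf <- is.list(classification) && !is.data.frame(classification)
  rows <- lapply(unique(lt), function(l) {
    cls <- if (per_leaf) classification[[l]] else classification
    sel <- lt == l
    cl <- as.character(labels[plots][sel])
    cls_map <- stats::setNames(cls$class, as.character(cls$cluster))
    plot_class <- cls_map[cl]
    slow <- growth[sel][plot_class == "slow" & !is.na(plot_class)]
    fast <- growth[sel][plot_class == "fast" & !is.na(plot_class)]
    base <- data.frame(leaf_type = l, n_slow = length(slow),
                       n_fast = length(fast),
                       slow_mean = if (length(slow)) mean(slow) else NA_real_,
                       fast_mean = if (length(fast)) mean(fast) else NA_real_,
                       stringsAsFactors = FALSE)
    if (length(slow) >= 2 && length(fast) >= 2) {
      wt <- welch_t(fast, slow)
      cbind(base, ratio = base$fast_mean / base$slow_mean, t = wt$t,
            df = wt$df, p = wt$p, testable = TRUE)
    } else {
      cbind(base, ratio = NA_real_, t = NA_real_, df = NA_real_,
            p = NA_real_, testable = FALSE)
    }
  })
  do.call(rbind, rows)
}
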