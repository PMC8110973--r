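# Quantile-regression age calibration. A linear tau-quantile regression
# with two free parameters always admits an optimal line interpolating two
# data points, so the exact fit is found by enumerating point pairs and
# minimising the check loss -- deterministic, with no solver dependence.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Fit exact linear quantile regressions of age on an ordination score
#'
#' For each requested quantile level the check (pinball) loss
#' \eqn{\sum_i \rho_\tau(y_i - b_0 - b_1 x_i)} is minimised exactly over
#' candidate lines through data-point pairs. Deterministic given the input
#' order; ties in loss are broken toward the smallest `|slope|`, then the
#' smallest intercept.
#'
#' @param x predictor scores (one per dated fauna).
#' @param y known ages, Ma.
#' @param taus quantile levels; default `c(0.05, 0.5, 0.95)` giving the
#'   lower bound, point and upper bound lines.
#' @param predictor label for the score used (e.g. `"ca_axis1"`).
#' @return object of class `calibration_model`: per-tau `coefficients`
#'   (intercept, slope), the calibration data, and the predictor label.
#' @export
fit_quantile_regression <- function(x, y, taus = c(0.05, 0.5, 0.95),
                                    predictor = "score") {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("quantile regression needs >= 3 dated faunas")
  if (stats::sd(x) == 0) stop("constant predictor: cannot calibrate")
  if (any(taus <= 0 | taus >= 1)) stop("taus must lie strictly in (0, 1)")
  n <- length(x)
  pairs <- utils::combn(n, 2)
  dx <- x[pairs[1, ]] - x[pairs[2, ]]
  keep <- abs(dx) > 1e-12
  slope <- (y[pairs[1, keep]] - y[pairs[2, keep]]) / dx[keep]
  inter <- y[pairs[1, keep]] - slope * x[pairs[1, keep]]
  # horizontal candidates through each point guard degenerate layouts
  slope <- c(slope, rep(0, n))
  inter <- c(inter, y)
  coefs <- vapply(taus, function(tau) {
    loss <- vapply(seq_along(slope), function(k)
      check_loss(y - inter[k] - slope[k] * x, tau), 0)
    best <- which(loss <= min(loss) + 1e-9)
    best <- best[order(abs(slope[best]), inter[best])][1]
    c(intercept = inter[best], slope = slope[best])
  }, c(intercept = 0, slope = 0))
  structure(list(taus = taus,
                 coefficients = t(coefs),
                 x = x, y = y, predictor = predictor),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("quantile-regression calibration on", x$predictor, "\n")
  tab <- data.frame(tau = x$taus, x$coefficients)
  print(tab, row.names = FALSE)
  cat(sprintf("  PPE: %.2f%%\n", ppe(x)))
  invisible(x)
}

#' Predict ages from a calibration model
#' @param object a `calibration_model`.
#' @param newdata numeric vector of scores.
#' @param tau one of the fitted quantile levels (default the median).
#' @param ... unused.
#' @export
predict.calibration_model <- function(object, newdata = object$x, tau = 0.5,
                                      ...) {
  k <- match(tau, object$taus)
  if (is.na(k)) stop("tau ", tau, " was not fitted")
  b <- object$coefficients[k, ]
  b[1] + b[2] * newdata
}

#' Prediction percentage error of a calibration equation
#'
#' Mean absolute relative error of the median-line predictions on the
#' calibration faunas, in percent. The denominator is the predicted value
#' by default (the %PE convention); `denominator = "observed"` toggles the
#' alternative.
#'
#' @param model a `calibration_model`.
#' @param x,y evaluation data; defaults to the calibration data.
#' @param denominator `"predicted"` or `"observed"`.
#' @param loo recompute each prediction leaving that fauna out of the fit.
#' @return percentage error (`>= 0`).
#' @export
ppe <- function(model, x = NULL, y = NULL,
                denominator = c("predicted", "observed"), loo = FALSE) {
  denominator <- match.arg(denominator)
  if (is.null(x) != is.null(y)) stop("supply both x and y or neither")
  if (is.null(x)) { x <- model$x; y <- model$y }
  if (loo) {
    yhat <- vapply(seq_along(x), function(i) {
      fit <- fit_quantile_regression(model$x[-i], model$y[-i], taus = 0.5,
                                     predictor = model$predictor)
      predict.calibration_model(fit, x[i], tau = 0.5)
    }, 0)
  } else {
    yhat <- predict.calibration_model(model, x, tau = 0.5)
  }
  den <- if (denominator == "predicted") yhat else y
  if (any(den <= 0))
    stop("non-positive denominator age; PPE undefined")
  mean(abs(y - yhat) / den) * 100
}

#' Estimate ages of undated faunas from a set of calibration equations
#'
#' Equations whose prediction percentage error is below `threshold` are
#' retained; each contributes a median-line point age and lower/upper bound
#' ages from the outer quantile lines. Per fauna the reported age,
#' `age_max` (older bound) and `age_min` (younger bound) are medians across
#' the selected equations.
#'
#' @param models list of `calibration_model` objects (e.g. one per
#'   ordination axis and the AEO score).
#' @param targets named list (by predictor label, matching the models) of
#'   named score vectors for the undated faunas; or a single named vector
#'   applied to every model.
#' @param threshold PPE selection threshold in percent (default 10).
#' @param ... passed to [ppe()] (e.g. `loo = TRUE`).
#' @return data.frame of class `age_estimates`: fauna, `age`, `age_max`,
#'   `age_min` (Ma), `n_equations`; the per-equation table is attached as
#'   the `equations` attribute.
#' @export
estimate_ages <- function(models, targets, threshold = 10, ...) {
  ppes <- vapply(models, ppe, 0, ...)
  keep <- ppes < threshold
  if (!any(keep))
    stop(sprintf(
      "no calibration equation has PPE below %g%% (best: %s = %.2f%%)",
      threshold, models[[which.min(ppes)]]$predictor, min(ppes)))
  models <- models[keep]
  per_model <- lapply(models, function(mod) {
    sc <- if (is.list(targets)) targets[[mod$predictor]] else targets
    if (is.null(sc)) stop("no target scores for predictor ", mod$predictor)
    lo_tau <- min(mod$taus); hi_tau <- max(mod$taus)
    point <- predict.calibration_model(mod, sc, tau = 0.5)
    b1 <- predict.calibration_model(mod, sc, tau = lo_tau)
    b2 <- predict.calibration_model(mod, sc, tau = hi_tau)
    data.frame(fauna = names(sc), predictor = mod$predictor,
               age = point, age_max = pmax(b1, b2), age_min = pmin(b1, b2),
               row.names = NULL)
  })
  eq <- do.call(rbind, per_model)
  agg <- function(col) tapply(eq[[col]], eq$fauna, stats::median)
  faunas <- sort(unique(eq$fauna))
  out <- data.frame(fauna = faunas,
                    age = as.numeric(agg("age")[faunas]),
                    age_max = as.numeric(agg("age_max")[faunas]),
                    age_min = as.numeric(agg("age_min")[faunas]),
                    n_equations = as.integer(table(eq$fauna)[faunas]),
                    row.names = NULL)
  attr(out, "equations") <- eq
  attr(out, "ppe") <- ppes
  class(out) <- c("age_estimates", "data.frame")
  out
}

#' Build the standard candidate-equation set
#'
#' One calibration model per candidate predictor: the AEO score and axes 1
#' and 2 of each ordination (NMDS and PCO on both coefficients, CA),
#' regressed on the known ages of the dated faunas.
#'
#' @param ordinations named list from [ordinate_all()].
#' @param aeo an `aeo` object from [ml_aeo()], or `NULL`.
#' @param ages named vector of known ages (Ma); faunas with `NA` are the
#'   calibration targets and are excluded from the fits.
#' @param taus quantile levels, as in [fit_quantile_regression()].
#' @return list with `models` (the fitted equations) and `targets` (scores
#'   of the undated faunas per predictor).
#' @export
candidate_equations <- function(ordinations, aeo = NULL, ages,
                                taus = c(0.05, 0.5, 0.95)) {
  preds <- list()
  for (nm in names(ordinations)) {
    sc <- ordinations[[nm]]$scores
    for (ax in seq_len(min(2L, ncol(sc))))
      preds[[paste0(nm, "_axis", ax)]] <- sc[, ax]
  }
  if (!is.null(aeo))
    preds[["aeo"]] <- stats::setNames(aeo$scores$score, aeo$scores$fauna)
  dated <- names(ages)[!is.na(ages)]
  undated <- setdiff(names(ages), dated)
  models <- list()
  targets <- list()
  for (nm in names(preds)) {
    sc <- preds[[nm]]
    fit <- try(fit_quantile_regression(sc[dated], ages[dated], taus = taus,
                                       predictor = nm), silent = TRUE)
    if (inherits(fit, "try-error")) next
    models[[nm]] <- fit
    targets[[nm]] <- sc[undated]
  }
  if (!length(models)) stop("no candidate equation could be fitted")
  list(models = models, targets = targets)
}

#' Spearman correlation of ordination scores with geography
#'
#' Tests whether the seriation axes track geography rather than time:
#' Spearman's rho between each axis and each coordinate, with rho^2
#' reported as percent variation explained.
#'
#' @param scores matrix of fauna scores (faunas in rows) or a named vector.
#' @param metadata a [fauna_metadata()] with `latitude`/`longitude`.
#' @return data.frame: axis, coordinate, rho, pct_explained, p_value.
#' @export
geography_correlation <- function(scores, metadata) {
  if (is.null(dim(scores)))
    scores <- matrix(scores, dimnames = list(names(scores), "axis1"))
  faunas <- intersect(rownames(scores), metadata$fauna)
  if (length(faunas) < 4) stop("need >= 4 faunas with coordinates")
  md <- metadata[match(faunas, metadata$fauna), ]
  out <- list()
  for (ax in colnames(scores)) for (coord in c("latitude", "longitude")) {
    v <- md[[coord]]
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        axis = ax, coordinate = coord, rho = NA_real_,
        pct_explained = NA_real_, p_value = NA_real_, note = "constant")
      next
    }
    ok <- !is.na(v)
    ct <- suppressWarnings(stats::cor.test(scores[faunas, ax][ok], v[ok],
                                           method = "spearman",
                                           exact = sum(ok) <= 10))
    out[[length(out) + 1L]] <- data.frame(
      axis = ax, coordinate = coord, rho = unname(ct$estimate),
      pct_explained = 100 * unname(ct$estimate)^2,
      p_value = ct$p.value, note = "")
  }
  do.call(rbind, out)
}
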