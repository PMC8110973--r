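#' Reference constants for 40Ar/39Ar reduction
#'
#' Total 40K decay constant (1/yr), the Fish Canyon sanidine monitor age
#' (Ma) used to solve the irradiation parameter J, and the atmospheric
#' 40Ar/36Ar ratio (modern value 298.56 by default; the older 295.5
#' convention is provided as `atm_legacy`). Every result object carries the
#' constants it was computed with.
#'
#' @return named list: `lambda`, `monitor_age`, `monitor_err`, `atm`,
#'   `atm_legacy`.
#' @export
argon_constants <- function() {
  list(lambda = 5.463e-10, monitor_age = 28.201, monitor_err = 0.046,
       atm = 298.56, atm_legacy = 295.5)
}

#' 40Ar/39Ar age equation
#'
#' \eqn{t = \lambda^{-1} \ln(1 + J R)} with `R` the radiogenic 40Ar*/39Ar
#' ratio; first-order error propagation over `R` and `J`.
#'
#' @param R radiogenic 40Ar*/39Ar ratio(s).
#' @param J irradiation parameter.
#' @param sR,sJ 1-sigma uncertainties (default 0).
#' @param lambda decay constant (1/yr).
#' @return data.frame with `age` (Ma) and `sigma` (1-sigma, Ma).
#' @export
ar_age <- function(R, J, sR = 0, sJ = 0, lambda = argon_constants()$lambda) {
  if (J <= 0 || lambda <= 0) stop("J and lambda must be positive")
  arg <- 1 + J * R
  if (any(arg <= 0)) stop("1 + J*R must be positive (age undefined)")
  t_yr <- log(arg) / lambda
  dR <- J / (lambda * arg)
  dJ <- R / (lambda * arg)
  sig <- sqrt((dR * sR)^2 + (dJ * sJ)^2)
  data.frame(age = t_yr / 1e6, sigma = sig / 1e6)
}

#' Solve J from a monitor of known age
#' @param R monitor 40Ar*/39Ar ratio.
#' @param age_ma monitor age (Ma), default Fish Canyon sanidine.
#' @param lambda decay constant (1/yr).
#' @return the irradiation parameter J.
#' @export
solve_j <- function(R, age_ma = argon_constants()$monitor_age,
                    lambda = argon_constants()$lambda) {
  (exp(lambda * age_ma * 1e6) - 1) / R
}

#' Construct a step-heating spectrum
#'
#' @param f39 per-step fraction of total 39Ar released (sums to 1).
#' @param R per-step 40Ar*/39Ar ratios.
#' @param sR per-step 1-sigma on `R`.
#' @param J,sJ irradiation parameter and its 1-sigma.
#' @param lambda decay constant (1/yr).
#' @param r36_40,s36,r39_40,s39 optional raw inverse-isochron ratios
#'   (36Ar/40Ar and 39Ar/40Ar) with 1-sigma errors.
#' @param corr optional per-step error correlation between the raw ratios.
#' @return object of class `step_heating_spectrum` (a data.frame of steps
#'   with `J`, `sJ`, `lambda` attributes).
#' @export
step_heating_spectrum <- function(f39, R, sR, J, sJ = 0,
                                  lambda = argon_constants()$lambda,
                                  r36_40 = NULL, s36 = NULL,
                                  r39_40 = NULL, s39 = NULL, corr = NULL) {
  n <- length(f39)
  if (length(R) != n || length(sR) != n) stop("per-step columns differ in length")
  if (any(f39 < 0)) stop("negative 39Ar fraction")
  if (abs(sum(f39) - 1) > 1e-6) stop("39Ar fractions must sum to 1")
  if (any(sR <= 0)) stop("sigma(R) must be positive")
  df <- data.frame(step = seq_len(n), f39 = f39, R = R, sR = sR)
  if (!is.null(r36_40)) {
    df$r36_40 <- r36_40; df$s36 <- s36
    df$r39_40 <- r39_40; df$s39 <- s39
    df$corr <- if (is.null(corr)) 0 else corr
  }
  structure(df, J = J, sJ = sJ, lambda = lambda,
            class = c("step_heating_spectrum", "data.frame"))
}

spectrum_ages <- function(s) {
  ar_age(s$R, attr(s, "J"), s$sR, attr(s, "sJ"), attr(s, "lambda"))
}

# Inverse-variance weighted mean; following the usual lab convention the
# standard error is inflated by sqrt(MSWD) when the scatter exceeds what
# the analytical errors explain (MSWD > 1).
weighted_mean_age <- function(ages, sigmas) {
  w <- 1 / sigmas^2
  mu <- sum(w * ages) / sum(w)
  mswd <- if (length(ages) > 1) sum(w * (ages - mu)^2) / (length(ages) - 1)
          else 0
  se <- sqrt(1 / sum(w)) * sqrt(max(1, mswd))
  list(age = mu, se = se, mswd = mswd)
}

#' Detect an age plateau in a step-heating spectrum
#'
#' A plateau is a contiguous run of at least `min_steps` steps releasing
#' more than `min_f39` of the 39Ar whose ages are mutually concordant:
#' under the default `"pairwise"` rule every pair of step ages in the run
#' must overlap at 2 sigma; `"weighted_mean"` instead requires every step
#' to overlap the run's weighted mean at 2 sigma. Among qualifying runs the
#' one releasing the most 39Ar wins, ties broken by lower MSWD. The
#' plateau age is the inverse-variance weighted mean with a 2-sigma error.
#'
#' @param s a [step_heating_spectrum()].
#' @param overlap concordance rule (see above).
#' @param min_steps minimum run length (default 3).
#' @param min_f39 minimum summed 39Ar fraction (default 0.5, exclusive).
#' @return object of class `plateau_result` (list: `steps`, `age`,
#'   `err2`, `f39`, `mswd`, `n_steps`), or `NULL` when no run qualifies.
#' @export
detect_plateau <- function(s, overlap = c("pairwise", "weighted_mean"),
                           min_steps = 3, min_f39 = 0.5) {
  overlap <- match.arg(overlap)
  if (nrow(s) < min_steps) return(NULL)
  a <- spectrum_ages(s)
  n <- nrow(s)
  best <- NULL
  for (i in seq_len(n - min_steps + 1)) {
    for (j in seq(i + min_steps - 1, n)) {
      idx <- i:j
      f <- sum(s$f39[idx])
      if (f <= min_f39) next
      t_ <- a$age[idx]; sg <- a$sigma[idx]
      if (overlap == "pairwise") {
        d <- abs(outer(t_, t_, "-"))
        lim <- 2 * outer(sg, sg, "+")
        if (any(d > lim)) next
      }
      wm <- weighted_mean_age(t_, sg)
      if (overlap == "weighted_mean" &&
          any(abs(t_ - wm$age) > 2 * (sg + wm$se))) next
      cand <- list(steps = idx, age = wm$age, err2 = 2 * wm$se,
                   f39 = f, mswd = wm$mswd, n_steps = length(idx))
      if (is.null(best) || cand$f39 > best$f39 + 1e-12 ||
          (abs(cand$f39 - best$f39) <= 1e-12 && cand$mswd < best$mswd))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  structure(c(best, list(constants = list(J = attr(s, "J"),
                                          lambda = attr(s, "lambda")))),
            class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  cat(sprintf("plateau: %.3f +/- %.3f Ma (2s), steps %d-%d, %.1f%% 39Ar, MSWD %.2f\n",
              x$age, x$err2, min(x$steps), max(x$steps), 100 * x$f39,
              x$mswd))
  invisible(x)
}

#' York errors-in-both-variables inverse-isochron fit
#'
#' Fits 36Ar/40Ar against 39Ar/40Ar by York's iterative weighted
#' least-squares with errors in both coordinates (and optional error
#' correlation). The y-intercept is the trapped component's 36Ar/40Ar, so
#' the trapped 40Ar/36Ar is its reciprocal; the x-intercept gives the
#' radiogenic 40Ar*/39Ar, converted to an age through [ar_age()].
#'
#' @param s a [step_heating_spectrum()] carrying raw ratio columns.
#' @param steps step indices to fit (default all).
#' @return object of class `isochron_result`: slope/intercept with
#'   1-sigma errors, `trapped` 40Ar/36Ar (with 1-sigma), isochron `age`
#'   and 2-sigma error, and MSWD.
#' @export
york_isochron <- function(s, steps = seq_len(nrow(s))) {
  if (is.null(s$r36_40)) stop("spectrum lacks raw isochron ratios")
  x <- s$r39_40[steps]; sx <- s$s39[steps]
  y <- s$r36_40[steps]; sy <- s$s36[steps]
  r <- s$corr[steps]
  if (length(unique(round(x / max(abs(x)), 9))) < 3)
    stop("degenerate isochron input: < 3 distinct abscissae")
  fit <- york_fit(x, y, sx, sy, r)
  b0 <- fit$intercept; b1 <- fit$slope
  trapped <- 1 / b0
  s_trapped <- fit$s_intercept / b0^2
  x0 <- -b0 / b1
  # var of x0 from (b0, b1) with covariance
  g <- c(-1 / b1, b0 / b1^2)
  v <- g[1]^2 * fit$s_intercept^2 + g[2]^2 * fit$s_slope^2 +
    2 * g[1] * g[2] * fit$cov_ab
  R <- 1 / x0
  sR <- sqrt(v) / x0^2
  age <- ar_age(R, attr(s, "J"), sR, attr(s, "sJ"), attr(s, "lambda"))
  structure(list(slope = b1, s_slope = fit$s_slope,
                 intercept = b0, s_intercept = fit$s_intercept,
                 trapped = trapped, s_trapped = s_trapped,
                 R = R, sR = sR,
                 age = age$age, err2 = 2 * age$sigma,
                 mswd = fit$mswd, steps = steps),
            class = "isochron_result")
}

#' @export
print.isochron_result <- function(x, ...) {
  cat(sprintf("inverse isochron: age %.3f +/- %.3f Ma (2s), trapped 40/36 = %.1f +/- %.1f, MSWD %.2f\n",
              x$age, x$err2, x$trapped, 2 * x$s_trapped, x$mswd))
  invisible(x)
}

# York (1969, 2004) iterative solution with correlated errors
york_fit <- function(x, y, sx, sy, r = 0, tol = 1e-12, maxit = 200) {
  wx <- 1 / sx^2; wy <- 1 / sy^2
  b <- stats::coef(stats::lm(y ~ x))[2] # seed slope
  for (it in seq_len(maxit)) {
    alpha <- sqrt(wx * wy)
    W <- wx * wy / (wx + b^2 * wy - 2 * b * r * alpha)
    Xb <- sum(W * x) / sum(W)
    Yb <- sum(W * y) / sum(W)
    U <- x - Xb; V <- y - Yb
    beta <- W * (U / wy + b * V / wx - (b * U + V) * r / alpha)
    b_new <- sum(W * beta * V) / sum(W * beta * U)
    if (abs(b_new - b) < tol * abs(b_new)) { b <- b_new; break }
    b <- b_new
  }
  a <- Yb - b * Xb
  xadj <- Xb + beta # York's adjusted abscissae
  xb <- sum(W * xadj) / sum(W)
  u <- xadj - xb
  s_b <- sqrt(1 / sum(W * u^2))
  s_a <- sqrt(1 / sum(W) + xb^2 * s_b^2)
  cov_ab <- -xb * s_b^2
  dof <- length(x) - 2
  mswd <- if (dof > 0) sum(W * (y - b * x - a)^2) / dof else 0
  infl <- sqrt(max(1, mswd)) # excess-scatter inflation, the usual convention
  list(slope = unname(b), intercept = unname(a),
       s_slope = s_b * infl, s_intercept = s_a * infl,
       cov_ab = cov_ab * infl^2, mswd = mswd)
}

#' Recompute the plateau with an isochron-derived trapped composition
#'
#' Replaces the atmospheric assumption in the radiogenic correction: per
#' step, \eqn{40Ar*/39Ar = (1 - (40/36)_{trap} \cdot r_{36}) / r_{39}}
#' where `r36`, `r39` are the measured 36Ar/40Ar and 39Ar/40Ar, then
#' re-runs [detect_plateau()]. With the trapped ratio equal to the
#' atmospheric value used to build `R`, this reproduces the uncorrected
#' plateau.
#'
#' The trapped-ratio uncertainty is a systematic shared by every step, so
#' it is not folded into the per-step errors (which govern concordance);
#' instead the plateau age is recomputed at `trapped +/- 1 sigma` and the
#' induced shift is added in quadrature to the plateau error.
#'
#' @param s a [step_heating_spectrum()] with raw ratios.
#' @param trapped an `isochron_result`, or a numeric trapped 40Ar/36Ar.
#' @param ... passed to [detect_plateau()].
#' @return a `plateau_result` (or `NULL`), from the corrected spectrum.
#' @export
plateau_with_trapped <- function(s, trapped, ...) {
  tr <- if (inherits(trapped, "isochron_result")) trapped$trapped
        else as.numeric(trapped)
  s_tr <- if (inherits(trapped, "isochron_result")) trapped$s_trapped else 0
  if (tr <= 0) stop("trapped 40Ar/36Ar must be positive")
  if (is.null(s$r36_40)) stop("spectrum lacks raw isochron ratios")
  correct <- function(tr) {
    R <- (1 - tr * s$r36_40) / s$r39_40
    dr36 <- -tr / s$r39_40
    dr39 <- -(1 - tr * s$r36_40) / s$r39_40^2
    sR <- sqrt((dr36 * s$s36)^2 + (dr39 * s$s39)^2 +
                 2 * dr36 * dr39 * s$corr * s$s36 * s$s39)
    step_heating_spectrum(s$f39, R, pmax(sR, 1e-12),
                          attr(s, "J"), attr(s, "sJ"), attr(s, "lambda"),
                          r36_40 = s$r36_40, s36 = s$s36,
                          r39_40 = s$r39_40, s39 = s$s39, corr = s$corr)
  }
  pl <- detect_plateau(correct(tr), ...)
  if (is.null(pl) || s_tr <= 0) return(pl)
  age_at <- function(trv) {
    a <- spectrum_ages(correct(trv))
    weighted_mean_age(a$age[pl$steps], a$sigma[pl$steps])$age
  }
  sys_shift <- (age_at(tr + s_tr) - age_at(tr - s_tr)) / 2
  pl$err2 <- sqrt(pl$err2^2 + (2 * sys_shift)^2)
  pl
}

#' Read a step-heating table from CSV
#'
#' Columns: `f39`, `R`, `sR` and optionally `r36_40`, `s36`, `r39_40`,
#' `s39`, `corr`; `J`, `sJ` (and optionally `lambda`) are given as
#' arguments or as `# key: value` header comments.
#'
#' @param path CSV file.
#' @param J,sJ,lambda reduction constants (override header values).
#' @return a [step_heating_spectrum()].
#' @export
read_step_table <- function(path, J = NULL, sJ = NULL, lambda = NULL) {
  hdr <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  hval <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(sub(".*:", "", ln[1]))
  }
  J <- J %||% hval("J")
  sJ <- sJ %||% hval("sJ") %||% 0
  lambda <- lambda %||% hval("lambda") %||% argon_constants()$lambda
  if (is.null(J)) stop("J must be supplied (argument or '# J:' header)")
  df <- utils::read.csv(path, comment.char = "#")
  step_heating_spectrum(df$f39, df$R, df$sR, J = J, sJ = sJ, lambda = lambda,
                        r36_40 = df$r36_40, s36 = df$s36,
                        r39_40 = df$r39_40, s39 = df$s39, corr = df$corr)
}
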