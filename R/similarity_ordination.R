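#' Pairwise contingency counts for two faunas
#'
#' For two faunas, `a` counts shared taxa, `b` taxa only in the first, `c`
#' taxa only in the second, and `n = a + b + c` (taxa absent from both are
#' ignored, as both coefficients here disregard joint absences).
#'
#' @param m an [occurrence_matrix()].
#' @param i,j fauna identifiers or column indices.
#' @return list with integer components `a`, `b`, `c`, `n`.
#' @export
contingency <- function(m, i, j) {
  x <- unclass(m)[, i]
  y <- unclass(m)[, j]
  a <- sum(x == 1L & y == 1L)
  b <- sum(x == 1L & y == 0L)
  c_ <- sum(x == 0L & y == 1L)
  list(a = a, b = b, c = c_, n = a + b + c_)
}

#' Corrected Forbes similarity and distance
#'
#' The corrected Forbes coefficient for binary data,
#' \deqn{F' = \frac{a(n + \sqrt n)}{a(n + \sqrt n) + \tfrac{3}{2} b c},}
#' with `n = a + b + c`, deliberately ignores the joint-absence cell so that
#' faunal resemblance is not inflated by shared gaps in sampling. The
#' distance is `1 - F'`.
#'
#' @param cc contingency counts as returned by [contingency()], or `a` when
#'   the counts are passed individually.
#' @param b,c counts of taxa exclusive to the first/second fauna (when `cc`
#'   is the `a` count).
#' @return distance in `[0, 1]`.
#' @seealso [bray_curtis_distance()]
#' @export
forbes_corrected_distance <- function(cc, b = NULL, c = NULL) {
  cc <- as_counts(cc, b, c)
  1 - forbes_similarity(cc$a, cc$b, cc$c)
}

# the 3/2 correction constant lives here only
FORBES_BC_WEIGHT <- 1.5

forbes_similarity <- function(a, b, c) {
  n <- a + b + c
  if (n == 0) stop("undefined distance: both faunas empty")
  num <- a * (n + sqrt(n))
  den <- num + FORBES_BC_WEIGHT * b * c
  if (den == 0) return(if (a > 0) 1 else 0) # a>0, bc=0 -> identity
  num / den
}

#' Bray-Curtis (Sorensen) distance on binary data
#'
#' On presence/absence data the Bray-Curtis coefficient reduces to the
#' Sorensen dissimilarity `d = (b + c) / (2a + b + c)`.
#'
#' @inheritParams forbes_corrected_distance
#' @return distance in `[0, 1]`.
#' @export
bray_curtis_distance <- function(cc, b = NULL, c = NULL) {
  cc <- as_counts(cc, b, c)
  den <- 2 * cc$a + cc$b + cc$c
  if (den == 0) stop("undefined distance: both faunas empty")
  (cc$b + cc$c) / den
}

as_counts <- function(cc, b, c) {
  if (is.list(cc)) cc else list(a = cc, b = b, c = c)
}

#' Distance matrix among faunas
#'
#' @param m an [occurrence_matrix()].
#' @param coef `"forbes"` (corrected Forbes) or `"bray"` (binary
#'   Bray-Curtis/Sorensen).
#' @return a [stats::dist] object labelled by fauna.
#' @export
fauna_distances <- function(m, coef = c("forbes", "bray")) {
  coef <- match.arg(coef)
  f <- switch(coef, forbes = forbes_corrected_distance, bray = bray_curtis_distance)
  nf <- ncol(m)
  d <- matrix(0, nf, nf, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(nf - 1)) for (j in seq(i + 1, nf)) {
    d[i, j] <- d[j, i] <- f(contingency(m, i, j))
  }
  stats::as.dist(d)
}

ordination_result <- function(method, scores, stress = NA_real_,
                              eigenvalues = NULL, var_explained = NULL,
                              extra = list()) {
  structure(c(list(method = method, scores = scores, stress = stress,
                   eigenvalues = eigenvalues, var_explained = var_explained),
              extra),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d faunas, %d axes\n",
              toupper(x$method), nrow(x$scores), ncol(x$scores)))
  if (!is.na(x$stress)) cat(sprintf("  stress: %.4f\n", x$stress))
  if (!is.null(x$var_explained))
    cat("  % variance:", paste(sprintf("%.1f", 100 * x$var_explained),
                               collapse = ", "), "\n")
  invisible(x)
}

# Flip each axis so its Spearman correlation with known ages is >= 0
# (makes downstream regression signs stable). Axes uncorrelatable with the
# ages (all NA, constant) are left alone.
orient_axes <- function(scores, ages) {
  if (is.null(ages)) return(scores)
  ok <- !is.na(ages)
  if (sum(ok) < 2) return(scores)
  for (k in seq_len(ncol(scores))) {
    s <- scores[ok, k]
    if (stats::sd(s) == 0) next
    rho <- suppressWarnings(stats::cor(s, ages[ok], method = "spearman"))
    if (!is.na(rho) && rho < 0) scores[, k] <- -scores[, k]
  }
  scores
}

#' Non-metric multidimensional scaling of a fauna distance matrix
#'
#' Kruskal stress-1 NMDS (monotone regression) run from multiple starts: the
#' first start uses the classical-scaling configuration, the rest random
#' configurations; the lowest-stress converged solution is kept. Results are
#' seed-reproducible.
#'
#' @param d a [stats::dist] of faunas (see [fauna_distances()]).
#' @param ndim number of axes (default 2).
#' @param nstarts number of starts (default 50).
#' @param seed integer seed for the random starts.
#' @param ages optional vector of known fauna ages (Ma, `NA` allowed), used
#'   only to orient axis signs.
#' @return an `ordination_result` with fauna scores and final stress.
#' @export
ordinate_nmds <- function(d, ndim = 2, nstarts = 50, seed = NULL, ages = NULL) {
  n <- attr(d, "Size")
  if (n < ndim + 1)
    stop("NMDS needs at least ndim + 1 faunas (degenerate configuration)")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  init <- try(stats::cmdscale(d, k = ndim), silent = TRUE)
  for (s in seq_len(nstarts)) {
    y <- if (s == 1 && !inherits(init, "try-error") && ncol(init) == ndim)
      init else matrix(stats::runif(n * ndim, -1, 1), n, ndim)
    fit <- try(vegan::monoMDS(d, y = y, k = ndim, model = "global",
                              maxit = 500), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best))
    stop("NMDS failed to converge in any of ", nstarts, " starts")
  scores <- best$points
  rownames(scores) <- attr(d, "Labels")
  colnames(scores) <- paste0("axis", seq_len(ndim))
  scores <- orient_axes(scores, ages)
  ordination_result("nmds", scores, stress = best$stress,
                    extra = list(nstarts = nstarts, seed = seed))
}

#' Principal coordinate analysis (classical scaling)
#'
#' Eigen-decomposition of the double-centred squared-distance matrix. Axis
#' scores are taken from positive eigenvalues only; negative eigenvalues
#' (possible for semi-metric coefficients) are reported untouched, with no
#' Cailliez/Lingoes correction.
#'
#' @inheritParams ordinate_nmds
#' @return an `ordination_result` with eigenvalues and % variance (over the
#'   positive eigenvalues).
#' @export
ordinate_pco <- function(d, ages = NULL) {
  n <- attr(d, "Size")
  if (n < 3) stop("PCO needs at least 3 faunas")
  # k = n - 1 requested; cmdscale warns when semi-metric distances yield
  # fewer positive eigenvalues, which is expected and reported downstream
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  scores <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(scores) <- paste0("axis", seq_along(pos))
  scores <- orient_axes(scores, ages)
  ordination_result("pco", scores, eigenvalues = eig,
                    var_explained = eig[pos] / sum(eig[pos]))
}

#' Correspondence analysis of the occurrence matrix
#'
#' Chi-square-metric singular value decomposition of the taxon-by-fauna
#' correspondence table; fauna (column) scores are returned. All-zero rows
#' or columns are rejected by name.
#'
#' @param m an [occurrence_matrix()].
#' @param ages optional known fauna ages for axis orientation.
#' @return an `ordination_result` with per-axis inertia proportions.
#' @export
ordinate_ca <- function(m, ages = NULL) {
  inc <- unclass(m)
  zr <- rowSums(inc) == 0
  zc <- colSums(inc) == 0
  if (any(zr)) stop("all-zero taxon row(s): ",
                    paste(rownames(inc)[zr], collapse = ", "))
  if (any(zc)) stop("all-zero fauna column(s): ",
                    paste(colnames(inc)[zc], collapse = ", "))
  fit <- vegan::cca(t(inc)) # faunas as rows = "sites"
  eig <- fit$CA$eig
  if (length(eig) == 0 || sum(eig) < .Machine$double.eps) {
    # no residual structure (e.g. identical columns): zero inertia
    scores <- matrix(0, ncol(inc), 2,
                     dimnames = list(colnames(inc), c("axis1", "axis2")))
    return(ordination_result("ca", scores, eigenvalues = numeric(),
                             var_explained = numeric(),
                             extra = list(total_inertia = 0)))
  }
  k <- length(eig)
  scores <- vegan::scores(fit, display = "sites", choices = seq_len(k),
                          scaling = 1)
  scores <- as.matrix(scores)
  colnames(scores) <- paste0("axis", seq_len(ncol(scores)))
  scores <- orient_axes(scores, ages)
  ordination_result("ca", scores, eigenvalues = eig,
                    var_explained = eig / sum(eig),
                    extra = list(total_inertia = fit$CA$tot.chi))
}

#' Run the standard set of fauna ordinations
#'
#' Convenience wrapper producing the candidate predictors used downstream in
#' age calibration: NMDS and PCO on both coefficients, plus CA.
#'
#' @param m an [occurrence_matrix()].
#' @param ages optional known fauna ages (orientation only).
#' @param nstarts,seed passed to [ordinate_nmds()].
#' @return named list of `ordination_result` objects:
#'   `nmds_forbes`, `nmds_bray`, `pco_forbes`, `pco_bray`, `ca`.
#' @export
ordinate_all <- function(m, ages = NULL, nstarts = 50, seed = NULL) {
  df <- fauna_distances(m, "forbes")
  db <- fauna_distances(m, "bray")
  list(nmds_forbes = ordinate_nmds(df, seed = seed, nstarts = nstarts, ages = ages),
       nmds_bray = ordinate_nmds(db, seed = if (is.null(seed)) NULL else seed + 1,
                                 nstarts = nstarts, ages = ages),
       pco_forbes = ordinate_pco(df, ages = ages),
       pco_bray = ordinate_pco(db, ages = ages),
       ca = ordinate_ca(m, ages = ages))
}
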