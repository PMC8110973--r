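#' Boundary-crosser counts per fauna bin
#'
#' Classifies every taxon range against each bin following the
#' boundary-crosser scheme: `Nbt` range through both boundaries, `NbL`
#' cross the bottom and last appear in the bin, `NFt` first appear in the
#' bin and cross the top, `NFL` are confined to the bin. Ranges run from a
#' taxon's first to last occurrence in the supplied order, so crossings are
#' range-through by construction; the `approach` governs the reported
#' richness (`"observed"` counts sampled presences only, `"range_through"`
#' additionally counts Lazarus taxa).
#'
#' @param m an [occurrence_matrix()]; composite boundary columns (see
#'   [add_boundary_composites()]) take part in range building but get `NA`
#'   richness.
#' @param order fauna order, oldest first (defaults to column order).
#' @param approach `"observed"` (approach 1) or `"range_through"`
#'   (approach 2).
#' @return data.frame of class `bin_crossings` with one row per bin:
#'   `fauna`, `Nbt`, `NbL`, `NFt`, `NFL`, `Nb`, `Nt`, `richness`,
#'   `composite`.
#' @export
bin_crossings <- function(m, order = faunas_of(m),
                          approach = c("observed", "range_through")) {
  approach <- match.arg(approach)
  order <- as.character(order)
  if (!setequal(order, faunas_of(m)) || length(order) != ncol(m))
    stop("'order' must be a permutation of the matrix faunas")
  A <- unclass(m)[, order, drop = FALSE]
  comp <- composite_of(m)[match(order, faunas_of(m))]
  first <- max.col(A, ties.method = "first")
  last <- max.col(A, ties.method = "last")
  nb <- length(order)
  rt <- A
  for (i in seq_len(nrow(rt))) rt[i, first[i]:last[i]] <- 1L
  rich_m <- if (approach == "observed") A else rt
  out <- data.frame(
    fauna = order,
    Nbt = vapply(seq_len(nb), function(k) sum(first < k & last > k), 0L),
    NbL = vapply(seq_len(nb), function(k) sum(first < k & last == k), 0L),
    NFt = vapply(seq_len(nb), function(k) sum(first == k & last > k), 0L),
    NFL = vapply(seq_len(nb), function(k) sum(first == k & last == k), 0L),
    richness = colSums(rich_m),
    composite = comp, row.names = NULL)
  out$Nb <- out$Nbt + out$NbL
  out$Nt <- out$Nbt + out$NFt
  out$richness[comp] <- NA_integer_
  class(out) <- c("bin_crossings", "data.frame")
  out
}

#' Foote per-capita origination and extinction rates
#'
#' From boundary-crosser counts: extinction `q = -ln(Nbt / Nb)` and
#' origination `p = -ln(Nbt / Nt)`, with net diversification `p - q` and
#' turnover `p + q`. Rates are per bin (no division by bin duration) unless
#' durations are supplied. Bins with `Nbt = 0` (or an undefined
#' denominator) get `NA` rates and are flagged, never zero-filled or made
#' infinite.
#'
#' @param bc a `bin_crossings` table.
#' @param durations optional per-bin durations (Ma) to express rates per
#'   Ma.
#' @return data.frame of class `turnover_table`: fauna, richness, `p`, `q`,
#'   `net`, `turnover`, `defined`.
#' @export
foote_rates <- function(bc, durations = NULL) {
  ok <- bc$Nbt > 0 & bc$Nb > 0 & bc$Nt > 0
  q <- p <- rep(NA_real_, nrow(bc))
  q[ok] <- -log(bc$Nbt[ok] / bc$Nb[ok])
  p[ok] <- -log(bc$Nbt[ok] / bc$Nt[ok])
  if (!is.null(durations)) {
    if (length(durations) != nrow(bc)) stop("one duration per bin required")
    p <- p / durations; q <- q / durations
  }
  out <- data.frame(fauna = bc$fauna, richness = bc$richness,
                    p = p, q = q, net = p - q, turnover = p + q,
                    defined = ok, composite = bc$composite, row.names = NULL)
  class(out) <- c("turnover_table", "data.frame")
  out
}

#' Classical rarefaction of the diversity and turnover metrics
#'
#' Per iteration, `floor(fraction * n)` occurrence records are drawn
#' without replacement within each fauna (its presences being the
#' records); richness and Foote rates are recomputed on the subsampled
#' matrix and summarised across iterations. Faunas whose quota falls below
#' 3 records are excluded, with a warning.
#'
#' @param m an [occurrence_matrix()].
#' @param order fauna order, oldest first.
#' @param fraction subsampling proportion per fauna (default 0.40).
#' @param iters iterations (default 1000).
#' @param seed integer seed.
#' @param approach as in [bin_crossings()].
#' @return data.frame: per fauna the mean and 2.5/97.5 percentiles of
#'   richness, `p` and `q` across iterations.
#' @export
rarefy_metrics <- function(m, order = faunas_of(m), fraction = 0.40,
                           iters = 1000, seed = NULL,
                           approach = c("observed", "range_through")) {
  approach <- match.arg(approach)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  A <- unclass(m)[, order, drop = FALSE]
  quota <- pmax(0L, as.integer(floor(fraction * colSums(A))))
  drop <- quota < 3L
  if (any(drop)) {
    warning("faunas excluded (quota < 3 records): ",
            paste(order[drop], collapse = ", "))
    A <- A[, !drop, drop = FALSE]
    quota <- quota[!drop]
    A <- A[rowSums(A) > 0, , drop = FALSE]
  }
  keep_order <- colnames(A)
  comp <- composite_of(m)[match(keep_order, faunas_of(m))]
  stats_one <- function() {
    B <- A
    for (j in seq_len(ncol(B))) {
      pres <- which(B[, j] == 1L)
      if (length(pres) > quota[j])
        B[sample(pres, length(pres) - quota[j]), j] <- 0L
    }
    keep <- rowSums(B) > 0
    B <- B[keep, , drop = FALSE]
    mm <- occurrence_matrix(B, composite = comp)
    tt <- foote_rates(bin_crossings(mm, approach = approach))
    rbind(tt$richness, tt$p, tt$q)
  }
  res <- replicate(iters, stats_one())
  summ <- function(k, fun, ...) apply(res[k, , , drop = FALSE], 2, fun, ...)
  qlo <- function(x) stats::quantile(x, 0.025, na.rm = TRUE)
  qhi <- function(x) stats::quantile(x, 0.975, na.rm = TRUE)
  data.frame(fauna = keep_order,
             richness_mean = summ(1, mean, na.rm = TRUE),
             richness_lower = summ(1, qlo), richness_upper = summ(1, qhi),
             p_mean = summ(2, mean, na.rm = TRUE),
             p_lower = summ(2, qlo), p_upper = summ(2, qhi),
             q_mean = summ(3, mean, na.rm = TRUE),
             q_lower = summ(3, qlo), q_upper = summ(3, qhi),
             quota = quota, row.names = NULL)
}

#' Closed-form classical rarefaction of richness
#'
#' Expected number of distinct taxa in a draw of `n` of the `N` occurrence
#' records, where taxon `t` has `counts[t]` records:
#' \eqn{E[S_n] = \sum_t 1 - \binom{N - m_t}{n} / \binom{N}{n}}.
#'
#' @param counts per-taxon record counts.
#' @param n subsample size.
#' @return expected richness.
#' @export
rarefy_richness <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n < 0 || n > N) stop("subsample size out of range")
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Per-fauna taxon counts by category
#'
#' Counts member taxa of each fauna by taxonomic group, diet class or body
#' size class. Taxa lacking the relevant label are excluded with a logged
#' count; a warning is raised when labels cover less than 90% of a fauna.
#'
#' @param m an [occurrence_matrix()].
#' @param traits a [taxon_traits()] table.
#' @param scheme `"group"`, `"diet"` or `"size"`.
#' @param order fauna order (columns of the result).
#' @return matrix of counts, categories x faunas, with the scheme
#'   vocabulary as rows; unlabeled counts in the `unlabeled` attribute.
#' @export
category_counts <- function(m, traits, scheme = c("group", "diet", "size"),
                            order = faunas_of(m)) {
  scheme <- match.arg(scheme)
  vocab <- switch(scheme, group = taxonomic_groups, diet = diet_classes,
                  size = body_size_classes)
  lab <- stats::setNames(traits[[scheme]], traits$taxon)[taxa_of(m)]
  A <- unclass(m)[, order, drop = FALSE]
  counts <- vapply(seq_along(order), function(j) {
    members <- lab[A[, j] == 1L]
    table(factor(members[!is.na(members)], levels = vocab))
  }, stats::setNames(integer(length(vocab)), vocab))
  colnames(counts) <- order
  unl <- vapply(seq_along(order), function(j) sum(is.na(lab[A[, j] == 1L])),
                0L)
  names(unl) <- order
  low <- colSums(A) > 0 & unl / colSums(A) > 0.10
  if (any(low))
    warning("trait coverage below 90% for: ",
            paste(order[low], collapse = ", "))
  if (any(unl > 0))
    message(sum(unl), " unlabeled member occurrences excluded from '",
            scheme, "' counts")
  attr(counts, "unlabeled") <- unl
  attr(counts, "scheme") <- scheme
  counts
}

#' Multinomial log-likelihood statistic for community-structure change
#'
#' Measures how much worse the preceding fauna's category proportions
#' explain the next fauna's counts than its own proportions do:
#' \deqn{\Delta LL = \sum_i m_i \ln \hat p^{self}_i -
#'                   \sum_i m_i \ln \hat p^{ref}_i \ \ge 0,}
#' where `m_i` are the next fauna's counts, self-proportions are the MLE
#' `m_i / n`, and the reference proportions are the previous fauna's counts
#' with `smoothing` added to every category (keeping the statistic finite
#' when a category is unobserved in the reference). Change is flagged
#' significant when `\Delta LL > cutoff` (2 log-likelihood units).
#'
#' @param prev,nxt category count vectors on the same vocabulary.
#' @param smoothing additive smoothing for the reference counts (default
#'   0.5).
#' @param cutoff significance cutoff in log-likelihood units (default 2).
#' @return list: `delta_ll`, `significant`, `n`.
#' @export
multinomial_change <- function(prev, nxt, smoothing = 0.5, cutoff = 2) {
  if (length(prev) != length(nxt))
    stop("count vectors must share a category vocabulary")
  if (!length(prev)) stop("empty category vocabulary")
  if (sum(prev) == 0 || sum(nxt) == 0) stop("empty fauna counts")
  p_ref <- (prev + smoothing) / sum(prev + smoothing)
  p_self <- nxt / sum(nxt)
  use <- nxt > 0
  dll <- sum(nxt[use] * log(p_self[use])) - sum(nxt[use] * log(p_ref[use]))
  list(delta_ll = dll, significant = dll > cutoff, n = sum(nxt))
}

#' Community-structure change along a faunal succession
#'
#' Applies [multinomial_change()] to each successive pair of faunas for a
#' category scheme.
#'
#' @inheritParams category_counts
#' @param approach `"observed"` or `"range_through"` (Lazarus taxa filled
#'   before counting).
#' @param smoothing,cutoff as in [multinomial_change()].
#' @return data.frame: fauna (the later of each pair), `delta_ll`,
#'   `significant`, `n`.
#' @export
community_change <- function(m, traits, scheme = c("group", "diet", "size"),
                             order = faunas_of(m),
                             approach = c("observed", "range_through"),
                             smoothing = 0.5, cutoff = 2) {
  approach <- match.arg(approach)
  if (approach == "range_through") m <- range_through_fill(m, order)
  cc <- category_counts(m, traits, scheme, order)
  out <- lapply(seq_len(ncol(cc) - 1L), function(k) {
    res <- multinomial_change(cc[, k], cc[, k + 1L],
                              smoothing = smoothing, cutoff = cutoff)
    data.frame(fauna = colnames(cc)[k + 1L], delta_ll = res$delta_ll,
               significant = res$significant, n = res$n)
  })
  do.call(rbind, out)
}
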