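#' Specification of a synthetic faunal succession
#'
#' Defines the study conditions the generators emulate: a constant-rate
#' origination/extinction (birth-death) process over ordered fauna bins,
#' sampled with a per-fauna detection probability. Defaults describe a
#' moderately turned-over, well-sampled Neogene succession: 10 faunas
#' spanning 9.5-2 Ma, per-bin per-capita rates 0.35, detection probability
#' 0.8, and a target of about 60 recorded taxa.
#'
#' @param n_taxa target total number of taxa (the founding cohort is scaled
#'   so the expected total matches).
#' @param n_faunas number of fauna bins.
#' @param ages strictly decreasing fauna ages (Ma).
#' @param p_star,q_star true per-capita per-bin origination/extinction
#'   rates.
#' @param r per-fauna detection probability in `(0, 1]`.
#' @param group_probs,diet_probs,size_probs trait label distributions.
#' @param fraction_dated fraction of faunas whose true age is exposed in
#'   the metadata (the rest are calibration targets).
#' @param seed integer seed.
#' @return list of class `succession_spec`.
#' @export
succession_spec <- function(n_taxa = 60, n_faunas = 10,
                            ages = seq(9.5, 2, length.out = n_faunas),
                            p_star = 0.35, q_star = 0.35, r = 0.8,
                            group_probs = NULL, diet_probs = NULL,
                            size_probs = NULL, fraction_dated = 0.6,
                            seed = 1) {
  if (any(diff(ages) >= 0)) stop("ages must be strictly decreasing (Ma)")
  if (p_star < 0 || q_star < 0) stop("rates must be nonnegative")
  if (r <= 0 || r > 1) stop("detection probability must be in (0, 1]")
  if (length(ages) != n_faunas) stop("one age per fauna required")
  structure(list(
    n_taxa = n_taxa, n_faunas = n_faunas, ages = ages,
    p_star = p_star, q_star = q_star, r = r,
    group_probs = group_probs %||%
      stats::setNames(rep(1 / 11, 11), taxonomic_groups),
    diet_probs = diet_probs %||%
      stats::setNames(c(0.10, 0.15, 0.30, 0.25, 0.20), diet_classes),
    size_probs = size_probs %||%
      stats::setNames(c(0.10, 0.20, 0.20, 0.20, 0.15, 0.10, 0.05),
                      body_size_classes),
    fraction_dated = fraction_dated, seed = seed),
    class = "succession_spec")
}

#' Simulate a faunal succession with known truth
#'
#' Taxon ranges follow a discrete birth-death process: taxa alive in a bin
#' survive to the next with probability `exp(-q_star)`; new taxa enter each
#' bin as a Poisson draw with mean `N * (exp(p_star) - 1)` over the
#' bottom-crossing cohort, so that complete sampling recovers the true
#' per-capita rates in expectation. Detection is Bernoulli(`r`) per
#' occupied bin; trait labels are drawn independently of ranges.
#'
#' @param spec a [succession_spec()].
#' @return list of class `synthetic_succession`: `matrix` (the sampled
#'   [occurrence_matrix()]), `metadata` ([fauna_metadata()], ages exposed
#'   for a `fraction_dated` subset), `traits` ([taxon_traits()]),
#'   `true_ranges` (per-taxon true first/last bin), `true_ages` (named,
#'   every fauna), and the `spec`.
#' @export
simulate_succession <- function(spec = succession_spec()) {
  set.seed(spec$seed)
  B <- spec$n_faunas
  surv <- exp(-spec$q_star)
  birth_mult <- exp(spec$p_star) - 1
  denom <- 1 + (B - 1) * surv * birth_mult
  founders <- max(3L, round(spec$n_taxa / denom))
  first <- integer(0); last <- integer(0)
  extend <- function(n_new, bin) {
    if (n_new <= 0) return(invisible())
    f <- rep(bin, n_new)
    l <- integer(n_new)
    for (k in seq_len(n_new)) {
      b <- bin
      while (b < B && stats::runif(1) < surv) b <- b + 1L
      l[k] <- b
    }
    first <<- c(first, f); last <<- c(last, l)
  }
  extend(founders, 1L)
  for (b in seq_len(B - 1L)) {
    crossers <- sum(first <= b & last > b)
    extend(stats::rpois(1, crossers * birth_mult), b + 1L)
  }
  n <- length(first)
  taxa <- sprintf("taxon%03d", seq_len(n))
  faunas <- sprintf("F%02d", seq_len(B))
  truth <- matrix(0L, n, B, dimnames = list(taxa, faunas))
  for (i in seq_len(n)) truth[i, first[i]:last[i]] <- 1L
  det <- matrix(stats::rbinom(n * B, 1, spec$r), n, B) * truth
  keep <- rowSums(det) > 0
  if (!any(keep) || any(colSums(det[keep, , drop = FALSE]) == 0))
    stop("simulated matrix has an empty fauna; increase n_taxa or r")
  m <- occurrence_matrix(det[keep, , drop = FALSE])
  groups <- sample(names(spec$group_probs), n, TRUE, spec$group_probs)
  diets <- sample(names(spec$diet_probs), n, TRUE, spec$diet_probs)
  sizes <- sample(names(spec$size_probs), n, TRUE, spec$size_probs)
  traits <- taxon_traits(data.frame(taxon = taxa, group = groups,
                                    diet = diets, size = sizes)[keep, ])
  dated <- seq_len(B) %in%
    sort(sample.int(B, max(3L, round(spec$fraction_dated * B))))
  # consecutive pairs of bins share a formation, oldest first
  section <- paste0("fm", ceiling(seq_len(B) / 2))
  meta <- fauna_metadata(data.frame(
    fauna = faunas,
    latitude = -37 + stats::runif(B, -3, 3),
    longitude = -63 + stats::runif(B, -3, 3),
    age_point = ifelse(dated, spec$ages, NA_real_),
    age_max = ifelse(dated, spec$ages + 0.2, NA_real_),
    age_min = ifelse(dated, spec$ages - 0.2, NA_real_),
    section = section))
  structure(list(matrix = m, metadata = meta, traits = traits,
                 true_ranges = data.frame(taxon = taxa, first = first,
                                          last = last)[keep, ],
                 true_ages = stats::setNames(spec$ages, faunas),
                 spec = spec),
            class = "synthetic_succession")
}

#' Specification of a synthetic step-heating spectrum
#'
#' A single trapped argon component of configurable 40Ar/36Ar composition,
#' with a per-step trapped-amount profile: concentrating trapped argon in
#' the early steps while setting `trapped_ratio` above the atmospheric
#' value reproduces the classic excess-argon signature (inflated early
#' apparent ages under an atmospheric correction), while keeping every
#' step on one exact inverse isochron.
#'
#' @param true_age true sample age (Ma).
#' @param J,sJ irradiation parameter and 1-sigma.
#' @param n_steps number of heating steps.
#' @param f39 per-step 39Ar release fractions (default mildly uneven).
#' @param trapped_frac per-step trapped 40Ar as a fraction of the step's
#'   radiogenic 40Ar*; the default declines from heavy early
#'   contamination to a nearly clean high-temperature tail.
#' @param trapped_ratio trapped 40Ar/36Ar. The default (1200) is well
#'   above atmospheric, so the default spectrum carries excess argon:
#'   early apparent ages are inflated under the atmospheric reduction,
#'   and only the isochron-derived trapped correction recovers an
#'   unbiased full spectrum. Set to `assumed_atm` for a clean sample.
#' @param noise relative 1-sigma measurement noise on the isotope ratios.
#' @param assumed_atm atmospheric ratio used when reducing the raw ratios
#'   to the reported 40Ar*/39Ar column.
#' @param lambda decay constant (1/yr).
#' @param seed integer seed.
#' @return list of class `spectrum_spec`.
#' @export
spectrum_spec <- function(true_age = 5.17, J = 0.001, sJ = 0, n_steps = 10,
                          f39 = NULL, trapped_frac = NULL,
                          trapped_ratio = 1200,
                          noise = 0.01,
                          assumed_atm = argon_constants()$atm_legacy,
                          lambda = argon_constants()$lambda, seed = 1) {
  if (n_steps < 3) stop("need at least 3 steps")
  if (noise <= 0) stop("noise sigma must be positive")
  f39 <- f39 %||% {
    w <- 0.5 + seq(0, 1, length.out = n_steps)
    w / sum(w)
  }
  trapped_frac <- trapped_frac %||% {
    tf <- rep(0.005, n_steps)
    ramp <- max(1L, floor(n_steps / 2) - 1L)
    tf[seq_len(ramp)] <- 1.5 * 0.5^(seq_len(ramp) - 1)
    tf
  }
  structure(list(true_age = true_age, J = J, sJ = sJ, n_steps = n_steps,
                 f39 = f39, trapped_frac = trapped_frac,
                 trapped_ratio = trapped_ratio, noise = noise,
                 assumed_atm = assumed_atm, lambda = lambda, seed = seed),
            class = "spectrum_spec")
}

#' Simulate a step-heating spectrum of known age
#'
#' Per step, radiogenic 40Ar* is the age equation inverted at the true
#' age; trapped 40Ar follows the spec's profile and composition; seeded
#' multiplicative noise perturbs the measured 36Ar and 39Ar signals. The
#' reported 40Ar*/39Ar column is reduced from the raw ratios with the
#' spec's `assumed_atm` atmospheric ratio, exactly as a lab reduction
#' assuming air would do.
#'
#' @param spec a [spectrum_spec()].
#' @return a [step_heating_spectrum()] with raw isochron ratios; the spec
#'   and the true age are attached as attributes.
#' @export
simulate_spectrum <- function(spec = spectrum_spec()) {
  set.seed(spec$seed)
  n <- spec$n_steps
  R_true <- (exp(spec$lambda * spec$true_age * 1e6) - 1) / spec$J
  a39 <- spec$f39                       # arbitrary units
  a40_rad <- R_true * a39
  a40_trap <- spec$trapped_frac * a40_rad
  a40 <- a40_rad + a40_trap
  a36 <- a40_trap / spec$trapped_ratio
  # noisy measurements of the 36/40 and 39/40 ratios
  r36 <- (a36 / a40) * (1 + stats::rnorm(n, 0, spec$noise))
  r39 <- (a39 / a40) * (1 + stats::rnorm(n, 0, spec$noise))
  s36 <- pmax(abs(a36 / a40) * spec$noise, 1e-12)
  s39 <- pmax(abs(a39 / a40) * spec$noise, 1e-12)
  # atmospheric reduction to 40Ar*/39Ar
  R <- (1 - spec$assumed_atm * r36) / r39
  dr36 <- -spec$assumed_atm / r39
  dr39 <- -(1 - spec$assumed_atm * r36) / r39^2
  sR <- pmax(sqrt((dr36 * s36)^2 + (dr39 * s39)^2), 1e-12)
  s <- step_heating_spectrum(spec$f39, R, sR, J = spec$J, sJ = spec$sJ,
                             lambda = spec$lambda,
                             r36_40 = r36, s36 = s36,
                             r39_40 = r39, s39 = s39, corr = rep(0, n))
  attr(s, "true_age") <- spec$true_age
  attr(s, "spec") <- spec
  s
}

#' Hand-auditable worked example succession
#'
#' An 8-taxon, 5-fauna nested succession whose expected values (Fitch
#' length on a reference tree, boundary-crosser counts, the unique
#' consistent temporal order) were derived by hand and are frozen in the
#' `expected` attribute.
#'
#' @return list: `matrix`, `metadata`, `traits`, and `expected` (a list
#'   with `aeo_order`, `bin3_Nbt`, `fitch_tree` in Newick, `fitch_length`).
#' @export
worked_fixture <- function() {
  faunas <- c("FA", "FB", "FC", "FD", "FE")
  # ranges (first-last bin): t1 1-2, t2 1-3, t3 2-3, t4 2-4, t5 3-4,
  # t6 3-5, t7 4-5, t8 5-5 (t8 a deliberate singleton)
  ranges <- rbind(t1 = c(1, 2), t2 = c(1, 3), t3 = c(2, 3), t4 = c(2, 4),
                  t5 = c(3, 4), t6 = c(3, 5), t7 = c(4, 5), t8 = c(5, 5))
  inc <- matrix(0L, 8, 5, dimnames = list(rownames(ranges), faunas))
  for (i in 1:8) inc[i, ranges[i, 1]:ranges[i, 2]] <- 1L
  m <- occurrence_matrix(inc)
  meta <- fauna_metadata(data.frame(
    fauna = faunas, latitude = c(-38, -38.5, -37.9, -38.2, -38.1),
    longitude = c(-61, -62, -60.5, -61.5, -60.8),
    age_point = c(9, 7, 5, 3, 1),
    age_max = c(9.5, 7.5, 5.5, 3.5, 1.5),
    age_min = c(8.5, 6.5, 4.5, 2.5, 0.5),
    section = c("fmW", "fmW", "fmE", "fmE", "fmE")))
  traits <- taxon_traits(data.frame(
    taxon = rownames(ranges),
    group = c("Notoungulata", "Litopterna", "Caviomorpha", "Sparassodonta",
              "Cingulata", "Cricetidae", "Carnivora", "Artiodactyla"),
    diet = c("grazer", "browser", "generalist", "carnivorous",
             "mixed feeder", "generalist", "carnivorous", "browser"),
    size = c("IV", "V", "II", "III", "IV", "I", "III", "IV")))
  expected <- list(
    # unique order consistent with the overlapping ranges
    aeo_order = faunas,
    # bin 3 (FC): t4 spans 2-4 -> crosses both boundaries
    bin3_Nbt = 1L,
    # hand-enumerated Fitch length of the caterpillar tree over all 8
    # characters; on the unrooted chain n1(FA,FB)-n2(FC)-n3(FD,FE) the
    # per-character minimal cuts are 1,1,2,2,2,1,1,1
    fitch_tree = "((((FA,FB),FC),FD),FE);",
    fitch_length = 11L)
  list(matrix = m, metadata = meta, traits = traits, expected = expected)
}
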