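#' Midpoint ages from per-fauna bounds
#'
#' For faunas dated only by an age range, the midpoint
#' `(age_max + age_min) / 2` (rounded to 2 decimals for reporting) is the
#' age used in calibration regressions. Faunas with a single bound pass
#' through with a flag.
#'
#' @param bounds data.frame with `fauna`, `age_max`, `age_min` (Ma), e.g. a
#'   [fauna_metadata()].
#' @return data.frame: fauna, `midpoint` (Ma, 2 dp), `flag` (`""` or
#'   `"single_bound"`/`"no_bounds"`).
#' @export
table1_midpoints <- function(bounds) {
  hi <- bounds$age_max; lo <- bounds$age_min
  mid <- round((hi + lo) / 2, 2)
  flag <- ifelse(is.na(hi) & is.na(lo), "no_bounds",
                 ifelse(is.na(hi) | is.na(lo), "single_bound", ""))
  single <- flag == "single_bound"
  mid[single] <- ifelse(is.na(hi[single]), lo[single], hi[single])
  data.frame(fauna = bounds$fauna, midpoint = mid, flag = flag,
             row.names = NULL)
}

#' Run the full biochronology pipeline
#'
#' Orchestrates the analysis sequence on one occurrence dataset: validate,
#' drop singletons, ordinate (NMDS/PCO on both coefficients, CA), AEO with
#' section constraints, optional PAE, quantile-regression age calibration
#' of undated faunas, diversity and turnover, and community-structure
#' change. Stage outputs are written as CSV/Newick files plus a JSON
#' manifest capturing the package version, configuration and seed, making
#' a run reproducible from the manifest alone.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   `occurrences`, `metadata`, `traits` (paths or in-memory objects),
#'   `out_dir`, `seed`, and optional toggles `run_pae` (default `FALSE`),
#'   `nboot` (AEO bootstrap, default 100), `nstarts` (NMDS starts, default
#'   50), `pae_additions` (default 10), `rarefy_fraction` (default 0.4),
#'   `rarefy_iters` (default 1000), `ppe_threshold` (default 10),
#'   `approach` (`"observed"` or `"range_through"`). Unknown keys are
#'   rejected.
#' @return list of stage results, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("occurrences", "metadata", "traits", "out_dir", "seed",
             "run_pae", "nboot", "nstarts", "pae_additions",
             "rarefy_fraction", "rarefy_iters", "ppe_threshold", "approach",
             "pae_root")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  need <- function(k, default = NULL) config[[k]] %||% default
  out_dir <- need("out_dir") %||% stop("config needs 'out_dir'")
  seed <- as.integer(need("seed", 1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  m <- need("occurrences") %||% stop("config needs 'occurrences'")
  if (is.character(m)) m <- read_occurrence_table(m)
  meta <- need("metadata")
  if (is.character(meta)) meta <- read_fauna_metadata(meta)
  traits <- need("traits")
  if (is.character(traits)) traits <- read_taxon_traits(traits)
  approach <- match.arg(need("approach", "observed"),
                        c("observed", "range_through"))

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }
  results <- list()

  results$validation <- stage("validate",
    validate_faunal_data(m, meta, traits))
  m2 <- stage("prepare", drop_singletons(m))

  ages <- if (!is.null(meta)) {
    mids <- table1_midpoints(meta)
    a <- ifelse(is.na(meta$age_point), mids$midpoint, meta$age_point)
    stats::setNames(a, meta$fauna)[faunas_of(m2)]
  } else NULL

  results$ordinations <- stage("ordinate",
    ordinate_all(m2, ages = ages, nstarts = need("nstarts", 50),
                 seed = seed))
  for (nm in names(results$ordinations))
    utils::write.csv(
      data.frame(fauna = rownames(results$ordinations[[nm]]$scores),
                 results$ordinations[[nm]]$scores),
      file.path(out_dir, paste0("scores_", nm, ".csv")), row.names = FALSE)

  sections <- if (!is.null(meta)) section_constraints(meta) else NULL
  results$aeo <- stage("aeo",
    ml_aeo(m2, sections = sections, nboot = need("nboot", 100),
           seed = seed, ages = ages))
  utils::write.csv(results$aeo$scores,
                   file.path(out_dir, "aeo_scores.csv"), row.names = FALSE)
  if (!is.null(results$aeo$bootstrap))
    utils::write.csv(results$aeo$bootstrap,
                     file.path(out_dir, "aeo_bootstrap.csv"),
                     row.names = FALSE)

  if (isTRUE(need("run_pae", FALSE))) {
    root <- need("pae_root", faunas_of(m2)[1])
    results$pae <- stage("pae",
      parsimony_search(m2, root = root,
                       n_additions = need("pae_additions", 10),
                       seed = seed))
    ape::write.tree(results$pae$trees, file.path(out_dir, "pae_trees.nwk"))
    cons <- strict_consensus(results$pae$trees)
    ape::write.tree(cons, file.path(out_dir, "pae_consensus.nwk"))
  }

  if (!is.null(ages) && any(is.na(ages)) && sum(!is.na(ages)) >= 3) {
    results$calibration <- stage("calibrate", {
      cand <- candidate_equations(results$ordinations, results$aeo, ages)
      estimate_ages(cand$models, cand$targets,
                    threshold = need("ppe_threshold", 10))
    })
    utils::write.csv(results$calibration,
                     file.path(out_dir, "age_estimates.csv"),
                     row.names = FALSE)
  }

  results$turnover <- stage("diversity", {
    bc <- bin_crossings(m, approach = approach)
    foote_rates(bc)
  })
  utils::write.csv(results$turnover,
                   file.path(out_dir, "turnover.csv"), row.names = FALSE)
  results$rarefaction <- stage("rarefaction",
    suppressWarnings(rarefy_metrics(m, fraction = need("rarefy_fraction", 0.4),
                                    iters = need("rarefy_iters", 1000),
                                    seed = seed, approach = approach)))
  utils::write.csv(results$rarefaction,
                   file.path(out_dir, "rarefaction.csv"), row.names = FALSE)

  if (!is.null(traits)) {
    results$community <- stage("structure", {
      out <- lapply(c("group", "diet", "size"), function(sch)
        cbind(scheme = sch,
              suppressWarnings(suppressMessages(
                community_change(m, traits, sch, approach = approach)))))
      do.call(rbind, out)
    })
    utils::write.csv(results$community,
                     file.path(out_dir, "community_change.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "pampachron",
    version = as.character(utils::packageVersion("pampachron")),
    seed = seed,
    approach = approach,
    n_taxa = nrow(m), n_faunas = ncol(m),
    config = config[!vapply(config, is.object, TRUE) &
                      !names(config) %in% c("occurrences", "metadata",
                                            "traits")],
    stages = names(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
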