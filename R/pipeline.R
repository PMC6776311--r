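#' Configuration for a full diet analysis run
#'
#' Collects inputs and tuning parameters for [run_full_analysis()]. Inputs
#' may be file paths (CSV, see the reader functions) or in-memory objects;
#' `NULL` inputs skip the corresponding stage with a warning.
#'
#' @param scats [scat_collection()] or path to a scat CSV (required)
#' @param isotopes isotope tibble or path to an isotope CSV
#' @param prey_reference prey reference tibble or path to its CSV
#' @param out_dir directory for output tables and the run log
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed integer seed (defaulted to 1 and logged if absent)
#' @param levene_center `"mean"` or `"median"`
#' @param equal_var_policy `"auto"`, `"pooled"`, or `"welch"` for pairwise
#'   t tests
#' @param min_prey_length_mm prey length filter applied to the reference
#'   (0 keeps everything)
#' @param log_transform_d15N log-transform delta-15N before the ANOVA
#' @param year_pooling named integer vector mapping years to pooled
#'   stratum labels. The default pools the field seasons into the two
#'   invasion strata (2010 with 2009: two years after the invasion; 2016
#'   with 2015: seven years after), which is what makes the two-factor
#'   river-by-year design estimable across rivers sampled in different
#'   calendar years.
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(scats, isotopes = NULL, prey_reference = NULL,
                            out_dir = "results", n_boot = 1000, seed = NULL,
                            levene_center = c("mean", "median"),
                            equal_var_policy = c("auto", "pooled", "welch"),
                            min_prey_length_mm = 0,
                            log_transform_d15N = TRUE,
                            year_pooling = c("2010" = 2009L, "2016" = 2015L)) {
  if (is.null(seed)) {
    seed <- 1L
    rlang::inform("no seed supplied; defaulting to seed = 1")
  }
  structure(list(scats = scats, isotopes = isotopes,
                 prey_reference = prey_reference, out_dir = out_dir,
                 n_boot = n_boot, seed = as.integer(seed),
                 levene_center = match.arg(levene_center),
                 equal_var_policy = match.arg(equal_var_policy),
                 min_prey_length_mm = min_prey_length_mm,
                 log_transform_d15N = isTRUE(log_transform_d15N),
                 year_pooling = year_pooling),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; path-valued inputs
#' are resolved relative to the working directory.
#'
#' @param path YAML file
#' @return list of class `analysis_config`
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("config not found: ", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    abort_schema(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(y$year_pooling)) {
    y$year_pooling <- unlist(y$year_pooling)
  }
  do.call(analysis_config, y)
}

#' Run the full scat-diet analysis
#'
#' Orchestrates every stage the package implements: occurrence tabulation,
#' niche breadth with bootstrap CIs, Mao Tau accumulation curves,
#' fractional trophic level (when a prey reference is available), and
#' isotope statistics (when isotope samples are available: group
#' summaries, Levene variance comparisons for both isotopes, two-factor
#' ANOVA on delta-15N and Bonferroni pairwise t tests). Group comparisons
#' follow the study scheme: within-river contrasts across years, and
#' across-river contrasts within the pooled recent stratum defined by
#' `year_pooling`.
#'
#' All tables are written as CSV under `out_dir` together with a run log
#' recording seed, configuration and package version. Runs with identical
#' config and seed produce byte-identical tables.
#'
#' @param config an [analysis_config()]
#' @return invisibly, a list with the output tibbles and their paths
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("scatniche run log",
                 paste0("package version: ",
                        as.character(utils::packageVersion("scatniche"))),
                 paste0("seed: ", config$seed),
                 paste0("n_boot: ", config$n_boot),
                 paste0("levene_center: ", config$levene_center),
                 paste0("equal_var_policy: ", config$equal_var_policy),
                 paste0("min_prey_length_mm: ", config$min_prey_length_mm))
  outputs <- list()
  ran <- character(0)

  collection <- config$scats
  if (is.character(collection)) collection <- read_scats(collection)
  if (!inherits(collection, "scat_collection")) {
    abort_schema("config$scats must be a scat_collection or a CSV path")
  }

  # occurrence + niche + accumulation always run off the scat records
  occ <- tabulate_occurrences(collection)
  outputs$occurrence <- write_table(occ, config$out_dir, "occurrence_table.csv")
  outputs$occurrence_groups <-
    write_table(occurrence_groups(occ), config$out_dir,
                "occurrence_groups.csv")
  ran <- c(ran, "occurrence")

  niche <- niche_breadth_table(collection, n_boot = config$n_boot,
                               seed = config$seed)
  outputs$niche <- write_table(niche, config$out_dir, "niche_breadth.csv")
  ran <- c(ran, "niche")

  accum <- accumulation_table(collection, n_boot = config$n_boot,
                              seed = config$seed)
  outputs$accumulation <- write_table(accum, config$out_dir,
                                      "accumulation_curves.csv")
  ran <- c(ran, "accumulation")

  prey <- config$prey_reference
  if (is.character(prey)) prey <- read_prey_reference(prey)
  if (!is.null(prey)) {
    if (config$min_prey_length_mm > 0) {
      prey <- filter_prey_by_length(prey, config$min_prey_length_mm)
    }
    ftl <- ftl_table(collection, prey, n_boot = config$n_boot,
                     seed = config$seed)
    outputs$trophic <- write_table(ftl, config$out_dir, "trophic_levels.csv")
    ran <- c(ran, "trophic")
  } else {
    rlang::warn("no prey reference supplied; trophic stage skipped")
    log_lines <- c(log_lines, "stage skipped: trophic (no prey reference)")
  }

  iso <- config$isotopes
  if (is.character(iso)) iso <- read_isotopes(iso)
  if (!is.null(iso)) {
    iso <- tibble::as_tibble(iso)
    iso$stratum <- pool_years(iso$year, config$year_pooling)
    grp_n <- dplyr::count(iso, .data$river, .data$stratum)
    drop <- grp_n[grp_n$n < 2, ]
    if (nrow(drop) > 0) {
      rlang::warn(paste0("isotope group(s) with n < 2 dropped: ",
                         paste(paste(drop$river, drop$stratum),
                               collapse = ", ")))
      iso <- dplyr::anti_join(iso, drop[, c("river", "stratum")],
                              by = c("river", "stratum"))
    }
    iso_out <- analyse_isotopes(iso, config)
    outputs$isotope_groups <- write_table(iso_out$groups, config$out_dir,
                                          "isotope_groups.csv")
    outputs$isotope_tests <- write_table(iso_out$tests, config$out_dir,
                                         "isotope_tests.csv")
    ran <- c(ran, "isotopes")
  } else {
    rlang::warn("no isotope samples supplied; isotope stage skipped")
    log_lines <- c(log_lines, "stage skipped: isotopes (no samples)")
  }

  if (length(ran) == 0) {
    rlang::abort("no analysis stage could run", class = "scatniche_no_stage")
  }
  log_lines <- c(log_lines, paste0("stages run: ", paste(ran, collapse = ", ")))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(outputs)
}

# within-river across-year and within-stratum across-river isotope tests
analyse_isotopes <- function(iso, config) {
  groups <- purrr::map(c("d15N", "d13C"), function(isoname) {
    vn <- variance_niche(
      dplyr::rename(iso, year_orig = "year", year = "stratum"),
      isotope = isoname, center = config$levene_center,
      contrasts = study_contrasts(iso))
    dplyr::mutate(vn$group_stats, isotope = isoname, .before = 1)
  })
  tests <- list()
  for (isoname in c("d15N", "d13C")) {
    vn <- variance_niche(
      dplyr::rename(iso, year_orig = "year", year = "stratum"),
      isotope = isoname, center = config$levene_center,
      contrasts = study_contrasts(iso))
    tests[[length(tests) + 1L]] <- tibble::tibble(
      isotope = isoname, test = "levene_omnibus", group1 = "all",
      group2 = "all", statistic = vn$omnibus$W,
      df = paste(vn$omnibus$df1, vn$omnibus$df2, sep = ","),
      p_value = vn$omnibus$p)
    tests[[length(tests) + 1L]] <- dplyr::mutate(
      dplyr::transmute(vn$pairwise, isotope = isoname,
                       test = "levene_pairwise",
                       group1 = .data$group1, group2 = .data$group2,
                       statistic = .data$W,
                       df = paste(.data$df1, .data$df2, sep = ","),
                       p_value = .data$p))
  }
  # two-factor ANOVA restricted to rivers observed in every stratum
  strata <- sort(unique(iso$stratum))
  full_rivers <- names(which(table(unique(iso[, c("river", "stratum")])$river)
                             == length(strata)))
  if (length(full_rivers) >= 2 && length(strata) >= 2) {
    sub <- iso[iso$river %in% full_rivers, ]
    an <- anova_two_factor(sub$d15N, sub$river, sub$stratum,
                           log_transform = config$log_transform_d15N)
    tests[[length(tests) + 1L]] <- dplyr::transmute(
      an[an$term != "Residuals", ],
      isotope = "d15N", test = paste0("anova_", .data$term),
      group1 = "all", group2 = "all", statistic = .data$statistic,
      df = as.character(.data$df), p_value = .data$p_value)
    key <- paste(sub$river, sub$stratum)
    pt <- pairwise_t_bonferroni(sub$d15N, key,
                                contrasts = study_contrasts(sub),
                                equal_var_policy = config$equal_var_policy,
                                center = config$levene_center)
    tests[[length(tests) + 1L]] <- dplyr::transmute(
      pt, isotope = "d15N", test = paste0("t_", .data$method),
      group1 = .data$group1, group2 = .data$group2, statistic = .data$t,
      df = as.character(round(.data$df, 3)), p_value = .data$p_adj)
  } else {
    rlang::warn("fewer than two rivers span all strata; ANOVA skipped")
  }
  list(groups = dplyr::bind_rows(groups), tests = dplyr::bind_rows(tests))
}

# contrasts of the study scheme on "river stratum" labels:
# same river across strata, and same (pooled, most recent) stratum across rivers
study_contrasts <- function(iso) {
  g <- dplyr::distinct(iso, .data$river, .data$stratum)
  out <- list()
  for (r in unique(g$river)) {
    ys <- sort(g$stratum[g$river == r])
    if (length(ys) >= 2) {
      for (cb in utils::combn(ys, 2, simplify = FALSE)) {
        out[[length(out) + 1L]] <- paste(r, cb)
      }
    }
  }
  recent <- max(g$stratum)
  rs <- sort(g$river[g$stratum == recent])
  if (length(rs) >= 2) {
    for (cb in utils::combn(rs, 2, simplify = FALSE)) {
      out[[length(out) + 1L]] <- paste(cb, recent)
    }
  }
  out
}

#' Map calendar years onto pooled comparison strata
#'
#' @param year integer vector of calendar years
#' @param pooling named integer vector; names are years to remap, values
#'   the stratum they pool into. Unlisted years map to themselves.
#' @return integer vector of strata
#' @export
pool_years <- function(year, pooling = c("2010" = 2009L, "2016" = 2015L)) {
  out <- as.integer(year)
  if (length(pooling) > 0) {
    hit <- match(as.character(out), names(pooling))
    out[!is.na(hit)] <- as.integer(pooling[hit[!is.na(hit)]])
  }
  out
}

write_table <- function(tbl, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(tibble::as_tibble(tbl), path)
  tbl
}
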