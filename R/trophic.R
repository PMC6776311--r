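#' Trophic enrichment factor constants
#'
#' Mean per-trophic-level isotopic enrichment: 3.4 per-mil (1 SD = 1.0) for
#' delta-15N and 0.4 per-mil (1 SD = 1.3) for delta-13C. These are the
#' widely used cross-taxon averages for converting isotopic shifts into
#' trophic-level shifts.
#'
#' @param delta15N_per_level per-mil delta-15N enrichment per trophic level
#' @param delta15N_sd its cross-taxon standard deviation
#' @param delta13C_per_level per-mil delta-13C enrichment per trophic level
#' @param delta13C_sd its cross-taxon standard deviation
#' @return list of class `tef_constants`
#' @export
tef_constants <- function(delta15N_per_level = 3.4, delta15N_sd = 1.0,
                          delta13C_per_level = 0.4, delta13C_sd = 1.3) {
  vals <- c(delta15N_per_level, delta15N_sd, delta13C_per_level, delta13C_sd)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all TEF constants must be positive")
  }
  structure(list(delta15N_per_level = delta15N_per_level,
                 delta15N_sd = delta15N_sd,
                 delta13C_per_level = delta13C_per_level,
                 delta13C_sd = delta13C_sd),
            class = "tef_constants")
}

#' Fractional trophic level of the predator
#'
#' FTL_i = 1 + sum_j FTL_j * DC_ij: one level above the diet-weighted mean
#' trophic level of the prey. DC_ij is the proportional contribution of
#' prey j, taken here from record counts (proportion-of-records). Taxa
#' without a known prey FTL are excluded and the remaining proportions are
#' renormalized; the exclusions are reported on the result.
#'
#' @param counts_by_taxon named numeric vector: record counts (or any
#'   weights proportional to diet contribution) per prey taxon
#' @param prey_reference tibble with columns `taxon` and `ftl` (see
#'   [read_prey_reference()])
#' @return object of class `trophic_result`: list with `ftl`, `dc` (named
#'   renormalized proportions over included taxa), `prey_ftl` (named FTL_j
#'   used), `excluded_taxa`
#' @examples
#' ref <- tibble::tibble(taxon = c("a", "b"), ftl = c(2.5, 3.2))
#' fractional_trophic_level(c(a = 6, b = 4), ref)  # 1 + 0.6*2.5 + 0.4*3.2
#' @export
fractional_trophic_level <- function(counts_by_taxon, prey_reference) {
  cnt <- counts_by_taxon
  if (is.null(names(cnt)) || any(!nzchar(names(cnt)))) {
    rlang::abort("counts_by_taxon must be named by taxon")
  }
  cnt <- cnt[cnt > 0]
  ftl_j <- prey_reference$ftl[match(names(cnt), prey_reference$taxon)]
  known <- !is.na(ftl_j)
  excluded <- names(cnt)[!known]
  if (!any(known)) {
    rlang::abort(paste0("no taxon with a known prey FTL; excluded: ",
                        paste(excluded, collapse = ", ")))
  }
  dc <- cnt[known] / sum(cnt[known])
  ftl_j <- ftl_j[known]
  names(ftl_j) <- names(dc)
  structure(list(ftl = 1 + sum(ftl_j * dc),
                 dc = dc, prey_ftl = ftl_j,
                 excluded_taxa = excluded),
            class = "trophic_result")
}

#' @export
print.trophic_result <- function(x, ...) {
  cat(sprintf("FTL = %.3f over %d prey taxa", x$ftl, length(x$dc)))
  if (length(x$excluded_taxa) > 0) {
    cat(" (excluded, no FTL: ", paste(x$excluded_taxa, collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Trophic-level shift implied by a delta-15N difference
#'
#' Divides a delta-15N difference (per-mil) by the per-level enrichment
#' factor, converting an isotopic shift between groups into fractional
#' trophic levels. A 3.4 per-mil difference is exactly one level under the
#' default constants.
#'
#' @param delta_d15N delta-15N difference in per-mil
#' @param tef a [tef_constants()] object
#' @return trophic-level shift (same sign as `delta_d15N`)
#' @export
ftl_shift_from_d15N <- function(delta_d15N, tef = tef_constants()) {
  stopifnot(inherits(tef, "tef_constants"))
  delta_d15N / tef$delta15N_per_level
}

#' Bootstrap confidence interval for the predator FTL
#'
#' Resamples scats with replacement, re-tabulates diet composition and
#' recomputes [fractional_trophic_level()] per replicate.
#'
#' @param scats list of per-scat item vectors (one group), or a
#'   single-group [scat_collection()]
#' @param prey_reference prey FTL lookup table
#' @inheritParams bootstrap_ci
#' @return object of class `trophic_result` with `ci_low`, `ci_high`,
#'   `n_boot` added
#' @export
ftl_bootstrap <- function(scats, prey_reference, n_boot = 1000, seed = NULL,
                          quantiles = c(0.025, 0.975)) {
  if (inherits(scats, "scat_collection")) {
    lst <- group_item_lists(scats)
    if (length(lst) != 1) {
      rlang::abort("collection spans several groups; bootstrap one group at a time")
    }
    scats <- lst[[1]]$scats
  }
  stat <- function(items_list) {
    tab <- table(unlist(items_list))
    cnt <- as.numeric(tab)
    names(cnt) <- names(tab)
    if (!any(!is.na(prey_reference$ftl[match(names(cnt),
                                             prey_reference$taxon)]))) {
      return(NA_real_)
    }
    fractional_trophic_level(cnt, prey_reference)$ftl
  }
  tab <- table(unlist(scats))
  cnt <- as.numeric(tab)
  names(cnt) <- names(tab)
  point <- fractional_trophic_level(cnt, prey_reference)
  ci <- bootstrap_ci(scats, stat, n_boot = n_boot, seed = seed,
                     quantiles = quantiles)
  point$ci_low <- ci$low
  point$ci_high <- ci$high
  point$n_boot <- n_boot
  point
}

#' Predator FTL per river-year group with bootstrap CIs
#'
#' @param collection a [scat_collection()]
#' @param prey_reference prey FTL lookup table
#' @param n_boot bootstrap replicates per group
#' @param seed integer seed
#' @return tibble: `river`, `year`, `n_scats`, `ftl`, `ci_low`, `ci_high`,
#'   `n_prey_taxa`, `excluded_taxa` (comma-separated)
#' @export
ftl_table <- function(collection, prey_reference, n_boot = 1000, seed = 1) {
  lst <- group_item_lists(collection)
  rows <- purrr::map(lst, function(g) {
    if (length(unlist(g$scats)) == 0) {
      rlang::warn(paste0("group ", g$river, " ", g$year,
                         " has no records; skipped"))
      return(NULL)
    }
    res <- ftl_bootstrap(g$scats, prey_reference, n_boot = n_boot,
                         seed = seed)
    tibble::tibble(river = g$river, year = g$year,
                   n_scats = length(g$scats),
                   ftl = res$ftl, ci_low = res$ci_low, ci_high = res$ci_high,
                   n_prey_taxa = length(res$dc),
                   excluded_taxa = paste(res$excluded_taxa, collapse = ","))
  })
  dplyr::bind_rows(rows)
}
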