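#' Levin's niche breadth index
#'
#' B = 1 / sum(p_j^2), the inverse Simpson concentration of diet
#' proportions. Ranges from 1 (all records in one prey category, a
#' specialist) to the number of categories (perfectly even use, a
#' generalist).
#'
#' @param proportions numeric vector of diet proportions; must be
#'   non-negative and sum to 1 (callers normalize from raw counts).
#' @return Levin's B, a scalar in `[1, number of nonzero categories]`
#' @examples
#' levins_B(rep(0.2, 5))  # maximally even: B = 5
#' @export
levins_B <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0)) {
    rlang::abort("proportions must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    rlang::abort("proportions must sum to 1; normalize counts first")
  }
  if (!any(p > 0)) rlang::abort("at least one proportion must be positive")
  1 / sum(p^2)
}

#' Standardized Levin's index from raw counts
#'
#' Computes B from the count-derived proportions and rescales it to
#' B_a = (B - 1) / (n - 1) in `[0, 1]`, where n is the number of prey
#' categories with at least one record. A single-category diet has
#' B_a = 0 by definition (the specialist limit). A conventional
#' interpretive label is attached: `"generalist"` when B_a > 0.6,
#' `"specialist"` when B_a < 0.4, `"intermediate"` otherwise.
#'
#' @param counts_by_taxon numeric vector of record counts (optionally
#'   named by taxon); zero-count categories are dropped.
#' @return object of class `niche_breadth`: list with `B`, `B_a`, `n`,
#'   `classification`.
#' @examples
#' standardized_levins(c(catfish = 36, cichlid = 20, crab = 17))
#' @export
standardized_levins <- function(counts_by_taxon) {
  cnt <- as.numeric(counts_by_taxon)
  if (any(!is.finite(cnt)) || any(cnt < 0)) {
    rlang::abort("counts must be finite and non-negative")
  }
  cnt <- cnt[cnt > 0]
  if (length(cnt) == 0) rlang::abort("all counts are zero")
  p <- cnt / sum(cnt)
  B <- 1 / sum(p^2)
  n <- length(cnt)
  B_a <- if (n == 1L) 0 else (B - 1) / (n - 1)
  structure(list(B = B, B_a = B_a, n = n,
                 classification = classify_niche(B_a)),
            class = "niche_breadth")
}

#' @export
print.niche_breadth <- function(x, ...) {
  cat(sprintf("Levin's B = %.3f over n = %d categories; B_a = %.3f (%s)\n",
              x$B, x$n, x$B_a, x$classification))
  invisible(x)
}

#' Interpretive niche-breadth label
#'
#' Conventional thresholds on the standardized index: B_a > 0.6 is read as
#' a generalist diet, B_a < 0.4 as a specialist diet. The label is
#' descriptive only and changes no computation.
#'
#' @param B_a standardized Levin's index in `[0, 1]`
#' @return `"generalist"`, `"specialist"`, or `"intermediate"`
#' @export
classify_niche <- function(B_a) {
  stopifnot(is.numeric(B_a))
  ifelse(B_a > 0.6, "generalist",
         ifelse(B_a < 0.4, "specialist", "intermediate"))
}

#' Scat-resampling bootstrap percentile interval
#'
#' Resamples scats (not individual prey records) with replacement to the
#' original sample size, recomputes the statistic on every replicate, and
#' returns empirical percentile bounds. Replicates where the statistic is
#' undefined (`NA`) are dropped with a warning; the interval errors out if
#' more than half are lost.
#'
#' @param scats list of per-scat item vectors (see [group_item_lists()]),
#'   or a single-group [scat_collection()]
#' @param statistic function mapping a list of item vectors to a scalar
#' @param n_boot number of bootstrap replicates (default 1000)
#' @param seed integer seed; identical seeds give identical intervals
#' @param quantiles lower/upper percentile probabilities
#' @return list with `low`, `high`, `n_boot`, `n_used`, `replicates`
#' @export
bootstrap_ci <- function(scats, statistic, n_boot = 1000, seed = NULL,
                         quantiles = c(0.025, 0.975)) {
  if (inherits(scats, "scat_collection")) {
    lst <- group_item_lists(scats)
    if (length(lst) != 1) {
      rlang::abort("collection spans several groups; bootstrap one group at a time")
    }
    scats <- lst[[1]]$scats
  }
  stopifnot(is.list(scats), length(scats) >= 1, is.function(statistic),
            n_boot >= 1, length(quantiles) == 2)
  quantiles <- sort(quantiles)
  H <- length(scats)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(H, H, replace = TRUE)
      as.numeric(statistic(scats[idx]))
    }, numeric(1))
  })
  bad <- !is.finite(reps)
  if (any(bad)) {
    rlang::warn(paste0(sum(bad), " bootstrap replicate(s) undefined; excluded"))
    if (mean(bad) > 0.5) {
      rlang::abort("statistic undefined on more than half of the replicates")
    }
    reps <- reps[!bad]
  }
  q <- stats::quantile(reps, probs = quantiles, names = FALSE, type = 7)
  list(low = q[1], high = q[2], n_boot = n_boot, n_used = length(reps),
       replicates = reps)
}

# statistic helpers over a list of per-scat item vectors
ba_statistic <- function(items_list) {
  tab <- table(unlist(items_list))
  if (length(tab) == 0) return(NA_real_)
  standardized_levins(as.numeric(tab))$B_a
}

#' Niche breadth per river-year group with bootstrap CIs
#'
#' Applies [standardized_levins()] to each group's record counts and
#' attaches scat-bootstrap percentile intervals on B_a. The category count
#' n is recomputed within each bootstrap replicate from the resampled
#' scats. Bounds are reported sorted ascending (`ci_low <= ci_high`).
#'
#' @param collection a [scat_collection()]
#' @param n_boot bootstrap replicates per group (default 1000)
#' @param seed integer seed for reproducibility
#' @param quantiles percentile bounds (default 2.5% and 97.5%)
#' @return tibble with one row per group: `river`, `year`, `n_scats`,
#'   `n_taxa`, `B`, `B_a`, `ci_low`, `ci_high`, `classification`
#' @export
niche_breadth_table <- function(collection, n_boot = 1000, seed = 1,
                                quantiles = c(0.025, 0.975)) {
  lst <- group_item_lists(collection)
  rows <- purrr::imap(lst, function(g, key) {
    tab <- table(unlist(g$scats))
    if (length(tab) == 0) {
      rlang::warn(paste0("group ", key, " has no records; skipped"))
      return(NULL)
    }
    nb <- standardized_levins(as.numeric(tab))
    ci <- bootstrap_ci(g$scats, ba_statistic, n_boot = n_boot,
                       seed = seed, quantiles = quantiles)
    tibble::tibble(river = g$river, year = g$year,
                   n_scats = length(g$scats), n_taxa = nb$n,
                   B = nb$B, B_a = nb$B_a,
                   ci_low = ci$low, ci_high = ci$high,
                   classification = nb$classification)
  })
  dplyr::bind_rows(rows)
}

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
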