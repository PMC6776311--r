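#' Combinatorial coefficient of the Mao Tau estimator
#'
#' alpha_jh = (H - h)! (H - j)! / ((H - h - j)! H!) is the probability that
#' a prey category occurring in exactly j of H scats is absent from a
#' random subset of h scats. Evaluated in log-gamma space so large scat
#' counts do not overflow; defined as 0 whenever j > H - h (the category
#' cannot be missed), which is what makes the curve hit the observed
#' richness at h = H.
#'
#' @param j number of scats a category occurs in (1..H); vectorized
#' @param h subset size (1..H)
#' @param H total number of scats
#' @return numeric vector of coefficients in `[0, 1]`
#' @export
alpha_coefficient <- function(j, h, H) {
  stopifnot(length(h) == 1, length(H) == 1, H >= 1)
  j <- as.numeric(j)
  if (h < 1 || h > H) rlang::abort("h must be in 1..H")
  if (any(j < 1 | j > H)) rlang::abort("j must be in 1..H")
  out <- numeric(length(j))
  ok <- j <= (H - h)
  if (any(ok)) {
    lg <- lgamma(H - h + 1) + lgamma(H - j[ok] + 1) -
      lgamma(H - h - j[ok] + 1) - lgamma(H + 1)
    out[ok] <- pmin(1, pmax(0, exp(lg)))
  }
  out
}

#' Mao Tau expected species-accumulation curve
#'
#' Analytic sample-based rarefaction: tau(h) = S_obs - sum_j alpha_jh S_j,
#' where S_j is the number of prey categories found in exactly j scats.
#' tau(h) equals the mean richness over all size-h subsets of the H scats,
#' so tau(1) is the mean per-scat richness and tau(H) = S_obs exactly.
#'
#' @param incidence_matrix binary scat-by-taxon matrix (rows = scats)
#' @return tibble of class `accumulation_curve` with columns `h`, `tau`;
#'   attributes `H`, `S_obs`.
#' @export
mao_tau_curve <- function(incidence_matrix) {
  m <- as.matrix(incidence_matrix)
  if (length(m) == 0) rlang::abort("incidence matrix is empty")
  if (!all(m %in% c(0, 1))) rlang::abort("incidence matrix must be binary")
  H <- nrow(m)
  inc <- colSums(m)
  inc <- inc[inc > 0]
  S_obs <- length(inc)
  sj <- table(inc)  # S_j: number of taxa with exactly j incidences
  jj <- as.numeric(names(sj))
  tau <- vapply(seq_len(H), function(h) {
    S_obs - sum(alpha_coefficient(jj, h, H) * as.numeric(sj))
  }, numeric(1))
  out <- tibble::tibble(h = seq_len(H), tau = tau)
  attr(out, "H") <- H
  attr(out, "S_obs") <- S_obs
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Scat-bootstrap band around an accumulation curve
#'
#' Resamples scats (matrix rows) with replacement, recomputes the Mao Tau
#' curve per replicate, and returns percentile bounds at each h. The
#' analytic curve itself needs no resampling; the band conveys sampling
#' uncertainty in the scat set.
#'
#' @inheritParams mao_tau_curve
#' @param n_boot bootstrap replicates
#' @param seed integer seed
#' @param quantiles percentile bounds
#' @return tibble with `h`, `tau`, `ci_low`, `ci_high`
#' @export
accumulation_ci <- function(incidence_matrix, n_boot = 1000, seed = NULL,
                            quantiles = c(0.025, 0.975)) {
  m <- as.matrix(incidence_matrix)
  base <- mao_tau_curve(m)
  H <- nrow(m)
  quantiles <- sort(quantiles)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(H, H, replace = TRUE)
      mao_tau_curve(m[idx, , drop = FALSE])$tau
    }, numeric(H))
  })
  reps <- matrix(reps, nrow = H)
  lo <- apply(reps, 1, stats::quantile, probs = quantiles[1], names = FALSE)
  hi <- apply(reps, 1, stats::quantile, probs = quantiles[2], names = FALSE)
  tibble::tibble(h = base$h, tau = base$tau, ci_low = lo, ci_high = hi)
}

#' Incidence matrix of one river-year group
#'
#' @param scats list of per-scat item vectors (one group)
#' @return binary matrix, scats in rows, taxa in columns
#' @export
incidence_matrix <- function(scats) {
  stopifnot(is.list(scats), length(scats) >= 1)
  taxa <- sort(unique(unlist(scats)))
  m <- matrix(0L, nrow = length(scats), ncol = length(taxa),
              dimnames = list(NULL, taxa))
  for (i in seq_along(scats)) m[i, match(scats[[i]], taxa)] <- 1L
  m
}

#' Accumulation curves for every river-year group
#'
#' @param collection a [scat_collection()]
#' @param n_boot bootstrap replicates for the band (0 to skip the band)
#' @param seed integer seed
#' @return long tibble: `river`, `year`, `h`, `tau`, and when `n_boot > 0`
#'   also `ci_low`, `ci_high`
#' @export
accumulation_table <- function(collection, n_boot = 1000, seed = 1) {
  lst <- group_item_lists(collection)
  rows <- purrr::map(lst, function(g) {
    if (length(unlist(g$scats)) == 0) {
      rlang::warn(paste0("group ", g$river, " ", g$year,
                         " has no records; skipped"))
      return(NULL)
    }
    m <- incidence_matrix(g$scats)
    cur <- if (n_boot > 0) {
      accumulation_ci(m, n_boot = n_boot, seed = seed)
    } else {
      mao_tau_curve(m)
    }
    dplyr::bind_cols(tibble::tibble(river = g$river, year = g$year,
                                    .rows = nrow(cur)), cur)
  })
  dplyr::bind_rows(rows)
}
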