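# Vectorized maximally selected log-rank scan.
#
# Patients are ordered by marker (descending); the cumulative row m of the
# at-risk / event indicator matrices gives the risk-set composition of the
# group {marker >= marker_(m)} at every distinct event time, so the
# standardized log-rank statistic for all candidate cuts comes out of two
# cumulative sums. Used both for the observed scan and for permutation
# reference draws.
logrank_scan <- function(time, event, marker, min_proportion) {
  n <- length(time)
  ut <- sort(unique(time[event == 1L]))
  k <- length(ut)
  if (k == 0L) return(NULL)
  pos <- findInterval(time, ut)            # t_i >= ut[j] iff j <= pos[i]
  atrisk <- outer(pos, seq_len(k), ">=") * 1
  ev <- matrix(0, n, k)
  has_ev <- event == 1L
  ev[cbind(which(has_ev), match(time[has_ev], ut))] <- 1
  d <- colSums(ev)
  nrisk <- colSums(atrisk)
  w <- ifelse(nrisk > 1, d * (nrisk - d) / ((nrisk - 1) * nrisk^2), 0)
  m_min <- max(1L, ceiling(min_proportion * n))
  m_max <- n - m_min

  scan_for <- function(ord) {
    n1 <- apply(atrisk[ord, , drop = FALSE], 2L, cumsum)
    o  <- cumsum(event[ord])
    e  <- as.numeric(n1 %*% (d / nrisk))
    v  <- as.numeric(n1 %*% (w * nrisk) - (n1 * n1) %*% w)
    z  <- ifelse(v > 0, (o - e) / sqrt(v), NA_real_)
    list(z = z)
  }

  list(ut = ut, scan_for = scan_for, m_min = m_min, m_max = m_max, n = n)
}

#' Maximally selected log-rank cut point
#'
#' Scans candidate cut points at the observed marker values, subject to a
#' minimum group-size constraint, and selects the cut with the largest
#' absolute standardized log-rank statistic (equivalently the smallest
#' log-rank p-value). The returned naive p-value ignores the selection over
#' candidate cuts; an optional permutation adjustment (permuting the marker
#' against the survival records and recording the maximal statistic)
#' accounts for it.
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @param marker Numeric marker; groups are `marker >= cut` (high) vs
#'   `marker < cut` (low). The scan is rank-based: any strictly increasing
#'   transform of the marker selects the same split.
#' @param min_proportion Minimum fraction of patients required on each side
#'   of an admissible cut (default 0.1).
#' @param n_perm Number of permutations for the selection-adjusted p-value;
#'   0 (default) skips the adjustment.
#' @param seed Optional seed for the permutation draw.
#'
#' @return Object of class `cutpoint_result`: `cutpoint`, `statistic`
#'   (standardized log-rank z at the cut), `chisq`, `p_naive`,
#'   `p_adjusted` (NA when `n_perm = 0`), `n_low`, `n_high`, and the full
#'   `scan` table (`cut`, `statistic`).
#' @examples
#' set.seed(1)
#' tm <- rexp(60, 0.02); mk <- rnorm(60)
#' optimal_cutpoint(pmin(tm, 60), as.integer(tm <= 60), mk)
#' @export
optimal_cutpoint <- function(time, event, marker, min_proportion = 0.1,
                             n_perm = 0, seed = NULL) {
  event <- check_surv_input(time, event)
  n <- length(time)
  if (length(marker) != n || !is.numeric(marker) || anyNA(marker)) {
    stop("`marker` must be numeric, without missing values, matching `time`",
         call. = FALSE)
  }
  if (n < 10L) stop("cut-point search requires at least 10 records", call. = FALSE)
  if (min_proportion <= 0 || min_proportion >= 0.5) {
    stop("`min_proportion` must be in (0, 0.5)", call. = FALSE)
  }
  sc <- logrank_scan(time, event, marker, min_proportion)
  if (is.null(sc)) stop("no events; cut-point search undefined", call. = FALSE)

  ord <- order(marker, decreasing = TRUE)
  mk_desc <- marker[ord]
  # a cut after position m is only real when the marker value changes there
  distinct <- c(mk_desc[-n] > mk_desc[-1], FALSE)
  valid <- seq_len(n) >= sc$m_min & seq_len(n) <= sc$m_max & distinct
  if (!any(valid)) {
    stop("no admissible candidate cut satisfies the minimum group proportion (",
         min_proportion, ")", call. = FALSE)
  }
  z <- sc$scan_for(ord)$z
  z_valid <- z[valid]
  if (all(is.na(z_valid))) {
    stop("log-rank statistic undefined at every admissible cut ",
         "(no informative events on both sides)", call. = FALSE)
  }
  idx <- which(valid)[which.max(abs(z_valid))]
  z_obs <- z[idx]
  cut <- mk_desc[idx]

  p_adj <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    max_obs <- abs(z_obs)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      zp <- sc$scan_for(sample.int(n))$z
      zp <- zp[valid]
      if (any(is.finite(zp)) && max(abs(zp), na.rm = TRUE) >= max_obs) {
        exceed <- exceed + 1L
      }
    }
    p_adj <- (1 + exceed) / (n_perm + 1)
  }

  structure(
    list(cutpoint = cut, statistic = z_obs, chisq = z_obs^2,
         p_naive = stats::pchisq(z_obs^2, 1, lower.tail = FALSE),
         p_adjusted = p_adj, n_perm = n_perm,
         n_high = idx, n_low = n - idx,
         min_proportion = min_proportion,
         scan = data.frame(cut = mk_desc[valid], statistic = z[valid])),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat("Maximally selected log-rank cut point\n")
  cat(sprintf("  cut: marker >= %.4g (n_high = %d, n_low = %d)\n",
              x$cutpoint, x$n_high, x$n_low))
  cat(sprintf("  |z| = %.3f, naive p = %.4g", abs(x$statistic), x$p_naive))
  if (x$n_perm > 0) {
    cat(sprintf(", permutation-adjusted p = %.4g (%d permutations)",
                x$p_adjusted, x$n_perm))
  }
  cat("\n")
  invisible(x)
}
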