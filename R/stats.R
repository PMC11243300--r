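# Cohort statistics ----------------------------------------------------------
#
# Paired Wilcoxon signed-rank tests between the rigid and compliant indicator
# populations, Spearman correlation of the relative changes with the
# morphometric descriptors, and the cut-height sensitivity re-test.  Zero
# differences use Pratt handling by default (rank with zeros, then drop);
# exact null distribution up to 50 nonzero pairs (tie-aware, via the
# generating polynomial of the midranks), normal approximation with
# continuity correction above.

#' Paired Wilcoxon signed-rank test
#'
#' @param x first sample (e.g. compliant indicator values) or differences if
#'   `y` is NULL
#' @param y optional second sample (paired)
#' @param zeros "pratt" (rank zeros, then drop) or "wilcoxon" (drop zeros
#'   before ranking)
#' @param exact_max use the exact null for up to this many nonzero pairs
#'   (the tie-aware generating-polynomial evaluation stays cheap well past
#'   typical cohort sizes; the continuity-corrected normal approximation
#'   takes over beyond)
#' @return list(statistic = W+ , p = two-sided p, n_nonzero, method, degenerate)
#' @export
signed_rank_test <- function(x, y = NULL, zeros = c("pratt", "wilcoxon"),
                             exact_max = 50) {
  zeros <- match.arg(zeros)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]                  # undefined indicator pairs are excluded
  if (zeros == "wilcoxon") d <- d[d != 0]
  nz <- d != 0
  if (length(d) == 0 || sum(nz) < 2 || all(d == 0))
    return(list(statistic = NA_real_, p = NA_real_, n_nonzero = sum(nz),
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))                  # zeros included under Pratt
  r_nz <- r[nz]; s_nz <- sign(d[nz])
  W <- sum(r_nz[s_nz > 0])
  m <- sum(nz)
  if (m <= exact_max) {
    # exact null over sign assignments; double ranks to make midranks integer
    r2 <- as.integer(round(2 * r_nz))
    tot <- sum(r2)
    f <- numeric(tot + 1); f[1] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1):(tot + 1)] <- g[(rr + 1):(tot + 1)] + f[1:(tot + 1 - rr)]
      f <- g / 1                      # counts; normalize at the end
    }
    f <- f / 2^m
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(f[(w2 + 1):(tot + 1)])
    p_le <- sum(f[1:(w2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- sum(r_nz) / 2
    sig <- sqrt(sum(r_nz^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sig
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  list(statistic = W, p = p, n_nonzero = m, method = method,
       degenerate = m < 5)
}

#' Spearman correlation matrix of deltas against descriptors
#'
#' Rank correlation with average-rank ties. Constant columns are flagged
#' undefined (NA) rather than propagating NaN. An internal identity audit
#' verifies Spearman = Pearson-on-ranks on every call.
#'
#' @param descriptors data.frame of per-case morphometrics
#' @param deltas data.frame of per-case relative indicator changes (%)
#' @return list(rho = cross-correlation matrix descriptors x deltas,
#'   max_abs = largest finite |rho|, undefined = flagged column pairs)
#' @export
spearman_matrix <- function(descriptors, deltas) {
  stopifnot(nrow(descriptors) == nrow(deltas), nrow(deltas) >= 5)
  D <- as.matrix(descriptors); G <- as.matrix(deltas)
  rho <- matrix(NA_real_, ncol(D), ncol(G),
                dimnames = list(colnames(D), colnames(G)))
  undef <- character()
  for (i in seq_len(ncol(D))) for (j in seq_len(ncol(G))) {
    xi <- D[, i]; yj <- G[, j]
    ok <- is.finite(xi) & is.finite(yj)
    if (sum(ok) < 5 || stats::sd(xi[ok]) == 0 || stats::sd(yj[ok]) == 0) {
      undef <- c(undef, paste(colnames(D)[i], colnames(G)[j], sep = ":"))
      next
    }
    rs <- cor(xi[ok], yj[ok], method = "spearman")
    rp <- cor(rank(xi[ok]), rank(yj[ok]), method = "pearson")
    stopifnot(abs(rs - rp) < 1e-10)     # identity audit
    rho[i, j] <- rs
  }
  list(rho = rho, max_abs = if (all(is.na(rho))) NA_real_ else
    max(abs(rho), na.rm = TRUE), undefined = undef)
}

#' Cut-height sensitivity re-test
#'
#' Re-runs the paired signed-rank tests at each cut height and reports which
#' significance conclusions flip relative to the reference height.
#'
#' @param table long data.frame with columns case, cut_height, indicator,
#'   rigid, compliant
#' @param ref_height reference cut height (mm)
#' @param alpha significance level
#' @return list(report = data.frame(indicator, cut_height, p, significant,
#'   flip), flips = flipped (indicator, height) pairs)
#' @export
sensitivity_rerun <- function(table, ref_height = 8, alpha = 0.05) {
  need <- c("case", "cut_height", "indicator", "rigid", "compliant")
  if (!all(need %in% names(table)))
    abort_sf("sensitivity table must have case/cut_height/indicator/rigid/compliant",
             "sacflow_input_error")
  hts <- sort(unique(table$cut_height))
  inds <- unique(table$indicator)
  if (!(ref_height %in% hts))
    abort_sf("reference cut height missing from the table", "sacflow_input_error")
  rows <- list()
  for (ind in inds) for (h in hts) {
    sub <- table[table$indicator == ind & table$cut_height == h, ]
    if (!nrow(sub))
      abort_sf(sprintf("missing data for %s at %g mm", ind, h),
               "sacflow_input_error")
    sub <- sub[order(sub$case), ]
    ts <- signed_rank_test(sub$compliant, sub$rigid)
    rows[[length(rows) + 1]] <- data.frame(
      indicator = ind, cut_height = h, p = ts$p,
      significant = isTRUE(ts$p < alpha), degenerate = ts$degenerate)
  }
  rep_ <- do.call(rbind, rows)
  ref <- rep_[rep_$cut_height == ref_height, c("indicator", "significant")]
  rep_$flip <- rep_$significant != ref$significant[match(rep_$indicator,
                                                         ref$indicator)]
  list(report = rep_, flips = rep_[rep_$flip & rep_$cut_height != ref_height,
                                   c("indicator", "cut_height")])
}
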