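#' GISTIC-style analysis configuration
#'
#' @param q_threshold Significance threshold on the q-value (default 0.25).
#' @param n_permutations Cyclic-shift permutation draws for the null
#'   (default 1000; below 100 the q resolution is coarse and a warning is
#'   issued).
#' @param cap Amplitude cap in log2 units applied to marker values before
#'   scoring (default 2.0).
#' @param peel_off Iteratively remove detected peaks to reveal further
#'   independent peaks on the same chromosome (default TRUE).
#' @param assoc_fdr FDR level for region-covariate association (default
#'   0.05).
#' @return List of class \code{gistic_config}.
#' @export
gistic_config <- function(q_threshold = 0.25, n_permutations = 1000,
                          cap = 2.0, peel_off = TRUE, assoc_fdr = 0.05) {
  stopifnot(q_threshold > 0, q_threshold < 1, cap > 0)
  if (n_permutations < 100) {
    warning("n_permutations < 100: q-value resolution will be coarse")
  }
  structure(list(q_threshold = q_threshold,
                 n_permutations = as.integer(n_permutations), cap = cap,
                 peel_off = peel_off, assoc_fdr = assoc_fdr),
            class = "gistic_config")
}

#' Marker-level G scores
#'
#' For direction \code{"gain"}, the score at marker m is the sum over
#' samples of \code{max(0, min(x, cap) - gain_thr_s)} where x is the
#' sample's segmented log2 ratio at m; for \code{"loss"} the symmetric
#' expression with the sign flipped. Missing markers contribute 0. G is
#' non-negative and invariant to sample order.
#'
#' @param X Segmented-value matrix (probes x samples), e.g. from
#'   \code{\link{seg_means_matrix}}.
#' @param thresholds Data frame from \code{\link{adaptive_thresholds}}
#'   aligned to the columns of \code{X}.
#' @param direction \code{"gain"} or \code{"loss"}.
#' @param cap Amplitude cap (default 2).
#' @return List: \code{G} (per-marker score vector) and \code{contrib}
#'   (markers x samples contribution matrix, the scored addends).
#' @export
gscores <- function(X, thresholds, direction = c("gain", "loss"),
                    cap = 2.0) {
  direction <- match.arg(direction)
  if (is.null(thresholds)) stop("sample thresholds are required")
  stopifnot(ncol(X) == nrow(thresholds))
  contrib <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (s in seq_len(ncol(X))) {
    x <- X[, s]
    c_s <- if (direction == "gain") {
      pmax(0, pmin(x, cap) - thresholds$gain_thr[s])
    } else {
      pmax(0, thresholds$loss_thr[s] - pmax(x, -cap))
    }
    c_s[is.na(c_s)] <- 0
    contrib[, s] <- c_s
  }
  list(G = rowSums(contrib), contrib = contrib, direction = direction)
}

#' Permutation null and marker q-values
#'
#' The null pools, over \code{n_permutations} draws, the G vectors obtained
#' by cyclically shifting each sample's contribution vector by an
#' independent uniform offset (preserving within-sample autocorrelation).
#' The per-marker p-value is the add-one fraction of the pooled null at or
#' above the observed G; q-values are Benjamini-Hochberg across markers.
#' Deterministic given the R random seed. When every observed G is zero the
#' permutations are skipped and all p = q = 1.
#'
#' @param scores Output of \code{\link{gscores}}.
#' @param config A \code{\link{gistic_config}}.
#' @return List: \code{p}, \code{q} (per-marker vectors) and
#'   \code{null_pool} (sorted pooled null, NULL when skipped).
#' @export
marker_null_and_q <- function(scores, config = gistic_config()) {
  G <- scores$G
  M <- length(G)
  if (max(G) <= 0) {
    return(list(p = rep(1, M), q = rep(1, M), null_pool = NULL))
  }
  pool <- gistic_null_pool_cpp(scores$contrib, config$n_permutations)
  p <- pvals_from_pool(G, pool)
  list(p = p, q = stats::p.adjust(p, "BH"), null_pool = pool)
}

# Add-one right-tail p-values of x against a sorted null pool.
pvals_from_pool <- function(x, pool) {
  n <- length(pool)
  eps <- 1e-9 * pmax(abs(x), 1)
  cnt_ge <- n - findInterval(x - eps, pool)
  (cnt_ge + 1) / (n + 1)
}

#' Delineate significant recurrent regions
#'
#' Maximal runs of markers with q below the threshold form wide regions;
#' the peak is the contiguous plateau of maximal G inside the region,
#' made robust to single-sample segmentation noise: markers whose G lies
#' within one sample's contribution of the maximum (the largest
#' contribution at the argmax marker) belong to the plateau, so one
#' spurious within-amplicon breakpoint in one sample cannot shrink the
#' peak. With peel-off, the carriers contributing at the peak are zeroed
#' on that chromosome, G and q are recomputed (against the original pooled
#' null), and the search iterates to reveal additional independent peaks;
#' each iteration strictly reduces total G, so the loop terminates.
#'
#' @param scores Output of \code{\link{gscores}}.
#' @param nullq Output of \code{\link{marker_null_and_q}}.
#' @param probes Aligned \code{probe_set}.
#' @param config A \code{\link{gistic_config}}.
#' @return Data frame with one row per region: \code{direction},
#'   \code{chrom}, \code{wide_start}, \code{wide_end}, \code{peak_start},
#'   \code{peak_end}, \code{peak_g}, \code{q_at_peak}, \code{iteration}.
#' @export
significant_regions <- function(scores, nullq, probes,
                                config = gistic_config()) {
  empty <- data.frame(direction = character(), chrom = character(),
                      wide_start = numeric(), wide_end = numeric(),
                      peak_start = numeric(), peak_end = numeric(),
                      peak_g = numeric(), q_at_peak = numeric(),
                      iteration = integer(), stringsAsFactors = FALSE)
  if (is.null(nullq$null_pool) && all(nullq$q >= config$q_threshold)) {
    return(empty)
  }
  contrib <- scores$contrib
  p <- nullq$p
  q <- nullq$q
  claimed <- rep(FALSE, nrow(contrib))
  out <- list()
  for (iter in 1:20) {
    G <- rowSums(contrib)
    sig <- q < config$q_threshold & !claimed
    if (!any(sig)) break
    found <- FALSE
    for (chr in unique(probes$chrom)) {
      rows <- probe_rows_chrom(probes, chr)
      r <- rle(sig[rows])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        run <- rows[starts[k]:ends[k]]
        gmax <- max(G[run])
        m_star <- run[which.max(G[run])]
        # leave-one-out tolerance: one sample's segmentation noise must
        # not move the peak
        tol <- max(contrib[m_star, ], 1e-9 * gmax)
        plat <- G[run] >= gmax - tol
        pr <- rle(plat)
        pe <- cumsum(pr$lengths)
        ps <- pe - pr$lengths + 1
        hit <- which(pr$values & ps <= which.max(G[run]) &
                       pe >= which.max(G[run]))[1]
        peak <- run[ps[hit]:pe[hit]]
        out[[length(out) + 1]] <- data.frame(
          direction = scores$direction, chrom = chr,
          wide_start = probes$start[run[1]],
          wide_end = probes$end[run[length(run)]],
          peak_start = probes$start[peak[1]],
          peak_end = probes$end[peak[length(peak)]],
          peak_g = gmax, q_at_peak = min(q[peak]),
          iteration = iter, stringsAsFactors = FALSE)
        claimed[run] <- TRUE
        found <- TRUE
        if (config$peel_off) {
          carriers <- which(colSums(
            contrib[peak, , drop = FALSE]) > 0)
          contrib[rows, carriers] <- 0
        }
      }
    }
    if (!found || !config$peel_off) break
    # recompute p/q with the peeled contributions
    G <- rowSums(contrib)
    p <- pvals_from_pool(G, nullq$null_pool)
    q <- stats::p.adjust(p, "BH")
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample mean segmented log2 ratio over a region
#'
#' @param region List or one-row data frame with \code{chrom} and either
#'   \code{start}/\code{end} or \code{wide_start}/\code{wide_end}.
#' @param X Segmented-value matrix (probes x samples).
#' @param probes Aligned \code{probe_set}.
#' @return Named numeric vector (one value per sample; NA when the region
#'   overlaps no probe with data).
#' @export
region_mean_log2 <- function(region, X, probes) {
  start <- if (!is.null(region[["start"]])) region[["start"]] else
    region[["wide_start"]]
  end <- if (!is.null(region[["end"]])) region[["end"]] else
    region[["wide_end"]]
  rows <- probe_rows_overlap(probes, region[["chrom"]], start, end)
  if (!length(rows)) {
    out <- rep(NA_real_, ncol(X))
    names(out) <- colnames(X)
    return(out)
  }
  v <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

#' Region-covariate association tests
#'
#' Welch two-sample t-test (pooled variance optional) on the per-sample
#' region-average log2 ratios between the two levels of a clinical
#' covariate, with Benjamini-Hochberg adjustment across regions.
#'
#' @param regions Region table from \code{\link{significant_regions}}.
#' @param X Segmented-value matrix (probes x samples).
#' @param probes Aligned \code{probe_set}.
#' @param metadata Data frame with a \code{sample} column matching
#'   \code{colnames(X)}.
#' @param covariate Name of a two-level covariate column.
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @param fdr Significance level on the adjusted p (default 0.05).
#' @return \code{regions} with added columns \code{t}, \code{p},
#'   \code{p_adj}, \code{significant}, \code{note}.
#' @export
region_covariate_association <- function(regions, X, probes, metadata,
                                         covariate, pooled = FALSE,
                                         fdr = 0.05) {
  grp <- metadata[[covariate]][match(colnames(X), metadata$sample)]
  lv <- unique(grp[!is.na(grp)])
  t_stat <- p_val <- rep(NA_real_, nrow(regions))
  note <- rep("", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    v <- region_mean_log2(regions[r, ], X, probes)
    keep <- !is.na(v) & !is.na(grp)
    if (length(lv) != 2 || sum(keep & grp == lv[1]) < 3 ||
        sum(keep & grp == lv[2]) < 3) {
      note[r] <- "degenerate covariate level: skipped"
      next
    }
    a <- v[keep & grp == lv[1]]
    b <- v[keep & grp == lv[2]]
    tt <- tryCatch(stats::t.test(a, b, var.equal = pooled),
                   error = function(e) NULL)
    if (is.null(tt)) {    # essentially constant data
      t_stat[r] <- 0
      p_val[r] <- 1
      note[r] <- "constant region means"
    } else {
      t_stat[r] <- unname(tt$statistic)
      p_val[r] <- tt$p.value
    }
  }
  regions$t <- t_stat
  regions$p <- p_val
  regions$p_adj <- stats::p.adjust(p_val, "BH")
  regions$significant <- !is.na(regions$p_adj) & regions$p_adj < fdr
  regions$note <- note
  regions
}

#' Full GISTIC-style scan for one direction
#'
#' Convenience wrapper: scores, permutation null, q-values and significant
#' regions in one call.
#'
#' @param X Segmented-value matrix.
#' @param thresholds Sample thresholds.
#' @param probes Aligned \code{probe_set}.
#' @param direction \code{"gain"} or \code{"loss"}.
#' @param config A \code{\link{gistic_config}}.
#' @return List: \code{scores}, \code{p}, \code{q}, \code{regions}.
#' @export
gistic_scan <- function(X, thresholds, probes,
                        direction = c("gain", "loss"),
                        config = gistic_config()) {
  direction <- match.arg(direction)
  sc <- gscores(X, thresholds, direction, cap = config$cap)
  nq <- marker_null_and_q(sc, config)
  regions <- significant_regions(sc, nq, probes, config)
  list(scores = sc, p = nq$p, q = nq$q, regions = regions)
}
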