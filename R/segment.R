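#' Segmentation configuration
#'
#' @param alpha Significance level of the permutation split test (default
#'   0.01).
#' @param n_permutations Permutation draws per split test (>= 100, default
#'   1000).
#' @param min_probes_keep Minimum probes per retained segment (default 4);
#'   applied by \code{\link{filter_min_probes}}.
#' @param smooth_window Smoothing window in bp for the sample-adaptive
#'   thresholds (default 250 kb).
#' @return A list of class \code{seg_config}.
#' @export
seg_config <- function(alpha = 0.01, n_permutations = 1000,
                       min_probes_keep = 4, smooth_window = 250000) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100,
            min_probes_keep >= 1, smooth_window > 0)
  structure(list(alpha = alpha, n_permutations = n_permutations,
                 min_probes_keep = min_probes_keep,
                 smooth_window = smooth_window), class = "seg_config")
}

#' Circular binary segmentation of probe-level profiles
#'
#' Per chromosome, recursively finds the circular-arc split maximizing the
#' two-sample t statistic between arc and complement; a split is accepted
#' when its permutation p-value (add-one estimator over random permutations
#' of the probe values within the piece) is below \code{alpha}, and the
#' resulting pieces are segmented recursively. Missing probes are excluded
#' from all statistics and belong to no segment. Deterministic given the R
#' random seed.
#'
#' @param cn Numeric matrix (probes x samples) or a single numeric vector.
#' @param probes The aligned \code{probe_set}.
#' @param config A \code{\link{seg_config}}.
#' @return Segment table: \code{sample}, \code{chrom}, \code{start},
#'   \code{end}, \code{probe_first}, \code{probe_last} (global probe row
#'   indices), \code{n_probes}, \code{seg_mean}.
#' @export
cbs_segment <- function(cn, probes, config = seg_config()) {
  if (is.null(dim(cn))) {
    cn <- matrix(cn, ncol = 1, dimnames = list(probes$probe, "sample_1"))
  }
  stopifnot(nrow(cn) == nrow(probes))
  out <- vector("list", ncol(cn) * length(unique(probes$chrom)))
  k <- 0
  for (s in seq_len(ncol(cn))) {
    for (chr in unique(probes$chrom)) {
      rows <- probe_rows_chrom(probes, chr)
      x <- cn[rows, s]
      ok <- which(!is.na(x))
      if (!length(ok)) {
        warning("sample ", colnames(cn)[s], ", chromosome ", chr,
                ": all probes missing, no segments")
        next
      }
      xv <- x[ok]
      bounds <- if (length(ok) >= 3) {
        cbs_chrom_cpp(xv, config$alpha, as.integer(config$n_permutations))
      } else integer(0)
      cut <- c(0L, bounds, length(ok))
      k <- k + 1
      first <- cut[-length(cut)] + 1
      last <- cut[-1]
      gi_first <- rows[ok[first]]
      gi_last <- rows[ok[last]]
      out[[k]] <- data.frame(
        sample = colnames(cn)[s], chrom = chr,
        start = probes$start[gi_first], end = probes$end[gi_last],
        probe_first = gi_first, probe_last = gi_last,
        n_probes = last - first + 1,
        seg_mean = vapply(seq_along(first), function(i)
          mean(xv[first[i]:last[i]]), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

#' Merge undersized segments into their closest neighbor
#'
#' Segments with fewer than \code{min} probes are merged into the adjacent
#' segment (same sample and chromosome) whose mean is closest; the merged
#' mean is the probe-weighted mean, so it remains the mean over member
#' probes. The segment partition is preserved.
#'
#' @param seg Segment table from \code{\link{cbs_segment}}.
#' @param min Minimum probes per segment (default 4).
#' @return Filtered segment table.
#' @export
filter_min_probes <- function(seg, min = 4) {
  pieces <- split(seg, list(seg$sample, seg$chrom), drop = TRUE)
  merged <- lapply(pieces, function(d) {
    d <- d[order(d$start), ]
    repeat {
      small <- which(d$n_probes < min)
      if (!length(small) || nrow(d) == 1) break
      i <- small[1]
      nb <- c(if (i > 1) i - 1, if (i < nrow(d)) i + 1)
      j <- nb[which.min(abs(d$seg_mean[nb] - d$seg_mean[i]))]
      a <- min(i, j); b <- max(i, j)
      w <- d$n_probes[c(a, b)]
      d$seg_mean[a] <- sum(d$seg_mean[c(a, b)] * w) / sum(w)
      d$n_probes[a] <- sum(w)
      d$end[a] <- d$end[b]
      d$probe_last[a] <- d$probe_last[b]
      d <- d[-b, ]
    }
    d
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$sample, match(out$chrom, unique(seg$chrom)),
                   out$start), ]
  rownames(out) <- NULL
  out
}

#' Windowed smoothing of probe-level values
#'
#' The smoothed value at a probe is the mean of the non-missing values of
#' all probes (itself included) whose centers lie within +/- window/2 of the
#' probe's center on the same chromosome. An isolated probe keeps its own
#' value; a probe with no non-missing neighbor is missing.
#'
#' @param cn Matrix (probes x samples) or vector.
#' @param probes Aligned \code{probe_set}.
#' @param window Window width in bp (default 250 kb).
#' @param stat \code{"mean"} (default) or \code{"median"}.
#' @return Smoothed object of the same shape.
#' @export
smooth_windows <- function(cn, probes, window = 250000,
                           stat = c("mean", "median")) {
  stat <- match.arg(stat)
  vec_in <- is.null(dim(cn))
  if (vec_in) cn <- matrix(cn, ncol = 1)
  out <- cn
  half <- window / 2
  for (chr in unique(probes$chrom)) {
    rows <- probe_rows_chrom(probes, chr)
    centers <- probes$center[rows]
    lo <- findInterval(centers - half - 0.5, centers) + 1
    hi <- findInterval(centers + half + 0.5, centers)
    for (s in seq_len(ncol(cn))) {
      x <- cn[rows, s]
      if (stat == "mean") {
        v <- ifelse(is.na(x), 0, x)
        m <- !is.na(x)
        cv <- c(0, cumsum(v))
        cm <- c(0, cumsum(m))
        cnt <- cm[hi + 1] - cm[lo]
        sm <- (cv[hi + 1] - cv[lo]) / cnt
        sm[cnt == 0] <- NA_real_
      } else {
        sm <- vapply(seq_along(x), function(i) {
          w <- x[lo[i]:hi[i]]
          if (all(is.na(w))) NA_real_ else median(w, na.rm = TRUE)
        }, numeric(1))
      }
      out[rows, s] <- sm
    }
  }
  if (vec_in) out[, 1] else out
}

#' Merge technical replicates by per-probe averaging
#'
#' @param cn Matrix (probes x replicate arrays) sharing one probe set.
#' @param groups Character/factor of length \code{ncol(cn)} mapping each
#'   array to its sample; missing values are ignored probe-wise.
#' @return Matrix probes x unique samples (per-probe mean over replicates).
#' @export
merge_replicates <- function(cn, groups) {
  if (length(groups) != ncol(cn)) {
    stop("groups must map every replicate column to a sample")
  }
  groups <- as.character(groups)
  u <- unique(groups)
  out <- matrix(NA_real_, nrow(cn), length(u),
                dimnames = list(rownames(cn), u))
  for (g in u) {
    out[, g] <- rowMeans(cn[, groups == g, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}
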