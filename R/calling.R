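#' CNA state ladder
#'
#' States form one ordinal ladder \code{loss < normal < gain <
#' amplification < high_amplification}, so an amplification counts as a
#' gain wherever gain frequencies are tallied.
#'
#' @return Named integer codes for the five states.
#' @export
state_levels <- function() {
  c(loss = 0L, normal = 1L, gain = 2L, amplification = 3L,
    high_amplification = 4L)
}

state_code <- function(name) {
  lv <- state_levels()
  if (!name %in% names(lv)) stop("unknown state ", name)
  lv[[name]]
}

#' State calling configuration
#'
#' Fixed amplification thresholds follow the cohort mode: in \code{"her2"}
#' mode high-level amplification is segmented log2 ratio >= 1.0; in
#' \code{"reference"} mode (assembled comparison cohorts) it is strictly
#' > 0.8. Amplification is >= 0.5 in both modes. Gain/loss use symmetric
#' sample-adaptive thresholds (+/- k * robust scale of the smoothed
#' profile).
#'
#' @param amp_threshold Amplification threshold (default 0.5).
#' @param high_amp_threshold High-level threshold; defaults to 1.0
#'   (\code{"her2"} mode) or 0.8 (\code{"reference"} mode).
#' @param adaptive_k Multiplier for the sample-adaptive gain/loss
#'   thresholds (default 2.0).
#' @param mode \code{"her2"} or \code{"reference"} (strict > comparison for
#'   the high-level threshold).
#' @return List of class \code{calling_config}.
#' @export
calling_config <- function(amp_threshold = 0.5, high_amp_threshold = NULL,
                           adaptive_k = 2.0,
                           mode = c("her2", "reference")) {
  mode <- match.arg(mode)
  if (is.null(high_amp_threshold)) {
    high_amp_threshold <- if (mode == "her2") 1.0 else 0.8
  }
  stopifnot(amp_threshold > 0, amp_threshold < high_amp_threshold,
            adaptive_k > 0)
  structure(list(amp_threshold = amp_threshold,
                 high_amp_threshold = high_amp_threshold,
                 adaptive_k = adaptive_k, mode = mode,
                 strict_high = (mode == "reference")),
            class = "calling_config")
}

#' Sample-adaptive gain/loss thresholds
#'
#' Symmetric thresholds +/- k * s per sample, where s is the MAD-based
#' robust scale (1.4826 * median absolute deviation) of the non-missing
#' smoothed log2 ratios. Robust to planted aberrations occupying a minority
#' of the genome.
#'
#' @param smoothed Smoothed matrix (probes x samples) from
#'   \code{\link{smooth_windows}}, or a vector for one sample.
#' @param k Threshold multiplier (default 2).
#' @return Data frame: \code{sample}, \code{gain_thr}, \code{loss_thr}.
#' @export
adaptive_thresholds <- function(smoothed, k = 2.0) {
  if (is.null(dim(smoothed))) {
    smoothed <- matrix(smoothed, ncol = 1,
                       dimnames = list(NULL, "sample_1"))
  }
  res <- lapply(seq_len(ncol(smoothed)), function(s) {
    x <- smoothed[, s]
    x <- x[!is.na(x)]
    if (length(x) < 50) {
      stop("fewer than 50 non-missing smoothed values for sample ",
           colnames(smoothed)[s], ": scale estimate unstable")
    }
    sc <- mad(x)  # 1.4826 * median(|x - median(x)|)
    data.frame(sample = colnames(smoothed)[s], gain_thr = k * sc,
               loss_thr = -k * sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-probe matrix of segment means
#'
#' @param seg Segment table with probe index columns (from
#'   \code{\link{cbs_segment}}).
#' @param probes The \code{probe_set} the segmentation refers to.
#' @param samples Optional sample order for the columns.
#' @return Numeric matrix probes x samples of segment means; NA for probes
#'   outside every segment.
#' @export
seg_means_matrix <- function(seg, probes, samples = NULL) {
  if (is.null(samples)) samples <- unique(seg$sample)
  X <- matrix(NA_real_, nrow(probes), length(samples),
              dimnames = list(probes$probe, samples))
  si <- match(seg$sample, samples)
  for (r in seq_len(nrow(seg))) {
    if (is.na(si[r])) next
    X[seg$probe_first[r]:seg$probe_last[r], si[r]] <- seg$seg_mean[r]
  }
  X
}

#' Call ordinal CNA states from segment means
#'
#' Per probe, from its segment mean m and the sample's thresholds:
#' high-level amplification when m >= high threshold (strictly > in
#' reference mode), else amplification when m >= 0.5, else gain when
#' m > gain threshold, else loss when m < loss threshold, else normal.
#' Raising a segment mean never lowers its state.
#'
#' @param seg Segment table (ideally after \code{\link{filter_min_probes}}).
#' @param probes Aligned \code{probe_set}.
#' @param thresholds Data frame from \code{\link{adaptive_thresholds}}.
#' @param config A \code{\link{calling_config}}.
#' @return Integer matrix (probes x samples) of state codes (see
#'   \code{\link{state_levels}}), with the thresholds stored in attribute
#'   \code{"thresholds"}.
#' @export
call_states <- function(seg, probes, thresholds, config = calling_config()) {
  X <- seg_means_matrix(seg, probes, samples = thresholds$sample)
  if (any(thresholds$gain_thr >= config$amp_threshold)) {
    bad <- thresholds$sample[thresholds$gain_thr >= config$amp_threshold][1]
    stop("degenerate configuration: adaptive gain threshold >= ",
         "amplification threshold for sample ", bad)
  }
  st <- matrix(NA_integer_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (s in seq_len(ncol(X))) {
    m <- X[, s]
    hi <- if (config$strict_high) m > config$high_amp_threshold else
      m >= config$high_amp_threshold
    code <- ifelse(hi, 4L,
             ifelse(m >= config$amp_threshold, 3L,
              ifelse(m > thresholds$gain_thr[s], 2L,
               ifelse(m < thresholds$loss_thr[s], 0L, 1L))))
    st[, s] <- code
  }
  attr(st, "thresholds") <- thresholds
  attr(st, "config") <- config
  st
}

#' Fraction of the genome altered
#'
#' Per sample, the fraction of non-missing probes called gained (state >=
#' gain; amplifications included via the ordinal ladder) and lost (state =
#' loss); the total is their sum.
#'
#' @param states State matrix from \code{\link{call_states}}.
#' @return Data frame: \code{sample}, \code{fga_gain}, \code{fga_loss},
#'   \code{fga_total}.
#' @export
fga <- function(states) {
  gain_code <- state_code("gain")
  res <- lapply(seq_len(ncol(states)), function(s) {
    x <- states[, s]
    x <- x[!is.na(x)]
    g <- if (length(x)) mean(x >= gain_code) else NA_real_
    l <- if (length(x)) mean(x == 0L) else NA_real_
    data.frame(sample = colnames(states)[s], fga_gain = g, fga_loss = l,
               fga_total = g + l, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pericentromeric (CEP17-style) amplification call
#'
#' Selects the three probes closest to the centromere on each arm of the
#' designated chromosome and calls the sample amplified when the mean
#' segmented log2 ratio of either triple reaches the amplification
#' threshold.
#'
#' @param seg Segment table.
#' @param probes Aligned \code{probe_set}.
#' @param assembly The \code{genome_assembly}.
#' @param chrom Chromosome whose centromere is probed.
#' @param config A \code{\link{calling_config}}.
#' @param samples Optional sample order.
#' @return Named logical vector (one element per sample); NA when both arm
#'   triples are entirely missing.
#' @export
cep17_call <- function(seg, probes, assembly, chrom,
                       config = calling_config(), samples = NULL) {
  X <- seg_means_matrix(seg, probes, samples = samples)
  ai <- match(chrom, assembly$chrom)
  if (is.na(ai)) stop("unknown chromosome ", chrom)
  cs <- assembly$cen_start[ai]; ce <- assembly$cen_end[ai]
  rows <- probe_rows_chrom(probes, chrom)
  p_rows <- rows[probes$center[rows] < cs]
  q_rows <- rows[probes$center[rows] > ce]
  if (length(p_rows) < 3 || length(q_rows) < 3) {
    warning("fewer than 3 probes on an arm of ", chrom,
            "; using available probes")
  }
  p_sel <- utils::tail(p_rows, 3)   # probes sorted by start: last = closest
  q_sel <- utils::head(q_rows, 3)
  arm_mean <- function(sel, s) {
    v <- X[sel, s]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out <- vapply(seq_len(ncol(X)), function(s) {
    pm <- arm_mean(p_sel, s); qm <- arm_mean(q_sel, s)
    if (is.na(pm) && is.na(qm)) return(NA)
    any(c(pm, qm) >= config$amp_threshold, na.rm = TRUE)
  }, logical(1))
  names(out) <- colnames(X)
  out
}
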