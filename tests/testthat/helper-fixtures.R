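# Small fixtures and independent oracle implementations used across tests.

tiny_assembly <- function(len = 2e7, cen_frac = 0.4, n_chrom = 1) {
  cs <- round(cen_frac * len)
  genome_assembly(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom),
                  rep(cs, n_chrom), rep(cs + 1e6 - 1, n_chrom))
}

tiny_probes <- function(n = 20, spacing = 1e5, chrom = "chr1") {
  s <- (seq_len(n) - 1) * spacing + 1
  probe_set(sprintf("p%03d", seq_len(n)), chrom, s, s + spacing - 1)
}

# O(n^2) windowed-mean oracle for smooth_windows
oracle_smooth <- function(x, centers, window) {
  half <- window / 2
  vapply(seq_along(x), function(i) {
    w <- x[abs(centers - centers[i]) <= half]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

# Exhaustive best circular-arc split via plain R two-sample t statistics
oracle_max_tsq <- function(x) {
  n <- length(x)
  best <- -1
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    if (i == 0 && j == n) next
    arc <- x[(i + 1):j]
    comp <- x[setdiff(seq_len(n), (i + 1):j)]
    d <- mean(arc) - mean(comp)
    ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
    tsq <- if (ss <= 1e-12) {
      if (d^2 <= 1e-12) 0 else Inf
    } else {
      d^2 * (n - 2) * length(arc) * length(comp) / (ss * n)
    }
    if (tsq > best) best <- tsq
  }
  best
}

# Per-base intersection oracle for the SRO: expand every carrier run to its
# base set, intersect, and return the span.
oracle_sro <- function(states, probes, anchor, min_state = "amplification") {
  mc <- cnascan::state_levels()[[min_state]]
  rows <- which(probes$chrom == anchor$chrom)
  anc <- rows[probes$start[rows] <= anchor$end &
                probes$end[rows] >= anchor$start]
  base_sets <- list()
  for (s in seq_len(ncol(states))) {
    v <- states[rows, s]
    loc <- match(anc, rows)
    if (any(is.na(v[loc])) || any(v[loc] < mc)) next
    lo <- min(loc); hi <- max(loc)
    while (lo > 1 && !is.na(v[lo - 1]) && v[lo - 1] >= mc) lo <- lo - 1
    while (hi < length(v) && !is.na(v[hi + 1]) && v[hi + 1] >= mc)
      hi <- hi + 1
    base_sets[[length(base_sets) + 1]] <-
      seq(probes$start[rows[lo]], probes$end[rows[hi]])
  }
  if (!length(base_sets)) return(NULL)
  inter <- Reduce(intersect, base_sets)
  c(start = min(inter), end = max(inter))
}

# Clause-by-clause firestorm oracle for a single sample/arm state vector.
# Returns TRUE when the arm qualifies under every rule clause.
oracle_firestorm_arm <- function(v, starts, ends, arm_length,
                                 min_peaks = 3, min_peak_probes = 4,
                                 max_gap_frac = 0.5) {
  high <- 4L; amp <- 3L
  runs <- list()
  i <- 1
  n <- length(v)
  while (i <= n) {
    if (!is.na(v[i]) && v[i] == high) {
      j <- i
      while (j < n && !is.na(v[j + 1]) && v[j + 1] == high) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  runs <- Filter(function(r) r[2] - r[1] + 1 >= min_peak_probes, runs)
  if (length(runs) < min_peaks) return(FALSE)
  for (k in seq_len(length(runs) - 1)) {
    between <- (runs[[k]][2] + 1):(runs[[k + 1]][1] - 1)
    if (!any(!is.na(v[between]) & v[between] < amp)) return(FALSE)
  }
  centers <- vapply(runs, function(r)
    floor((starts[r[1]] + ends[r[2]]) / 2), numeric(1))
  max(diff(centers)) < max_gap_frac * arm_length
}

# Brute-force per-marker G-score oracle
oracle_gscores <- function(X, thresholds, direction, cap = 2) {
  M <- nrow(X)
  G <- numeric(M)
  for (m in seq_len(M)) for (s in seq_len(ncol(X))) {
    x <- X[m, s]
    if (is.na(x)) next
    G[m] <- G[m] + if (direction == "gain") {
      max(0, min(x, cap) - thresholds$gain_thr[s])
    } else {
      max(0, thresholds$loss_thr[s] - max(x, -cap))
    }
  }
  G
}

# Build a state matrix directly from integer codes (probes x samples)
make_states <- function(codes, samples = NULL) {
  m <- as.matrix(codes)
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  }
  storage.mode(m) <- "integer"
  m
}
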