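#' Correlate expression of a region's genes with the region's copy number
#'
#' Pearson correlation, per gene located within the region, between the
#' gene's expression and the per-sample region-average segmented log2 ratio
#' across shared samples. Genes with zero expression variance are excluded;
#' genes with fewer than \code{min_samples} paired observations are skipped
#' with a note.
#'
#' @param region List/row with \code{chrom}, \code{start}, \code{end}.
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene table (\code{gene}, \code{chrom}, \code{start},
#'   \code{end}) aligned to \code{expr} rows.
#' @param X Segmented-value matrix (probes x samples).
#' @param probes Aligned \code{probe_set}.
#' @param min_samples Minimum paired samples (default 10).
#' @return Data frame: \code{gene}, \code{r}, \code{n}, \code{note}.
#' @export
region_expression_correlation <- function(region, expr, genes, X, probes,
                                          min_samples = 10) {
  gi <- which(genes$chrom == region[["chrom"]] &
                genes$start <= region[["end"]] &
                genes$end >= region[["start"]])
  rm_log2 <- region_mean_log2(region, X, probes)
  shared <- intersect(colnames(expr), names(rm_log2))
  out <- lapply(gi, function(g) {
    e <- expr[g, shared]
    v <- rm_log2[shared]
    keep <- !is.na(e) & !is.na(v)
    if (sum(keep) < min_samples) {
      return(data.frame(gene = genes$gene[g], r = NA_real_,
                        n = sum(keep), note = "fewer than min_samples",
                        stringsAsFactors = FALSE))
    }
    if (sd(e[keep]) == 0) return(NULL)  # zero-variance gene: excluded
    data.frame(gene = genes$gene[g], r = cor(e[keep], v[keep]),
               n = sum(keep), note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene = character(), r = numeric(), n = integer(),
                      note = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Row-wise Pearson correlation between two matrices with matched rows,
# after column permutation `perm` of the second. Rows must be pre-centered
# and scaled to unit SD (done by .std_rows); returns r per row.
.std_rows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2))
  list(z = ctr / ifelse(s == 0, 1, s), ok = s > 0)
}

#' Permutation-derived correlation cutoff
#'
#' For each permutation the copy-number sample labels are shuffled (one
#' shared permutation per draw, preserving gene-gene structure) and all
#' gene-level Pearson correlations are recomputed; the null correlations
#' are pooled over genes and permutations and the cutoff is the
#' \code{1 - p} empirical quantile of the pool (inverse-ECDF, so
#' \code{p = 1} returns the pool minimum). Deterministic given the R seed.
#'
#' @param expr Expression matrix (genes x samples).
#' @param cn Copy-number matrix matched row-by-row to \code{expr} (each
#'   gene's probe values), or a single vector shared by all genes.
#' @param n_perm Number of permutations (>= 100).
#' @param p Tail probability (default 0.05).
#' @return List: \code{cutoff}, \code{null_pool} (sorted ascending).
#' @export
permutation_cutoff <- function(expr, cn, n_perm = 1000, p = 0.05) {
  stopifnot(n_perm >= 100)
  if (is.null(dim(cn))) {
    cn <- matrix(cn, nrow(expr), length(cn), byrow = TRUE)
  }
  stopifnot(dim(cn) == dim(expr))
  ez <- .std_rows(expr)
  cz <- .std_rows(cn)
  ok <- ez$ok & cz$ok
  E <- ez$z[ok, , drop = FALSE]
  C <- cz$z[ok, , drop = FALSE]
  n_s <- ncol(E)
  pool <- matrix(NA_real_, nrow(E), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_s)
    pool[, b] <- rowSums(E * C[, perm, drop = FALSE])
  }
  pool <- sort(as.vector(pool))
  k <- max(1, ceiling((1 - p) * length(pool)))
  list(cutoff = pool[k], null_pool = pool)
}

#' Genome-wide dosage scan
#'
#' Matches each gene to the probe with the nearest center on its
#' chromosome, keeps genes whose expression SD exceeds \code{sd_min},
#' correlates expression with the matched probe's segmented log2 ratio,
#' derives one-sided (positive-tail) add-one p-values from the pooled
#' permutation null, adjusts by Benjamini-Hochberg, and flags significance
#' at adjusted p below \code{alpha}.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene table aligned to \code{expr} rows (needs \code{gene},
#'   \code{chrom}, \code{start}, \code{end}).
#' @param X Segmented-value matrix (probes x samples).
#' @param probes Aligned \code{probe_set}.
#' @param n_perm Permutations for the pooled null (default 1000).
#' @param sd_min Expression SD filter, exclusive (default 0.5).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param two_sided Use |r| for the null and the observed statistic; the
#'   default is the one-sided positive tail, since dosage effects are
#'   directional.
#' @return Data frame of class \code{dosage_result}: \code{gene},
#'   \code{probe}, \code{r}, \code{p}, \code{p_adj}, \code{significant},
#'   \code{cutoff05}, \code{n}, \code{sd_expr}; skipped genes are absent
#'   and counted in attribute \code{"skipped"}.
#' @export
global_dosage_scan <- function(expr, genes, X, probes, n_perm = 1000,
                               sd_min = 0.5, alpha = 0.05,
                               two_sided = FALSE) {
  shared <- intersect(colnames(expr), colnames(X))
  if (length(shared) < 10) stop("fewer than 10 shared samples")
  expr <- expr[, shared, drop = FALSE]
  probe_row <- match_gene_probes(
    data.frame(chrom = genes$chrom,
               mid = floor((genes$start + genes$end) / 2)), probes)
  skipped <- c(no_probe = sum(is.na(probe_row)))
  keep <- !is.na(probe_row)
  sd_e <- apply(expr, 1, sd)
  skipped["low_sd"] <- sum(keep & sd_e <= sd_min)
  keep <- keep & sd_e > sd_min
  cnm <- X[probe_row[keep], shared, drop = FALSE]
  ok_cn <- rowSums(is.na(cnm)) == 0
  skipped["missing_cn"] <- sum(!ok_cn)
  idx <- which(keep)[ok_cn]
  cnm <- cnm[ok_cn, , drop = FALSE]
  ez <- .std_rows(expr[idx, , drop = FALSE])
  cz <- .std_rows(cnm)
  varless <- !(ez$ok & cz$ok)
  r_obs <- rowSums(ez$z * cz$z)
  r_obs[varless] <- NA_real_
  stat_obs <- if (two_sided) abs(r_obs) else r_obs
  n_s <- length(shared)
  pool <- matrix(NA_real_, length(idx), n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n_s)
    pool[, b] <- rowSums(ez$z * cz$z[, perm, drop = FALSE])
  }
  pool <- pool[!varless, , drop = FALSE]
  if (two_sided) pool <- abs(pool)
  pool <- sort(as.vector(pool))
  pv <- rep(NA_real_, length(idx))
  pv[!varless] <- pvals_from_pool(stat_obs[!varless], pool)
  k05 <- max(1, ceiling(0.95 * length(pool)))
  out <- data.frame(
    gene = genes$gene[idx], probe = probes$probe[probe_row[idx]],
    r = r_obs, p = pv, p_adj = stats::p.adjust(pv, "BH"),
    n = n_s, sd_expr = sd_e[idx], stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$cutoff05 <- pool[k05]
  attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  class(out) <- c("dosage_result", "data.frame")
  out
}
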