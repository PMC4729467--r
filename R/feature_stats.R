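# Single-feature statistics: Pearson/Spearman screening, a paired Wilcoxon
# signed-rank test computed after [0,1] min-max normalization, the
# kcat-versus-1/KM independence check, and alignment-column conservation.

#' Correlate two vectors
#'
#' Product-moment (Pearson) or rank (Spearman, average ranks for ties)
#' correlation. Zero variance in either vector yields a flagged undefined
#' result instead of NaN.
#'
#' @param x,y Equal-length finite numeric vectors (length >= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return List: `estimate`, `method`, `n`, `defined`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(estimate = NA_real_, method = method, n = length(x),
                defined = FALSE))
  }
  list(estimate = cor(x, y, method = method), method = method, n = length(x),
       defined = TRUE)
}

#' Paired Wilcoxon signed-rank test after [0,1] normalization
#'
#' Both vectors are min-max normalized to `[0, 1]`, differenced, zero
#' differences dropped, and the two-sided signed-rank p-value computed: by
#' exact enumeration of all sign patterns for n <= `exact_max` retained
#' pairs, and by the normal approximation with continuity and tie
#' corrections above that.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest n for the exact enumeration (default 12).
#' @return List: `p`, `statistic` (W+, sum of positive ranks), `n` (pairs
#'   retained), `exact`, `all_zero` (TRUE with p = 1 when every difference
#'   vanished).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  }
  d <- norm01(x) - norm01(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(p = 1, statistic = 0, n = 0L, exact = TRUE, all_zero = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.numeric(signs %*% r)
    eps <- 1e-9
    p_le <- mean(sums <= W + eps)
    p_ge <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    list(p = p, statistic = W, n = n, exact = TRUE, all_zero = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-z))
    list(p = p, statistic = W, n = n, exact = FALSE, all_zero = FALSE)
  }
}

#' Screen every feature against a kinetic target
#'
#' For each feature column (and each target channel, if `targets` is a
#' matrix), computes the Pearson and Spearman correlations and the Wilcoxon
#' signed-rank p-value against the per-mutant log-scale constants, using
#' only mutants with a measurable (non-`NA`) target. The report is sorted
#' by absolute Pearson correlation within each channel.
#'
#' @param table A [feature_table()] (or matrix) with mutant rownames.
#' @param targets Named numeric vector, or a matrix/data frame with one
#'   column per channel and mutant rownames; `NA` marks unmeasurable.
#' @return Data frame: `channel`, `feature`, `pcc`, `src`, `wilcoxon_p`, `n`.
#' @export
single_feature_screen <- function(table, targets) {
  X <- unclass(table)
  if (is.null(dim(targets))) {
    targets <- matrix(targets, ncol = 1,
                      dimnames = list(names(targets), "target"))
  }
  targets <- as.matrix(targets)
  out <- list()
  for (ch in colnames(targets)) {
    y <- targets[, ch]
    ids <- intersect(rownames(X), names(y)[!is.na(y)])
    if (length(ids) < 3L) stop("fewer than 3 measurable mutants for ", ch)
    yy <- y[ids]
    rows <- lapply(colnames(X), function(f) {
      xx <- X[ids, f]
      pcc <- correlate(xx, yy, "pearson")
      src <- correlate(xx, yy, "spearman")
      wp <- wilcoxon_signed_rank(xx, yy)
      data.frame(channel = ch, feature = f, pcc = pcc$estimate,
                 src = src$estimate, wilcoxon_p = wp$p, n = length(ids),
                 stringsAsFactors = FALSE)
    })
    rep <- do.call(rbind, rows)
    out[[ch]] <- rep[order(-abs(rep$pcc)), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Independence of kcat and 1/KM across mutants
#'
#' Correlation of log10 kcat against log10(1/KM) over mutants where both are
#' measurable; a weak correlation supports treating the two constants as
#' independent targets.
#'
#' @param fits List of [fit_kinetics()] results.
#' @param method Correlation method.
#' @return [correlate()] result.
#' @export
independence_check <- function(fits, method = "pearson") {
  ok <- vapply(fits, function(f) {
    f$fit_kind %in% c("MM", "MM_substrate_inhibition")
  }, logical(1))
  if (sum(ok) < 3L) stop("need >= 3 mutants with measurable kcat and KM")
  kc <- vapply(fits[ok], function(f) f$kcat, numeric(1))
  km <- vapply(fits[ok], function(f) f$KM, numeric(1))
  correlate(log10(kc), log10(1 / km), method)
}

#' Per-column conservation of an alignment
#'
#' For each non-gap position of the reference sequence, the percentage of
#' all aligned sequences (reference included) carrying the same residue;
#' gaps in other sequences count as mismatches. Positions are renumbered to
#' reference coordinates.
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   or a path to an aligned FASTA file (read with Biostrings).
#' @param reference Identifier of the reference sequence.
#' @return Data frame of class `conservation_profile`: `position` (1-based
#'   in the reference), `residue`, `percent`, `n_sequences`.
#' @export
column_conservation <- function(alignment, reference) {
  if (length(alignment) == 1L && file.exists(alignment)) {
    aln <- Biostrings::readAAStringSet(alignment)
    alignment <- stats::setNames(as.character(aln), names(aln))
  }
  if (!reference %in% names(alignment)) {
    stop("reference sequence '", reference, "' not in alignment")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned (unequal lengths)")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ref <- mat[match(reference, names(alignment)), ]
  keep <- !(ref %in% c("-", "."))
  cols <- which(keep)
  percent <- vapply(cols, function(j) {
    100 * sum(mat[, j] == ref[j]) / nrow(mat)
  }, numeric(1))
  out <- data.frame(position = seq_along(cols), residue = ref[cols],
                    percent = percent, n_sequences = nrow(mat),
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Write the screening report CSV
#'
#' @param report Result of [single_feature_screen()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
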