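# Feature screening and linear classification of risk vs neutral SNPs
# from histone-modification levels, with a 10-portion 70/30 split and
# ROC/AUC evaluation.

#' Histone-modification levels per SNP
#'
#' For every tag set (one per HM type), estimates the cross-strand shift
#' from point-mode strand profiles around the SNPs, moves the 5' tag ends
#' oppositely by that shift, counts the shifted ends in the `window`-bp
#' region `[pos - window/2, pos + window/2)` around each SNP, and divides
#' by the genome-average point coverage `n_tags / genome_length`.
#'
#' @param tagsets named list of `TagSet`s, one per HM type.
#' @param snps a `snp_table` (or data.frame with `chrom`, `pos`); its
#'   `risk_label` column, when present, provides the labels.
#' @param window window width in bp (default 200).
#' @param genome_length total genome length (normalisation denominator).
#' @param max_shift cap on the strand shift (default 100).
#' @param shift_window half-window used for shift estimation (default 500).
#' @param chrom_lengths optional named chromosome lengths.
#' @return numeric matrix (SNPs x HM types) of class `feature_matrix`,
#'   with the label vector in `attr(, "labels")` when available.
#' @export
hm_levels <- function(tagsets, snps, window = 200L, genome_length,
                      max_shift = 100L, shift_window = 500L,
                      chrom_lengths = NULL) {
  if (genome_length <= 0) stop("genome_length must be positive")
  sites <- .as_sites(snps)
  half <- window %/% 2L
  mats <- lapply(tagsets, function(tags) {
    iv <- tags$intervals
    n_tags <- nrow(iv)
    cvg <- n_tags / genome_length
    s <- 0L
    if (n_tags > 0) {
      pair <- tryCatch(
        strand_count_profiles(tags, sites, W = shift_window,
                              count = "point", chrom_lengths = chrom_lengths),
        error = function(e) NULL)
      if (!is.null(pair)) {
        s <- suppressWarnings(estimate_shift(pair, max_shift)$shift)
      }
    }
    fp <- .five_prime(iv)
    shifted <- ifelse(iv$strand == "-", fp - s, fp + s)
    counts <- numeric(nrow(sites))
    for (chr in unique(sites$chrom)) {
      sp <- sort(shifted[iv$chrom == chr])
      sel <- which(sites$chrom == chr)
      p <- sites$pos[sel]
      counts[sel] <- findInterval(p + half - 1L, sp) -
        findInterval(p - half - 1L, sp)
    }
    if (cvg > 0) counts / cvg else counts
  })
  x <- do.call(cbind, mats)
  colnames(x) <- names(tagsets) %||% paste0("HM", seq_along(tagsets))
  class(x) <- c("feature_matrix", class(x))
  if ("risk_label" %in% names(snps)) attr(x, "labels") <- snps$risk_label
  x
}

#' Collapse risk labels to risk / neutral / other
#'
#' Maps the four-level `risk_label` (`risk_coding`, `risk_noncoding`,
#' `neutral`, `other`) to the two-class vocabulary used by the
#' discriminator.
#'
#' @param risk_label character vector of catalog labels.
#' @return character vector with entries `"risk"`, `"neutral"`, `"other"`.
#' @export
collapse_risk_labels <- function(risk_label) {
  out <- rep("other", length(risk_label))
  out[risk_label %in% c("risk_coding", "risk_noncoding")] <- "risk"
  out[risk_label == "neutral"] <- "neutral"
  out
}

#' Per-HM differential test between risk and neutral SNPs
#'
#' Welch two-sample t-test of each feature column between the two label
#' groups; two-sided p, ranked by p, with a Bonferroni column.
#'
#' @param x feature matrix (SNPs x HM types).
#' @param labels vector with entries `"risk"`/`"neutral"` (any other
#'   labelling with exactly two groups also works; the first group in
#'   `groups` is the "risk" side of the t statistic).
#' @param groups the two group labels to compare.
#' @return data.frame with columns `hm`, `t`, `p`, `p_bonferroni`,
#'   ordered by increasing p.
#' @export
differential_hm_test <- function(x, labels = attr(x, "labels"),
                                 groups = c("risk", "neutral")) {
  stopifnot(!is.null(labels), nrow(x) == length(labels))
  a <- x[labels == groups[1L], , drop = FALSE]
  b <- x[labels == groups[2L], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 observations per group")
  res <- lapply(seq_len(ncol(x)), function(j) {
    tt <- t.test(a[, j], b[, j])
    data.frame(hm = colnames(x)[j], t = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * ncol(x))
  out[order(out$p), , drop = FALSE]
}

#' Random 10-portion split into 70% train / 30% test
#'
#' Rows are shuffled with the given seed and partitioned into ten
#' near-equal portions (sizes differing by at most one); portions 1-7
#' form the training set and portions 8-10 the test set. Reproducible per
#' seed.
#'
#' @param n number of rows (or a matrix/data.frame whose rows are split).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test` and the
#'   per-row `portion` assignment (in shuffled order).
#' @export
split_ten_portions <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L) n <- nrow(n)
  n <- as.integer(n)
  stopifnot(n >= 10L)
  perm <- .with_seed(seed, sample.int(n))
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  portion <- rep(seq_len(10L), times = sizes)
  list(train = sort(perm[portion <= 7L]), test = sort(perm[portion > 7L]),
       portion = portion[order(perm)])
}

#' Fit a linear classifier with the constant term fixed at 1
#'
#' Least-squares fit of 0/1 labels (risk = 1, neutral = 0) on the
#' mean-centred features with the constant term of the score forced to 1:
#' the slope vector `w` minimises
#' `sum((label - 1 - w . (x - xbar))^2)` over the training rows, and the
#' score of an example is `1 + w . (x - xbar)`. Centring matters: with a
#' frozen constant and raw (non-negative) features the least-squares
#' solution is dominated by reproducing the overall label mean through
#' `w . x`, which anti-orients the discriminative direction; on centred
#' features `w` is the usual covariance direction, so a feature that
#' separates the classes yields risk-ranked scores. Because ROC analysis
#' is invariant under strictly increasing score transforms, the frozen
#' constant itself cannot change the AUC.
#'
#' A singular design yields the minimum-norm solution with a warning.
#'
#' @param x numeric feature matrix (examples x features).
#' @param y labels: logical/0-1 vector, or characters matched against
#'   `positive`.
#' @param positive label counted as the positive (risk) class when `y`
#'   is not numeric.
#' @return list of class `linear_classifier` with `slopes`, `center`
#'   (training feature means) and `intercept` (always 1).
#' @export
fit_linear_classifier <- function(x, y, positive = "risk") {
  x <- as.matrix(x)
  y01 <- if (is.numeric(y)) as.numeric(y)
         else as.numeric(y == positive)
  stopifnot(nrow(x) == length(y01))
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  target <- y01 - 1
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < ncol(xc)) {
    warning("singular design matrix; returning the minimum-norm solution")
  }
  w <- if (r == 0L) rep(0, ncol(xc)) else {
    u <- sv$u[, seq_len(r), drop = FALSE]
    v <- sv$v[, seq_len(r), drop = FALSE]
    drop(v %*% (crossprod(u, target) / sv$d[seq_len(r)]))
  }
  structure(list(slopes = setNames(as.numeric(w), colnames(x)),
                 center = center, intercept = 1),
            class = "linear_classifier")
}

#' Score examples with a fitted linear classifier
#'
#' @param object a `linear_classifier`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric vector of scores `1 + w . (x - center)`.
#' @export
predict.linear_classifier <- function(object, newdata, ...) {
  xc <- sweep(as.matrix(newdata), 2L, object$center)
  drop(xc %*% object$slopes) + object$intercept
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; examples tied at a threshold
#' contribute a diagonal ROC segment, so the trapezoid AUC equals the
#' Mann-Whitney statistic (ties counted one half) exactly.
#'
#' @param scores numeric scores (higher = more risk-like).
#' @param labels logical/0-1 vector or characters matched against
#'   `positive`.
#' @param positive positive-class label.
#' @return list of class `roc_result` with `roc` (data.frame `fpr`,
#'   `tpr`, `threshold`, a monotone staircase from (0,0) to (1,1)) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "risk") {
  pos <- if (is.logical(labels)) labels
         else if (is.numeric(labels)) labels > 0
         else labels == positive
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0 || N == 0) stop("need at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- pos[o]
  n <- length(s)
  last <- c(s[-n] != s[-1L], TRUE)  # last index within each tie group
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  fpr <- c(0, fp / N)
  tpr <- c(0, tp / P)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(roc = data.frame(fpr = fpr, tpr = tpr,
                                  threshold = c(Inf, s[last])),
                 auc = auc),
            class = "roc_result")
}

#' Train/test a risk-vs-neutral classifier
#'
#' Convenience wrapper implementing the full evaluation: 10-portion 70/30
#' split, least-squares linear classifier (intercept fixed at 1) on the
#' training portion, scoring of the test portion and ROC/AUC.
#'
#' @param x feature matrix (examples x features).
#' @param labels label vector (`"risk"` / `"neutral"` or logical/0-1).
#' @param seed split seed.
#' @param positive positive-class label.
#' @return list of class `ClassifierResult` with `slopes`, `intercept`,
#'   `scores` (test-set scores), `test_labels`, `roc`, `auc`,
#'   `split_seed`.
#' @export
risk_classifier <- function(x, labels = attr(x, "labels"), seed = 1L,
                            positive = "risk") {
  x <- unclass(as.matrix(x))
  stopifnot(!is.null(labels), nrow(x) == length(labels))
  sp <- split_ten_portions(nrow(x), seed)
  fit <- fit_linear_classifier(x[sp$train, , drop = FALSE],
                               labels[sp$train], positive = positive)
  scores <- predict(fit, x[sp$test, , drop = FALSE])
  rr <- roc_auc(scores, labels[sp$test], positive = positive)
  structure(list(slopes = fit$slopes, intercept = fit$intercept,
                 scores = scores, test_labels = labels[sp$test],
                 roc = rr$roc, auc = rr$auc, split_seed = seed),
            class = "ClassifierResult")
}

#' @export
print.ClassifierResult <- function(x, ...) {
  cat("ClassifierResult: AUC =", round(x$auc, 4), "on",
      length(x$scores), "test examples (split seed", x$split_seed, ")\n")
  invisible(x)
}
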