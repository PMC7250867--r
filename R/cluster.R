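#' Confidence contrast of temporal-generalization matrices
#'
#' Cellwise main-effect-of-confidence contrast, averaging over change and no
#' change of mind:
#' `(high_no - low_no) + (high_change - low_change)`.
#'
#' @param tg A `tg_matrix` (one subject) or a list of them (one per subject).
#' @return A matrix, or list of matrices, of contrast values.
#' @export
confidence_contrast <- function(tg) {
  one <- function(x) {
    if (inherits(x, "tg_matrix")) x <- list(
      high_no = x$auc[, , "high_no"], low_no = x$auc[, , "low_no"],
      high_change = x$auc[, , "high_change"], low_change = x$auc[, , "low_change"])
    need <- c("high_no", "low_no", "high_change", "low_change")
    miss <- setdiff(need, names(x))
    if (length(miss)) abort(paste0("missing condition cell(s): ",
                                   paste(miss, collapse = ", ")))
    (x$high_no - x$low_no) + (x$high_change - x$low_change)
  }
  if (inherits(tg, "tg_matrix") ||
      (is.list(tg) && !is.null(names(tg)) && "high_no" %in% names(tg))) {
    one(tg)
  } else {
    lapply(tg, one)
  }
}

#' Cluster-based sign-flip permutation test
#'
#' One-sample test of per-subject contrast matrices against zero with
#' cluster-level correction for multiple comparisons: cells whose one-sample
#' t exceeds the cluster-forming threshold (two-tailed p < `cluster_alpha`)
#' are grouped into clusters of adjacent cells (4-connectivity), each
#' cluster's mass is the sum of its t values, and the null distribution of
#' the maximum cluster mass is built by randomly flipping the sign of each
#' subject's contrast (positive and negative clusters handled separately).
#'
#' Positive and negative clusters are formed separately. With
#' `null = "combined"` (the default) each cluster's corrected p value compares
#' its absolute mass against the permutation maximum of the absolute cluster
#' mass over both signs, which controls the family-wise error of the whole
#' (two-sided) map at the nominal level. `null = "per_sign"` instead compares
#' each sign's clusters against that sign's own 5% permutation quantile — a
#' directed test per sign, at the cost of a doubled map-wise error rate when
#' both directions are interrogated.
#'
#' @param contrasts List of per-subject matrices (equal dimensions), or a 3-D
#'   array subjects x rows x cols.
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param cluster_alpha Two-tailed cluster-forming threshold (default 0.05).
#' @param null `"combined"` or `"per_sign"` (see Details).
#' @param seed Integer seed.
#' @return An object of class `cluster_test`: a `clusters` tibble (`id`,
#'   `sign`, `n_cells`, `mass`, `p.value`), the cellwise `t` matrix, integer
#'   label matrices `labels_pos`/`labels_neg`, and the permutation null
#'   maxima.
#' @export
cluster_permutation <- function(contrasts, n_perm = 1000,
                                cluster_alpha = 0.05,
                                null = c("combined", "per_sign"), seed = 1L) {
  null <- match.arg(null)
  if (is.list(contrasts)) {
    dims <- dim(contrasts[[1]])
    X <- aperm(simplify2array(contrasts), c(3, 1, 2))
  } else {
    stopifnot(is.array(contrasts), length(dim(contrasts)) == 3)
    X <- contrasts
    dims <- dim(X)[2:3]
  }
  S <- dim(X)[1]
  if (S < 5) abort("at least 5 subjects are required")
  nr <- dims[1]; nc <- dims[2]
  Xm <- matrix(X, S, nr * nc)          # subjects x cells
  ss <- colSums(Xm^2)                  # invariant under sign flips
  tcrit <- qt(1 - cluster_alpha / 2, S - 1)

  cell_t <- function(mean_vec) {
    v <- (ss - S * mean_vec^2) / (S - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    mean_vec / sqrt(v / S)
  }
  tobs <- cell_t(colMeans(Xm))
  tmat <- matrix(tobs, nr, nc)

  find_clusters <- function(tm) {
    lab_pos <- .label_components_cpp(tm > tcrit)
    lab_neg <- .label_components_cpp(tm < -tcrit)
    mass_pos <- if (max(lab_pos) > 0)
      vapply(seq_len(max(lab_pos)), function(k) sum(tm[lab_pos == k]), 1) else numeric(0)
    mass_neg <- if (max(lab_neg) > 0)
      vapply(seq_len(max(lab_neg)), function(k) sum(tm[lab_neg == k]), 1) else numeric(0)
    list(lab_pos = lab_pos, lab_neg = lab_neg,
         mass_pos = mass_pos, mass_neg = mass_neg)
  }
  obs <- find_clusters(tmat)

  set.seed(seed)
  null_pos <- numeric(n_perm); null_neg <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), S, replace = TRUE)
    tm <- matrix(cell_t(colMeans(Xm * flips)), nr, nc)
    cl <- find_clusters(tm)
    null_pos[p] <- if (length(cl$mass_pos)) max(cl$mass_pos) else 0
    null_neg[p] <- if (length(cl$mass_neg)) min(cl$mass_neg) else 0
  }

  null_abs <- pmax(null_pos, -null_neg)
  rows <- list()
  for (k in seq_along(obs$mass_pos)) {
    p <- if (null == "combined") {
      (1 + sum(null_abs >= obs$mass_pos[k])) / (n_perm + 1)
    } else {
      (1 + sum(null_pos >= obs$mass_pos[k])) / (n_perm + 1)
    }
    rows[[length(rows) + 1]] <- tibble(
      id = length(rows) + 1L, sign = "positive",
      n_cells = sum(obs$lab_pos == k), mass = obs$mass_pos[k], p.value = p)
  }
  for (k in seq_along(obs$mass_neg)) {
    p <- if (null == "combined") {
      (1 + sum(null_abs >= -obs$mass_neg[k])) / (n_perm + 1)
    } else {
      (1 + sum(null_neg <= obs$mass_neg[k])) / (n_perm + 1)
    }
    rows[[length(rows) + 1]] <- tibble(
      id = length(rows) + 1L, sign = "negative",
      n_cells = sum(obs$lab_neg == k), mass = obs$mass_neg[k], p.value = p)
  }
  clusters <- if (length(rows)) bind_rows(rows) else
    tibble(id = integer(), sign = character(), n_cells = integer(),
           mass = numeric(), p.value = numeric())
  structure(list(clusters = clusters, t = tmat,
                 labels_pos = obs$lab_pos, labels_neg = obs$lab_neg,
                 null_max_pos = null_pos, null_min_neg = null_neg,
                 null_max_abs = null_abs, null = null,
                 n_perm = n_perm, cluster_alpha = cluster_alpha,
                 n_subjects = S),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d subjects, %d permutations, threshold p < %g\n",
              x$n_subjects, x$n_perm, x$cluster_alpha))
  if (nrow(x$clusters) == 0) cat("  no supra-threshold clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' @export
autoplot.cluster_test <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$t)),
                           col = seq_len(ncol(object$t)))
  df$t <- as.vector(t(object$t))
  sig_ids <- object$clusters$id[object$clusters$p.value < 0.05]
  lab <- matrix(0L, nrow(object$t), ncol(object$t))
  k <- 0L
  for (i in seq_len(max(object$labels_pos))) {
    k <- k + 1L; if (k %in% sig_ids) lab[object$labels_pos == i] <- 1L
  }
  for (i in seq_len(max(object$labels_neg))) {
    k <- k + 1L; if (k %in% sig_ids) lab[object$labels_neg == i] <- 1L
  }
  df$significant <- as.vector(t(lab)) == 1L
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$t)) +
    geom_tile() +
    geom_point(data = df[df$significant, ], size = 0.4) +
    scale_fill_gradient2(low = "navy", high = "firebrick") +
    labs(x = "test timepoint", y = "train timepoint", fill = "t",
         title = "Confidence contrast with significant clusters dotted") +
    theme_minimal()
}
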