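metabolite_cols <- function(table, cols = NULL) {
  if (!is.null(cols)) return(intersect(cols, names(table)))
  grep("^m[0-9]+$", names(table), value = TRUE)
}

#' Fit a two-component PCA chemotype model on a peak table
#'
#' Columns are mean-centred and scaled to unit variance (autoscaling, the
#' convention of SIMCA-style chemometrics) before extracting the leading
#' principal components. Zero-variance metabolites are dropped with a
#' warning. An optional `log10(area + 1)` transform is available for
#' strongly heteroscedastic panels.
#'
#' @param table Peak table: one row per (line, replicate), metabolite
#'   columns named `m01`, `m02`, ... with non-negative areas; any other
#'   columns (`line_id`, `replicate`, `class`) are carried into the scores.
#' @param k Number of components (default 2).
#' @param log_transform Apply `log10(x + 1)` before scaling.
#' @param cols Optional explicit metabolite column names.
#' @return An object of class `chemotype_pca`: list with `fit` (the
#'   underlying [stats::prcomp]), `scores` (tibble of id columns + `PC1..k`),
#'   `loadings`, `explained` (variance fractions), `dropped` (zero-variance
#'   columns), `k`, `log_transform`.
#' @export
fit_pca <- function(table, k = 2L, log_transform = FALSE, cols = NULL) {
  mcols <- metabolite_cols(table, cols)
  if (length(mcols) < 2L) stop("need at least 2 metabolite columns")
  if (nrow(table) < k + 1L) stop("need at least k + 1 rows to fit ", k, " components")
  x <- as.matrix(table[, mcols])
  if (any(x < 0, na.rm = TRUE)) stop("peak areas must be non-negative")
  if (log_transform) x <- log10(x + 1)
  v <- apply(x, 2L, stats::var)
  dropped <- mcols[v == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance metabolite(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < k) stop("fewer than k metabolites with nonzero variance")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(k, ncol(fit$x))
  scores <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE])
  id_cols <- setdiff(names(table), mcols)
  scores <- dplyr::bind_cols(table[, id_cols, drop = FALSE], scores)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(fit = fit, scores = scores,
         loadings = tibble::as_tibble(fit$rotation[, seq_len(k), drop = FALSE]) |>
           dplyr::mutate(metabolite = rownames(fit$rotation), .before = 1L),
         explained = explained[seq_len(k)], dropped = dropped, k = k,
         log_transform = log_transform),
    class = "chemotype_pca"
  )
}

#' @export
print.chemotype_pca <- function(x, ...) {
  cat("Chemotype PCA (", x$k, " components, ", nrow(x$scores), " observations)\n",
      sep = "")
  cat("Explained variance:",
      paste0(sprintf("PC%d %.1f%%", seq_len(x$k), 100 * x$explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project new observations into a fitted chemotype PCA
#'
#' @param object A `chemotype_pca`.
#' @param newdata Peak table with the metabolites the model was fitted on.
#' @param ... Unused.
#' @return Tibble of id columns + PC scores.
#' @export
predict.chemotype_pca <- function(object, newdata, ...) {
  mcols <- rownames(object$fit$rotation)
  x <- as.matrix(newdata[, mcols])
  if (object$log_transform) x <- log10(x + 1)
  sc <- stats::predict(object$fit, x)[, seq_len(object$k), drop = FALSE]
  id_cols <- setdiff(names(newdata), metabolite_cols(newdata))
  dplyr::bind_cols(newdata[, id_cols, drop = FALSE], tibble::as_tibble(sc))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a chemotype PCA
#'
#' @param x A `chemotype_pca`.
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy chemotype_pca
#' @export
tidy.chemotype_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") x$scores else x$loadings
}

#' One-row model summary of a chemotype PCA
#'
#' @param x A `chemotype_pca`.
#' @param ... Unused.
#' @method glance chemotype_pca
#' @export
glance.chemotype_pca <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$scores), k = x$k,
    var_explained = sum(x$explained),
    n_metabolites = nrow(x$fit$rotation),
    n_dropped = length(x$dropped)
  )
}

#' Score plot of a chemotype PCA
#'
#' @param object A `chemotype_pca`.
#' @param colour Column of the scores to colour by (default `"class"` when
#'   present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chemotype_pca
#' @export
autoplot.chemotype_pca <- function(object, colour = NULL, ...) {
  sc <- object$scores
  if (is.null(colour)) colour <- if ("class" %in% names(sc)) "class" else NULL
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data[[colour]])
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2L])
    ) +
    ggplot2::theme_minimal()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Assign query lines to reference chemotype classes in PC space
#'
#' Each query observation is assigned the nearest reference-class centroid
#' by Euclidean distance in score space. A query further from every
#' centroid than `threshold_factor` times the median within-reference
#' replicate-to-centroid distance is declared `"novel"` — mutants whose
#' metabolite profile matches none of the characterised loci.
#'
#' @param scores Tibble of query scores with `PC..` columns and a `line_id`.
#' @param references Tibble of reference scores with a `class` column and
#'   the same `PC..` columns (at least 2 replicates per class).
#' @param threshold_factor Novelty multiplier (default 3).
#' @return Tibble: `line_id`, `assigned` (class label or `"novel"`),
#'   `distance` (to the nearest centroid; `Inf` with no references), and the
#'   PC scores.
#' @export
assign_chemotype <- function(scores, references, threshold_factor = 3) {
  pcs <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  stopifnot(length(pcs) >= 1L)
  if (is.null(references) || nrow(references) == 0L) {
    out <- scores
    out$assigned <- "novel"
    out$distance <- Inf
    return(dplyr::relocate(out, "line_id", "assigned", "distance"))
  }
  stopifnot(all(pcs %in% names(references)), "class" %in% names(references))
  counts <- table(references$class)
  if (any(counts < 2L)) {
    stop("reference class(es) with < 2 replicates: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  cent <- references |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(pcs), mean), .groups = "drop") |>
    dplyr::arrange(.data$class)
  cmat <- as.matrix(cent[, pcs])
  # spread of replicates about their own centroid sets the novelty scale
  within <- sqrt(rowSums((as.matrix(references[, pcs]) -
                            cmat[match(references$class, cent$class), , drop = FALSE])^2))
  threshold <- threshold_factor * stats::median(within)
  qmat <- as.matrix(scores[, pcs])
  d <- sqrt(outer(rowSums(qmat^2), rowSums(cmat^2), "+") - 2 * qmat %*% t(cmat))
  d[d < 0 | is.na(d)] <- 0
  nearest <- apply(d, 1L, which.min)  # ties: first = lexicographically smallest class
  dist_min <- d[cbind(seq_len(nrow(d)), nearest)]
  out <- scores
  out$assigned <- ifelse(dist_min > threshold, "novel", cent$class[nearest])
  out$distance <- dist_min
  dplyr::relocate(out, "line_id", "assigned", "distance")
}

#' Rank marker metabolites separating two groups
#'
#' Features are ranked by the absolute Welch (unequal-variance) t statistic,
#' with ties broken by absolute log2 fold change. This is the statistic used
#' for marker *selection*; per-metabolite hypothesis tests against a control
#' group use [compare_groups()] (classical Student's t) instead.
#'
#' @param table Peak table with a grouping column.
#' @param group_a,group_b Group labels to contrast (b vs a).
#' @param top_n Number of top markers to return (default 240). If larger
#'   than the number of features, all are returned with a warning.
#' @param group_col Name of the grouping column (default `"class"`).
#' @param cols Optional explicit metabolite columns.
#' @return Tibble: `metabolite`, `t` (Welch), `log2_fc`
#'   (`log2(mean_b / mean_a)`), `p`, `rank`; `top_n` rows, best first.
#' @export
rank_markers <- function(table, group_a, group_b, top_n = 240L,
                         group_col = "class", cols = NULL) {
  mcols <- metabolite_cols(table, cols)
  a <- table[table[[group_col]] == group_a, mcols, drop = FALSE]
  b <- table[table[[group_col]] == group_b, mcols, drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) stop("need >= 2 replicates per group")
  stats_tb <- purrr::map_dfr(mcols, function(m) {
    xa <- a[[m]]; xb <- b[[m]]
    tt <- tryCatch(stats::t.test(xb, xa, var.equal = FALSE),
                   error = function(e) NULL)  # constant data
    tibble::tibble(
      metabolite = m,
      t = if (is.null(tt)) 0 else unname(tt$statistic),
      log2_fc = log2(mean(xb) / mean(xa)),
      p = if (is.null(tt)) 1 else tt$p.value
    )
  })
  ord <- order(-abs(stats_tb$t), -abs(stats_tb$log2_fc), stats_tb$metabolite)
  stats_tb <- stats_tb[ord, ]
  stats_tb$rank <- seq_len(nrow(stats_tb))
  if (top_n > nrow(stats_tb)) {
    warning("top_n (", top_n, ") exceeds feature count (", nrow(stats_tb),
            "); returning all features", call. = FALSE)
    top_n <- nrow(stats_tb)
  }
  stats_tb[seq_len(top_n), ]
}

#' Compare one metabolite between two groups (Student's t test)
#'
#' Two-sided equal-variance Student's t test on raw peak areas, the test
#' reported alongside group bar plots in targeted-metabolomics figures.
#'
#' @param table Peak table with a grouping column.
#' @param metabolite Metabolite column name.
#' @param group_a,group_b Group labels; fold change is `mean_b / mean_a`.
#' @param group_col Grouping column (default `"class"`).
#' @return One-row tibble: `metabolite`, `fold_change`, `t`, `df`, `p`,
#'   `mean_a`, `mean_b`.
#' @export
compare_groups <- function(table, metabolite, group_a, group_b,
                           group_col = "class") {
  xa <- table[[metabolite]][table[[group_col]] == group_a]
  xb <- table[[metabolite]][table[[group_col]] == group_b]
  if (length(xa) < 2L || length(xb) < 2L) stop("need >= 2 replicates per group")
  tt <- tryCatch(stats::t.test(xa, xb, var.equal = TRUE),
                 error = function(e) NULL)  # both groups constant
  if (is.null(tt)) {
    t_stat <- if (mean(xa) == mean(xb)) 0 else Inf
    p <- if (mean(xa) == mean(xb)) 1 else 0
    df <- length(xa) + length(xb) - 2L
  } else {
    t_stat <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
  }
  tibble::tibble(
    metabolite = metabolite, fold_change = mean(xb) / mean(xa),
    t = t_stat, df = df, p = p, mean_a = mean(xa), mean_b = mean(xb)
  )
}

#' Chi-square goodness-of-fit test for a Mendelian segregation ratio
#'
#' Pearson chi-square test of observed genotype-class counts against an
#' expected ratio (default 1:2:1, the F2 expectation for a single
#' codominant locus).
#'
#' @param counts Non-negative integer counts (e.g. hom WT, het, hom
#'   mutant), total > 0.
#' @param ratio Expected ratio, same length as `counts` (default
#'   `c(1, 2, 1)`).
#' @return One-row tibble of class `segregation_result`: `statistic`, `df`,
#'   `p_value`, plus `observed` and `expected` list-columns.
#' @examples
#' segregation_test(c(48, 96, 48))
#' @export
segregation_test <- function(counts, ratio = c(1, 2, 1)) {
  if (length(counts) != length(ratio)) {
    stop("counts (", length(counts), ") and ratio (", length(ratio),
         ") must have the same number of classes")
  }
  stopifnot(all(counts >= 0), sum(counts) > 0, all(ratio > 0))
  ht <- suppressWarnings(stats::chisq.test(x = counts, p = ratio / sum(ratio)))
  out <- tibble::tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    observed = list(as.numeric(counts)), expected = list(unname(ht$expected))
  )
  class(out) <- c("segregation_result", class(out))
  out
}

#' @method glance segregation_result
#' @export
glance.segregation_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = sum(x$observed[[1L]]))
}
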