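#' Molecular-networking parameters
#'
#' Defaults are the classical GNPS molecular-networking settings used for
#' triterpene-glycoside work: parent mass tolerance 1 Da, fragment ion
#' tolerance 0.5 Da, minimum pair cosine 0.6, minimum matched peaks 3,
#' minimum cluster size 2, minimum peak intensity 25 (an absolute raw
#' intensity floor; instrument dependent).
#'
#' @param parent_mass_tol,fragment_tol Mass tolerances in Da.
#' @param min_cosine Minimum modified cosine for an edge, in `[0, 1]`.
#' @param min_matched_peaks Minimum number of matched peak pairs per edge.
#' @param min_cluster_size Connected components smaller than this are
#'   dropped from the network.
#' @param min_peak_intensity Raw-intensity floor applied before scoring.
#' @param sqrt_transform Square-root the intensities before L2
#'   normalisation (standard GNPS practice; disable to score on raw
#'   relative intensities).
#' @return A `network_params` list.
#' @export
network_params <- function(parent_mass_tol = 1.0, fragment_tol = 0.5,
                           min_cosine = 0.6, min_matched_peaks = 3L,
                           min_cluster_size = 2L, min_peak_intensity = 25,
                           sqrt_transform = TRUE) {
  stopifnot(parent_mass_tol > 0, fragment_tol > 0,
            min_cosine >= 0, min_cosine <= 1,
            min_matched_peaks >= 1, min_cluster_size >= 1,
            min_peak_intensity >= 0)
  structure(list(parent_mass_tol = parent_mass_tol, fragment_tol = fragment_tol,
                 min_cosine = min_cosine,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 min_cluster_size = as.integer(min_cluster_size),
                 min_peak_intensity = min_peak_intensity,
                 sqrt_transform = isTRUE(sqrt_transform)),
            class = "network_params")
}

#' Construct a spectra table
#'
#' @param spectrum_id Character ids.
#' @param precursor_mz Precursor m/z of the deprotonated ion.
#' @param peaks List of two-column tibbles/data frames `mz`, `intensity`
#'   (intensities non-negative; peaks are sorted by m/z on construction).
#' @param polarity `"negative"` (default) or `"positive"`.
#' @return A tibble with one row per spectrum and a `peaks` list-column.
#' @export
spectra_table <- function(spectrum_id, precursor_mz, peaks,
                          polarity = "negative") {
  stopifnot(length(spectrum_id) == length(precursor_mz),
            length(peaks) == length(spectrum_id), all(precursor_mz > 0))
  peaks <- lapply(peaks, function(p) {
    p <- tibble::as_tibble(p)
    stopifnot(all(c("mz", "intensity") %in% names(p)), all(p$intensity >= 0))
    dplyr::arrange(p, .data$mz)
  })
  tibble::tibble(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 polarity = polarity, peaks = peaks)
}

#' Intensity-filter and normalise spectra
#'
#' Removes peaks below the raw-intensity floor, then (optionally)
#' square-root transforms and L2-normalises the surviving intensities so
#' the self-cosine of every spectrum is 1. Input rows are untouched; the
#' processed peak lists land in a new `peaks` column, with `n_peaks` and an
#' `empty` flag (spectra losing all peaks are flagged and later excluded
#' from networking).
#'
#' @param spectra A [spectra_table()].
#' @param params A [network_params()].
#' @return The spectra table with processed `peaks`, `raw_peaks`,
#'   `total_intensity` (raw, post-floor), `n_peaks` and `empty` columns.
#' @export
preprocess_spectra <- function(spectra, params = network_params()) {
  out <- spectra
  out$raw_peaks <- spectra$peaks
  processed <- lapply(spectra$peaks, function(p) {
    p <- p[p$intensity >= params$min_peak_intensity, , drop = FALSE]
    if (nrow(p) > 0L) {
      w <- if (params$sqrt_transform) sqrt(p$intensity) else p$intensity
      p$intensity <- w / sqrt(sum(w^2))
    }
    p
  })
  out$peaks <- processed
  out$total_intensity <- vapply(
    seq_along(processed),
    function(i) {
      raw <- spectra$peaks[[i]]
      sum(raw$intensity[raw$intensity >= params$min_peak_intensity])
    }, numeric(1))
  out$n_peaks <- vapply(processed, nrow, integer(1))
  out$empty <- out$n_peaks == 0L
  out
}

#' Modified cosine similarity between two preprocessed spectra
#'
#' A peak pair (i in a, j in b) is matchable when the fragment m/z agree
#' directly (`|mz_i - mz_j| <= fragment_tol`) or when they differ by the
#' precursor mass difference (`|mz_i - mz_j - (prec_a - prec_b)| <=
#' fragment_tol`), which links fragments that retain versus lose the
#' structural modification. The score is the sum of intensity products over
#' a one-to-one matching, chosen greedily by descending product; with
#' L2-normalised intensities it lies in `[0, 1]` and is symmetric.
#'
#' @param a,b One-row preprocessed spectra (from [preprocess_spectra()]),
#'   or lists with `precursor_mz` and `peaks`.
#' @param params A [network_params()].
#' @return A list with `cosine` and `matched_peaks`.
#' @export
modified_cosine <- function(a, b, params = network_params()) {
  pa <- if (is.data.frame(a$peaks)) a$peaks else a$peaks[[1]]
  pb <- if (is.data.frame(b$peaks)) b$peaks else b$peaks[[1]]
  prec_a <- a$precursor_mz[[1]]; prec_b <- b$precursor_mz[[1]]
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(list(cosine = 0, matched_peaks = 0L))
  dprec <- prec_a - prec_b
  dm <- outer(pa$mz, pb$mz, "-")
  matchable <- abs(dm) <= params$fragment_tol | abs(dm - dprec) <= params$fragment_tol
  if (!any(matchable)) return(list(cosine = 0, matched_peaks = 0L))
  idx <- which(matchable, arr.ind = TRUE)
  prod <- pa$intensity[idx[, 1L]] * pb$intensity[idx[, 2L]]
  ord <- order(-prod, idx[, 1L], idx[, 2L])
  used_a <- logical(nrow(pa)); used_b <- logical(nrow(pb))
  score <- 0; matched <- 0L
  for (r in ord) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    score <- score + prod[r]
    matched <- matched + 1L
  }
  list(cosine = min(score, 1), matched_peaks = matched)
}

#' Build a molecular network from MS/MS spectra
#'
#' Preprocesses the spectra, scores every pair with the modified cosine,
#' keeps edges meeting the cosine and matched-peak thresholds, and drops
#' connected components smaller than `min_cluster_size` (singletons at the
#' defaults).
#'
#' @param spectra A [spectra_table()] (raw; preprocessing is applied here).
#' @param params A [network_params()].
#' @return An object of class `spectral_network`: list with `nodes` (the
#'   preprocessed spectra retained in the network), `edges` (tibble
#'   `node_a`, `node_b`, `cosine`, `matched_peaks`, `precursor_delta`),
#'   `all_edges` (pre component-filter), and `params`.
#' @export
build_network <- function(spectra, params = network_params()) {
  stopifnot(nrow(spectra) >= 2L)
  prep <- preprocess_spectra(spectra, params)
  live <- prep[!prep$empty, ]
  live <- live[order(live$spectrum_id), ]
  n <- nrow(live)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sc <- modified_cosine(live[i, ], live[j, ], params)
        if (sc$cosine >= params$min_cosine &&
            sc$matched_peaks >= params$min_matched_peaks) {
          edges[[length(edges) + 1L]] <- tibble::tibble(
            node_a = live$spectrum_id[i], node_b = live$spectrum_id[j],
            cosine = sc$cosine, matched_peaks = sc$matched_peaks,
            precursor_delta = live$precursor_mz[i] - live$precursor_mz[j]
          )
        }
      }
    }
  }
  all_edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(node_a = character(), node_b = character(),
                   cosine = numeric(), matched_peaks = integer(),
                   precursor_delta = numeric())
  net <- structure(list(nodes = live, edges = all_edges, all_edges = all_edges,
                        params = params),
                   class = "spectral_network")
  prune_components(net)
}

prune_components <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = net$nodes$spectrum_id
  )
  comp <- igraph::components(g)
  keep_ids <- names(comp$membership)[comp$csize[comp$membership] >= net$params$min_cluster_size]
  net$nodes <- net$nodes[net$nodes$spectrum_id %in% keep_ids, ]
  net$edges <- net$edges[net$edges$node_a %in% keep_ids &
                           net$edges$node_b %in% keep_ids, ]
  net
}

#' @export
print.spectral_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = x$nodes$spectrum_id)
  cat("Spectral network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      igraph::components(g)$no, "component(s)\n")
  invisible(x)
}

#' Collapse isomeric nodes sharing a precursor mass
#'
#' Within each connected component, nodes whose precursor m/z agree within
#' `mass_tol` are treated as isomers (same molecular weight, no structural
#' information in the precursor) and only the node with the highest total
#' raw intensity is kept. Edges are re-derived among the survivors from the
#' originally passing pairs, and the cluster-size filter is re-applied.
#'
#' @param net A `spectral_network`.
#' @param mass_tol Precursor agreement tolerance in Da (default 0.01).
#' @return The deduplicated `spectral_network`.
#' @export
dedup_isomers <- function(net, mass_tol = 0.01) {
  g <- igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = net$nodes$spectrum_id)
  comp <- igraph::components(g)$membership
  nodes <- net$nodes
  nodes$component <- comp[nodes$spectrum_id]
  keep <- nodes |>
    dplyr::group_by(.data$component) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$precursor_mz), ]
      grp <- cumsum(c(1, diff(d$precursor_mz) > mass_tol))
      d$mass_group <- grp
      d |>
        dplyr::group_by(.data$mass_group) |>
        dplyr::slice_max(.data$total_intensity, n = 1L, with_ties = FALSE) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()
  keep_ids <- keep$spectrum_id
  net$nodes <- net$nodes[net$nodes$spectrum_id %in% keep_ids, ]
  net$edges <- net$all_edges[net$all_edges$node_a %in% keep_ids &
                               net$all_edges$node_b %in% keep_ids, ]
  prune_components(net)
}

#' Library of diagnostic neutral losses
#'
#' Monoisotopic masses of the neutral fragments lost between related
#' triterpene-glycoside ions, computed from the elemental formulas of the
#' departed groups: hexosyl C6H10O5 (162.0528), N-methylanthraniloyl C8H7NO
#' (133.0528), benzoyl C7H4O (104.0262).
#'
#' @param hexosyl,n_methylanthraniloyl,benzoyl Masses in Da.
#' @return Named numeric vector.
#' @export
loss_library <- function(hexosyl = 162.0528, n_methylanthraniloyl = 133.0528,
                         benzoyl = 104.0262) {
  c(hexosyl = hexosyl, n_methylanthraniloyl = n_methylanthraniloyl,
    benzoyl = benzoyl)
}

#' Annotate network edges with diagnostic neutral losses
#'
#' Each edge's absolute precursor mass difference is compared with the loss
#' library; when it matches a library mass within `loss_tol` the edge is
#' annotated with that loss name, otherwise `"none"`. The nominal
#' (rounded-integer) loss is also reported.
#'
#' @param net A `spectral_network`.
#' @param library Named masses from [loss_library()].
#' @param loss_tol Matching tolerance in Da (default 0.1).
#' @return The network with `loss_annotation` and `nominal_loss` edge
#'   columns.
#' @export
annotate_losses <- function(net, library = loss_library(), loss_tol = 0.1) {
  stopifnot(all(library > 0), !anyDuplicated(names(library)))
  if (length(library) > 1L) {
    gaps <- diff(sort(library))
    if (any(gaps < 2 * loss_tol)) {
      stop("loss library entries closer than 2 * loss_tol are ambiguous")
    }
  }
  delta <- abs(net$edges$precursor_delta)
  ann <- rep("none", length(delta))
  for (nm in names(library)) {
    ann[abs(delta - library[[nm]]) <= loss_tol] <- nm
  }
  net$edges$loss_annotation <- ann
  net$edges$nominal_loss <- as.integer(round(delta))
  net
}

#' Export a network to GraphML
#'
#' Nodes carry precursor m/z and total raw intensity; edges carry cosine,
#' matched peaks, precursor delta and any loss annotation.
#'
#' @param net A `spectral_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  verts <- data.frame(name = net$nodes$spectrum_id,
                      precursor_mz = net$nodes$precursor_mz,
                      total_intensity = net$nodes$total_intensity)
  g <- igraph::graph_from_data_frame(as.data.frame(net$edges),
                                     directed = FALSE, vertices = verts)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot a spectral network
#'
#' @param object A `spectral_network`.
#' @param ... Unused.
#' @return A ggplot of the network with edges labelled by annotated loss.
#' @method autoplot spectral_network
#' @export
autoplot.spectral_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(object$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = object$nodes$spectrum_id)
  xy <- igraph::layout_with_fr(g)
  lay <- tibble::tibble(spectrum_id = igraph::V(g)$name,
                        x = xy[, 1L], y = xy[, 2L]) |>
    dplyr::left_join(object$nodes[, c("spectrum_id", "precursor_mz")],
                     by = "spectrum_id")
  ed <- object$edges
  if (!"loss_annotation" %in% names(ed)) ed$loss_annotation <- "none"
  ed <- ed |>
    dplyr::left_join(lay[, c("spectrum_id", "x", "y")],
                     by = c(node_a = "spectrum_id")) |>
    dplyr::left_join(lay[, c("spectrum_id", "x", "y")],
                     by = c(node_b = "spectrum_id"), suffix = c("", "_b"))
  p <- ggplot2::ggplot(lay, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_b, yend = .data$y_b,
                   colour = .data$loss_annotation)
    ) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$precursor_mz)),
                       vjust = -1, size = 3) +
    ggplot2::labs(colour = "neutral loss") +
    ggplot2::theme_void()
  p
}
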