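#' Sliding-window scan parameters
#'
#' @param window_size Window width in bases (default 10 kb, the width used
#'   for intersection mapping of independently induced alleles).
#' @param step Offset between consecutive window starts (default 1 kb).
#' @param min_lines Number of mutant lines that must each carry at least
#'   one variant inside a window for it to qualify; `"all"` (default)
#'   requires every line in the cohort.
#' @return A `window_scan_params` list.
#' @export
window_scan_params <- function(window_size = 10000L, step = 1000L,
                               min_lines = "all") {
  stopifnot(step >= 1, step <= window_size)
  if (!identical(min_lines, "all")) stopifnot(is.numeric(min_lines), min_lines >= 1)
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 min_lines = min_lines),
            class = "window_scan_params")
}

#' Scan the genome for windows where all mutant lines carry a variant
#'
#' Enumerates windows `[s, s + window_size - 1]` at offsets
#' `s = 1, 1 + step, ...` on each chromosome and keeps those in which at
#' least `min_lines` lines (all of them by default) each have one or more
#' variants. Because the lines carry independently induced alleles of the
#' same gene, the causal locus is expected to be the region where every
#' line has a hit; variants need not be at shared positions.
#'
#' @param variants Tibble of (filtered) variants across the cohort, with
#'   columns `chrom`, `pos`, `line_id`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param params A [window_scan_params()].
#' @return A sorted tibble of qualifying windows: `chrom`, `start`, `end`,
#'   `n_lines` (number of supporting lines).
#' @export
window_scan <- function(variants, chrom_lengths, params = window_scan_params()) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  lines <- unique(variants$line_id)
  bad <- setdiff(unique(variants$chrom), names(chrom_lengths))
  if (length(bad) > 0L) stop("variants on chromosome(s) absent from chrom_lengths: ",
                             paste(bad, collapse = ", "))
  n_required <- if (identical(params$min_lines, "all")) length(lines) else
    min(as.integer(params$min_lines), length(lines))
  if (length(lines) == 0L) return(empty_windows())
  if (identical(params$min_lines, "all")) {
    per_line_n <- table(variants$line_id)
    if (any(per_line_n == 0L)) message("window_scan: a line has no variants; no window can qualify")
  }
  w <- params$window_size; st <- params$step
  out <- lapply(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    offsets <- seq.int(1L, len, by = st)
    n_off <- length(offsets)
    # per line: does any variant fall in window i? window i covers
    # [offsets[i], offsets[i]+w-1]; variant at p supports offset indices
    # with offsets in [p-w+1, p].
    support <- matrix(FALSE, nrow = n_off, ncol = length(lines),
                      dimnames = list(NULL, lines))
    vc <- variants[variants$chrom == chr, ]
    for (li in seq_along(lines)) {
      pos <- vc$pos[vc$line_id == lines[li]]
      for (p in pos) {
        lo <- ceiling((max(p - w + 1L, 1L) - 1L) / st) + 1L
        hi <- floor((p - 1L) / st) + 1L
        if (hi >= lo && lo <= n_off) support[lo:min(hi, n_off), li] <- TRUE
      }
    }
    ok <- rowSums(support) >= n_required
    if (!any(ok)) return(NULL)
    tibble::tibble(chrom = chr, start = offsets[ok],
                   end = pmin(offsets[ok] + w - 1L, len),
                   n_lines = rowSums(support)[ok])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_windows())
  dplyr::arrange(res, .data$chrom, .data$start)
}

empty_windows <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 n_lines = integer())
}

#' Merge qualifying windows into maximal candidate intervals
#'
#' Overlapping or bookended windows on the same chromosome are merged into
#' disjoint intervals whose union of bases equals the union of the input
#' windows. When the cohort's variants are supplied, each interval gains a
#' `line_variants` list-column mapping line ids to the variant positions
#' that fall inside it.
#'
#' @param windows Sorted window tibble from [window_scan()].
#' @param variants Optional variant tibble (`chrom`, `pos`, `line_id`) used
#'   to aggregate per-line supporting positions.
#' @return A tibble of intervals: `chrom`, `start`, `end`, `n_windows`,
#'   plus `n_lines` and `line_variants` when `variants` is given.
#' @export
merge_windows <- function(windows, variants = NULL) {
  if (nrow(windows) == 0L) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer())
    return(out)
  }
  windows <- dplyr::arrange(windows, .data$chrom, .data$start)
  merged <- windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(new_run = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -1L) + 1L)) |>
    dplyr::group_by(.data$chrom, .data$new_run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"new_run") |>
    dplyr::select("chrom", "start", "end", "n_windows") |>
    dplyr::arrange(.data$chrom, .data$start)
  if (!is.null(variants)) {
    merged$line_variants <- lapply(seq_len(nrow(merged)), function(i) {
      inside <- variants[variants$chrom == merged$chrom[i] &
                           variants$pos >= merged$start[i] &
                           variants$pos <= merged$end[i], ]
      split(inside$pos, inside$line_id)
    })
    merged$n_lines <- vapply(merged$line_variants, length, integer(1))
  }
  merged
}

#' Intersect candidate intervals with gene models
#'
#' A gene is a candidate iff any of its CDS segments overlaps any interval
#' by at least one base. Overlap is computed with IRanges.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param genes Gene-model tibble as from [gene_models()] /
#'   [read_gff_genes()]: `gene_id`, `chrom`, `strand`, `cds_segments`.
#' @return A tibble of `(chrom, start, end, gene_id)` candidate pairs in
#'   deterministic `(chrom, start, gene_id)` order.
#' @export
overlap_genes <- function(intervals, genes) {
  if (nrow(intervals) == 0L || nrow(genes) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character()))
  }
  segs <- tidyr::unnest(genes[, c("gene_id", "chrom", "cds_segments")],
                        "cds_segments")
  hits <- lapply(seq_len(nrow(intervals)), function(i) {
    ok <- segs$chrom == intervals$chrom[i] &
      segs$start <= intervals$end[i] & segs$end >= intervals$start[i]
    if (!any(ok)) return(NULL)
    tibble::tibble(chrom = intervals$chrom[i], start = intervals$start[i],
                   end = intervals$end[i], gene_id = unique(segs$gene_id[ok]))
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), gene_id = character()))
  }
  dplyr::arrange(dplyr::distinct(out), .data$chrom, .data$start, .data$gene_id)
}

#' Construct a gene-model tibble
#'
#' @param gene_id,chrom,strand Vectors of gene id, chromosome and strand.
#' @param cds_segments List of tibbles with 1-based inclusive `start`/`end`
#'   columns, one per gene, sorted and non-overlapping.
#' @return A gene-model tibble with the CDS segments as a list-column.
#' @export
gene_models <- function(gene_id, chrom, strand, cds_segments) {
  stopifnot(length(gene_id) == length(chrom), length(chrom) == length(strand),
            length(cds_segments) == length(gene_id))
  for (s in cds_segments) {
    stopifnot(all(s$start <= s$end), !is.unsorted(s$start))
    if (nrow(s) > 1L) stopifnot(all(s$start[-1L] > s$end[-nrow(s)]))
  }
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds_segments = cds_segments)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene and CDS features via rtracklayer and assembles CDS segments
#' per gene (by `Parent`/`ID` or `gene_id` attributes, falling back to the
#' CDS's own ID prefix).
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble (see [gene_models()]).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  parent <- if (!is.null(cds$Parent) && any(lengths(cds$Parent) > 0)) {
    vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, character(1))
  } else {
    as.character(cds$ID)
  }
  parent <- sub("\\.(mrna|t)\\d+$", "", sub("^(transcript|mrna|cds)[:.]", "", parent))
  tb <- tibble::tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(BiocGenerics::strand(cds)),
    start = BiocGenerics::start(cds),
    end = BiocGenerics::end(cds)
  )
  tb |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    tidyr::nest(cds_segments = c("start", "end")) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, purrr::map_int(.data$cds_segments, ~ min(.x$start)))
}

#' Write candidate intervals as BED
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention. An empty interval set produces a file holding only
#' the header comment.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  lines <- c("#chrom\tstart\tend",
             if (nrow(intervals) > 0L)
               sprintf("%s\t%d\t%d", intervals$chrom,
                       intervals$start - 1L, intervals$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 file back into 1-based inclusive intervals
#'
#' @param path Path to a BED file written by [write_bed()] (or any BED3).
#' @return An interval tibble (`chrom`, `start`, `end`), 1-based inclusive.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)) + 1L,
    end = as.integer(vapply(parts, `[[`, character(1), 3L))
  )
}
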