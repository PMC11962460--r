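# Shared fixtures and independent oracles used across the suite.

# Write a minimal single-sample VCF; records is a data frame with
# chrom, pos, ref, alt and optional gt / dp columns.
write_test_vcf <- function(records, path, sample = "line01",
                           contigs = c(chr1 = 1000000L)) {
  gt <- if ("gt" %in% names(records)) records$gt else rep("1/1", nrow(records))
  dp <- if ("dp" %in% names(records)) records$dp else rep(30L, nrow(records))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    if (nrow(records) > 0L)
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%d",
              records$chrom, records$pos, records$ref, records$alt, gt, dp)
  ), path)
  path
}

# Random CDS: ATG + non-stop codons + one terminal stop.
make_cds <- function(n_codons, codon_overrides = list()) {
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(bases, bases, bases), 1L, paste0, collapse = "")
  inner <- sample(setdiff(all_codons, stops), n_codons - 2L, replace = TRUE)
  codons <- c("ATG", inner, sample(stops, 1L))
  for (idx in names(codon_overrides)) {
    codons[as.integer(idx)] <- codon_overrides[[idx]]
  }
  paste0(codons, collapse = "")
}

# Exhaustive per-offset window scan, the oracle for window_scan().
oracle_window_scan <- function(variants, chrom_lengths, window_size, step,
                               n_required = length(unique(variants$line_id))) {
  lines <- unique(variants$line_id)
  out <- list()
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    for (s in seq(1L, len, by = step)) {
      e <- min(s + window_size - 1L, len)
      n_sup <- sum(vapply(lines, function(l) {
        any(variants$chrom == chr & variants$line_id == l &
              variants$pos >= s & variants$pos <= e)
      }, logical(1)))
      if (n_sup >= n_required) {
        out[[length(out) + 1L]] <- data.frame(chrom = chr, start = s, end = e)
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(chrom = character(),
                                        start = integer(), end = integer()))))
}

# Exhaustive maximum one-to-one matching score, the oracle for
# modified_cosine(). Recurses over all assignments of matchable pairs.
oracle_modified_cosine <- function(pa, pb, prec_a, prec_b, fragment_tol = 0.5) {
  dprec <- prec_a - prec_b
  pairs <- list()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      d <- pa$mz[i] - pb$mz[j]
      if (abs(d) <= fragment_tol || abs(d - dprec) <= fragment_tol) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0L) return(list(cosine = 0, matched_peaks = 0L))
  best <- new.env()
  best$score <- 0; best$matched <- 0L
  recurse <- function(k, used_a, used_b, score, matched) {
    if (score > best$score ||
        (score == best$score && matched > best$matched)) {
      best$score <- score; best$matched <- matched
    }
    if (k > length(pairs)) return()
    recurse(k + 1L, used_a, used_b, score, matched)  # skip pair k
    p <- pairs[[k]]
    if (!used_a[p[1L]] && !used_b[p[2L]]) {
      used_a[p[1L]] <- TRUE; used_b[p[2L]] <- TRUE
      recurse(k + 1L, used_a, used_b,
              score + pa$intensity[p[1L]] * pb$intensity[p[2L]], matched + 1L)
    }
  }
  recurse(1L, logical(nrow(pa)), logical(nrow(pb)), 0, 0L)
  list(cosine = best$score, matched_peaks = best$matched)
}

# Normalised random spectrum for similarity tests.
random_processed_spectrum <- function(n_peaks, mz_range = c(100, 900)) {
  mz <- sort(stats::runif(n_peaks, mz_range[1L], mz_range[2L]))
  int <- stats::runif(n_peaks, 0.1, 1)
  int <- int / sqrt(sum(int^2))
  list(precursor_mz = max(mz) + stats::runif(1, 20, 120),
       peaks = tibble::tibble(mz = mz, intensity = int))
}

# Assign mutant lines to chemotype classes at line level: fit a joint PCA,
# average replicate scores per line, nearest reference centroid.
classify_lines <- function(table, ref_prefix = "ref_", threshold_factor = 3) {
  pca <- suppressWarnings(fit_pca(table))
  sc <- tidy(pca)
  refs <- sc[startsWith(sc$line_id, ref_prefix), ]
  qry <- sc[!startsWith(sc$line_id, ref_prefix), ] |>
    dplyr::group_by(line_id, class) |>
    dplyr::summarise(PC1 = mean(PC1), PC2 = mean(PC2), .groups = "drop")
  assign_chemotype(qry, refs, threshold_factor = threshold_factor)
}

# Three-line random variant set on a 100-kb toy genome.
toy_variants_acc <- function(seed, n_lines = 3L, n_per_line = 12L, len = 1e5) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_lines), function(i) {
    tibble::tibble(chrom = "chr1", pos = sort(sample.int(len, n_per_line)),
                   line_id = sprintf("line%02d", i))
  }))
}
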