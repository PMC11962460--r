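#' Codon arithmetic for CDS positions
#'
#' Maps 1-based positions within a coding sequence onto codon coordinates:
#' the residue index and the position within the codon.
#'
#' @param cds_pos Integer vector of 1-based CDS positions (`>= 1`).
#' @return A tibble with columns `cds_pos`, `codon_index` (1-based residue
#'   number) and `codon_offset` (1, 2 or 3 within the codon).
#' @examples
#' codon_index(c(404, 963, 1, 3, 4))
#' @export
codon_index <- function(cds_pos) {
  stopifnot(is.numeric(cds_pos), all(cds_pos >= 1), all(cds_pos == floor(cds_pos)))
  cds_pos <- as.integer(cds_pos)
  tibble::tibble(
    cds_pos = cds_pos,
    codon_index = (cds_pos - 1L) %/% 3L + 1L,
    codon_offset = (cds_pos - 1L) %% 3L + 1L
  )
}

#' Validate a coding sequence
#'
#' Checks that a CDS has length divisible by 3, starts with ATG, contains a
#' single stop codon and that it sits at the end. Simulated CDS are held to
#' this strictly; real-world CDS often violate it (partial models,
#' selenocysteine readthrough), so by default violations warn rather than
#' fail.
#'
#' @param cds A single character string over `{A,C,G,T}`.
#' @param strict If `TRUE`, violations are errors instead of warnings.
#' @return `cds` invisibly.
#' @export
validate_cds <- function(cds, strict = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  signal <- if (strict) stop else warning
  if (grepl("[^ACGT]", cds)) stop("CDS contains characters outside {A,C,G,T}")
  if (nchar(cds) %% 3L != 0L) {
    # codon partition is ill-defined; stop the analysis here
    signal("CDS length not divisible by 3", call. = FALSE)
    return(invisible(cds))
  }
  codons <- substring(cds, seq(1L, nchar(cds) - 2L, by = 3L), seq(3L, nchar(cds), by = 3L))
  if (codons[1L] != "ATG") signal("CDS does not start with ATG", call. = FALSE)
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(stops) != 1L || stops[length(stops)] != length(codons)) {
    signal("CDS should contain exactly one stop codon, at the end", call. = FALSE)
  }
  invisible(cds)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa))) stop("cannot translate codon(s): ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Annotate a coding substitution with its codon-level consequence
#'
#' Translates the affected codon before and after a single-nucleotide
#' substitution using the standard genetic code and classifies the change as
#' synonymous, missense, stop_gained or stop_lost. The short form follows
#' the conventional residue notation (e.g. `"P135L"`), with premature stops
#' rendered as `"stop"` (e.g. `"W321stop"`).
#'
#' @param cds Coding sequence (single string, frame anchored at position 1).
#' @param cds_pos 1-based position of the substitution within the CDS.
#' @param ref,alt Reference and alternate nucleotides; `ref` must match the
#'   CDS base at `cds_pos`.
#' @param code Named character vector mapping codons to amino acids
#'   (default: the standard genetic code).
#' @return A one-row tibble: `cds_pos`, `ref`, `alt`, `codon_index`,
#'   `codon_offset`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`
#'   (single-letter, `"*"` for stop), `class`, `short_form`, and
#'   `start_lost` (flag: the ATG start codon was hit non-synonymously).
#' @examples
#' cds <- paste0("ATG", strrep("GCT", 150), "TAA")
#' annotate_cds_variant(cds, cds_pos = 5, ref = "C", alt = "T")
#' @export
annotate_cds_variant <- function(cds, cds_pos, ref, alt,
                                 code = Biostrings::GENETIC_CODE) {
  stopifnot(length(cds_pos) == 1L, length(ref) == 1L, length(alt) == 1L)
  cds <- toupper(cds)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"), ref != alt)
  if (cds_pos < 1L || cds_pos > nchar(cds)) {
    stop("cds_pos ", cds_pos, " outside CDS of length ", nchar(cds))
  }
  at <- substring(cds, cds_pos, cds_pos)
  if (at != ref) {
    stop("reference mismatch at CDS position ", cds_pos,
         ": expected ", ref, ", CDS has ", at)
  }
  ci <- codon_index(cds_pos)
  cstart <- (ci$codon_index - 1L) * 3L + 1L
  ref_codon <- substring(cds, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substring(alt_codon, ci$codon_offset, ci$codon_offset) <- alt
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  class <- if (alt_aa == "*" && ref_aa != "*") {
    "stop_gained"
  } else if (ref_aa == "*" && alt_aa != "*") {
    "stop_lost"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else {
    "missense"
  }
  render <- function(aa) ifelse(aa == "*", "stop", aa)
  start_lost <- ci$codon_index == 1L && ref_codon == "ATG" && class != "synonymous"
  if (start_lost) {
    warning("substitution disrupts the ATG start codon; classified as missense of M1",
            call. = FALSE)
  }
  tibble::tibble(
    cds_pos = as.integer(cds_pos), ref = ref, alt = alt,
    codon_index = ci$codon_index, codon_offset = ci$codon_offset,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa, class = class,
    short_form = paste0(render(ref_aa), ci$codon_index, render(alt_aa)),
    start_lost = start_lost
  )
}

#' Map a genomic position into CDS coordinates
#'
#' Strand-aware conversion of a chromosomal position to a 1-based position
#' within the spliced CDS of a gene model. On the plus strand segment
#' lengths accumulate left to right; on the minus strand right to left. The
#' caller is responsible for complementing the observed alleles when the
#' returned strand is `"-"`.
#'
#' @param gene A one-row gene model as produced by [gene_models()]: columns
#'   `gene_id`, `chrom`, `strand`, and `cds_segments` (list-column of
#'   tibbles with `start`, `end`, 1-based inclusive, sorted by genomic
#'   coordinate, non-overlapping).
#' @param chrom_pos 1-based genomic position; must fall inside a CDS segment.
#' @return A list with `cds_pos` and `strand`.
#' @export
map_genomic_to_cds <- function(gene, chrom_pos) {
  segs <- gene$cds_segments[[1L]]
  stopifnot(nrow(segs) >= 1L, all(segs$start <= segs$end))
  hit <- which(chrom_pos >= segs$start & chrom_pos <= segs$end)
  if (length(hit) == 0L) {
    where <- if (chrom_pos >= min(segs$start) && chrom_pos <= max(segs$end)) {
      "intronic"
    } else {
      "outside the gene span (intergenic)"
    }
    stop("position ", chrom_pos, " is ", where, " for gene ", gene$gene_id)
  }
  lens <- segs$end - segs$start + 1L
  if (identical(gene$strand, "+")) {
    cds_pos <- sum(lens[seq_len(hit - 1L)]) + (chrom_pos - segs$start[hit]) + 1L
  } else if (identical(gene$strand, "-")) {
    n <- nrow(segs)
    after <- if (hit < n) sum(lens[(hit + 1L):n]) else 0L
    cds_pos <- after + (segs$end[hit] - chrom_pos) + 1L
  } else {
    stop("strand must be '+' or '-', got ", gene$strand)
  }
  list(cds_pos = as.integer(cds_pos), strand = gene$strand)
}

#' Annotate genomic variants against gene models
#'
#' Convenience wrapper linking interval-mapping hits to consequence calls:
#' for each variant falling in a CDS segment of `gene`, converts the genomic
#' position to a CDS position (complementing alleles on the minus strand)
#' and annotates the substitution against the supplied coding sequence.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt` (and optionally
#'   `line_id`, carried through).
#' @param gene One-row gene model (see [map_genomic_to_cds()]).
#' @param cds The gene's coding sequence (plus-strand CDS, 5'→3').
#' @return A tibble of consequence calls, one row per variant inside the
#'   CDS, with `line_id` and genomic coordinates carried through.
#' @export
annotate_gene_variants <- function(variants, gene, cds) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!identical(v$chrom, gene$chrom)) return(NULL)
    m <- tryCatch(map_genomic_to_cds(gene, v$pos), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    ref <- v$ref; alt <- v$alt
    if (m$strand == "-") { ref <- comp[[ref]]; alt <- comp[[alt]] }
    call <- annotate_cds_variant(cds, m$cds_pos, ref, alt)
    call$chrom <- v$chrom
    call$pos <- v$pos
    call$line_id <- if ("line_id" %in% names(v)) v$line_id else NA_character_
    call$gene_id <- gene$gene_id
    call
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      cds_pos = integer(), ref = character(), alt = character(),
      codon_index = integer(), codon_offset = integer(),
      ref_codon = character(), alt_codon = character(),
      ref_aa = character(), alt_aa = character(), class = character(),
      short_form = character(), start_lost = logical(),
      chrom = character(), pos = integer(), line_id = character(),
      gene_id = character()
    )
  }
  out
}
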