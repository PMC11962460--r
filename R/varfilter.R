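#' Read single-sample variant calls from a VCF file
#'
#' Parses a single-sample VCF (v4.2) into a tidy variant table. Only
#' biallelic single-nucleotide substitutions are retained; indels and
#' multiallelic records are skipped and their count reported via a message.
#' Genotypes are collapsed to `hom_alt` / `het`; records without a usable
#' GT field get `NA` and are excluded later when a policy requires
#' homozygosity.
#'
#' @param path Path to a VCF file.
#' @param line_id Identifier for the mutant line; defaults to the sample
#'   name in the VCF header.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `genotype` (`"hom_alt"`, `"het"` or `NA`), `depth` (from the DP format
#'   field where present, else `NA`) and `line_id`.
#' @export
read_vcf <- function(path, line_id = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixmat <- vcfR::getFIX(v)
  if (is.null(dim(fixmat))) fixmat <- t(fixmat)  # single record: vector
  fix <- as.data.frame(fixmat, stringsAsFactors = FALSE)
  n_total <- nrow(fix)
  if (is.null(line_id)) {
    samples <- colnames(v@gt)
    samples <- setdiff(samples, "FORMAT")
    line_id <- if (length(samples) >= 1L) samples[1L] else NA_character_
  }
  if (n_total == 0L) {
    return(tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), genotype = character(), depth = integer(),
      line_id = character()
    ))
  }
  is_snv <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0L) {
    message("read_vcf: skipped ", n_skipped,
            " non-SNV or multiallelic record(s) in ", basename(path))
  }
  get_fmt <- function(element) {
    if (ncol(v@gt) < 2L) return(rep(NA_character_, n_total))
    m <- vcfR::extract.gt(v, element = element)
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    m[, 1L]
  }
  gt_raw <- get_fmt("GT")
  dp_raw <- suppressWarnings(as.integer(get_fmt("DP")))
  genotype <- dplyr::case_when(
    gt_raw %in% c("1/1", "1|1") ~ "hom_alt",
    gt_raw %in% c("0/1", "1/0", "0|1", "1|0") ~ "het",
    TRUE ~ NA_character_
  )
  tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    genotype = genotype,
    depth = dp_raw,
    line_id = line_id
  )[is_snv, ]
}

#' Mutagen-spectrum filtering policy
#'
#' Sodium azide (like EMS) induces predominantly G:C→A:T transitions, so a
#' stringency filter restricting candidate variants to that class removes
#' most background calls while retaining induced alleles. The class is
#' interpreted strand-symmetrically on the reference strand as the REF/ALT
#' pairs G→A and C→T (the complementary events appear as the other member
#' of the pair in a reference-stranded VCF).
#'
#' @param transitions_only Keep only G→A and C→T substitutions.
#' @param require_homozygous Keep only homozygous-alternate calls (selfed
#'   mutant lines are expected to be homozygous at induced sites).
#' @param min_depth Minimum read depth, or `NULL` to not filter on depth.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(transitions_only = TRUE, require_homozygous = TRUE,
                          min_depth = NULL) {
  if (!is.null(min_depth)) stopifnot(is.numeric(min_depth), min_depth >= 0)
  structure(
    list(transitions_only = isTRUE(transitions_only),
         require_homozygous = isTRUE(require_homozygous),
         min_depth = min_depth),
    class = "filter_policy"
  )
}

#' Apply a mutagen-spectrum filter to a variant table
#'
#' Subsets a variant table according to a [filter_policy()]: the output is
#' always a subset of the input with order preserved, so the operation is
#' idempotent and tightening any policy field can only shrink the result.
#'
#' @param variants Tibble as returned by [read_vcf()].
#' @param policy A [filter_policy()].
#' @return The retained variants.
#' @examples
#' v <- tibble::tibble(
#'   chrom = "chr1", pos = 1:4,
#'   ref = c("C", "G", "A", "C"), alt = c("T", "A", "G", "G"),
#'   genotype = "hom_alt", depth = 30L, line_id = "m1"
#' )
#' apply_filter(v, filter_policy())
#' @export
apply_filter <- function(variants, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  keep <- rep(TRUE, nrow(variants))
  if (policy$transitions_only) {
    keep <- keep & ((variants$ref == "G" & variants$alt == "A") |
                      (variants$ref == "C" & variants$alt == "T"))
  }
  if (policy$require_homozygous) {
    keep <- keep & !is.na(variants$genotype) & variants$genotype == "hom_alt"
  }
  if (!is.null(policy$min_depth)) {
    keep <- keep & !is.na(variants$depth) & variants$depth >= policy$min_depth
  }
  variants[keep, ]
}
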