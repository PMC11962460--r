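#' Configuration for the synthetic mutant-cohort generator
#'
#' Bundles every knob of the three generators ([simulate_cohort()],
#' [simulate_peak_table()], [simulate_spectra()]). The defaults describe a
#' desk-scale surrogate of a sodium-azide mutagenised diploid-oat screen:
#' a 10-Mb two-chromosome genome carrying 200 genes, four independent
#' mutant lines with ~50 homozygous background SNVs each (5 per Mb, the
#' dense end of reported azide loads) of which 80% are G:C→A:T
#' transitions, one causal transition per line in a shared gene, a
#' 28-metabolite targeted panel, and a triterpene-glycoside MS/MS series
#' related by hexosyl / N-methylanthraniloyl / benzoyl neutral losses.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   generator output.
#' @param n_chromosomes,chrom_length Genome shape (defaults 2 x 5 Mb).
#' @param n_genes Number of intron-less genes (default 200).
#' @param gene_length_range CDS length range in bases; lengths are drawn
#'   uniformly and rounded to codon multiples (default 1–5 kb).
#' @param n_lines Number of independent mutant lines (default 4).
#' @param background_snvs_per_line Poisson mean of background homozygous
#'   SNVs per line (default 50, i.e. 5 per Mb; chosen so the expected
#'   number of genome-wide coincidence windows — 10 kb regions where all
#'   four lines carry a background variant by chance — stays near 0.01,
#'   matching the single-interval behaviour of the real-data pipeline).
#' @param p_transition_gc_at Probability that a background SNV is a
#'   G:C→A:T transition (default 0.8, the azide spectrum).
#' @param causal_gene_id Gene that every line carries one causal transition
#'   in (default `"g042"`; ids run `g001..gNNN` in coordinate order).
#' @param het_fraction Fraction of background SNVs emitted as heterozygous
#'   calls, for exercising the homozygosity filter (default 0).
#' @param metabolite_panel Metabolite column ids (default `m01`–`m28`: the
#'   targeted avenacin panel 1–24 plus the four phenolic-glucoside markers
#'   25–28 the chemotype profiles reference).
#' @param class_profiles Named list mapping chemotype class to a named
#'   vector of mean peak areas over the panel (default
#'   [chemotype_profiles()]).
#' @param peak_cv Per-metabolite coefficient of variation of the log-normal
#'   peak noise (default 0.15, triplicate-scale variability).
#' @param parent_mz Precursor m/z of the series parent ion, `[M-H]^-`
#'   (default 959.4907).
#' @param spectrum_series Tibble with columns `name` and `loss`: a chain of
#'   compounds where each member's precursor is the previous member's minus
#'   `loss` (first row, the parent, has loss 0). Default: parent,
#'   -hexosyl (162.0528), -N-methylanthraniloyl (133.0528),
#'   -benzoyl (104.0262).
#' @param n_fragment_peaks Fragment peaks per parent spectrum (default 10).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 5e6,
                       n_genes = 200L,
                       gene_length_range = c(1002L, 4998L),
                       n_lines = 4L,
                       background_snvs_per_line = 50,
                       p_transition_gc_at = 0.8,
                       causal_gene_id = "g042",
                       het_fraction = 0,
                       metabolite_panel = sprintf("m%02d", 1:28),
                       class_profiles = chemotype_profiles(metabolite_panel),
                       peak_cv = 0.15,
                       parent_mz = 959.4907,
                       spectrum_series = default_spectrum_series(),
                       n_fragment_peaks = 10L) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    n_chromosomes >= 1, chrom_length >= 1, n_genes >= 1, n_lines >= 1,
    length(gene_length_range) == 2L, all(gene_length_range > 0),
    gene_length_range[1L] <= gene_length_range[2L],
    background_snvs_per_line >= 0,
    p_transition_gc_at >= 0, p_transition_gc_at <= 1,
    het_fraction >= 0, het_fraction <= 1,
    peak_cv >= 0, parent_mz > 0, n_fragment_peaks >= 1
  )
  stopifnot(all(c("name", "loss") %in% names(spectrum_series)),
            nrow(spectrum_series) >= 1L, spectrum_series$loss[1L] == 0)
  structure(
    list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
         chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         n_lines = as.integer(n_lines),
         background_snvs_per_line = background_snvs_per_line,
         p_transition_gc_at = p_transition_gc_at,
         causal_gene_id = causal_gene_id, het_fraction = het_fraction,
         metabolite_panel = metabolite_panel, class_profiles = class_profiles,
         peak_cv = peak_cv, parent_mz = parent_mz,
         spectrum_series = spectrum_series,
         n_fragment_peaks = as.integer(n_fragment_peaks)),
    class = "sim_config"
  )
}

#' Default MS/MS compound series
#'
#' A chain of four related `[M-H]^-` ions: the glycosylated, acylated
#' parent and derivatives successively lacking a hexosyl (162.0528 Da,
#' C6H10O5), an N-methylanthraniloyl (133.0528 Da, C8H7NO) and a benzoyl
#' (104.0262 Da, C7H4O) group.
#'
#' @return Tibble with `name` and `loss` columns.
#' @export
default_spectrum_series <- function() {
  tibble::tibble(
    name = c("parent", "deglucosyl", "des_nma", "des_benzoyl"),
    loss = c(0, 162.0528, 133.0528, 104.0262)
  )
}

#' Reference chemotype mean profiles
#'
#' Mean peak areas (arbitrary units) per metabolite for the wild type and
#' the mutant classes the screen distinguishes. The panel follows the
#' avenacin pathway logic: `m01`–`m04` the four avenacin end products
#' (A-1, A-2, B-1, B-2), `m05`/`m06`/`m12` monodeglucosyl intermediates,
#' `m11`/`m25`/`m26` des-acyl intermediates, `m19`/`m27`/`m28` the
#' N-methylanthraniloyl-, benzoyl- and feruloyl-glucoside acyl donors;
#' remaining panel members are minor intermediates whose abundance tracks
#' the overall pathway flux of the class (near the detection floor in
#' scaffold-less mutants, near wild-type level in end-product classes).
#'
#' * `WT`: end products high, intermediates at trace level.
#' * `sad1`: no triterpene scaffold — the whole avenacin panel is absent.
#' * `sad3`: transglucosidase block — monodeglucosyl forms accumulate, end
#'   products collapse.
#' * `sad7`: acyltransferase block — des-acyl forms accumulate.
#' * `sad4`: hybrid — intermediates of both the sad3 and sad7 type present
#'   together with reduced end products, and the acyl glucosides reduced.
#' * `pal2`: phenylpropanoid entry block — benzoyl-dependent avenacins A-2
#'   and B-2 reduced, A-1/B-1 unaffected; benzoyl and feruloyl glucosides
#'   down >65%, the anthranilate-derived glucoside down 17%.
#' * `cyp94d65`: C-23 oxidase block — A-series absent, B-series (including
#'   the monodeglucosyl B intermediate) elevated.
#'
#' @param panel Metabolite ids the profiles should cover.
#' @param trace Baseline area for minor peaks (default 1).
#' @return Named list of named mean vectors.
#' @export
chemotype_profiles <- function(panel = sprintf("m%02d", 1:28), trace = 1) {
  base <- stats::setNames(rep(trace, length(panel)), panel)
  set_if <- function(prof, ...) {
    vals <- c(...)
    keep <- intersect(names(vals), names(prof))
    prof[keep] <- vals[keep]
    prof
  }
  # named avenacin-pathway members; the remaining panel columns are minor
  # intermediates whose abundance tracks overall pathway flux of the class
  pathway <- c(sprintf("m%02d", 1:6), "m11", "m12", "m19", "m25", "m26",
               "m27", "m28")
  with_flux <- function(prof, flux) {
    minor <- setdiff(names(prof), pathway)
    prof[minor] <- trace * flux
    prof
  }
  wt <- with_flux(set_if(base, m01 = 100, m02 = 80, m03 = 60, m04 = 50,
                         m19 = 40, m27 = 40, m28 = 40), 1)
  sad1 <- base
  sad1[intersect(setdiff(pathway, c("m19", "m27", "m28")), panel)] <- 0
  sad1 <- with_flux(set_if(sad1, m19 = 40, m27 = 40, m28 = 40), 0.15)
  list(
    WT = wt,
    sad1 = sad1,
    sad3 = with_flux(set_if(base, m01 = 10, m02 = 8, m03 = 6, m04 = 5,
                            m05 = 60, m06 = 50, m12 = 40,
                            m19 = 40, m27 = 40, m28 = 40), 0.5),
    sad7 = with_flux(set_if(base, m01 = 10, m02 = 8, m03 = 6, m04 = 5,
                            m11 = 60, m25 = 50, m26 = 40,
                            m19 = 40, m27 = 40, m28 = 40), 0.5),
    sad4 = with_flux(set_if(base, m01 = 40, m02 = 32, m03 = 24, m04 = 20,
                            m05 = 40, m06 = 35, m12 = 3,
                            m11 = 45, m25 = 3, m26 = 3,
                            m19 = 2, m27 = 2, m28 = 2), 0.7),
    pal2 = with_flux(set_if(base, m01 = 100, m02 = 24, m03 = 60, m04 = 15,
                            m05 = 40, m06 = 35,
                            m19 = 33.2, m27 = 12, m28 = 13), 0.85),
    cyp94d65 = with_flux(set_if(base, m01 = 0, m02 = 0, m03 = 150, m04 = 125,
                                m05 = 0, m06 = 0, m11 = 0, m12 = 40,
                                m25 = 0, m26 = 0,
                                m19 = 40, m27 = 40, m28 = 40), 0.9)
  )
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  non_stop <- setdiff(
    apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = ""),
    STOP_CODONS
  )
  inner <- sample(setdiff(non_stop, "ATG"), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste0(inner, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Simulate a mutagenised cohort: genome, gene models and per-line variants
#'
#' Generates a random genome with intron-less genes (ATG start, single
#' terminal stop, codon-multiple lengths), then for each mutant line draws
#' Poisson-distributed background homozygous SNVs with the configured
#' mutagen spectrum plus exactly one causal G:C→A:T transition at a
#' distinct CDS position of the causal gene. When `dir` is given, the
#' cohort is written out as FASTA (reference), GFF3 (genes), one
#' single-sample VCF v4.2 per line, and a JSON ground-truth manifest.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return A `sim_cohort` list: `genome` (named character vector of
#'   chromosome sequences), `chrom_lengths`, `genes` (gene-model tibble
#'   with a `cds_seq` column), `variants` (all lines; `is_causal` flag),
#'   `manifest` (ground truth incl. intended consequence short forms), and
#'   `paths` when written.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(config$chrom_length, length(chroms)), chroms)

  base_vecs <- lapply(chroms, function(ch)
    sample(BASES, config$chrom_length, replace = TRUE))
  names(base_vecs) <- chroms

  # genes in slots so placement is non-overlapping and coordinate-ordered
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = length(chroms) + 1L)))
  gene_rows <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    slot <- config$chrom_length %/% ng
    if (slot <= config$gene_length_range[2L] + 2L) {
      stop("chromosome too short for ", ng, " genes of up to ",
           config$gene_length_range[2L], " bases")
    }
    for (g in seq_len(ng)) {
      gid <- gid + 1L
      n_codons <- sample(seq(config$gene_length_range[1L] %/% 3L,
                             config$gene_length_range[2L] %/% 3L), 1L)
      len <- 3L * n_codons
      start <- (g - 1L) * slot + sample.int(slot - len - 1L, 1L)
      cds <- random_cds(n_codons)
      base_vecs[[ci]][start:(start + len - 1L)] <- strsplit(cds, "")[[1L]]
      gene_rows[[gid]] <- tibble::tibble(
        gene_id = sprintf("g%03d", gid), chrom = chroms[ci], strand = "+",
        start = start, end = start + len - 1L, cds_seq = cds
      )
    }
  }
  genes <- dplyr::bind_rows(gene_rows)
  genes$cds_segments <- purrr::map2(genes$start, genes$end,
                                    ~ tibble::tibble(start = .x, end = .y))
  if (!config$causal_gene_id %in% genes$gene_id) {
    stop("causal_gene_id '", config$causal_gene_id,
         "' not present in the generated annotation (ids g001..",
         sprintf("g%03d", config$n_genes), ")")
  }
  causal <- genes[genes$gene_id == config$causal_gene_id, ]
  causal_bases <- base_vecs[[causal$chrom]][causal$start:causal$end]
  usable <- which(causal_bases %in% c("G", "C"))
  if (length(usable) < config$n_lines) {
    stop("causal gene has only ", length(usable),
         " G/C sites but ", config$n_lines, " lines need distinct causal hits")
  }
  causal_offsets <- usable[sample.int(length(usable), config$n_lines)]

  lines <- sprintf("line%02d", seq_len(config$n_lines))
  genome_starts <- unname(c(0, cumsum(chrom_lengths))[seq_along(chroms)])
  total_len <- sum(chrom_lengths)
  lookup_base <- function(gpos) {
    ci <- findInterval(gpos, genome_starts + 1)
    list(chrom = chroms[ci], pos = gpos - genome_starts[ci],
         ref = base_vecs[[ci]][gpos - genome_starts[ci]])
  }

  var_rows <- list()
  for (li in seq_along(lines)) {
    n_bg <- stats::rpois(1L, config$background_snvs_per_line)
    bg <- if (n_bg > 0L) {
      is_trans <- stats::runif(n_bg) < config$p_transition_gc_at
      rows <- vector("list", n_bg)
      for (k in seq_len(n_bg)) {
        repeat {
          hit <- lookup_base(sample.int(total_len, 1L))
          if (!is_trans[k] || hit$ref %in% c("G", "C")) break
        }
        alt <- if (is_trans[k]) {
          if (hit$ref == "G") "A" else "T"
        } else {
          # exclude the azide transition so the spectrum fraction stays at p
          choices <- switch(hit$ref, G = c("C", "T"), C = c("A", "G"),
                            A = c("C", "G", "T"), T = c("A", "C", "G"))
          sample(choices, 1L)
        }
        rows[[k]] <- tibble::tibble(chrom = hit$chrom, pos = hit$pos,
                                    ref = hit$ref, alt = alt)
      }
      dplyr::bind_rows(rows)
    } else {
      tibble::tibble(chrom = character(), pos = integer(),
                     ref = character(), alt = character())
    }
    cpos <- causal$start + causal_offsets[li] - 1L
    cref <- causal_bases[causal_offsets[li]]
    cv <- tibble::tibble(chrom = causal$chrom, pos = cpos, ref = cref,
                         alt = if (cref == "G") "A" else "T")
    bg <- bg[!(bg$chrom == cv$chrom & bg$pos == cv$pos), ]
    all <- dplyr::bind_rows(
      dplyr::mutate(bg, is_causal = FALSE),
      dplyr::mutate(cv, is_causal = TRUE)
    )
    all <- all[!duplicated(paste(all$chrom, all$pos)), ]
    n_het <- if (config$het_fraction > 0) {
      bg_idx <- which(!all$is_causal)
      sel <- bg_idx[stats::runif(length(bg_idx)) < config$het_fraction]
      sel
    } else {
      integer()
    }
    all$genotype <- "hom_alt"
    all$genotype[n_het] <- "het"
    all$depth <- stats::rpois(nrow(all), 30L) + 1L
    all$line_id <- lines[li]
    var_rows[[li]] <- dplyr::arrange(all, .data$chrom, .data$pos)
  }
  variants <- dplyr::bind_rows(var_rows)

  causal_calls <- variants[variants$is_causal, ] |>
    dplyr::rowwise() |>
    dplyr::group_map(function(v, ...) {
      cds_pos <- v$pos - causal$start + 1L
      call <- annotate_cds_variant(causal$cds_seq, cds_pos, v$ref, v$alt)
      tibble::tibble(line_id = v$line_id, chrom = v$chrom, pos = v$pos,
                     cds_pos = cds_pos, ref = v$ref, alt = v$alt,
                     class = call$class, short_form = call$short_form)
    }) |>
    dplyr::bind_rows()

  manifest <- list(
    seed = config$seed,
    causal_gene_id = config$causal_gene_id,
    causal_chrom = causal$chrom,
    causal_start = causal$start,
    causal_end = causal$end,
    lines = lines,
    causal_variants = causal_calls
  )

  genome <- vapply(base_vecs, paste0, character(1), collapse = "")
  cohort <- structure(
    list(genome = genome, chrom_lengths = chrom_lengths,
         genes = genes, variants = variants, manifest = manifest,
         config = config),
    class = "sim_cohort"
  )
  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(x$genome), "chromosome(s),",
      nrow(x$genes), "genes,", length(x$manifest$lines), "mutant line(s),",
      nrow(x$variants), "variants\n")
  cat("Causal gene:", x$manifest$causal_gene_id, "(",
      x$manifest$causal_chrom, ":", x$manifest$causal_start, "-",
      x$manifest$causal_end, ")\n")
  invisible(x)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "reference.fasta")
  seqs <- Biostrings::DNAStringSet(cohort$genome)
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)

  gff <- file.path(dir, "genes.gff3")
  g <- cohort$genes
  writeLines(c(
    "##gff-version 3",
    unlist(lapply(seq_len(nrow(g)), function(i) c(
      sprintf("%s\tsimdata\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i]),
      sprintf("%s\tsimdata\tmRNA\t%d\t%d\t.\t%s\t.\tID=transcript:%s.t1;Parent=gene:%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i], g$gene_id[i]),
      sprintf("%s\tsimdata\tCDS\t%d\t%d\t.\t%s\t0\tID=CDS:%s;Parent=transcript:%s.t1",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i], g$gene_id[i])
    )))
  ), gff)

  vcf_paths <- character()
  for (line in cohort$manifest$lines) {
    v <- cohort$variants[cohort$variants$line_id == line, ]
    path <- file.path(dir, paste0(line, ".vcf"))
    gt <- ifelse(v$genotype == "hom_alt", "1/1", "0/1")
    writeLines(c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=%s,length=%d>", names(cohort$chrom_lengths),
              cohort$chrom_lengths),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", line),
      if (nrow(v) > 0L)
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%d",
                v$chrom, v$pos, v$ref, v$alt, gt, v$depth)
    ), path)
    vcf_paths <- c(vcf_paths, path)
  }

  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(cohort$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  cohort$paths <- list(fasta = fasta, gff3 = gff, vcf = vcf_paths,
                       manifest = manifest_path)
  cohort
}

#' Simulate a targeted-metabolomics peak table
#'
#' Draws replicate peak areas for each line around its chemotype-class mean
#' profile with multiplicative log-normal noise (median at the class mean,
#' coefficient of variation `config$peak_cv`); metabolites absent in a
#' class (mean 0) stay exactly 0.
#'
#' @param config A [sim_config()].
#' @param class_assignments Named character vector `line_id -> class`;
#'   every class must have a profile in `config$class_profiles`.
#' @param n_replicates Replicates per line (default 3; 0 gives an empty
#'   table with the full header).
#' @return Peak-table tibble: `line_id`, `replicate`, `class`, then one
#'   column per panel metabolite.
#' @export
simulate_peak_table <- function(config, class_assignments, n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 0)
  unknown <- !class_assignments %in% names(config$class_profiles)
  if (any(unknown)) {
    stop("no chemotype profile for class '",
         class_assignments[unknown][1L], "' (line ",
         names(class_assignments)[unknown][1L], ")")
  }
  set.seed(config$seed + 1L)
  panel <- config$metabolite_panel
  empty <- tibble::as_tibble(c(
    list(line_id = character(), replicate = integer(), class = character()),
    stats::setNames(rep(list(numeric()), length(panel)), panel)
  ))
  if (n_replicates == 0L || length(class_assignments) == 0L) return(empty)
  sdlog <- sqrt(log(1 + config$peak_cv^2))
  rows <- list()
  for (line in names(class_assignments)) {
    cls <- class_assignments[[line]]
    mu <- config$class_profiles[[cls]][panel]
    for (r in seq_len(n_replicates)) {
      noise <- exp(stats::rnorm(length(panel), 0, sdlog))
      vals <- ifelse(mu > 0, mu * noise, 0)
      rows[[length(rows) + 1L]] <- tibble::as_tibble(c(
        list(line_id = line, replicate = r, class = cls),
        stats::setNames(as.list(vals), panel)
      ))
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate an MS/MS spectrum series linked by neutral losses
#'
#' Builds the parent spectrum of the configured compound chain and then
#' each derivative by subtracting the step's neutral loss from the
#' precursor, shifting the modification-bearing fragments accordingly and
#' keeping low-mass fragments shared, so consecutive members exceed the
#' modified-cosine networking thresholds by construction.
#'
#' @param config A [sim_config()].
#' @param path Optional MGF output path.
#' @return A [spectra_table()] (one row per series member).
#' @export
simulate_spectra <- function(config, path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  series <- config$spectrum_series
  n <- nrow(series)
  prec <- config$parent_mz - cumsum(series$loss)
  if (any(prec <= 50)) stop("spectrum series losses exceed the parent mass")
  nf <- config$n_fragment_peaks
  n_low <- max(3L, nf %/% 2L)
  low <- sort(stats::runif(n_low, 120, min(prec) - 60))
  high <- sort(stats::runif(nf - n_low, min(prec) - 50, prec[1L] - 20))
  peaks <- tibble::tibble(
    mz = c(low, high),
    intensity = stats::runif(nf, 100, 1000)
  )
  out <- vector("list", n)
  out[[1L]] <- peaks
  if (n > 1L) {
    for (k in 2:n) {
      prev <- out[[k - 1L]]
      shift <- prev$mz > prec[k] - 10
      p <- prev
      p$mz[shift] <- p$mz[shift] - series$loss[k]
      p$intensity <- p$intensity * stats::runif(nrow(p), 0.85, 1.18)
      extra <- tibble::tibble(
        mz = stats::runif(2L, 120, prec[k] - 20),
        intensity = stats::runif(2L, 100, 400)
      )
      out[[k]] <- dplyr::arrange(dplyr::bind_rows(p, extra), .data$mz)
    }
  }
  spectra <- spectra_table(
    spectrum_id = sprintf("%s_%.2f", series$name, prec),
    precursor_mz = prec,
    peaks = out,
    polarity = "negative"
  )
  if (!is.null(path)) write_mgf(spectra, path)
  spectra
}
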