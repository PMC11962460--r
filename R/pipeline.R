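#' Build a pipeline run configuration
#'
#' Collects the per-stage parameter blocks and the single seed every stage
#' draws its randomness from. The configuration can also be read from a
#' declarative YAML file (see [read_run_config()]) so runs are diffable and
#' reproducible.
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory for stage results and the manifest.
#' @param sim A [sim_config()] (its seed is overridden by `seed`), or
#'   `NULL` to skip simulation (then `vcf_paths`, `gff3_path` etc. must
#'   point at existing inputs).
#' @param class_assignments Named vector `line -> chemotype class` used for
#'   the simulated peak table; defaults to calling every line `sad4` plus
#'   reference lines for each profile class.
#' @param n_replicates Peak-table replicates per line.
#' @param policy A [filter_policy()].
#' @param scan A [window_scan_params()].
#' @param net A [network_params()].
#' @param with_spectra Run the networking stage (default `TRUE`).
#' @param vcf_paths,gff3_path,fasta_path Inputs when `sim` is `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("azidomap_run_"),
                       sim = sim_config(seed = seed),
                       class_assignments = NULL, n_replicates = 3L,
                       policy = filter_policy(),
                       scan = window_scan_params(),
                       net = network_params(),
                       with_spectra = TRUE,
                       vcf_paths = NULL, gff3_path = NULL, fasta_path = NULL) {
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
         class_assignments = class_assignments, n_replicates = n_replicates,
         policy = policy, scan = scan, net = net,
         with_spectra = isTRUE(with_spectra),
         vcf_paths = vcf_paths, gff3_path = gff3_path,
         fasta_path = fasta_path),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys: `seed`, `out_dir`, `with_spectra`,
#' `n_replicates`, plus nested blocks `sim`, `policy`, `scan`, `net` whose
#' entries are passed to the respective constructors. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "with_spectra", "n_replicates",
             "sim", "policy", "scan", "net", "class_assignments")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  args <- list()
  for (k in c("seed", "out_dir", "with_spectra", "n_replicates")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  if (!is.null(raw$class_assignments)) {
    args$class_assignments <- unlist(raw$class_assignments)
  }
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$policy)) args$policy <- do.call(filter_policy, raw$policy)
  if (!is.null(raw$scan)) args$scan <- do.call(window_scan_params, raw$scan)
  if (!is.null(raw$net)) args$net <- do.call(network_params, raw$net)
  do.call(run_config, args)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full chemotyping-to-candidate-gene pipeline
#'
#' Orchestrates the stages end to end: simulate the cohort (optional),
#' chemotype the lines by PCA against reference profiles, build and
#' annotate the MS/MS network, filter each line's variants by the mutagen
#' spectrum, scan for windows where all lines carry a variant, intersect
#' candidate intervals with the annotation and annotate consequences of
#' the variants inside the candidate gene(s). All stage outputs plus a
#' manifest (seed, parameters, per-output MD5 hashes) land in
#' `config$out_dir`; identical config and seed give identical hashes. A
#' stage failure aborts the run naming the stage, leaving a `FAILED`
#' marker next to the partial outputs.
#'
#' @param config A [run_config()] or path to a YAML configuration.
#' @return An `azidomap_run` list: `candidates`, `intervals`,
#'   `consequences`, `assignments`, `network`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  done <- FALSE
  on.exit(if (!done) writeLines("pipeline aborted", failed_marker))

  if (is.null(config$sim)) {
    stopifnot(!is.null(config$vcf_paths), !is.null(config$gff3_path))
    genes <- stage("annotation", read_gff_genes(config$gff3_path))
    variants <- stage("read_vcf", dplyr::bind_rows(lapply(config$vcf_paths, read_vcf)))
    chrom_lengths <- NULL
    cohort <- NULL
  } else {
    cohort <- stage("simulate", simulate_cohort(config$sim,
                                                dir = file.path(config$out_dir, "sim")))
    genes <- cohort$genes
    variants <- stage("read_vcf",
                      dplyr::bind_rows(lapply(cohort$paths$vcf, read_vcf)))
    chrom_lengths <- cohort$chrom_lengths
  }

  assignments <- NULL
  if (!is.null(cohort)) {
    classes <- config$class_assignments
    if (is.null(classes)) {
      classes <- stats::setNames(rep("sad4", length(cohort$manifest$lines)),
                                 cohort$manifest$lines)
    }
    ref_classes <- names(config$sim$class_profiles)
    ref_assign <- stats::setNames(ref_classes, paste0("ref_", ref_classes))
    table <- stage("peak_table", simulate_peak_table(
      config$sim, c(ref_assign, classes), n_replicates = config$n_replicates))
    assignments <- stage("chemotype", {
      pca <- fit_pca(table)
      sc <- tidy(pca)
      is_ref <- startsWith(sc$line_id, "ref_")
      refs <- sc[is_ref, ]
      refs$class <- sub("^ref_", "", refs$line_id)
      pcs <- grep("^PC[0-9]+$", names(sc), value = TRUE)
      # mutant lines are classified by their replicate-averaged scores
      qry <- sc[!is_ref, ] |>
        dplyr::group_by(.data$line_id) |>
        dplyr::summarise(dplyr::across(dplyr::all_of(pcs), mean),
                         .groups = "drop")
      assign_chemotype(qry, refs)
    })
    readr::write_csv(table, file.path(config$out_dir, "peak_table.csv"))
    readr::write_tsv(assignments[, setdiff(names(assignments), "peaks")],
                     file.path(config$out_dir, "assignments.tsv"))
  }

  network <- NULL
  if (config$with_spectra && !is.null(config$sim)) {
    network <- stage("msnetwork", {
      spectra <- simulate_spectra(config$sim,
                                  path = file.path(config$out_dir, "spectra.mgf"))
      net <- build_network(spectra, config$net)
      net <- dedup_isomers(net)
      annotate_losses(net)
    })
    readr::write_tsv(network$edges, file.path(config$out_dir, "edges.tsv"))
    write_graphml(network, file.path(config$out_dir, "network.graphml"))
  } else {
    message("[msnetwork] skipped (no spectra configured)")
  }

  filtered <- stage("filter", apply_filter(variants, config$policy))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(filtered$pos, filtered$chrom, max)
  }
  windows <- stage("mapscan", window_scan(filtered, chrom_lengths, config$scan))
  intervals <- merge_windows(windows, filtered)
  candidates <- overlap_genes(intervals, genes)
  write_bed(intervals, file.path(config$out_dir, "intervals.bed"))
  readr::write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))

  consequences <- stage("consequence", {
    calls <- lapply(unique(candidates$gene_id), function(gid) {
      gene <- genes[genes$gene_id == gid, ]
      cds <- if (!is.null(cohort)) gene$cds_seq else NA_character_
      if (is.na(cds)) return(NULL)
      annotate_gene_variants(filtered, gene, cds)
    })
    dplyr::bind_rows(calls)
  })
  if (nrow(consequences) > 0L) {
    readr::write_tsv(
      consequences[, c("gene_id", "line_id", "cds_pos", "ref", "alt",
                       "class", "short_form")],
      file.path(config$out_dir, "consequences.tsv"))
  }

  outputs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  hashes <- tools::md5sum(outputs)
  names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "", names(hashes))
  manifest <- list(
    seed = config$seed,
    params = list(
      policy = unclass(config$policy), scan = unclass(config$scan),
      net = unclass(config$net)
    ),
    outputs = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  done <- TRUE
  structure(
    list(candidates = candidates, intervals = intervals,
         consequences = consequences, assignments = assignments,
         network = network, manifest = manifest, out_dir = config$out_dir),
    class = "azidomap_run"
  )
}

#' @export
print.azidomap_run <- function(x, ...) {
  cat("azidomap pipeline run (seed", x$manifest$seed, ")\n")
  cat("  candidate intervals:", nrow(x$intervals), "\n")
  cat("  candidate genes:", paste(unique(x$candidates$gene_id), collapse = ", "), "\n")
  if (!is.null(x$assignments)) {
    cat("  chemotype calls:",
        paste(sprintf("%s=%s", x$assignments$line_id, x$assignments$assigned),
              collapse = ", "), "\n")
  }
  invisible(x)
}
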