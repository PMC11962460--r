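small_cfg <- function(seed = 1, causal_gene_id = "g004", ...) {
  sim_config(seed = seed, n_chromosomes = 1L, chrom_length = 200000L,
             n_genes = 8L, n_lines = 3L, background_snvs_per_line = 20,
             causal_gene_id = causal_gene_id, ...)
}

test_that("identical seed and config give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co1 <- simulate_cohort(small_cfg(seed = 5), dir = d1)
  co2 <- simulate_cohort(small_cfg(seed = 5), dir = d2)
  for (f in c("reference.fasta", "genes.gff3", "line01.vcf", "line02.vcf",
              "line03.vcf")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_identical(
    simulate_peak_table(small_cfg(seed = 5), c(l1 = "WT", l2 = "sad3")),
    simulate_peak_table(small_cfg(seed = 5), c(l1 = "WT", l2 = "sad3"))
  )
  expect_identical(simulate_spectra(small_cfg(seed = 5)),
                   simulate_spectra(small_cfg(seed = 5)))
  # a different seed changes the variants
  co3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(co1$variants$pos, co3$variants$pos))
})

test_that("every line carries a causal transition inside the causal gene", {
  co <- simulate_cohort(small_cfg(seed = 2))
  span <- c(co$manifest$causal_start, co$manifest$causal_end)
  for (line in co$manifest$lines) {
    v <- co$variants[co$variants$line_id == line, ]
    inside <- v[v$chrom == co$manifest$causal_chrom &
                  v$pos >= span[1] & v$pos <= span[2], ]
    expect_gte(nrow(inside), 1L)
  }
  causal <- co$variants[co$variants$is_causal, ]
  expect_equal(nrow(causal), 3L)
  expect_equal(length(unique(causal$pos)), 3L)  # distinct CDS positions
  # causal hits always pass the azide transition filter by construction
  expect_equal(nrow(apply_filter(causal, filter_policy())), 3L)
})

test_that("the mutagen spectrum parameter controls the transition fraction", {
  co_all <- simulate_cohort(small_cfg(seed = 3, p_transition_gc_at = 1))
  bg <- co_all$variants[!co_all$variants$is_causal, ]
  expect_true(all((bg$ref == "G" & bg$alt == "A") |
                    (bg$ref == "C" & bg$alt == "T")))

  # empirical fraction converges to p (binomial tolerance at n >= 1000)
  cfg <- sim_config(seed = 4, n_chromosomes = 1L, chrom_length = 500000L,
                    n_genes = 10L, n_lines = 4L,
                    background_snvs_per_line = 400,
                    p_transition_gc_at = 0.7, causal_gene_id = "g005")
  co <- simulate_cohort(cfg)
  bg <- co$variants[!co$variants$is_causal, ]
  n <- nrow(bg)
  expect_gte(n, 1000L)
  frac <- mean((bg$ref == "G" & bg$alt == "A") | (bg$ref == "C" & bg$alt == "T"))
  expect_lt(abs(frac - 0.7), 4 * sqrt(0.7 * 0.3 / n))
})

test_that("the simulator refuses impossible causal-gene configurations", {
  expect_error(simulate_cohort(small_cfg(causal_gene_id = "g999")),
               "not present")
})

test_that("heterozygous contamination is produced and filterable", {
  co <- simulate_cohort(small_cfg(seed = 12, het_fraction = 0.5))
  expect_gt(sum(co$variants$genotype == "het"), 0)
  kept <- apply_filter(co$variants, filter_policy())
  expect_true(all(kept$genotype == "hom_alt"))
  expect_false(any(co$variants$is_causal & co$variants$genotype == "het"))
})

test_that("written VCFs parse back to the simulated homozygous SNV sets", {
  d <- withr::local_tempdir()
  co <- simulate_cohort(small_cfg(seed = 8), dir = d)
  v <- read_vcf(co$paths$vcf[1])
  truth <- co$variants[co$variants$line_id == "line01", ]
  expect_equal(v$pos, truth$pos)
  expect_equal(v$ref, truth$ref)
  expect_equal(v$alt, truth$alt)
  expect_equal(v$line_id[1], "line01")
})

test_that("class profiles encode the published chemotype contrasts", {
  cfg <- sim_config(seed = 19)
  tb <- simulate_peak_table(cfg, c(wt = "WT", cyp = "cyp94d65", pal = "pal2"),
                            n_replicates = 20)
  mean_of <- function(cls, m) mean(tb[[m]][tb$class == cls])
  # C-23 oxidase block: A-series absent, B-series elevated over WT
  expect_equal(mean_of("cyp94d65", "m01"), 0)
  expect_equal(mean_of("cyp94d65", "m02"), 0)
  expect_gt(mean_of("cyp94d65", "m03"), mean_of("WT", "m03"))
  expect_gt(mean_of("cyp94d65", "m04"), mean_of("WT", "m04"))
  # phenylpropanoid block: benzoyl glucoside down > 65%, NMA glucoside ~17%
  expect_lte(mean_of("pal2", "m27") / mean_of("WT", "m27"), 0.35)
  expect_equal(mean_of("pal2", "m19") / mean_of("WT", "m19"), 0.83,
               tolerance = 0.1)
  expect_gt(mean_of("pal2", "m28") / mean_of("WT", "m28"), 0)
  expect_lte(mean_of("pal2", "m28") / mean_of("WT", "m28"), 0.35)
  expect_true(all(as.matrix(tb[, cfg$metabolite_panel]) >= 0))
})

test_that("zero replicates give an empty table with the full header", {
  tb <- simulate_peak_table(sim_config(seed = 1), c(l1 = "WT"), n_replicates = 0)
  expect_equal(nrow(tb), 0L)
  expect_true(all(sprintf("m%02d", 1:28) %in% names(tb)))
  expect_error(simulate_peak_table(sim_config(seed = 1), c(lx = "unknown")),
               "lx")
})

test_that("spectrum series precursors step down by the configured losses", {
  sp <- simulate_spectra(sim_config(seed = 7))
  expect_equal(nrow(sp), 4L)
  expect_equal(sp$precursor_mz[1], 959.4907, tolerance = 1e-6)
  expect_equal(sp$precursor_mz[1] - sp$precursor_mz[2], 162.0528,
               tolerance = 1e-6)
  # the printed hexosyl-loss derivative of the 959.49 parent
  expect_equal(sp$precursor_mz[2], 959.49 - 162.0528, tolerance = 0.01)

  single <- sim_config(seed = 7,
                       spectrum_series = tibble::tibble(name = "parent", loss = 0))
  expect_equal(nrow(simulate_spectra(single)), 1L)
})

test_that("consecutive series members clear the networking thresholds", {
  sp <- simulate_spectra(sim_config(seed = 16))
  prep <- preprocess_spectra(sp)
  for (i in seq_len(nrow(prep) - 1L)) {
    sc <- modified_cosine(prep[i, ], prep[i + 1L, ])
    expect_gte(sc$cosine, 0.6)
    expect_gte(sc$matched_peaks, 3L)
  }
  net <- build_network(sp)
  g <- igraph::graph_from_data_frame(net$edges[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = net$nodes$spectrum_id)
  expect_equal(igraph::components(g)$no, 1L)
  expect_equal(nrow(net$nodes), 4L)
})
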