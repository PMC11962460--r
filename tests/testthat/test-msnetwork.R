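test_that("preprocessing floors intensities and L2-normalises", {
  sp <- spectra_table("s1", 500, list(tibble::tibble(mz = c(100, 200),
                                                     intensity = c(24, 26))))
  prep <- preprocess_spectra(sp)
  p <- prep$peaks[[1]]
  expect_equal(p$mz, 200)
  expect_equal(p$intensity, 1)
  expect_false(prep$empty)

  empty <- preprocess_spectra(
    spectra_table("s2", 500, list(tibble::tibble(mz = c(100, 200),
                                                 intensity = c(5, 10)))))
  expect_true(empty$empty)

  # normalisation identity on random spectra
  set.seed(6)
  for (i in 1:5) {
    n <- sample(3:20, 1)
    sp <- spectra_table("sR", 900,
                        list(tibble::tibble(mz = sort(stats::runif(n, 100, 800)),
                                            intensity = stats::runif(n, 30, 2000))))
    expect_equal(sum(preprocess_spectra(sp)$peaks[[1]]$intensity^2), 1,
                 tolerance = 1e-12)
  }
})

test_that("modified cosine is 1 on self, 0 without matchable pairs, and symmetric", {
  set.seed(9)
  a <- random_processed_spectrum(8)
  expect_equal(modified_cosine(list(precursor_mz = a$precursor_mz, peaks = a$peaks),
                               list(precursor_mz = a$precursor_mz, peaks = a$peaks))$cosine,
               1, tolerance = 1e-9)

  b <- list(precursor_mz = a$precursor_mz,
            peaks = tibble::tibble(mz = a$peaks$mz + 7.77, intensity = a$peaks$intensity))
  off <- modified_cosine(a, b)
  expect_equal(off$cosine, 0)
  expect_equal(off$matched_peaks, 0L)

  c <- random_processed_spectrum(6)
  expect_equal(modified_cosine(a, c), modified_cosine(c, a))
})

test_that("greedy matching equals the exhaustive oracle on small spectra", {
  set.seed(15)
  params <- network_params()
  for (rep in 1:30) {
    na <- sample(2:6, 1); nb <- sample(2:na, 1)
    a <- random_processed_spectrum(na)
    # craft b as a partially shifted copy so both match rules fire
    delta <- sample(c(0, 162.0528, 133.0528), 1)
    b_mz <- a$peaks$mz
    shift <- stats::runif(na) < 0.5
    b_mz[shift] <- b_mz[shift] - delta
    b_mz <- b_mz + stats::rnorm(na, 0, 0.1)
    b <- list(precursor_mz = a$precursor_mz - delta,
              peaks = tibble::tibble(mz = sort(b_mz[seq_len(nb)]),
                                     intensity = stats::runif(nb, 0.1, 1)))
    b$peaks$intensity <- b$peaks$intensity / sqrt(sum(b$peaks$intensity^2))
    got <- modified_cosine(a, b, params)
    oracle <- oracle_modified_cosine(a$peaks, b$peaks, a$precursor_mz,
                                     b$precursor_mz, params$fragment_tol)
    expect_lte(got$cosine, oracle$cosine + 1e-12)  # greedy never beats optimal
    expect_equal(got$cosine, oracle$cosine, tolerance = 1e-9,
                 info = paste("instance", rep))
    expect_gte(got$cosine, 0)
    expect_lte(got$cosine, 1 + 1e-12)
  }
})

test_that("zero precursor delta reduces modified cosine to the plain cosine", {
  set.seed(18)
  a <- random_processed_spectrum(7)
  b <- random_processed_spectrum(7)
  b$precursor_mz <- a$precursor_mz  # delta 0: only direct matches possible
  got <- modified_cosine(a, b)
  plain <- oracle_modified_cosine(a$peaks, b$peaks, 1, 1, 0.5)  # equal precursors
  expect_equal(got$cosine, plain$cosine, tolerance = 1e-9)
})

test_that("network keeps thresholded edges and drops singleton components", {
  pk <- tibble::tibble(mz = c(150, 250, 350, 450), intensity = c(100, 200, 300, 400))
  sp <- spectra_table(c("a", "b", "lone"), c(900, 900, 555),
                      list(pk, pk, tibble::tibble(mz = c(111, 222),
                                                  intensity = c(500, 500))))
  net <- build_network(sp)
  expect_equal(sort(net$nodes$spectrum_id), c("a", "b"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$cosine, 1, tolerance = 1e-9)

  # edge set invariant to input order
  net2 <- build_network(sp[c(3, 1, 2), ])
  expect_equal(dplyr::arrange(net$edges, node_a),
               dplyr::arrange(net2$edges, node_a))
})

test_that("isomer nodes collapse to the highest-intensity representative", {
  pk1 <- tibble::tibble(mz = c(150, 250, 350), intensity = c(100, 200, 300))
  pk2 <- tibble::tibble(mz = c(150, 250, 350), intensity = c(1000, 2000, 3000))
  sp <- spectra_table(c("iso_lo", "iso_hi", "other"), c(900, 900.005, 738),
                      list(pk1, pk2, pk1))
  net <- build_network(sp, network_params(min_cosine = 0.5))
  expect_equal(nrow(net$nodes), 3L)
  dd <- dedup_isomers(net)
  expect_false("iso_lo" %in% dd$nodes$spectrum_id)
  expect_true("iso_hi" %in% dd$nodes$spectrum_id)

  # all-distinct precursors: untouched
  sp2 <- spectra_table(c("a", "b"), c(900, 738), list(pk1, pk1))
  net2 <- build_network(sp2, network_params(min_cosine = 0.5))
  expect_equal(dedup_isomers(net2)$nodes$spectrum_id, net2$nodes$spectrum_id)
})

test_that("precursor deltas annotate with the diagnostic neutral losses", {
  pk <- tibble::tibble(mz = c(150, 250, 350, 450), intensity = rep(500, 4))
  ions <- c(959.49, 797.43, 826.437, 855.464, 959.49 - 0.001)
  sp <- spectra_table(sprintf("i%.3f", ions), ions,
                      list(pk, pk, pk, pk, pk))
  net <- build_network(sp, network_params(min_cosine = 0.5))
  net <- annotate_losses(net)
  e <- net$edges
  hex <- e[(e$node_a == "i959.490" & e$node_b == "i797.430") |
             (e$node_b == "i959.490" & e$node_a == "i797.430"), ]
  expect_equal(hex$loss_annotation, "hexosyl")
  expect_equal(hex$nominal_loss, 162L)
  nma <- e[abs(abs(e$precursor_delta) - 133.053) < 0.01, ]
  expect_true(all(nma$loss_annotation == "n_methylanthraniloyl"))
  bz <- e[abs(abs(e$precursor_delta) - 104.026) < 0.01, ]
  expect_true(all(bz$loss_annotation == "benzoyl"))
  iso <- e[abs(e$precursor_delta) < 0.01, ]
  expect_true(all(iso$loss_annotation == "none"))

  expect_error(annotate_losses(net, library = c(a = 100, b = 100.05)),
               "ambiguous")
})

test_that("MGF files round-trip spectra", {
  set.seed(27)
  sp <- simulate_spectra(sim_config(seed = 27))
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_equal(back$spectrum_id, sp$spectrum_id)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-6)
  expect_equal(back$polarity, sp$polarity)
  for (i in seq_len(nrow(sp))) {
    expect_equal(back$peaks[[i]]$mz, sp$peaks[[i]]$mz, tolerance = 1e-6)
    expect_equal(back$peaks[[i]]$intensity, sp$peaks[[i]]$intensity,
                 tolerance = 1e-4)
  }
})

test_that("graphml export writes a parseable graph", {
  pk <- tibble::tibble(mz = c(150, 250, 350), intensity = rep(500, 3))
  sp <- spectra_table(c("a", "b"), c(900, 737.947), list(pk, pk))
  net <- annotate_losses(build_network(sp, network_params(min_cosine = 0.5)))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
})
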