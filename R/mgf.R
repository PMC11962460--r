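# Mascot Generic Format I/O. Deliberately minimal: TITLE, PEPMASS and
# CHARGE headers plus the peak list are all the networking stage needs.

#' Write spectra to an MGF file
#'
#' @param spectra A [spectra_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    charge <- if (identical(spectra$polarity[i], "negative")) "1-" else "1+"
    p <- spectra$peaks[[i]]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", spectra$spectrum_id[i]),
      sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]),
      paste0("CHARGE=", charge),
      sprintf("%.6f %.4f", p$mz, p$intensity),
      "END IONS",
      ""
    ), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path Path to an MGF file with `BEGIN IONS`/`END IONS` blocks,
#'   `PEPMASS`, optional `TITLE` and `CHARGE` headers.
#' @return A [spectra_table()].
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF: ", path)
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced BEGIN/END IONS")
  specs <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1L):(e - 1L)]
    kv <- grepl("^[A-Z]+=", block)
    headers <- block[kv]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), headers, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
    }
    title <- get("TITLE")
    pepmass <- as.numeric(strsplit(get("PEPMASS"), "[ \t]")[[1L]][1L])
    charge <- get("CHARGE")
    polarity <- if (!is.na(charge) && grepl("-", charge)) "negative" else "positive"
    pk <- block[!kv & nzchar(trimws(block))]
    peaks <- if (length(pk)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), as.numeric))
      tibble::tibble(mz = mat[, 1L], intensity = mat[, 2L])
    } else {
      tibble::tibble(mz = numeric(), intensity = numeric())
    }
    list(title = title, pepmass = pepmass, polarity = polarity, peaks = peaks)
  })
  ids <- vapply(specs, `[[`, character(1), "title")
  ids[is.na(ids)] <- paste0("spectrum_", which(is.na(ids)))
  spectra_table(
    spectrum_id = ids,
    precursor_mz = vapply(specs, `[[`, numeric(1), "pepmass"),
    peaks = lapply(specs, `[[`, "peaks"),
    polarity = vapply(specs, `[[`, character(1), "polarity")
  )
}
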