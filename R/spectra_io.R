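# Reading and writing tandem mass spectra.
#
# The canonical dialect is MGF (BEGIN IONS / TITLE / PEPMASS / CHARGE "2+" /
# peak lines / END IONS). MS2 is supported for reading; mzML reading
# delegates to the mzR parser when that package is available.

#' Construct a tandem mass spectrum
#'
#' @param scan_id Text identifier for the scan.
#' @param precursor_mz Precursor m/z in Thomson (> proton mass).
#' @param precursor_charge Positive integer charge state.
#' @param mz Numeric vector of fragment peak m/z values (> 0).
#' @param intensity Numeric vector of peak intensities (>= 0).
#' @return An object of class `"spectrum"`: a list with fields `scan_id`,
#'   `precursor_mz`, `precursor_charge` and a `peaks` data frame sorted
#'   ascending by m/z. Exact duplicate m/z values are collapsed keeping the
#'   maximum intensity.
#' @export
spectrum <- function(scan_id, precursor_mz, precursor_charge, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(precursor_charge) != 1L || precursor_charge < 1L)
    stop("precursor_charge must be a single integer >= 1")
  if (precursor_mz <= 0) stop("precursor_mz must be positive")
  if (length(mz)) {
    if (any(mz <= 0)) stop("peak m/z values must be positive")
    if (any(intensity < 0)) stop("peak intensities must be non-negative")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- unname(tapply(intensity, match(mz, unique(mz)), max))
      mz <- unique(mz)
    }
  }
  structure(list(
    scan_id = as.character(scan_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    peaks = data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s: precursor %.4f Th, charge %d+, %d peaks>\n",
              x$scan_id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read tandem mass spectra from a file
#'
#' Reads spectra in file order. MGF blocks without a CHARGE line are assigned
#' charge 2 (a common engine convention) and a message is emitted.
#'
#' @param path Path to the spectrum file.
#' @param format One of `"mgf"`, `"ms2"`, `"mzml"`. Defaults to the file
#'   extension.
#' @return A list of [spectrum()] objects.
#' @export
read_spectra <- function(path, format = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  switch(format,
    mgf  = read_mgf(path),
    ms2  = read_ms2(path),
    mzml = read_mzml(path),
    stop("unknown spectrum format: '", format, "' (expected mgf, ms2 or mzml)")
  )
}

read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS / END IONS in ", path)
  out <- vector("list", length(begins))
  missing_charge <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "#")]
    is_header <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_header]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    scan_id <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("scan_%d", k)
    if (!"PEPMASS" %in% keys)
      stop("malformed MGF record '", scan_id, "': missing PEPMASS")
    pepmass <- suppressWarnings(
      as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1]))
    if (is.na(pepmass))
      stop("malformed MGF record '", scan_id, "': unparsable PEPMASS")
    if ("CHARGE" %in% keys) {
      ch <- vals[match("CHARGE", keys)]
      charge <- suppressWarnings(as.integer(sub("^([0-9]+)\\+?.*$", "\\1", ch)))
      if (is.na(charge))
        stop("malformed MGF record '", scan_id, "': unparsable CHARGE '", ch, "'")
    } else {
      charge <- 2L
      missing_charge <- missing_charge + 1L
    }
    peak_lines <- block[!is_header]
    if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
      it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
      if (anyNA(mz) || anyNA(it))
        stop("malformed MGF record '", scan_id, "': unparsable peak line")
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    out[[k]] <- spectrum(scan_id, pepmass, charge, mz, it)
  }
  if (missing_charge > 0L)
    message(missing_charge, " MGF block(s) lacked CHARGE; assigned charge 2")
  out
}

read_ms2 <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "H")]
  starts <- which(startsWith(lines, "S"))
  if (!length(starts)) return(list())
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    s <- strsplit(block[1L], "[ \t]+")[[1]]
    scan_id <- s[2]
    pre_mz <- as.numeric(s[length(s)])
    zline <- block[startsWith(block, "Z")]
    charge <- if (length(zline)) as.integer(strsplit(zline[1L], "[ \t]+")[[1]][2]) else 2L
    peak_lines <- block[!grepl("^[SZIDE]", block)]
    if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "[ \t]+")
      mz <- as.numeric(vapply(fields, `[`, "", 1L))
      it <- as.numeric(vapply(fields, `[`, "", 2L))
      if (anyNA(mz) || anyNA(it))
        stop("malformed MS2 record '", scan_id, "': unparsable peak line")
    } else {
      mz <- numeric(0); it <- numeric(0)
    }
    out[[k]] <- spectrum(scan_id, pre_mz, charge, mz, it)
  }
  out
}

read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- NULL
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  h <- h[h$msLevel == 2L, , drop = FALSE]
  lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(f, h$seqNum[i])
    charge <- h$precursorCharge[i]
    if (is.na(charge) || charge < 1L) charge <- 2L
    spectrum(as.character(h$seqNum[i]), h$precursorMZ[i], charge,
             pk[, 1], pk[, 2])
  })
}

#' Write spectra to an MGF file
#'
#' Emits standard MGF blocks readable by [read_spectra()]; m/z and intensity
#' are written with six decimal places.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    peak_lines <- if (nrow(s$peaks))
      sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity) else character(0)
    paste(c("BEGIN IONS",
            paste0("TITLE=", s$scan_id),
            sprintf("PEPMASS=%.6f", s$precursor_mz),
            sprintf("CHARGE=%d+", s$precursor_charge),
            peak_lines,
            "END IONS"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}
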