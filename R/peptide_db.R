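# Protein database handling: FASTA input, in-silico tryptic digestion,
# variable-modification enumeration, and a neutral-mass-sorted peptide index
# supporting narrow through open precursor windows.

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `accession` (first whitespace-delimited
#'   token of the header) and `sequence` (upper-cased, whitespace stripped).
#'   An empty file yields a zero-row data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L)
    return(data.frame(accession = character(0), sequence = character(0)))
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(aa)))
  if (any(!nzchar(seqs)))
    stop("FASTA record with empty sequence: ",
         names(aa)[which(!nzchar(seqs))[1L]])
  data.frame(
    accession = vapply(strsplit(names(aa), "[ \t]+"), `[`, "", 1L),
    sequence = unname(seqs)
  )
}

#' Write proteins to a FASTA file
#'
#' @param proteins Data frame with `accession` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  writeLines(paste0(">", proteins$accession, "\n", proteins$sequence), path)
  invisible(path)
}

#' Digestion parameters
#'
#' @param enzyme Cleavage rule; only `"trypsin"` (after K or R, not before P)
#'   is built in.
#' @param max_missed_cleavages Maximum internal cleavage sites left uncut.
#' @param ntt Required number of enzymatic termini: 2 (fully enzymatic) or 1
#'   (semi-enzymatic forms also emitted). Protein termini count as enzymatic.
#' @param min_length,max_length Peptide length bounds in residues.
#' @return An object of class `"digest_params"`.
#' @export
digest_params <- function(enzyme = "trypsin", max_missed_cleavages = 2L,
                          ntt = 2L, min_length = 6L, max_length = 50L) {
  if (!identical(enzyme, "trypsin")) stop("unsupported enzyme: ", enzyme)
  if (min_length < 1L || max_length < min_length)
    stop("need 1 <= min_length <= max_length")
  if (!ntt %in% c(1L, 2L)) stop("ntt must be 1 or 2")
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 ntt = as.integer(ntt),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_params")
}

# Tryptic cleavage sites of a sequence: i means a cut between residues i and
# i+1 (1-based), i.e. after a K/R not followed by P.
cleavage_sites <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  i[chars[i] %in% c("K", "R") & chars[i + 1L] != "P"]
}

#' In-silico enzymatic digestion of one protein
#'
#' For `ntt = 2` returns every substring bounded by cleavage sites (or the
#' protein termini) spanning at most `max_missed_cleavages` internal sites;
#' for `ntt = 1` additionally all semi-enzymatic forms with exactly one
#' enzymatic terminus. Duplicate peptide strings within the protein are
#' emitted once (keeping the most enzymatic form with the fewest missed
#' cleavages).
#'
#' @param sequence Protein residue string.
#' @param params A [digest_params()].
#' @return Data frame with columns `peptide`, `missed_cleavages`,
#'   `ntt_of_form`.
#' @export
digest <- function(sequence, params = digest_params()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence)
  bounds <- c(0L, sites, n)
  mc <- params$max_missed_cleavages
  pep <- character(0); mcs <- integer(0); ntts <- integer(0)
  nb <- length(bounds)
  for (a in seq_len(nb - 1L)) {
    for (b in (a + 1L):min(nb, a + 1L + mc)) {
      len <- bounds[b] - bounds[a]
      if (len < params$min_length) next
      if (len > params$max_length) break
      pep <- c(pep, substr(sequence, bounds[a] + 1L, bounds[b]))
      mcs <- c(mcs, b - a - 1L)
      ntts <- c(ntts, 2L)
    }
  }
  if (params$ntt == 1L) {
    is_boundary <- logical(n + 1L)
    is_boundary[bounds + 1L] <- TRUE
    site_cum <- cumsum(tabulate(sites, nbins = n))  # sites <= position
    n_sites_within <- function(s, e) {
      # cleavage sites strictly inside substring (s, e], i.e. in (s, e)
      hi <- if (e >= 2L) site_cum[e - 1L] else 0L
      lo <- if (s >= 1L) site_cum[s] else 0L
      hi - lo
    }
    for (s in 0:(n - 1L)) {
      for (e in (s + 1L):n) {
        len <- e - s
        if (len < params$min_length) next
        if (len > params$max_length) break
        term <- is_boundary[s + 1L] + is_boundary[e + 1L]
        if (term != 1L) next
        if (n_sites_within(s, e) > mc) next
        pep <- c(pep, substr(sequence, s + 1L, e))
        mcs <- c(mcs, n_sites_within(s, e))
        ntts <- c(ntts, 1L)
      }
    }
  }
  if (!length(pep))
    return(data.frame(peptide = character(0), missed_cleavages = integer(0),
                      ntt_of_form = integer(0)))
  o <- order(pep, -ntts, mcs)
  pep <- pep[o]; mcs <- mcs[o]; ntts <- ntts[o]
  keep <- !duplicated(pep)
  data.frame(peptide = pep[keep], missed_cleavages = mcs[keep],
             ntt_of_form = ntts[keep], row.names = NULL)
}

#' Modification specification
#'
#' Variable mods are given in the engine-family string grammar
#' `"<max><residues>+<delta>"`, comma-separated, e.g.
#' `"2M+15.994915,2NQ+0.984016,1STY+79.966331"`; static mods omit the
#' count, e.g. `"C+57.021464"`.
#'
#' @param variable Variable-modification spec string (may be `""`).
#' @param static Static-modification spec string (may be `""`).
#' @return An object of class `"mod_spec"`: list with `static` (named
#'   residue -> delta vector) and `variable` (list of
#'   `list(residues, delta, max_occ)`).
#' @export
mod_spec <- function(variable = "", static = "") {
  parse_items <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    if (!nzchar(s)) return(list())
    items <- strsplit(s, ",", fixed = TRUE)[[1]]
    lapply(items, function(it) {
      m <- regmatches(it, regexec("^([0-9]*)([A-Za-z]+)([+-][0-9.]+)$", it))[[1]]
      if (length(m) != 4L) stop("unparsable mod spec item: '", it, "'")
      list(max_occ = if (nzchar(m[2])) as.integer(m[2]) else NA_integer_,
           residues = strsplit(toupper(m[3]), "")[[1]],
           delta = as.numeric(m[4]))
    })
  }
  var_items <- parse_items(variable)
  if (any(vapply(var_items, function(x) is.na(x$max_occ), logical(1))))
    stop("variable mod items need a max-occurrence count prefix")
  static_items <- parse_items(static)
  static_map <- numeric(0)
  for (it in static_items)
    for (r in it$residues) {
      static_map[r] <- (if (r %in% names(static_map)) static_map[r] else 0) +
        it$delta
    }
  structure(list(
    static = static_map,
    variable = lapply(var_items, function(x)
      list(residues = x$residues, delta = x$delta, max_occ = x$max_occ))
  ), class = "mod_spec")
}

# Canonical text form of a modification set, used for deduplication and for
# the results table: "pos:delta" (1-based), semicolon-joined, sorted by pos.
serialize_mods <- function(mod_pos, mod_delta) {
  if (!length(mod_pos)) return("")
  o <- order(mod_pos)
  paste(sprintf("%d:%.6f", mod_pos[o], mod_delta[o]), collapse = ";")
}

#' Enumerate modified forms of a peptide
#'
#' Static mods are applied to every matching residue unconditionally.
#' Variable mods are applied in all position combinations, with per-mod
#' occurrence counts from 0 to `max_occ` and at most one variable mod per
#' position; the unmodified (static-only) form is always included.
#'
#' @param peptide Peptide residue string.
#' @param mods A [mod_spec()].
#' @return List of forms, each `list(sequence, mod_pos, mod_delta,
#'   neutral_mass)` with positions 1-based.
#' @export
enumerate_modified_forms <- function(peptide, mods = mod_spec()) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  np <- length(chars)
  static_pos <- which(chars %in% names(mods$static))
  static_delta <- unname(mods$static[chars[static_pos]])
  # per-variable-mod candidate positions
  var_sets <- lapply(mods$variable, function(v) which(chars %in% v$residues))
  combos <- list(list(pos = integer(0), delta = numeric(0)))
  for (k in seq_along(mods$variable)) {
    v <- mods$variable[[k]]
    cand <- var_sets[[k]]
    new_combos <- list()
    for (cb in combos) {
      avail <- setdiff(cand, cb$pos)
      for (j in 0:min(v$max_occ, length(avail))) {
        sel <- if (j == 0L) list(integer(0)) else
          lapply(utils::combn(seq_along(avail), j, simplify = FALSE),
                 function(ii) avail[ii])
        for (s in sel) {
          new_combos[[length(new_combos) + 1L]] <-
            list(pos = c(cb$pos, s), delta = c(cb$delta, rep(v$delta, j)))
        }
      }
    }
    combos <- new_combos
  }
  lapply(combos, function(cb) {
    pos <- c(static_pos, cb$pos)
    delta <- c(static_delta, cb$delta)
    if (length(pos)) {
      # merge static + variable deltas landing on one residue
      agg <- tapply(delta, pos, sum)
      pos <- as.integer(names(agg))
      delta <- unname(agg)
      o <- order(pos)
      pos <- pos[o]; delta <- delta[o]
    }
    list(sequence = peptide, mod_pos = as.integer(pos), mod_delta = delta,
         neutral_mass = peptide_mass(peptide, as.integer(pos), delta))
  })
}

#' Build a mass-sorted peptide index from a proteome
#'
#' Digests every protein, enumerates modified forms, deduplicates globally
#' by (sequence, modification set) merging parent accessions, and sorts by
#' neutral mass (ties broken lexicographically by sequence then serialized
#' mods, making candidate lists deterministic). Peptides containing
#' ambiguous residues (B, J, O, U, X, Z) are skipped with one warning.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param params A [digest_params()].
#' @param mods A [mod_spec()].
#' @return A `"peptide_index"`: data frame with columns `sequence`, `mods`
#'   (serialized), `neutral_mass`, `ntt_of_form`, `missed_cleavages`, and
#'   list columns `mod_pos`, `mod_delta`, `proteins`.
#' @export
build_index <- function(proteins, params = digest_params(),
                        mods = mod_spec()) {
  pep_map <- new.env(parent = emptyenv())
  n_skipped <- 0L
  for (i in seq_len(nrow(proteins))) {
    dg <- digest(proteins$sequence[i], params)
    for (j in seq_len(nrow(dg))) {
      p <- dg$peptide[j]
      if (grepl(paste0("[", paste(AMBIGUOUS_RESIDUES, collapse = ""), "]"), p)) {
        n_skipped <- n_skipped + 1L
        next
      }
      e <- get0(p, envir = pep_map)
      if (is.null(e)) {
        assign(p, list(proteins = proteins$accession[i],
                       mc = dg$missed_cleavages[j], ntt = dg$ntt_of_form[j]),
               envir = pep_map)
      } else {
        e$proteins <- union(e$proteins, proteins$accession[i])
        e$ntt <- max(e$ntt, dg$ntt_of_form[j])
        e$mc <- min(e$mc, dg$missed_cleavages[j])
        assign(p, e, envir = pep_map)
      }
    }
  }
  if (n_skipped > 0L)
    warning(n_skipped, " peptide(s) with ambiguous residues skipped")
  peptides <- ls(pep_map)
  rows <- vector("list", 0L)
  for (p in peptides) {
    e <- get(p, envir = pep_map)
    forms <- enumerate_modified_forms(p, mods)
    for (f in forms) {
      rows[[length(rows) + 1L]] <- list(
        sequence = p, mods = serialize_mods(f$mod_pos, f$mod_delta),
        neutral_mass = f$neutral_mass, ntt_of_form = e$ntt,
        missed_cleavages = e$mc, mod_pos = f$mod_pos,
        mod_delta = f$mod_delta, proteins = sort(e$proteins))
    }
  }
  if (!length(rows)) {
    idx <- data.frame(sequence = character(0), mods = character(0),
                      neutral_mass = numeric(0), ntt_of_form = integer(0),
                      missed_cleavages = integer(0))
    idx$mod_pos <- list(); idx$mod_delta <- list(); idx$proteins <- list()
    class(idx) <- c("peptide_index", "data.frame")
    return(idx)
  }
  idx <- data.frame(
    sequence = vapply(rows, `[[`, "", "sequence"),
    mods = vapply(rows, `[[`, "", "mods"),
    neutral_mass = vapply(rows, `[[`, 0, "neutral_mass"),
    ntt_of_form = vapply(rows, `[[`, 0L, "ntt_of_form"),
    missed_cleavages = vapply(rows, `[[`, 0L, "missed_cleavages"),
    stringsAsFactors = FALSE
  )
  idx$mod_pos <- lapply(rows, `[[`, "mod_pos")
  idx$mod_delta <- lapply(rows, `[[`, "mod_delta")
  idx$proteins <- lapply(rows, `[[`, "proteins")
  o <- order(idx$neutral_mass, idx$sequence, idx$mods)
  idx <- idx[o, , drop = FALSE]
  rownames(idx) <- NULL
  class(idx) <- c("peptide_index", "data.frame")
  idx
}

#' Extract candidate peptides within a precursor window
#'
#' Binary search over the mass-sorted index for all entries whose neutral
#' mass lies within `tolerance` of the spectrum neutral mass (inclusive
#' bounds). In ppm mode the window half-width is
#' `spectrum_neutral_mass * tolerance * 1e-6`.
#'
#' @param index A `"peptide_index"` from [build_index()].
#' @param spectrum_neutral_mass Query neutral mass in Da.
#' @param tolerance Window half-width (> 0).
#' @param unit `"Da"` or `"ppm"`.
#' @return The matching rows of the index (possibly zero rows), in mass
#'   order.
#' @export
extract_candidates <- function(index, spectrum_neutral_mass, tolerance,
                               unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (tolerance <= 0) stop("tolerance must be positive")
  w <- if (unit == "ppm") spectrum_neutral_mass * tolerance * 1e-6 else tolerance
  m <- index$neutral_mass
  first <- findInterval(spectrum_neutral_mass - w, m, left.open = TRUE) + 1L
  last <- findInterval(spectrum_neutral_mass + w, m)
  if (last < first) return(index[integer(0), , drop = FALSE])
  index[first:last, , drop = FALSE]
}

#' Mean candidate counts across precursor tolerances
#'
#' For each tolerance, the mean over the given spectra of the number of
#' index entries within the window — the standard candidate-count profile
#' reported when widening a search from narrow to open tolerances.
#'
#' @param index A `"peptide_index"`.
#' @param spectra List of [spectrum()] objects.
#' @param tolerances Numeric vector of window half-widths in Da.
#' @return Data frame with columns `tolerance` and `mean_candidates`.
#' @export
candidate_report <- function(index, spectra, tolerances) {
  if (!length(spectra)) stop("candidate_report requires at least one spectrum")
  masses <- vapply(spectra, function(s)
    neutral_mass(s$precursor_mz, s$precursor_charge), 0)
  means <- vapply(tolerances, function(tol) {
    mean(vapply(masses, function(m)
      nrow(extract_candidates(index, m, tol)), 0))
  }, 0)
  data.frame(tolerance = tolerances, mean_candidates = means)
}
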