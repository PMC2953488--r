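# File I/O: per-window sample TSVs, PMF and monitor tables, landmark JSON,
# multi-frame XYZ/PDB trajectories. All tabular artifacts are TSV with
# '#'-prefixed header lines; units are fixed to Angstrom and kcal/mol.

provenance_lines <- function(extra = character()) {
  ver <- as.character(utils::packageVersion("ringpmf"))
  c(sprintf("# generated-by ringpmf %s", ver), extra)
}

# Tiny non-cryptographic string hash (djb2) for provenance stamping.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write an umbrella window to a sample TSV
#'
#' Format: comment header `# center=<A> k=<kcal/mol/A^2>`, then one sample
#' per line.
#'
#' @param window an [umbrella_window()].
#' @param path output file.
#' @param provenance optional extra `#` header lines.
#' @export
write_window_tsv <- function(window, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance,
               sprintf("# center=%.10g k=%.10g", window$center, window$k)), con)
  writeLines(sprintf("%.10g", window$samples), con)
  invisible(path)
}

#' Read an umbrella window from a sample TSV
#'
#' @param path file written by [write_window_tsv()] (or any file with a
#'   `# center=... k=...` header and one sample per line).
#' @return An [umbrella_window()].
#' @export
read_window_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*center=", lines, value = TRUE)
  if (length(hdr) == 0L)
    stop(errorCondition(paste0("no '# center=... k=...' header in ", path),
                        class = c("ringpmf_input_error", "ringpmf_error", "error")))
  center <- as.numeric(sub(".*center=([-0-9.eE+]+).*", "\\1", hdr[1L]))
  k <- as.numeric(sub(".*k=([-0-9.eE+]+).*", "\\1", hdr[1L]))
  dat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  umbrella_window(center, k, as.numeric(dat),
                  label = sub("\\.tsv$", "", basename(path)))
}

#' Write/read a window manifest
#'
#' The manifest is a JSON array of per-window sample file paths (relative
#' to the manifest's directory).
#'
#' @param files character vector of window file paths.
#' @param path manifest path.
#' @return `read_window_manifest` returns a list of [umbrella_window()].
#' @export
write_window_manifest <- function(files, path) {
  jsonlite::write_json(list(windows = basename(files)), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_window_manifest
#' @export
read_window_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  files <- file.path(dirname(path), m$windows)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L)
    stop(errorCondition(paste0("missing window file(s): ",
                               paste(missing, collapse = ", ")),
         class = c("ringpmf_input_error", "ringpmf_error", "error")))
  lapply(files, read_window_tsv)
}

#' Write a PMF profile as TSV
#'
#' Columns: bin_center (A), G (kcal/mol, NA on empty bins), count.
#'
#' @param profile a `pmf_profile`.
#' @param path output file.
#' @param provenance optional extra `#` header lines.
#' @export
write_pmf_tsv <- function(profile, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance,
               sprintf("# temperature_K=%g bin_width_A=%g",
                       profile$temperature, profile$bin_width),
               "# bin_center_A\tG_kcal_mol\tcount"), con)
  utils::write.table(
    data.frame(profile$bin_centers, profile$G, profile$counts),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PMF profile written by [write_pmf_tsv()]
#' @param path input file.
#' @return A `pmf_profile`.
#' @export
read_pmf_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*temperature_K=", lines, value = TRUE)
  temperature <- if (length(hdr)) as.numeric(sub(".*temperature_K=([-0-9.eE+]+).*", "\\1", hdr[1L])) else NA_real_
  bw <- if (length(hdr)) as.numeric(sub(".*bin_width_A=([-0-9.eE+]+).*", "\\1", hdr[1L])) else NA_real_
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                           col.names = c("bin_center", "G", "count"))
  new_pmf_profile(dat$bin_center, dat$G, dat$count, temperature, bw)
}

#' Write landmarks as JSON
#' @param lm a `pmf_landmarks` object.
#' @param path output file.
#' @param provenance optional named list merged into the JSON.
#' @export
write_landmarks_json <- function(lm, path, provenance = NULL) {
  out <- list(reactant_min = lm$reactant_min, ts_pos = lm$ts_pos,
              product_min = lm$product_min, barrier = lm$barrier,
              delta_g = lm$delta_g)
  if (!is.null(provenance)) out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a data.frame as a headered TSV
#' @param df data.frame.
#' @param path output file.
#' @param provenance optional extra `#` header lines.
#' @export
write_table_tsv <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance, paste0("# ", paste(names(df), collapse = "\t"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a headered TSV written by [write_table_tsv()]
#' @param path input file.
#' @return data.frame with the column names from the last `#` header line.
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  cols <- strsplit(sub("^#\\s*", "", hdr[length(hdr)]), "\t")[[1L]]
  utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                    col.names = cols, stringsAsFactors = FALSE)
}

#' Write a trajectory as multi-frame XYZ
#'
#' The atom-name column carries the frame's labels, so a round trip
#' preserves them.
#'
#' @param frames list of [md_frame()] objects.
#' @param path output file.
#' @export
write_xyz <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    writeLines(c(sprintf("%d", length(fr$labels)),
                 sprintf("frame %d time_ps %g", i - 1L, fr$time)), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", fr$labels,
                       fr$xyz[, 1L], fr$xyz[, 2L], fr$xyz[, 3L]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path XYZ file; the first column of each atom line is used as the
#'   atom label (element = label with trailing digits stripped).
#' @return List of [md_frame()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || i + 1L + nat > length(lines))
      stop(errorCondition(paste0("malformed XYZ file: ", path),
           class = c("ringpmf_input_error", "ringpmf_error", "error")))
    comment <- lines[i + 1L]
    tm <- if (grepl("time_ps", comment))
      as.numeric(sub(".*time_ps\\s+([-0-9.eE+]+).*", "\\1", comment)) else NA_real_
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    labels <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- md_frame(labels, xyz, time = tm)
    i <- i + 2L + nat
  }
  if (length(frames) == 0L)
    stop(errorCondition(paste0("no frames in XYZ file: ", path),
         class = c("ringpmf_input_error", "ringpmf_error", "error")))
  frames
}

#' Read a (multi-model) PDB file as a list of frames
#'
#' Uses bio3d's PDB reader; only atom names and coordinates are kept
#' (occupancy and B-factors are ignored). Atom labels are the PDB atom
#' names, de-duplicated with a numeric suffix where repeated.
#'
#' @param path PDB file, optionally with multiple MODEL records.
#' @return List of [md_frame()] objects.
#' @export
read_pdb_frames <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  labels <- pdb$atom$elety
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  nfr <- dim(pdb$xyz)[1L]
  lapply(seq_len(nfr), function(i) {
    m <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
    md_frame(labels, m, time = NA_real_)
  })
}
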