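#' Load a run configuration
#'
#' Reads a YAML or JSON configuration with blocks `system`, `rates`,
#' `ffs`, `fit`, `synth` and `global`. Unknown top-level keys and unknown
#' keys inside the `system` block are rejected by name; defaults (4-nt
#' toehold, 20-bp domain, 25 C) are applied to the `system` block.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a validated list of class `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || length(raw) == 0) {
    stop("empty config; at least a 'system' block is required ",
         "(known blocks: system, rates, ffs, fit, synth, global)",
         call. = FALSE)
  }
  known_blocks <- c("system", "rates", "ffs", "fit", "synth", "global")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown) > 0) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         "; known blocks are ", paste(known_blocks, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$system)) {
    stop("missing required block 'system'", call. = FALSE)
  }
  sys_known <- c("toehold_length", "domain_length", "mismatch_position",
                 "mismatch_type", "target", "incumbent", "invader",
                 "temperature")
  sys_unknown <- setdiff(names(raw$system), sys_known)
  if (length(sys_unknown) > 0) {
    stop("unknown key(s) in system block: ",
         paste(sys_unknown, collapse = ", "), call. = FALSE)
  }
  defaults <- list(toehold_length = 4L, domain_length = 20L,
                   temperature = 25)
  for (key in names(defaults)) {
    if (is.null(raw$system[[key]])) raw$system[[key]] <- defaults[[key]]
  }
  num_keys <- c("toehold_length", "domain_length", "temperature")
  for (key in num_keys) {
    if (!is.numeric(raw$system[[key]])) {
      stop(sprintf("system key '%s' must be numeric, got %s", key,
                   class(raw$system[[key]])[1]), call. = FALSE)
    }
  }
  structure(raw, class = "run_config")
}

#' Write a run configuration
#'
#' @param config a `run_config` (or plain list)
#' @param path output path (`.yaml` or `.json`)
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

#' Read and write fluorescence traces as CSV
#'
#' Traces are stored with a `time_s` header column plus `signal` (or the
#' two-channel `cy3`, `cy5`). A `time_min` header is accepted and converted
#' to seconds on read. Malformed rows and non-monotonic time raise errors.
#'
#' @param path CSV path
#' @return a [tmsd_trace()]
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",")[[1]]
  time_col <- intersect(c("time_s", "time_min"), header)
  if (length(time_col) != 1) {
    stop("trace CSV must have a 'time_s' (or 'time_min') column",
         call. = FALSE)
  }
  body <- lines[-1]
  fields <- strsplit(body, ",")
  bad <- which(lengths(fields) != length(header))
  if (length(bad) > 0) {
    stop(sprintf("malformed trace row at line %d: expected %d fields",
                 bad[1] + 1, length(header)), call. = FALSE)
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE)
  nan_cells <- vapply(df, function(col) any(is.na(col) | is.nan(col)),
                      logical(1))
  if (any(nan_cells)) {
    stop("trace contains NaN/missing cells in column(s): ",
         paste(names(df)[nan_cells], collapse = ", "), call. = FALSE)
  }
  time_s <- if (time_col == "time_min") df$time_min * 60 else df$time_s
  if (any(diff(time_s) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  sig_cols <- setdiff(names(df), time_col)
  do.call(tmsd_trace, c(list(time_s = time_s), as.list(df[sig_cols])))
}

#' @rdname read_trace
#' @param trace a [tmsd_trace()]
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path
#' @return named character vector of sequences
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(seqs), names(seqs)))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no FASTA records in ", path, call. = FALSE)
  nm <- sub("^>\\s*", "", lines[idx])
  ends <- c(idx[-1] - 1, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    paste(lines[(idx[i] + 1):ends[i]], collapse = "")
  }, "")
  stats::setNames(toupper(gsub("\\s", "", seqs)), nm)
}

#' Export a free-energy profile as CSV
#'
#' @param profile a [displacement_profile()]
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(tibble::tibble(n = profile$n, G_kBT = profile$G_kBT),
                   path)
  invisible(path)
}

#' Export a conditional-probability decomposition as CSV
#'
#' @param decomposition a [conditional_probabilities()] result
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_decomposition <- function(decomposition, path) {
  readr::write_csv(as.data.frame(decomposition), path)
  invisible(path)
}
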