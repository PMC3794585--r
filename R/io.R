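## Tab-separated time-course dialect.
##
## Columns: generation, selection_origin (FOA|URA), replicate, frac_foa_r,
## optionally frac_ura and the raw plate counts n_nonselective/n_ura/n_foa.
## '#'-prefixed lines are metadata; a header row is required; fraction
## columns accept "%"-suffixed values, which are divided by 100 on read.

#' Write time courses as a tab-separated table
#'
#' @param courses A [time_course()] or list of them.
#' @param path Output file path.
#' @param metadata Optional character vector of extra metadata lines (written
#'   with a `# ` prefix).
#' @param timestamp Include a creation-time metadata line (default `FALSE` so
#'   identical inputs give byte-identical files).
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(courses, path, metadata = NULL,
                             timestamp = FALSE) {
  if (inherits(courses, "time_course")) courses <- list(courses)
  dat <- do.call(rbind, lapply(courses, function(tc) {
    p <- tc$points
    d <- data.frame(generation = p$generation,
                    selection_origin = tc$selection_origin,
                    replicate = tc$replicate,
                    frac_foa_r = p$frac_foa_r)
    d$frac_ura <- if ("frac_ura" %in% names(p)) p$frac_ura else NA_real_
    if ("n_nonselective" %in% names(p)) {
      d$n_nonselective <- p$n_nonselective
      d$n_ura <- p$n_ura
      d$n_foa <- p$n_foa
    }
    d
  }))
  has_counts <- "n_nonselective" %in% names(dat)
  header <- c("generation", "selection_origin", "replicate", "frac_foa_r",
              "frac_ura", if (has_counts) c("n_nonselective", "n_ura", "n_foa"))
  fmt_frac <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  rows <- paste(sprintf("%.6f", dat$generation), dat$selection_origin,
                dat$replicate, fmt_frac(dat$frac_foa_r),
                fmt_frac(dat$frac_ura), sep = "\t")
  if (has_counts) {
    rows <- paste(rows, dat$n_nonselective, dat$n_ura, dat$n_foa, sep = "\t")
  }
  lines <- c("# pevconv time course",
             if (timestamp) sprintf("# created: %s", format(Sys.time())),
             if (!is.null(metadata)) paste("#", metadata),
             paste(header, collapse = "\t"),
             rows)
  writeLines(lines, path)
  invisible(path)
}

# Parse one numeric column with percent support, reporting the source line
# number on failure.
parse_column <- function(x, what, line_nos) {
  pct <- grepl("%$", x)
  out <- suppressWarnings(as.numeric(sub("%$", "", x)))
  out[x == "NA" | x == ""] <- NA_real_
  bad <- is.na(out) & !(x == "NA" | x == "")
  if (any(bad)) {
    stop(sprintf("malformed numeric in column '%s' at line %d: '%s'", what,
                 line_nos[which(bad)[1]], x[which(bad)[1]]), call. = FALSE)
  }
  out[pct] <- out[pct] / 100
  out
}

#' Read time courses from a tab-separated table
#'
#' Parses the dialect written by [write_timecourse()]: `#` lines are skipped,
#' a header row is required, missing optional columns are tolerated, and
#' percent-suffixed fractions are divided by 100. Rows are grouped into one
#' [time_course()] per (selection_origin, replicate) pair, preserving input
#' order within groups. Malformed numbers are reported with their line
#' number; fractions outside `[0, 1.2]` are rejected naming the value.
#'
#' @param path Input file path.
#' @return A list of [time_course()] objects (empty, with a warning, if the
#'   file holds no data rows).
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  line_nos <- which(keep)
  rows <- raw[keep]
  if (length(rows) == 0L) {
    warning("no header or data rows found; returning empty collection",
            call. = FALSE)
    return(list())
  }
  header <- strsplit(rows[1], "\t", fixed = TRUE)[[1]]
  required <- c("generation", "selection_origin", "frac_foa_r")
  if (!all(required %in% header)) {
    stop(sprintf("header must contain %s (got: %s)",
                 paste(required, collapse = ", "),
                 paste(header, collapse = ", ")), call. = FALSE)
  }
  if (length(rows) == 1L) {
    warning("file contains a header but no data rows; returning empty collection",
            call. = FALSE)
    return(list())
  }
  body <- rows[-1]
  body_lines <- line_nos[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(cells)
  if (any(nf != length(header))) {
    stop(sprintf("line %d has %d fields, expected %d",
                 body_lines[which(nf != length(header))[1]],
                 nf[nf != length(header)][1], length(header)), call. = FALSE)
  }
  m <- do.call(rbind, cells)
  colnames(m) <- header
  col <- function(nm) if (nm %in% header) m[, nm] else NULL

  gen <- parse_column(col("generation"), "generation", body_lines)
  origin <- col("selection_origin")
  if (!all(origin %in% c("FOA", "URA"))) {
    stop(sprintf("selection_origin must be FOA or URA (line %d: '%s')",
                 body_lines[which(!origin %in% c("FOA", "URA"))[1]],
                 origin[!origin %in% c("FOA", "URA")][1]), call. = FALSE)
  }
  repl <- if ("replicate" %in% header) {
    as.integer(parse_column(col("replicate"), "replicate", body_lines))
  } else rep(1L, nrow(m))
  foa <- parse_column(col("frac_foa_r"), "frac_foa_r", body_lines)
  if (any(foa < 0 | foa > 1.2, na.rm = TRUE)) {
    bad <- which(foa < 0 | foa > 1.2)[1]
    stop(sprintf("frac_foa_r value %g (line %d) outside [0, 1.2]", foa[bad],
                 body_lines[bad]), call. = FALSE)
  }
  ura <- if ("frac_ura" %in% header) {
    parse_column(col("frac_ura"), "frac_ura", body_lines)
  } else NULL
  counts <- if (all(c("n_nonselective", "n_ura", "n_foa") %in% header)) {
    data.frame(
      n_nonselective = parse_column(col("n_nonselective"), "n_nonselective",
                                    body_lines),
      n_ura = parse_column(col("n_ura"), "n_ura", body_lines),
      n_foa = parse_column(col("n_foa"), "n_foa", body_lines)
    )
  } else NULL

  groups <- split(seq_len(nrow(m)), list(origin, repl), drop = TRUE)
  # stable order: by origin then replicate as they first appear
  first <- vapply(groups, min, numeric(1))
  groups <- groups[order(first)]
  lapply(groups, function(idx) {
    time_course(origin[idx[1]], gen[idx], foa[idx],
                frac_ura = if (!is.null(ura) && !anyNA(ura[idx])) ura[idx],
                counts = if (!is.null(counts)) counts[idx, , drop = FALSE],
                replicate = repl[idx[1]])
  })
}

# Valid flat-config keys, shared by the config reader and the CLI.
config_keys <- function() {
  c("c_sa", "c_as", "y0", "generations", "tol", "seed", "n_clones",
    "founder_prob", "colonies", "events", "threshold", "fold", "fixture",
    "out", "format")
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Unknown keys are rejected with a listing of the valid keys. Values are
#' kept as strings; consumers parse them exactly as the matching command-line
#' flags.
#'
#' @param path Config file path.
#' @return Named list of string values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- readLines(path)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) return(list())
  parts <- regmatches(raw, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.*)$",
                                   raw))
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop(sprintf("cannot parse config line: '%s'", raw[which(bad)[1]]),
         call. = FALSE)
  }
  keys <- vapply(parts, `[[`, character(1), 2L)
  vals <- vapply(parts, `[[`, character(1), 3L)
  unknown <- setdiff(keys, config_keys())
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s; valid keys are: %s",
                 paste(unknown, collapse = ", "),
                 paste(config_keys(), collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.list(trimws(vals)), keys)
}
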