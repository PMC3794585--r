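#' Dual-selection time-course measurements
#'
#' A time course records plating measurements of the FOA-resistant fraction
#' (and optionally the URA+ fraction and raw colony counts) at known
#' generation numbers after release from selection. The initial selection
#' fixes the model's starting condition: prior growth on FOA plates selects
#' silenced cells (`y0 = 0`), prior growth on uracil dropout selects active
#' cells (`y0 = 1`).
#'
#' Counting noise in the plating ratio can push observed fractions slightly
#' above 1 (values such as 103-109% occur in real colony-count tables), so
#' observed fractions up to 1.2 are accepted; model comparisons clamp them to
#' `[0, 1]`.
#'
#' @param selection_origin `"FOA"` or `"URA"`.
#' @param generation Non-decreasing vector of generation numbers (real, >= 0).
#' @param frac_foa_r FOA-resistant fraction at each generation, in `[0, 1.2]`.
#'   Percent strings are accepted.
#' @param frac_ura Optional URA+ fraction, same length.
#' @param counts Optional data frame with columns `n_nonselective`, `n_ura`,
#'   `n_foa` (raw colony counts per plate).
#' @param replicate Integer replicate label (default 1).
#' @param y0 Initial active fraction; defaults to 0 for FOA origin and 1 for
#'   URA origin.
#' @return An object of class `time_course`: list with `selection_origin`,
#'   `replicate`, `y0`, and data frame `points`.
#' @examples
#' time_course("URA", c(0, 10, 20), c(0.05, 0.25, 0.30))
#' @export
time_course <- function(selection_origin = c("FOA", "URA"), generation,
                        frac_foa_r, frac_ura = NULL, counts = NULL,
                        replicate = 1L, y0 = NULL) {
  selection_origin <- match.arg(selection_origin)
  frac_foa_r <- parse_fraction(frac_foa_r, "frac_foa_r")
  if (any(generation < 0)) stop("generations must be >= 0", call. = FALSE)
  if (is.unsorted(generation)) {
    stop("generations must be non-decreasing within a replicate", call. = FALSE)
  }
  check_range(frac_foa_r, "frac_foa_r", 0, 1.2)
  stopifnot(length(frac_foa_r) == length(generation))
  pts <- data.frame(generation = as.numeric(generation),
                    frac_foa_r = frac_foa_r)
  if (!is.null(frac_ura)) {
    frac_ura <- parse_fraction(frac_ura, "frac_ura")
    check_range(frac_ura, "frac_ura", 0, 1.2)
    stopifnot(length(frac_ura) == length(generation))
    pts$frac_ura <- frac_ura
  }
  if (!is.null(counts)) {
    stopifnot(is.data.frame(counts), nrow(counts) == length(generation),
              all(c("n_nonselective", "n_ura", "n_foa") %in% names(counts)))
    pts <- cbind(pts, counts[c("n_nonselective", "n_ura", "n_foa")])
  }
  structure(list(
    selection_origin = selection_origin,
    replicate = as.integer(replicate),
    y0 = y0 %||% if (selection_origin == "FOA") 0 else 1,
    points = pts
  ), class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course: origin %s (y0 = %g), replicate %d, %d points over generations %g-%g\n",
              x$selection_origin, x$y0, x$replicate, nrow(x$points),
              min(x$points$generation), max(x$points$generation)))
  invisible(x)
}

# Flatten one course or a list of courses into (y0, generation, obs) with the
# observed FOA-resistant fraction clamped to [0, 1] for model comparison.
flatten_courses <- function(courses) {
  if (inherits(courses, "time_course")) courses <- list(courses)
  if (!is.list(courses) || length(courses) == 0L ||
      !all(vapply(courses, inherits, logical(1), "time_course"))) {
    stop("courses must be a time_course or a non-empty list of them",
         call. = FALSE)
  }
  do.call(rbind, lapply(courses, function(tc) {
    data.frame(y0 = tc$y0,
               origin = tc$selection_origin,
               generation = tc$points$generation,
               obs = pmin(pmax(tc$points$frac_foa_r, 0), 1))
  }))
}
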