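#' Spectra containers
#'
#' A `SpectraSet` holds a collection of absorbance spectra sharing one
#' wavenumber grid, together with per-spectrum metadata. It is the currency
#' passed between every stage of the pipeline. Internally it is a list with
#' three elements:
#'
#' * `grid` — strictly increasing, uniformly spaced wavenumbers (cm\eqn{^{-1}});
#' * `intensities` — an `n_spectra x n_points` numeric matrix of absorbances
#'   (a.u.), one row per spectrum, columns aligned with `grid`;
#' * `meta` — a `data.frame` with columns `spectrum_id`, `fish_id`, `day`
#'   (integer postmortem day) and `fibre_id`.
#'
#' A single `Spectrum` is a list with `wavenumbers`, `intensities` and a
#' `meta` list holding the same four fields.
#'
#' @param grid numeric vector of wavenumbers, strictly increasing and
#'   uniformly spaced (relative step deviation below `1e-9`).
#' @param intensities numeric matrix, one row per spectrum, `length(grid)`
#'   columns; all values finite.
#' @param meta data.frame with columns `spectrum_id`, `fish_id`, `day`,
#'   `fibre_id`; `spectrum_id` must be unique.
#' @return `spectra_set()` returns a validated `SpectraSet`.
#' @examples
#' grid <- seq(600, 620, by = 2)
#' m <- matrix(rnorm(22, 10), nrow = 2)
#' meta <- data.frame(spectrum_id = c("a", "b"), fish_id = "f1",
#'                    day = 0L, fibre_id = c("c1", "c2"))
#' s <- spectra_set(grid, m, meta)
#' n_spectra(s)
#' @export
spectra_set <- function(grid, intensities, meta) {
  grid <- as.numeric(grid)
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, nrow = nrow(meta), byrow = TRUE)
  storage.mode(intensities) <- "double"
  meta <- validate_meta(meta)
  if (length(grid) > 0) check_grid(grid)
  if (ncol(intensities) != length(grid))
    abort("intensities must have one column per grid point", "freshir_format_error")
  if (nrow(intensities) != nrow(meta))
    abort("intensities must have one row per metadata row", "freshir_format_error")
  if (nrow(intensities) > 0 && ncol(intensities) > 0 && !all(is.finite(intensities)))
    abort("intensities contain non-finite values", "freshir_validation_error")
  structure(list(grid = grid, intensities = intensities, meta = meta),
            class = "SpectraSet")
}

validate_meta <- function(meta) {
  req <- c("spectrum_id", "fish_id", "day", "fibre_id")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    abort(paste0("missing metadata column(s): ", paste(miss, collapse = ", ")),
          "freshir_format_error")
  meta <- as.data.frame(meta)[, req]
  day_num <- suppressWarnings(as.numeric(meta$day))
  if (anyNA(day_num) || any(day_num != round(day_num)) || any(day_num < 0))
    abort("day labels must be non-negative integers", "freshir_format_error")
  meta$day <- as.integer(round(day_num))
  meta$spectrum_id <- as.character(meta$spectrum_id)
  meta$fish_id <- as.character(meta$fish_id)
  meta$fibre_id <- as.character(meta$fibre_id)
  if (anyDuplicated(meta$spectrum_id))
    abort(paste0("duplicate spectrum_id: ",
                 paste(unique(meta$spectrum_id[duplicated(meta$spectrum_id)]),
                       collapse = ", ")), "freshir_format_error")
  rownames(meta) <- NULL
  meta
}

# strictly increasing + uniform step within 1e-9 relative tolerance
check_grid <- function(grid) {
  if (length(grid) < 2)
    abort("a wavenumber grid needs at least 2 points", "freshir_validation_error")
  d <- diff(grid)
  if (any(d <= 0))
    abort("wavenumbers must be strictly increasing", "freshir_validation_error")
  step <- stats::median(d)
  if (max(abs(d - step)) / step > 1e-9)
    abort("wavenumber grid is not uniformly spaced (relative step deviation > 1e-9)",
          "freshir_grid_error")
  invisible(grid)
}

#' @rdname spectra_set
#' @param set a `SpectraSet`.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' @export
print.SpectraSet <- function(x, ...) {
  cat(sprintf("<SpectraSet> %d spectra x %d points", n_spectra(x), length(x$grid)))
  if (length(x$grid))
    cat(sprintf(" [%g-%g cm-1, step %g]", min(x$grid), max(x$grid),
                stats::median(diff(x$grid))))
  cat("\n")
  if (n_spectra(x))
    cat("  days:", paste(sort(unique(x$meta$day)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.SpectraSet` <- function(x, i, ...) {
  spectra_set(x$grid, x$intensities[i, , drop = FALSE], x$meta[i, , drop = FALSE])
}

#' Extract one spectrum from a set
#'
#' @param set a `SpectraSet`.
#' @param i row index or `spectrum_id`.
#' @return a `Spectrum` (list with `wavenumbers`, `intensities`, `meta`).
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) {
    i <- match(i, set$meta$spectrum_id)
    if (is.na(i)) abort("unknown spectrum_id", "freshir_format_error")
  }
  structure(list(wavenumbers = set$grid,
                 intensities = set$intensities[i, ],
                 meta = as.list(set$meta[i, ])),
            class = "Spectrum")
}

#' Subset a SpectraSet by postmortem day
#'
#' @param set a `SpectraSet`.
#' @param days integer vector of day labels to keep.
#' @export
subset_days <- function(set, days) set[set$meta$day %in% days]

#' Read spectra from CSV
#'
#' Reads a `SpectraSet` from one of two tabular layouts:
#'
#' * `long_csv` (canonical interchange format): columns `spectrum_id`,
#'   `fish_id`, `day`, `fibre_id`, `wavenumber`, `intensity`; one row per
#'   (spectrum, wavenumber) pair.
#' * `wide_csv`: the four metadata columns followed by one column per
#'   wavenumber, named by its numeric value.
#'
#' Rows of each spectrum are sorted by wavenumber on load (instrument
#' exports sometimes come descending), all spectra are required to share an
#' identical grid, and the grid must be uniformly spaced.
#'
#' @param path path to a CSV file (UTF-8, "." decimal separator, header row).
#' @param format `"long_csv"` or `"wide_csv"`.
#' @return a validated `SpectraSet`.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("long_csv", "wide_csv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    abort(paste0("file not found: ", path), "freshir_io_error")
  dt <- suppressWarnings(
    data.table::fread(path, colClasses = list(character = "spectrum_id"),
                      data.table = FALSE, showProgress = FALSE))
  if (format == "long_csv") read_spectra_long(dt) else read_spectra_wide(dt)
}

read_spectra_long <- function(dt) {
  req <- c("spectrum_id", "fish_id", "day", "fibre_id", "wavenumber", "intensity")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          "freshir_format_error")
  if (nrow(dt) == 0) return(empty_set())
  for (col in c("wavenumber", "intensity")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    if (anyNA(v) & !anyNA(dt[[col]])) {
      bad <- which(is.na(v))[1]
      abort(sprintf("non-numeric %s at data row %d: '%s'", col, bad, dt[[col]][bad]),
            "freshir_parse_error")
    }
    if (anyNA(v))
      abort(sprintf("missing %s at data row %d", col, which(is.na(v))[1]),
            "freshir_parse_error")
    dt[[col]] <- v
  }
  ids <- unique(dt$spectrum_id)  # order of first appearance
  rows <- split(seq_len(nrow(dt)), factor(dt$spectrum_id, levels = ids))
  grid <- NULL
  mats <- vector("list", length(ids))
  meta <- vector("list", length(ids))
  bad_ids <- character()
  for (k in seq_along(ids)) {
    idx <- rows[[k]]
    o <- order(dt$wavenumber[idx])
    wn <- dt$wavenumber[idx][o]
    if (is.null(grid)) grid <- wn
    else if (!identical(grid, wn)) { bad_ids <- c(bad_ids, ids[k]); next }
    mats[[k]] <- dt$intensity[idx][o]
    meta[[k]] <- dt[idx[1], c("spectrum_id", "fish_id", "day", "fibre_id")]
  }
  if (length(bad_ids))
    abort(paste0("wavenumber grid mismatch for spectrum_id: ",
                 paste(bad_ids, collapse = ", ")), "freshir_grid_error")
  spectra_set(grid, do.call(rbind, mats), do.call(rbind, meta))
}

read_spectra_wide <- function(dt) {
  req <- c("spectrum_id", "fish_id", "day", "fibre_id")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
          "freshir_format_error")
  wn_cols <- setdiff(names(dt), req)
  if (nrow(dt) == 0 || length(wn_cols) == 0) return(empty_set())
  grid <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(grid))
    abort(paste0("non-numeric wavenumber column name: ",
                 paste(wn_cols[is.na(grid)], collapse = ", ")),
          "freshir_format_error")
  o <- order(grid)
  mat <- as.matrix(dt[, wn_cols[o], drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 1, as.numeric))))[1]
    abort(sprintf("non-numeric intensity in row %d", bad %||% 1L),
          "freshir_parse_error")
  }
  dimnames(mat) <- NULL
  spectra_set(grid[o], mat, dt[, req])
}

empty_set <- function() {
  spectra_set(numeric(0), matrix(numeric(0), nrow = 0, ncol = 0),
              data.frame(spectrum_id = character(), fish_id = character(),
                         day = integer(), fibre_id = character()))
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]; numeric values are written with enough
#' digits for a lossless round-trip at 15 significant digits.
#'
#' @param set a `SpectraSet`.
#' @param path output file path.
#' @param format `"long_csv"` or `"wide_csv"`.
#' @export
write_spectra <- function(set, path, format = c("long_csv", "wide_csv")) {
  format <- match.arg(format)
  if (!inherits(set, "SpectraSet"))
    abort("set must be a SpectraSet", "freshir_format_error")
  n <- n_spectra(set)
  p <- length(set$grid)
  if (format == "long_csv") {
    df <- data.frame(
      spectrum_id = rep(set$meta$spectrum_id, each = p),
      fish_id = rep(set$meta$fish_id, each = p),
      day = rep(set$meta$day, each = p),
      fibre_id = rep(set$meta$fibre_id, each = p),
      wavenumber = rep(set$grid, times = n),
      intensity = as.vector(t(set$intensities)))
  } else {
    df <- set$meta
    if (p > 0) {
      mat <- as.data.frame(set$intensities)
      names(mat) <- format(set$grid, digits = 15, trim = TRUE, scientific = FALSE)
      df <- cbind(df, mat)
    }
  }
  ok <- tryCatch({ data.table::fwrite(df, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    abort(paste0("cannot write ", path, ": ", conditionMessage(ok)),
          "freshir_io_error")
  invisible(path)
}
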