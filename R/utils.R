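# Internal helpers: classed conditions, well-coordinate handling, seeded RNG.

ds_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("dualscreen_", class), "dualscreen_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

ds_warn <- function(message, class) {
  warning(structure(
    class = c(paste0("dualscreen_", class), "dualscreen_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse 384-well coordinates
#'
#' Accepts coordinates like `"A1"`, `"a01"` or `"P24"` (rows A--P, columns
#' 1--24, 1-based as printed on plate maps).
#'
#' @param well character vector of well labels.
#' @return data.frame with columns `well` (canonical label, no zero padding),
#'   `row` (1--16) and `col` (1--24).
#' @examples
#' parse_well(c("A1", "p24"))
#' @export
parse_well <- function(well) {
  well <- as.character(well)
  m <- regmatches(well, regexec("^([A-Pa-p])0?([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  row <- col <- rep(NA_integer_, length(well))
  if (any(!bad)) {
    row[!bad] <- match(toupper(vapply(m[!bad], `[`, "", 2L)), LETTERS[1:16])
    col[!bad] <- as.integer(vapply(m[!bad], `[`, "", 3L))
  }
  bad <- bad | is.na(row) | is.na(col) | col < 1L | col > 24L
  if (any(bad)) {
    ds_abort(sprintf(
      "unparseable 384-well coordinate(s): %s (rows A-P, columns 1-24)",
      paste(unique(well[bad]), collapse = ", ")
    ), "record_error")
  }
  data.frame(well = paste0(LETTERS[row], col), row = row, col = col,
             stringsAsFactors = FALSE)
}

well_name <- function(row, col) paste0(LETTERS[row], col)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multiplicative lognormal noise with unit mean and coefficient of variation
# `cv`; degenerates to exactly 1 when cv = 0 so noise-free runs are exact.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Stable hash of an R object (used for run-manifest config hashes).
config_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(x, control = c("exact", "showAttributes")), tf)
  unname(tools::md5sum(tf))
}

# U+2212 minus signs occur in some public exports; normalize before as.numeric.
ascii_minus <- function(x) gsub("−", "-", x)

as_num <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(as.numeric(ascii_minus(trimws(as.character(x)))))
}
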